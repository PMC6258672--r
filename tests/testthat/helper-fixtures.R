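# Session-memoised fixtures: generated once, shared across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) assign(name, maker(), envir = .fixtures)
  .fixtures[[name]]
}

# standard synthetic tissue (geometry only) used by many tests
fix_tissue <- function(seed = 1, n_cells = 200) {
  fixture(sprintf("tissue_%d_%d", seed, n_cells), function() {
    gen <- generate_equilibrium_network(synth_config(n_cells = n_cells, seed = seed))
    gen$network <- restrict_threefold(gen$network)
    gen
  })
}

# small tissue rendered with default noise, plus processed E-cadherin image
fix_rendered <- function() {
  fixture("rendered_small", function() {
    # near-hexagonal rendered tissue (low disorder)
    cfg <- synth_config(n_cells = 60, domain = c(300, 300), seed = 5,
                        jitter = 0.4)
    gen <- generate_equilibrium_network(cfg)
    dens <- assign_intensities(gen$network, gen$truth, cfg)
    imgs <- render_images(gen$network, dens, cfg, gen$truth)
    list(cfg = cfg, gen = gen, dens = dens, imgs = imgs)
  })
}

# the same small tissue rendered noise- and blur-free (identity render)
fix_identity_render <- function() {
  fixture("identity_render", function() {
    cfg <- synth_config(n_cells = 60, domain = c(300, 300), seed = 5,
                        psf_sigma = 0, z_blur = 0, gain = 0, read_noise = 0,
                        haze = 0)
    gen <- generate_equilibrium_network(cfg)
    dens <- assign_intensities(gen$network, gen$truth, cfg)
    imgs <- render_images(gen$network, dens, cfg, gen$truth)
    list(cfg = cfg, gen = gen, dens = dens, imgs = imgs)
  })
}

# hand-built four-cell configuration around one central junction:
# cells a = 1 (left), b = 2 (right), c = 3 (top, at vertex vL),
# d = 4 (bottom, at vertex v0); junction ids: 10 = central (a,b),
# 11 = (b,d) carries T1, 12 = (a,d) carries T2, 13 = (a,c) carries T3,
# 14 = (b,c) carries T4.
fix_quad_net <- function(swap_sides = FALSE) {
  vertices <- data.frame(
    id = 1:6,
    x = c(0, 0, 2, -2, -2, 2),
    y = c(0, 2, -1, -1, 3, 3))
  a <- if (swap_sides) 2L else 1L
  b <- if (swap_sides) 1L else 2L
  junctions <- data.frame(
    id = c(10L, 11L, 12L, 13L, 14L),
    v1 = c(1L, 1L, 1L, 2L, 2L),
    v2 = c(2L, 3L, 4L, 5L, 6L),
    cell_a = c(a, 2L, 1L, 1L, 2L),
    cell_b = c(b, 4L, 4L, 3L, 3L),
    length = c(2, sqrt(5), sqrt(5), sqrt(5), sqrt(5)),
    angle = c(90, chord_angle(2, -1), chord_angle(-2, -1),
              chord_angle(-2, 1), chord_angle(2, 1)),
    boundary = FALSE)
  cells <- data.frame(id = 1:4, cx = c(-1, 1, 0, 0), cy = c(1, 1, 3, -1),
                      boundary = FALSE)
  tissue_network(vertices, junctions, cells)
}

quad_tensions <- function(T1 = 3, T2 = 1, T3 = 2, T4 = 1, Tc = 1.5) {
  data.frame(junction_id = c(10L, 11L, 12L, 13L, 14L),
             tension = c(Tc, T1, T2, T3, T4))
}

# regular hexagonal tissue as a label image (axis-aligned brick-like
# honeycomb is awkward; instead reuse the generator at zero jitter)
fix_hex_tissue <- function() {
  fixture("hex_tissue", function() {
    gen <- generate_equilibrium_network(
      synth_config(n_cells = 64, domain = c(260, 260), seed = 2,
                   jitter = 0, relax = 0))
    gen$network <- restrict_threefold(gen$network)
    gen
  })
}

# 2 x 1 brick lattice label image: two rows of rectangular cells with
# offset vertical walls (every interior vertex is three-fold)
brick_labels <- function(W = 60, H = 40) {
  lab <- matrix(0L, W, H)
  top <- findInterval(seq_len(W), c(0, 20, 40)) # cells 1..3
  bot <- findInterval(seq_len(W), c(0, 10, 30, 50)) + 3L # cells 4..7
  for (x in seq_len(W)) {
    lab[x, 1:20] <- top[x]
    lab[x, 21:H] <- bot[x]
  }
  .skel <- getFromNamespace(".skeletonize_labels", "junctionforce")
  .skel(lab)
}
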