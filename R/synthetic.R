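#' Configuration for the synthetic tissue generator
#'
#' Bundles every knob of the synthetic test bed: geometry of the cell packing,
#' the statistical structure of the junctional channel densities (Myosin-II
#' tension-coupled and DV-enriched, E-cadherin AP-enriched with an
#' inverse-length density confound, Vinculin with a constitutive E-cadherin
#' term plus a load term), image rendering, and the overdamped ablation
#' simulator with optional E-cadherin turnover. All randomness flows from
#' `seed`.
#'
#' Polarity amplitudes are expressed directly as the expected ratio of
#' averaged line densities between the two extreme 15-degree angle bins
#' (the PCP amplitude), implemented as a linear ramp between 15 and 75
#' degrees so that the extreme bins sit exactly at the two plateau values.
#'
#' @param n_cells target number of cells.
#' @param domain image domain `c(width, height)` in pixels.
#' @param seed integer seed; mandatory for any stochastic output.
#' @param jitter geometric disorder in `[0, 1]`: 0 seeds an exact triangular
#'   lattice (perfect hexagonal tissue); positive values switch to an
#'   isotropic hard-disk point process whose exclusion radius shrinks as
#'   `(1 - 0.45 * jitter)` times the mean cell spacing.
#' @param relax number of Lloyd relaxation sweeps (centroidal smoothing).
#' @param min_junction_px minimum interior junction length (px); shorter
#'   Voronoi edges (near-cocircular seed quadruples) are annealed away by
#'   nudging the involved seeds, since real segmented snapshots only contain
#'   optically resolvable junctions. The default sits just above twice the
#'   tri-cellular vertex exclusion radius (3 px), below which a junction has
#'   an empty ROI and no separable vertices. 0 disables.
#' @param stretch anisotropy of the point process (>1 compresses x spacing,
#'   producing an excess of DV-oriented short junctions).
#' @param m0,e0 baseline Myosin-II / E-cadherin line densities (a.u.).
#' @param pcp_myo Myosin-II polarity amplitude (DV/AP ratio of extreme bins).
#' @param pcp_ecad E-cadherin polarity amplitude (AP/DV ratio).
#' @param alpha constitutive Vinculin recruitment per unit E-cadherin.
#' @param beta load-dependent Vinculin recruitment per unit relative tension
#'   and unit E-cadherin (dimensionless), so that the noiseless Vinc/E-cad
#'   ratio is `alpha + beta * T` independent of junction length.
#' @param confound strength of the 1/length density confound, as a fraction
#'   of `e0` at the mean junction length.
#' @param noise_myo multiplicative noise SD on Myosin-II.
#' @param noise_ecad,noise_vinc additive noise SD as a fraction of `e0`.
#' @param band_halfwidth half-width (px) of the painted junctional band.
#' @param psf_sigma in-focus point-spread-function SD (px); 0 disables blur.
#' @param z_blur extra blur SD per plane of defocus (px).
#' @param n_planes,focus_plane z-stack depth and index of the in-focus plane
#'   (z increases towards the basal side).
#' @param haze fraction of `e0` painted as smooth basal background haze.
#' @param gain photon gain for Poisson noise (0 disables), `read_noise`
#'   Gaussian read noise SD (a.u.).
#' @param medial_myo medial (apical cell-interior) Myosin-II area density as
#'   a fraction of `m0`.
#' @param gamma drag coefficient of the overdamped ablation relaxation
#'   (tension units x s / px). The default keeps the standard 2-s recoil
#'   read-out deep in the initial-recoil regime (endpoint displacement well
#'   under a pixel per tension unit), which is the regime in which recoil
#'   velocity reads out the released tension.
#' @param k_on,k_off0,shear_sens E-cadherin turnover: on-rate, basal off-rate
#'   and the factor by which shear stress scales the off-rate
#'   (`dE/dt = k_on - k_off0 (1 + shear_sens * tau) E`). This turnover model
#'   is synthetic: it encodes the hypothesis that shear enhances E-cadherin
#'   dissociation so that pipeline logic can be exercised against a known
#'   direction of effect.
#'
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_cells = 200, domain = c(640, 640), seed = 1,
                         jitter = 0.7, relax = 1, stretch = 1,
                         min_junction_px = 6,
                         m0 = 100, e0 = 120,
                         pcp_myo = 2.0, pcp_ecad = 1.5,
                         alpha = 0.3, beta = 0.15, confound = 0.6,
                         noise_myo = 0.15, noise_ecad = 0.10, noise_vinc = 0.10,
                         band_halfwidth = 3, psf_sigma = 0.7, z_blur = 1.2,
                         n_planes = 7, focus_plane = 3, haze = 0.05,
                         gain = 5, read_noise = 2, medial_myo = 0.4,
                         gamma = 20, k_on = 10, k_off0 = 0.1, shear_sens = 5) {
  if (is.null(seed) || !is.finite(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(cfg$n_cells >= 4, all(cfg$domain > 0),
            cfg$pcp_myo >= 0, cfg$pcp_ecad >= 0, cfg$gamma > 0)
  class(cfg) <- "synth_config"
  cfg
}

# polygon centroid (area-weighted); pts is closed or open ring
.poly_centroid <- function(x, y) {
  n <- length(x)
  xi <- c(x, x[1]); yi <- c(y, y[1])
  cr <- xi[1:n] * yi[2:(n + 1)] - xi[2:(n + 1)] * yi[1:n]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((xi[1:n] + xi[2:(n + 1)]) * cr) / (6 * a),
    sum((yi[1:n] + yi[2:(n + 1)]) * cr) / (6 * a))
}

#' Generate an exactly force-balanced synthetic tissue
#'
#' Samples a jittered (optionally anisotropic) point grid, relaxes it with a
#' few Lloyd sweeps, and takes the Voronoi diagram as the cell network. The
#' Delaunay triangulation of the same points is its perpendicular dual, so
#' assigning each junction a ground-truth tension equal to the length of its
#' dual Delaunay edge puts every interior three-fold vertex in exact force
#' balance (the three rotated Delaunay edges of the triangle close).
#'
#' @param config a [synth_config()].
#' @return list with `network` (a [tissue_network()]) and `truth`
#'   (list: `tensions` data.frame with `junction_id`, `tension` normalised to
#'   mean one over interior junctions, `points` the generating seeds,
#'   `config`).
#' @export
generate_equilibrium_network <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  W <- config$domain[1]; H <- config$domain[2]

  # jittered triangular lattice: hexagonal packing is the generic epithelial
  # geometry and keeps vertices far from four-fold degeneracy
  aspect <- config$stretch^2
  s <- sqrt(2 * W * H / (sqrt(3) * config$n_cells))
  sx <- s / sqrt(aspect); sy <- sx * sqrt(3) / 2 * aspect
  # pad the point process by a few cell rows beyond the image so that the
  # anisotropy radiating from the flat window walls (clipped Voronoi tiles,
  # Lloyd drift) has decayed before it reaches analysed cells
  pad <- 2.5 * s
  rw <- c(-pad, W + pad, -pad, H + pad)
  if (config$jitter == 0) {
    # exact triangular lattice: perfect hexagonal tissue
    ny <- max(2, floor((H + 2 * pad) / sy)); nx <- max(2, floor((W + 2 * pad) / sx))
    offx <- -pad + (W + 2 * pad - nx * sx) / 2
    offy <- -pad + (H + 2 * pad - ny * sy) / 2
    px <- offx + rep(seq_len(nx) - 0.5, ny) * sx +
      rep(ifelse(seq_len(ny) %% 2 == 0, sx / 2, 0), each = nx)
    py <- offy + (rep(seq_len(ny), each = nx) - 0.5) * sy
  } else {
    # hard-disk point process: statistically isotropic (no lattice axes), so
    # dual-edge length is independent of orientation and neither tension nor
    # intensity inherits a spurious angular structure; the exclusion radius
    # shrinks with increasing disorder
    rex <- (1 - 0.45 * min(config$jitter, 1)) * s
    n_tot <- round(config$n_cells * (rw[2] - rw[1]) * (rw[4] - rw[3]) / (W * H))
    px <- py <- numeric(0)
    tries <- 0L
    while (length(px) < n_tot && tries < 80L * n_tot) {
      cx <- stats::runif(1, rw[1], rw[2]); cy <- stats::runif(1, rw[3], rw[4])
      tries <- tries + 1L
      ok <- !length(px) ||
        min(((px - cx) * sqrt(aspect))^2 + ((py - cy) / sqrt(aspect))^2) >= rex^2
      if (ok) { px <- c(px, cx); py <- c(py, cy) }
    }
  }

  dd <- tryCatch(deldir::deldir(px, py, rw = rw),
                 error = function(e) {
                   # degenerate (e.g. cocircular) configurations: jitter and retry
                   warning("degenerate point set; resampling with jitter")
                   deldir::deldir(px + stats::rnorm(length(px), 0, s * 1e-3),
                                  py + stats::rnorm(length(py), 0, s * 1e-3),
                                  rw = rw)
                 })
  for (it in seq_len(config$relax)) {
    tl <- deldir::tile.list(dd)
    cent <- vapply(tl, function(t) .poly_centroid(t$x, t$y), numeric(2))
    px <- pmin(pmax(cent[1, ], rw[1] + 1), rw[2] - 1)
    py <- pmin(pmax(cent[2, ], rw[3] + 1), rw[4] - 1)
    dd <- deldir::deldir(px, py, rw = rw)
  }

  # anneal away sub-resolution Voronoi edges (near-cocircular seed
  # quadruples): real segmented snapshots only contain junctions the optics
  # can resolve, so the study-condition tissue should too
  if (config$min_junction_px > 0) {
    for (it in 1:120) {
      sg0 <- dd$dirsgs
      len0 <- sqrt((sg0$x1 - sg0$x2)^2 + (sg0$y1 - sg0$y2)^2)
      short <- which(!(sg0$bp1 | sg0$bp2) & len0 < config$min_junction_px)
      if (!length(short)) break
      # a short Voronoi edge marks a near-cocircular seed quadruple; small
      # random nudges of the involved seeds break the degeneracy, with the
      # step escalating while stuck
      mov <- unique(c(sg0$ind1[short], sg0$ind2[short]))
      th <- stats::runif(length(mov), 0, 2 * pi)
      step <- 0.04 * s * (1 + (it %/% 20) * 0.5)
      px[mov] <- pmin(pmax(px[mov] + step * cos(th), rw[1] + 1), rw[2] - 1)
      py[mov] <- pmin(pmax(py[mov] + step * sin(th), rw[3] + 1), rw[4] - 1)
      dd <- deldir::deldir(px, py, rw = rw)
      if (it %% 30 == 0) {
        # periodic Lloyd sweep to smooth out the accumulated nudges
        tl <- deldir::tile.list(dd)
        cent <- vapply(tl, function(t) .poly_centroid(t$x, t$y), numeric(2))
        px <- pmin(pmax(cent[1, ], rw[1] + 1), rw[2] - 1)
        py <- pmin(pmax(cent[2, ], rw[3] + 1), rw[4] - 1)
        dd <- deldir::deldir(px, py, rw = rw)
      }
    }
    if (length(short)) {
      warning("could not anneal away all sub-resolution junctions (",
              length(short), " remain)")
    }
  }

  sg <- dd$dirsgs
  seglen <- sqrt((sg$x1 - sg$x2)^2 + (sg$y1 - sg$y2)^2)
  keep <- seglen > 1e-9
  degen_cells <- unique(c(sg$ind1[!keep], sg$ind2[!keep]))
  sg <- sg[keep, , drop = FALSE]
  seglen <- seglen[keep]

  # vertices: unclipped Voronoi segment endpoints (circumcentres)
  key1 <- ifelse(sg$bp1, NA, paste(round(sg$x1, 6), round(sg$y1, 6)))
  key2 <- ifelse(sg$bp2, NA, paste(round(sg$x2, 6), round(sg$y2, 6)))
  allkey <- unique(stats::na.omit(c(key1, key2)))
  vid1 <- match(key1, allkey); vid2 <- match(key2, allkey)
  # full-precision coordinates from the first occurrence of each key
  kx <- c(sg$x1, sg$x2); ky <- c(sg$y1, sg$y2)
  first <- match(allkey, c(key1, key2))
  vertices <- data.frame(id = seq_along(allkey), x = kx[first], y = ky[first])

  ang <- chord_angle(sg$x2 - sg$x1, sg$y2 - sg$y1)
  junctions <- data.frame(
    id = seq_len(nrow(sg)), v1 = vid1, v2 = vid2,
    cell_a = sg$ind1, cell_b = sg$ind2,
    length = seglen, angle = ang,
    boundary = sg$bp1 | sg$bp2
  )

  # deldir reports segment endpoints at limited precision; recompute each
  # vertex as the exact circumcentre of its three cells so that the rotated
  # Delaunay triangles close to machine precision
  for (v in vertices$id) {
    inc <- junctions[(!is.na(junctions$v1) & junctions$v1 == v) |
                       (!is.na(junctions$v2) & junctions$v2 == v), ]
    cc3 <- unique(c(inc$cell_a, inc$cell_b))
    if (length(cc3) != 3) next
    # translate the first point to the origin before solving: avoids the
    # catastrophic cancellation of the textbook determinant formula
    ax <- px[cc3[2]] - px[cc3[1]]; ay <- py[cc3[2]] - py[cc3[1]]
    bx <- px[cc3[3]] - px[cc3[1]]; by <- py[cc3[3]] - py[cc3[1]]
    d <- 2 * (ax * by - ay * bx)
    if (abs(d) < 1e-12) next
    a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2
    ux <- (by * a2 - ay * b2) / d
    uy <- (ax * b2 - bx * a2) / d
    i <- match(v, vertices$id)
    vertices$x[i] <- px[cc3[1]] + ux; vertices$y[i] <- py[cc3[1]] + uy
  }
  # refresh junction geometry from the exact vertex positions
  for (i in seq_len(nrow(junctions))) {
    v1 <- junctions$v1[i]; v2 <- junctions$v2[i]
    if (is.na(v1) || is.na(v2)) next
    i1 <- match(v1, vertices$id); i2 <- match(v2, vertices$id)
    dx <- vertices$x[i2] - vertices$x[i1]; dy <- vertices$y[i2] - vertices$y[i1]
    len <- sqrt(dx^2 + dy^2)
    if (len <= 1e-9) next
    junctions$length[i] <- len
    junctions$angle[i] <- chord_angle(dx, dy)
  }

  # junctions leaving the visible image rectangle cannot be measured there
  i1 <- match(junctions$v1, vertices$id); i2 <- match(junctions$v2, vertices$id)
  e1x <- ifelse(is.na(i1), sg$x1, vertices$x[i1])
  e1y <- ifelse(is.na(i1), sg$y1, vertices$y[i1])
  e2x <- ifelse(is.na(i2), sg$x2, vertices$x[i2])
  e2y <- ifelse(is.na(i2), sg$y2, vertices$y[i2])
  outside <- pmin(e1x, e2x) < 0 | pmax(e1x, e2x) > W |
    pmin(e1y, e2y) < 0 | pmax(e1y, e2y) > H
  junctions$boundary <- junctions$boundary | outside

  bnd_cells <- unique(c(sg$ind1[junctions$boundary], sg$ind2[junctions$boundary],
                        degen_cells))
  cells <- data.frame(id = seq_along(px), cx = px, cy = py,
                      boundary = seq_along(px) %in% bnd_cells)

  paths <- lapply(seq_len(nrow(sg)), function(i) {
    v1 <- junctions$v1[i]; v2 <- junctions$v2[i]
    p1 <- if (!is.na(v1)) { k <- match(v1, vertices$id); c(vertices$x[k], vertices$y[k]) }
          else c(sg$x1[i], sg$y1[i])
    p2 <- if (!is.na(v2)) { k <- match(v2, vertices$id); c(vertices$x[k], vertices$y[k]) }
          else c(sg$x2[i], sg$y2[i])
    rbind(p1, p2)
  })
  names(paths) <- as.character(junctions$id)

  net <- tissue_network(vertices, junctions, cells, paths = paths)

  ten <- sqrt((px[sg$ind1] - px[sg$ind2])^2 + (py[sg$ind1] - py[sg$ind2])^2)
  interior <- !junctions$boundary
  ten <- ten / mean(ten[interior])
  truth <- list(
    tensions = data.frame(junction_id = junctions$id, tension = ten),
    points = cbind(x = px, y = py),
    config = config
  )
  list(network = net, truth = truth)
}

# linear polarity ramp: 0 on [0,15], 1 on [75,90] degrees
.polarity_ramp <- function(angle) pmin(1, pmax(0, (angle - 15) / 60))

#' Assign channel line densities to junctions
#'
#' Emulates the statistical structure of the junctional markers: Myosin-II
#' proportional to tension and enriched on vertical (DV) junctions,
#' E-cadherin enriched on transverse (AP) junctions with an additive
#' 1/length density confound, and Vinculin recruited onto E-cadherin
#' complexes constitutively (`alpha`) plus in proportion to the load per
#' complex (`beta * tension`), so the noiseless Vinc/E-cad ratio equals
#' `alpha + beta * T` and is free of the length confound. All noise is
#' seeded; densities are clipped at zero.
#'
#' @param network a `tissue_network` from [generate_equilibrium_network()].
#' @param truth matching ground-truth list.
#' @param config the [synth_config()] used for generation.
#' @return data.frame with one row per junction: `junction_id`, `myosin`,
#'   `ecadherin`, `vinculin`, `angle`, `length`, `boundary`.
#' @export
assign_intensities <- function(network, truth, config = truth$config) {
  jn <- network$junctions
  set.seed(config$seed + 1L)
  Tj <- truth$tensions$tension[match(jn$id, truth$tensions$junction_id)]
  h <- .polarity_ramp(jn$angle)
  Lmean <- mean(jn$length[!jn$boundary])

  myo <- config$m0 * Tj * (1 + (config$pcp_myo - 1) * h) *
    (1 + stats::rnorm(nrow(jn), 0, config$noise_myo))
  cc <- config$confound * config$e0 * Lmean
  ecad <- config$e0 * (1 + (config$pcp_ecad - 1) * (1 - h)) + cc / jn$length +
    stats::rnorm(nrow(jn), 0, config$noise_ecad * config$e0)
  vinc <- (config$alpha + config$beta * Tj) * ecad +
    stats::rnorm(nrow(jn), 0, config$noise_vinc * config$e0)

  data.frame(junction_id = jn$id,
             myosin = pmax(myo, 0), ecadherin = pmax(ecad, 0),
             vinculin = pmax(vinc, 0),
             angle = jn$angle, length = jn$length, boundary = jn$boundary)
}

#' Render a synthetic multichannel z-stack and label image
#'
#' Paints each junction path as a band of constant line density, adds a
#' medial Myosin-II pool inside cells, applies per-plane defocus blur and
#' attenuation around the designated in-focus plane, low-frequency haze on
#' the basal-most planes, and Poisson plus Gaussian camera noise. Returns
#' ground-truth labels (0 = one-pixel boundary skeleton) and the focus plane.
#'
#' @param network a `tissue_network` whose coordinates live in the pixel
#'   domain `config$domain`.
#' @param densities data.frame from [assign_intensities()].
#' @param config the [synth_config()].
#' @param truth ground-truth list holding the generating points (used for the
#'   exact Voronoi label image).
#' @return list with `stacks` (named list of `width x height x n_planes`
#'   arrays for channels `myosin`, `ecadherin`, `vinculin`), `labels`,
#'   `focus_plane`, `junction_map` (band id image used for painting).
#' @export
render_images <- function(network, densities, config, truth) {
  W <- as.integer(config$domain[1]); H <- as.integer(config$domain[2])
  set.seed(config$seed + 2L)

  # exact Voronoi labels from the generating points (nearest seed per pixel)
  pts <- truth$points
  X <- matrix(rep(seq_len(W), H), W, H)
  Y <- matrix(rep(seq_len(H), each = W), W, H)
  D <- matrix(Inf, W, H); lab <- matrix(0L, W, H)
  for (i in seq_len(nrow(pts))) {
    d2 <- (X - pts[i, "x"])^2 + (Y - pts[i, "y"])^2
    upd <- d2 < D
    D[upd] <- d2[upd]; lab[upd] <- i
  }
  lab <- .skeletonize_labels(lab)

  jmap <- junction_pixel_map(network, c(W, H),
                             halfwidth = config$band_halfwidth,
                             vertex_radius = 0)

  base <- list()
  for (ch in c("myosin", "ecadherin", "vinculin")) {
    img <- matrix(0, W, H)
    dens <- densities[[ch]]
    inside <- jmap > 0
    img[inside] <- dens[match(jmap[inside], densities$junction_id)]
    img[is.na(img)] <- 0
    if (ch == "myosin" && config$medial_myo > 0) {
      med <- lab > 0 & jmap == 0
      img[med] <- config$medial_myo * config$m0
    }
    base[[ch]] <- img
  }

  stacks <- list()
  k <- config$focus_plane; Z <- config$n_planes
  for (ch in names(base)) {
    st <- array(0, dim = c(W, H, Z))
    for (z in seq_len(Z)) {
      dz <- abs(z - k)
      sig <- config$psf_sigma + config$z_blur * dz
      pl <- if (sig > 0) as.matrix(EBImage::gblur(base[[ch]], sigma = sig)) else base[[ch]]
      pl <- pl * exp(-dz^2 / 2)
      if (z > Z - 3 && config$haze > 0) {
        pl <- pl + config$haze * config$e0 *
          as.matrix(EBImage::gblur(base[[ch]] / max(1e-9, max(base[[ch]])),
                                   sigma = 15))
      }
      if (config$gain > 0) {
        pl <- stats::rpois(length(pl), lambda = pmax(pl, 0) * config$gain) /
          config$gain
        dim(pl) <- c(W, H)
      }
      if (config$read_noise > 0) {
        pl <- pl + stats::rnorm(length(pl), 0, config$read_noise)
        dim(pl) <- c(W, H)
      }
      st[, , z] <- pl
    }
    stacks[[ch]] <- st
  }
  list(stacks = stacks, labels = lab, focus_plane = k, junction_map = jmap)
}

# set a one-pixel-wide boundary skeleton (0) between differing labels
.skeletonize_labels <- function(lab) {
  W <- nrow(lab); H <- ncol(lab)
  bnd <- matrix(FALSE, W, H)
  bnd[-W, ] <- bnd[-W, ] | lab[-W, ] != lab[-1, ]
  bnd[, -H] <- bnd[, -H] | lab[, -H] != lab[, -1]
  lab[bnd] <- 0L
  lab
}

#' Simulate a laser ablation on a synthetic tissue
#'
#' Sets the ablated junction's tension to zero and relaxes the vertex
#' positions with overdamped dynamics (`v = F / gamma`, forces summing the
#' remaining junctional tensions at each vertex; tensions are held fixed,
#' consistent with quasi-static cytoskeletal kinetics). Optionally evolves
#' E-cadherin line densities with a shear-sensitive turnover model, with the
#' shear of every eligible junction recomputed from the current geometry at
#' each step. Emits vertex tracks for the two ablated endpoints and
#' per-frame densities for all junctions.
#'
#' @param network a restricted `tissue_network` (see [restrict_threefold()]).
#' @param truth ground-truth list with exact tensions.
#' @param junction id of the (interior, retained) junction to ablate.
#' @param config a [synth_config()] (uses `gamma`, `k_on`, `k_off0`,
#'   `shear_sens`, `seed`).
#' @param n_steps,dt number and size (s) of explicit Euler steps.
#' @param turnover logical; evolve E-cadherin densities.
#' @return an `ablation_event` list: `junction`, `released_tension`, `times`,
#'   `tracks` (t, vertex, x, y for the two endpoints), `densities`
#'   (t, junction_id, channel, density), `network`, `tensions` (pre-ablation).
#' @export
simulate_ablation <- function(network, truth, junction, config,
                              n_steps = 40, dt = 0.05, turnover = TRUE) {
  jn <- network$junctions
  if (is.null(jn$retained)) { network <- restrict_threefold(network); jn <- network$junctions }
  jrow <- jn[jn$id == junction, ]
  if (nrow(jrow) != 1 || !isTRUE(jrow$retained)) {
    stop("ablated junction must be a retained interior junction")
  }
  tens <- truth$tensions$tension[match(jn$id, truth$tensions$junction_id)]
  names(tens) <- as.character(jn$id)
  released <- tens[as.character(junction)]

  P <- as.matrix(network$vertices[, c("x", "y")])
  rownames(P) <- as.character(network$vertices$id)
  deg <- network$vertices$degree
  # move only fully interior vertices (all incident junctions carry tension)
  jint <- !jn$boundary & !is.na(jn$v1) & !is.na(jn$v2)
  iv1 <- match(jn$v1[jint], network$vertices$id)
  iv2 <- match(jn$v2[jint], network$vertices$id)
  tInt <- tens[jint]
  idInt <- jn$id[jint]
  touched <- tabulate(c(iv1, iv2), nbins = nrow(P))
  movable <- touched == deg & deg == 3

  post_tens <- tInt
  post_tens[idInt == junction] <- 0

  quad <- NULL
  if (turnover) {
    tdf <- data.frame(junction_id = jn$id, tension = tens)
    sh0 <- compute_shear(network, tdf)
    elig <- sh0$eligible
    # steady-state E-cadherin under pre-ablation shear
    tau0 <- ifelse(elig, sh0$tau, 0)
    E <- config$k_on / (config$k_off0 * (1 + config$shear_sens * tau0))
    quad <- sh0
  }

  v1 <- jrow$v1; v2 <- jrow$v2
  times <- seq(0, n_steps * dt, by = dt)
  tracks <- vector("list", length(times))
  dens <- vector("list", length(times))
  cur_tens <- tens
  cur_tens[as.character(junction)] <- 0

  for (si in seq_along(times)) {
    i1 <- match(v1, network$vertices$id); i2 <- match(v2, network$vertices$id)
    tracks[[si]] <- data.frame(t = times[si],
                               vertex = c(v1, v2),
                               x = P[c(i1, i2), 1], y = P[c(i1, i2), 2])
    if (turnover) {
      dens[[si]] <- data.frame(t = times[si], junction_id = jn$id,
                               channel = "ecadherin", density = E)
    }
    if (si == length(times)) break

    dxy <- P[iv2, , drop = FALSE] - P[iv1, , drop = FALSE]
    len <- sqrt(rowSums(dxy^2))
    u <- dxy / pmax(len, 1e-12)
    Fv <- matrix(0, nrow(P), 2)
    fx <- post_tens * u[, 1]; fy <- post_tens * u[, 2]
    Fv[, 1] <- Fv[, 1] + tabulate2(iv1, fx, nrow(P)) - tabulate2(iv2, fx, nrow(P))
    Fv[, 2] <- Fv[, 2] + tabulate2(iv1, fy, nrow(P)) - tabulate2(iv2, fy, nrow(P))
    P[movable, ] <- P[movable, ] + dt * Fv[movable, ] / config$gamma

    if (turnover) {
      tau <- rep(0, nrow(jn))
      ok <- quad$eligible
      # recompute shear with current lengths, tensions fixed (ablated = 0)
      curL <- rep(NA_real_, nrow(jn))
      curL[jint] <- sqrt(rowSums((P[iv2, , drop = FALSE] - P[iv1, , drop = FALSE])^2))
      q <- quad
      tq <- function(ids) cur_tens[as.character(ids)]
      tau[ok] <- abs((tq(q$T1_id[ok]) + tq(q$T3_id[ok])) -
                       (tq(q$T2_id[ok]) + tq(q$T4_id[ok]))) /
        (2 * pmax(curL[ok], 1e-9))
      E <- E + dt * (config$k_on - config$k_off0 * (1 + config$shear_sens * tau) * E)
    }
  }

  structure(list(
    junction = junction, released_tension = unname(released),
    times = times, t0 = 0,
    tracks = do.call(rbind, tracks),
    densities = if (turnover) do.call(rbind, dens) else NULL,
    network = network,
    tensions = data.frame(junction_id = jn$id, tension = tens)
  ), class = "ablation_event")
}

#' Match a rebuilt network's junctions to generator ground truth
#'
#' Maps every cell label of a segmented/rebuilt network to the generator
#' cell with the largest pixel overlap, then matches junctions by their
#' unordered cell pair and attaches the true tension.
#'
#' @param network a `tissue_network` built from a segmentation whose label
#'   image (`network$labels`) lives on the same pixel grid as the
#'   generator's.
#' @param generated the list returned by [generate_equilibrium_network()].
#' @param true_labels the generator's label image (from [render_images()]).
#' @return data.frame `junction_id`, `true_junction_id`, `true_tension`
#'   (NA where no ground-truth junction matches).
#' @export
match_to_ground_truth <- function(network, generated, true_labels) {
  seg <- network$labels
  if (is.null(seg)) stop("network carries no label image")
  ids <- setdiff(unique(as.vector(seg)), 0L)
  map <- vapply(ids, function(sid) {
    ov <- table(true_labels[seg == sid])
    ov <- ov[names(ov) != "0"]
    if (!length(ov)) return(NA_integer_)
    as.integer(names(ov)[which.max(ov)])
  }, integer(1))
  names(map) <- as.character(ids)

  jn <- network$junctions
  ta <- map[as.character(jn$cell_a)]; tb <- map[as.character(jn$cell_b)]
  key <- paste(pmin(ta, tb), pmax(ta, tb))
  gj <- generated$network$junctions
  gkey <- paste(pmin(gj$cell_a, gj$cell_b), pmax(gj$cell_a, gj$cell_b))
  idx <- match(key, gkey)
  data.frame(
    junction_id = jn$id,
    true_junction_id = gj$id[idx],
    true_tension = generated$truth$tensions$tension[
      match(gj$id[idx], generated$truth$tensions$junction_id)]
  )
}

# sum `vals` into `n` bins given by integer index `idx`
tabulate2 <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
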