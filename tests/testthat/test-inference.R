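test_that("dual topology counts nodes, edges and triangles", {
  # two cells sharing one edge: 2 Q-nodes, 1 dual edge, 0 triangles
  vertices <- data.frame(id = 1:2, x = c(0, 0), y = c(0, 2))
  junctions <- data.frame(id = 1L, v1 = 1L, v2 = 2L, cell_a = 1L, cell_b = 2L,
                          length = 2, angle = 90, boundary = FALSE,
                          retained = TRUE, exclude_reason = NA_character_)
  cells <- data.frame(id = 1:2, cx = c(-1, 1), cy = c(1, 1), boundary = FALSE,
                      retained = TRUE, exclude_reason = NA_character_)
  net <- tissue_network(vertices, junctions, cells)
  net$junctions$retained <- TRUE; net$cells$retained <- TRUE
  dual <- build_dual_topology(net)
  expect_length(dual$cells, 2)
  expect_identical(nrow(dual$edges), 1L)
  expect_identical(nrow(dual$triangles), 0L)

  # single cell: no interior junction
  net1 <- net
  net1$junctions$retained <- FALSE
  expect_error(build_dual_topology(net1), "no interior junction")
})

test_that("dual topology of a Voronoi tissue is the interior Delaunay graph", {
  gen <- fix_tissue()
  dual <- build_dual_topology(gen$network)
  pts <- gen$truth$points
  dd <- deldir::deldir(pts[, "x"], pts[, "y"])
  del_pairs <- paste(pmin(dd$delsgs$ind1, dd$delsgs$ind2),
                     pmax(dd$delsgs$ind1, dd$delsgs$ind2))
  dual_pairs <- paste(pmin(dual$edges$cell_a, dual$edges$cell_b),
                      pmax(dual$edges$cell_a, dual$edges$cell_b))
  expect_true(all(dual_pairs %in% del_pairs))
  # every dual triangle is a Delaunay triangle of the seed points
  tl <- deldir::triang.list(dd)
  tri_keys <- vapply(tl, function(t) paste(sort(t$ptNum), collapse = "-"), "")
  got <- apply(dual$triangles[, c("cell_1", "cell_2", "cell_3")], 1,
               function(r) paste(sort(r), collapse = "-"))
  expect_true(all(got %in% tri_keys))
  expect_gt(nrow(dual$triangles), 0)
})

test_that("tensions are recovered exactly on equilibrium tissues", {
  gen <- fix_tissue()
  ti <- infer_tensions(gen$network)
  tru <- gen$truth$tensions$tension[match(ti$tensions$junction_id,
                                          gen$truth$tensions$junction_id)]
  expect_gte(stats::cor(tru, ti$tensions$tension), 0.999)
  expect_lt(abs(ti$lambda[1]), 1e-8)
  expect_lt(abs(mean(ti$tensions$tension) - 1), 1e-12)
})

test_that("mean inferred tension is one on every run", {
  for (s in c(2, 7)) {
    gen <- fix_tissue(seed = s)
    ti <- infer_tensions(gen$network)
    expect_lt(abs(mean(ti$tensions$tension) - 1), 1e-12)
  }
})

test_that("a regular hexagonal lattice infers equal tensions", {
  gen <- fix_hex_tissue()
  ti <- infer_tensions(gen$network)
  expect_lt(max(abs(ti$tensions$tension - 1)), 1e-6)
})

test_that("inference is invariant to rigid transforms and rescaling", {
  gen <- fix_tissue()
  ti0 <- infer_tensions(gen$network)
  th <- 0.7; s <- 2.3; shift <- c(111, -55)
  net <- gen$network
  x <- net$vertices$x; y <- net$vertices$y
  net$vertices$x <- s * (cos(th) * x - sin(th) * y) + shift[1]
  net$vertices$y <- s * (sin(th) * x + cos(th) * y) + shift[2]
  net$paths <- lapply(net$paths, function(p) {
    cbind(s * (cos(th) * p[, 1] - sin(th) * p[, 2]) + shift[1],
          s * (sin(th) * p[, 1] + cos(th) * p[, 2]) + shift[2])
  })
  ti1 <- infer_tensions(net)
  expect_equal(ti1$tensions$tension, ti0$tensions$tension, tolerance = 1e-9)
})

test_that("inference survives one-percent vertex jitter", {
  gen <- fix_tissue()
  net <- gen$network
  L <- mean(net$junctions$length[net$junctions$retained])
  set.seed(99)
  net$vertices$x <- net$vertices$x + stats::rnorm(nrow(net$vertices), 0, 0.01 * L)
  net$vertices$y <- net$vertices$y + stats::rnorm(nrow(net$vertices), 0, 0.01 * L)
  ti <- infer_tensions(net)
  tru <- gen$truth$tensions$tension[match(ti$tensions$junction_id,
                                          gen$truth$tensions$junction_id)]
  expect_gte(stats::cor(tru, ti$tensions$tension), 0.95)
})

test_that("force balance residuals vanish on exact tissues", {
  gen <- fix_tissue()
  fb <- force_balance_residual(gen$network, gen$truth$tensions)
  expect_lt(fb$median, 1e-10)
  expect_gt(nrow(fb$residuals), 50)
})

test_that("symmetric and collinear vertex residuals follow closed forms", {
  # three junctions at 120 degrees with equal tensions: residual 0
  vertices <- data.frame(id = 1:4,
                         x = c(0, cos(pi / 2), cos(pi * 7 / 6), cos(pi * 11 / 6)),
                         y = c(0, sin(pi / 2), sin(pi * 7 / 6), sin(pi * 11 / 6)))
  junctions <- data.frame(id = 1:3, v1 = 1L, v2 = 2:4,
                          cell_a = c(1L, 2L, 3L), cell_b = c(2L, 3L, 1L),
                          length = 1, angle = c(90, chord_angle(cos(pi * 7 / 6), sin(pi * 7 / 6)),
                                                chord_angle(cos(pi * 11 / 6), sin(pi * 11 / 6))),
                          boundary = FALSE)
  cells <- data.frame(id = 1:3, cx = 0, cy = 0, boundary = FALSE)
  star <- tissue_network(vertices, junctions, cells)
  fb <- force_balance_residual(star, data.frame(junction_id = 1:3, tension = 1))
  expect_lt(max(fb$residuals$residual), 1e-12)

  # two collinear junctions with unequal tensions at a degree-2 vertex
  v2 <- data.frame(id = 1:3, x = c(0, -1, 2), y = 0)
  j2 <- data.frame(id = 1:2, v1 = 1L, v2 = c(2L, 3L), cell_a = 1L, cell_b = 2L,
                   length = c(1, 2), angle = 0, boundary = FALSE)
  c2 <- data.frame(id = 1:2, cx = 0, cy = c(1, -1), boundary = FALSE)
  line <- tissue_network(v2, j2, c2)
  fb2 <- force_balance_residual(line, data.frame(junction_id = 1:2,
                                                 tension = c(2, 0.5)))
  expect_equal(fb2$residuals$residual, 1.5)
})

test_that("vertices lacking a tension are skipped and counted", {
  gen <- fix_tissue()
  ti <- infer_tensions(gen$network)
  fb <- force_balance_residual(gen$network, ti)
  expect_gt(fb$n_skipped, 0)
  expect_gt(nrow(fb$residuals), 0)
})
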