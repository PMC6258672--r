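#' Junctional pixel probability from a processed intensity image
#'
#' Stand-in for an external pixel classifier: maps intensities through a
#' logistic centred on the Otsu threshold between junctional and interior
#' pixels, so that junctional pixels score above 0.5. The softness is a
#' fraction of the threshold.
#'
#' @param image processed 2-D intensity image.
#' @param softness logistic width as a fraction of the Otsu threshold.
#' @return matrix of probabilities in `[0, 1]`.
#' @export
junction_probability <- function(image, softness = 0.25) {
  rng <- range(image)
  if (diff(rng) < 1e-12) stop("constant image has no junctional structure")
  sc <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(sc))
  1 / (1 + exp(-(sc - thr) / (softness * max(thr, 1e-6))))
}

#' Watershed segmentation of a junctional probability map
#'
#' Cells are basins of the distance transform of the sub-threshold
#' (non-junctional) pixels; a watershed labels the basins and the labels are
#' then propagated over the remaining pixels so that every pixel belongs to
#' exactly one cell, after which a one-pixel-wide boundary skeleton (label 0)
#' is re-drawn between differing labels.
#'
#' @param probability_map 2-D matrix `[x, y]` with values in `[0, 1]`;
#'   junctional pixels high.
#' @param threshold probability below which a pixel counts as cell interior.
#' @param tolerance,ext watershed parameters (see `EBImage::watershed`).
#' @param lambda spatial regularisation of the label propagation across the
#'   junctional band; large values grow fronts at equal Euclidean rate so
#'   that cell boundaries meet at the band midline.
#' @return integer label matrix, 0 on the boundary skeleton.
#' @export
segment_cells <- function(probability_map, threshold = 0.5,
                          tolerance = 1, ext = 1, lambda = 100) {
  p <- probability_map
  if (length(p) == 0 || max(p) - min(p) < 1e-9) {
    stop("no cells: probability map is empty or constant")
  }
  if (min(p) < -1e-6 || max(p) > 1 + 1e-6) {
    stop("probability map values must lie in [0, 1]")
  }
  mask <- p < threshold
  if (!any(mask)) stop("no cells: no sub-threshold interior pixels")
  dm <- EBImage::distmap(mask * 1)
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = ext)
  if (max(ws) < 1) stop("no cells: watershed found no basins")
  filled <- EBImage::propagate(x = p, seeds = ws, lambda = lambda)
  .skeletonize_labels(matrix(as.integer(as.matrix(filled)),
                             nrow(p), ncol(p)))
}

#' Extract a tissue network from a label image
#'
#' Vertices are clusters of boundary pixels adjacent to three or more
#' labels (sub-pixel position = cluster centroid); junctions are the
#' connected runs of boundary pixels adjacent to exactly two labels, with
#' their ordered pixel path, arc length (path plus the links to the end
#' vertices) and end-to-end chord angle. Cells store centroids and a
#' boundary flag (touching the image frame). Junction angles use the chord,
#' not the curved path, since junctional curvature is negligible in the
#' tissues this is built for.
#'
#' @param labels integer label matrix `[x, y]`, 0 = boundary skeleton.
#' @param pixel_size micrometres per pixel.
#' @param ap_axis AP-axis unit vector in image coordinates.
#' @param refine_vertices refine each vertex to the least-squares
#'   intersection of total-least-squares line fits of its incident junction
#'   paths (sub-pixel accuracy for straight junctions; junction curvature is
#'   negligible in this tissue).
#' @return a [tissue_network()].
#' @export
build_network <- function(labels, pixel_size = 1, ap_axis = c(1, 0),
                          refine_vertices = TRUE) {
  W <- nrow(labels); H <- ncol(labels)
  shifts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                  c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  bnd <- which(labels == 0L)
  if (!length(bnd)) stop("label image has no boundary skeleton")

  nb <- matrix(0L, length(bnd), nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    sh <- .shift_matrix(labels, shifts[s, 1], shifts[s, 2])
    nb[, s] <- sh[bnd]
  }
  adj <- apply(nb, 1, function(r) sort(unique(r[r > 0L])), simplify = FALSE)
  n_adj <- lengths(adj)

  # triple-point detection needs a radius-2 neighbourhood: where the skeleton
  # is locally two pixels wide no single pixel touches three cells at radius 1
  shifts2 <- as.matrix(expand.grid(dx = -2:2, dy = -2:2))
  shifts2 <- shifts2[!(shifts2[, 1] == 0 & shifts2[, 2] == 0), , drop = FALSE]
  nb2 <- matrix(0L, length(bnd), nrow(shifts2))
  for (s in seq_len(nrow(shifts2))) {
    sh <- .shift_matrix(labels, shifts2[s, 1], shifts2[s, 2])
    nb2[, s] <- sh[bnd]
  }
  n_adj2 <- apply(nb2, 1, function(r) length(unique(r[r > 0L])))

  tri_mask <- matrix(FALSE, W, H); tri_mask[bnd[n_adj2 >= 3]] <- TRUE
  if (!any(tri_mask)) stop("no vertices: label image has no triple points")
  tri_lab <- .bwlabel8(tri_mask * 1)

  nver <- max(tri_lab)
  vx <- vy <- numeric(nver)
  vcells <- vector("list", nver)
  tri_cells_per_pix <- apply(nb2[n_adj2 >= 3, , drop = FALSE], 1,
                             function(r) sort(unique(r[r > 0L])),
                             simplify = FALSE)
  tri_pix <- bnd[n_adj2 >= 3]
  tri_ids <- tri_lab[tri_pix]
  for (v in seq_len(nver)) {
    pp <- tri_pix[tri_ids == v]
    vx[v] <- mean((pp - 1) %% W + 1)
    vy[v] <- mean((pp - 1) %/% W + 1)
    vcells[[v]] <- sort(unique(unlist(tri_cells_per_pix[tri_ids == v])))
  }
  vertices <- data.frame(id = seq_len(nver), x = vx, y = vy)

  # junction pixels: exactly two adjacent labels and not a triple point,
  # grouped by cell pair
  pair_sel <- n_adj == 2 & n_adj2 < 3
  pair_pix <- bnd[pair_sel]
  pair_ab <- do.call(rbind, adj[pair_sel])
  pkey <- paste(pair_ab[, 1], pair_ab[, 2])

  junctions <- list(); paths <- list(); jid <- 0L
  for (key in unique(pkey)) {
    sel <- pkey == key
    ab <- pair_ab[which(sel)[1], ]
    m <- matrix(0, W, H); m[pair_pix[sel]] <- 1
    comp <- .bwlabel8(m)
    for (cpt in seq_len(max(comp))) {
      pp <- which(comp == cpt)
      xy <- cbind((pp - 1) %% W + 1, (pp - 1) %/% W + 1)
      path <- .order_path(xy)
      # attach end vertices: nearest triple cluster around each path end
      vids <- vapply(list(path[1, ], path[nrow(path), ]), function(e) {
        .find_vertex(e, tri_lab, vcells, ab, W, H)
      }, integer(1))
      arclen <- if (nrow(path) > 1) {
        sum(sqrt(rowSums((path[-1, , drop = FALSE] -
                            path[-nrow(path), , drop = FALSE])^2)))
      } else 0
      p1 <- path[1, ]; p2 <- path[nrow(path), ]
      if (!is.na(vids[1])) { arclen <- arclen + sqrt(sum((c(vx[vids[1]], vy[vids[1]]) - p1)^2)) }
      if (!is.na(vids[2])) { arclen <- arclen + sqrt(sum((c(vx[vids[2]], vy[vids[2]]) - p2)^2)) }
      e1 <- if (!is.na(vids[1])) c(vx[vids[1]], vy[vids[1]]) else p1
      e2 <- if (!is.na(vids[2])) c(vx[vids[2]], vy[vids[2]]) else p2
      chord <- e2 - e1
      if (sqrt(sum(chord^2)) < 1e-9 || arclen <= 0) next
      jid <- jid + 1L
      junctions[[jid]] <- data.frame(
        id = jid, v1 = vids[1], v2 = vids[2],
        cell_a = ab[1], cell_b = ab[2],
        length = max(arclen, 1e-6),
        angle = chord_angle(chord[1], chord[2], ap_axis),
        boundary = is.na(vids[1]) || is.na(vids[2]))
      paths[[as.character(jid)]] <- rbind(e1, path, e2)
    }
  }
  if (!jid) stop("no junctions found")
  junctions <- do.call(rbind, junctions)

  ids <- sort(unique(labels[labels > 0L]))
  pix <- which(labels > 0L)
  lv <- labels[pix]
  cx <- tapply((pix - 1) %% W + 1, lv, mean)
  cy <- tapply((pix - 1) %/% W + 1, lv, mean)
  frame_labels <- unique(c(labels[1, ], labels[W, ], labels[, 1], labels[, H]))
  cells <- data.frame(id = as.integer(names(cx)), cx = as.numeric(cx),
                      cy = as.numeric(cy),
                      boundary = as.integer(names(cx)) %in% frame_labels)

  net <- tissue_network(vertices, junctions, cells, paths = paths,
                        pixel_size = pixel_size, ap_axis = ap_axis,
                        labels = labels)
  if (refine_vertices) net <- .refine_vertices(net)
  net
}

# refine vertex positions to the least-squares intersection point of the
# incident junctions' fitted lines, then refresh junction chord geometry
.refine_vertices <- function(net, max_shift = 4) {
  V <- net$vertices
  for (i in seq_len(nrow(V))) {
    vid <- V$id[i]
    inc <- net$junctions[(!is.na(net$junctions$v1) & net$junctions$v1 == vid) |
                           (!is.na(net$junctions$v2) & net$junctions$v2 == vid), ,
                         drop = FALSE]
    if (nrow(inc) < 2) next
    M <- matrix(0, 2, 2); b <- c(0, 0); nl <- 0
    for (k in seq_len(nrow(inc))) {
      path <- net$paths[[as.character(inc$id[k])]]
      if (is.null(path) || nrow(path) < 6) next
      pix <- path[2:(nrow(path) - 1), , drop = FALSE]  # skeleton pixels only
      p0 <- colMeans(pix)
      u <- svd(sweep(pix, 2, p0))$v[, 1]
      P <- diag(2) - u %*% t(u)
      M <- M + P; b <- b + P %*% p0; nl <- nl + 1
    }
    if (nl < 2 || abs(det(M)) < 1e-6) next
    vnew <- as.vector(solve(M, b))
    if (sqrt(sum((vnew - c(V$x[i], V$y[i]))^2)) <= max_shift) {
      V$x[i] <- vnew[1]; V$y[i] <- vnew[2]
    }
  }
  net$vertices <- V
  # refresh chord-derived junction geometry and path endpoints
  for (j in seq_len(nrow(net$junctions))) {
    v1 <- net$junctions$v1[j]; v2 <- net$junctions$v2[j]
    key <- as.character(net$junctions$id[j])
    path <- net$paths[[key]]
    if (!is.na(v1)) {
      i1 <- match(v1, V$id)
      path[1, ] <- c(V$x[i1], V$y[i1])
    }
    if (!is.na(v2)) {
      i2 <- match(v2, V$id)
      path[nrow(path), ] <- c(V$x[i2], V$y[i2])
    }
    net$paths[[key]] <- path
    steps <- sqrt(rowSums((path[-1, , drop = FALSE] -
                             path[-nrow(path), , drop = FALSE])^2))
    net$junctions$length[j] <- max(sum(steps), 1e-6)
    chord <- path[nrow(path), ] - path[1, ]
    if (sqrt(sum(chord^2)) > 1e-9) {
      net$junctions$angle[j] <- chord_angle(chord[1], chord[2], net$ap_axis)
    }
  }
  net
}

# 8-connected component labelling of a binary mask (EBImage::bwlabel is
# 4-connected; labelling the 3x3-dilated mask and masking back merges
# diagonal staircases into single components)
.bwlabel8 <- function(mask) {
  dil <- EBImage::dilate(mask, EBImage::makeBrush(3, shape = "box"))
  lab <- matrix(as.integer(as.matrix(EBImage::bwlabel(dil))), nrow(mask), ncol(mask))
  lab[mask == 0] <- 0L
  # relabel to consecutive ids over the surviving components
  ids <- sort(unique(lab[lab > 0]))
  matrix(match(lab, ids, nomatch = 0L), nrow(mask), ncol(mask))
}

# order 1-px-wide curve pixels into a chain (greedy nearest neighbour from
# an extremal pixel)
.order_path <- function(xy) {
  n <- nrow(xy)
  if (n <= 2) return(xy)
  # endpoint: pixel with fewest component neighbours (chebyshev distance 1)
  cheb <- function(i) {
    pmax(abs(xy[, 1] - xy[i, 1]), abs(xy[, 2] - xy[i, 2]))
  }
  nnb <- vapply(seq_len(n), function(i) sum(cheb(i) == 1), integer(1))
  start <- which.min(nnb)
  ord <- integer(n); used <- logical(n)
  ord[1] <- start; used[start] <- TRUE
  for (k in 2:n) {
    prev <- ord[k - 1]
    d <- (xy[, 1] - xy[prev, 1])^2 + (xy[, 2] - xy[prev, 2])^2
    d[used] <- Inf
    nxt <- which.min(d)
    if (!is.finite(d[nxt])) break
    ord[k] <- nxt; used[nxt] <- TRUE
  }
  xy[ord[ord > 0], , drop = FALSE]
}

# vertex id whose triple cluster is near pixel `e` and whose cell set
# contains both cells of the junction; NA when none (frame-clipped end)
.find_vertex <- function(e, tri_lab, vcells, ab, W, H) {
  for (r in 1:2) {
    xs <- max(1, e[1] - r):min(W, e[1] + r)
    ys <- max(1, e[2] - r):min(H, e[2] + r)
    cand <- unique(tri_lab[xs, ys])
    cand <- cand[cand > 0]
    if (!length(cand)) next
    good <- cand[vapply(cand, function(v) all(ab %in% vcells[[v]]), logical(1))]
    if (length(good)) return(good[1])
    if (r == 2 && length(cand)) return(cand[1])
  }
  NA_integer_
}
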