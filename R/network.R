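#' Tissue network container
#'
#' A `tissue_network` represents a segmented epithelial tissue as a planar
#' graph of vertices (tri-cellular junction points), junctions (cell-cell
#' contacts) and cells. Coordinates are pixel-centred, origin at the top-left
#' corner of the image, with `x` running along image columns. The
#' anterior-posterior (AP) axis defaults to `+x`; junction angles are measured
#' relative to it and folded into `[0, 90]` degrees, so 0 means AP-parallel
#' (transverse) and 90 means DV-parallel (vertical).
#'
#' @param vertices data.frame with columns `id`, `x`, `y`.
#' @param junctions data.frame with columns `id`, `v1`, `v2` (vertex ids, `NA`
#'   where a junction end is clipped at the image frame), `cell_a`, `cell_b`
#'   (adjacent cell ids, `cell_b` may be `NA` for frame-bordering junctions),
#'   `length` (arc length, px), `angle` (degrees in `[0, 90]` w.r.t. the AP
#'   axis) and `boundary` (logical).
#' @param cells data.frame with columns `id`, `cx`, `cy` (centroid) and
#'   `boundary` (logical: touches the image frame or has a clipped junction).
#' @param paths optional named list of n x 2 matrices, one per junction id,
#'   giving the ordered pixel path of the junction.
#' @param cell_junctions,cell_vertices optional named lists mapping cell id to
#'   the ordered junction/vertex ids of that cell. Recomputed from `junctions`
#'   when omitted.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param ap_axis unit vector of the AP axis in image coordinates.
#' @param labels optional integer label image (matrix indexed `[x, y]`,
#'   0 = boundary skeleton) that the network was extracted from.
#'
#' @return An object of class `tissue_network`.
#' @export
tissue_network <- function(vertices, junctions, cells, paths = NULL,
                           cell_junctions = NULL, cell_vertices = NULL,
                           pixel_size = 1, ap_axis = c(1, 0), labels = NULL) {
  stopifnot(is.data.frame(vertices), is.data.frame(junctions), is.data.frame(cells))
  need_v <- c("id", "x", "y")
  need_j <- c("id", "v1", "v2", "cell_a", "cell_b", "length", "angle", "boundary")
  need_c <- c("id", "cx", "cy", "boundary")
  if (!all(need_v %in% names(vertices))) stop("vertices must have columns ", paste(need_v, collapse = ", "))
  if (!all(need_j %in% names(junctions))) stop("junctions must have columns ", paste(need_j, collapse = ", "))
  if (!all(need_c %in% names(cells))) stop("cells must have columns ", paste(need_c, collapse = ", "))
  if (nrow(junctions) > 0) {
    if (any(junctions$length <= 0)) stop("junction lengths must be > 0")
    if (any(junctions$angle < -1e-9 | junctions$angle > 90 + 1e-9)) {
      stop("junction angles must lie in [0, 90] degrees")
    }
  }
  ap_axis <- ap_axis / sqrt(sum(ap_axis^2))

  net <- structure(list(
    vertices = vertices, junctions = junctions, cells = cells,
    paths = paths, pixel_size = pixel_size, ap_axis = ap_axis,
    labels = labels, schema_version = "1.0"
  ), class = "tissue_network")

  if (is.null(cell_junctions) || is.null(cell_vertices)) {
    inc <- .cell_incidence(net)
    net$cell_junctions <- inc$cell_junctions
    net$cell_vertices <- inc$cell_vertices
  } else {
    net$cell_junctions <- cell_junctions
    net$cell_vertices <- cell_vertices
  }
  net$vertices$degree <- vertex_degrees(net)
  net
}

#' @export
print.tissue_network <- function(x, ...) {
  cat("<tissue_network> ", nrow(x$cells), " cells, ", nrow(x$junctions),
      " junctions, ", nrow(x$vertices), " vertices\n", sep = "")
  cat("  boundary cells: ", sum(x$cells$boundary),
      "; pixel size: ", x$pixel_size, " um/px\n", sep = "")
  if (!is.null(x$cells$retained)) {
    cat("  retained (three-fold, interior) cells: ", sum(x$cells$retained), "\n", sep = "")
  }
  invisible(x)
}

# junction/vertex incidence lists per cell, ordered by angle around centroid
.cell_incidence <- function(net) {
  jn <- net$junctions
  vv <- net$vertices
  cj <- vector("list", nrow(net$cells))
  cv <- vector("list", nrow(net$cells))
  names(cj) <- names(cv) <- as.character(net$cells$id)
  for (k in seq_len(nrow(net$cells))) {
    cid <- net$cells$id[k]
    jj <- jn[!is.na(jn$cell_a) & jn$cell_a == cid |
             !is.na(jn$cell_b) & jn$cell_b == cid, , drop = FALSE]
    if (nrow(jj) == 0) next
    # order junctions by the angle of their midpoint around the cell centroid
    mx <- my <- numeric(nrow(jj))
    for (i in seq_len(nrow(jj))) {
      v1 <- jj$v1[i]; v2 <- jj$v2[i]
      p1 <- if (!is.na(v1)) unlist(vv[vv$id == v1, c("x", "y")]) else c(NA, NA)
      p2 <- if (!is.na(v2)) unlist(vv[vv$id == v2, c("x", "y")]) else c(NA, NA)
      mx[i] <- mean(c(p1[1], p2[1]), na.rm = TRUE)
      my[i] <- mean(c(p1[2], p2[2]), na.rm = TRUE)
    }
    ord <- order(atan2(my - net$cells$cy[k], mx - net$cells$cx[k]))
    cj[[k]] <- jj$id[ord]
    vs <- unique(stats::na.omit(c(rbind(jj$v1[ord], jj$v2[ord]))))
    cv[[k]] <- vs
  }
  list(cell_junctions = cj, cell_vertices = cv)
}

#' Vertex degrees of a tissue network
#'
#' Number of junctions incident to each vertex (boundary-clipped junction ends
#' do not contribute).
#'
#' @param net a `tissue_network`.
#' @return integer vector aligned with `net$vertices`.
#' @export
vertex_degrees <- function(net) {
  ends <- c(net$junctions$v1, net$junctions$v2)
  tab <- table(factor(ends[!is.na(ends)], levels = net$vertices$id))
  as.integer(tab)
}

#' Angle of a chord relative to the AP axis
#'
#' Folded into `[0, 90]` degrees; invariant to reversing the chord.
#'
#' @param dx,dy chord components in image coordinates.
#' @param ap_axis unit vector of the AP axis.
#' @return angle in degrees.
#' @export
chord_angle <- function(dx, dy, ap_axis = c(1, 0)) {
  ap <- ap_axis / sqrt(sum(ap_axis^2))
  len <- sqrt(dx^2 + dy^2)
  if (any(len == 0)) stop("zero-length chord has no angle")
  cosang <- pmin(1, abs(dx * ap[1] + dy * ap[2]) / len)
  acos(cosang) * 180 / pi
}

#' Classify a junction orientation
#'
#' Junctions are grouped by their angle to the AP axis into `vertical`
#' (DV-oriented), `transverse` (AP-oriented) and `oblique` classes. The
#' numeric cutoffs are a configurable analysis choice; defaults place
#' vertical at `[60, 90]` and transverse at `[0, 30]`.
#'
#' @param angle angle(s) in degrees, must lie in `[0, 90]`.
#' @param scheme list with numeric ranges `vertical` and `transverse`
#'   (inclusive bounds). The two ranges must not overlap.
#' @return character vector of labels in
#'   `c("vertical", "transverse", "oblique")`.
#' @export
classify_orientation <- function(angle,
                                 scheme = list(vertical = c(60, 90),
                                               transverse = c(0, 30))) {
  if (any(!is.finite(angle)) || any(angle < 0) || any(angle > 90)) {
    stop("angle must lie in [0, 90] degrees")
  }
  if (max(scheme$transverse) >= min(scheme$vertical)) {
    stop("vertical and transverse ranges overlap")
  }
  out <- rep("oblique", length(angle))
  out[angle >= scheme$vertical[1] & angle <= scheme$vertical[2]] <- "vertical"
  out[angle >= scheme$transverse[1] & angle <= scheme$transverse[2]] <- "transverse"
  out
}

#' Restrict a network to cells with exclusively three-fold vertices
#'
#' To guarantee that the dual tension network is a triangulation, force
#' inference only uses cells all of whose vertices are three-fold (exactly
#' three junctions meet). Cells touching the image frame are likewise
#' excluded, because their geometry (and hence force balance) is truncated.
#' Nothing is deleted: cells and junctions are flagged with `retained` and an
#' `exclude_reason` so that exclusion accounting stays complete.
#'
#' @param net a `tissue_network`.
#' @return the network with `retained`/`exclude_reason` columns added to
#'   `cells` and `junctions`.
#' @export
restrict_threefold <- function(net) {
  stopifnot(inherits(net, "tissue_network"))
  deg <- net$vertices$degree
  names(deg) <- as.character(net$vertices$id)

  nc <- nrow(net$cells)
  retained <- logical(nc)
  reason <- rep(NA_character_, nc)
  for (k in seq_len(nc)) {
    if (isTRUE(net$cells$boundary[k])) { reason[k] <- "boundary_cell"; next }
    vids <- net$cell_vertices[[as.character(net$cells$id[k])]]
    if (is.null(vids) || length(vids) < 3) { reason[k] <- "degenerate_cell"; next }
    jn <- net$junctions[net$junctions$id %in%
                          net$cell_junctions[[as.character(net$cells$id[k])]], ]
    if (any(is.na(jn$v1) | is.na(jn$v2))) { reason[k] <- "boundary_cell"; next }
    if (any(deg[as.character(vids)] != 3L)) { reason[k] <- "non_threefold_vertex"; next }
    retained[k] <- TRUE
  }
  net$cells$retained <- retained
  net$cells$exclude_reason <- reason

  kept_ids <- net$cells$id[retained]
  jret <- !is.na(net$junctions$cell_a) & !is.na(net$junctions$cell_b) &
    net$junctions$cell_a %in% kept_ids & net$junctions$cell_b %in% kept_ids &
    !net$junctions$boundary
  jreason <- rep(NA_character_, nrow(net$junctions))
  jreason[!jret & net$junctions$boundary] <- "boundary_junction"
  jreason[!jret & !net$junctions$boundary] <- "cell_excluded"
  net$junctions$retained <- jret
  net$junctions$exclude_reason <- jreason
  net
}

# positions of a junction's end vertices; list(p1, p2) or NULL if clipped
.junction_endpoints <- function(net, jrow) {
  v1 <- jrow$v1; v2 <- jrow$v2
  if (is.na(v1) || is.na(v2)) return(NULL)
  i1 <- match(v1, net$vertices$id); i2 <- match(v2, net$vertices$id)
  list(p1 = c(net$vertices$x[i1], net$vertices$y[i1]),
       p2 = c(net$vertices$x[i2], net$vertices$y[i2]))
}
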