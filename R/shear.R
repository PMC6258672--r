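#' Neighbour quadruple of a junction
#'
#' The tension of a junction shared by cells `a` and `b` splits into cortical
#' tensions carried by each cell's cortex. Requiring cortical tensions to be
#' continuous at the two end vertices links the central junction to the four
#' junctions that meet it there: with `d` the third cell at one end (vertex
#' "0") and `c` the third cell at the other end (vertex "L"),
#' `T1` is the junction between cells `b` and `d`, `T2` between `a` and `d`,
#' `T3` between `a` and `c`, and `T4` between `b` and `c`. `T1`/`T3` thus lie
#' on opposite cell sides at opposite ends (the diagonal pairing), which is
#' what makes their sums comparable in the shear formula.
#'
#' @param network a restricted `tissue_network`.
#' @param junction id of the central junction; both its end vertices must be
#'   three-fold and the junction interior.
#' @return list with `T1_id`, `T2_id`, `T3_id`, `T4_id`, `cell_a`, `cell_b`,
#'   `cell_c`, `cell_d`, `v0`, `vL`; or a list with `reason` when the
#'   junction is ineligible.
#' @export
neighbor_quadruple <- function(network, junction) {
  jn <- network$junctions
  i <- match(junction, jn$id)
  if (is.na(i)) return(list(reason = "unknown_junction"))
  if (isTRUE(jn$boundary[i]) || is.na(jn$cell_a[i]) || is.na(jn$cell_b[i])) {
    return(list(reason = "boundary_junction"))
  }
  v0 <- jn$v1[i]; vL <- jn$v2[i]
  if (is.na(v0) || is.na(vL)) return(list(reason = "boundary_junction"))
  deg <- stats::setNames(network$vertices$degree, as.character(network$vertices$id))
  if (deg[as.character(v0)] != 3 || deg[as.character(vL)] != 3) {
    return(list(reason = "non_threefold_vertex"))
  }
  a <- jn$cell_a[i]; b <- jn$cell_b[i]

  inc <- function(v) jn[((!is.na(jn$v1) & jn$v1 == v) |
                           (!is.na(jn$v2) & jn$v2 == v)) & jn$id != junction, ,
                        drop = FALSE]
  at0 <- inc(v0); atL <- inc(vL)
  if (nrow(at0) != 2 || nrow(atL) != 2) return(list(reason = "incomplete_vertex"))
  third <- function(two) {
    cc <- c(two$cell_a, two$cell_b)
    cc <- cc[!is.na(cc) & !(cc %in% c(a, b))]
    u <- unique(cc)
    if (length(u) == 1) u else NA_integer_
  }
  d <- third(at0); cc <- third(atL)
  if (is.na(d) || is.na(cc)) return(list(reason = "missing_third_cell"))

  pick <- function(two, c1, c2) {
    hit <- (two$cell_a %in% c(c1, c2)) & (two$cell_b %in% c(c1, c2))
    if (sum(hit, na.rm = TRUE) != 1) NA_integer_ else two$id[which(hit)]
  }
  T1 <- pick(at0, b, d); T2 <- pick(at0, a, d)
  T3 <- pick(atL, a, cc); T4 <- pick(atL, b, cc)
  if (any(is.na(c(T1, T2, T3, T4)))) return(list(reason = "missing_neighbor"))
  list(T1_id = T1, T2_id = T2, T3_id = T3, T4_id = T4,
       cell_a = a, cell_b = b, cell_c = cc, cell_d = d, v0 = v0, vL = vL)
}

#' Shear stress on junctions from neighbouring tensions
#'
#' The average shear stress along a junction is the mean gradient of the
#' cortical tension, which continuity at the vertices expresses through the
#' four neighbouring junction tensions:
#' \deqn{\tau = \frac{1}{2L} | (T_1 + T_3) - (T_2 + T_4) |,}
#' with `L` the junction length. The unsigned value is reported; the side
#' carrying the larger summed cortical tension is retained as metadata.
#' Junctions whose quadruple is incomplete or whose neighbours lack a
#' tension carry an exclusion reason, never a silent zero.
#'
#' @param network a restricted `tissue_network`.
#' @param tensions `inferred_tensions` object or data.frame with
#'   `junction_id`, `tension`.
#' @param junctions junction ids to evaluate; defaults to all junctions with
#'   a tension.
#' @return data.frame of class `shear_estimate`: `junction_id`, `tau`,
#'   `T1_id` ... `T4_id`, `T1` ... `T4`, `L`, `dominant_side` (`"T1T3"` or
#'   `"T2T4"` or `NA` on ties), `eligible`, `reason`.
#' @export
compute_shear <- function(network, tensions, junctions = NULL) {
  tdf <- if (inherits(tensions, "inferred_tensions")) tensions$tensions else tensions
  tmap <- stats::setNames(tdf$tension, as.character(tdf$junction_id))
  jn <- network$junctions
  if (is.null(junctions)) junctions <- tdf$junction_id

  out <- data.frame(junction_id = junctions, tau = NA_real_,
                    T1_id = NA_integer_, T2_id = NA_integer_,
                    T3_id = NA_integer_, T4_id = NA_integer_,
                    T1 = NA_real_, T2 = NA_real_, T3 = NA_real_, T4 = NA_real_,
                    L = NA_real_, dominant_side = NA_character_,
                    eligible = FALSE, reason = NA_character_)
  for (k in seq_along(junctions)) {
    j <- junctions[k]
    q <- neighbor_quadruple(network, j)
    if (!is.null(q$reason)) { out$reason[k] <- q$reason; next }
    tt <- tmap[as.character(c(q$T1_id, q$T2_id, q$T3_id, q$T4_id))]
    if (any(is.na(tt))) { out$reason[k] <- "neighbor_without_tension"; next }
    L <- jn$length[match(j, jn$id)]
    if (!is.finite(L) || L <= 0) stop("junction length must be positive")
    s13 <- tt[1] + tt[3]; s24 <- tt[2] + tt[4]
    out[k, c("T1_id", "T2_id", "T3_id", "T4_id")] <-
      c(q$T1_id, q$T2_id, q$T3_id, q$T4_id)
    out[k, c("T1", "T2", "T3", "T4")] <- tt
    out$L[k] <- L
    out$tau[k] <- abs(s13 - s24) / (2 * L)
    out$dominant_side[k] <- if (s13 > s24) "T1T3" else if (s24 > s13) "T2T4"
      else NA_character_
    out$eligible[k] <- TRUE
  }
  class(out) <- c("shear_estimate", class(out))
  out
}
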