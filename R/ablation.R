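#' Initial recoil velocity of an ablated junction
#'
#' The separation speed of the two endpoint vertices of a cut junction over
#' a short window after the ablation is a standard proxy for the tension the
#' junction carried. The velocity is
#' `(d(t0 + window) - d(t0)) / window` with `d` the inter-endpoint distance.
#' When no track point exists exactly at a requested time, the nearest frame
#' within `tolerance_s` is used with a warning; beyond that it is an error.
#'
#' @param event an `ablation_event` (see [simulate_ablation()]) or any list
#'   with `tracks` (data.frame `t`, `vertex`, `x`, `y` for the two endpoint
#'   vertices) and `t0` (ablation time, s).
#' @param window_s recoil window in seconds (default 2).
#' @param tolerance_s nearest-frame matching tolerance (default 0.5).
#' @return recoil velocity (distance units per second).
#' @export
recoil_velocity <- function(event, window_s = 2, tolerance_s = 0.5) {
  tr <- event$tracks
  t0 <- if (!is.null(event$t0)) event$t0 else 0
  verts <- unique(tr$vertex)
  if (length(verts) != 2) stop("tracks must cover exactly two endpoint vertices")
  d_at <- function(tt) {
    p <- lapply(verts, function(v) {
      sub <- tr[tr$vertex == v, ]
      i <- which.min(abs(sub$t - tt))
      dtt <- abs(sub$t[i] - tt)
      if (dtt > tolerance_s) {
        stop(sprintf("no track point within %.2f s of t = %.2f s",
                     tolerance_s, tt))
      }
      if (dtt > 1e-9) {
        warning(sprintf("using nearest frame %.2f s for requested %.2f s",
                        sub$t[i], tt))
      }
      c(sub$x[i], sub$y[i])
    })
    sqrt(sum((p[[1]] - p[[2]])^2))
  }
  (d_at(t0 + window_s) - d_at(t0)) / window_s
}

#' Neighbour-normalised junction intensity
#'
#' The ablated junction's line density divided by the mean line density of
#' the neighbouring junctions, per frame. Normalisation against 20 or more
#' neighbours is required to suppress embryo-to-embryo intensity variation.
#'
#' @param event an `ablation_event` with `densities` (data.frame `t`,
#'   `junction_id`, `channel`, `density`) and `junction` (ablated id).
#' @param channel channel name to normalise.
#' @param min_neighbors minimum neighbour count (default 20).
#' @return data.frame `t`, `ratio`.
#' @export
normalized_junction_intensity <- function(event, channel = "ecadherin",
                                          min_neighbors = 20) {
  dd <- event$densities
  if (is.null(dd)) stop("event carries no densities")
  dd <- dd[dd$channel == channel, ]
  out <- lapply(split(dd, dd$t), function(fr) {
    abl <- fr$density[fr$junction_id == event$junction]
    nb <- fr$density[fr$junction_id != event$junction & is.finite(fr$density)]
    if (length(nb) < min_neighbors) {
      stop("need at least ", min_neighbors, " neighbouring junction densities")
    }
    data.frame(t = fr$t[1], ratio = abl / mean(nb))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$t), ]
}

#' Select junctions whose shear increases after an ablation
#'
#' Cutting a junction releases its tension, which increases the asymmetry of
#' the neighbouring cortical tensions on any adjacent junction where the cut
#' junction sat on the weaker side. Concretely, a junction adjacent to the
#' ablated one is selected iff, in its own neighbour quadruple,
#' `(T1 + T3) > (T2 + T4)` (strict) and the ablated junction plays the role
#' of `T2` or `T4`. Ineligible candidates are skipped with a reason.
#'
#' @param network a restricted `tissue_network`.
#' @param tensions pre-ablation `inferred_tensions` or data.frame
#'   (`junction_id`, `tension`).
#' @param ablated_junction id of the cut junction.
#' @return data.frame `junction_id`, `selected`, `role` (`"T2"`, `"T4"`,
#'   `"T1"`, `"T3"` or `NA`), `reason` for skipped candidates.
#' @export
select_shear_increase <- function(network, tensions, ablated_junction) {
  jn <- network$junctions
  arow <- jn[jn$id == ablated_junction, ]
  if (nrow(arow) != 1) stop("unknown ablated junction")
  vset <- stats::na.omit(c(arow$v1, arow$v2))
  cand <- jn$id[(jn$v1 %in% vset | jn$v2 %in% vset) & jn$id != ablated_junction]
  cand <- unique(cand[!is.na(cand)])

  out <- data.frame(junction_id = cand, selected = FALSE,
                    role = NA_character_, reason = NA_character_)
  for (k in seq_along(cand)) {
    q <- neighbor_quadruple(network, cand[k])
    if (!is.null(q$reason)) { out$reason[k] <- q$reason; next }
    ids <- c(T1 = q$T1_id, T2 = q$T2_id, T3 = q$T3_id, T4 = q$T4_id)
    tdf <- if (inherits(tensions, "inferred_tensions")) tensions$tensions else tensions
    tmap <- stats::setNames(tdf$tension, as.character(tdf$junction_id))
    tt <- tmap[as.character(ids)]
    if (any(is.na(tt))) { out$reason[k] <- "neighbor_without_tension"; next }
    role <- names(ids)[ids == ablated_junction]
    out$role[k] <- if (length(role)) role[1] else NA_character_
    s13 <- tt[1] + tt[3]; s24 <- tt[2] + tt[4]
    # the quadruple labelling is relative to an arbitrary side assignment:
    # relabelling a<->b maps (T1,T3)<->(T2,T4), so "ablate T2 or T4 when
    # (T1+T3) dominates" and its mirror image are the same physical rule --
    # the cut junction must sit on the strictly weaker diagonal
    out$selected[k] <- length(role) > 0 &&
      ((role[1] %in% c("T2", "T4") && s13 > s24) ||
         (role[1] %in% c("T1", "T3") && s24 > s13))
  }
  out
}

#' Relative change of a time series over a fixed window
#'
#' `(v(t0 + dt) - v(t0)) / v(t0)`, with nearest-frame matching within
#' `tolerance_s`.
#'
#' @param series data.frame with columns `t` and `value`, or a numeric
#'   vector with times in `names`.
#' @param t0 window start time (s).
#' @param dt window length in seconds (default 20).
#' @param tolerance_s nearest-frame matching tolerance (default 0.5).
#' @return relative change (dimensionless fraction).
#' @export
relative_change <- function(series, t0 = 0, dt = 20, tolerance_s = 0.5) {
  if (is.numeric(series) && !is.null(names(series))) {
    series <- data.frame(t = as.numeric(names(series)), value = unname(series))
  }
  v_at <- function(tt) {
    i <- which.min(abs(series$t - tt))
    if (abs(series$t[i] - tt) > tolerance_s) {
      stop(sprintf("no frame within %.2f s of t = %.2f s", tolerance_s, tt))
    }
    series$value[i]
  }
  v0 <- v_at(t0)
  if (!is.finite(v0) || v0 == 0) stop("initial value is zero or undefined")
  (v_at(t0 + dt) - v0) / v0
}
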