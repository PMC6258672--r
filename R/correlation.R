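#' Length-conditioned (conditional) correlation
#'
#' Junctional line densities and inferred tensions are all roughly
#' proportional to the inverse of junction length, so any two of them
#' correlate spuriously through length. Conditioning removes the confound:
#' within each snapshot, junctions are sorted by length (ties broken by
#' index, deterministically) and chunked into bins of exactly `bin_size`
#' junctions of adjacent length (the remainder is dropped); a correlation
#' coefficient is computed inside every bin, where length is effectively
#' constant. Pooling the per-bin coefficients across snapshots gives the
#' conditional-correlation distribution; grouping bins by their rounded mean
#' length gives the by-length curve.
#'
#' @param x,y numeric vectors, one value per junction.
#' @param lengths junction lengths, same order.
#' @param snapshot optional snapshot/frame identifier per junction; binning
#'   is performed independently within each snapshot.
#' @param bin_size junctions per bin (default 10).
#' @param method `"pearson"` or `"spearman"`.
#' @param length_resolution rounding (px) used to group bins of equal length
#'   for the by-length curve.
#' @return list of class `conditional_correlation`: data.frame `bins`
#'   (`snapshot`, `bin`, `mean_length`, `r`, `n`), `coefficients` (pooled
#'   vector), `median`, `by_length` (data.frame `length`, `mean_r`, `se_r`,
#'   `n_bins`), `bin_size`, `method`.
#' @export
conditional_correlation <- function(x, y, lengths, snapshot = NULL,
                                    bin_size = 10,
                                    method = c("pearson", "spearman"),
                                    length_resolution = 1) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(y) == n, length(lengths) == n)
  if (is.null(snapshot)) snapshot <- rep(1L, n)

  rows <- list()
  for (s in unique(snapshot)) {
    sel <- which(snapshot == s)
    if (length(sel) < bin_size) {
      warning("snapshot ", s, " has fewer than ", bin_size,
              " junctions; skipped")
      next
    }
    ord <- sel[order(lengths[sel], sel)]
    nb <- length(ord) %/% bin_size
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * bin_size + 1):(b * bin_size)]
      r <- suppressWarnings(stats::cor(x[idx], y[idx], method = method))
      rows[[length(rows) + 1]] <- data.frame(
        snapshot = s, bin = b, mean_length = mean(lengths[idx]),
        r = r, n = bin_size)
    }
  }
  bins <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snapshot = integer(0), bin = integer(0),
               mean_length = numeric(0), r = numeric(0), n = integer(0))
  co <- bins$r[is.finite(bins$r)]

  by_len <- NULL
  if (nrow(bins)) {
    key <- round(bins$mean_length / length_resolution) * length_resolution
    mu <- tapply(bins$r, key, mean, na.rm = TRUE)
    se <- tapply(bins$r, key, function(v) {
      v <- v[is.finite(v)]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    })
    nb <- tapply(bins$r, key, length)
    by_len <- data.frame(length = as.numeric(names(mu)),
                         mean_r = as.numeric(mu), se_r = as.numeric(se),
                         n_bins = as.integer(nb))
  }
  structure(list(bins = bins, coefficients = co,
                 median = if (length(co)) stats::median(co) else NA_real_,
                 by_length = by_len, bin_size = bin_size, method = method),
            class = "conditional_correlation")
}

#' Per-cell (local) correlation with a permutation null
#'
#' Correlating two junctional quantities within each cell is immune to slow
#' spatial and temporal intensity drift: only junctions of the same cell,
#' imaged together, enter each coefficient. Cells with fewer than
#' `min_junctions` junctions carrying both values are excluded and counted.
#' The statistical null is built by permuting the `y` values across all
#' junctions of the snapshot (which preserves the per-cell topology and both
#' marginal distributions) and recomputing the per-cell coefficients;
#' `n_null` seeded permutations give a pooled null distribution and a
#' distribution of null medians.
#'
#' @param network a `tissue_network` (its `cell_junctions` incidence is used;
#'   only retained cells when `restrict_threefold` flags are present).
#' @param x,y named numeric vectors (names = junction ids) or plain vectors
#'   aligned with `network$junctions$id`.
#' @param min_junctions minimum junctions per cell (default 4).
#' @param n_null number of null permutations.
#' @param seed integer seed for the permutations.
#' @return list of class `local_correlation`: data.frame `cells` (`cell_id`,
#'   `r`, `n_junctions`), `median`, `null_r` (pooled), `null_medians`,
#'   `n_excluded_cells`, `p_greater` (one-sided Mann-Whitney p of observed
#'   per-cell r against the pooled null).
#' @export
local_correlation <- function(network, x, y, min_junctions = 4,
                              n_null = 1000, seed = 1) {
  jids <- network$junctions$id
  if (is.null(names(x))) names(x) <- as.character(jids)
  if (is.null(names(y))) names(y) <- as.character(jids)

  cells <- network$cells
  if (!is.null(cells$retained)) cells <- cells[cells$retained, , drop = FALSE]
  groups <- list()
  for (cid in cells$id) {
    jj <- as.character(network$cell_junctions[[as.character(cid)]])
    jj <- jj[jj %in% names(x) & jj %in% names(y)]
    jj <- jj[is.finite(x[jj]) & is.finite(y[jj])]
    if (length(jj) >= min_junctions) groups[[as.character(cid)]] <- jj
  }
  n_excl <- nrow(cells) - length(groups)
  if (!length(groups)) {
    return(structure(list(cells = data.frame(cell_id = integer(0), r = numeric(0),
                                             n_junctions = integer(0)),
                          median = NA_real_, null_r = numeric(0),
                          null_medians = numeric(0),
                          n_excluded_cells = n_excl, p_greater = NA_real_,
                          empty = TRUE),
                     class = "local_correlation"))
  }

  percell_r <- function(yv) {
    vapply(groups, function(jj) {
      suppressWarnings(stats::cor(x[jj], yv[jj]))
    }, numeric(1))
  }
  robs <- percell_r(y)

  null_r <- NULL; null_med <- NULL
  if (n_null > 0) {
    set.seed(seed)
    pool <- names(y)
    null_r <- matrix(NA_real_, length(groups), n_null)
    for (p in seq_len(n_null)) {
      yp <- y
      names(yp) <- sample(pool)
      null_r[, p] <- percell_r(yp)
    }
    null_med <- apply(null_r, 2, stats::median, na.rm = TRUE)
    null_r <- as.vector(null_r)
    null_r <- null_r[is.finite(null_r)]
  }

  pg <- NA_real_
  if (length(null_r) && sum(is.finite(robs)) > 1) {
    pg <- stats::wilcox.test(robs[is.finite(robs)], null_r,
                             alternative = "greater", exact = FALSE)$p.value
  }
  structure(list(
    cells = data.frame(cell_id = as.integer(names(groups)),
                       r = unname(robs),
                       n_junctions = vapply(groups, length, integer(1))),
    median = stats::median(robs, na.rm = TRUE),
    null_r = null_r, null_medians = null_med,
    n_excluded_cells = n_excl, p_greater = pg
  ), class = "local_correlation")
}

#' Bootstrap distribution of the sample mean
#'
#' @param values numeric vector (n >= 1).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @return numeric vector of `n_boot` resample means.
#' @export
bootstrap_mean <- function(values, n_boot = 10000, seed = 1) {
  n <- length(values)
  if (n < 1) stop("need at least one value")
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  rowMeans(matrix(values[idx], nrow = n_boot))
}

#' Correlation-method choice rule
#'
#' Small samples do not justify the linearity assumption of Pearson
#' correlation, so rank (Spearman) correlation is used below 100 points.
#'
#' @param n_points number of data points.
#' @param override `NULL`, `"pearson"` or `"spearman"` to force a method.
#' @return `"spearman"` or `"pearson"`.
#' @export
choose_method <- function(n_points, override = NULL) {
  if (!is.null(override)) {
    return(match.arg(override, c("pearson", "spearman")))
  }
  if (n_points < 100) "spearman" else "pearson"
}
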