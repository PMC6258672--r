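#' Rasterise junction paths into an id image
#'
#' Paints every junction path into an integer image and expands each painted
#' curve by `halfwidth` rounds of 8-neighbour dilation (pixels keep the id of
#' the nearest painted path in BFS order, with deterministic tie-breaking),
#' then clears a disk of `vertex_radius` pixels around every vertex so that
#' tri-cellular regions never contribute to junctional measurements. This is
#' the single rasteriser shared by the image renderer and the ROI extractor,
#' so a rendered band is by construction a superset of the matching ROI.
#'
#' @param network a `tissue_network` registered to the image.
#' @param dim image dimensions `c(width, height)` in pixels.
#' @param halfwidth number of dilation rounds (band half-width in px).
#' @param vertex_radius exclusion radius around vertices (px); 0 disables.
#' @return integer matrix `[x, y]`, 0 where no junction claims the pixel.
#' @export
junction_pixel_map <- function(network, dim, halfwidth = 2, vertex_radius = 0) {
  W <- as.integer(dim[1]); H <- as.integer(dim[2])
  idimg <- matrix(0L, W, H)

  for (i in seq_len(nrow(network$junctions))) {
    jid <- network$junctions$id[i]
    path <- network$paths[[as.character(jid)]]
    if (is.null(path)) {
      ep <- .junction_endpoints(network, network$junctions[i, ])
      if (is.null(ep)) next
      path <- rbind(ep$p1, ep$p2)
    }
    pix <- .rasterize_path(path)
    ok <- pix[, 1] >= 1 & pix[, 1] <= W & pix[, 2] >= 1 & pix[, 2] <= H
    pix <- pix[ok, , drop = FALSE]
    free <- idimg[pix] == 0L
    idimg[pix[free, , drop = FALSE]] <- jid
  }

  if (halfwidth > 0) {
    shifts <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                    c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
    for (round in seq_len(halfwidth)) {
      cur <- idimg
      for (si in seq_len(nrow(shifts))) {
        sh <- .shift_matrix(cur, shifts[si, 1], shifts[si, 2])
        take <- idimg == 0L & sh > 0L
        idimg[take] <- sh[take]
      }
    }
  }

  if (vertex_radius > 0 && nrow(network$vertices) > 0) {
    r <- vertex_radius
    for (i in seq_len(nrow(network$vertices))) {
      vx <- network$vertices$x[i]; vy <- network$vertices$y[i]
      x_lo <- max(1, floor(vx - r)); x_hi <- min(W, ceiling(vx + r))
      y_lo <- max(1, floor(vy - r)); y_hi <- min(H, ceiling(vy + r))
      if (x_lo > x_hi || y_lo > y_hi) next
      xs <- x_lo:x_hi; ys <- y_lo:y_hi
      dd <- outer((xs - vx)^2, (ys - vy)^2, "+")
      sub <- idimg[xs, ys, drop = FALSE]
      sub[dd <= r^2] <- 0L
      idimg[xs, ys] <- sub
    }
  }
  idimg
}

# integer pixels along a polyline, sampled densely then uniqued in order
.rasterize_path <- function(path) {
  segs <- list()
  for (k in seq_len(nrow(path) - 1)) {
    p <- path[k, ]; q <- path[k + 1, ]
    n <- max(2, ceiling(sqrt(sum((q - p)^2)) * 4))
    tt <- seq(0, 1, length.out = n)
    segs[[k]] <- cbind(round(p[1] + tt * (q[1] - p[1])),
                       round(p[2] + tt * (q[2] - p[2])))
  }
  pix <- do.call(rbind, segs)
  pix[!duplicated(pix), , drop = FALSE]
}

.shift_matrix <- function(m, dx, dy) {
  W <- nrow(m); H <- ncol(m)
  out <- matrix(0L, W, H)
  xs_src <- max(1, 1 - dx):min(W, W - dx)
  ys_src <- max(1, 1 - dy):min(H, H - dy)
  out[xs_src + dx, ys_src + dy] <- m[xs_src, ys_src]
  out
}

#' Extract junctional and medial regions of interest
#'
#' Junctional ROIs are bands of about `junction_width` pixels around each
#' junction path with tri-cellular vertex disks excluded; medial ROIs are
#' cell interiors at least `medial_margin` pixels away from any junctional
#' ROI pixel or vertex disk. The two ROI classes are disjoint by
#' construction.
#'
#' @param network a `tissue_network` carrying a label image (`network$labels`)
#'   or accompanied by `labels`.
#' @param dim image dimensions; defaults to `dim(labels)`.
#' @param junction_width full band width in px (default 5).
#' @param vertex_radius vertex exclusion radius in px (default 3).
#' @param medial_margin minimum distance (px) between medial pixels and any
#'   junctional ROI pixel (default 2).
#' @param labels integer label image (cell id per pixel, 0 = boundary).
#' @return list of class `roi_map`: `junctional` and `medial` integer images,
#'   `empty_junctions` and `empty_cells` (ids whose ROI came out empty,
#'   flagged rather than silently dropped), and the parameters used.
#' @export
extract_rois <- function(network, dim = NULL, junction_width = 5,
                         vertex_radius = 3, medial_margin = 2,
                         labels = network$labels) {
  if (is.null(labels) && is.null(dim)) stop("need a label image or explicit dim")
  if (is.null(dim)) dim <- base::dim(labels)
  hw <- floor(junction_width / 2)
  jroi <- junction_pixel_map(network, dim, halfwidth = hw,
                             vertex_radius = vertex_radius)
  empty_j <- setdiff(network$junctions$id, unique(as.vector(jroi)))

  medial <- NULL; empty_c <- integer(0)
  if (!is.null(labels)) {
    jmask <- (jroi > 0) * 1
    # also exclude vertex disks from the medial distance computation
    vmask <- junction_pixel_map(network, dim, halfwidth = hw, vertex_radius = 0)
    jmask[vmask > 0 & jroi == 0] <- 1   # vertex-disk pixels count as junctional
    D <- as.matrix(EBImage::distmap(1 - jmask))
    medial <- labels
    medial[D < medial_margin | jmask > 0] <- 0L
    empty_c <- setdiff(setdiff(unique(as.vector(labels)), 0L),
                       unique(as.vector(medial)))
  }

  structure(list(junctional = jroi, medial = medial,
                 empty_junctions = empty_j, empty_cells = empty_c,
                 junction_width = junction_width,
                 vertex_radius = vertex_radius,
                 medial_margin = medial_margin),
            class = "roi_map")
}

#' Mean channel densities over ROIs
#'
#' Line density of a junction is the mean pixel intensity over its junctional
#' ROI; the medial area density of a cell is the mean over its medial ROI.
#' Empty ROIs yield `NaN` and are flagged.
#'
#' @param image 2-D intensity image (same dimensions as the ROI maps).
#' @param rois an `roi_map` from [extract_rois()].
#' @return list of class `channel_densities` with data.frames `junctions`
#'   (`junction_id`, `density`, `n_pixels`, `empty`) and `cells`
#'   (`cell_id`, `density`, `n_pixels`, `empty`).
#' @export
roi_density <- function(image, rois) {
  stopifnot(inherits(rois, "roi_map"))
  if (!all(dim(image) == dim(rois$junctional))) {
    stop("image and ROI map dimensions differ")
  }
  jt <- .roi_means(image, rois$junctional)
  if (length(rois$empty_junctions)) {
    jt <- rbind(jt, data.frame(id = rois$empty_junctions, density = NaN,
                               n_pixels = 0L, empty = TRUE))
    jt <- jt[order(jt$id), ]
  }
  names(jt)[1] <- "junction_id"
  out <- list(junctions = jt)
  if (!is.null(rois$medial)) {
    ct <- .roi_means(image, rois$medial)
    if (length(rois$empty_cells)) {
      ct <- rbind(ct, data.frame(id = rois$empty_cells, density = NaN,
                                 n_pixels = 0L, empty = TRUE))
      ct <- ct[order(ct$id), ]
    }
    names(ct)[1] <- "cell_id"
    out$cells <- ct
  }
  structure(out, class = "channel_densities")
}

.roi_means <- function(image, idimg) {
  sel <- idimg > 0
  ids <- idimg[sel]
  if (!length(ids)) {
    return(data.frame(id = integer(0), density = numeric(0),
                      n_pixels = integer(0), empty = logical(0)))
  }
  mu <- tapply(image[sel], ids, mean)
  n <- tapply(image[sel], ids, length)
  data.frame(id = as.integer(names(mu)), density = as.numeric(mu),
             n_pixels = as.integer(n), empty = FALSE)
}

#' Planar-polarity profile from junction line densities
#'
#' Junctions are grouped into six 15-degree angle bins (0-15, ..., 75-90
#' relative to the AP axis); the averaged line density (ALD) is the mean of
#' the junction line densities within each bin. The PCP amplitude is the
#' ratio of the two extreme bins, reported in the requested orientation
#' (`"DV/AP"` divides the 75-90 ALD by the 0-15 ALD). The relative-intensity
#' profile normalises all six ALDs by the smaller of the two extreme bins,
#' so it is >= 1 at one extreme by construction.
#'
#' @param densities numeric vector of junction line densities.
#' @param angles matching junction angles in degrees, in `[0, 90]`.
#' @param mode `"DV/AP"` or `"AP/DV"` orientation of the PCP ratio.
#' @return list of class `polarity_profile`: `ald` (named length-6 vector),
#'   `n_per_bin`, `pcp`, `mode`, `relative_intensity`.
#' @export
polarity_profile <- function(densities, angles, mode = c("DV/AP", "AP/DV")) {
  mode <- match.arg(mode)
  ok <- is.finite(densities) & is.finite(angles)
  densities <- densities[ok]; angles <- angles[ok]
  if (any(angles < 0 | angles > 90)) stop("angles must lie in [0, 90]")
  edges <- seq(0, 90, by = 15)
  bin <- cut(angles, breaks = edges, include.lowest = TRUE, right = FALSE)
  bin[angles == 90] <- levels(bin)[6]
  ald <- tapply(densities, bin, mean)
  n <- tapply(densities, bin, length)
  n[is.na(n)] <- 0
  labels <- c("0-15", "15-30", "30-45", "45-60", "60-75", "75-90")
  names(ald) <- names(n) <- labels
  if (n[["0-15"]] == 0) stop("empty extreme angle bin: 0-15")
  if (n[["75-90"]] == 0) stop("empty extreme angle bin: 75-90")
  lo <- ald[["0-15"]]; hi <- ald[["75-90"]]
  if (min(lo, hi) <= 0) stop("extreme-bin ALD must be positive for a PCP ratio")
  pcp <- if (mode == "DV/AP") hi / lo else lo / hi
  structure(list(ald = ald, n_per_bin = as.integer(n), pcp = unname(pcp),
                 mode = mode, relative_intensity = ald / min(lo, hi)),
            class = "polarity_profile")
}

#' Focus-resolved projection of a fluorescence z-stack
#'
#' Selects the in-focus plane by a per-tile Sobel gradient-energy metric
#' (the plane with the largest median tile score), builds the signal image as
#' the maximum-intensity projection of that plane plus the next two basal
#' planes, builds the background image as the maximum projection of the
#' basal-most three planes followed by a large-radius median filter, and
#' returns `pmax(signal - background, 0)`. The z index is assumed to
#' increase towards the basal side.
#'
#' @param zstack 3-D array `[x, y, z]` with at least 3 planes (>= 6
#'   recommended so that signal and background planes can differ).
#' @param tile tile size (px) of the focus metric.
#' @param bg_radius median-filter radius (px) for the background image.
#' @return list of class `processed_image`: `image`, `focus_plane`,
#'   `signal`, `background`.
#' @export
preprocess_stack <- function(zstack, tile = 64, bg_radius = 50) {
  d <- dim(zstack)
  if (length(d) != 3 || d[3] < 3) stop("stack must have at least 3 z-planes")
  Z <- d[3]
  scores <- vapply(seq_len(Z), function(z) {
    .focus_score(zstack[, , z], tile)
  }, numeric(1))
  k <- which.max(scores)
  sig_planes <- k:min(k + 2, Z)
  signal <- apply(zstack[, , sig_planes, drop = FALSE], c(1, 2), max)
  bgp <- max(1, Z - 2):Z
  bg <- apply(zstack[, , bgp, drop = FALSE], c(1, 2), max)
  bg <- median_filter(bg, bg_radius)
  structure(list(image = pmax(signal - bg, 0), focus_plane = k,
                 signal = signal, background = bg),
            class = "processed_image")
}

# median tile score of Sobel gradient energy
.focus_score <- function(img, tile) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(img, kx))
  gy <- as.matrix(EBImage::filter2(img, t(kx)))
  g2 <- gx^2 + gy^2
  W <- nrow(g2); H <- ncol(g2)
  tx <- pmin((seq_len(W) - 1) %/% tile + 1, max(1, W %/% tile))
  ty <- pmin((seq_len(H) - 1) %/% tile + 1, max(1, H %/% tile))
  idx <- outer(tx, (ty - 1) * max(tx), "+")
  stats::median(tapply(g2, idx, mean))
}

#' Median filter with arbitrary radius
#'
#' Thin wrapper around `EBImage::medianFilter` that rescales to the unit
#' interval (the EBImage implementation requires it) and guards constant
#' images.
#'
#' @param img numeric matrix.
#' @param radius filter radius in px.
#' @return filtered matrix, same dimensions.
#' @export
median_filter <- function(img, radius) {
  if (radius < 1) return(img)
  lo <- min(img); hi <- max(img)
  if (hi - lo < 1e-12) return(img)
  sc <- (img - lo) / (hi - lo)
  out <- as.matrix(EBImage::medianFilter(sc, size = radius))
  out * (hi - lo) + lo
}

#' Pixel-scale ratio profile of two registered channels
#'
#' Identifies marker-positive pixels by a signal-to-noise criterion on the
#' denominator channel (SNR = (I - local median background) / robust noise
#' scale, with the noise scale 1.4826 x MAD of the background-subtracted
#' intensities over non-junctional pixels), keeps pixels with SNR > 1
#' (optionally restricted to a junctional mask), bins them by denominator
#' intensity in contiguous bins of fixed width, and reports the mean
#' per-pixel ratio per bin.
#'
#' @param num_image numerator channel (e.g. Vinculin), 2-D matrix.
#' @param den_image denominator channel (e.g. E-cadherin), same dimensions.
#' @param junction_mask optional logical matrix restricting the analysis to
#'   junctional pixels; also defines the non-junctional pixels used for the
#'   noise estimate.
#' @param bin_width intensity bin width in a.u. (default 25).
#' @param bg_radius median-filter radius of the local background model.
#' @param snr_threshold minimum SNR for a pixel to qualify.
#' @return list of class `pixel_ratio_profile`: data.frame `bins`
#'   (`bin_lo`, `bin_hi`, `mean_ratio`, `n_pixels`), `snr_threshold`,
#'   `noise_scale`, `empty` flag.
#' @export
pixel_ratio_profile <- function(num_image, den_image, junction_mask = NULL,
                                bin_width = 25, bg_radius = 50,
                                snr_threshold = 1) {
  stopifnot(all(dim(num_image) == dim(den_image)))
  bg <- median_filter(den_image, bg_radius)
  resid <- den_image - bg
  noise_pix <- if (is.null(junction_mask)) resid else resid[!junction_mask]
  scale <- 1.4826 * stats::mad(noise_pix, constant = 1)
  if (scale <= 0) scale <- stats::sd(noise_pix)
  if (!is.finite(scale) || scale <= 0) scale <- 1e-9
  snr <- resid / scale
  sel <- snr > snr_threshold & den_image > 0
  if (!is.null(junction_mask)) sel <- sel & junction_mask
  if (!any(sel)) {
    return(structure(list(bins = data.frame(bin_lo = numeric(0),
                                            bin_hi = numeric(0),
                                            mean_ratio = numeric(0),
                                            n_pixels = integer(0)),
                          snr_threshold = snr_threshold,
                          noise_scale = scale, empty = TRUE),
                     class = "pixel_ratio_profile"))
  }
  den <- den_image[sel]; num <- num_image[sel]
  ratio <- num / den
  bidx <- floor(den / bin_width)
  mu <- tapply(ratio, bidx, mean)
  n <- tapply(ratio, bidx, length)
  lo <- as.numeric(names(mu)) * bin_width
  structure(list(bins = data.frame(bin_lo = lo, bin_hi = lo + bin_width,
                                   mean_ratio = as.numeric(mu),
                                   n_pixels = as.integer(n)),
                 snr_threshold = snr_threshold, noise_scale = scale,
                 empty = FALSE),
            class = "pixel_ratio_profile")
}
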