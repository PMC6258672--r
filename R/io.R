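#' Write a tissue network to a structured JSON file
#'
#' Coordinates are in pixels; the schema is versioned. Paths are stored as
#' flat coordinate arrays per junction.
#'
#' @param net a `tissue_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  obj <- list(
    schema = "tissue_network", schema_version = net$schema_version,
    pixel_size = net$pixel_size, ap_axis = net$ap_axis,
    vertices = net$vertices, junctions = net$junctions, cells = net$cells,
    cell_junctions = net$cell_junctions, cell_vertices = net$cell_vertices,
    paths = lapply(net$paths, function(p) as.vector(t(p)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a tissue network written by [write_network()]
#'
#' @param path JSON file path.
#' @return a `tissue_network`.
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "tissue_network")) {
    stop("not a tissue_network file")
  }
  paths <- lapply(obj$paths, function(v) matrix(unlist(v), ncol = 2, byrow = TRUE))
  cj <- lapply(obj$cell_junctions, unlist)
  cv <- lapply(obj$cell_vertices, unlist)
  tissue_network(as.data.frame(obj$vertices), as.data.frame(obj$junctions),
                 as.data.frame(obj$cells), paths = paths,
                 cell_junctions = cj, cell_vertices = cv,
                 pixel_size = obj$pixel_size, ap_axis = unlist(obj$ap_axis))
}

#' Write inferred tensions as CSV with a metadata sidecar
#'
#' The CSV has one row per junction (`junction_id`, `cell_a`, `cell_b`,
#' `tension`, `length`, `angle`, `component`); the Lagrange-multiplier
#' eigenvalue(s) and normalisation constants go to `<path>.meta.json`.
#'
#' @param tensions an `inferred_tensions` object.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_tensions <- function(tensions, path) {
  utils::write.csv(tensions$tensions, path, row.names = FALSE)
  jsonlite::write_json(
    list(schema = "inferred_tensions", schema_version = tensions$schema_version,
         lambda = tensions$lambda, normalization = tensions$normalization,
         n_excluded = nrow(tensions$excluded),
         excluded_reasons = as.list(table(tensions$excluded$reason))),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a grayscale image (TIFF or PNG) as an `[x, y]` matrix
#'
#' 8/16-bit images come back on their native integer scale; floating-point
#' TIFFs are passed through. The row/column layout of the readers is
#' transposed so that the first index is the image x (column) coordinate.
#'
#' @param path image file.
#' @param as_probability rescale integer data to `[0, 1]`.
#' @return numeric matrix `[x, y]`.
#' @export
read_gray_image <- function(path, as_probability = FALSE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = !as_probability),
    png = {
      x <- png::readPNG(path)
      if (!as_probability) x * 255 else x
    },
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3) img <- img[, , 1]
  t(img)[, , drop = TRUE]
}

#' Write a matrix as a grayscale image
#'
#' @param img numeric matrix `[x, y]`.
#' @param path output path (`.tif`/`.tiff` or `.png`).
#' @param max_value scale used to map to the unit interval before writing.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path, max_value = max(img, 1)) {
  m <- t(pmin(pmax(img / max_value, 0), 1))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = 16),
    png = png::writePNG(m, path),
    stop("unsupported image format: ", ext))
  invisible(path)
}
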