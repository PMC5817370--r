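# Raster I/O. CT/SUV rasters can be read from PNG (gray, rescaled to
# [0, 255]), NIfTI (values used as stored; SUV maps should use this or a
# delimited text matrix so that absolute SUV units survive), or CSV/TSV
# numeric matrices. Masks are written as 8-bit PNG with values {0, 255}.

#' Read a 2D raster
#'
#' @param path file ending in `.png`, `.nii`, `.nii.gz`, `.csv` or `.tsv`.
#' @param scale255 for PNG input, multiply the `[0, 1]` gray values by 255.
#' @return A numeric matrix.
#' @export
read_raster <- function(path, scale255 = TRUE) {
  if (!file.exists(path)) {
    stop_petct(sprintf("input file not found: %s", path), "input_error")
  }
  lp <- tolower(path)
  if (grepl("\\.png$", lp)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    if (scale255) img <- img * 255
    return(unclass(img))
  }
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) > 2) arr <- arr[, , 1]
    return(matrix(as.numeric(arr), nrow(arr), ncol(arr)))
  }
  if (grepl("\\.csv$", lp)) {
    return(as.matrix(read.csv(path, header = FALSE)))
  }
  if (grepl("\\.tsv$", lp)) {
    return(as.matrix(read.delim(path, header = FALSE)))
  }
  stop_petct(sprintf("unsupported raster format: %s", path), "input_error")
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask 0/1 raster.
#' @param path output path ending in `.png`.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' Any pixel above half intensity counts as foreground.
#'
#' @param path PNG path.
#' @return 0/1 integer raster.
#' @export
read_mask_png <- function(path) {
  m <- read_raster(path, scale255 = FALSE)
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' Write a contour polyline as CSV
#'
#' @param vertices two-column (row, col) matrix.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_contour_csv <- function(vertices, path) {
  df <- as.data.frame(vertices)
  names(df) <- c("row", "col")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @importFrom utils read.delim
NULL
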