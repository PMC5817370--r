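#' Bundle a co-registered CT/SUV slice pair
#'
#' @param ct gray raster with values in `[0, 255]`.
#' @param suv nonnegative SUV raster on the same pixel grid.
#' @param pixel_spacing_mm isotropic pixel spacing in mm.
#' @return An object of class `pet_ct_slice`.
#' @export
pet_ct_slice <- function(ct, suv, pixel_spacing_mm = 1) {
  check_raster(ct, "ct"); check_raster(suv, "suv")
  check_same_grid(ct, suv, c("ct", "suv"))
  if (pixel_spacing_mm <= 0) {
    stop_petct("pixel_spacing_mm must be > 0", "parameter_error")
  }
  if (any(suv < 0)) stop_petct("suv must be nonnegative", "parameter_error")
  structure(list(ct = ct, suv = suv, pixel_spacing_mm = pixel_spacing_mm),
            class = "pet_ct_slice")
}

as_pet_ct_slice <- function(x) {
  if (inherits(x, "pet_ct_slice")) return(x)
  if (inherits(x, "phantom_sample")) {
    return(pet_ct_slice(x$ct, x$suv, x$spec$pixel_spacing_mm))
  }
  stop_petct("expected a pet_ct_slice or phantom_sample", "parameter_error")
}

#' Otsu threshold on the 0-255 gray scale
#'
#' Maximizes the between-class variance over a 256-bin histogram of the gray
#' raster (computed by [EBImage::otsu()]), returning the threshold on the
#' original gray scale.
#'
#' @param gray gray raster with values in `[0, 255]`.
#' @return Scalar threshold; pixels `> threshold` form the high-gray class.
#' @export
otsu_threshold <- function(gray) {
  check_raster(gray, "gray")
  if (length(unique(as.vector(gray))) < 2L) {
    stop_petct("gray raster is constant; Otsu threshold undefined",
               "degenerate_input_error")
  }
  EBImage::otsu(gray / 255, range = c(0, 1), levels = 256) * 255
}

#' Segment the lung parenchyma on a CT slice
#'
#' Splits the CT slice at the Otsu threshold, keeps the low-gray (air-like)
#' class, discards components touching the image border (air outside the
#' body), fills holes (nodules and vessels sit as high-gray islands inside
#' the parenchyma), applies a morphological opening with a disk structuring
#' element, and returns the union of the largest one or two remaining
#' components (the two lungs).
#'
#' @param slice a [pet_ct_slice()] (or `phantom_sample`).
#' @param open_radius_px radius in pixels of the opening disk.
#' @return 0/1 integer raster marking the lung parenchyma.
#' @export
segment_lung_parenchyma <- function(slice, open_radius_px = 2L) {
  slice <- as_pet_ct_slice(slice)
  th <- otsu_threshold(slice$ct)
  low <- matrix(as.integer(slice$ct <= th), nrow(slice$ct), ncol(slice$ct))

  lab <- label_components(low, connectivity = 8L)
  if (max(lab) == 0L) stop_petct("no low-gray component found", "empty_mask_error")
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- setdiff(border_labels, 0L)
  keep <- low
  keep[lab %in% border_labels] <- 0L
  if (sum(keep) == 0L) {
    stop_petct("no lung-like component found away from the border",
               "empty_mask_error")
  }
  keep <- fill_holes(keep)

  if (open_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(open_radius_px) + 1L, "disc")
    keep <- matrix(as.integer(as.matrix(EBImage::opening(keep, brush)) > 0),
                   nrow(keep), ncol(keep))
  }
  lab2 <- label_components(keep, connectivity = 8L)
  if (max(lab2) == 0L) {
    stop_petct("lung mask empty after opening", "empty_mask_error")
  }
  sizes <- tabulate(lab2[lab2 > 0])
  sel <- order(sizes, decreasing = TRUE)[seq_len(min(2L, length(sizes)))]
  matrix(as.integer(lab2 %in% sel), nrow(keep), ncol(keep))
}

#' Locate the maximum-SUV pixel inside a mask
#'
#' Ties are broken in row-major order (smallest row, then smallest column).
#'
#' @param suv SUV raster.
#' @param lung_mask 0/1 raster restricting the search.
#' @return Integer `(row, col)` of the maximum-SUV pixel.
#' @export
find_max_suv_pixel <- function(suv, lung_mask) {
  check_raster(suv, "suv")
  check_same_grid(suv, lung_mask, c("suv", "lung_mask"))
  idx <- which(lung_mask > 0)
  if (length(idx) == 0L) stop_petct("lung mask is empty", "empty_mask_error")
  vals <- suv[idx]
  best <- idx[vals == max(vals)]
  nr <- nrow(suv)
  r <- (best - 1L) %% nr + 1L
  c_ <- (best - 1L) %/% nr + 1L
  o <- order(r, c_)[1L]
  c(row = r[o], col = c_[o])
}

#' Extract the circular pulmonary-nodule ROI
#'
#' Segments the lung parenchyma, finds the maximum-SUV pixel `O` within it,
#' and builds a circular template of radius `radius_R_mm` (30 mm by default,
#' chosen to cover nodules up to 30 mm in diameter) centred on `O`. All
#' downstream computation is restricted to this template.
#'
#' @param slice a [pet_ct_slice()] (or `phantom_sample`).
#' @param radius_R_mm template radius in mm.
#' @param open_radius_px opening radius passed to [segment_lung_parenchyma()].
#' @return A list of class `roi_result` with `roi_mask`, `center_O`,
#'   `radius_R_mm`, `radius_px` (rounded to the nearest pixel) and
#'   `lung_mask`.
#' @export
extract_roi <- function(slice, radius_R_mm = 30, open_radius_px = 2L) {
  slice <- as_pet_ct_slice(slice)
  if (radius_R_mm <= 0) stop_petct("radius_R_mm must be > 0", "parameter_error")
  lung <- segment_lung_parenchyma(slice, open_radius_px)
  center <- find_max_suv_pixel(slice$suv, lung)
  radius_px <- round(radius_R_mm / slice$pixel_spacing_mm)
  nr <- nrow(slice$ct); nc <- ncol(slice$ct)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  roi <- matrix(as.integer((rr - center[1])^2 + (cc - center[2])^2 <=
                             radius_px^2), nr, nc)
  structure(list(roi_mask = roi, center_O = center, radius_R_mm = radius_R_mm,
                 radius_px = radius_px, lung_mask = lung),
            class = "roi_result")
}
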