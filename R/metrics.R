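# Segmentation evaluation: Dice overlap, symmetric Hausdorff distance on
# contour pixel sets, and the false-positive fraction relative to the
# ground-truth area.

#' Dice similarity coefficient
#'
#' `DSC = 2 |Ag intersect Ar| / (|Ag| + |Ar|) * 100`, on the 0-100 scale.
#'
#' @param Ag,Ar 0/1 rasters on the same grid (ground truth and result); at
#'   least one must be nonempty.
#' @return Overlap percentage in `[0, 100]`.
#' @export
dice <- function(Ag, Ar) {
  check_same_grid(Ag, Ar, c("Ag", "Ar"))
  a <- Ag > 0; b <- Ar > 0
  if (!any(a) && !any(b)) {
    stop_petct("both masks are empty; Dice undefined", "undefined_metric_error")
  }
  2 * sum(a & b) / (sum(a) + sum(b)) * 100
}

#' Symmetric Hausdorff distance between contour point sets
#'
#' `HD = max(h(A, B), h(B, A))` with `h(A, B) = max_a min_b ||a - b||`,
#' Euclidean in pixel units, scaled by `spacing_mm` to mm.
#'
#' @param A,B two-column (row, col) matrices of contour points; or 0/1 mask
#'   rasters, from which 4-connected boundary pixels are extracted.
#' @param spacing_mm mm per pixel.
#' @return Hausdorff distance in mm (equal to pixels when `spacing_mm = 1`).
#' @export
hausdorff <- function(A, B, spacing_mm = 1) {
  pa <- if (is.matrix(A) && ncol(A) == 2) A else mask_boundary_pixels(A)
  pb <- if (is.matrix(B) && ncol(B) == 2) B else mask_boundary_pixels(B)
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    stop_petct("empty contour set; Hausdorff undefined", "undefined_metric_error")
  }
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  h_ab <- sqrt(max(apply(d2, 1, min)))
  h_ba <- sqrt(max(apply(d2, 2, min)))
  max(h_ab, h_ba) * spacing_mm
}

#' False-positive fraction
#'
#' `FP = (|Ar| - |Ag intersect Ar|) / |Ag| * 100`: false-positive pixels as
#' a percentage of the ground-truth area. Values above 100 are possible
#' when the result grossly oversegments.
#'
#' @param Ag,Ar 0/1 rasters on the same grid; `Ag` must be nonempty.
#' @return Nonnegative percentage.
#' @export
false_positive <- function(Ag, Ar) {
  check_same_grid(Ag, Ar, c("Ag", "Ar"))
  a <- Ag > 0; b <- Ar > 0
  if (!any(a)) {
    stop_petct("ground truth is empty; FP undefined", "undefined_metric_error")
  }
  (sum(b) - sum(a & b)) / sum(a) * 100
}

#' Full metric report for a mask pair
#'
#' @param truth,pred 0/1 rasters (ground truth and prediction).
#' @param spacing_mm mm per pixel, used for the Hausdorff distance.
#' @return A list with `dsc_percent`, `hd_mm`, `hd_px` and `fp_percent`.
#' @export
metric_report <- function(truth, pred, spacing_mm = 1) {
  hd_px <- hausdorff(truth, pred, spacing_mm = 1)
  list(dsc_percent = dice(truth, pred),
       hd_mm = hd_px * spacing_mm,
       hd_px = hd_px,
       fp_percent = false_positive(truth, pred))
}
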