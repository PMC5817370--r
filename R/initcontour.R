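#' Automatic threshold iteration
#'
#' Finds a gray threshold separating nodule from background inside the ROI
#' by fixed-point iteration on class means: starting from
#' `T0 = (G_max + G_min) / 2`, the ROI is repeatedly split into a background
#' set `B` (gray `< T`) and a nodule set `N` (gray `>= T`), and `T` is
#' updated to the midpoint of the two class means until successive
#' thresholds differ by at most `lambda_tol`.
#'
#' If one class empties at some iteration, its mean is taken to be the
#' current threshold, which leaves `T` unchanged and triggers convergence.
#'
#' @param gray numeric vector or raster of ROI gray values.
#' @param lambda_tol convergence tolerance on `|T_n - T_(n-1)|` (default 0.1).
#' @param max_iter safety cap on the number of updates.
#' @return A list of class `threshold_iter_state` with `T`, `G_max`, `G_min`,
#'   `alpha_b`, `alpha_n`, `iter` (number of updates performed) and `trace`
#'   (thresholds after each update, starting at `T0`).
#' @export
iterate_threshold <- function(gray, lambda_tol = 0.1, max_iter = 1000L) {
  v <- as.vector(gray)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop_petct("empty ROI", "degenerate_input_error")
  if (lambda_tol <= 0) stop_petct("lambda_tol must be > 0", "parameter_error")
  g_max <- max(v); g_min <- min(v)
  if (g_max == g_min) {
    stop_petct("ROI gray values are constant", "degenerate_input_error")
  }
  t_cur <- (g_max + g_min) / 2
  trace <- t_cur
  alpha_b <- alpha_n <- NA_real_
  iter <- 0L
  repeat {
    b <- v[v < t_cur]
    n <- v[v >= t_cur]
    alpha_b <- if (length(b) > 0L) mean(b) else t_cur
    alpha_n <- if (length(n) > 0L) mean(n) else t_cur
    t_new <- (alpha_b + alpha_n) / 2
    iter <- iter + 1L
    trace <- c(trace, t_new)
    done <- abs(t_new - t_cur) <= lambda_tol
    t_cur <- t_new
    if (done || iter >= max_iter) break
  }
  structure(list(T = t_cur, G_max = g_max, G_min = g_min,
                 alpha_b = alpha_b, alpha_n = alpha_n,
                 lambda_tol = lambda_tol, iter = iter, trace = trace),
            class = "threshold_iter_state")
}

#' Binarize a gray raster at a threshold
#'
#' Pixels with gray `>= T` map to 1 (nodule class), the rest to 0.
#'
#' @param gray gray raster.
#' @param T threshold.
#' @return 0/1 integer raster.
#' @export
binarize <- function(gray, T) {
  check_raster(gray, "gray")
  matrix(as.integer(gray >= T), nrow(gray), ncol(gray))
}

#' Select the initial contour as the largest binary component
#'
#' Labels the 8-connected foreground components of a binary raster, measures
#' each component's filled (hole-free) area, and returns the sub-pixel
#' boundary polyline of the maximum-area component, traced on the 0.5-level
#' of its filled mask. Area ties are broken in favour of the component whose
#' first pixel comes earliest in row-major order.
#'
#' @param binary 0/1 raster.
#' @return A list of class `contour_polyline` with `vertices` (closed
#'   (row, col) polyline), `closed`, `enclosed_area_px` and `mask` (the
#'   filled component mask).
#' @export
select_initial_contour <- function(binary) {
  check_raster(binary, "binary")
  lab <- label_components(binary, connectivity = 8L)
  k <- max(lab)
  if (k == 0L) stop_petct("binary raster has no foreground", "empty_mask_error")
  areas <- numeric(k)
  masks <- vector("list", k)
  for (i in seq_len(k)) {
    m <- fill_holes(matrix(as.integer(lab == i), nrow(lab), ncol(lab)))
    masks[[i]] <- m
    areas[i] <- sum(m)
  }
  # labels are already in row-major first-pixel order, so which.max's
  # first-maximum rule is the documented tie-break
  best <- which.max(areas)
  tr <- trace_mask_contour(masks[[best]])
  structure(list(vertices = tr$vertices, closed = tr$closed,
                 enclosed_area_px = areas[best], mask = masks[[best]]),
            class = "contour_polyline")
}
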