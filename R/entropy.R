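# SUV information-entropy edge guide.
#
# For a point x on the evolving contour, a circular neighbourhood R(x) of
# radius r pixels is cut by the zero level set into an inside part (phi >= 0)
# and an outside part (phi < 0). On each part the SUV values are summarized
# by a Gaussian density (mean and standard deviation of the part), the
# densities over the part are normalized to a probability vector, and its
# Shannon entropy H_i (bits) is taken: a homogeneous part gives near-equal
# probabilities and maximal entropy log2(n_i); a part straddling nodule and
# background gives a skewed distribution and an entropy deficit
# D_i = log2(n_i) - H_i > 0.
#
# The guide value is the base-2 exponential of the entropy standardized to
# the size m of the whole (grid-clipped) neighbourhood,
#   F_i = 2^-(H_i + log2(m / n_i)) = 2^(D_i) / m,
# i.e. the inverse perplexity the part would have at full-disk size given
# its evenness. Two choices matter here. The exponential base matches the
# entropy's log base, so F is a unit-free probability-scale quantity (a
# natural-base exponential of a bit-valued entropy would make F depend on
# the entropy unit). The log2(m/n_i) standardization removes the region-
# size term of the entropy, which otherwise weights the smaller half of
# every neighbourhood more strongly than the larger one regardless of
# homogeneity and systematically biases the force balance inward for small
# nodules. F_i is small (1/m) where the part is SUV-homogeneous, freezing
# the data force so the contour stops there, and grows with the deficit
# where the part mixes nodule and background, letting the contour move on;
# always 0 < F_i <= 1.

#' Shannon entropy of a probability vector
#'
#' `H = -sum(p * log2(p))` in bits, with `0 * log2(0)` taken as 0.
#'
#' @param p nonnegative vector summing to 1 (within 1e-9).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop_petct("probabilities must be finite and nonnegative",
               "invalid_distribution_error")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop_petct("probabilities must sum to 1", "invalid_distribution_error")
  }
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

#' SUV information entropy of a pixel region
#'
#' Fits a Gaussian to the SUV values of the region (standard deviation
#' floored at `sigma_floor`), evaluates the density at every region pixel,
#' normalizes the densities to sum to 1, and returns their Shannon entropy.
#' A constant region yields equal probabilities and hence `log2(n)` bits for
#' a region of `n` pixels, the maximum possible.
#'
#' @param suv SUV raster (or a plain numeric vector of region values).
#' @param region logical/0-1 mask or index vector selecting the region;
#'   omit when `suv` is already a vector of region values.
#' @param sigma_floor minimum standard deviation, in SUV units.
#' @return Entropy in bits.
#' @export
suv_region_entropy <- function(suv, region = NULL, sigma_floor = 1e-3) {
  vals <- if (is.null(region)) as.vector(suv) else {
    if (is.matrix(region)) suv[region > 0] else suv[region]
  }
  if (length(vals) == 0L) stop_petct("region is empty", "empty_region_error")
  ci <- mean(vals)
  si <- stats::sd(vals)
  if (!is.finite(si)) si <- 0
  si <- max(si, sigma_floor)
  dens <- stats::dnorm(vals, mean = ci, sd = si)
  shannon_entropy(dens / sum(dens))
}

#' Edge-guide values at one contour point
#'
#' Splits the circular neighbourhood of `x` (clipped to the grid, `m`
#' pixels) by the sign of `phi` (`phi >= 0` is inside) and returns, for the
#' inside (`F1`) and outside (`F2`) parts of `n_i` pixels each,
#' `F_i = 2^-(H_SUV_i + log2(m / n_i))`: the base-2 exponential of the SUV
#' region entropy standardized to the full neighbourhood size, so that the
#' two parts are weighted on an equal footing regardless of how the contour
#' cuts the disk. An SUV-homogeneous part gives the minimum `F_i = 1/m`
#' (the contour stops there); a part mixing nodule and background uptake
#' gives a larger `F_i` (the contour keeps evolving).
#' If either part is empty the point is not on the contour in any useful
#' sense and `(1, 1)` is returned with a warning.
#'
#' @param suv SUV raster.
#' @param phi level-set raster (positive inside).
#' @param x integer `(row, col)` of the contour point.
#' @param radius_r_px neighbourhood radius in pixels (default 15).
#' @param sigma_floor minimum standard deviation for the region Gaussian.
#' @return Named numeric vector `c(F1 = , F2 = )`, both in `(0, 1]`.
#' @export
edge_guide <- function(suv, phi, x, radius_r_px = 15L, sigma_floor = 1e-3) {
  check_raster(suv, "suv"); check_same_grid(suv, phi, c("suv", "phi"))
  off <- disk_offsets(radius_r_px)
  r <- x[1] + off$dr; c_ <- x[2] + off$dc
  ok <- r >= 1L & r <= nrow(suv) & c_ >= 1L & c_ <= ncol(suv)
  lin <- (c_[ok] - 1L) * nrow(suv) + r[ok]
  inside <- phi[lin] >= 0
  if (!any(inside) || all(inside)) {
    warning("edge_guide: neighbourhood lies entirely on one side of the contour")
    return(c(F1 = 1, F2 = 1))
  }
  h3 <- suv_region_entropy(suv[lin][inside], sigma_floor = sigma_floor)
  h4 <- suv_region_entropy(suv[lin][!inside], sigma_floor = sigma_floor)
  m <- length(lin)
  c(F1 = 2^(-(h3 + log2(m / sum(inside)))),
    F2 = 2^(-(h4 + log2(m / sum(!inside)))))
}

#' Build the edge-guide field for one evolution iteration
#'
#' Evaluates [edge_guide()] at every pixel within `band_px` of the zero
#' crossing of `phi` (where the smoothed Dirac factor of the evolution is
#' non-negligible) and sets `F1 = F2 = 1` elsewhere. The computation is
#' vectorized over all band pixels.
#'
#' @param suv SUV raster.
#' @param phi level-set raster with a nonempty zero crossing.
#' @param radius_r_px neighbourhood radius in pixels.
#' @param band_px half-width of the recomputation band: the guide is
#'   evaluated where `|phi| <= band_px` (and at all zero-crossing pixels);
#'   use `Inf` to evaluate at every pixel. The default configuration uses 6,
#'   the 4-sigma support radius of the Gaussian fitting kernel, beyond which
#'   the inside/outside fits coincide and the data forces cancel anyway.
#' @param sigma_floor minimum standard deviation for the region Gaussian.
#' @return A list of class `guide_field` with rasters `F1`, `F2`,
#'   `H_suv_inside`, `H_suv_outside` (entropies are `NA` outside the band).
#' @export
build_guide_field <- function(suv, phi, radius_r_px = 15L, band_px = 3,
                              sigma_floor = 1e-3) {
  check_raster(suv, "suv"); check_same_grid(suv, phi, c("suv", "phi"))
  nr <- nrow(suv); nc <- ncol(suv)
  pos <- phi >= 0
  zc <- pos & (shift_mat(!pos, 1L, 0L) | shift_mat(!pos, -1L, 0L) |
                 shift_mat(!pos, 0L, 1L) | shift_mat(!pos, 0L, -1L))
  zc <- zc | (!pos & (shift_mat(pos, 1L, 0L) | shift_mat(pos, -1L, 0L) |
                        shift_mat(pos, 0L, 1L) | shift_mat(pos, 0L, -1L)))
  if (!any(zc)) {
    stop_petct("level set has no zero crossing; contour has collapsed",
               "evolution_collapsed_error")
  }
  if (is.finite(band_px)) {
    # The Dirac factor that gates the data force is a function of the level
    # value itself, so the recomputation band is |phi| <= band_px (plus the
    # zero-crossing pixels, whose levels can exceed it at steep walls).
    band_idx <- which(abs(phi) <= band_px | zc)
  } else {
    band_idx <- seq_len(nr * nc)
  }

  F1 <- matrix(1, nr, nc); F2 <- matrix(1, nr, nc)
  H3 <- matrix(NA_real_, nr, nc); H4 <- matrix(NA_real_, nr, nc)

  off <- disk_offsets(radius_r_px)
  ent <- .guide_entropies(suv, pos, band_idx - 1L, off$dr, off$dc,
                          sigma_floor)
  h3 <- ent$h3
  h4 <- ent$h4
  m_x <- ent$n3 + ent$n4  # grid-clipped neighbourhood size at each point
  usable <- is.finite(h3) & is.finite(h4)
  f1 <- ifelse(usable, 2^(-(h3 + log2(m_x / ent$n3))), 1)
  f2 <- ifelse(usable, 2^(-(h4 + log2(m_x / ent$n4))), 1)
  F1[band_idx] <- f1
  F2[band_idx] <- f2
  H3[band_idx] <- h3
  H4[band_idx] <- h4
  structure(list(F1 = F1, F2 = F2, H_suv_inside = H3, H_suv_outside = H4,
                 radius_r_px = radius_r_px, band_px = band_px,
                 sigma_floor = sigma_floor),
            class = "guide_field")
}
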