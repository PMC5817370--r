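# Entropy-guided joint-vector LBF level-set evolution.
#
# The contour is the zero level set of phi (positive inside). Each iteration
# recomputes (i) the local Gaussian-weighted fits f1/f2 of both the CT and
# the rescaled SUV channel, gated by the smoothed Heaviside of phi, and
# (ii) the SUV entropy edge-guide field near the contour; the data terms
# e1/e2 are the guide-weighted squared joint residuals. phi then takes an
# explicit gradient-descent step on the total energy
#   F = E_fit + nu * L(phi) + mu * P(phi),
# with L the contour length (Dirac-weighted gradient magnitude) and P the
# distance-regularizing penalty keeping |grad phi| near 1 (which replaces
# explicit reinitialization).

#' Smoothed Heaviside function
#'
#' `H_eps(x) = 1/2 (1 + (2/pi) atan(x/eps))`, rising from 0 to 1 with a
#' width controlled by `epsilon`.
#'
#' @param x numeric scalar, vector or raster.
#' @param epsilon positive smoothing width.
#' @return Values in `(0, 1)`.
#' @export
heaviside_smooth <- function(x, epsilon = 1) {
  if (epsilon <= 0) stop_petct("epsilon must be > 0", "parameter_error")
  0.5 * (1 + (2 / pi) * atan(x / epsilon))
}

#' Smoothed Dirac function
#'
#' `delta_eps(x) = (1/pi) eps / (eps^2 + x^2)`, the derivative of
#' [heaviside_smooth()]; it restricts contour forces to a band around the
#' zero level set.
#'
#' @inheritParams heaviside_smooth
#' @return Nonnegative values.
#' @export
dirac_smooth <- function(x, epsilon = 1) {
  if (epsilon <= 0) stop_petct("epsilon must be > 0", "parameter_error")
  (1 / pi) * epsilon / (epsilon^2 + x^2)
}

# Truncated (4 sigma) Gaussian kernel, normalized to unit sum.
gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(4 * sigma))
  s <- seq(-half, half)
  k <- exp(-outer(s^2, s^2, "+") / (2 * sigma^2))
  k / sum(k)
}

#' Local Gaussian-weighted fitting values of one channel
#'
#' Computes the inside/outside local fitting rasters of the LBF model:
#' `f1 = K * (I H) / K * H` and `f2 = K * (I (1-H)) / K * (1-H)` with
#' `H = H_eps(phi)` and `K` a truncated Gaussian kernel of standard
#' deviation `sigma_g`, applied by convolution with replicated borders.
#' Denominators are floored at 1e-12.
#'
#' @param channel intensity raster.
#' @param phi level-set raster (positive inside).
#' @param sigma_g Gaussian kernel standard deviation (default 1.5).
#' @param epsilon Heaviside smoothing width.
#' @return List with rasters `f1` (inside fit) and `f2` (outside fit).
#' @export
gaussian_fit <- function(channel, phi, sigma_g = 1.5, epsilon = 1) {
  check_raster(channel, "channel")
  check_same_grid(channel, phi, c("channel", "phi"))
  if (sigma_g <= 0) stop_petct("sigma_g must be > 0", "parameter_error")
  k <- gaussian_kernel(sigma_g)
  h <- heaviside_smooth(phi, epsilon)
  conv <- function(m) as.matrix(EBImage::filter2(m, k, boundary = "replicate"))
  f1 <- conv(channel * h) / pmax(conv(h), 1e-12)
  f2 <- conv(channel * (1 - h)) / pmax(conv(1 - h), 1e-12)
  list(f1 = f1, f2 = f2)
}

# Joint fits of the CT channel and the ROI-rescaled SUV channel.
joint_gaussian_fit <- function(ct, suv_scaled, phi, sigma_g, epsilon) {
  fc <- gaussian_fit(ct, phi, sigma_g, epsilon)
  fs <- gaussian_fit(suv_scaled, phi, sigma_g, epsilon)
  list(f1_ct = fc$f1, f2_ct = fc$f2, f1_suv = fs$f1, f2_suv = fs$f2,
       sigma_g = sigma_g)
}

#' Entropy-weighted joint data terms
#'
#' `e1 = F1 (Lambda1 (I_ct - f1_ct)^2 + Lambda2 (I_suv - f1_suv)^2)` and
#' analogously `e2` with the outside fits and `F2`. Setting `Lambda2 = 0`
#' reduces to an entropy-weighted single-channel LBF residual; a guide of
#' all ones reduces to the plain joint residual.
#'
#' @param ct CT gray raster.
#' @param suv SUV raster on the same intensity scale as the fits (the
#'   pipeline rescales SUV to `[0, 255]` over the ROI); may be `NULL` when
#'   `Lambda2 = 0`.
#' @param fit joint fit list as returned by the internal joint Gaussian fit
#'   (`f1_ct`, `f2_ct`, `f1_suv`, `f2_suv`).
#' @param guide a `guide_field` (rasters `F1`, `F2`), or `NULL` for no
#'   weighting.
#' @param Lambda1,Lambda2 channel coefficients of the diagonal matrix
#'   coupling the CT and SUV residuals (defaults 1, 1).
#' @return List with rasters `e1` and `e2`.
#' @export
pointwise_data_terms <- function(ct, suv, fit, guide = NULL,
                                 Lambda1 = 1, Lambda2 = 1) {
  r1 <- Lambda1 * (ct - fit$f1_ct)^2
  r2 <- Lambda1 * (ct - fit$f2_ct)^2
  if (Lambda2 != 0) {
    r1 <- r1 + Lambda2 * (suv - fit$f1_suv)^2
    r2 <- r2 + Lambda2 * (suv - fit$f2_suv)^2
  }
  if (is.null(guide)) {
    list(e1 = r1, e2 = r2)
  } else {
    list(e1 = guide$F1 * r1, e2 = guide$F2 * r2)
  }
}

#' Mean curvature of the level-set function
#'
#' Central-difference divergence of the normalized gradient,
#' `div(grad phi / |grad phi|)`, with `|grad phi|` floored at 1e-10 and
#' replicated borders. Under the positive-inside convention the value on a
#' level circle of radius `rho` has magnitude `1/rho` and negative sign for
#' a convex interior (the normal field points inward).
#'
#' @param phi level-set raster (at least 3 x 3).
#' @return Curvature raster.
#' @export
curvature <- function(phi) {
  check_raster(phi, "phi")
  if (nrow(phi) < 3 || ncol(phi) < 3) {
    stop_petct("phi must be at least 3 x 3", "parameter_error")
  }
  gr <- (shift_mat(phi, -1L, 0L) - shift_mat(phi, 1L, 0L)) / 2
  gc <- (shift_mat(phi, 0L, -1L) - shift_mat(phi, 0L, 1L)) / 2
  nrm <- pmax(sqrt(gr^2 + gc^2), 1e-10)
  nr_ <- gr / nrm
  nc_ <- gc / nrm
  (shift_mat(nr_, -1L, 0L) - shift_mat(nr_, 1L, 0L)) / 2 +
    (shift_mat(nc_, 0L, -1L) - shift_mat(nc_, 0L, 1L)) / 2
}

laplacian <- function(phi) {
  shift_mat(phi, -1L, 0L) + shift_mat(phi, 1L, 0L) +
    shift_mat(phi, 0L, -1L) + shift_mat(phi, 0L, 1L) - 4 * phi
}

grad_norm <- function(phi) {
  gr <- (shift_mat(phi, -1L, 0L) - shift_mat(phi, 1L, 0L)) / 2
  gc <- (shift_mat(phi, 0L, -1L) - shift_mat(phi, 0L, 1L)) / 2
  sqrt(gr^2 + gc^2)
}

#' Total level-set energy
#'
#' `F = E_fit + nu L + mu P` with
#' `E_fit = sum(lambda1 e1 H_eps(phi) + lambda2 e2 (1 - H_eps(phi)))`,
#' `L = sum(delta_eps(phi) |grad phi|)` (zero-level-curve length) and
#' `P = sum((|grad phi| - 1)^2 / 2)` (distance regularization), using grid
#' sums with unit pixel measure.
#'
#' @param e1,e2 data-term rasters from [pointwise_data_terms()].
#' @param phi level-set raster.
#' @param lambda1,lambda2 region weights.
#' @param nu length-term coefficient.
#' @param mu distance-regularizer coefficient.
#' @param epsilon Heaviside/Dirac smoothing width.
#' @return List with `E_fit`, `L`, `P` and the total `F`.
#' @export
total_energy <- function(e1, e2, phi, lambda1 = 1, lambda2 = 1,
                         nu = 0.001 * 255^2, mu = 1, epsilon = 1) {
  h <- heaviside_smooth(phi, epsilon)
  g <- grad_norm(phi)
  e_fit <- sum(lambda1 * e1 * h + lambda2 * e2 * (1 - h))
  l_len <- sum(dirac_smooth(phi, epsilon) * g)
  p_reg <- sum(0.5 * (g - 1)^2)
  f_tot <- e_fit + nu * l_len + mu * p_reg
  if (!is.finite(f_tot)) {
    stop_petct("level-set energy is not finite", "numerical_blowup_error")
  }
  list(E_fit = e_fit, L = l_len, P = p_reg, F = f_tot)
}

#' One gradient-descent update of the level-set function
#'
#' `phi <- phi + dt (-delta(phi)(lambda1 e1 - lambda2 e2)
#'   + nu delta(phi) div(grad phi / |grad phi|)
#'   + mu (lap phi - div(grad phi / |grad phi|)))`.
#'
#' @param phi level-set raster.
#' @param e1,e2 data-term rasters (held fixed during the update).
#' @param dt time step.
#' @param lambda1,lambda2,nu,mu,epsilon as in [total_energy()].
#' @return Updated `phi` raster.
#' @export
level_set_step <- function(phi, e1, e2, dt = 0.1, lambda1 = 1, lambda2 = 1,
                           nu = 0.001 * 255^2, mu = 1, epsilon = 1) {
  out <- phi + dt * evolution_force(phi, e1, e2, lambda1, lambda2, nu, mu,
                                    epsilon)
  if (any(!is.finite(out))) {
    stop_petct("level-set function is not finite after update",
               "numerical_blowup_error")
  }
  out
}

evolution_force <- function(phi, e1, e2, lambda1, lambda2, nu, mu, epsilon) {
  del <- dirac_smooth(phi, epsilon)
  kap <- curvature(phi)
  -del * (lambda1 * e1 - lambda2 * e2) + nu * del * kap +
    mu * (laplacian(phi) - kap)
}

# One energy-monitored descent update, shared by the full model and the
# classic-LBF reference path. The effective time step is the current sticky
# dt clamped so no pixel's level moves by more than max_disp per step (an
# explicit-scheme stability guard), then halved (persistently, up to
# max_halvings over the whole run) while the step would increase the energy
# under the current, fixed data terms.
descend_once <- function(phi, e1, e2, en, dt_state, cfg) {
  force <- evolution_force(phi, e1, e2, cfg$lambda1, cfg$lambda2,
                           cfg$nu, cfg$mu, cfg$epsilon)
  fmax <- max(abs(force))
  dt_eff <- if (fmax > 0) min(dt_state$dt, cfg$max_disp / fmax) else dt_state$dt
  repeat {
    cand <- phi + dt_eff * force
    if (any(!is.finite(cand))) {
      stop_petct("level-set function is not finite after update",
                 "numerical_blowup_error")
    }
    en_new <- total_energy(e1, e2, cand, cfg$lambda1, cfg$lambda2,
                           cfg$nu, cfg$mu, cfg$epsilon)
    if (en_new$F <= en$F || dt_state$halvings >= cfg$max_halvings) break
    dt_eff <- dt_eff / 2
    dt_state$dt <- dt_state$dt / 2
    dt_state$halvings <- dt_state$halvings + 1L
  }
  list(phi = cand, dt_state = dt_state)
}

# Rescale SUV to [0, 255] over the ROI so the CT and SUV residuals are
# commensurable under Lambda1 = Lambda2 = 1.
rescale_suv <- function(suv, roi_mask = NULL) {
  vals <- if (is.null(roi_mask)) as.vector(suv) else suv[roi_mask > 0]
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) return(matrix(0, nrow(suv), ncol(suv)))
  pmin(pmax((suv - lo) / (hi - lo) * 255, 0), 255)
}

#' Run the entropy-guided joint-vector level-set evolution
#'
#' Initializes phi as the signed Euclidean distance to the initial mask
#' (positive inside), then repeats: recompute the joint CT/SUV fits and the
#' entropy guide field, assemble the data terms, take a gradient-descent
#' step (halving `dt` up to `max_halvings` times whenever the step would
#' increase the energy under the current fits), and stop once the energy is
#' stable (`|F_k - F_(k-1)| <= chi`) or `K_max` iterations are reached.
#'
#' @param ct CT gray raster (values in `[0, 255]`).
#' @param suv SUV raster on the same grid (raw SUV units); used both for the
#'   entropy guide and, min-max rescaled to `[0, 255]` over `roi_mask`, as
#'   the second channel of the joint fit. Pass `NULL` (with
#'   `config$Lambda2 = 0`) for single-channel evolution.
#' @param init_mask 0/1 raster of the initial contour's interior.
#' @param config a [seg_config()] list.
#' @param roi_mask optional 0/1 raster used for the SUV rescaling range.
#' @param use_guide logical; `FALSE` replaces the entropy guide by all-ones
#'   weights.
#' @param keep_trace logical; record the per-iteration energy decomposition.
#' @return A list of class `levelset_result` with `mask` (`phi >= 0`),
#'   `phi`, `k`, `stop_reason` (`"converged"` or `"max_iterations"`) and
#'   `energy_trace` (data frame with `k`, `E_fit`, `L`, `P`, `F`).
#' @export
evolve_contour <- function(ct, suv, init_mask, config = seg_config(),
                           roi_mask = NULL, use_guide = TRUE,
                           keep_trace = TRUE) {
  check_raster(ct, "ct")
  cfg <- config
  if (sum(init_mask) == 0) {
    stop_petct("initial mask is empty", "empty_mask_error")
  }
  if (is.null(suv) && (cfg$Lambda2 != 0 || use_guide)) {
    stop_petct("suv is required unless Lambda2 = 0 and the guide is disabled",
               "parameter_error")
  }
  suv_scaled <- if (!is.null(suv)) rescale_suv(suv, roi_mask) else
    matrix(0, nrow(ct), ncol(ct))

  phi <- signed_distance(init_mask)
  k <- 0L
  f_prev <- NA_real_
  stop_reason <- "max_iterations"
  trace <- vector("list", cfg$K_max)
  dt_state <- list(dt = cfg$dt, halvings = 0L)

  while (k < cfg$K_max) {
    fit <- joint_gaussian_fit(ct, suv_scaled, phi, cfg$sigma_g, cfg$epsilon)
    guide <- if (use_guide) {
      build_guide_field(suv, phi, cfg$r_px, cfg$band_px, cfg$sigma_floor)
    } else NULL
    terms <- pointwise_data_terms(ct, suv_scaled, fit, guide,
                                  cfg$Lambda1, cfg$Lambda2)
    en <- total_energy(terms$e1, terms$e2, phi, cfg$lambda1, cfg$lambda2,
                       cfg$nu, cfg$mu, cfg$epsilon)
    dn <- descend_once(phi, terms$e1, terms$e2, en, dt_state, cfg)
    phi <- dn$phi
    dt_state <- dn$dt_state
    k <- k + 1L
    if (keep_trace) {
      trace[[k]] <- data.frame(k = k, E_fit = en$E_fit, L = en$L, P = en$P,
                               F = en$F)
    }
    if (is.finite(f_prev) && abs(en$F - f_prev) <= cfg$chi) {
      stop_reason <- "converged"
      break
    }
    f_prev <- en$F
  }
  if (!any(phi >= 0) || all(phi >= 0)) {
    stop_petct("contour vanished during evolution", "evolution_collapsed_error")
  }
  mask <- matrix(as.integer(phi >= 0), nrow(phi), ncol(phi))
  structure(list(mask = mask, phi = phi, k = k, stop_reason = stop_reason,
                 energy_trace = if (keep_trace)
                   do.call(rbind, trace[seq_len(k)]) else NULL),
            class = "levelset_result")
}

#' Classic single-channel LBF evolution (reference baseline)
#'
#' A plain local-binary-fitting level set on the CT channel only: no SUV
#' channel and no entropy guide. Used as the comparison baseline that
#' exhibits edge leakage along vessels, and as the reduction target of the
#' full model when `Lambda2 = 0` and the guide is disabled.
#'
#' @param ct CT gray raster.
#' @param init_mask 0/1 raster of the initial contour's interior.
#' @param config a [seg_config()] list.
#' @param keep_trace logical; record the per-iteration energies.
#' @return A `levelset_result`, as for [evolve_contour()].
#' @export
lbf_classic <- function(ct, init_mask, config = seg_config(),
                        keep_trace = TRUE) {
  check_raster(ct, "ct")
  cfg <- config
  if (sum(init_mask) == 0) {
    stop_petct("initial mask is empty", "empty_mask_error")
  }
  phi <- signed_distance(init_mask)
  k <- 0L
  f_prev <- NA_real_
  stop_reason <- "max_iterations"
  trace <- vector("list", cfg$K_max)
  dt_state <- list(dt = cfg$dt, halvings = 0L)
  while (k < cfg$K_max) {
    fit <- gaussian_fit(ct, phi, cfg$sigma_g, cfg$epsilon)
    e1 <- cfg$Lambda1 * (ct - fit$f1)^2
    e2 <- cfg$Lambda1 * (ct - fit$f2)^2
    en <- total_energy(e1, e2, phi, cfg$lambda1, cfg$lambda2,
                       cfg$nu, cfg$mu, cfg$epsilon)
    dn <- descend_once(phi, e1, e2, en, dt_state, cfg)
    phi <- dn$phi
    dt_state <- dn$dt_state
    k <- k + 1L
    if (keep_trace) {
      trace[[k]] <- data.frame(k = k, E_fit = en$E_fit, L = en$L, P = en$P,
                               F = en$F)
    }
    if (is.finite(f_prev) && abs(en$F - f_prev) <= cfg$chi) {
      stop_reason <- "converged"
      break
    }
    f_prev <- en$F
  }
  if (!any(phi >= 0) || all(phi >= 0)) {
    stop_petct("contour vanished during evolution", "evolution_collapsed_error")
  }
  mask <- matrix(as.integer(phi >= 0), nrow(phi), ncol(phi))
  structure(list(mask = mask, phi = phi, k = k, stop_reason = stop_reason,
                 energy_trace = if (keep_trace)
                   do.call(rbind, trace[seq_len(k)]) else NULL),
            class = "levelset_result")
}
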