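#' Specify a synthetic vessel-attached-nodule phantom
#'
#' Builds the parameter set for a synthetic, co-registered CT/SUV slice pair
#' containing a roughly circular pulmonary nodule attached to an elongated
#' vessel. The nodule and vessel have near-identical CT gray values (the
#' configuration in which purely gray-driven active contours leak along the
#' vessel), while the nodule's SUV is markedly higher than the vessel's,
#' which is the contrast the entropy edge guide exploits.
#'
#' Default tissue levels are chosen on physiological grounds: a metabolically
#' active nodule (SUV 8) against a small-vessel blood pool whose effective SUV
#' is diluted by partial-volume averaging (SUV 1.0) and quiet parenchyma
#' (SUV 0.5); CT soft-tissue grays 150 (nodule) and 145 (vessel) over dark
#' parenchyma (40) inside a bright thorax background (200).
#'
#' @param grid_size pixels per side of the square grid.
#' @param pixel_spacing_mm isotropic pixel spacing in mm.
#' @param nodule_center integer (row, col) of the nodule centre in pixels.
#' @param nodule_radius_mm nodule radius in mm (> 0).
#' @param vessel_width_mm full width of the vessel band in mm (> 0).
#' @param vessel_length_mm total length of the vessel segment in mm; the
#'   segment is centred on the nodule, so it extends half this length on
#'   either side.
#' @param vessel_angle_deg orientation of the vessel centreline, which runs
#'   through the nodule (and hence through its edge), in degrees.
#' @param ct_gray_nodule,ct_gray_vessel,ct_gray_parenchyma,ct_gray_background
#'   CT gray levels in `[0, 255]`.
#' @param suv_nodule,suv_vessel,suv_parenchyma nonnegative SUV levels; must
#'   satisfy `suv_nodule > suv_vessel >= suv_parenchyma`.
#' @param noise_sigma_ct,noise_sigma_suv additive Gaussian noise scales.
#' @param bias_amplitude amplitude of the smooth multiplicative inhomogeneity
#'   field applied to the CT channel (a low-order cosine product around 1).
#' @param pet_block_factor integer >= 1 emulating the coarser native PET
#'   grid: the noiseless SUV layout is block-averaged over square blocks of
#'   this many pixels and bilinearly upsampled back to the CT grid,
#'   blurring it the way registration of a low-resolution PET onto the CT
#'   grid does. 1 (the default) keeps the SUV raster at CT resolution.
#' @param lung_radius_frac radius of the circular lung field as a fraction of
#'   `grid_size`.
#' @param seed integer RNG seed; identical specs and seeds give bit-identical
#'   samples.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_cohort()]
#' @export
phantom_spec <- function(grid_size = 128L,
                         pixel_spacing_mm = 1,
                         nodule_center = c(64L, 64L),
                         nodule_radius_mm = 5,
                         vessel_width_mm = 3,
                         vessel_length_mm = 30,
                         vessel_angle_deg = 30,
                         ct_gray_nodule = 150,
                         ct_gray_vessel = 145,
                         ct_gray_parenchyma = 40,
                         ct_gray_background = 200,
                         suv_nodule = 8,
                         suv_vessel = 1,
                         suv_parenchyma = 0.5,
                         noise_sigma_ct = 5,
                         noise_sigma_suv = 0.15,
                         bias_amplitude = 0.1,
                         pet_block_factor = 1L,
                         lung_radius_frac = 0.42,
                         seed = 1L) {
  spec <- list(
    grid_size = as.integer(grid_size),
    pixel_spacing_mm = pixel_spacing_mm,
    nodule_center = as.numeric(nodule_center),
    nodule_radius_mm = nodule_radius_mm,
    vessel_width_mm = vessel_width_mm,
    vessel_length_mm = vessel_length_mm,
    vessel_angle_deg = vessel_angle_deg,
    ct_gray_nodule = ct_gray_nodule,
    ct_gray_vessel = ct_gray_vessel,
    ct_gray_parenchyma = ct_gray_parenchyma,
    ct_gray_background = ct_gray_background,
    suv_nodule = suv_nodule,
    suv_vessel = suv_vessel,
    suv_parenchyma = suv_parenchyma,
    noise_sigma_ct = noise_sigma_ct,
    noise_sigma_suv = noise_sigma_suv,
    bias_amplitude = bias_amplitude,
    pet_block_factor = as.integer(pet_block_factor),
    lung_radius_frac = lung_radius_frac,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$nodule_radius_mm <= 0) {
    stop_petct("nodule_radius_mm must be > 0", "parameter_error")
  }
  if (spec$vessel_width_mm <= 0) {
    stop_petct("vessel_width_mm must be > 0", "parameter_error")
  }
  if (spec$vessel_length_mm <= 0) {
    stop_petct("vessel_length_mm must be > 0", "parameter_error")
  }
  if (spec$pixel_spacing_mm <= 0) {
    stop_petct("pixel_spacing_mm must be > 0", "parameter_error")
  }
  if (spec$pet_block_factor < 1) {
    stop_petct("pet_block_factor must be >= 1", "parameter_error")
  }
  if (!(spec$suv_nodule > spec$suv_vessel &&
        spec$suv_vessel >= spec$suv_parenchyma &&
        spec$suv_parenchyma >= 0)) {
    stop_petct("SUV levels must satisfy nodule > vessel >= parenchyma >= 0",
               "parameter_error")
  }
  r_px <- spec$nodule_radius_mm / spec$pixel_spacing_mm
  ctr <- spec$nodule_center
  if (any(ctr - r_px < 1) || any(ctr + r_px > spec$grid_size)) {
    stop_petct("nodule does not fit inside the grid", "parameter_error")
  }
  invisible(spec)
}

#' Generate one synthetic PET-CT phantom slice
#'
#' Renders the piecewise-constant tissue layout of `spec` (thorax background,
#' circular lung field of parenchyma, vessel band clipped to the lung field,
#' nodule disk drawn on top), multiplies the CT channel by a smooth low-order
#' cosine bias field, adds Gaussian noise to both channels, and returns the
#' pair together with the exact rasterized ground-truth nodule mask.
#'
#' A pixel belongs to the nodule iff its centre lies within the nodule circle
#' (distance ties count as inside). The truth mask covers the nodule disk
#' only: vessel pixels outside the disk are excluded, so the sample genuinely
#' poses the juxta-vascular segmentation problem.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_sample` with elements `ct` (gray raster
#'   clipped to `[0, 255]`), `suv` (nonnegative SUV raster), `truth_mask`
#'   (0/1 integer raster), `truth_contour` (closed (row, col) polyline of the
#'   nodule boundary) and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  n <- spec$grid_size
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)

  ctr_grid <- (n + 1) / 2
  lung <- (rr - ctr_grid)^2 + (cc - ctr_grid)^2 <=
    (spec$lung_radius_frac * n)^2

  r_px <- spec$nodule_radius_mm / spec$pixel_spacing_mm
  w_px <- spec$vessel_width_mm / spec$pixel_spacing_mm
  d2 <- (rr - spec$nodule_center[1])^2 + (cc - spec$nodule_center[2])^2
  nodule <- d2 <= r_px^2

  # vessel segment: a band of finite length whose centreline runs through
  # the nodule centre (and hence through its edge), clipped to the lung field
  theta <- spec$vessel_angle_deg * pi / 180
  l_px <- spec$vessel_length_mm / spec$pixel_spacing_mm
  # perpendicular and along-line distances to the centreline in (row, col)
  dist_line <- abs(-sin(theta) * (rr - spec$nodule_center[1]) +
                     cos(theta) * (cc - spec$nodule_center[2]))
  dist_along <- abs(cos(theta) * (rr - spec$nodule_center[1]) +
                      sin(theta) * (cc - spec$nodule_center[2]))
  vessel <- lung & dist_line <= w_px / 2 & dist_along <= l_px / 2 & !nodule

  ct0 <- matrix(spec$ct_gray_background, n, n)
  ct0[lung] <- spec$ct_gray_parenchyma
  ct0[vessel] <- spec$ct_gray_vessel
  ct0[nodule] <- spec$ct_gray_nodule

  suv0 <- matrix(0, n, n)
  suv0[lung] <- spec$suv_parenchyma
  suv0[vessel] <- spec$suv_vessel
  suv0[nodule] <- spec$suv_nodule

  bias <- 1 + spec$bias_amplitude *
    cos(pi * (rr - 1) / (n - 1)) * cos(pi * (cc - 1) / (n - 1))

  if (spec$pet_block_factor > 1L) {
    suv0 <- block_resample(suv0, spec$pet_block_factor)
  }

  sample <- with_seed(spec$seed, {
    ct <- ct0 * bias
    if (spec$noise_sigma_ct > 0) {
      ct <- ct + matrix(rnorm(n * n, 0, spec$noise_sigma_ct), n, n)
    }
    suv <- suv0
    if (spec$noise_sigma_suv > 0) {
      suv <- suv + matrix(rnorm(n * n, 0, spec$noise_sigma_suv), n, n)
    }
    list(ct = pmin(pmax(ct, 0), 255), suv = pmax(suv, 0))
  })

  truth <- matrix(as.integer(nodule), n, n)
  contour <- trace_mask_contour(truth)
  structure(list(ct = sample$ct, suv = sample$suv, truth_mask = truth,
                 truth_contour = contour$vertices, spec = spec),
            class = "phantom_sample")
}

#' Generate a seeded cohort of phantom slices
#'
#' Draws `n` phantoms from `base_spec` with jittered nodule radius, centre,
#' vessel width and vessel angle, each rendered under its own derived seed.
#' The whole cohort is reproducible from `(base_spec, seed)`.
#'
#' @param base_spec a [phantom_spec()] giving the shared tissue levels and
#'   noise scales.
#' @param n number of samples (>= 1).
#' @param seed integer seed for the cohort-level jitter draws.
#' @param radius_range_mm range of nodule radii (uniform jitter), in mm.
#' @param width_jitter_frac relative half-width of the vessel-width jitter.
#' @param center_jitter_px maximum absolute (row, col) centre displacement.
#' @return A list of `n` `phantom_sample` objects.
#' @export
generate_cohort <- function(base_spec, n, seed = base_spec$seed,
                            radius_range_mm = c(3, 12),
                            width_jitter_frac = 0.3,
                            center_jitter_px = 5) {
  if (n < 1) stop_petct("n must be >= 1", "parameter_error")
  if (!inherits(base_spec, "phantom_spec")) {
    base_spec <- do.call(phantom_spec, base_spec)
  }
  draws <- with_seed(seed, {
    list(
      radius = stats::runif(n, radius_range_mm[1], radius_range_mm[2]),
      angle = stats::runif(n, 0, 180),
      width = base_spec$vessel_width_mm *
        stats::runif(n, 1 - width_jitter_frac, 1 + width_jitter_frac),
      drow = stats::runif(n, -center_jitter_px, center_jitter_px),
      dcol = stats::runif(n, -center_jitter_px, center_jitter_px),
      seeds = sample.int(.Machine$integer.max %/% 2L, n)
    )
  })
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$nodule_radius_mm <- draws$radius[i]
    sp$vessel_angle_deg <- draws$angle[i]
    sp$vessel_width_mm <- draws$width[i]
    sp$nodule_center <- round(base_spec$nodule_center +
                                c(draws$drow[i], draws$dcol[i]))
    sp$seed <- draws$seeds[i]
    generate_phantom(sp)
  })
}

# Emulate a coarse native PET grid: average over f x f pixel blocks, then
# bilinearly interpolate the block centres back to the full grid.
block_resample <- function(m, f) {
  n <- nrow(m)
  nb <- ceiling(n / f)
  pad <- nb * f
  mp <- matrix(0, pad, pad)
  mp[seq_len(n), seq_len(n)] <- m
  if (pad > n) {  # replicate the last rows/cols into the padding
    mp[(n + 1):pad, seq_len(n)] <- m[rep(n, pad - n), ]
    mp[, (n + 1):pad] <- mp[, rep(n, pad - n)]
  }
  blocks <- matrix(0, nb, nb)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    blocks[i, j] <- mean(mp[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
  }
  centers <- (seq_len(nb) - 0.5) * f + 0.5  # block centres on the fine grid
  interp1 <- function(x) {  # piecewise-linear with flat extrapolation
    idx <- findInterval(x, centers, all.inside = TRUE)
    x0 <- centers[idx]; x1 <- centers[idx + 1]
    w <- pmin(pmax((x - x0) / (x1 - x0), 0), 1)
    list(idx = idx, w = w)
  }
  gx <- interp1(seq_len(n))
  out <- matrix(0, n, n)
  for (j in seq_len(n)) {
    col0 <- blocks[, gx$idx[j]] * (1 - gx$w[j]) + blocks[, gx$idx[j] + 1] * gx$w[j]
    out[, j] <- col0[gx$idx] * (1 - gx$w) + col0[gx$idx + 1] * gx$w
  }
  out
}

#' Write a phantom sample to disk
#'
#' Writes the CT and SUV rasters as NIfTI, the truth mask as an 8-bit PNG
#' with values `{0, 255}`, the truth contour as a CSV of (row, col) vertices
#' and the spec as YAML.
#'
#' @param sample a `phantom_sample`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_phantom <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ct = file.path(dir, "ct.nii.gz"),
    suv = file.path(dir, "suv.nii.gz"),
    mask = file.path(dir, "truth_mask.png"),
    contour = file.path(dir, "truth_contour.csv"),
    spec = file.path(dir, "phantom_spec.yaml")
  )
  RNifti::writeNifti(RNifti::asNifti(sample$ct), paths["ct"])
  RNifti::writeNifti(RNifti::asNifti(sample$suv), paths["suv"])
  write_mask_png(sample$truth_mask, paths["mask"])
  write.csv(as.data.frame(sample$truth_contour), paths["contour"],
            row.names = FALSE)
  yaml::write_yaml(unclass(sample$spec), paths["spec"])
  invisible(paths)
}
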