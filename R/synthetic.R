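# Synthetic paired-cohort generator: ground-truth lesions with controllable
# complexity, observed through two acquisition models (high-resolution
# isotropic vs anisotropic thick-slice clinical grids) with a
# segmentation-variability model.

# deterministic 31-bit sub-seed from a master seed and indices
derive_seed <- function(master, ...) {
  ix <- c(...)
  s <- as.double(master) %% 2147483629
  for (v in ix) s <- (s * 48271 + as.double(v) * 16807 + 11) %% 2147483629
  as.integer(s)
}

#' Synthetic lesion specification
#'
#' The ground-truth lesion is a star-convex core whose radius field is
#' `R * (1 + amplitude * (B(u) - 0.5))`, with `B` a multi-scale spherical bump
#' field (lobe concentrations log-uniform in `spike_kappa`, weights scaled by
#' `kappa^-spike_alpha`, clipped at 1), optionally joined by capsule tendrils,
#' a thin trans-midline bridge capsule, and thin disc-shaped sheet extensions
#' emulating spread along white-matter tracts.
#'
#' @param base_radius core radius R, mm.
#' @param spike_amplitude surface-modulation amplitude, fraction of R in [0,1].
#' @param spike_count number of bump lobes.
#' @param spike_kappa range of the lobe concentration parameter.
#' @param spike_alpha spectral exponent for lobe weights.
#' @param tendril_count number of capsule tendrils.
#' @param tendril_length capsule length beyond the core, mm.
#' @param tendril_radius capsule radius, mm (< base_radius).
#' @param bridge logical: add a thin +x bridge capsule of radius
#'   `tendril_radius`.
#' @param sheet_count number of thin disc extensions.
#' @param sheet_thickness range of sheet thickness, mm.
#' @param sheet_radius_frac range of sheet disc radius as a fraction of R.
#' @param seed integer; all randomness is a pure function of it.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(base_radius, spike_amplitude = 0, spike_count = 48L,
                        spike_kappa = c(8, 300), spike_alpha = 0.35,
                        tendril_count = 0L, tendril_length = 10,
                        tendril_radius = 1.2, bridge = FALSE,
                        sheet_count = 0L, sheet_thickness = c(0.9, 1.6),
                        sheet_radius_frac = c(0.45, 0.8), seed = 1L) {
  if (base_radius <= 0) stop("base_radius must be positive", call. = FALSE)
  if (spike_amplitude < 0 || spike_amplitude > 1)
    stop("spike_amplitude must lie in [0, 1]", call. = FALSE)
  if (tendril_radius >= base_radius)
    stop("tendril_radius must be smaller than base_radius", call. = FALSE)
  structure(list(base_radius = base_radius, spike_amplitude = spike_amplitude,
                 spike_count = as.integer(spike_count), spike_kappa = spike_kappa,
                 spike_alpha = spike_alpha,
                 tendril_count = as.integer(tendril_count),
                 tendril_length = tendril_length, tendril_radius = tendril_radius,
                 bridge = isTRUE(bridge),
                 sheet_count = as.integer(sheet_count),
                 sheet_thickness = sheet_thickness,
                 sheet_radius_frac = sheet_radius_frac,
                 seed = as.integer(seed)),
            class = "lesion_spec")
}

runit <- function(n) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Voxelize a synthetic lesion
#'
#' Deterministic given `spec$seed`; the lesion is a single 26-connected
#' component by construction (all extensions overlap the core).
#'
#' @param spec a [lesion_spec()].
#' @param grid_spacing isotropic truth-grid spacing, mm; must be at most
#'   `base_radius / 10`.
#' @return a [lesion_mask()].
#' @export
generate_lesion <- function(spec, grid_spacing) {
  stopifnot(inherits(spec, "lesion_spec"))
  h <- as.numeric(grid_spacing)
  R <- spec$base_radius
  if (h <= 0 || h > R / 10 + 1e-9)
    stop("grid_spacing must be positive and at most base_radius/10", call. = FALSE)
  set.seed(spec$seed)
  amp <- spec$spike_amplitude
  split <- 0.5
  nb <- if (amp > 0) spec$spike_count else 0L
  if (nb > 0) {
    dirs <- runit(nb)
    kap <- exp(runif(nb, log(spec$spike_kappa[1]), log(spec$spike_kappa[2])))
    w <- runif(nb, 0.4, 1.0) * (spec$spike_kappa[1] / kap)^spec$spike_alpha
  } else {
    dirs <- matrix(0, 0, 3); kap <- numeric(0); w <- numeric(0)
  }
  caps <- matrix(0, 0, 7)
  reach <- 0
  if (spec$tendril_count > 0) {
    td <- runit(spec$tendril_count)
    for (i in seq_len(spec$tendril_count)) {
      p0 <- 0.4 * R * td[i, ]
      p1 <- (R + spec$tendril_length) * td[i, ]
      caps <- rbind(caps, c(p0, p1, spec$tendril_radius))
    }
    reach <- max(reach, R + spec$tendril_length)
  }
  if (spec$bridge) {
    caps <- rbind(caps, c(0.2 * R, 0, 0, R + 1.5 * spec$tendril_length, 0, 0,
                          spec$tendril_radius))
    reach <- max(reach, R + 1.5 * spec$tendril_length)
  }
  sheets <- matrix(0, 0, 8)
  if (spec$sheet_count > 0) {
    sd_ <- runit(spec$sheet_count)
    for (i in seq_len(spec$sheet_count)) {
      srad <- runif(1, spec$sheet_radius_frac[1], spec$sheet_radius_frac[2]) * R
      th <- runif(1, spec$sheet_thickness[1], spec$sheet_thickness[2])
      nv <- c(crossprod3(sd_[i, ], rnorm(3)))
      nv <- nv / sqrt(sum(nv^2))
      ctr <- 0.75 * R * sd_[i, ]
      sheets <- rbind(sheets, c(nv, ctr, srad, th))
      reach <- max(reach, 0.75 * R + srad)
    }
  }
  maxext <- max(R * (1 + (1 - split) * amp), reach) + 3
  n <- as.integer(ceiling(2 * maxext / h)) + 1L
  origin <- -h * (n - 1) / 2
  g <- cpp_rasterize_lesion(c(n, n, n), rep(origin, 3), h, R, amp, split,
                            dirs, kap, w, caps, sheets)
  lesion_mask(array(g, dim = c(n, n, n)), rep(h, 3),
              label = sprintf("synthetic-R%.1f-a%.2f-seed%d", R, amp, spec$seed))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Acquisition and segmentation specification
#'
#' Models the observation of a ground-truth lesion: Gaussian point-spread
#' blur plus voxel box-averaging (combined in quadrature), sampling on an
#' anisotropic grid with random phase and patient orientation, a smooth random
#' boundary-displacement field plus a global threshold perturbation
#' (segmentation variability across scan sessions and raters), and
#' thresholding into a binary mask.
#'
#' @param spacing per-axis voxel size, mm.
#' @param psf_fwhm per-axis point-spread FWHM, mm.
#' @param segmentation_threshold occupancy threshold in (0,1); use
#'   [calibrate_threshold()] for volume-unbiased thresholds.
#' @param seed integer seed for all per-scan randomness.
#' @param psf_jitter relative PSF variation between scans (0 disables).
#' @param threshold_jitter SD of the global threshold perturbation.
#' @param displacement_sd SD of the boundary displacement field, mm.
#' @param displacement_corr correlation length of the displacement field, mm.
#' @param rotation_deg maximal per-axis patient rotation, degrees.
#' @return object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(spacing, psf_fwhm, segmentation_threshold = 0.5,
                             seed = 1L, psf_jitter = 0.15,
                             threshold_jitter = 0.025, displacement_sd = 0.7,
                             displacement_corr = 7, rotation_deg = 15) {
  spacing <- as.numeric(spacing); psf_fwhm <- as.numeric(psf_fwhm)
  if (any(spacing <= 0) || any(psf_fwhm < 0)) stop("spacing/psf must be positive", call. = FALSE)
  if (segmentation_threshold <= 0 || segmentation_threshold >= 1)
    stop("segmentation_threshold must lie in (0,1)", call. = FALSE)
  structure(list(spacing = spacing, psf_fwhm = psf_fwhm,
                 segmentation_threshold = segmentation_threshold,
                 seed = as.integer(seed), psf_jitter = psf_jitter,
                 threshold_jitter = threshold_jitter,
                 displacement_sd = displacement_sd,
                 displacement_corr = displacement_corr,
                 rotation_deg = rotation_deg),
            class = "acquisition_spec")
}

rotation_matrix <- function(deg3) {
  a <- deg3 * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Simulate the observation of a lesion at a given acquisition
#'
#' Blur-and-threshold partial-volume model: the binary truth is blurred with
#' sigma_eff = sqrt((psf/2.3548)^2 + spacing^2/12) per axis, sampled on the
#' (randomly rotated and phased) acquisition grid, perturbed by the
#' segmentation-variability model, and thresholded. Structures thinner than
#' the slice thickness fall below threshold and are lost - the mechanism
#' behind resolution-dependent volume and complexity differences.
#'
#' @param truth a [lesion_mask()] on an isotropic grid.
#' @param acq an [acquisition_spec()]; its spacing must be at least the truth
#'   spacing on every axis.
#' @return a [lesion_mask()] on the acquisition grid.
#' @export
degrade_acquisition <- function(truth, acq) {
  stopifnot(inherits(truth, "lesion_mask"), inherits(acq, "acquisition_spec"))
  h <- truth$spacing[1]
  if (diff(range(truth$spacing)) > 1e-9)
    stop("truth mask must be isotropic", call. = FALSE)
  if (any(acq$spacing < h - 1e-9))
    stop("acquisition spacing must not be finer than the truth grid", call. = FALSE)
  set.seed(acq$seed)
  psf <- acq$psf_fwhm * runif(1, 1 - acq$psf_jitter, 1 + acq$psf_jitter)
  sig_vox <- sqrt((psf / 2.3548)^2 + acq$spacing^2 / 12) / h
  d <- dim(truth$grid)
  fld <- cpp_gauss_blur(as.numeric(truth$grid), as.integer(d), sig_vox, 0L)
  sp <- acq$spacing / h
  ctr <- (d - 1) / 2
  rot <- rotation_matrix(runif(3, -acq$rotation_deg, acq$rotation_deg))
  phase <- runif(3)
  odim <- pmax(as.integer(floor((d - 1) / sp)) + 1L, 2L)
  ax <- lapply(1:3, function(i) (phase[i] + seq_len(odim[i]) - 1) * sp[i] - ctr[i])
  P <- cbind(rep(ax[[1]], times = odim[2] * odim[3]),
             rep(rep(ax[[2]], each = odim[1]), times = odim[3]),
             rep(ax[[3]], each = odim[1] * odim[2]))
  coords <- P %*% t(rot)
  coords <- sweep(coords, 2, ctr, "+")
  if (acq$displacement_sd > 0) {
    nctl <- pmax(3L, as.integer(ceiling(d * h / acq$displacement_corr)) + 1L)
    for (axix in 1:3) {
      ctl <- rnorm(prod(nctl), 0, acq$displacement_sd / h)
      step <- (nctl - 1) / pmax(odim - 1, 1)
      dis <- cpp_resample(ctl, nctl, odim, c(0, 0, 0), step)
      coords[, axix] <- coords[, axix] + dis
    }
  }
  samp <- cpp_interp(fld, as.integer(d), coords)
  thr <- acq$segmentation_threshold + rnorm(1, 0, acq$threshold_jitter)
  g <- array(samp >= thr, dim = odim)
  if (!any(g)) stop("degraded mask is empty (lesion below threshold)", call. = FALSE)
  lesion_mask(g, acq$spacing, label = sprintf("%s-acq%d", truth$label, acq$seed))
}

#' Volume-unbiased segmentation thresholds for an acquisition
#'
#' For each reference radius, generates a spherical phantom, applies the
#' deterministic part of the observation model (nominal PSF, zero phase, no
#' rotation or displacement) and bisects the threshold until the measured
#' voxel volume matches the phantom volume. Interpolating the resulting curve
#' at a lesion's equivalent-sphere radius emulates raters who delineate
#' simple convex lesions without systematic volume bias, while partial-volume
#' loss of complex structure remains.
#'
#' @param acq an [acquisition_spec()].
#' @param radii reference sphere radii, mm.
#' @param truth_spacing phantom voxelization spacing, mm.
#' @return data.frame with columns `radius`, `threshold`.
#' @export
calibrate_threshold <- function(acq, radii, truth_spacing = NULL) {
  stopifnot(inherits(acq, "acquisition_spec"))
  if (is.null(truth_spacing)) truth_spacing <- min(radii) / 10
  thr <- vapply(radii, function(R) {
    h <- min(truth_spacing, R / 10)
    ball <- generate_lesion(lesion_spec(base_radius = R, spike_amplitude = 0, seed = 1L),
                            h)
    vt <- sum(ball$grid) * h^3
    sig_vox <- sqrt((acq$psf_fwhm / 2.3548)^2 + acq$spacing^2 / 12) / h
    d <- dim(ball$grid)
    fld <- cpp_gauss_blur(as.numeric(ball$grid), as.integer(d), sig_vox, 0L)
    sp <- acq$spacing / h
    odim <- pmax(as.integer(floor((d - 1) / sp)) + 1L, 2L)
    samp <- cpp_resample(fld, as.integer(d), odim, c(0, 0, 0), sp)
    vx <- prod(acq$spacing)
    lo <- 0.25; hi <- 0.75
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      if (sum(samp >= mid) * vx > vt) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  data.frame(radius = radii, threshold = thr)
}

#' Study scenarios
#'
#' A scenario bundles the lesion-population distributions, the truth-grid
#' spacing, the two acquisition geometries and the analysis spacing.
#' `scenario_default()` is the full-size design (radii 10-25 mm, clinical
#' grid 0.4 x 0.4 x 5 mm); `scenario_replicate()` is a reduced-size variant
#' (radii 9-14 mm, clinical 0.5 x 0.5 x 3 mm) for replicate studies;
#' `scenario_null()` is the replicate geometry with zero complexity, used for
#' type-I-error calibration.
#'
#' @param name scenario label.
#' @param radius_range,amplitude_range,sheet_count_range lesion-population
#'   distributions (uniform / discrete uniform).
#' @param bridge_prob probability of a trans-midline bridge.
#' @param tendril_count_range tendril count range (discrete uniform).
#' @param truth_spacing truth voxelization, mm.
#' @param hq_spacing,hq_psf high-quality acquisition geometry, mm.
#' @param cl_spacing,cl_psf clinical acquisition geometry, mm.
#' @param target_spacing isotropic analysis spacing, mm.
#' @return list of class `cohort_scenario`.
#' @export
scenario <- function(name, radius_range, amplitude_range, sheet_count_range,
                     bridge_prob, tendril_count_range = c(0L, 0L),
                     truth_spacing, hq_spacing, hq_psf, cl_spacing, cl_psf,
                     target_spacing, psf_jitter = 0.15, threshold_jitter = 0.025,
                     displacement_sd = 0.7, displacement_corr = 7,
                     rotation_deg = 15) {
  structure(list(name = name, radius_range = radius_range,
                 amplitude_range = amplitude_range,
                 sheet_count_range = as.integer(sheet_count_range),
                 bridge_prob = bridge_prob,
                 tendril_count_range = as.integer(tendril_count_range),
                 truth_spacing = truth_spacing,
                 hq_spacing = hq_spacing, hq_psf = hq_psf,
                 cl_spacing = cl_spacing, cl_psf = cl_psf,
                 target_spacing = target_spacing,
                 psf_jitter = psf_jitter, threshold_jitter = threshold_jitter,
                 displacement_sd = displacement_sd,
                 displacement_corr = displacement_corr,
                 rotation_deg = rotation_deg),
            class = "cohort_scenario")
}

#' @rdname scenario
#' @export
scenario_default <- function() {
  scenario("default", radius_range = c(10, 25), amplitude_range = c(0.4, 0.8),
           sheet_count_range = c(3L, 7L), bridge_prob = 0.3,
           truth_spacing = 0.4,
           hq_spacing = c(0.75, 0.75, 0.75), hq_psf = c(1, 1, 1),
           cl_spacing = c(0.4, 0.4, 5.0), cl_psf = c(0.8, 0.8, 6.0),
           target_spacing = 0.5)
}

#' @rdname scenario
#' @export
scenario_replicate <- function() {
  scenario("replicate", radius_range = c(9, 14), amplitude_range = c(0.4, 0.8),
           sheet_count_range = c(3L, 7L), bridge_prob = 0.3,
           tendril_count_range = c(2L, 6L),
           truth_spacing = 0.5,
           hq_spacing = c(0.75, 0.75, 0.75), hq_psf = c(1, 1, 1),
           cl_spacing = c(0.5, 0.5, 3.0), cl_psf = c(0.8, 0.8, 3.6),
           target_spacing = 0.7,
           threshold_jitter = 0.02, displacement_sd = 0.5, displacement_corr = 6)
}

#' @rdname scenario
#' @export
scenario_null <- function() {
  sc <- scenario_replicate()
  sc$name <- "null"
  sc$amplitude_range <- c(0, 0)
  sc$sheet_count_range <- c(0L, 0L)
  sc$bridge_prob <- 0
  sc
}

# draw one subject's lesion spec from the scenario distributions
draw_subject_spec <- function(sc, seed) {
  set.seed(seed)
  R <- runif(1, sc$radius_range[1], sc$radius_range[2])
  amp <- if (sc$amplitude_range[2] > 0)
    runif(1, sc$amplitude_range[1], sc$amplitude_range[2]) else 0
  ns <- if (sc$sheet_count_range[2] > 0)
    sample(sc$sheet_count_range[1]:sc$sheet_count_range[2], 1) else 0L
  nt <- if (sc$tendril_count_range[2] > 0)
    sample(sc$tendril_count_range[1]:sc$tendril_count_range[2], 1) else 0L
  br <- runif(1) < sc$bridge_prob
  lesion_spec(base_radius = R, spike_amplitude = amp, sheet_count = ns,
              tendril_count = nt, tendril_length = runif(1, 0.3, 0.8) * R,
              tendril_radius = runif(1, 0.8, 1.6),
              bridge = br, seed = derive_seed(seed, 7L))
}

scenario_calibration <- function(sc) {
  radii <- seq(sc$radius_range[1] * 0.85, sc$radius_range[2] * 1.15, length.out = 6)
  list(hq = calibrate_threshold(
         acquisition_spec(sc$hq_spacing, sc$hq_psf), radii,
         truth_spacing = sc$truth_spacing),
       cl = calibrate_threshold(
         acquisition_spec(sc$cl_spacing, sc$cl_psf), radii,
         truth_spacing = sc$truth_spacing))
}

interp_threshold <- function(calib, radius) {
  approx(calib$radius, calib$threshold, xout = radius, rule = 2)$y
}

# simulate one subject: truth + both observations
simulate_subject <- function(sc, subject_seed, calib) {
  spec <- draw_subject_spec(sc, subject_seed)
  truth <- generate_lesion(spec, sc$truth_spacing)
  r_eq <- (3 * sum(truth$grid) * sc$truth_spacing^3 / (4 * pi))^(1 / 3)
  mkacq <- function(spc, psf, thr, seed)
    acquisition_spec(spc, psf, segmentation_threshold = thr, seed = seed,
                     psf_jitter = sc$psf_jitter,
                     threshold_jitter = sc$threshold_jitter,
                     displacement_sd = sc$displacement_sd,
                     displacement_corr = sc$displacement_corr,
                     rotation_deg = sc$rotation_deg)
  hq <- degrade_acquisition(truth, mkacq(sc$hq_spacing, sc$hq_psf,
    interp_threshold(calib$hq, r_eq), derive_seed(subject_seed, 101L)))
  cl <- degrade_acquisition(truth, mkacq(sc$cl_spacing, sc$cl_psf,
    interp_threshold(calib$cl, r_eq), derive_seed(subject_seed, 202L)))
  list(spec = spec, truth = truth, highquality = hq, clinical = cl)
}

#' Write a synthetic paired cohort to disk
#'
#' One high-quality and one clinical NIfTI mask per subject, plus a manifest
#' CSV (`subject_id,highquality_path,clinical_path`) and a provenance file
#' recording the scenario parameters and the master seed. Fully reproducible
#' from `master_seed`.
#'
#' @param n_subjects number of subjects (>= 5).
#' @param scenario a [scenario()] (default [scenario_default()]).
#' @param master_seed integer master seed.
#' @param dir output directory (created if missing).
#' @return path of the manifest CSV (invisibly: manifest data.frame attached
#'   as attribute `manifest`).
#' @export
make_paired_cohort <- function(n_subjects, scenario = scenario_default(),
                               master_seed = 1L, dir) {
  if (n_subjects < 5) stop("need at least 5 subjects", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  calib <- scenario_calibration(scenario)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", i)
    sub <- simulate_subject(scenario, derive_seed(master_seed, i), calib)
    hq_path <- file.path(dir, sprintf("%s_highquality.nii.gz", sid))
    cl_path <- file.path(dir, sprintf("%s_clinical.nii.gz", sid))
    write_mask(sub$highquality, hq_path)
    write_mask(sub$clinical, cl_path)
    rows[[i]] <- data.frame(subject_id = sid,
                            highquality_path = basename(hq_path),
                            clinical_path = basename(cl_path),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  prov <- c(sprintf("scenario: %s", scenario$name),
            sprintf("master_seed: %d", master_seed),
            sprintf("n_subjects: %d", n_subjects),
            sprintf("truth_spacing_mm: %g", scenario$truth_spacing),
            sprintf("radius_range_mm: %g %g", scenario$radius_range[1], scenario$radius_range[2]),
            sprintf("amplitude_range: %g %g", scenario$amplitude_range[1], scenario$amplitude_range[2]),
            sprintf("sheet_count_range: %d %d", scenario$sheet_count_range[1], scenario$sheet_count_range[2]),
            sprintf("bridge_prob: %g", scenario$bridge_prob),
            sprintf("hq_spacing_mm: %s", paste(scenario$hq_spacing, collapse = " ")),
            sprintf("hq_psf_mm: %s", paste(scenario$hq_psf, collapse = " ")),
            sprintf("cl_spacing_mm: %s", paste(scenario$cl_spacing, collapse = " ")),
            sprintf("cl_psf_mm: %s", paste(scenario$cl_psf, collapse = " ")),
            sprintf("target_spacing_mm: %g", scenario$target_spacing))
  writeLines(prov, file.path(dir, "scenario.txt"))
  attr(mpath, "manifest") <- manifest
  invisible(mpath)
}
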