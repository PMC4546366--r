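# Synthetic beating-left-ventricle phantom with analytic ground truth.
#
# The cavity on slice s at phase t is the disk of angular radius profile
#   rho(theta, t, s) = R(s) * (1 - c(theta, s) * g(t)),
# where R is the end-diastolic endocardial radius, c the per-sector radial
# contraction amplitude (blended across sector boundaries by a cosine taper)
# and g a periodic waveform with g = 0 at end-diastole and 1 at end-systole.
# Contraction acts on the radius, so a sector with uniform amplitude c has
# analytic RFAC = (1 - (1-c)^2) * 100.

DEFAULT_SECTORS <- c("anterior", "antero-septal", "septal",
                     "inferior", "posterior", "lateral")

default_radius_profile <- function(n_slices, r_base = 1.55) {
  # prolate-hemisphere cap sampled below the base: nondecreasing apex->base,
  # EDV ~ 39 ul at 7 slices / 1 mm spacing
  pos <- seq_len(n_slices) / n_slices
  r_base * sqrt(1 - (1 - pos)^2)
}

default_waveform <- function(n_phases) {
  # raised-cosine contraction: g(1) = 0 (end-diastole), peak 1 mid-cycle
  # (normalized so the maximum is exactly 1 for odd phase counts too)
  g <- (1 - cos(2 * pi * (seq_len(n_phases) - 1) / n_phases)) / 2
  g / max(g)
}

#' Specification of a synthetic cine left-ventricle phantom
#'
#' Defaults emulate a mouse short-axis cine acquisition: 7 slices spaced
#' 1 mm covering the ventricle apex to base, 12 phases per cardiac cycle,
#' and a radius profile giving an end-diastolic volume of about 39 ul.
#'
#' @param n_slices number of short-axis slices, apex to base.
#' @param n_phases phases per cardiac cycle (>= 8 recommended).
#' @param matrix_px image side length in pixels.
#' @param pixel_mm pixel size in mm.
#' @param slice_spacing_mm inter-slice spacing in mm.
#' @param radius_profile end-diastolic endocardial radius per slice (mm),
#'   apex to base, positive and nondecreasing.
#' @param contraction_field radial contraction amplitude, either a single
#'   number, a length-6 per-sector vector, or a `n_sectors x n_slices`
#'   matrix; all values must be < 1.
#' @param waveform length-`n_phases` vector in `[0, 1]` with `waveform[1] = 0`
#'   and maximum 1 at the systolic phase, or `NULL` for a raised cosine.
#' @param jitter_px boundary noise SD in pixels (0 = deterministic shape).
#' @param taper_deg angular width of the cosine blend between sectors with
#'   different contraction (degrees).
#' @param sector_labels sector names in circumferential order.
#' @param reference_angle_deg orientation of the start boundary of the first
#'   sector (0 = image "up", increasing clockwise).
#' @param seed RNG seed for the boundary jitter.
#' @param subject_id identifier carried into the generated study.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 7L, n_phases = 12L, matrix_px = 128L,
                         pixel_mm = 10.24 / matrix_px, slice_spacing_mm = 1,
                         radius_profile = default_radius_profile(n_slices),
                         contraction_field = 0.45, waveform = NULL,
                         jitter_px = 0, taper_deg = 10,
                         sector_labels = DEFAULT_SECTORS,
                         reference_angle_deg = 0,
                         seed = NULL, subject_id = "phantom") {
  n_sectors <- length(sector_labels)
  cf <- contraction_field
  if (is.null(dim(cf))) {
    if (length(cf) == 1L) cf <- rep(cf, n_sectors)
    if (length(cf) != n_sectors)
      stop("contraction_field must be scalar, per-sector, or a matrix")
    cf <- matrix(cf, n_sectors, n_slices)
  }
  cf <- as.matrix(cf)
  if (!all(dim(cf) == c(n_sectors, n_slices)))
    stop("contraction_field matrix must be n_sectors x n_slices")
  if (is.null(waveform)) waveform <- default_waveform(n_phases)
  spec <- structure(list(
    n_slices = as.integer(n_slices), n_phases = as.integer(n_phases),
    matrix_px = as.integer(matrix_px), pixel_mm = pixel_mm,
    slice_spacing_mm = slice_spacing_mm, radius_profile = radius_profile,
    contraction_field = cf, waveform = waveform, jitter_px = jitter_px,
    taper_deg = taper_deg, sector_labels = sector_labels,
    reference_angle_deg = reference_angle_deg, seed = seed,
    subject_id = subject_id), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (n_slices < 1L || n_phases < 2L || matrix_px < 8L)
      stop("phantom dimensions out of range")
    if (length(radius_profile) != n_slices)
      stop("radius_profile must have one entry per slice")
    if (any(radius_profile <= 0) || any(diff(radius_profile) < -1e-12))
      stop("radius_profile must be positive and nondecreasing apex->base")
    if (length(waveform) != n_phases)
      stop("waveform must have one value per phase")
    if (abs(waveform[1]) > 1e-12 || abs(max(waveform) - 1) > 1e-9 ||
        any(waveform < -1e-12) || any(waveform > 1 + 1e-9))
      stop("waveform must lie in [0,1] with g(0)=0 and max 1")
    if (jitter_px < 0) stop("jitter_px must be >= 0")
    bad <- which(contraction_field >= 1, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "contraction amplitude >= 1 collapses the cavity (sector '%s', slice %d)",
        sector_labels[bad[1, 1]], bad[1, 2]))
    }
    if (any(contraction_field <= -0.3) || any(contraction_field >= 0.9))
      warning("contraction amplitudes outside the typical (-0.3, 0.9) range")
  })
  invisible(spec)
}

# Blended contraction amplitude as a function of angle (degrees, absolute
# image convention) for one slice. Cosine taper of width `taper_deg` centred
# on each sector boundary.
blend_contraction <- function(theta_deg, c_sector, reference_angle_deg,
                              taper_deg) {
  ns <- length(c_sector)
  w <- 360 / ns
  rel <- (theta_deg - reference_angle_deg) %% 360
  idx <- pmin(floor(rel / w) + 1L, ns)
  cval <- c_sector[idx]
  if (taper_deg > 0) {
    half <- taper_deg / 2
    pos <- rel - (idx - 1L) * w      # position within the sector, [0, w)
    nxt <- c_sector[idx %% ns + 1L]
    prv <- c_sector[(idx - 2L) %% ns + 1L]
    # approaching the forward boundary
    f <- pos > w - half
    if (any(f)) {
      u <- (pos[f] - (w - half)) / taper_deg      # in [0, 0.5)
      mix <- (1 - cos(pi * u)) / 2
      cval[f] <- cval[f] * (1 - mix) + nxt[f] * mix
    }
    # just past the backward boundary
    b <- pos < half
    if (any(b)) {
      u <- (pos[b] + half) / taper_deg            # in [0.5, 1)
      mix <- (1 - cos(pi * u)) / 2
      cval[b] <- prv[b] * (1 - mix) + cval[b] * mix
    }
  }
  cval
}

# Per-sector integrals of the blended field: returns list with I0 = sector
# arc (rad), I1 = int c dtheta, I2 = int c^2 dtheta for each sector of one
# slice, integrated on a fine angular grid (midpoint rule).
sector_field_integrals <- function(c_sector, reference_angle_deg, taper_deg,
                                   n_grid_per_sector = 2048L) {
  ns <- length(c_sector)
  w <- 360 / ns
  out <- vector("list", ns)
  for (j in seq_len(ns)) {
    a0 <- reference_angle_deg + (j - 1) * w
    th <- a0 + (seq_len(n_grid_per_sector) - 0.5) * w / n_grid_per_sector
    cv <- blend_contraction(th, c_sector, reference_angle_deg, taper_deg)
    dth <- (w / n_grid_per_sector) * pi / 180
    out[[j]] <- c(I0 = ns2rad(w), I1 = sum(cv) * dth, I2 = sum(cv^2) * dth)
  }
  out
}

ns2rad <- function(deg) deg * pi / 180

#' Generate a synthetic cine study from a phantom specification
#'
#' Rasterizes the phantom cavity on every (slice, phase) and attaches the
#' analytic ground truth: per-sector cavity areas obtained by integrating the
#' blended contraction field, the analytic per-cell RFAC, and the systolic
#' phase (argmax of the waveform). Equal seeds give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return a `cine_study` (see [load_cine()]) with a `ground_truth` element:
#'   `area_mm2` (slice x phase x sector analytic areas), `rfac_pct`
#'   (slice x sector), `ed_phase`, `es_phase`.
#' @examples
#' st <- generate_lv_phantom(phantom_spec(matrix_px = 64, n_phases = 8))
#' dim(st$masks)
#' @export
generate_lv_phantom <- function(spec) {
  validate_phantom_spec(spec)
  m <- spec$matrix_px
  ns <- length(spec$sector_labels)
  ctr <- (m - 1) / 2
  px <- seq_len(m) - 1
  dx <- matrix(px - ctr, m, m) * spec$pixel_mm            # rows = x
  dy <- matrix(px - ctr, m, m, byrow = TRUE) * spec$pixel_mm
  r <- sqrt(dx^2 + dy^2)
  th <- image_angle_deg(dx, dy)

  masks <- array(FALSE, dim = c(m, m, spec$n_slices, spec$n_phases))
  gt_area <- array(NA_real_,
                   dim = c(spec$n_slices, spec$n_phases, ns),
                   dimnames = list(NULL, NULL, spec$sector_labels))
  g <- spec$waveform
  # minimum radius check across the blended field
  for (s in seq_len(spec$n_slices)) {
    cmax <- max(spec$contraction_field[, s])
    if (spec$radius_profile[s] * (1 - cmax * max(g)) <= 0) {
      j <- which.max(spec$contraction_field[, s])
      stop(sprintf("cavity radius vanishes in sector '%s', slice %d",
                   spec$sector_labels[j], s))
    }
  }
  with_seed(spec$seed, {
    for (s in seq_len(spec$n_slices)) {
      cs <- spec$contraction_field[, s]
      cv <- blend_contraction(th, cs, spec$reference_angle_deg, spec$taper_deg)
      ints <- sector_field_integrals(cs, spec$reference_angle_deg,
                                     spec$taper_deg)
      R <- spec$radius_profile[s]
      for (t in seq_len(spec$n_phases)) {
        rho <- R * (1 - cv * g[t])
        if (spec$jitter_px > 0) {
          rho <- rho + stats::rnorm(length(rho), 0,
                                    spec$jitter_px * spec$pixel_mm)
        }
        masks[, , s, t] <- r <= rho
        for (j in seq_len(ns)) {
          I <- ints[[j]]
          # A_j(t) = R^2/2 * int (1 - c g)^2 dtheta
          gt_area[s, t, j] <- R^2 / 2 *
            (I["I0"] - 2 * g[t] * I["I1"] + g[t]^2 * I["I2"])
        }
      }
    }
  })
  es <- which.max(g)
  eda <- gt_area[, 1L, , drop = FALSE]
  esa <- gt_area[, es, , drop = FALSE]
  gt_rfac <- 100 * (eda[, 1, ] - esa[, 1, ]) / eda[, 1, ]
  gt_rfac <- matrix(gt_rfac, spec$n_slices, ns,
                    dimnames = list(NULL, spec$sector_labels))
  study <- new_cine_study(
    subject_id = spec$subject_id, masks = masks,
    pixel_mm = spec$pixel_mm, slice_spacing_mm = spec$slice_spacing_mm,
    sector_labels = spec$sector_labels,
    reference_angle_deg = spec$reference_angle_deg)
  study$ground_truth <- list(area_mm2 = gt_area, rfac_pct = gt_rfac,
                             ed_phase = 1L, es_phase = as.integer(es),
                             contraction_field = spec$contraction_field)
  study$spec <- spec
  study
}

#' Analytic RFAC for a sector-uniform radial contraction amplitude
#'
#' With contraction acting on the radius, area scales with the squared radius
#' and `RFAC = (1 - (1 - c)^2) * 100`.
#'
#' @param c contraction amplitude(s), `c < 1`.
#' @return RFAC in percent.
#' @export
analytic_rfac <- function(c) (1 - (1 - c)^2) * 100

#' Contraction amplitude producing a target analytic RFAC
#' @param rfac_pct target RFAC in percent (< 100).
#' @return amplitude `c = 1 - sqrt(1 - rfac/100)`.
#' @export
contraction_for_rfac <- function(rfac_pct) 1 - sqrt(1 - rfac_pct / 100)
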