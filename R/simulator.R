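# Seeded simulator: leaves, instrument readings, and rendered leaf images
# with the statistical structure of the six-species greenhouse study, so the
# whole pipeline is testable without a laser in the room.

#' Default generative parameters for the six study species
#'
#' Marginal means and SDs of water mass, leaf area and dry mass, the
#' per-species calibration slopes, and the leaf counts of the original
#' study design. Species codes: C_A *Corylus avellana*, O_C *Ostrya
#' carpinifolia*, Q_S *Quercus suber*, V_V *Vitis vinifera* (cv. Sangiovese),
#' Q_I *Quercus ilex*, L_N *Laurus nobilis*. Q_S leaves are small and use the
#' two-point transmission protocol; all others use four points.
#'
#' @format Data frame with one row per species and columns `species_code`,
#'   `mw_mean`, `mw_sd` (mg), `la_mean`, `la_sd` (cm^2), `ldm_mean`,
#'   `ldm_sd` (mg), `slope_K` (cm^2 mg^-1), `C0` (cm^2), `corr_mw_la`,
#'   `n_points`, `n_leaves`.
#' @export
species_defaults <- function() {
  data.frame(
    species_code = c("C_A", "O_C", "Q_S", "V_V", "Q_I", "L_N"),
    mw_mean  = c(407.18, 181.70, 49.29, 1040.40, 139.55, 202.75),
    mw_sd    = c(221.43, 36.18, 14.52, 397.13, 59.22, 81.00),
    la_mean  = c(43.64, 20.38, 5.00, 85.35, 11.27, 12.62),
    la_sd    = c(27.82, 4.99, 1.16, 24.19, 4.14, 4.80),
    ldm_mean = c(231.45, 118.50, 41.86, 263.70, 155.91, 193.25),
    ldm_sd   = c(106.95, 22.32, 10.82, 145.44, 63.69, 67.20),
    slope_K  = c(0.47, 0.45, 0.45, 0.39, 0.45, 0.31),
    C0       = 0,
    corr_mw_la = 0.98,
    n_points = c(4L, 4L, 2L, 4L, 4L, 4L),
    n_leaves = c(11L, 10L, 7L, 10L, 11L, 10L),
    stringsAsFactors = FALSE
  )
}

#' Generative parameters for one species
#'
#' @param species_code one of `"C_A"`, `"O_C"`, `"Q_S"`, `"V_V"`, `"Q_I"`,
#'   `"L_N"`, or a one-row data frame / list with the [species_defaults()]
#'   columns for a custom species.
#' @param ... fields to override (e.g. `C0 = 5`, `corr_mw_la = 0`).
#' @return An object of class `species_params`.
#' @export
species_params <- function(species_code, ...) {
  if (is.character(species_code)) {
    tab <- species_defaults()
    row <- tab[tab$species_code == species_code, ]
    if (nrow(row) != 1L) {
      leafthz_error(sprintf("unknown species code '%s'", species_code),
                    "leafthz_domain_error")
    }
    p <- as.list(row)
  } else {
    p <- as.list(as.data.frame(species_code))
  }
  over <- list(...)
  p[names(over)] <- over
  for (f in c("mw_mean", "mw_sd", "la_mean", "la_sd", "ldm_mean", "ldm_sd",
              "slope_K")) {
    check_positive(p[[f]], f)
  }
  if (abs(p$corr_mw_la) >= 1) {
    leafthz_error("`corr_mw_la` must lie in (-1, 1)", "leafthz_domain_error")
  }
  if (!p$n_points %in% c(2L, 4L)) {
    leafthz_error("`n_points` must be 2 or 4", "leafthz_protocol_error")
  }
  structure(p, class = "species_params")
}

#' Instrument noise parameters
#'
#' A compact stand-in for the laser / detector / lock-in chain: nominal beam
#' intensity, slow drift between the before/after incident readings,
#' within-leaf heterogeneity of the per-point optical depth, and additive
#' detector noise. Defaults are calibrated so the instrument-only per-leaf
#' optical-depth error stays within the smallest per-species across-leaf
#' dispersion observed on the real instrument (about 0.08 in tau); the
#' across-leaf tau SD is then dominated, as it must be, by genuine
#' leaf-to-leaf variation.
#'
#' @param I0_nominal nominal incident intensity, detector units.
#' @param drift_sd relative SD of the before/after incident readings.
#' @param point_tau_sd relative SD of per-point optical-depth heterogeneity.
#' @param detector_sd additive detector noise SD, intensity units.
#' @return An object of class `instrument_params`.
#' @export
instrument_params <- function(I0_nominal = 1000, drift_sd = 0.01,
                              point_tau_sd = 0.02,
                              detector_sd = 0.0002 * I0_nominal) {
  check_positive(I0_nominal, "I0_nominal")
  for (f in c("drift_sd", "point_tau_sd", "detector_sd")) {
    v <- get(f)
    if (!is.finite(v) || v < 0) {
      leafthz_error(sprintf("`%s` must be >= 0", f), "leafthz_domain_error")
    }
  }
  structure(list(I0_nominal = I0_nominal, drift_sd = drift_sd,
                 point_tau_sd = point_tau_sd, detector_sd = detector_sd),
            class = "instrument_params")
}

# Lognormal parameters matching a target mean m and variance v.
lognormal_moments <- function(m, v) {
  list(mu = log(m^2 / sqrt(v + m^2)), sigma2 = log(1 + v / m^2))
}

# Deterministic 32-bit sub-seed: master seed plus a stream counter, pushed
# through a multiplicative congruential step so neighboring counters decohere.
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + counter) %% 2147483629) + 1L
}

#' Sample synthetic leaves for one species
#'
#' Water mass and leaf area are drawn from a bivariate lognormal whose
#' marginal means and SDs moment-match the species parameters (positive
#' support matters: the study species have SDs up to half the mean, so
#' Gaussian marginals would truncate). Log-scale correlation between water
#' mass and area is `corr_mw_la`; dry mass is lognormal, correlated with
#' area at the same level, and water and dry mass are conditionally
#' independent given area. Fresh mass is water plus dry mass.
#'
#' @param params a [species_params()].
#' @param n number of leaves (>= 1).
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @return Data frame with one row per leaf: `species_code`, `leaf_id`,
#'   `fresh_mass_mg`, `dry_mass_mg`, `water_mass_mg`, `leaf_area_cm2`,
#'   `sla_cm2_mg`, `n_points`.
#' @export
sample_leaves <- function(params, n, seed) {
  stopifnot(inherits(params, "species_params"))
  if (n < 1L) leafthz_error("`n` must be >= 1", "leafthz_domain_error")
  set.seed(seed)
  mw <- lognormal_moments(params$mw_mean, params$mw_sd^2)
  la <- lognormal_moments(params$la_mean, params$la_sd^2)
  ld <- lognormal_moments(params$ldm_mean, params$ldm_sd^2)
  r <- params$corr_mw_la
  s <- sqrt(c(mw$sigma2, la$sigma2, ld$sigma2))
  corr <- rbind(c(1, r, r^2),   # Mw, LA, LDM; Mw _||_ LDM | LA
                c(r, 1, r),
                c(r^2, r, 1))
  z <- MASS::mvrnorm(n, mu = c(mw$mu, la$mu, ld$mu),
                     Sigma = corr * tcrossprod(s))
  z <- matrix(z, ncol = 3)
  M_w <- exp(z[, 1]); L_A <- exp(z[, 2]); LDM <- exp(z[, 3])
  data.frame(
    species_code = params$species_code,
    leaf_id = sprintf("%s_%03d", params$species_code, seq_len(n)),
    fresh_mass_mg = M_w + LDM,
    dry_mass_mg = LDM,
    water_mass_mg = M_w,
    leaf_area_cm2 = L_A,
    sla_cm2_mg = L_A / LDM,
    n_points = params$n_points,
    stringsAsFactors = FALSE
  )
}

#' Simulate one leaf's transmission measurement
#'
#' The true per-point optical depth is the forward model value
#' `(K * M_w + C0) / L_A` perturbed by relative within-leaf heterogeneity;
#' transmitted intensities are `I0 * exp(-tau_i)` plus additive detector
#' noise, clipped below at a small positive floor (`1e-6 * I0`, with a
#' warning when clipping occurs); the two incident readings carry the
#' relative drift.
#'
#' @param leaf one-row data frame from [sample_leaves()] (or any row with
#'   `water_mass_mg`, `leaf_area_cm2`, `n_points`).
#' @param sp a [species_params()].
#' @param inst an [instrument_params()].
#' @param seed integer RNG seed.
#' @return A [transmission_record()].
#' @export
simulate_measurement <- function(leaf, sp, inst = instrument_params(), seed) {
  stopifnot(inherits(sp, "species_params"), inherits(inst, "instrument_params"))
  set.seed(seed)
  fmp <- forward_model_params(sp$slope_K, sp$C0)
  tau_true <- forward_tau(leaf$water_mass_mg, leaf$leaf_area_cm2, fmp)
  np <- as.integer(leaf$n_points)
  tau_i <- tau_true * (1 + rnorm(np, 0, inst$point_tau_sd))
  itr <- inst$I0_nominal * exp(-tau_i) + rnorm(np, 0, inst$detector_sd)
  floor_i <- 1e-6 * inst$I0_nominal
  if (any(itr < floor_i)) {
    leafthz_warning("transmitted intensity clipped at the detector floor",
                    "leafthz_intensity_clipped")
    itr <- pmax(itr, floor_i)
  }
  i0 <- inst$I0_nominal * (1 + rnorm(2, 0, inst$drift_sd))
  i0 <- pmax(i0, floor_i)
  transmission_record(i0[1], i0[2], itr, small_leaf = np == 2L)
}

#' Render a synthetic leaf image
#'
#' Draws a green superellipse blade of exactly the leaf's area on a white
#' background, with 2x2 supersampled edge anti-aliasing and optional
#' Gaussian speckle. The analytic blade area (which equals `leaf_area_cm2`)
#' is returned alongside the raster for use as segmentation ground truth.
#'
#' @param leaf one-row data frame with `leaf_area_cm2`.
#' @param seed integer RNG seed (drives the speckle; geometry is
#'   deterministic).
#' @param cm_per_px rendering scale, default 0.005 cm/px (200 px per cm).
#' @param aspect blade length-to-width ratio.
#' @param exponent superellipse exponent (2 = ellipse).
#' @param speckle Gaussian pixel-noise SD on `[0, 1]` channels, default 0.
#' @return List with `image` (a [leaf_image()]) and `true_area_cm2`.
#' @export
render_leaf_image <- function(leaf, seed, cm_per_px = 0.005, aspect = 1.6,
                              exponent = 2, speckle = 0) {
  check_positive(leaf$leaf_area_cm2, "leaf_area_cm2")
  check_positive(cm_per_px, "cm_per_px")
  set.seed(seed)
  area_px <- leaf$leaf_area_cm2 / cm_per_px^2
  # superellipse |x/a|^p + |y/b|^p <= 1 has area 4ab * gamma(1+1/p)^2 / gamma(1+2/p)
  cp <- 4 * gamma(1 + 1 / exponent)^2 / gamma(1 + 2 / exponent)
  b <- sqrt(area_px / (cp * aspect))
  a <- aspect * b
  if (2 * min(a, b) < 50) {
    leafthz_error("rendering resolution too low: blade under 50 px across",
                  "leafthz_fixture_error")
  }
  H <- ceiling(2 * b * 1.2); W <- ceiling(2 * a * 1.2)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  # 2x2 supersampled coverage of the implicit region
  off <- c(-0.25, 0.25)
  cov <- matrix(0, H, W)
  for (dx in off) for (dy in off) {
    xs <- abs((seq_len(W) - 1 + dx - cx) / a)^exponent
    ys <- abs((seq_len(H) - 1 + dy - cy) / b)^exponent
    cov <- cov + (outer(ys, xs, "+") <= 1)
  }
  cov <- cov / 4
  leaf_rgb <- c(0.20, 0.55, 0.15)
  px <- array(0, c(H, W, 3))
  for (ch in 1:3) px[, , ch] <- 1 + cov * (leaf_rgb[ch] - 1)
  if (speckle > 0) {
    px <- px + array(rnorm(length(px), 0, speckle), dim(px))
    px <- pmin(pmax(px, 0), 1)
  }
  list(image = leaf_image(px, cm_per_px),
       true_area_cm2 = cp * a * b * cm_per_px^2)
}

#' Simulate a complete multi-species study
#'
#' Samples leaves per species, simulates each leaf's transmission record,
#' and assembles the measurement table in the package's CSV dialect together
#' with a ground-truth companion table. Sub-seeds are derived from the
#' master seed by a documented counter scheme (species i uses counter i for
#' leaf sampling; leaf j of species i uses counter `1000 * i + j` for its
#' measurement), so any subset is reproducible on its own.
#'
#' @param species character vector of species codes, default all six.
#' @param n_per_species integer vector of leaf counts (recycled); default
#'   the study design counts from [species_defaults()].
#' @param inst an [instrument_params()].
#' @param seed master integer seed.
#' @param path optional CSV path for the measurement table.
#' @param truth_path optional CSV path for the ground-truth table.
#' @param species_table optional data frame of generative parameters in the
#'   [species_defaults()] layout (overrides the built-ins).
#' @return List with data frames `measurements` (the CSV dialect: one row
#'   per leaf with raw intensities and masses) and `truth` (true `M_w`,
#'   `L_A`, `tau` per leaf).
#' @export
simulate_study <- function(species = species_defaults()$species_code,
                           n_per_species = NULL,
                           inst = instrument_params(), seed,
                           path = NULL, truth_path = NULL,
                           species_table = NULL) {
  tab <- if (is.null(species_table)) species_defaults() else species_table
  if (is.null(n_per_species)) {
    n_per_species <- tab$n_leaves[match(species, tab$species_code)]
  }
  n_per_species <- rep_len(n_per_species, length(species))
  meas <- list(); truth <- list()
  for (i in seq_along(species)) {
    sp <- species_params(tab[tab$species_code == species[i], ])
    leaves <- sample_leaves(sp, n_per_species[i], derive_seed(seed, i))
    fmp <- forward_model_params(sp$slope_K, sp$C0)
    rows <- lapply(seq_len(nrow(leaves)), function(j) {
      leaf <- leaves[j, ]
      rec <- simulate_measurement(leaf, sp, inst,
                                  derive_seed(seed, 1000 * i + j))
      itr <- rec$I_tr_points
      data.frame(
        species_code = leaf$species_code,
        plant_id = sprintf("P%d", (j - 1L) %% 5L + 1L),
        leaf_id = leaf$leaf_id,
        I0_before = rec$I0_before, I0_after = rec$I0_after,
        Itr_1 = itr[1], Itr_2 = itr[2],
        Itr_3 = if (rec$n_points >= 3L) itr[3] else NA_real_,
        Itr_4 = if (rec$n_points >= 4L) itr[4] else NA_real_,
        fresh_mass_mg = leaf$fresh_mass_mg,
        dry_mass_mg = leaf$dry_mass_mg,
        leaf_area_cm2 = leaf$leaf_area_cm2,
        image_path = "",
        stringsAsFactors = FALSE
      )
    })
    meas[[i]] <- do.call(rbind, rows)
    truth[[i]] <- data.frame(
      species_code = leaves$species_code,
      leaf_id = leaves$leaf_id,
      water_mass_mg = leaves$water_mass_mg,
      leaf_area_cm2 = leaves$leaf_area_cm2,
      tau_true = forward_tau(leaves$water_mass_mg, leaves$leaf_area_cm2, fmp),
      stringsAsFactors = FALSE
    )
  }
  out <- list(measurements = do.call(rbind, meas),
              truth = do.call(rbind, truth))
  rownames(out$measurements) <- NULL
  rownames(out$truth) <- NULL
  if (!is.null(path)) write.csv(out$measurements, path, row.names = FALSE)
  if (!is.null(truth_path)) write.csv(out$truth, truth_path, row.names = FALSE)
  out
}
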