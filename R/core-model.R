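# Physical model: Beer-Lambert optical depth and its gravimetric counterpart.

#' Physical constants of the water absorption model
#'
#' At 2.55 THz the absorption coefficient of liquid water is close to
#' 500 cm^-1, and water density is ~1000 mg cm^-3. Their ratio
#' `alpha / rho_w` is the theoretical slope relating optical depth to water
#' mass per unit area.
#'
#' @param alpha water absorption coefficient, cm^-1.
#' @param rho_w water density, mg cm^-3.
#' @return An object of class `physical_constants`.
#' @export
physical_constants <- function(alpha = 500, rho_w = 1000) {
  check_positive(alpha, "alpha")
  check_positive(rho_w, "rho_w")
  structure(list(alpha = alpha, rho_w = rho_w), class = "physical_constants")
}

#' Forward-model parameters
#'
#' Slope `K` (cm^2 mg^-1) and intercept `C0` (cm^2) of the linear relation
#' `tau * L_A = K * M_w + C0`. With `C0 = 0` this is the pure Beer-Lambert
#' water model; a nonzero `C0` absorbs residual absorption/scattering by dry
#' matter. Both equations share one code path: the forward model always
#' computes `(K * M_w + C0) / L_A`.
#'
#' @param K slope, cm^2 mg^-1; must be > 0.
#' @param C0 intercept, cm^2.
#' @return An object of class `forward_model_params`.
#' @export
forward_model_params <- function(K, C0 = 0) {
  check_positive(K, "K")
  if (!is.finite(C0)) leafthz_error("`C0` must be finite", "leafthz_domain_error")
  structure(list(K = K, C0 = C0), class = "forward_model_params")
}

#' One leaf's raw transmission readings
#'
#' The measurement protocol reads the incident beam intensity twice (before
#' and after the leaf measurements) and the transmitted intensity at four
#' points on the adaxial surface -- two points for small-leaved species.
#'
#' @param I0_before,I0_after incident intensity readings (detector units, > 0).
#' @param I_tr_points numeric vector of 2 or 4 transmitted intensities (> 0).
#' @param small_leaf logical; `TRUE` permits the two-point protocol. With
#'   `strict = TRUE` (default) a two-point record for a non-small leaf is a
#'   protocol error.
#' @param strict enforce the point-count/leaf-size pairing.
#' @return An object of class `transmission_record`.
#' @export
transmission_record <- function(I0_before, I0_after, I_tr_points,
                                small_leaf = FALSE, strict = TRUE) {
  check_positive(I0_before, "I0_before", "leafthz_invalid_intensity")
  check_positive(I0_after, "I0_after", "leafthz_invalid_intensity")
  n <- length(I_tr_points)
  if (!n %in% c(2L, 4L)) {
    leafthz_error("transmission protocol requires 2 or 4 points",
                  "leafthz_protocol_error")
  }
  check_positive(I_tr_points, "I_tr_points", "leafthz_invalid_intensity")
  if (strict && n == 2L && !small_leaf) {
    leafthz_error(
      "two-point protocol is reserved for small leaves; pass small_leaf = TRUE or strict = FALSE",
      "leafthz_protocol_error")
  }
  structure(list(I0_before = I0_before, I0_after = I0_after,
                 I_tr_points = as.numeric(I_tr_points), n_points = n),
            class = "transmission_record")
}

#' Average the two incident-beam readings
#'
#' @param I0_before,I0_after incident intensities (> 0), read before and
#'   after the leaf transmission measurements.
#' @return Their arithmetic mean.
#' @export
average_incident <- function(I0_before, I0_after) {
  check_positive(I0_before, "I0_before", "leafthz_invalid_intensity")
  check_positive(I0_after, "I0_after", "leafthz_invalid_intensity")
  (I0_before + I0_after) / 2
}

#' Aggregate the per-point transmitted intensities
#'
#' @param points numeric vector of 2-4 strictly positive transmitted
#'   intensities taken at different locations on the leaf.
#' @return Their arithmetic mean.
#' @export
aggregate_transmission <- function(points) {
  if (length(points) < 2L || length(points) > 4L) {
    leafthz_error("expected 2 to 4 transmission points", "leafthz_protocol_error")
  }
  check_positive(points, "points", "leafthz_invalid_intensity")
  mean(points)
}

#' Optical depth from incident and transmitted intensity
#'
#' `tau = ln(I0 / I_Tr)`. A transmitted reading above the incident one gives
#' a negative optical depth; that is physically possible under beam drift and
#' detector noise, so it is flagged with a warning rather than an error --
#' downstream calibration must tolerate it.
#'
#' @param I0_mean mean incident intensity (> 0).
#' @param Itr_mean mean transmitted intensity (> 0).
#' @return Optical depth (dimensionless); vectorized.
#' @export
optical_depth <- function(I0_mean, Itr_mean) {
  check_positive(I0_mean, "I0_mean", "leafthz_invalid_intensity")
  check_positive(Itr_mean, "Itr_mean", "leafthz_invalid_intensity")
  tau <- log(I0_mean / Itr_mean)
  if (any(tau < 0)) {
    leafthz_warning("transmitted intensity exceeds incident: negative optical depth",
                    "leafthz_negative_tau")
  }
  tau
}

#' Optical depth of a full transmission record
#'
#' The default pools intensities before the log: `tau = ln(mean I0 / mean
#' I_Tr)`, i.e. intensities are averaged first, as the measurement protocol
#' describes. `method = "per_point"` instead averages the per-point optical
#' depths `ln(mean I0 / I_tr_i)`; by concavity of the log it is never smaller
#' than the pooled value.
#'
#' @param rec a [transmission_record()].
#' @param method `"pooled"` (default) or `"per_point"`.
#' @return Optical depth (dimensionless).
#' @export
record_optical_depth <- function(rec, method = c("pooled", "per_point")) {
  method <- match.arg(method)
  stopifnot(inherits(rec, "transmission_record"))
  I0 <- average_incident(rec$I0_before, rec$I0_after)
  if (method == "pooled") {
    optical_depth(I0, aggregate_transmission(rec$I_tr_points))
  } else {
    mean(optical_depth(rep(I0, rec$n_points), rec$I_tr_points))
  }
}

#' Forward model: optical depth from water mass and area
#'
#' `tau = (K * M_w + C0) / L_A`; with `C0 = 0` this is the Beer-Lambert
#' relation `tau = K * M_w / L_A`.
#'
#' @param M_w water mass, mg (>= 0); vectorized.
#' @param L_A projected leaf area, cm^2 (> 0).
#' @param params a [forward_model_params()].
#' @return Optical depth (dimensionless).
#' @export
forward_tau <- function(M_w, L_A, params) {
  stopifnot(inherits(params, "forward_model_params"))
  if (anyNA(M_w) || any(M_w < 0)) {
    leafthz_error("`M_w` must be non-negative", "leafthz_domain_error")
  }
  check_positive(L_A, "L_A")
  (params$K * M_w + params$C0) / L_A
}

#' Invert the forward model
#'
#' Algebraic inverse of [forward_tau()]: `M_w = (tau * L_A - C0) / K`.
#'
#' @inheritParams forward_tau
#' @param tau optical depth.
#' @return Water mass, mg.
#' @export
invert_tau <- function(tau, L_A, params) {
  stopifnot(inherits(params, "forward_model_params"))
  check_positive(L_A, "L_A")
  (tau * L_A - params$C0) / params$K
}

#' Effective water thickness
#'
#' The thickness of a pure-water slab holding the leaf's water volume spread
#' over its area: `d_w = M_w / (rho_w * L_A)`. Beer-Lambert gives
#' `tau = alpha * d_w`, which is the forward model with `K = alpha / rho_w`.
#'
#' @param M_w water mass, mg (>= 0).
#' @param L_A leaf area, cm^2 (> 0).
#' @param constants a [physical_constants()].
#' @return Water thickness, cm.
#' @export
effective_water_thickness <- function(M_w, L_A, constants = physical_constants()) {
  stopifnot(inherits(constants, "physical_constants"))
  if (anyNA(M_w) || any(M_w < 0)) {
    leafthz_error("`M_w` must be non-negative", "leafthz_domain_error")
  }
  check_positive(L_A, "L_A")
  M_w / (constants$rho_w * L_A)
}

#' Gravimetric water mass
#'
#' Fresh mass minus oven-dry mass (105 degrees C, 24 h).
#'
#' @param fresh,dry masses in mg; `fresh >= dry > 0`.
#' @return Water mass, mg; vectorized.
#' @export
water_mass <- function(fresh, dry) {
  check_positive(dry, "dry")
  check_positive(fresh, "fresh")
  if (any(dry > fresh)) {
    leafthz_error("dry mass exceeds fresh mass", "leafthz_gravimetry_error")
  }
  fresh - dry
}

#' Specific leaf area
#'
#' Leaf area per unit dry mass, cm^2 mg^-1. Low SLA is typical of thick
#' and/or waxy leaves.
#'
#' @param L_A leaf area, cm^2 (> 0).
#' @param dry dry mass, mg (> 0).
#' @return SLA, cm^2 mg^-1; vectorized.
#' @export
specific_leaf_area <- function(L_A, dry) {
  check_positive(L_A, "L_A")
  check_positive(dry, "dry")
  L_A / dry
}
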