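# Per-species linear calibration tau * L_A = C1 * M_w + C0 and its inverse.
#
# Regression direction follows the measurement design: the optically derived
# product tau * L_A is the response, gravimetric water mass the predictor;
# prediction of water mass is the algebraic inverse of the fit, not a reverse
# regression.

required_fit_cols <- c("water_mass_mg", "leaf_area_cm2", "tau")

#' Fit the water-mass calibration for one species
#'
#' Ordinary least squares of `y = tau * leaf_area` on `x = water_mass`.
#' Reports slope `C1` (cm^2 mg^-1), intercept `C0` (cm^2), their standard
#' errors and covariance, plain and adjusted R^2, the two-sided Pearson
#' correlation test, and the residual standard deviation.
#'
#' @param records data frame with columns `water_mass_mg`, `leaf_area_cm2`,
#'   `tau` (one row per leaf); a `species_code` column, if present, is carried
#'   into the result.
#' @return An object of class `calibration_model`.
#' @export
fit_calibration <- function(records) {
  records <- as.data.frame(records)
  miss <- setdiff(required_fit_cols, names(records))
  if (length(miss)) {
    leafthz_error(paste("missing columns:", paste(miss, collapse = ", ")),
                  "leafthz_format_error")
  }
  x <- records$water_mass_mg
  y <- records$tau * records$leaf_area_cm2
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    leafthz_error("calibration needs >= 3 leaves with finite tau, area and mass",
                  "leafthz_insufficient_data")
  }
  if (var(x) == 0) {
    leafthz_error("water mass has zero variance: degenerate design",
                  "leafthz_degenerate_design")
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(
    species_code = if ("species_code" %in% names(records))
      as.character(records$species_code[1]) else NA_character_,
    C1 = unname(coef(fit)[2]),
    C0 = unname(coef(fit)[1]),
    se_C1 = sm$coefficients[2, 2],
    se_C0 = sm$coefficients[1, 2],
    cov_C0_C1 = vcov(fit)[1, 2],
    R2 = sm$r.squared,
    adj_R2 = sm$adj.r.squared,
    pearson_r = unname(ct$estimate),
    pearson_p = ct$p.value,
    residual_sd = sm$sigma,
    n = n
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration (%s, n = %d): tau*L_A = %.4f * M_w %+.4f\n",
              ifelse(is.na(x$species_code), "?", x$species_code), x$n,
              x$C1, x$C0))
  cat(sprintf("  C1 = %.4f +/- %.4f cm^2/mg, C0 = %.3f +/- %.3f cm^2\n",
              x$C1, x$se_C1, x$C0, x$se_C0))
  cat(sprintf("  adj R^2 = %.4f, Pearson r = %.4f (p = %.3g)\n",
              x$adj_R2, x$pearson_r, x$pearson_p))
  invisible(x)
}

#' Zero-intercept calibration slope
#'
#' Least squares through the origin, `K = sum(x y) / sum(x^2)`, for the pure
#' Beer-Lambert relation `tau * L_A = K * M_w`.
#'
#' @inheritParams fit_calibration
#' @return Slope `K`, cm^2 mg^-1.
#' @export
fit_zero_intercept <- function(records) {
  records <- as.data.frame(records)
  miss <- setdiff(required_fit_cols, names(records))
  if (length(miss)) {
    leafthz_error(paste("missing columns:", paste(miss, collapse = ", ")),
                  "leafthz_format_error")
  }
  x <- records$water_mass_mg
  y <- records$tau * records$leaf_area_cm2
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x)) leafthz_error("no finite records", "leafthz_insufficient_data")
  if (sum(x^2) == 0) {
    leafthz_error("all water masses are zero: degenerate design",
                  "leafthz_degenerate_design")
  }
  sum(x * y) / sum(x^2)
}

#' Adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)`; may be negative for poor fits.
#'
#' @param R2 coefficient of determination in `[0, 1]`.
#' @param n number of observations.
#' @param p number of regressors (1 throughout this package).
#' @return Adjusted R^2.
#' @export
adjusted_r2 <- function(R2, n, p = 1L) {
  if (anyNA(R2) || any(R2 < 0) || any(R2 > 1)) {
    leafthz_error("`R2` must lie in [0, 1]", "leafthz_domain_error")
  }
  if (n <= p + 1L) {
    leafthz_error("adjusted R^2 needs n > p + 1", "leafthz_domain_error")
  }
  1 - (1 - R2) * (n - 1) / (n - p - 1)
}

#' Two-sided Pearson correlation test
#'
#' Sample correlation with the t-transform p-value on n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with elements `r` and `p`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    leafthz_error("`x` and `y` must have equal length >= 3",
                  "leafthz_insufficient_data")
  }
  if (var(x) == 0 || var(y) == 0) {
    leafthz_error("zero variance in `x` or `y`", "leafthz_degenerate_design")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Predict leaf water mass from a nondestructive measurement
#'
#' Inverts the fitted calibration: `M_w = (tau * L_A - C0) / C1`. The
#' standard error propagates, to first order (delta method), the residual
#' scatter of a new observation and the sampling uncertainty of the
#' coefficients:
#' `var(M_w) = (residual_sd^2 + se_C0^2 + M_w^2 se_C1^2 + 2 M_w cov(C0, C1)) / C1^2`.
#' The interval uses the t-quantile on n - 2 degrees of freedom. A negative
#' prediction (possible when `tau * L_A < C0`) is returned as-is with a
#' warning; truncation would bias validation statistics.
#'
#' @param tau measured optical depth.
#' @param L_A measured leaf area, cm^2.
#' @param model a [fit_calibration()] result; `C1` must be > 0.
#' @param confidence interval coverage, default 0.95.
#' @return An object of class `prediction_result`: list with `M_w_hat` (mg),
#'   `se` (mg), `interval` (low, high) and `confidence`.
#' @export
predict_water_mass <- function(tau, L_A, model, confidence = 0.95) {
  stopifnot(inherits(model, "calibration_model"))
  check_positive(L_A, "L_A")
  if (!is.finite(model$C1) || model$C1 <= 0) {
    leafthz_error("calibration slope C1 must be positive to invert",
                  "leafthz_non_invertible_calibration")
  }
  if (confidence <= 0 || confidence >= 1) {
    leafthz_error("`confidence` must be in (0, 1)", "leafthz_domain_error")
  }
  m <- (tau * L_A - model$C0) / model$C1
  if (any(m < 0)) {
    leafthz_warning("negative predicted water mass (tau * L_A < C0)",
                    "leafthz_negative_prediction")
  }
  v <- (model$residual_sd^2 + model$se_C0^2 + m^2 * model$se_C1^2 +
          2 * m * model$cov_C0_C1) / model$C1^2
  se <- sqrt(pmax(v, 0))
  tq <- qt(1 - (1 - confidence) / 2, df = model$n - 2L)
  structure(list(M_w_hat = m, se = se,
                 interval = cbind(low = m - tq * se, high = m + tq * se),
                 confidence = confidence),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  for (i in seq_along(x$M_w_hat)) {
    cat(sprintf("M_w_hat = %.1f mg, se = %.1f, %g%% CI [%.1f, %.1f]\n",
                x$M_w_hat[i], x$se[i], 100 * x$confidence,
                x$interval[i, "low"], x$interval[i, "high"]))
  }
  invisible(x)
}

# Tukey-Kramer all-pairs p-values for named group vectors, via one-way aov.
tukey_pairwise <- function(groups) {
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  TukeyHSD(aov(value ~ group, data = df))$group
}

#' Compact letter display from Tukey-Kramer comparisons
#'
#' All-pairs Tukey-Kramer mean comparisons (valid for unequal group sizes)
#' at level `alpha`, summarized as shared-letter sets by the standard
#' insert-and-absorb algorithm: groups that do not share a letter differ
#' significantly. Letters are assigned with groups ordered by descending
#' mean.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param alpha family-wise significance level, default 0.05.
#' @return Named character vector of letter strings, one per group.
#' @export
tukey_letters <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L || is.null(names(groups))) {
    leafthz_error("need >= 2 named groups", "leafthz_insufficient_data")
  }
  if (any(lengths(groups) < 2L)) {
    leafthz_error("every group needs >= 2 values", "leafthz_insufficient_data")
  }
  ord <- names(groups)[order(-vapply(groups, mean, numeric(1)))]
  hsd <- tukey_pairwise(groups)
  # significant pairs at alpha
  pair_names <- strsplit(rownames(hsd), "-", fixed = TRUE)
  sig <- lapply(which(hsd[, "p adj"] <= alpha), function(i) pair_names[[i]])

  letters_sets <- list(ord)  # start: one letter containing every group
  for (pair in sig) {
    k <- 1L
    while (k <= length(letters_sets)) {
      s <- letters_sets[[k]]
      if (all(pair %in% s)) {
        # insert: split the offending set into two, each missing one member
        letters_sets[[k]] <- setdiff(s, pair[1])
        letters_sets <- append(letters_sets, list(setdiff(s, pair[2])), after = k)
        k <- k + 1L
      }
      k <- k + 1L
    }
    # absorb: drop sets contained in another
    keep <- rep(TRUE, length(letters_sets))
    for (i in seq_along(letters_sets)) {
      for (j in seq_along(letters_sets)) {
        if (i != j && keep[j] &&
            all(letters_sets[[i]] %in% letters_sets[[j]]) &&
            !(all(letters_sets[[j]] %in% letters_sets[[i]]) && i < j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    letters_sets <- letters_sets[keep]
  }
  # order letter columns by the highest-mean group they contain
  first_pos <- vapply(letters_sets, function(s) min(match(s, ord)), numeric(1))
  letters_sets <- letters_sets[order(first_pos)]
  out <- setNames(rep("", length(groups)), names(groups))
  for (i in seq_along(letters_sets)) {
    for (g in letters_sets[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  out
}

#' Per-species correlation table
#'
#' For each species, three simple regressions -- `tau` on `M_w`, `tau` on
#' `L_A`, and `tau * L_A` on `M_w` -- each summarized as adjusted R^2 with a
#' significance flag from the two-sided Pearson test. Only the composite
#' product is expected to correlate with water mass across leaves of varying
#' area; the single-variable rows typically do not.
#'
#' @param records data frame with columns `species_code`, `water_mass_mg`,
#'   `leaf_area_cm2`, `tau`.
#' @param alpha significance level for the star, default 0.05.
#' @return Data frame with columns `species_code`, `relation`, `adj_R2`,
#'   `pearson_r`, `pearson_p`, `significant`.
#' @export
correlation_table <- function(records, alpha = 0.05) {
  records <- as.data.frame(records)
  miss <- setdiff(c("species_code", required_fit_cols), names(records))
  if (length(miss)) {
    leafthz_error(paste("missing columns:", paste(miss, collapse = ", ")),
                  "leafthz_format_error")
  }
  one <- function(x, y, sp, label) {
    n <- sum(is.finite(x) & is.finite(y))
    if (n < 3L) {
      leafthz_error(sprintf("species %s has < 3 usable leaves", sp),
                    "leafthz_insufficient_data")
    }
    if (var(x) == 0 || var(y) == 0) {  # constant predictor or response
      return(data.frame(species_code = sp, relation = label,
                        adj_R2 = NA_real_, pearson_r = NA_real_,
                        pearson_p = NA_real_, significant = FALSE))
    }
    r2 <- summary(lm(y ~ x))$r.squared
    pt_ <- pearson_test(x, y)
    data.frame(species_code = sp, relation = label,
               adj_R2 = adjusted_r2(r2, n, 1L),
               pearson_r = pt_$r, pearson_p = pt_$p,
               significant = pt_$p <= alpha)
  }
  out <- lapply(split(records, records$species_code), function(d) {
    sp <- as.character(d$species_code[1])
    rbind(
      one(d$water_mass_mg, d$tau, sp, "tau_vs_Mw"),
      one(d$leaf_area_cm2, d$tau, sp, "tau_vs_LA"),
      one(d$water_mass_mg, d$tau * d$leaf_area_cm2, sp, "tauLA_vs_Mw")
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
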