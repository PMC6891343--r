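# Measurement-table I/O and study reporting.
#
# CSV dialect (fixed to avoid locale ambiguity): comma separator, point
# decimal, UTF-8, header row. One row per leaf:
#   species_code, plant_id, leaf_id, I0_before, I0_after, Itr_1..Itr_4
#   (Itr_3/Itr_4 may be blank for the two-point protocol), fresh_mass_mg,
#   dry_mass_mg, leaf_area_cm2 (optional), image_path (optional).

measurement_columns <- c("species_code", "plant_id", "leaf_id",
                         "I0_before", "I0_after",
                         "Itr_1", "Itr_2", "Itr_3", "Itr_4",
                         "fresh_mass_mg", "dry_mass_mg")

#' Read and validate a measurement table
#'
#' Parses the measurement CSV, computes per-leaf derived quantities (water
#' mass, optical depth, SLA where possible), and rejects invalid rows with
#' row-numbered messages instead of failing the whole file. Blank `Itr_3` /
#' `Itr_4` yields a two-point record.
#'
#' @param path CSV file path.
#' @param tau_method `"pooled"` (average intensities, then log; default) or
#'   `"per_point"`.
#' @return List with `records` (data frame of valid leaves, including
#'   derived `water_mass_mg` and `tau`) and `rejected` (data frame of `row`,
#'   `reason`).
#' @export
read_measurements <- function(path, tau_method = c("pooled", "per_point")) {
  tau_method <- match.arg(tau_method)
  if (!file.exists(path)) {
    leafthz_error(sprintf("file not found: %s", path), "leafthz_format_error")
  }
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) leafthz_error(paste("cannot parse CSV:", conditionMessage(e)),
                                      "leafthz_format_error"))
  miss <- setdiff(measurement_columns, names(df))
  if (length(miss)) {
    leafthz_error(paste("missing required columns:", paste(miss, collapse = ", ")),
                  "leafthz_format_error")
  }
  num_cols <- setdiff(measurement_columns, c("species_code", "plant_id", "leaf_id"))
  for (cc in c(num_cols, intersect("leaf_area_cm2", names(df)))) {
    bad <- !is.na(df[[cc]]) & df[[cc]] != "" & is.na(suppressWarnings(as.numeric(df[[cc]])))
    if (any(bad)) {
      leafthz_error(sprintf("non-numeric value in column '%s', row %d",
                            cc, which(bad)[1]), "leafthz_parse_error")
    }
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  }
  keep <- rep(TRUE, nrow(df)); reasons <- character(nrow(df))
  recs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    itr <- as.numeric(r[c("Itr_1", "Itr_2", "Itr_3", "Itr_4")])
    itr <- itr[!is.na(itr)]
    res <- tryCatch({
      rec <- transmission_record(r$I0_before, r$I0_after, itr, strict = FALSE)
      mw <- water_mass(r$fresh_mass_mg, r$dry_mass_mg)
      tau <- withCallingHandlers(
        record_optical_depth(rec, method = tau_method),
        leafthz_negative_tau = function(w) invokeRestart("muffleWarning"))
      la <- if ("leaf_area_cm2" %in% names(r)) r$leaf_area_cm2 else NA_real_
      data.frame(species_code = r$species_code, plant_id = r$plant_id,
                 leaf_id = r$leaf_id,
                 fresh_mass_mg = r$fresh_mass_mg, dry_mass_mg = r$dry_mass_mg,
                 water_mass_mg = mw, leaf_area_cm2 = la,
                 sla_cm2_mg = if (is.na(la)) NA_real_ else la / r$dry_mass_mg,
                 tau = tau, n_points = rec$n_points,
                 I0_before = r$I0_before, I0_after = r$I0_after,
                 Itr_1 = df$Itr_1[i], Itr_2 = df$Itr_2[i],
                 Itr_3 = df$Itr_3[i], Itr_4 = df$Itr_4[i],
                 stringsAsFactors = FALSE)
    }, leafthz_error = function(e) conditionMessage(e))
    if (is.character(res)) {
      keep[i] <- FALSE
      reasons[i] <- res
    } else {
      recs[[i]] <- res
    }
  }
  list(records = if (any(keep)) do.call(rbind, recs[keep]) else NULL,
       rejected = data.frame(row = which(!keep), reason = reasons[!keep],
                             stringsAsFactors = FALSE))
}

#' Save a calibration model as JSON
#'
#' Stores every model field plus metadata: the significance level in force,
#' an input digest (md5 of the fitting data when supplied), and optionally a
#' timestamp (off by default so identical inputs give identical files).
#'
#' @param model a [fit_calibration()] result.
#' @param path output JSON path.
#' @param alpha significance level recorded alongside the fit.
#' @param input optional data frame the model was fitted to (digested, not
#'   stored).
#' @param timestamp logical; include a wall-clock timestamp.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, alpha = 0.05, input = NULL,
                             timestamp = FALSE) {
  stopifnot(inherits(model, "calibration_model"))
  meta <- list(alpha = alpha,
               input_digest = if (is.null(input)) NA_character_ else
                 unname(tools::md5sum(local({
                   tf <- tempfile(); write.csv(input, tf, row.names = FALSE); tf
                 }))))
  if (timestamp) meta$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(c(unclass(model), list(metadata = meta)), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Load a calibration model saved by [write_model_json()]
#'
#' @param path JSON path.
#' @return A `calibration_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$metadata <- NULL
  structure(obj, class = "calibration_model")
}

#' Build a study report
#'
#' Assembles, per species: the fitted calibration table; a trait summary
#' (mean +/- SD of water mass, area, dry mass, SLA with Tukey-Kramer compact
#' letters when more than one species is present); and the three-relation
#' correlation table. Machine-readable JSON is written first; rendered text
#' tables (numbers to 2 decimals) and one scatter figure per species are
#' derived from the same numbers. Identical inputs give byte-identical JSON.
#'
#' @param records data frame of validated leaves ([read_measurements()]
#'   `$records` layout).
#' @param models named list of `calibration_model` objects (one per
#'   species); fitted on the fly from `records` when `NULL`.
#' @param alpha significance level for letters and stars.
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `report.txt` and `fit_<species>.png`.
#' @return An object of class `study_report` (list with `summary`,
#'   `calibrations`, `correlations`, `alpha`).
#' @export
build_report <- function(records, models = NULL, alpha = 0.05, out_dir = NULL) {
  records <- as.data.frame(records)
  if (!nrow(records)) leafthz_error("no records to report", "leafthz_empty_report")
  by_sp <- split(records, records$species_code)
  if (is.null(models)) {
    models <- lapply(by_sp, fit_calibration)
  }
  if (!length(models)) leafthz_error("no fitted models", "leafthz_empty_report")

  if (!"sla_cm2_mg" %in% names(records) &&
      all(c("leaf_area_cm2", "dry_mass_mg") %in% names(records))) {
    records$sla_cm2_mg <- records$leaf_area_cm2 / records$dry_mass_mg
    by_sp <- split(records, records$species_code)
  }
  traits <- intersect(c("water_mass_mg", "leaf_area_cm2", "dry_mass_mg",
                        "sla_cm2_mg"), names(records))
  summary_rows <- lapply(traits, function(tr) {
    vals <- lapply(by_sp, function(d) d[[tr]][is.finite(d[[tr]])])
    lets <- if (length(vals) > 1L && all(lengths(vals) >= 2L))
      tukey_letters(vals, alpha) else setNames(rep(NA_character_, length(vals)),
                                               names(vals))
    data.frame(trait = tr, species_code = names(vals),
               mean = vapply(vals, mean, numeric(1)),
               sd = vapply(vals, sd, numeric(1)),
               letters = unname(lets[names(vals)]),
               stringsAsFactors = FALSE)
  })
  summary_tab <- do.call(rbind, summary_rows)
  rownames(summary_tab) <- NULL

  calib_tab <- do.call(rbind, lapply(names(models), function(sp) {
    m <- models[[sp]]
    data.frame(species_code = sp, C1 = m$C1, se_C1 = m$se_C1, C0 = m$C0,
               se_C0 = m$se_C0, adj_R2 = m$adj_R2, pearson_r = m$pearson_r,
               pearson_p = m$pearson_p, n = m$n, stringsAsFactors = FALSE)
  }))
  rownames(calib_tab) <- NULL

  report <- structure(list(summary = summary_tab, calibrations = calib_tab,
                           correlations = correlation_table(records, alpha),
                           alpha = alpha),
                      class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
    writeLines(render_report_text(report), file.path(out_dir, "report.txt"))
    for (sp in names(models)) {
      d <- by_sp[[sp]]
      png(file.path(out_dir, paste0("fit_", sp, ".png")), 600, 500)
      plot(d$water_mass_mg, d$tau * d$leaf_area_cm2,
           xlab = "water mass (mg)",
           ylab = expression(tau %.% L[A] ~ (cm^2)),
           main = sprintf("%s: tau*L_A vs M_w", sp), pch = 19)
      abline(models[[sp]]$C0, models[[sp]]$C1, col = "red", lwd = 2)
      dev.off()
    }
  }
  report
}

render_report_text <- function(report) {
  f2 <- function(x) formatC(x, format = "f", digits = 2)
  out <- c("== Trait summary (mean +/- SD; shared letters: not significantly different) ==")
  for (tr in unique(report$summary$trait)) {
    d <- report$summary[report$summary$trait == tr, ]
    out <- c(out, paste0(tr, ":"),
             sprintf("  %-4s %s +/- %s %s", d$species_code, f2(d$mean),
                     f2(d$sd), ifelse(is.na(d$letters), "", d$letters)))
  }
  out <- c(out, "", "== Calibration tau*L_A = C1*M_w + C0 ==",
           sprintf("  %-4s C1 = %s +/- %s, C0 = %s, adj R^2 = %s (n = %d)",
                   report$calibrations$species_code,
                   f2(report$calibrations$C1), f2(report$calibrations$se_C1),
                   f2(report$calibrations$C0), f2(report$calibrations$adj_R2),
                   report$calibrations$n))
  out <- c(out, "", "== Correlations (adj R^2; * = Pearson p <= alpha) ==",
           sprintf("  %-4s %-12s %s%s", report$correlations$species_code,
                   report$correlations$relation, f2(report$correlations$adj_R2),
                   ifelse(report$correlations$significant, " *", " ns")))
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat(paste(render_report_text(x), collapse = "\n"), "\n")
  invisible(x)
}
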