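# Shared fixtures: all synthetic, built in code at test time.

quiet_inst <- function() {
  instrument_params(drift_sd = 0, point_tau_sd = 0, detector_sd = 0)
}

# Attach derived water mass and pooled tau to a simulate_study measurement
# table without going through CSV (the CSV round trip has its own test).
records_from_measurements <- function(m, method = "pooled") {
  m$water_mass_mg <- m$fresh_mass_mg - m$dry_mass_mg
  m$tau <- vapply(seq_len(nrow(m)), function(i) {
    itr <- as.numeric(m[i, c("Itr_1", "Itr_2", "Itr_3", "Itr_4")])
    itr <- itr[!is.na(itr)]
    rec <- transmission_record(m$I0_before[i], m$I0_after[i], itr,
                               strict = FALSE)
    suppressWarnings(record_optical_depth(rec, method = method))
  }, numeric(1))
  m
}

# Simulate one species' calibration records directly (no CSV).
sim_species_records <- function(code, n, seed, inst = instrument_params(),
                                ...) {
  sp <- species_params(code, ...)
  leaves <- sample_leaves(sp, n, seed)
  tau <- vapply(seq_len(n), function(j) {
    rec <- suppressWarnings(
      simulate_measurement(leaves[j, ], sp, inst, seed * 131 + j))
    suppressWarnings(record_optical_depth(rec))
  }, numeric(1))
  data.frame(species_code = code,
             water_mass_mg = leaves$water_mass_mg,
             leaf_area_cm2 = leaves$leaf_area_cm2,
             tau = tau)
}

# Noiseless records lying exactly on tau * L_A = K * M_w + C0.
exact_records <- function(M_w, L_A, K, C0 = 0, code = "XX") {
  data.frame(species_code = code, water_mass_mg = M_w, leaf_area_cm2 = L_A,
             tau = (K * M_w + C0) / L_A)
}

# Even-odd (crossing-number) point-in-polygon, used as the independent
# rasterization oracle for the shoelace formula.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Explicit Tukey-Kramer two-sided p-value for groups i, j (independent of
# stats::TukeyHSD): studentized range on the pooled within-group variance.
tukey_kramer_p <- function(groups, i, j) {
  k <- length(groups)
  N <- sum(lengths(groups))
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / (N - k)
  se <- sqrt(s2 / 2 * (1 / length(groups[[i]]) + 1 / length(groups[[j]])))
  q <- abs(mean(groups[[i]]) - mean(groups[[j]])) / se
  stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
}
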