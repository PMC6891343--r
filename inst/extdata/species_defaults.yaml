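# Generative parameters for the six study species (synthetic study defaults).
# Units: masses mg, areas cm^2, slope_K cm^2/mg. corr_mw_la is the log-scale
# correlation between water mass and leaf area.
C_A:
  mw_mean: 407.18
  mw_sd: 221.43
  la_mean: 43.64
  la_sd: 27.82
  ldm_mean: 231.45
  ldm_sd: 106.95
  slope_K: 0.47
  C0: 0.0
  corr_mw_la: 0.98
  n_points: 4
  n_leaves: 11
O_C:
  mw_mean: 181.70
  mw_sd: 36.18
  la_mean: 20.38
  la_sd: 4.99
  ldm_mean: 118.50
  ldm_sd: 22.32
  slope_K: 0.45
  C0: 0.0
  corr_mw_la: 0.98
  n_points: 4
  n_leaves: 10
Q_S:
  mw_mean: 49.29
  mw_sd: 14.52
  la_mean: 5.00
  la_sd: 1.16
  ldm_mean: 41.86
  ldm_sd: 10.82
  slope_K: 0.45
  C0: 0.0
  corr_mw_la: 0.98
  n_points: 2
  n_leaves: 7
V_V:
  mw_mean: 1040.40
  mw_sd: 397.13
  la_mean: 85.35
  la_sd: 24.19
  ldm_mean: 263.70
  ldm_sd: 145.44
  slope_K: 0.39
  C0: 0.0
  corr_mw_la: 0.98
  n_points: 4
  n_leaves: 10
Q_I:
  mw_mean: 139.55
  mw_sd: 59.22
  la_mean: 11.27
  la_sd: 4.14
  ldm_mean: 155.91
  ldm_sd: 63.69
  slope_K: 0.45
  C0: 0.0
  corr_mw_la: 0.98
  n_points: 4
  n_leaves: 11
L_N:
  mw_mean: 202.75
  mw_sd: 81.00
  la_mean: 12.62
  la_sd: 4.80
  ldm_mean: 193.25
  ldm_sd: 67.20
  slope_K: 0.31
  C0: 0.0
  corr_mw_la: 0.98
  n_points: 4
  n_leaves: 10
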