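# Independent brute-force comparators used as oracles. These re-state the
# published threshold and band tables as literal if-chains, written
# separately from the package's lookup code.

# -- SIRS: value strictly outside [lower, upper] of the printed table ----
oracle_sirs_flags <- function(hr, rr, temp, wbc, phase) {
  lim <- if (phase == "day") {
    list(hr = c(70, 130), rr = c(14, 29), temp = c(37.1, 39.9))
  } else {
    list(hr = c(68, 116), rr = c(10, 23), temp = c(37.8, 39.7))
  }
  c(hr = hr < lim$hr[1] || hr > lim$hr[2],
    rr = rr < lim$rr[1] || rr > lim$rr[2],
    temp = temp < lim$temp[1] || temp > lim$temp[2],
    wbc = wbc < 12.1 || wbc > 26.2)
}

# -- SOFA: literal transcription of the six-system band table ------------
oracle_sofa <- function(pf, creat, bili, plat, map, snort) {
  resp <- if (pf >= 400) 0 else if (pf < 100) 4 else if (pf < 200) 3 else
    if (pf < 300) 2 else 1
  cr <- floor(creat * 10 + 0.5) / 10 # half-away rounding at 1 decimal
  ren <- if (cr >= 5.0) 4 else if (cr >= 3.5) 3 else if (cr >= 2.5) 2 else
    if (cr >= 1.5) 1 else 0
  bi <- floor(bili * 10 + 0.5) / 10
  hep <- if (bi > 10) 4 else if (bi >= 5.1) 3 else if (bi >= 2.1) 2 else
    if (bi >= 0.7) 1 else 0
  hem <- if (plat <= 20) 4 else if (plat <= 50) 3 else if (plat <= 100) 2
  else if (plat <= 150) 1 else 0
  mp <- floor(map + 0.5)
  cv <- if (mp < 40) 4 else if (mp <= 49) 3 else if (mp <= 59) 2 else
    if (mp <= 70) 1 else 0
  neu <- if (snort >= 10) 0 else if (snort >= 8) 1 else if (snort >= 6) 2
  else if (snort >= 4) 3 else 4
  c(respiratory = resp, renal = ren, hepatic = hep, hematological = hem,
    cardiovascular = cv, neurological = neu)
}

# -- NEWS2: literal per-parameter band lookup on the derived edges -------
# (edges re-derived here from the printed means/SDs, independent of
#  derive_news2_table)
oracle_news2_points <- function(parameter, value, phase) {
  half_away <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d
  ms <- list(
    day = list(rr = c(22, 3.9), sbp = c(140, 14), hr = c(100, 15.1),
               temp = c(38.5, 0.69)),
    night = list(rr = c(16, 3.1), sbp = c(132.5, 12.5), hr = c(92, 12.0),
                 temp = c(38.8, 0.47)))
  if (parameter == "spo2") {
    p <- if (value >= 96) 0 else if (value >= 94) 1 else
      if (value >= 92) 2 else 3
    return(p)
  }
  if (parameter == "snort") return(if (value >= 10) 0 else 3)
  st <- ms[[phase]][[parameter]]
  d <- if (parameter == "temp") 1 else 0
  e <- half_away(st[1] + (-4:4)[-5] * st[2], d) # m4 m3 m2 m1 p1 p2 p3 p4
  names(e) <- c("m4", "m3", "m2", "m1", "p1", "p2", "p3", "p4")
  if (value >= e["p4"]) 3 else if (value >= e["p3"]) 2 else
    if (value >= e["p2"]) 1 else if (value <= e["m4"]) 3 else
    if (value <= e["m3"]) 2 else if (value <= e["m2"]) 1 else 0
}

# -- exact Mann-Whitney by subset enumeration on the raw values ----------
# U counted over pairs (not ranks); two-sided tail of |U - nx ny / 2|.
oracle_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  n <- length(pooled)
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  mu <- nx * length(y) / 2
  obs <- abs(u_of(x, y) - mu)
  idx <- utils::combn(n, nx)
  devs <- apply(idx, 2, function(i) abs(u_of(pooled[i], pooled[-i]) - mu))
  mean(devs >= obs - 1e-9)
}

# -- small, fast simulation configs --------------------------------------
tiny_config <- function(..., seed = 1) {
  simulation_config(n_control = 2, n_pat = 2, duration_h = 24,
                    baseline_h = 12, telemetry_step_min = 60,
                    seed = seed, ...)
}

# zero-noise, zero-amplitude channels: samples equal the phase means
quiet_channels <- function() {
  lapply(default_channels(), function(s) {
    s$amplitude <- 0
    s$amplitude2 <- 0
    s$noise_sd <- 0
    s
  })
}

random_snapshot <- function() {
  vitals_snapshot(
    phase = sample(c("day", "night"), 1),
    hr = stats::runif(1, 40, 220), rr = stats::runif(1, 5, 45),
    temp = stats::runif(1, 35, 42), wbc = stats::runif(1, 1, 35),
    platelets = stats::runif(1, 10, 500),
    creatinine = stats::runif(1, 0.1, 6),
    bilirubin = stats::runif(1, 0.02, 12),
    map = stats::runif(1, 30, 130), pf_ratio = stats::runif(1, 60, 500),
    snort = sample(2:11, 1), spo2 = stats::runif(1, 85, 100),
    sbp = stats::runif(1, 70, 210))
}
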