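test_that("clock times partition into day and night, counts conserved", {
  expect_identical(diurnal_phase(12), "day")
  expect_identical(diurnal_phase(0), "night")
  expect_identical(diurnal_phase(c(6, 17.99, 18, 5.99)),
                   c("day", "day", "night", "night"))
  # 48 h of minute-resolution samples: exactly half day, half night
  t_min <- seq(0, 48 - 1 / 60, by = 1 / 60)
  s <- data.frame(clock_hour = (8 + t_min) %% 24, value = 0)
  parts <- partition_diurnal(s)
  expect_equal(nrow(parts$day), nrow(parts$night))
  expect_equal(nrow(parts$day) + nrow(parts$night), nrow(s))
  s$clock_hour[1] <- NA
  expect_error(partition_diurnal(s), "timestamp")
})

test_that("diurnal statistics recover constants and the two-value SD", {
  mk_animal <- function(values) {
    t <- seq(-12, -1)
    clock <- (8 + t) %% 24
    list(telemetry = data.frame(
      time_h = t, clock_hour = clock,
      phase = diurnal_phase(clock), channel = "hr",
      value = values, stringsAsFactors = FALSE),
      labs = data.frame(time_h = c(-8, 0), analyte = "wbc",
                        value = c(19.1, 19.1)))
  }
  st <- compute_diurnal_stats(list(mk_animal(rep(5, 12))),
                              window_start = -12)
  expect_true(all(st$mean[st$parameter == "hr"] == 5))
  expect_true(all(st$sd[st$parameter == "hr"] == 0))
  # sample SD of two values {a, b} is |a - b| / sqrt(2)
  a <- 3; b <- 10
  two <- mk_animal(rep(5, 12))
  two$labs$value <- c(a, b)
  st2 <- compute_diurnal_stats(list(two), window_start = -12)
  expect_equal(st2$sd[st2$parameter == "wbc"], abs(a - b) / sqrt(2))
  # insufficient data errors name the parameter and phase
  short <- mk_animal(rep(5, 12))
  short$labs <- short$labs[1, ]
  expect_error(compute_diurnal_stats(list(short), window_start = -12),
               "wbc.*pooled")
})

test_that("baseline statistics of a simulated healthy cohort recover the
          configured means", {
  cfg <- simulation_config(n_control = 6, n_pat = 0, duration_h = 0,
                           baseline_h = 48, telemetry_step_min = 15,
                           seed = 21)
  st <- compute_diurnal_stats(simulate_cohort(cfg))
  hr_day <- st[st$parameter == "hr" & st$phase == "day", ]
  # autocorrelated noise: use a generous SE bound from the marginal SD
  expect_lt(abs(hr_day$mean - 100), 5)
  expect_lt(abs(hr_day$sd - 15.1), 4)
  hr_night <- st[st$parameter == "hr" & st$phase == "night", ]
  expect_lt(abs(hr_night$mean - 92), 5)
})

test_that("SIRS thresholds are round(mean +/- 2 SD) at display precision", {
  tab <- derive_sirs_table(printed_baseline_stats())
  hr_day <- tab[tab$parameter == "hr" & tab$phase == "day", ]
  expect_equal(c(hr_day$upper, hr_day$lower), c(130, 70))
  hr_night <- tab[tab$parameter == "hr" & tab$phase == "night", ]
  expect_equal(c(hr_night$upper, hr_night$lower), c(116, 68))
  temp_day <- tab[tab$parameter == "temp" & tab$phase == "day", ]
  expect_equal(c(temp_day$upper, temp_day$lower), c(39.9, 37.1))
  wbc <- tab[tab$parameter == "wbc", ]
  expect_equal(wbc$lower, 12.1)
  # degenerate SD collapses both bounds onto the mean
  st0 <- diurnal_stats(parameter = c("hr", "hr", "rr", "rr", "temp",
                                     "temp", "wbc"),
                       phase = c("day", "night", "day", "night", "day",
                                 "night", "pooled"),
                       mean = c(100, 92, 22, 16, 38.5, 38.8, 19.1),
                       sd = 0)
  tab0 <- derive_sirs_table(st0)
  expect_equal(tab0$lower, tab0$upper)
  expect_equal(tab0$upper, tab0$mean)
  # missing parameter is an explicit error
  expect_error(derive_sirs_table(st0[st0$parameter != "rr", ]), "rr")
})

test_that("NEWS2 band edges sit at mean +/- 1..4 SD, rounded", {
  tab <- derive_news2_table(printed_baseline_stats())
  night <- tab[tab$parameter == "hr" & tab$phase == "night", ]
  edges <- setNames(night$edge, night$band)
  expect_equal(unname(edges[c("m1", "p1")]), c(80, 104)) # 0-point band
  expect_equal(unname(edges[c("p2", "p3", "p4")]), c(116, 128, 140))
  day <- tab[tab$parameter == "hr" & tab$phase == "day", ]
  d <- setNames(day$edge, day$band)
  expect_equal(unname(d[c("m1", "p1")]), c(85, 115))
  expect_equal(unname(d[c("m4", "m2", "p2", "p3")]), c(40, 70, 130, 145))
})

test_that("widening the SD widens every band; shifting the mean translates
          all edges", {
  base <- printed_baseline_stats()
  t1 <- derive_news2_table(base)
  wide <- base; wide$sd <- wide$sd * 2
  t2 <- derive_news2_table(wide)
  shift <- base; shift$mean <- shift$mean + 10
  t3 <- derive_news2_table(shift)
  key <- paste(t1$parameter, t1$phase, t1$band)
  stopifnot(identical(key, paste(t2$parameter, t2$phase, t2$band)))
  k <- c(m4 = -4, m3 = -3, m2 = -2, m1 = -1, p1 = 1, p2 = 2, p3 = 3,
         p4 = 4)[t1$band]
  expect_true(all(sign(t2$edge - t1$edge) == sign(k) |
                    t2$edge == t1$edge))
  expect_true(all(abs((t3$edge - t1$edge) - 10) <= 0.5 + 1e-9))
})

test_that("the derived-vs-printed audit flags exactly the inconsistent
          published cells", {
  st <- printed_baseline_stats()
  a_sirs <- audit_sirs_table(derive_sirs_table(st))
  bad <- a_sirs[!is.na(a_sirs$match) & !a_sirs$match, ]
  bad_keys <- sort(paste(bad$parameter, bad$phase, bad$bound))
  expect_identical(bad_keys,
                   sort(c("rr day upper", "rr night upper",
                          "temp night lower", "wbc pooled upper")))
  # the self-consistent rows all match
  good <- a_sirs[a_sirs$parameter == "hr" |
                   (a_sirs$parameter == "temp" & a_sirs$phase == "day"), ]
  expect_true(all(good$match))
  a_n2 <- audit_news2_table(derive_news2_table(st))
  hr_cells <- a_n2[a_n2$parameter == "hr" &
                     a_n2$band %in% c("m1", "m2", "p1", "p2", "p3"), ]
  expect_true(all(hr_cells$match))
  # known discrepant cells are flagged, not silently matched
  expect_false(a_n2$match[a_n2$parameter == "hr" & a_n2$phase == "night" &
                            a_n2$band == "m4"])
})

test_that("rounding is half away from zero at display precision", {
  expect_equal(round_half_away(130.2), 130)
  expect_equal(round_half_away(69.8), 70)
  expect_equal(round_half_away(115.1), 115)
  expect_equal(round_half_away(84.9), 85)
  expect_equal(round_half_away(39.88, 1), 39.9)
  expect_equal(round_half_away(0.5), 1)   # never round-half-even
  expect_equal(round_half_away(-0.5), -1)
  expect_equal(round_half_away(82.5), 83)
})

test_that("threshold tables round-trip through YAML with provenance", {
  st <- printed_baseline_stats()
  sirs <- derive_sirs_table(st)
  news2 <- derive_news2_table(st)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_thresholds_yaml(sirs, news2, st, path)
  back <- read_thresholds_yaml(path)
  expect_equal(back$sirs$upper, sirs$upper)
  expect_equal(back$sirs$lower, sirs$lower)
  expect_equal(back$news2$edge, news2$edge)
  expect_match(back$provenance$rounding, "half away")
})
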