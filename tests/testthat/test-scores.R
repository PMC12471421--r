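sirs_tab <- printed_sirs_table()
bands <- derive_news2_table(printed_baseline_stats())

test_that("the injured-group extrema score as the published bands dictate", {
  # tachycardic, leukopenic snapshot: 2 of 4 criteria -> SIRS state
  snap <- vitals_snapshot(phase = "day", hr = 201, rr = 20, temp = 39.2,
                          wbc = 3.9)
  res <- evaluate_sirs(snap, sirs_tab)
  expect_identical(res$criteria,
                   c(hr = TRUE, rr = FALSE, temp = FALSE, wbc = TRUE))
  expect_equal(res$n_met, 2)
  expect_true(res$sirs_state)

  # SOFA worked components at the published extreme values
  expect_equal(sofa_component("respiratory", 418.15), 0L)
  expect_equal(sofa_component("hematological", 132.2), 1L)
  expect_equal(sofa_component("renal", 2.0), 1L)
  expect_equal(sofa_component("hepatic", 0.53), 0L)
  expect_equal(sofa_component("cardiovascular", 100), 0L)
  expect_equal(sofa_component("neurological", 11), 0L)
  tot <- sofa_total(vitals_snapshot(phase = "day", pf_ratio = 418.15,
                                    creatinine = 2.0, bilirubin = 0.53,
                                    platelets = 132.2, map = 100,
                                    snort = 11),
                    baseline_total = 0)
  expect_equal(unname(tot$components), c(0L, 1L, 0L, 1L, 0L, 0L))
  expect_equal(tot$total, 2)
  expect_true(tot$sepsis_flag)

  # NEWS2: peak tachycardia is extreme; depressed SNORT is extreme
  expect_equal(news2_points("hr", 201, "day", bands),
               list(points = 3L, extreme = TRUE))
  expect_equal(news2_points("hr", 92, "night", bands),
               list(points = 0L, extreme = FALSE))
  expect_equal(news2_points("snort", 6.6, "day", bands),
               list(points = 3L, extreme = TRUE))
})

test_that("snapshots at the phase means score zero everywhere", {
  snap <- vitals_snapshot(phase = "night", hr = 92, rr = 16, temp = 38.8,
                          wbc = 19.1, platelets = 350, creatinine = 1.0,
                          bilirubin = 0.4, map = 104, pf_ratio = 448,
                          snort = 11, spo2 = 97, sbp = 132.5)
  expect_equal(evaluate_sirs(snap, sirs_tab)$n_met, 0)
  expect_false(evaluate_sirs(snap, sirs_tab)$sirs_state)
  st <- sofa_total(snap, 0)
  expect_equal(st$total, 0)
  expect_false(st$sepsis_flag)
  n2 <- news2_total(snap, bands)
  expect_equal(n2$total, 0)
  expect_false(n2$positive)
})

test_that("SIRS handles missing parameters as unknown criteria", {
  snap <- vitals_snapshot(phase = "day", hr = 201, rr = 20, temp = 39.2)
  res <- evaluate_sirs(snap, sirs_tab)
  expect_true(is.na(res$criteria["wbc"]))
  expect_equal(res$n_known, 3)
  expect_false(res$complete)
  expect_equal(res$n_met, 1)
})

test_that("every SOFA band edge maps to its published score on both
          sides", {
  cases <- list(
    # respiratory: >=400 -> 0, then <400 / <300 / <200 / <100
    list("respiratory", c(400, 399.9, 300, 299.9, 200, 199.9, 100, 99.9),
         c(0, 1, 1, 2, 2, 3, 3, 4)),
    # renal closed intervals after 1-decimal rounding
    list("renal", c(0.3, 1.4, 1.44, 1.45, 2.4, 2.5, 3.4, 3.5, 4.9, 5.0),
         c(0, 0, 0, 1, 1, 2, 2, 3, 3, 4)),
    # hepatic closed intervals; below-table values score 0
    list("hepatic", c(0.11, 0.3, 0.6, 0.64, 0.65, 2.0, 2.1, 5.0, 5.1,
                      10.0, 10.1),
         c(0, 0, 0, 0, 1, 1, 2, 2, 3, 3, 4)),
    # hematological closed upper edges
    list("hematological", c(151, 150, 101, 100, 51, 50, 21, 20),
         c(0, 1, 1, 2, 2, 3, 3, 4)),
    # cardiovascular: 70 itself scores 1, integer rounding first
    list("cardiovascular", c(71, 70.5, 70, 60, 59.4, 59, 50, 49, 40, 39),
         c(0, 0, 1, 1, 2, 2, 2, 3, 3, 4)),
    # neurological SNORT ranges
    list("neurological", c(11, 10, 9.9, 8, 7.9, 6, 5.9, 4, 3.9, 2),
         c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4)))
  for (case in cases) {
    got <- vapply(case[[2]], function(v)
      as.integer(sofa_component(case[[1]], v)), 1L)
    expect_equal(got, as.integer(case[[3]]), label = case[[1]])
  }
  # out-of-table note below the lowest renal band
  sc <- sofa_component("renal", 0.2)
  expect_equal(as.integer(sc), 0L)
  expect_identical(attr(sc, "note"), "below lowest defined band")
})

test_that("NEWS2 band edges score their published column on both sides", {
  # day HR: 0-band 85-115, then 130 / 145 / 161-ish (derived 160)
  day_hr <- list(c(84, 0), c(85, 0), c(115, 0), c(116, 0), c(129, 0),
                 c(130, 1), c(144, 1), c(145, 2), c(160, 3),
                 c(70, 1), c(69, 1), c(40, 3), c(41, 2))
  for (cs in day_hr) {
    expect_equal(news2_points("hr", cs[1], "day", bands)$points,
                 as.integer(cs[2]), label = paste("day hr", cs[1]))
  }
  # night HR printed columns: 116 -> 1, 128 -> 2, 140 -> 3, 68 -> 1, 45/44 -> 3
  night_hr <- list(c(104, 0), c(115, 0), c(116, 1), c(127, 1), c(128, 2),
                   c(139, 2), c(140, 3), c(80, 0), c(69, 0), c(68, 1),
                   c(57, 1), c(56, 2), c(45, 2), c(44, 3))
  for (cs in night_hr) {
    expect_equal(news2_points("hr", cs[1], "night", bands)$points,
                 as.integer(cs[2]), label = paste("night hr", cs[1]))
  }
  # fixed SpO2 row
  spo2 <- list(c(96, 0), c(95, 1), c(94, 1), c(93, 2), c(92, 2), c(91, 3))
  for (cs in spo2) {
    expect_equal(news2_points("spo2", cs[1], "day", bands)$points,
                 as.integer(cs[2]), label = paste("spo2", cs[1]))
  }
  # fixed SNORT row
  expect_equal(news2_points("snort", 10, "day", bands)$points, 0L)
  expect_equal(news2_points("snort", 9.9, "day", bands)$points, 3L)
  expect_error(news2_points("wbc", 10, "day", bands), "no rows")
})

test_that("NEWS2 positivity follows the sum >= 5 or extreme-value rule", {
  # one extreme parameter alone is positive
  snap <- vitals_snapshot(phase = "day", hr = 100, rr = 22, temp = 38.5,
                          snort = 6)
  res <- news2_total(snap, bands)
  expect_equal(res$total, 3)
  expect_true(res$extreme_flag)
  expect_true(res$positive)
  # five single points sum to a positive score without any extreme
  snap5 <- vitals_snapshot(phase = "day", hr = 131, rr = 14, temp = 39.9,
                           sbp = 112, spo2 = 95, snort = 11)
  res5 <- news2_total(snap5, bands)
  expect_equal(res5$total, 5)
  expect_false(res5$extreme_flag)
  expect_true(res5$positive)
  # missing SpO2/SBP contribute nothing but are recorded
  part <- news2_total(vitals_snapshot(phase = "day", hr = 100, rr = 22,
                                      temp = 38.5, snort = 11), bands)
  expect_false(part$complete)
  expect_setequal(part$missing, c("spo2", "sbp"))
  expect_equal(part$total, 0)
  expect_error(news2_total(vitals_snapshot(phase = "day", snort = 11),
                           bands), "core parameters")
})

test_that("SNORT totals are validated sums clipped to [2, 11]", {
  r <- snort_rubric()
  expect_equal(sum(r$max), 11)
  expect_equal(sum(r$min), 2)
  expect_equal(snort_score(setNames(r$max, r$item)), 11L)
  expect_equal(snort_score(setNames(r$min, r$item)), 2L)
  bad <- setNames(r$max, r$item); bad[1] <- bad[1] + 1
  expect_error(snort_score(bad), "out of range")
  expect_error(snort_score(setNames(r$max, rev(letters[1:5]))), "named")
  set.seed(4)
  for (i in 1:25) {
    s <- setNames(mapply(function(lo, hi) sample(lo:hi, 1), r$min, r$max),
                  r$item)
    expect_equal(snort_score(s), as.integer(min(max(sum(s), 2), 11)))
  }
})

test_that("scoring matches the independent brute-force comparators on
          random snapshots", {
  set.seed(101)
  for (i in 1:400) {
    snap <- random_snapshot()
    # SIRS
    res <- evaluate_sirs(snap, sirs_tab)
    expect_identical(unname(res$criteria),
                     unname(oracle_sirs_flags(snap$hr, snap$rr, snap$temp,
                                              snap$wbc, snap$phase)))
    # SOFA
    tot <- sofa_total(snap, 0)
    expect_identical(unname(as.integer(tot$components)),
                     unname(as.integer(
                       oracle_sofa(snap$pf_ratio, snap$creatinine,
                                   snap$bilirubin, snap$platelets,
                                   snap$map, snap$snort))))
    expect_equal(tot$total, sum(oracle_sofa(snap$pf_ratio, snap$creatinine,
                                            snap$bilirubin, snap$platelets,
                                            snap$map, snap$snort)))
    # NEWS2 per parameter
    for (p in c("rr", "sbp", "hr", "temp", "spo2", "snort")) {
      expect_equal(news2_points(p, snap[[p]], snap$phase, bands)$points,
                   as.integer(oracle_news2_points(p, snap[[p]],
                                                  snap$phase)),
                   label = paste(p, snap[[p]], snap$phase))
    }
  }
})

test_that("worsening any single parameter never lowers a score", {
  set.seed(55)
  worsen <- function(snap, p, amount) {
    # push the value away from the healthy center
    centers <- c(hr = 96, rr = 19, temp = 38.65, wbc = 19.1,
                 platelets = 350, creatinine = 1, bilirubin = 0.45,
                 map = 105, pf_ratio = 450, snort = 11, spo2 = 100,
                 sbp = 136)
    v <- snap[[p]]
    if (p %in% c("platelets", "pf_ratio", "snort", "spo2")) {
      snap[[p]] <- max(v - amount, c(platelets = 1, pf_ratio = 1,
                                     snort = 2, spo2 = 1)[[p]])
    } else {
      snap[[p]] <- v + if (v >= centers[[p]]) amount else -amount
    }
    snap
  }
  params <- c("hr", "rr", "temp", "wbc", "platelets", "creatinine",
              "bilirubin", "map", "pf_ratio", "snort", "spo2", "sbp")
  for (i in 1:60) {
    snap <- random_snapshot()
    base_sirs <- evaluate_sirs(snap, sirs_tab)$n_met
    base_sofa <- sofa_total(snap, 0)$total
    base_news <- news2_total(snap, bands)$total
    p <- sample(params, 1)
    amount <- stats::runif(1, 0, 40) *
      if (p %in% c("temp", "creatinine", "bilirubin", "wbc")) 0.1 else 1
    worse <- worsen(snap, p, amount)
    expect_gte(evaluate_sirs(worse, sirs_tab)$n_met, base_sirs)
    expect_gte(sofa_total(worse, 0)$total, base_sofa)
    expect_gte(news2_total(worse, bands)$total, base_news)
  }
})

test_that("score ranges are always respected", {
  set.seed(77)
  for (i in 1:200) {
    snap <- random_snapshot()
    expect_true(evaluate_sirs(snap, sirs_tab)$n_met %in% 0:4)
    tot <- sofa_total(snap, 0)
    expect_true(tot$total >= 0 && tot$total <= 24)
    expect_true(all(tot$components %in% 0:4))
    n2 <- news2_total(snap, bands)
    expect_true(all(n2$points[!is.na(n2$points)] %in% 0:3))
  }
})

test_that("snapshot validation rejects unphysical values", {
  expect_error(vitals_snapshot(hr = -5), "hr")
  expect_error(vitals_snapshot(spo2 = 104), "spo2")
  expect_error(vitals_snapshot(snort = 1), "snort")
})
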