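cluster1_baseline <- function() {
  c(walk = 0.33, cycle = 0.03, IPT = 0.125, bus = 0.18, `2W` = 0.084,
    car = 0.112, train = 0.139)
}

test_that("one half-point step moves exactly 0.005 of share between modes", {
  base <- cluster1_baseline()
  def <- scenario_def("2W", "car")
  s1 <- shift_shares(base, def, 1)
  expect_equal(unname(s1["car"]), 0.117)
  expect_equal(unname(s1["2W"]), 0.079)
  others <- setdiff(names(base), c("car", "2W"))
  expect_equal(s1[others], base[others])
  expect_equal(sum(s1), sum(base), tolerance = 1e-12)

  expect_equal(shift_shares(base, def, 0), base)
  tiny <- base; tiny["2W"] <- 0.004
  expect_null(shift_shares(tiny, def, 1))
  expect_error(shift_shares(base, def, -1), "step_index")
})

test_that("relative risk is a share-ratio power product", {
  base <- cluster1_baseline()
  ex <- scenario_exponents()
  expect_identical(relative_risk(base, base, ex), 1)

  s1 <- shift_shares(base, scenario_def("2W", "car"), 1)
  got <- relative_risk(s1, base, ex)
  # direct scalar evaluation oracle
  want <- (0.117 / 0.112)^0.26 * (0.079 / 0.084)^0.39
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(round(got, 4), 0.9875)

  # constant-multiplier equivalence: absolute distances give the same RR
  expect_equal(relative_risk(s1 * 3.7e6, base * 3.7e6, ex), got,
               tolerance = 1e-12)

  zero <- base; zero["walk"] <- 0
  expect_error(relative_risk(zero, base, ex), "negative exponent")
  expect_error(relative_risk(base, zero, ex), "baseline")
})

test_that("scenario curves have ten points unless truncated early", {
  base <- cluster1_baseline()
  cur <- run_scenario(base, scenario_def("2W", "car"))
  expect_equal(nrow(cur$steps), 10)
  expect_false(cur$truncated)
  expect_identical(cur$steps$rr[1], 1)

  low <- base; low["cycle"] <- 0.018; low["walk"] <- base[["walk"]] + 0.012
  cur2 <- run_scenario(low, scenario_def("cycle", "2W"))
  expect_equal(nrow(cur2$steps), 4)  # steps 0..3; 0.018/0.005 allows 3 shifts
  expect_true(cur2$truncated)
})

test_that("share totals are conserved and log-RR is additive over steps", {
  base <- cluster1_baseline()
  for (def in list(scenario_def("2W", "car"), scenario_def("walk", "2W"))) {
    cur <- run_scenario(base, def)
    share_cols <- names(base)
    totals <- rowSums(cur$steps[, share_cols])
    expect_true(all(abs(totals - sum(base)) < 1e-12))
    # per-step factor product reproduces the directly computed RR
    shares_i <- lapply(seq_len(nrow(cur$steps)) - 1,
                       function(i) shift_shares(base, def, i))
    for (i in seq_along(shares_i)[-1]) {
      step_factor <- relative_risk(shares_i[[i]], shares_i[[i - 1]],
                                   def$exponents)
      expect_equal(cur$steps$rr[i], cur$steps$rr[i - 1] * step_factor,
                   tolerance = 1e-12)
    }
  }
})

test_that("shift from a protective to a risky mode raises RR monotonically", {
  base <- cluster1_baseline()
  ex <- scenario_exponents()
  for (pair in list(c("walk", "2W"), c("cycle", "2W"), c("walk", "car"))) {
    expect_lt(ex[pair[1]], 0)
    expect_gt(ex[pair[2]], 0)
    cur <- run_scenario(base, scenario_def(pair[1], pair[2]))
    expect_true(all(diff(cur$steps$rr) > 0))
  }
})

test_that("2W-to-car shape depends on the baseline car:2W ratio", {
  ex <- scenario_exponents()
  rest <- c(walk = 0.2, cycle = 0.1, IPT = 0.1, bus = 0.2)
  mk <- function(car, w2) c(rest, car = car, `2W` = w2,
                            train = 1 - sum(rest) - car - w2)
  # high ratio (the printed 0.112/0.084 = 1.33): already past the critical
  # point, RR declines throughout
  high <- run_scenario(mk(0.112, 0.084), scenario_def("2W", "car"))
  expect_true(all(diff(high$steps$rr) < 0))
  # low ratio (0.3): strictly increasing over all ten steps
  low <- run_scenario(mk(0.075, 0.25), scenario_def("2W", "car"))
  expect_true(all(diff(low$steps$rr) > 0))
  # intermediate ratio (~0.55): rises to a critical point then falls
  mid <- run_scenario(mk(0.11, 0.20), scenario_def("2W", "car"))
  tp <- detect_turning_point(mid, direction = "max")
  expect_false(is.na(tp))
  expect_gt(tp, 0)
  expect_lt(tp, 9)
})

test_that("turning-point detection finds the first interior extremum", {
  expect_true(is.na(detect_turning_point(c(1.0, 1.02, 1.05, 1.1))))
  expect_equal(detect_turning_point(c(1.0, 0.98, 0.97, 0.99)), 2L)
  expect_true(is.na(detect_turning_point(c(1.0, 0.99, 0.98, 0.97))))
  expect_equal(detect_turning_point(c(1.0, 1.03, 1.02, 1.04),
                                    direction = "max"), 1L)
  expect_error(detect_turning_point(c(1, 2)), "3 points")
})

test_that("a both-negative exponent pair can produce a genuine U", {
  base <- c(walk = 0.1, cycle = 0.01, IPT = 0.14, bus = 0.3, `2W` = 0.25,
            car = 0.2)
  # walk (-0.36) to cycle (-0.2): losing the strongly protective mode first
  # dominates, then the growing cycle term wins: RR falls then rises
  cur <- run_scenario(base, scenario_def("walk", "cycle", n_steps = 10))
  tp <- detect_turning_point(cur)
  expect_false(is.na(tp))
  expect_true(cur$steps$rr[tp + 1] < 1)
})

test_that("run_scenarios produces A/B/C curves for every baseline row", {
  profiles <- data.frame(cluster = 1:2,
                         share_walk = c(0.33, 0.2), share_cycle = c(0.03, 0.2),
                         share_IPT = c(0.125, 0.05), share_bus = c(0.18, 0.2),
                         `share_2W` = c(0.084, 0.25), share_car = c(0.112, 0.1),
                         check.names = FALSE)
  out <- run_scenarios(profiles)
  expect_setequal(unique(out$scenario), c("A", "B", "C"))
  expect_equal(sum(out$step == 0), 6)  # 2 baselines x 3 scenarios
  expect_true(all(out$rr[out$step == 0] == 1))
})

test_that("full-precision exponents differ from rounded in the 3rd decimal", {
  r <- scenario_exponents("rounded")
  f <- scenario_exponents("full")
  expect_equal(names(r), names(f))
  expect_lt(max(abs(r - f)), 0.01)
  base <- cluster1_baseline()
  s1 <- shift_shares(base, scenario_def("2W", "car"), 1)
  expect_false(relative_risk(s1, base, r) == relative_risk(s1, base, f))
})
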