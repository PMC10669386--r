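test_that("triangular membership evaluates hat and degenerate shoulders", {
  mf <- c(0, 50, 100)
  expect_equal(fz_membership(mf, 50), 1)
  expect_equal(fz_membership(mf, 125), 0)
  expect_equal(fz_membership(mf, -5), 0)
  expect_equal(fz_membership(mf, 25), 0.5)
  # one-sided ramps with membership 1 at the peak
  expect_equal(fz_membership(c(0, 0, 50), 0), 1)
  expect_equal(fz_membership(c(0, 0, 50), 25), 0.5)
  expect_equal(fz_membership(c(50, 100, 100), 100), 1)
  expect_equal(fz_membership(c(50, 100, 100), 75), 0.5)
  expect_error(fz_membership(c(2, 1, 3), 1), "a <= b <= c")
})

test_that("fuzzification clamps, covers, and partitions adjacent labels", {
  sys <- default_fuzzy_system()
  d <- fz_fuzzify(sys$ceg, 0.25)
  expect_equal(unname(d["B"]), 1)
  expect_true(all(d >= 0 & d <= 1))
  # evenly spaced partition with touching feet: adjacent degrees sum to 1
  for (x in c(0.1, 0.37, 0.61, 0.9)) {
    expect_equal(sum(fz_fuzzify(sys$ceg, x)), 1)
  }
  for (v in c(1.3, 2.5, 3.9)) {
    expect_equal(sum(fz_fuzzify(sys$voltage, v)), 1)
  }
  # clamp contract: below-domain input behaves as the domain end
  lo <- fz_fuzzify(sys$voltage, 0.2)
  at_lo <- fz_fuzzify(sys$voltage, 1.0)
  expect_equal(as.numeric(lo), as.numeric(at_lo))
  expect_true(isTRUE(attr(lo, "clamped")))
  expect_null(attr(at_lo, "clamped"))
})

test_that("system construction enforces completeness and coverage", {
  sys <- default_fuzzy_system()
  expect_equal(nrow(sys$rules), 20)
  # dropping a rule breaks grid completeness at load time
  expect_error(fuzzy_system(sys$voltage, sys$ceg, sys$error,
                            sys$rules[-1, ], sys$resolution),
               "exactly once")
  expect_error(fuzzy_system(sys$voltage, sys$ceg, sys$error,
                            rbind(sys$rules, sys$rules[1, ])),
               "exactly once")
  bad <- sys$rules; bad$error[1] <- "Z"
  expect_error(fuzzy_system(sys$voltage, sys$ceg, sys$error, bad), "unknown")
  # gap in the domain fails the coverage invariant
  expect_error(fuzzy_variable("v", c(0, 10),
                              list(lo = c(0, 1, 2), hi = c(8, 9, 10))),
               "not fully covered")
})

test_that("single-rule firing reproduces the clipped consequent exactly", {
  sys <- default_fuzzy_system()
  # voltage at the LoGl peak and severity at the A peak: only rule
  # (LoGl, A) -> A fires, at activation 1, so the aggregate is the full
  # output triangle A
  curve <- fz_infer(sys, 1.0, 0.0)
  expect_equal(curve$mu, fz_membership(sys$error$mfs$A, curve$x))
  expect_true(all(curve$mu >= 0 & curve$mu <= 1))
  expect_equal(fz_defuzzify(curve),
               oracle_centroid(sys, 1.0, 0.0, factor = 10), tolerance = 0.01)
})

test_that("centroid defuzzification matches analytic and integration oracles", {
  x <- seq(0, 100, length.out = 1001)
  # symmetric triangle centred at 50
  sym <- list(x = x, mu = fz_membership(c(0, 50, 100), x))
  expect_equal(fz_defuzzify(sym), 50)
  # right triangle (0, 0, 50): analytic centroid 50/3
  rt <- list(x = x, mu = fz_membership(c(0, 0, 50), x))
  expect_equal(fz_defuzzify(rt), 50 / 3, tolerance = 0.1)

  # dense trapezoidal-integration oracle on random inputs
  sys <- default_fuzzy_system()
  set.seed(3)
  for (i in 1:8) {
    v <- runif(1, 1, 4.5)
    s <- runif(1)
    expect_equal(fz_defuzzify(fz_infer(sys, v, s)),
                 oracle_centroid(sys, v, s), tolerance = 0.1)
  }

  expect_error(fz_defuzzify(list(x = x, mu = numeric(length(x)))),
               "no rule fired")
})

test_that("predicted error is monotone in severity and bounded", {
  sys <- default_fuzzy_system()
  sev <- seq(0, 1, by = 0.02)
  for (v in c(1.0, 1.8, 3.0, 4.5)) {
    err <- fz_predict_error(sys, rep(v, length(sev)), sev)
    expect_true(all(diff(err) >= -1e-9),
                info = sprintf("severity sweep at %.1f V", v))
    expect_true(all(err >= 0 & err <= 100))
  }
  set.seed(11)
  err <- fz_predict_error(sys, runif(200, 0, 6), runif(200, -0.2, 1.2))
  expect_true(all(err >= 0 & err <= 100))
})

test_that("inference is invariant to rule order", {
  sys <- default_fuzzy_system()
  set.seed(5)
  shuffled <- fuzzy_system(sys$voltage, sys$ceg, sys$error,
                           sys$rules[sample(nrow(sys$rules)), ],
                           sys$resolution)
  for (i in 1:5) {
    v <- runif(1, 1, 4.5); s <- runif(1)
    expect_identical(fz_infer(sys, v, s)$mu, fz_infer(shuffled, v, s)$mu)
  }
})

test_that("system configuration round-trips bit-exactly through JSON and YAML", {
  sys <- default_fuzzy_system()
  for (ext in c(".json", ".yaml")) {
    f <- tempfile(fileext = ext)
    write_fuzzy_system(sys, f)
    back <- read_fuzzy_system(f)
    expect_identical(back$voltage$mfs, sys$voltage$mfs)
    expect_identical(back$ceg$mfs, sys$ceg$mfs)
    expect_identical(back$error$mfs, sys$error$mfs)
    expect_identical(back$resolution, sys$resolution)
    expect_equal(back$rules, sys$rules)
    expect_identical(fz_predict_error(back, 2.2, 0.3),
                     fz_predict_error(sys, 2.2, 0.3))
  }
})
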