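test_that("effective attenuation follows both published and diffusion forms", {
  expect_equal(mu_eff(optical_properties(0, 2, 1)), 0)
  expect_equal(mu_eff(optical_properties(0, 2, 1), "diffusion"), 0)
  expect_equal(mu_eff(optical_properties(0.5, 1.5, 1)), 2)
  expect_equal(mu_eff(optical_properties(1, 0, 1), "diffusion"), sqrt(3))
  expect_error(optical_properties(-0.1, 1, 1), "mu_a")
})

test_that("transmitted intensity attenuates exponentially and never exceeds the source", {
  p <- optical_properties(0.5, 1.5, 1)
  expect_equal(transmitted_intensity(p, 1), exp(-2))
  expect_equal(transmitted_intensity(optical_properties(0, 1, 10), 3), 3)
  # strictly decreasing in path length
  I <- vapply(seq(0.5, 5, by = 0.5), function(L) {
    transmitted_intensity(optical_properties(0.3, 1, L), 1)
  }, numeric(1))
  expect_true(all(diff(I) < 0))
  # energy sanity over random properties
  set.seed(2)
  for (i in 1:50) {
    pr <- optical_properties(runif(1, 0, 2), runif(1, 0, 3), runif(1, 0, 10))
    I0 <- runif(1, 0.1, 10)
    expect_lte(transmitted_intensity(pr, I0), I0)
  }
  expect_error(transmitted_intensity(p, 0), "I0")
})

test_that("amplifier gain is 1 + r2/r1", {
  expect_equal(amplifier_gain(10e3, 0), 1)
  expect_equal(amplifier_gain(5e3, 5e3), 2)
  expect_equal(amplifier_gain(10e3, 30e3), 4)
  expect_error(amplifier_gain(0, 1), "r1")
})

test_that("glucose-to-voltage chain hits its anchors and is monotone", {
  chain <- default_sensor_chain()
  v <- glucose_to_voltage(c(103, 175), chain$map, chain$props, chain$circuit)
  expect_equal(v, c(1.22, 3.5), tolerance = 1e-12)
  # k_abs < 0 by construction: voltage strictly increasing in glucose
  expect_lt(chain$map$k_abs, 0)
  sweep <- glucose_to_voltage(seq(60, 250, by = 1), chain$map, chain$props,
                              chain$circuit)
  expect_true(all(diff(sweep) > 0))
  # zero coupling makes the voltage flat
  flat_map <- glucose_optics_map(chain$map$mu_a0, 0)
  flat <- glucose_to_voltage(c(80, 120, 200), flat_map, chain$props,
                             chain$circuit)
  expect_equal(flat[1], flat[2])
  expect_equal(flat[2], flat[3])
  # positive coupling flips the direction
  pos_map <- glucose_optics_map(0.1, 1e-3)
  dec <- glucose_to_voltage(c(100, 170), pos_map, chain$props, chain$circuit)
  expect_gt(dec[1], dec[2])
  # the diffusion-form chain also passes through its anchors
  dchain <- default_sensor_chain("diffusion")
  vd <- glucose_to_voltage(c(103, 175), dchain$map, dchain$props,
                           dchain$circuit, "diffusion")
  expect_equal(vd, c(1.22, 3.5), tolerance = 1e-12)
})

test_that("cohort generation matches the study protocol and is reproducible", {
  spec <- cohort_spec(seed = 99)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 360)                      # 30 participants x 12
  participants <- co[!duplicated(co$participant_id), ]
  expect_equal(nrow(participants), 30)
  expect_equal(sum(participants$diabetic), 15)
  expect_equal(unique(table(co$participant_id)), 12L)
  expect_equal(sort(unique(co$time_min)), seq(0, 165, by = 15))
  expect_true(all(co$fasting[co$time_min < 60]))
  expect_true(all(c("reference_glucose", "v_finger", "v_tear", "age",
                    "device_glucose", "gender", "diabetic", "fasting")
                  %in% names(co)))
  expect_true(all(co$v_finger >= 0 & co$v_finger <= 5))
  expect_true(all(co$v_tear >= 0 & co$v_tear <= 5))
  expect_equal(attr(co, "metadata")$seed, 99)

  # same seed, identical records; different seed, different draws
  expect_identical(generate_cohort(spec), co)
  expect_false(identical(generate_cohort(cohort_spec(seed = 100)), co))
  # the generator restores the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_cohort(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("simulated groups separate in finger voltage at default noise", {
  co <- generate_cohort(cohort_spec(seed = 4))
  rng <- summarize_group_ranges(co)
  healthy_max <- rng$v_max[rng$group == "healthy"]
  diabetic_min <- rng$v_min[rng$group == "diabetic"]
  expect_lt(healthy_max, diabetic_min)
})

test_that("cohort spec validates its parameters", {
  expect_error(cohort_spec(n_participants = 1), "n_participants")
  expect_error(cohort_spec(repeats_per_participant = 0), "repeats")
  expect_error(cohort_spec(diabetic_fraction = 1.5), "diabetic_fraction")
  expect_error(cohort_spec(voltage_noise_sd = -1), "sd")
})
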