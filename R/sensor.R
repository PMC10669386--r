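#' Tissue optical properties
#'
#' @param mu_a absorption coefficient, mm^-1.
#' @param mu_s_prime reduced scattering coefficient, mm^-1.
#' @param path_length optical path length through tissue, mm.
#' @return object of class `optical_properties`.
#' @export
optical_properties <- function(mu_a, mu_s_prime, path_length) {
  check_scalar(mu_a, "mu_a", lower = 0)
  check_scalar(mu_s_prime, "mu_s_prime", lower = 0)
  check_scalar(path_length, "path_length", lower = 0)
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime,
                 path_length = path_length),
            class = "optical_properties")
}

#' Effective attenuation coefficient
#'
#' Combines absorption and reduced scattering into a single attenuation
#' rate. Two forms are provided: `"printed"` (the default),
#' `2 * mu_a * (mu_a + mu_s')`, and `"diffusion"`, the diffusion-theory
#' form `sqrt(3 * mu_a * (mu_a + mu_s'))`. The mode used is recorded in
#' simulator metadata.
#'
#' @param props an [optical_properties()] object.
#' @param formula `"printed"` or `"diffusion"`.
#' @return effective attenuation coefficient, mm^-1.
#' @examples
#' mu_eff(optical_properties(0.5, 1.5, 1))               # 2.0
#' mu_eff(optical_properties(1, 0, 1), "diffusion")      # sqrt(3)
#' @export
mu_eff <- function(props, formula = c("printed", "diffusion")) {
  formula <- match.arg(formula)
  stopifnot(inherits(props, "optical_properties"))
  base <- props$mu_a * (props$mu_a + props$mu_s_prime)
  if (formula == "printed") 2 * base else sqrt(3 * base)
}

#' Transmitted optical intensity (Bouguer-Lambert)
#'
#' `I = I0 * exp(-mu_eff * L)`: exponential attenuation of the source
#' intensity over the tissue path. Always `0 < I <= I0`.
#'
#' @inheritParams mu_eff
#' @param I0 source intensity, arbitrary optical power units, > 0.
#' @return transmitted intensity, same units as `I0`.
#' @examples
#' transmitted_intensity(optical_properties(0.5, 1.5, 1), 1)  # exp(-2)
#' @export
transmitted_intensity <- function(props, I0, formula = c("printed", "diffusion")) {
  check_scalar(I0, "I0", lower = 0, strict = TRUE)
  I0 * exp(-mu_eff(props, formula) * props$path_length)
}

#' Non-inverting amplifier gain
#'
#' `G = 1 + r2 / r1` for the gain stage following the transimpedance
#' front end.
#'
#' @param r1,r2 gain-setting resistors, ohms (`r1 > 0`, `r2 >= 0`).
#' @return dimensionless gain >= 1.
#' @examples
#' amplifier_gain(10e3, 30e3)  # 4
#' @export
amplifier_gain <- function(r1, r2) {
  check_scalar(r1, "r1", lower = 0, strict = TRUE)
  check_scalar(r2, "r2", lower = 0)
  1 + r2 / r1
}

#' Acquisition-circuit parameters
#'
#' The transimpedance stage (a 300 kOhm feedback resistor in the
#' physical device) is folded into a single responsivity constant:
#' output volts per unit transmitted intensity before the gain stage.
#' PWM drive frequency and emitter wavelength are carried as metadata
#' only; they do not enter the computation.
#'
#' @param I0 source intensity, arbitrary units, > 0.
#' @param responsivity volts per intensity unit at the transimpedance
#'   output, > 0.
#' @param r1,r2 gain-stage resistors, ohms.
#' @param pwm_frequency PWM drive frequency metadata, Hz.
#' @param wavelength_nm emitter wavelength metadata, nm.
#' @return object of class `circuit_params`.
#' @export
circuit_params <- function(I0 = 1, responsivity = 1, r1 = 10e3, r2 = 30e3,
                           pwm_frequency = 1000, wavelength_nm = 940) {
  check_scalar(I0, "I0", lower = 0, strict = TRUE)
  check_scalar(responsivity, "responsivity", lower = 0, strict = TRUE)
  gain <- amplifier_gain(r1, r2)
  structure(list(I0 = I0, responsivity = responsivity, r1 = r1, r2 = r2,
                 gain = gain, pwm_frequency = pwm_frequency,
                 wavelength_nm = wavelength_nm),
            class = "circuit_params")
}

#' Linear glucose-to-absorption map
#'
#' `mu_a(g) = mu_a0 + k_abs * g`: the tissue absorption coefficient as
#' an affine function of glucose concentration. A negative `k_abs`
#' (less attenuation at higher glucose) makes the output voltage
#' increase with glucose, matching the observed direction of the
#' recorded signals.
#'
#' @param mu_a0 baseline absorption at zero glucose, mm^-1, >= 0.
#' @param k_abs absorption change per glucose unit, mm^-1 per (mg/dL).
#' @return object of class `glucose_optics_map`.
#' @export
glucose_optics_map <- function(mu_a0, k_abs) {
  check_scalar(mu_a0, "mu_a0", lower = 0)
  check_scalar(k_abs, "k_abs")
  structure(list(mu_a0 = mu_a0, k_abs = k_abs), class = "glucose_optics_map")
}

#' Default sensor chain calibrated to the observed signal span
#'
#' Solves the optical/circuit chain in closed form so that, with the
#' printed attenuation formula, the forward model passes exactly
#' through the two anchor measurements (103 mg/dL, 1.22 V) and
#' (175 mg/dL, 3.50 V) — the extremes of the recorded fingertip
#' signals. Fixed choices: reduced scattering 1 mm^-1, path length
#' 5 mm (trans-fingertip), absorption 0.30 mm^-1 at the low anchor,
#' unit source intensity and a 10k/30k gain stage; the responsivity
#' then follows from the anchors.
#'
#' @param formula attenuation formula passed to [mu_eff()].
#' @return list with components `map` ([glucose_optics_map()]), `props`
#'   ([optical_properties()]), `circuit` ([circuit_params()]) and
#'   `formula`.
#' @examples
#' chain <- default_sensor_chain()
#' glucose_to_voltage(c(103, 175), chain$map, chain$props, chain$circuit)
#' @export
default_sensor_chain <- function(formula = c("printed", "diffusion")) {
  formula <- match.arg(formula)
  g1 <- 103; v1 <- 1.22
  g2 <- 175; v2 <- 3.5
  s <- 1; L <- 5; a1 <- 0.30
  f1 <- if (formula == "printed") 2 * a1 * (a1 + s) else sqrt(3 * a1 * (a1 + s))
  f2 <- f1 - log(v2 / v1) / L
  a2 <- if (formula == "printed") {
    (-s + sqrt(s^2 + 2 * f2)) / 2          # solves 2a(a+s) = f2
  } else {
    (-s + sqrt(s^2 + 4 * f2^2 / 3)) / 2    # solves sqrt(3a(a+s)) = f2
  }
  k_abs <- (a2 - a1) / (g2 - g1)
  mu_a0 <- a1 - k_abs * g1
  gain <- amplifier_gain(10e3, 30e3)
  responsivity <- v1 / (gain * exp(-f1 * L))
  list(map = glucose_optics_map(mu_a0, k_abs),
       props = optical_properties(mu_a0, s, L),
       circuit = circuit_params(I0 = 1, responsivity = responsivity),
       formula = formula)
}

#' Forward model: glucose concentration to sensor voltage
#'
#' Composes the chain: glucose sets the absorption coefficient through
#' the linear map, Bouguer-Lambert attenuation gives the transmitted
#' intensity, and the transimpedance responsivity and gain stage
#' convert it to the output voltage.
#'
#' @param glucose numeric vector of glucose concentrations, mg/dL.
#' @param map a [glucose_optics_map()].
#' @param props an [optical_properties()]; its `mu_a` is replaced by
#'   the map's value at each glucose level.
#' @param circuit a [circuit_params()].
#' @param formula attenuation formula passed to [mu_eff()].
#' @return numeric vector of noise-free output voltages, volts.
#' @export
glucose_to_voltage <- function(glucose, map, props, circuit,
                               formula = c("printed", "diffusion")) {
  formula <- match.arg(formula)
  check_glucose(glucose, "glucose")
  stopifnot(inherits(map, "glucose_optics_map"),
            inherits(props, "optical_properties"),
            inherits(circuit, "circuit_params"))
  mu_a <- map$mu_a0 + map$k_abs * glucose
  if (any(mu_a < 0)) {
    stop_invalid("glucose", "drives the absorption coefficient negative")
  }
  vapply(mu_a, function(a) {
    p <- optical_properties(a, props$mu_s_prime, props$path_length)
    transmitted_intensity(p, circuit$I0, formula) *
      circuit$responsivity * circuit$gain
  }, numeric(1))
}

#' Synthetic cohort specification
#'
#' Parameters of the simulated measurement study. Defaults reproduce
#' the study protocol: 30 participants, half diabetic, 12 repeated
#' measurements per participant at 15-minute intervals spanning a meal
#' (4 pre-meal, 8 post-meal), 360 records in total. Group glucose
#' distributions default to healthy 115 +/- 10 and diabetic
#' 165 +/- 10 mg/dL; participant baselines are drawn from those
#' normals truncated at +/- `baseline_trunc` sd, keeping simulated
#' participants inside the per-group spreads the recorded cohort
#' actually shows. The post-meal excursion is a deterministic decaying
#' profile scaled by a per-group peak (tight healthy regulation, a
#' larger impaired diabetic response).
#'
#' @param n_participants number of participants (>= 2).
#' @param diabetic_fraction fraction of participants flagged diabetic.
#' @param repeats_per_participant measurements per participant (>= 1).
#' @param interval_minutes minutes between successive measurements.
#' @param glucose_mean,glucose_sd named numeric `c(healthy=, diabetic=)`
#'   group baseline distributions, mg/dL.
#' @param baseline_trunc truncation of the baseline normal, in sd units.
#' @param meal_peak named numeric `c(healthy=, diabetic=)` peak post-meal
#'   glucose excursion, mg/dL.
#' @param repeat_sd within-participant measurement-to-measurement
#'   glucose variation, mg/dL.
#' @param voltage_noise_sd additive Gaussian noise on the finger
#'   channel, volts.
#' @param tear_slope,tear_offset,tear_noise_sd tear channel as an affine
#'   function of the finger voltage plus noise (defaults fit to the
#'   recorded paired channels).
#' @param device_rel_sd relative error sd of the simulated reference
#'   device's displayed glucose.
#' @param rail_voltage supply rail, volts; recorded voltages saturate
#'   here (the microcontroller ADC cannot read above its rail).
#' @param seed integer RNG seed; the cohort is fully reproducible from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 30, diabetic_fraction = 0.5,
                        repeats_per_participant = 12, interval_minutes = 15,
                        glucose_mean = c(healthy = 115, diabetic = 165),
                        glucose_sd = c(healthy = 10, diabetic = 10),
                        baseline_trunc = 1,
                        meal_peak = c(healthy = 8, diabetic = 40),
                        repeat_sd = 2,
                        voltage_noise_sd = 0.02,
                        tear_slope = 1.24, tear_offset = -0.16,
                        tear_noise_sd = 0.1,
                        device_rel_sd = 0.05,
                        rail_voltage = 5,
                        seed = 1L) {
  if (n_participants < 2) stop_invalid("n_participants", "must be >= 2")
  if (repeats_per_participant < 1) stop_invalid("repeats_per_participant", "must be >= 1")
  if (diabetic_fraction < 0 || diabetic_fraction > 1) {
    stop_invalid("diabetic_fraction", "must be in [0, 1]")
  }
  sds <- c(glucose_sd, repeat_sd, voltage_noise_sd, tear_noise_sd, device_rel_sd)
  if (any(sds < 0)) stop_invalid("sd", "standard deviations must be >= 0")
  structure(as.list(environment()), class = "cohort_spec")
}

# decaying post-meal excursion shape (unit peak), aligned so measurement
# 5 is the first post-meal sample; padded/cropped to the repeat count
.meal_shape <- function(repeats) {
  shape <- c(0, 0, 0, 0, 0.3, 1, 0.9, 0.7, 0.5, 0.35, 0.2, 0.1)
  if (repeats <= length(shape)) shape[seq_len(repeats)]
  else c(shape, rep(0, repeats - length(shape)))
}

#' Generate a synthetic measurement cohort
#'
#' Draws a full study-shaped cohort through the physics chain: baseline
#' glucose per participant, a deterministic post-meal excursion plus
#' within-participant noise per repeat, finger voltage from
#' [glucose_to_voltage()] plus additive noise, a tear channel affine in
#' the finger voltage, and a simulated reference-device estimate. Fully
#' reproducible from `spec$seed`; recorded voltages are rounded to six
#' decimals so cohorts compare exactly across platforms.
#'
#' @param spec a [cohort_spec()].
#' @param chain a sensor chain as returned by [default_sensor_chain()].
#' @return data.frame with columns `participant_id`, `time_min`, then
#'   the measurement schema (`reference_glucose`, `v_finger`, `v_tear`,
#'   `age`, `device_glucose`, `gender`, `diabetic`, `fasting`), one row
#'   per measurement. Attribute `metadata` records the seed and the
#'   attenuation formula used.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 7))
#' nrow(cohort)  # 360
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            chain = default_sensor_chain()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_participants
  reps <- spec$repeats_per_participant
  n_diab <- round(n * spec$diabetic_fraction)
  diabetic <- c(rep(TRUE, n_diab), rep(FALSE, n - n_diab))
  group <- ifelse(diabetic, "diabetic", "healthy")

  # participant-level draws
  tr <- spec$baseline_trunc
  baseline <- spec$glucose_mean[group] + spec$glucose_sd[group] *
    stats::qnorm(stats::runif(n, stats::pnorm(-tr), stats::pnorm(tr)))
  age <- ifelse(diabetic, sample(40:65, n, replace = TRUE),
                sample(16:30, n, replace = TRUE))
  gender <- sample(c("M", "F"), n, replace = TRUE)

  shape <- .meal_shape(reps)
  rows <- vector("list", n)
  for (p in seq_len(n)) {
    glucose <- baseline[p] + spec$meal_peak[group[p]] * shape +
      stats::rnorm(reps, 0, spec$repeat_sd)
    glucose <- clamp(glucose, 40, 600)
    v_clean <- glucose_to_voltage(glucose, chain$map, chain$props,
                                  chain$circuit, chain$formula)
    v_finger <- clamp(v_clean + stats::rnorm(reps, 0, spec$voltage_noise_sd),
                      0, spec$rail_voltage)
    v_tear <- clamp(spec$tear_slope * v_finger + spec$tear_offset +
                      stats::rnorm(reps, 0, spec$tear_noise_sd),
                    0, spec$rail_voltage)
    device <- pmax(round(glucose *
      (1 + stats::rnorm(reps, 0, spec$device_rel_sd))), 1)
    rows[[p]] <- data.frame(
      participant_id = p,
      time_min = (seq_len(reps) - 1) * spec$interval_minutes,
      reference_glucose = round(glucose),
      v_finger = round(v_finger, 6),
      v_tear = round(v_tear, 6),
      age = age[p],
      device_glucose = device,
      gender = gender[p],
      diabetic = diabetic[p],
      fasting = shape == 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "metadata") <- list(seed = spec$seed, formula = chain$formula,
                                pwm_frequency = chain$circuit$pwm_frequency,
                                wavelength_nm = chain$circuit$wavelength_nm)
  out
}
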