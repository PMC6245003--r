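# Shared fixtures, generated once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 60 s noiseless trial with ground truth
short_trial <- function() {
  get_fixture("short_trial", function() make_gait_trial(gait_params(duration = 60)))
}

short_events <- function() {
  get_fixture("short_events", function() detect_heel_strikes(short_trial()))
}

# 130 s noiseless baseline trial (>= 100 strides) and its summary
baseline_trial <- function() {
  get_fixture("baseline_trial",
              function() make_gait_trial(gait_params(duration = 130)))
}

baseline_steps <- function() {
  get_fixture("baseline_steps", function() {
    step_table(baseline_trial(), detect_heel_strikes(baseline_trial()))
  })
}

baseline_sum <- function() {
  get_fixture("baseline_sum", function() baseline_summary(baseline_steps()))
}

# Point-mass trial: everything static, constant belts; for closed-form MoS.
# CoM sits at the origin, the right heel/malleolus at the given positions.
make_pointmass_trial <- function(l = 1.34, v_belt = 1.2, heel_ap = 0.30,
                                 mall_ml = 0.10, n = 400, fs = 100) {
  const3 <- function(x, y, z) {
    cbind(x = rep(x, n), y = rep(y, n), z = rep(z, n))
  }
  markers <- list(
    heel_L = const3(-mall_ml, heel_ap - 0.68, 0.02),
    heel_R = const3(mall_ml, heel_ap, 0.02),
    malleolus_L = const3(-mall_ml, heel_ap - 0.64, 0.07),
    malleolus_R = const3(mall_ml, heel_ap + 0.04, 0.07),
    trochanter_L = const3(-0.1, 0, l / 1.34),
    trochanter_R = const3(0.1, 0, l / 1.34),
    pelvis = const3(0, 0, 0.95),
    trunk = const3(0, 0, 1.35)
  )
  gait_trial(
    fs = fs, markers = markers, com = const3(0, 0, 1),
    belt_speed_L = rep(v_belt, n), belt_speed_R = rep(v_belt, n),
    meta = list(dominant_side = "R", comfortable_speed = v_belt)
  )
}

expect_gs_error <- function(expr, class) {
  expect_error(expr, class = paste0("gaitstab_", class))
}
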