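test_that("gait parameters are validated", {
  expect_gs_error(gait_params(duration = 3), "validation")
  expect_gs_error(gait_params(step_time = -0.5), "validation")
  expect_gs_error(gait_params(marker_noise_sd = -1), "validation")
  expect_gs_error(gait_params(dominant_side = "X"), "validation")
})

test_that("the sway profile meets its printed constraints exactly", {
  prof <- make_platform_profile(0.05, 0.7, 2.04, direction = 1, fs = 100)
  expect_equal(prof[length(prof)], 0.05, tolerance = 1e-12)
  expect_equal(prof[1], 0, tolerance = 1e-12)
  # trapezoid acceleration time: smaller root of a t^2 - a T t + d = 0
  t_a <- (0.7 - sqrt(0.7^2 - 4 * 0.05 / 2.04)) / 2
  expect_equal(t_a, 0.0370, tolerance = 1e-3)
  # numerical peak acceleration within 5 % of 2.04
  acc <- diff(diff(prof)) * 100^2
  expect_lt(abs(max(abs(acc)) - 2.04) / 2.04, 0.05)
  # mirrored direction
  prof_m <- make_platform_profile(0.05, 0.7, 2.04, direction = -1, fs = 100)
  expect_equal(prof_m, -prof, tolerance = 1e-12)
  expect_gs_error(make_platform_profile(0.5, 0.7, 2.04), "infeasible_profile")
  expect_gs_error(perturbation_spec("sway_ipsi", displacement = 0.5),
                  "infeasible_profile")
})

test_that("belt profiles hit the printed speed factors and accelerations", {
  prof <- make_belt_profile(1.2, 1.6, ramp = 0.4, hold = 0.55, fs = 100)
  expect_equal(max(prof), 1.92, tolerance = 1e-12)  # 160 %
  expect_equal(prof[1], 1.2, tolerance = 1e-12)
  expect_equal(prof[length(prof)], 1.2, tolerance = 1e-12)
  dec <- make_belt_profile(1.2, 0.4, ramp = 0.4, hold = 0.55, fs = 100)
  expect_equal(min(dec), 0.48, tolerance = 1e-12)   # 40 %
  expect_equal(make_belt_profile(1.2, 1, fs = 100), rep(1.2, 136))
  # minimum-jerk peak acceleration 1.875 * dv / T across comfortable speeds:
  # 2.43 m/s^2 at 0.864 m/s, 5.13 m/s^2 at 1.824 m/s
  for (vc in c(0.864, 1.2, 1.824)) {
    p <- make_belt_profile(vc, 1.6, ramp = 0.4, hold = 0.55, fs = 1000)
    peak <- max(abs(diff(p))) * 1000
    expect_equal(peak, 1.875 * 0.6 * vc / 0.4, tolerance = 0.01)
  }
  expect_equal(1.875 * 0.6 * 0.864 / 0.4, 2.43, tolerance = 1e-12)
  expect_equal(1.875 * 0.6 * 1.824 / 0.4, 5.13, tolerance = 1e-12)
})

test_that("generation is deterministic given the seed", {
  p <- gait_params(duration = 20, marker_noise_sd = 0.002, seed = 99)
  t1 <- make_gait_trial(p)
  t2 <- make_gait_trial(p)
  expect_identical(t1$markers, t2$markers)
  p2 <- p
  p2$seed <- 100L
  t3 <- make_gait_trial(p2)
  expect_false(identical(t1$markers$heel_L, t3$markers$heel_L))
})

test_that("programmed gait parameters survive the full pipeline round trip", {
  tr <- short_trial()
  st <- step_table(tr, short_events(), filter = FALSE)
  truth <- tr$truth$steps
  m <- merge(st, truth, by = "hs_sample", suffixes = c("_m", "_t"))
  expect_gte(nrow(m), nrow(truth) - 1L)
  expect_lt(max(abs(m$step_time_m - 0.55)), 0.01 + 1e-9)
  expect_lt(max(abs(m$step_length_m - 0.68)), 1e-3)
  expect_lt(max(abs(m$step_width_m - 0.12)), 1e-3)
  # measured margins match the analytic truth
  expect_lt(max(abs(m$mos_ml_m - m$mos_ml_t)), 1e-3)
  expect_lt(max(abs(m$mos_ap_m - m$mos_ap_t)), 1e-3)

  wide <- make_gait_trial(gait_params(duration = 30, step_width = 0.20))
  stw <- step_table(wide, detect_heel_strikes(wide), filter = FALSE)
  expect_lt(max(abs(stw$step_width - 0.20)), 1e-3)
})

test_that("platform excursion is bounded at 15 cm", {
  reqs <- lapply(c(10, 26, 42, 58), function(s) {
    list(ptype = "sway_contra", at_stride = s,
         spec = perturbation_spec("sway_contra", return_to_center = FALSE))
  })
  expect_gs_error(
    make_gait_trial(gait_params(duration = 90), reqs),
    "excursion_exceeded"
  )
  # three same-direction sways reach exactly 15 cm: allowed
  tr3 <- make_gait_trial(gait_params(duration = 90), reqs[1:3])
  expect_equal(max(abs(tr3$platform_ml)), 0.15, tolerance = 1e-9)
  # with the default return-to-centre, four repetitions stay within 5 cm
  tr4 <- make_gait_trial(gait_params(duration = 90),
                         lapply(c(10, 26, 42, 58), function(s) {
                           list(ptype = "sway_contra", at_stride = s)
                         }))
  expect_lte(max(abs(tr4$platform_ml)), 0.05 + 1e-9)
})

test_that("belt perturbations rewrite only the non-dominant belt", {
  tr <- make_gait_trial(gait_params(duration = 70),
                        list(list(ptype = "belt_acc", at_stride = 20)))
  expect_equal(tr$belt_speed_R, rep(1.2, length(tr$t)))
  expect_equal(max(tr$belt_speed_L), 1.92, tolerance = 1e-9)
  i0 <- tr$events$trigger_sample[1]
  expect_equal(tr$belt_speed_L[seq_len(i0 - 1L)], rep(1.2, i0 - 1L))
})

test_that("a session has the protocol structure and is seed-reproducible", {
  s1 <- make_session(gait_params(duration = 60), seed = 3)
  expect_setequal(names(s1$trials), PERTURBATION_TYPES)
  for (tr in s1$trials) {
    expect_identical(nrow(tr$events), 4L)
    expect_identical(tr$events$repetition_index, 1:4)
  }
  expect_gte(sum(detect_heel_strikes(s1$baseline)$side == "L") - 1L, 100L)
  s2 <- make_session(gait_params(duration = 60), seed = 3)
  expect_identical(s1$order, s2$order)
  expect_identical(s1$trials[[1]]$markers$heel_L, s2$trials[[1]]$markers$heel_L)
  # windows are extractable without overlap for every event
  tr <- s1$trials$sway_contra
  st <- step_table(tr, detect_heel_strikes(tr))
  for (i in 1:4) {
    w <- extract_peri_window(st, tr$events[i, ], "R",
                             other_events = tr$events[-i, ])
    expect_identical(w$post$side[1], "R")
  }
})

test_that("injecting a perturbation preserves the unperturbed samples", {
  base <- make_gait_trial(gait_params(duration = 70))
  tr <- inject_perturbation(base, "visual", at_stride = 20)
  expect_identical(nrow(tr$events), 1L)
  expect_equal(tr$markers$heel_L, base$markers$heel_L, tolerance = 1e-12)
  tr2 <- inject_perturbation(base, "sway_ipsi", at_stride = 20,
                             script = response_script())
  i0 <- tr2$events$trigger_sample[1]
  expect_equal(tr2$markers$heel_L[seq_len(i0), "y"],
               base$markers$heel_L[seq_len(i0), "y"], tolerance = 1e-12)
})

test_that("scripted deviations are realized exactly in the ground truth", {
  scr <- response_script(d_time = c(0.02, -0.01, 0, 0, 0, 0),
                         d_ap = c(0.03, -0.02, 0.01, 0, 0, 0),
                         d_ml = c(-0.04, 0.02, 0.01, 0, 0, 0))
  tr <- make_gait_trial(gait_params(duration = 70),
                        list(list(ptype = "auditory", at_stride = 20,
                                  script = scr)))
  post <- tr$truth$steps[!is.na(tr$truth$steps$post_index), ]
  expect_identical(nrow(post), 6L)
  expect_equal(post$dev_step_time, scr$d_time, tolerance = 1e-9)
  expect_equal(post$dev_step_length[1], 0.03, tolerance = 1e-9)
  expect_equal(post$dev_step_width[1], -0.04, tolerance = 1e-9)
})
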