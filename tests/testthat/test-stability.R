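test_that("XCoM closed form: identity at zero velocity, 1/omega0 scaling", {
  par <- xcom_params(l = 1.34)
  expect_equal(par$omega0, sqrt(9.81 / 1.34), tolerance = 1e-12)
  pos <- cbind(runif(50, -0.1, 0.1), runif(50), rep(1, 50))
  zero <- matrix(0, 50, 3)
  expect_equal(unname(compute_xcom(pos, zero, par)), unname(pos[, 1:2]))
  # CoM at 0, v_ml = 0.270571 m/s, l = 1.34 -> XCoM_ml = 0.100 m
  v <- cbind(rep(0.270571, 10), 0, 0)
  x <- compute_xcom(matrix(0, 10, 3), v, par)
  expect_equal(x[, "ml"], rep(0.1, 10), tolerance = 1e-5)
  # doubling v doubles XCoM - CoM
  x2 <- compute_xcom(matrix(0, 10, 3), 2 * v, par)
  expect_equal(x2[, "ml"], 2 * x[, "ml"], tolerance = 1e-12)
  expect_gs_error(compute_xcom(matrix(NA_real_, 2, 3), matrix(0, 2, 3), par),
                  "non_finite")
})

test_that("XCoM velocity scaling matches 1/omega0 over a pendulum-length grid", {
  for (l in 1.34 * c(0.8, 0.9, 1, 1.2, 1.5)) {
    par <- xcom_params(l = l)
    v <- cbind(seq(-1, 1, length.out = 21), 0.5, 0)
    x <- compute_xcom(matrix(0, 21, 3), v, par)
    expect_equal(x[, "ml"], v[, 1] / sqrt(9.81 / l), tolerance = 1e-12)
  }
})

test_that("com_velocity honours the frame convention", {
  tr <- make_pointmass_trial(v_belt = 1.2)
  ev <- gait_events(c(50L, 105L, 160L, 215L), c("L", "R", "L", "R"), tr)
  v_belt <- com_velocity(tr, frame = "belt", events = ev, filter = FALSE)
  expect_equal(v_belt[, "y"], rep(1.2, nrow(v_belt)), tolerance = 1e-12)
  v_lab <- com_velocity(tr, frame = "lab", filter = FALSE)
  expect_equal(max(abs(v_lab)), 0, tolerance = 1e-12)
  # central difference is exact on linear data
  tr2 <- tr
  tr2$com[, "y"] <- 0.3 * tr2$t + 1
  v2 <- com_velocity(tr2, frame = "lab", filter = FALSE)
  expect_equal(v2[, "y"], rep(0.3, nrow(v2)), tolerance = 1e-9)
})

test_that("point-mass margins of stability match the closed form to 1e-9", {
  for (l in 1.34 * c(0.8, 1, 1.2)) {
    for (v_belt in c(0.9, 1.2, 1.6)) {
      for (heel_ap in c(0.20, 0.30, 0.40)) {
        for (mall_ml in c(0.05, 0.12)) {
          tr <- make_pointmass_trial(l, v_belt, heel_ap, mall_ml)
          ev <- gait_events(c(100L, 200L), c("L", "R"), tr)
          par <- xcom_params(l = l)
          mos <- compute_step_mos(tr, ev, params = par, filter = FALSE)
          omega0 <- sqrt(9.81 / l)
          # right leading foot: XCoM_ap = v/omega0, heel ahead of the CoM
          expect_equal(mos$mos_ap[2], v_belt / omega0 - heel_ap,
                       tolerance = 1e-9)
          expect_equal(mos$mos_ml[2], mall_ml, tolerance = 1e-9)
          # left leading foot: mirrored malleolus, heel one step behind
          expect_equal(mos$mos_ml[1], mall_ml, tolerance = 1e-9)
          expect_equal(mos$mos_ap[1], v_belt / omega0 - (heel_ap - 0.68),
                       tolerance = 1e-9)
        }
      }
    }
  }
  # spec anchor: v = 1.2, l = 1.34, right heel at 0.30 -> 0.1435 m
  tr <- make_pointmass_trial(1.34, 1.2, 0.30, 0.10)
  ev <- gait_events(c(100L, 200L), c("L", "R"), tr)
  mos <- compute_step_mos(tr, ev, params = xcom_params(l = 1.34), filter = FALSE)
  expect_equal(mos$mos_ap[2], 0.1435, tolerance = 5e-4)
})

test_that("mos_ml flips sign under ML mirroring and mos_ap shifts with the heel", {
  tr <- short_trial()
  ev <- short_events()
  par <- xcom_params(trial = tr)
  mos <- compute_step_mos(tr, ev, params = par, filter = FALSE)
  mirrored <- tr
  for (m in TRIAL_MARKERS) mirrored$markers[[m]][, "x"] <- -mirrored$markers[[m]][, "x"]
  mirrored$com[, "x"] <- -mirrored$com[, "x"]
  mos_m <- compute_step_mos(mirrored, ev, params = par, filter = FALSE)
  expect_equal(mos_m$mos_ml, -mos$mos_ml, tolerance = 1e-9)
  expect_equal(mos_m$mos_ap, mos$mos_ap, tolerance = 1e-12)

  # moving the leading heel forward by delta reduces mos_ap by exactly delta
  delta <- 0.037
  shifted <- tr
  shifted$markers$heel_L[, "y"] <- shifted$markers$heel_L[, "y"] + delta
  shifted$markers$heel_R[, "y"] <- shifted$markers$heel_R[, "y"] + delta
  mos_s <- compute_step_mos(shifted, ev, params = par, filter = FALSE)
  expect_equal(mos_s$mos_ap, mos$mos_ap - delta, tolerance = 1e-9)
})

test_that("spatio-temporal parameters recover the programmed gait", {
  tr <- short_trial()
  st <- spatiotemporal(tr, short_events(), filter = FALSE)
  expect_lt(max(abs(st$step_time - 0.55)), 0.01 + 1e-9)   # 1 sample
  expect_lt(max(abs(st$step_length - 0.68)), 1e-3)
  expect_lt(max(abs(st$step_width - 0.12)), 1e-3)

  # same-ML heels give zero width; swapping labels leaves width unchanged
  tr2 <- make_pointmass_trial(mall_ml = 0)
  tr2$markers$heel_L[, "x"] <- 0.04
  tr2$markers$heel_R[, "x"] <- 0.04
  ev2 <- gait_events(c(100L, 200L, 300L), c("L", "R", "L"), tr2)
  expect_equal(spatiotemporal(tr2, ev2, filter = FALSE)$step_width, c(0, 0))
  ev_sw <- gait_events(c(100L, 200L, 300L), c("R", "L", "R"), tr2)
  expect_equal(spatiotemporal(tr2, ev_sw, filter = FALSE)$step_width,
               spatiotemporal(tr2, ev2, filter = FALSE)$step_width)
})

test_that("baseline summary uses exactly 100 steps per side and flags shortfalls", {
  bs <- baseline_sum()
  expect_true(all(bs$n == 100))
  expect_identical(nrow(bs), 10L)  # 5 parameters x 2 sides
  expect_true(all(bs$sd >= 0))

  # identical steps give zero SD
  steps <- baseline_steps()
  flat <- steps
  for (p in c("step_time", "step_length", "step_width", "mos_ml", "mos_ap")) {
    flat[[p]] <- ifelse(flat$dominant, 1, 2)
  }
  bf <- baseline_summary(flat)
  expect_equal(bf$sd, rep(0, 10))

  short <- steps[seq_len(100), ]  # ~50 steps per side
  expect_gs_error(baseline_summary(short), "insufficient_baseline")
})
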