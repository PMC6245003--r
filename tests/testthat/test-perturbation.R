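# Hand-built baseline summaries and windows for arithmetic checks.
fake_baseline <- function(bd, bnd, parameter = "mos_ml") {
  structure(
    data.frame(
      parameter = parameter,
      side_role = c("D", "ND"),
      mean = c(bd, bnd),
      sd = 0, n = 100
    ),
    class = c("baseline_summary", "data.frame")
  )
}

fake_window <- function(values, parameter = "mos_ml", ptype = "visual") {
  post <- data.frame(dominant = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  post[[parameter]] <- values
  post$label <- paste0(1:6, c("D", "ND"))
  structure(list(event = list(ptype = ptype, repetition_index = 1L),
                 pre = NULL, post = post),
            class = "peri_window")
}

test_that("6S is zero at baseline and sums absolute deviations", {
  b <- fake_baseline(0.06, 0.05)
  expect_identical(six_s(b, fake_window(c(0.06, 0.05, 0.06, 0.05, 0.06, 0.05)),
                         "mos_ml"), 0)
  # six steps each deviating by +0.01 -> 0.06
  w <- fake_window(c(0.06, 0.05, 0.06, 0.05, 0.06, 0.05) + 0.01)
  expect_equal(six_s(b, w, "mos_ml"), 0.06, tolerance = 1e-12)
  # mixed-sign deviations
  dev <- c(0.02, -0.01, 0.00, 0.03, -0.02, 0.01)
  w2 <- fake_window(c(0.06, 0.05, 0.06, 0.05, 0.06, 0.05) + dev)
  expect_equal(six_s(b, w2, "mos_ml"), 0.09, tolerance = 1e-12)
})

test_that("6S equals a brute-force side-matched L1 sum on random step sets", {
  set.seed(101)
  worst <- 0
  for (i in seq_len(1000)) {
    bd <- rnorm(1)
    bnd <- rnorm(1)
    vals <- rnorm(6)
    got <- six_s(fake_baseline(bd, bnd), fake_window(vals), "mos_ml")
    # independent brute force over the printed double sum
    B <- c(bd, bnd)
    want <- 0
    for (side in 1:2) {
      for (j in 1:3) {
        want <- want + sqrt((B[side] - vals[side + (j - 1) * 2])^2)
      }
    }
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-12)
})

test_that("6S is permutation-invariant within sides and scales linearly", {
  b <- fake_baseline(0.1, 0.2)
  dev <- c(0.03, -0.01, -0.02, 0.04, 0.01, -0.05)
  base6 <- c(0.1, 0.2, 0.1, 0.2, 0.1, 0.2)
  s0 <- six_s(b, fake_window(base6 + dev), "mos_ml")
  # permute the dominant-side deviations (positions 1, 3, 5)
  dev_p <- dev
  dev_p[c(1, 3, 5)] <- dev[c(5, 1, 3)]
  dev_p[c(2, 4, 6)] <- dev[c(6, 2, 4)]
  expect_equal(six_s(b, fake_window(base6 + dev_p), "mos_ml"), s0,
               tolerance = 1e-12)
  for (c_scale in c(0, 0.5, 2, 7)) {
    expect_equal(six_s(b, fake_window(base6 + c_scale * dev), "mos_ml"),
                 c_scale * s0, tolerance = 1e-10)
  }
})

test_that("peri-window extraction labels steps and enforces the protocol", {
  tr <- make_gait_trial(gait_params(duration = 70),
                        list(list(ptype = "visual", at_stride = 20)))
  st <- step_table(tr, detect_heel_strikes(tr))
  ev <- tr$events[1, ]
  w <- extract_peri_window(st, ev, "R")
  expect_identical(w$post$label, c("1D", "2ND", "3D", "4ND", "5D", "6ND"))
  expect_identical(w$post$side[1], "R")  # 1D lands dominant
  expect_identical(w$pre$label, rep(c("PD", "NPD"), 3))
  expect_identical(nrow(w$pre), 6L)

  # trigger away from any heel strike
  ev_off <- ev
  ev_off$trigger_sample <- ev$trigger_sample - 10L
  expect_gs_error(extract_peri_window(st, ev_off, "R"), "trigger_misaligned")

  # trigger at a dominant-side strike
  ev_dom <- ev
  ev_dom$trigger_sample <- w$post$hs_sample[1]
  expect_gs_error(extract_peri_window(st, ev_dom, "R"), "trigger_misaligned")

  # a second event 4 steps later overlaps the window
  other <- ev
  other$trigger_sample <- st$hs_sample[which(st$hs_sample == ev$trigger_sample) + 4L]
  expect_gs_error(extract_peri_window(st, ev, "R", other_events = other),
                  "window_overlap")

  # too close to the trial edge
  ev_edge <- ev
  ev_edge$trigger_sample <- st$hs_sample[3]
  expect_gs_error(extract_peri_window(st, ev_edge, "L"), "incomplete_window")
})

test_that("repetition averaging keeps the last three", {
  res <- data.frame(
    ptype = "sway_contra", repetition_index = 1:4,
    parameter = "mos_ml", six_s = c(0.4, 0.2, 0.2, 0.2)
  )
  avg <- average_repetitions(res)
  expect_equal(avg$six_s, 0.2, tolerance = 1e-12)
  expect_identical(avg$n_reps, 3L)

  res3 <- res[1:3, ]
  avg3 <- average_repetitions(res3)
  expect_equal(avg3$six_s, mean(c(0.4, 0.2, 0.2)), tolerance = 1e-12)

  expect_warning(average_repetitions(res[1:2, ]),
                 class = "gaitstab_few_repetitions")
  # identical repetitions average to themselves
  res_id <- res
  res_id$six_s <- 0.31
  expect_equal(average_repetitions(res_id)$six_s, 0.31, tolerance = 1e-12)
})

test_that("the peri-step table has one row per type, label and parameter", {
  tr <- make_gait_trial(
    gait_params(duration = 110),
    list(list(ptype = "visual", at_stride = 15, repetition_index = 1),
         list(ptype = "visual", at_stride = 45, repetition_index = 2),
         list(ptype = "visual", at_stride = 75, repetition_index = 3))
  )
  st <- step_table(tr, detect_heel_strikes(tr))
  windows <- lapply(seq_len(3), function(i) {
    extract_peri_window(st, tr$events[i, ], "R")
  })
  tab <- peri_step_table(windows)
  expect_identical(nrow(tab), 8L * 5L)
  expect_identical(tab$n_windows, rep(3L, 40L))
  # unperturbed identical windows: essentially zero SD
  expect_lt(max(tab$sd), 1e-6)
})

test_that("a scripted first-step width deficit shows up as 1D below PD", {
  scr <- response_script(d_ml = c(-0.05, 0, 0, 0, 0, 0))
  tr <- make_gait_trial(gait_params(duration = 70),
                        list(list(ptype = "auditory", at_stride = 20,
                                  script = scr)))
  st <- step_table(tr, detect_heel_strikes(tr))
  w <- extract_peri_window(st, tr$events[1, ], "R")
  tab <- peri_step_table(list(w))
  wid <- tab[tab$parameter == "step_width", ]
  expect_lt(wid$mean[wid$label == "1D"], wid$mean[wid$label == "PD"])
})
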