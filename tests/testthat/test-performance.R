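test_that("response classification follows the go/no-go contingency table", {
  # go + timely touch -> hit; go + late/no touch -> miss
  expect_equal(as.character(classify_response(TRUE, TRUE, 0.8 * 485, 485)),
               "hit")
  expect_equal(as.character(classify_response(TRUE, TRUE, 500, 485)), "miss")
  expect_equal(as.character(classify_response(TRUE, FALSE, NA, 485)), "miss")
  expect_equal(as.character(classify_response(FALSE, TRUE, 300, 485)),
               "false_alarm")
  expect_equal(as.character(classify_response(FALSE, FALSE, NA, 485)),
               "correct_rejection")
  # a released touch demotes a hit to a miss
  expect_equal(as.character(classify_response(TRUE, TRUE, 300, 485,
                                              held = FALSE)), "miss")
  expect_error(classify_response(TRUE, FALSE, 300, 485), "touched = FALSE")
})

test_that("response types partition go and no-go trials", {
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- 40
      is_go <- runif(n) < 0.5
      touched <- runif(n) < 0.6
      tt <- ifelse(touched, runif(n, 100, 700), NA)
      r <- classify_response(is_go, touched, tt, 485)
      expect_equal(sum(r %in% c("hit", "miss")), sum(is_go))
      expect_equal(sum(r %in% c("correct_rejection", "false_alarm")),
                   sum(!is_go))
    }
  })
})

test_that("d-prime matches the normal-quantile oracle and corrections", {
  expect_equal(dprime(0.5, 0.5, 10, 10)$dprime, 0)
  r <- dprime(0.841345, 0.158655, 100, 100)
  expect_equal(r$dprime, 2, tolerance = 1e-4)
  expect_equal(r$criterion, 0, tolerance = 1e-4)
  expect_false(r$correction_applied)
  # 1/(2N) clamp of a perfect hit rate at n = 20
  r2 <- dprime(1, 0.2, 20, 20, correction = "clamp")
  expect_equal(r2$hit_rate_adj, 0.975)
  expect_true(r2$correction_applied)
  # log-linear rule
  r3 <- dprime(1, 0.2, 20, 20, correction = "loglinear")
  expect_equal(r3$hit_rate_adj, (20 + 0.5) / 21)
  expect_error(dprime(0.5, 0.5, 0, 10), "at least one")
})

test_that("d-prime is antisymmetric in H/F and monotone", {
  withr::with_seed(11, {
    for (i in 1:25) {
      h <- runif(1, 0.05, 0.95); f <- runif(1, 0.05, 0.95)
      a <- dprime(h, f, 50, 50)$dprime
      b <- dprime(f, h, 50, 50)$dprime
      expect_equal(a, -b, tolerance = 1e-12)
      expect_gt(dprime(min(h + 0.04, 1), f, 50, 50)$dprime, a)
      expect_lt(dprime(h, min(f + 0.04, 1), 50, 50)$dprime, a)
    }
  })
})

test_that("performance summaries use the schedule denominators", {
  sch <- generate_tpt_block(GEOM, seed = 3)
  # all hits and correct rejections -> 100% everywhere
  rec <- dplyr::mutate(sch,
                       subject = "s1",
                       touched = is_go,
                       touch_time_ms = ifelse(is_go, 300, NA),
                       response_type = classify_response(
                         is_go, touched, touch_time_ms,
                         flight_duration_ms + jitter_ms),
                       correct = response_type %in%
                         c("hit", "correct_rejection"))
  s <- summarize_performance(rec)
  expect_true(all(s$by_speed$percent_correct == 100))
  expect_true(all(s$by_cell$percent_correct == 100))
  expect_equal(nrow(s$by_cell), 9L)  # 3 speeds x 3 fixations, probes excluded
  expect_true(all(s$by_cell$n == 8L))
  expect_true(all(s$rates_by_speed$hit_rate == 1))
  expect_true(all(s$rates_by_speed$fa_rate == 0))

  # known mixture: first 20 go-touch trials forced late -> misses
  rec2 <- rec
  go_idx <- which(rec2$is_go)[1:20]
  rec2$touch_time_ms[go_idx] <- rec2$flight_duration_ms[go_idx] + 100
  rec2$response_type <- classify_response(rec2$is_go, rec2$touched,
                                          rec2$touch_time_ms,
                                          rec2$flight_duration_ms +
                                            rec2$jitter_ms)
  rec2$correct <- rec2$response_type %in% c("hit", "correct_rejection")
  s2 <- summarize_performance(rec2, include_probes = TRUE)
  expect_equal(s2$overall$percent_correct, 100 * (80 - 20) / 80)
})

test_that("a chance responder scores about 50% correct", {
  p <- quiet_profile(dprime = c(`385` = 0, `485` = 0, `585` = 0),
                     criterion = 0, late_touch_prob = 0)
  sch <- generate_tpt_schedule(GEOM, blocks = 3, seed = 17)
  withr::with_seed(21, {
    dec <- lapply(seq_len(nrow(sch)), function(i)
      simulate_decision(p, as.list(sch[i, ])))
  })
  touched <- vapply(dec, `[[`, logical(1), "touched")
  tt <- vapply(dec, `[[`, numeric(1), "planned_touch_ms")
  r <- classify_response(sch$is_go, touched, ifelse(touched, tt, NA),
                         sch$flight_duration_ms + sch$jitter_ms)
  pc <- mean(r %in% c("hit", "correct_rejection"))
  # binomial 99% interval around 0.5 at n = 240
  expect_lt(abs(pc - 0.5), 2.58 * sqrt(0.25 / nrow(sch)) + 0.02)
})

test_that("reaction-time filtering applies the catch and maximum rules", {
  sch <- generate_rtt_schedule(2)
  press <- rep(300, 50)
  press[1] <- 100   # catch
  press[2] <- 800   # too slow
  press[3] <- NA    # no press
  press[4] <- -50   # before stimulus
  res <- rtt_reaction_times(press, sch)
  expect_equal(res$trials$status[1:4],
               c("catch", "invalid", "no_press", "before_stimulus"))
  expect_equal(res$summary$n_included, 46L)
  expect_equal(res$summary$mean_rt_ms, 300)
  expect_equal(res$summary$n_catch, 1L)
  expect_equal(res$summary$n_invalid, 3L)
  # boundary: 125 ms is a valid press, 750 ms is a valid press
  res2 <- rtt_reaction_times(c(125, 750, rep(300, 48)), sch)
  expect_equal(res2$summary$n_included, 50L)
})

test_that("empirical d-prime converges to the generating value", {
  p <- subject_profile("control")
  go_spec <- list(is_go = TRUE, flight_duration_ms = 485, jitter_ms = 0)
  ng_spec <- list(is_go = FALSE, flight_duration_ms = 485, jitter_ms = 0)
  est <- withr::with_seed(13, replicate(20, {
    dec_g <- replicate(72, simulate_decision(p, go_spec)$touched)
    dec_n <- replicate(72, simulate_decision(p, ng_spec)$touched)
    dprime(mean(dec_g), mean(dec_n), 72, 72)$dprime
  }))
  expect_lt(abs(mean(est) - p$dprime[["485"]]), 0.15)
})
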