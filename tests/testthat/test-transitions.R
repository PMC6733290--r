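test_that("line intersection is exact and guards against parallel lines", {
  expect_equal(intersect_lines(1, 0, -1, 2), 1)
  expect_error(intersect_lines(0, 0, 1e-12, 1),
               class = "lyoglass_parallel_lines")
  err <- tryCatch(intersect_lines(0.5, 0, 0.5 + 1e-12, 1),
                  lyoglass_parallel_lines = function(e) e)
  expect_s3_class(err, "lyoglass_parallel_lines")
  expect_true(abs(err$slope_difference) < 1e-9)
})

test_that("noiseless three-segment series refits to the generating parameters exactly", {
  row <- reference_transition_params()[2, ]  # 0.021 / 0.054 / 0.023, 219 / 339 K
  fit <- fit_three_regions(ref_series(row))
  expect_equal(fit$regions$slope, c(0.021, 0.054, 0.023), tolerance = 1e-9)
  expect_equal(fit$tg_beta, 219, tolerance = 1e-6)
  expect_equal(fit$tg_alpha, 339, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-12)
  # lines reconstructed from the fit intersect at the printed transitions
  r <- fit$regions
  expect_equal(intersect_lines(r$slope[1], r$intercept[1],
                               r$slope[2], r$intercept[2]), 219,
               tolerance = 1e-6)
})

test_that("a single straight line yields equal slopes and a balanced tie-break", {
  tt <- seq(100, 380, 10)
  d <- tibble::tibble(temperature = tt, absorption = 2 + 0.05 * tt)
  fit <- fit_three_regions(d)
  expect_equal(fit$regions$slope, rep(0.05, 3), tolerance = 1e-10)
  expect_lt(fit$sse, 1e-18)
  counts <- fit$regions$n_points
  expect_lt(max(counts) - min(counts), 3)  # most balanced segmentation
  expect_true(is.na(fit$tg_beta) && is.na(fit$tg_alpha))
})

test_that("selected segmentation attains the brute-force minimum SSE", {
  s <- simulate_temperature_series(c(0.02, 0.06, 0.01), c(200, 300),
                                   temperatures = seq(100, 380, 20),
                                   noise_sd = 0.05, seed = 4)
  fit <- fit_three_regions(s)
  expect_equal(fit$sse, brute_force_sse(s), tolerance = 1e-9)
})

test_that("transition estimates transform correctly under axis changes", {
  s <- simulate_temperature_series(c(0.02, 0.06, 0.01), c(200, 300),
                                   noise_sd = 0.03, seed = 9)
  f0 <- fit_three_regions(s)
  # affine rescale of the absorption axis: Tg unchanged
  s2 <- s
  s2$absorption <- 3 * s2$absorption + 7
  f2 <- fit_three_regions(s2)
  expect_equal(f2$tg_beta, f0$tg_beta, tolerance = 1e-9)
  expect_equal(f2$tg_alpha, f0$tg_alpha, tolerance = 1e-9)
  # temperature shift: Tg shifts by the same offset
  s3 <- s
  s3$temperature <- s3$temperature + 40
  f3 <- fit_three_regions(s3)
  expect_equal(f3$tg_beta, f0$tg_beta + 40, tolerance = 1e-9)
  expect_equal(f3$tg_alpha, f0$tg_alpha + 40, tolerance = 1e-9)
})

test_that("breakpoints are recovered within one grid step for moderately noisy data", {
  tt <- seq(100, 380, 10)
  hits <- vapply(1:50, function(seed) {
    s <- simulate_temperature_series(c(0.02, 0.06, 0.01), c(200, 300),
                                     temperatures = tt, noise_sd = 0.05,
                                     seed = seed)
    f <- fit_three_regions(s)
    abs(tt[f$breakpoints[1]] - 200) <= 10 && abs(tt[f$breakpoints[2]] - 300) <= 10
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("breakpoint-recovery error does not improve as noise grows", {
  tt <- seq(100, 380, 10)
  err_at <- function(noise_sd) {
    median(vapply(1:20, function(seed) {
      s <- simulate_temperature_series(c(0.02, 0.06, 0.01), c(200, 300),
                                       temperatures = tt, noise_sd = noise_sd,
                                       seed = 1000 + seed)
      f <- fit_three_regions(s)
      abs(tt[f$breakpoints[1]] - 200) + abs(tt[f$breakpoints[2]] - 300)
    }, numeric(1)))
  }
  errs <- vapply(c(0.01, 0.05, 0.25), err_at, numeric(1))
  expect_true(all(diff(errs) >= 0))
})

test_that("weighted fits use replicate SDs when available", {
  s <- simulate_temperature_series(c(0.02, 0.06, 0.01), c(200, 300),
                                   noise_sd = 0.05, replicates = 3, seed = 2)
  fit <- fit_three_regions(s)
  expect_true(fit$weighted)
  fit_unw <- fit_three_regions(s[, c("temperature", "absorption")])
  expect_false(fit_unw$weighted)
})

test_that("mobility classification follows the slope-ratio rule with statistical support", {
  mk_fit <- function(m2, m3, se2 = 1e-4, se3 = 1e-4) {
    f <- fit_three_regions(simulate_temperature_series(
      c(0.02, m2, m3), c(200, 300), noise_sd = 0))
    f$regions$slope[2:3] <- c(m2, m3)
    f$regions$slope_se[2:3] <- c(se2, se3)
    f
  }
  # plateau after a steep mid region: confined
  expect_equal(classify_mobility(mk_fit(0.074, 0.0051)), "confined")
  # gradient keeps increasing: unconfined
  expect_equal(classify_mobility(mk_fit(0.028, 0.048)), "unconfined")
  # equal slopes: strict inequality means unconfined
  expect_equal(classify_mobility(mk_fit(0.05, 0.05)), "unconfined")
  # a decrease without statistical support is not called confined
  expect_equal(classify_mobility(mk_fit(0.05, 0.045, se2 = 0.01, se3 = 0.01)),
               "unconfined")
})

test_that("cycle comparison flags slope hysteresis and ignores offsets", {
  base <- simulate_temperature_series(c(0.02, 0.06, 0.001), c(200, 300),
                                      noise_sd = 0.01, seed = 21)
  same <- compare_cycles(base, base)
  expect_false(same$hysteresis)
  expect_equal(same$delta_m3, 0)

  cycle2 <- simulate_temperature_series(c(0.02, 0.06, 0.05), c(200, 300),
                                        noise_sd = 0.01, seed = 22)
  comp <- compare_cycles(base, cycle2)
  expect_true(comp$hysteresis)
  expect_gt(comp$delta_m3, 0.03)

  shifted <- base
  shifted$absorption <- shifted$absorption + 1.5
  expect_false(compare_cycles(base, shifted)$hysteresis)
})

test_that("the summary table preserves order, labels and round-trips its values", {
  ref <- reference_transition_params()
  fits <- lapply(seq_len(nrow(ref)), function(i) {
    fit_three_regions(ref_series(ref[i, ], temperatures = seq(100, 380, 10)))
  })
  tab <- tabulate_transitions(fits)
  expect_equal(nrow(tab), 9)
  expect_equal(tab$formulation, ref$formulation)
  expect_equal(tab$m2, ref$m2, tolerance = 1e-6)
  # unlabelled fits get deterministic default labels
  s <- ref_series(ref[1, ])
  f <- fit_three_regions(tibble::tibble(temperature = s$temperature,
                                        absorption = s$absorption))
  expect_equal(tabulate_transitions(list(f))$formulation, "fit_1")
})

test_that("tidy and glance expose the fit in rectangular form", {
  fit <- fit_three_regions(ref_series(reference_transition_params()[1, ]))
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_true(all(c("region", "slope", "slope_se", "intercept") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$tg_beta, 262, tolerance = 1e-6)
  expect_s3_class(autoplot(fit), "ggplot")
})
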