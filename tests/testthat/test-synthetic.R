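test_that("binomial cascade has the promised measure structure", {
  w <- gen_binomial_cascade(0.5, 10)
  expect_length(w, 2^10)
  expect_true(all(w > 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # p = 0.5 splits every branch equally: uniform measure
  expect_equal(max(w) - min(w), 0, tolerance = 1e-15)

  w6 <- gen_binomial_cascade(0.6, 12)
  expect_equal(sum(w6), 1, tolerance = 1e-12)
  expect_equal(sort(unique(round(log(range(w6)), 8))),
               round(12 * log(c(0.4, 0.6)), 8))

  un <- gen_binomial_cascade(0.6, 10, normalize = FALSE)
  expect_equal(mean(un), 1, tolerance = 1e-12)

  expect_error(gen_binomial_cascade(1.2, 10), "outside its allowed range")
  expect_error(gen_binomial_cascade(0.6, 3), "outside its allowed range")
})

test_that("randomized cascade is seed-reproducible and multiset-stable", {
  a <- gen_binomial_cascade(0.7, 10, randomize = TRUE, seed = 42)
  b <- gen_binomial_cascade(0.7, 10, randomize = TRUE, seed = 42)
  expect_identical(a, b)
  c2 <- gen_binomial_cascade(0.7, 10, randomize = TRUE, seed = 43)
  expect_false(identical(a, c2))
  # branch randomization permutes multipliers within levels: the value
  # multiset is that of some binomial cascade with the same p
  det <- gen_binomial_cascade(0.7, 10)
  expect_equal(sort(a), sort(det), tolerance = 1e-12)
})

test_that("closed-form h(q) behaves as multifractal theory requires", {
  expect_equal(theory_h_binomial(2, 0.5), 1)
  expect_equal(theory_h_binomial(2, 0.6), 0.9717, tolerance = 1e-4)
  # strictly decreasing in q for asymmetric multipliers
  q <- seq(-5, 5, 0.5)
  h <- theory_h_binomial(q, 0.6)
  expect_true(all(diff(h) < 0))
  expect_gt(theory_h_binomial(-5, 0.6), theory_h_binomial(5, 0.6))
  # continuous extension at q = 0
  expect_equal(theory_h_binomial(0, 0.6),
               theory_h_binomial(1e-7, 0.6), tolerance = 1e-5)
  expect_error(theory_h_binomial(2, 1.5), "outside its allowed range")
})

test_that("fGn generator hits its Hurst target and is reproducible", {
  x <- gen_fgn(0.5, 4096, seed = 1)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 1, tolerance = 1e-12)
  expect_lt(abs(acf(x, plot = FALSE)$acf[2]), 0.05)

  expect_identical(gen_fgn(0.8, 1024, seed = 7), gen_fgn(0.8, 1024, seed = 7))

  y <- gen_fgn(0.8, 2^16, seed = 3)
  fit <- mfdfa(y, q = 2, scale_max = 2^13)
  expect_equal(fit$H, 0.8, tolerance = 0.05)

  expect_error(gen_fgn(1.2, 1024), "outside its allowed range")
})

test_that("fGn at H = 0.5 passes whiteness screening across seeds", {
  pvals <- vapply(1:100, function(s) {
    stats::Box.test(gen_fgn(0.5, 1024, seed = s), lag = 20,
                    type = "Ljung-Box")$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("respirometry trace plants its increment source faithfully", {
  # degenerate: no increments, no drift -> constant at baseline
  tr0 <- gen_respirometry_trace(duration_s = 2^10, baseline_vo2 = 200,
                                drift_amplitude = 0, increment_scale = 0,
                                seed = 1)
  expect_equal(unique(tr0$vo2_ml_per_h), 200)

  # exact recovery of planted increments when drift is off
  tr <- gen_respirometry_trace(duration_s = 2^12, drift_amplitude = 0,
                               increment_source = "cascade", seed = 5)
  expect_equal(log_ratio_increments(tr), attr(tr, "increments"),
               tolerance = 1e-12)
  expect_true(all(tr$vo2_ml_per_h > 0))

  # deterministic under seed
  tr2 <- gen_respirometry_trace(duration_s = 2^12, drift_amplitude = 0,
                                increment_source = "cascade", seed = 5)
  expect_identical(tr$vo2_ml_per_h, tr2$vo2_ml_per_h)

  # planted cascade -> multifractal increments downstream
  trc <- gen_respirometry_trace(duration_s = 2^14 + 1, drift_amplitude = 0,
                                increment_source = "cascade", seed = 2)
  fitc <- mfdfa(log_ratio_increments(trc), scale_max = 2^11)
  expect_gt(fitc$delta_h, 0.1)

  # planted white noise -> H near 1/2
  trw <- gen_respirometry_trace(duration_s = 2^14 + 1, drift_amplitude = 0,
                                increment_source = "white", seed = 2)
  fitw <- mfdfa(log_ratio_increments(trw), q = 2, scale_max = 2^11)
  expect_equal(fitw$H, 0.5, tolerance = 0.08)

  expect_error(gen_respirometry_trace(duration_s = 512), "2\\^10")
  expect_error(gen_respirometry_trace(drift_amplitude = 1.5),
               "outside its allowed range")
})

test_that("two-group generator matches its SEM contract", {
  m <- data.frame(name = c("a", "b"), mean_1 = c(0, 10), sem_1 = c(1, 2),
                  mean_2 = c(0, 10), sem_2 = c(1, 2))
  tab <- gen_two_group_table(m, n_per_group = 2000, seed = 1)
  expect_equal(nrow(tab), 4000)
  expect_equal(levels(tab$group), c("CTRL", "TREAT"))
  # generating SD = sem * sqrt(n)
  expect_equal(sd(tab$a[tab$group == "CTRL"]), sqrt(2000), tolerance = 0.05)
  # equal group means -> t near 0 at large n
  expect_lt(abs(t_from_raw(tab$b[tab$group == "CTRL"],
                           tab$b[tab$group == "TREAT"])$t), 3)
  expect_identical(gen_two_group_table(m, seed = 9),
                   gen_two_group_table(m, seed = 9))
  m$sem_1[1] <- 0
  expect_error(gen_two_group_table(m), "SEM")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_fgn(0.7, 512, seed = 1))
  invisible(gen_two_group_table(behavior_reference_summary(), seed = 2))
  invisible(gen_binomial_cascade(0.6, 8, randomize = TRUE, seed = 3))
  expect_identical(.Random.seed, before)
})
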