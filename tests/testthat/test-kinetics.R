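test_that("single-reaction fit with frozen tau equals the closed form -ln(1 - m)", {
  k_true <- make_rate_table(seed = 31)
  lv <- levels_from_truth(k_true, tau = 1)[[1]]
  fit <- fit_virtual_time_rates(lv, fix_tau = 1, min_count = 1)
  expect_equal(unname(fit$k[lv$context]), -log(1 - lv$level), tolerance = 1e-10)
})

test_that("noise-free multi-reaction fit recovers rates after gauge alignment", {
  k_true <- make_rate_table(seed = 32)
  tau_true <- c(0.2, 0.7, 1.5, 4)
  ll <- levels_from_truth(k_true, tau_true)
  fit <- fit_virtual_time_rates(ll, seed = 33)
  expect_true(fit$converged)
  g <- exp(mean(log(k_true)))
  expect_equal(unname(fit$k[names(k_true)]), unname(k_true / g),
               tolerance = 1e-6)
  expect_equal(unname(fit$tau), tau_true * g, tolerance = 1e-6)
  # gauge: geometric mean of fitted rates is 1
  expect_equal(exp(mean(log(fit$k))), 1, tolerance = 1e-10)
})

test_that("the fitter is gauge invariant under k -> ck, tau -> tau/c", {
  k_true <- make_rate_table(seed = 34)
  tau_true <- c(0.3, 1, 3)
  base <- fit_virtual_time_rates(levels_from_truth(k_true, tau_true), seed = 35)
  for (c_scale in c(0.1, 10)) {
    scaled <- fit_virtual_time_rates(
      levels_from_truth(k_true * c_scale, tau_true / c_scale), seed = 35)
    expect_equal(scaled$k, base$k, tolerance = 1e-8)
    expect_equal(scaled$tau, base$tau, tolerance = 1e-8)
  }
})

test_that("degenerate contexts get sentinel rates and monotonicity holds", {
  k_true <- make_rate_table(seed = 36)
  ll <- levels_from_truth(k_true, c(0.5, 2))
  ll <- lapply(ll, function(d) {
    d$level[d$context == "AACGAA"] <- 0     # never methylated
    d$level[d$context == "TTCGTT"] <- 1     # stuck at plateau
    d
  })
  fit <- fit_virtual_time_rates(ll, seed = 37)
  expect_identical(unname(fit$k["AACGAA"]), 0)
  expect_identical(unname(fit$k["TTCGTT"]), Inf)
  expect_identical(fit$flagged$zero, "AACGAA")
  expect_identical(fit$flagged$saturated, "TTCGTT")

  # noise-free k ordering equals the level ordering within one reaction
  others <- setdiff(names(k_true), c("AACGAA", "TTCGTT"))
  lv1 <- ll[[1]]
  expect_identical(order(fit$k[others]),
                   order(lv1$level[match(others, lv1$context)]))
})

test_that("contexts observed in fewer than two reactions are excluded", {
  k_true <- make_rate_table(seed = 38)
  ll <- levels_from_truth(k_true, c(0.5, 2))
  ll[[1]]$n_total[1] <- 3L   # below min_count in reaction 1
  fit <- fit_virtual_time_rates(ll, min_count = 10, seed = 39)
  expect_identical(fit$excluded_contexts, ll[[1]]$context[1])
  expect_false(ll[[1]]$context[1] %in% names(fit$k))
})

test_that("CpN class rates are recovered relative to CpG", {
  # identical CpG and CpA levels -> relative rate 1
  mk <- function(kg, ka, tau, n = 1000L) {
    data.frame(class = c("CpG", "CpA"),
               n_meth = NA_integer_, n_total = n,
               level = 1 - exp(-c(kg, ka) * tau))
  }
  same <- lapply(c(0.4, 1.2), function(t) mk(1, 1, t))
  rel <- fit_cpn_class_rates(same, seed = 40)
  expect_equal(unname(rel["CpA"]), 1, tolerance = 1e-8)

  # binomially sampled levels with k_CpA = 0.1 k_CpG at n = 1e5 reads
  set.seed(41)
  taus <- c(0.3, 0.8, 2)
  noisy <- lapply(taus, function(t) {
    p <- 1 - exp(-c(1, 0.1) * t)
    n <- 1e5L
    data.frame(class = c("CpG", "CpA"), n_meth = NA_integer_, n_total = n,
               level = rbinom(2, n, p) / n)
  })
  rel2 <- fit_cpn_class_rates(noisy, seed = 42)
  expect_lt(abs(rel2[["CpA"]] / 0.1 - 1), 0.05)

  # shared virtual times from a CpG rate table are honoured
  k_true <- make_rate_table(seed = 43)
  cpg_fit <- fit_virtual_time_rates(levels_from_truth(k_true, taus), seed = 44)
  shared <- lapply(seq_along(taus), function(j) {
    t_eff <- unname(cpg_fit$tau[j])   # gauge-consistent times
    data.frame(class = c("CpG", "CpA"), n_meth = NA_integer_, n_total = 1000L,
               level = 1 - exp(-c(2, 0.5) * t_eff))
  })
  rel3 <- fit_cpn_class_rates(shared, shared_tau = cpg_fit, seed = 45)
  expect_equal(unname(rel3[["CpA"]]), 0.25, tolerance = 1e-6)
})

test_that("initial rates come from OLS with duplicate-time collapsing", {
  r1 <- initial_rate(c(0, 2, 4, 8), c(0, 4, 8, 16))
  expect_equal(r1$slope, 2)
  expect_equal(r1$intercept, 0)
  expect_equal(r1$r_squared, 1)

  r2 <- initial_rate(c(2, 4, 8, 12), c(5, 9, 17, 25))
  expect_equal(r2$slope, 2)
  expect_equal(r2$intercept, 1)

  # duplicated times collapse to the mean signal
  r3 <- initial_rate(c(0, 2, 2, 4), c(0, 3, 5, 8))
  expect_equal(r3$n_points, 3L)
  expect_equal(r3$slope, 2)

  expect_error(initial_rate(c(0, 1), c(0, 1)), ">= 3")

  # noisy line: slope recovered within 2 SE
  set.seed(48)
  tt <- seq(0, 10, length.out = 12)
  r4 <- initial_rate(tt, 3 * tt + rnorm(12, 0, 0.5))
  expect_lt(abs(r4$slope - 3), 2 * r4$slope_se)
})

test_that("hm - fm differencing isolates the central-site rate", {
  hm <- initial_rate(c(0, 2, 4, 8), c(0, 6, 12, 24))   # slope 3
  fm <- initial_rate(c(0, 2, 4, 8), c(0, 2.4, 4.8, 9.6)) # slope 1.2
  d <- hm_fm_difference(hm, fm)
  expect_equal(d$rate, 1.8)
  expect_false(d$negative_flag)
  expect_true(hm_fm_difference(fm, hm)$negative_flag)
  expect_equal(hm_fm_difference(hm, hm)$rate, 0)
})

test_that("substrate preference averages NNCGNN rates over both strands", {
  ctx <- all_contexts("CG")
  flat <- setNames(rep(1, 256), ctx)
  seq1 <- "ATATTACGGAATAT"
  expect_equal(predict_substrate_preference(seq1, flat)$mean_rate, 1)

  # one CpG: upper context TACGGA, lower TCCGTA; assign rates 2 and 4
  rates <- flat
  rates["TACGGA"] <- 2
  rates[revcomp("TACGGA")] <- 4
  ps <- predict_substrate_preference(seq1, rates)
  expect_equal(ps$mean_rate, 3)

  # palindromic context contributes the same rate twice
  seq2 <- "ATATTGCGCAATAT"   # context TGCGCA, revcomp TGCGCA
  expect_identical(revcomp("TGCGCA"), "TGCGCA")
  ps2 <- predict_substrate_preference(seq2, rates)
  expect_equal(ps2$per_site$rate[1], ps2$per_site$rate[2])

  # edge CpGs without full context are skipped and counted
  seq3 <- "CGATTACGGAAT"
  ps3 <- predict_substrate_preference(seq3, flat)
  expect_identical(ps3$n_skipped, 1L)
})
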