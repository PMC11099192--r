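test_that("base frequencies count directly and sum to one per position", {
  seqs <- c(paste0(strrep("A", 8), "A", "A", "CG", strrep("A", 10)),
            paste0(strrep("A", 8), "C", "A", "CG", strrep("A", 10)),
            paste0(strrep("A", 8), "G", "A", "CG", strrep("A", 10)),
            paste0(strrep("A", 8), "T", "A", "CG", strrep("A", 10)))
  calls <- make_calls(seqs, c("methylated", "methylated", "unmethylated",
                              "unmethylated"))
  fr <- base_frequencies(calls)
  expect_true(all(abs(colSums(fr$f_total) - 1) < 1e-12))
  expect_true(all(abs(colSums(fr$f_meth) - 1) < 1e-12))
  # position -2 saw one of each base in the total pool
  expect_equal(unname(fr$f_total[, "-2"]), rep(0.25, 4))
  # error with an empty product pool
  none <- make_calls(seqs, rep("unmethylated", 4))
  expect_error(base_frequencies(none), "no product pool")
})

test_that("o/e is the ratio of pool frequencies with the normalization invariant", {
  wins <- random_windows(400, seed = 21)
  meth <- rep(c("methylated", "unmethylated"), each = 200)
  calls <- make_calls(wins, meth)
  fr <- base_frequencies(calls)
  prof <- oe_profile(fr)
  expect_s3_class(prof, "flank_profile")
  expect_equal(prof$oe, fr$f_meth / fr$f_total, tolerance = 1e-12)
  # sum_b f_total(b,p) * oe(b,p) = 1 at every position
  norm <- colSums(fr$f_total * prof$oe, na.rm = TRUE)
  expect_true(all(abs(norm - 1) < 1e-9))

  # identical pools -> o/e identically 1
  all_meth <- make_calls(wins, rep("methylated", 400))
  prof1 <- oe_profile(base_frequencies(all_meth))
  expect_true(all(abs(prof1$oe - 1) < 1e-12))
})

test_that("preference-free simulation gives a flat profile within binomial bands", {
  ctx <- all_contexts("CG")
  kin <- true_kinetics(setNames(rep(0.7, 256), ctx), 1)
  pp <- pipeline_calls(default_layout, kin, 1, 10000, seed = 22)
  prof <- oe_profile(base_frequencies(pp$calls))
  n_m <- prof$n_methylated
  # |oe - 1| < 4 binomial SD of a frequency ratio at f ~ 0.25
  band <- 4 * sqrt(0.25 * 0.75 / n_m) / 0.25
  expect_true(all(abs(prof$oe - 1) < band))
})

test_that("merging pools counts: self-merge is identity, halves equal the whole", {
  wins <- random_windows(600, seed = 23)
  set.seed(24)
  meth <- sample(c("methylated", "unmethylated"), 600, TRUE)
  calls <- make_calls(wins, meth)
  whole <- oe_profile(base_frequencies(calls))
  self <- merge_profiles(list(whole, whole))
  expect_equal(self$oe, whole$oe, tolerance = 1e-12)
  expect_equal(attr(self, "replicate_correlations")[1, 2], 1)

  h1 <- oe_profile(base_frequencies(make_calls(wins[1:300], meth[1:300])))
  h2 <- oe_profile(base_frequencies(make_calls(wins[301:600], meth[301:600])))
  merged <- merge_profiles(list(h1, h2))
  expect_equal(merged$oe, whole$oe, tolerance = 1e-12)

  h2$site_class <- "CpA"
  expect_error(merge_profiles(list(h1, h2)), "mixed site_class")
})

test_that("profile correlation is symmetric, affine-invariant and errors when underpowered", {
  x <- c(1, 2, 3); y <- c(3, 2, 1)
  expect_equal(correlate_profiles(x, y), -1)
  expect_equal(correlate_profiles(x, x), 1)
  expect_equal(correlate_profiles(x, 2 * x - 0.5), 1)
  z <- c(0.3, 1.7, 0.9, 1.2)
  expect_equal(correlate_profiles(z, c(2, 0.1, 0.5, 1)),
               correlate_profiles(c(2, 0.1, 0.5, 1), z))
  expect_error(correlate_profiles(c(1, 2), c(1, 2)), "fewer than 3")
})

test_that("context levels are per-context ratios matching the kinetic closed form", {
  # 10 identical-context windows, 3 methylated -> level 0.3
  win <- paste0("AAAAAAAA", "TA", "CG", "GA", "AAAAAAAA")
  calls <- make_calls(rep(win, 10),
                      c(rep("methylated", 3), rep("unmethylated", 7)))
  lv <- context_levels(calls)
  expect_identical(lv$context, "TACGGA")
  expect_equal(lv$level, 0.3)

  # saturation: everything methylated -> every observed context at 1
  wins <- random_windows(300, seed = 25)
  sat <- context_levels(make_calls(wins, rep("methylated", 300)))
  expect_true(all(sat$level == 1))

  # simulated reads at known k, tau match 1 - exp(-k tau) within 4 SD
  k <- make_rate_table(seed = 26)
  kin <- true_kinetics(k, virtual_times = 0.9)
  pp <- pipeline_calls(default_layout, kin, 1, 20000, seed = 27)
  lv2 <- context_levels(pp$calls)
  lv2 <- lv2[lv2$n_total >= 30, ]
  p_true <- 1 - exp(-k[lv2$context] * 0.9)
  sd4 <- 4 * sqrt(p_true * (1 - p_true) / lv2$n_total)
  expect_true(all(abs(lv2$level - p_true) <= pmax(sd4, 1e-9)))
})

test_that("CCWGG-flagged calls are excluded from CpA/CpT context levels", {
  w_flag <- paste0("AAAAAAAAA", "C", "CA", "GG", "AAAAAAAA")   # CCAGG
  w_ok <- paste0("AAAAAAAAA", "A", "CA", "GG", "AAAAAAAA")
  calls <- make_calls(c(w_flag, w_ok), rep("methylated", 2),
                      site_class = "CpA", ccwgg_flag = c(TRUE, FALSE))
  lv <- context_levels(calls, site_class = "CpA")
  expect_identical(nrow(lv), 1L)
  expect_identical(lv$context, "AACAGG")
})

test_that("extreme-decile composition enriches the discriminating base", {
  ctx <- all_contexts("CG")
  # value 2 iff the -2 base is C, else 1
  vals <- setNames(ifelse(substr(ctx, 1, 1) == "C", 2, 1), ctx)
  ex <- extreme_site_composition(vals)
  expect_equal(unname(ex$top["C", "-2"]), 4)
  expect_true(all(substr(ex$top_contexts, 1, 1) == "C"))
  # 26 contexts per decile (ceiling of 25.6)
  expect_length(ex$top_contexts, 26L)

  # flat values: deterministic lexicographic tie-break, enrichment defined
  flat <- setNames(rep(1, 256), ctx)
  ex_flat <- extreme_site_composition(flat)
  expect_identical(ex_flat$top_contexts, sort(ctx)[1:26])
  expect_error(extreme_site_composition(vals[1:10]), "at least 20")
})
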