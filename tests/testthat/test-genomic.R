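test_that("methylome loading filters coverage, validates CpGs and extracts contexts", {
  # toy genome: three internal CpGs far from the edges
  g <- c(chrT = paste0(strrep("A", 20), "CG", strrep("T", 20), "CG",
                       strrep("A", 20), "CG", strrep("T", 20)))
  cpos <- c(20L, 42L, 64L)  # 0-based C positions
  calls <- data.frame(chrom = "chrT", pos = cpos, strand = "+",
                      meth_count = c(2L, 5L, 1L), total_count = c(5L, 5L, 2L),
                      stringsAsFactors = FALSE)
  sites <- load_methylome(calls, g, min_coverage = 5)
  expect_identical(nrow(sites), 2L)
  expect_identical(attr(sites, "log")$n_low_coverage, 1L)
  expect_identical(substr(sites$context6, 3, 4), c("CG", "CG"))
  expect_identical(nchar(sites$context22), c(22L, 22L))

  # threshold above every coverage -> empty set
  expect_identical(nrow(load_methylome(calls, g, min_coverage = 6)), 0L)

  # a call not on a CpG cytosine is rejected and counted
  bad <- rbind(calls, data.frame(chrom = "chrT", pos = 5L, strand = "+",
                                 meth_count = 5L, total_count = 5L))
  expect_identical(attr(load_methylome(bad, g), "log")$n_not_cpg, 1L)

  expect_error(load_methylome(calls, c(other = "ACGT")), "missing from genome")
})

test_that("loaded contexts equal the simulator's truth, on both strands", {
  pref <- make_rate_table(seed = 51)
  sim <- simulate_methylome(30000, pref, mean_level = 0.2, coverage_mean = 20,
                            seed = 52)
  sites <- load_methylome(sim$calls, sim$genome, min_coverage = 5)
  key <- paste(sites$pos, sites$strand)
  tr <- sim$truth[match(key, paste(sim$truth$pos, sim$truth$strand)), ]
  expect_identical(sites$context6, tr$context6)
  expect_true(all(substr(sites$context6, 3, 4) == "CG"))
})

test_that("context means and o/e behave like averages and ratios", {
  g <- c(chrT = paste0(strrep("A", 15), "TACGGA", strrep("A", 15), "TACGGA",
                       strrep("A", 15)))
  cpos <- c(17L, 38L)
  calls <- data.frame(chrom = "chrT", pos = cpos, strand = "+",
                      meth_count = c(2L, 4L), total_count = c(10L, 10L),
                      stringsAsFactors = FALSE)
  sites <- load_methylome(calls, g)
  cm <- mean_by_context(sites)
  expect_equal(unname(cm$context_means["TACGGA"]), 0.3)
  expect_equal(cm$overall_mean, 0.3)
  expect_equal(unname(genomic_oe(cm)["TACGGA"]), 1)

  # saturation
  calls$meth_count <- calls$total_count
  cm_sat <- mean_by_context(load_methylome(calls, g))
  expect_equal(cm_sat$overall_mean, 1)
  expect_true(all(genomic_oe(cm_sat) == 1))

  # arithmetic: context at 3%, overall 1.5% -> o/e 2
  fake <- list(context_means = c(AACGAA = 0.03), n_sites = c(AACGAA = 10L),
               overall_mean = 0.015)
  expect_equal(unname(genomic_oe(fake)["AACGAA"]), 2)
  fake$overall_mean <- 0
  expect_error(genomic_oe(fake), "zero")
})

test_that("o/e of context means is invariant under global level rescaling", {
  pref <- make_rate_table(seed = 53)
  sim <- simulate_methylome(50000, pref, mean_level = 0.1, coverage_mean = 15,
                            seed = 54)
  sites <- load_methylome(sim$calls, sim$genome)
  cm <- mean_by_context(sites)
  cm_scaled <- cm
  cm_scaled$context_means <- cm$context_means * 3.7
  cm_scaled$overall_mean <- cm$overall_mean * 3.7
  expect_equal(genomic_oe(cm_scaled), genomic_oe(cm), tolerance = 1e-12)
})

test_that("NNCG aggregation weights contexts by site counts", {
  fake <- list(context_means = c(AACGAA = 0.1, AACGTT = 0.3),
               n_sites = c(AACGAA = 1L, AACGTT = 3L),
               overall_mean = 0.25)
  oe <- genomic_oe(fake, granularity = "NNCG")
  expect_equal(unname(oe["AACG"]), ((0.1 * 1 + 0.3 * 3) / 4) / 0.25)
})

test_that("sliding-window correlation matches a direct Pearson computation", {
  pref <- make_rate_table(seed = 55)
  sim <- simulate_methylome(20000, pref, mean_level = 0.3, coverage_mean = 30,
                            seed = 56)
  sites <- load_methylome(sim$calls, sim$genome)
  wc <- local_correlation(sites, pref, window = 22)
  expect_identical(wc$n_windows, nrow(sites) - 22L + 1L)
  # direct check of a few windows against stats::cor
  pv <- unname(pref[sites$context6])
  for (i in c(1L, 50L, wc$n_windows)) {
    idx <- i:(i + 21L)
    expected <- suppressWarnings(cor(sites$level[idx], pv[idx]))
    if (is.na(expected)) expect_true(is.na(wc$r[i]))
    else expect_equal(wc$r[i], expected, tolerance = 1e-10)
  }
  # a window with constant methylation is skipped
  s2 <- sites[1:30, ]
  s2$level <- 0.5
  s2$meth_count <- s2$total_count  # irrelevant to r, level drives it
  wc2 <- local_correlation(s2, pref, window = 22)
  expect_identical(wc2$n_skipped, wc2$n_windows)
  # perfect tracking gives r = 1
  s3 <- sites[1:30, ]
  s3$level <- pv[1:30] * 0.01
  wc3 <- local_correlation(s3, pref, window = 22)
  expect_true(all(abs(wc3$r - 1) < 1e-9))

  expect_error(local_correlation(sites, pref, window = 2), ">= 3")
})

test_that("randomization Z separates signal from shuffled preferences", {
  pref <- make_rate_table(seed = 57)
  sim <- simulate_methylome(100000, pref, mean_level = 0.2, coverage_mean = 15,
                            seed = 58)
  sites <- load_methylome(sim$calls, sim$genome)
  z_sig <- randomization_z(sites, pref, n_randomizations = 20, seed = 59)
  expect_gt(z_sig$Z, 3)
  expect_lt(z_sig$p, 0.01)

  # preference shuffled before the analysis: no signal
  set.seed(60)
  shuffled <- setNames(sample(unname(pref)), names(pref))
  z_null <- randomization_z(sites, shuffled, n_randomizations = 20, seed = 61)
  expect_lt(abs(z_null$Z), 3)

  expect_error(randomization_z(sites, pref, n_randomizations = 5), ">= 20")
})

test_that("strand collapsing preserves context means up to binomial noise", {
  # strand-symmetric preference: pref(ctx) = pref(revcomp(ctx)), so the two
  # records of a CpG share one true level and collapsing only pools counts
  pref0 <- make_rate_table(seed = 62)
  pref <- (pref0 + pref0[revcomp(names(pref0))]) / 2
  sim <- simulate_methylome(80000, pref, mean_level = 0.3, coverage_mean = 20,
                            seed = 63)
  per_strand <- load_methylome(sim$calls, sim$genome)
  collapsed <- load_methylome(sim$calls, sim$genome, collapse_strands = TRUE)
  expect_lt(nrow(collapsed), nrow(per_strand))
  cm_s <- mean_by_context(per_strand)
  cm_c <- mean_by_context(collapsed)
  # overall means agree closely; per-context means correlate strongly
  expect_lt(abs(cm_s$overall_mean - cm_c$overall_mean), 0.02)
  expect_gt(correlate_profiles(cm_s$context_means, cm_c$context_means), 0.8)
})

test_that("methylation-call tables round-trip through TSV and Bismark dialect", {
  calls <- data.frame(chrom = "chr1", pos = c(10L, 20L), strand = c("+", "-"),
                      meth_count = c(1L, 3L), total_count = c(4L, 6L),
                      stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_meth_calls(calls, f)
  expect_identical(read_meth_calls(f), calls)
  # Bismark coverage dialect: chrom, start 1-based, end, pct, meth, unmeth
  bis <- data.frame(chrom = "chr1", start = 11L, end = 11L, pct = 25,
                    m = 1L, u = 3L)
  write.table(bis, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  back <- read_meth_calls(f)
  expect_identical(back$pos, 10L)
  expect_identical(back$total_count, 4L)
  unlink(f)
})
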