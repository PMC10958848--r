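test_that("simulate_truth places exactly n_truth unique in-region SNVs, reproducibly", {
  cfg <- small_config(n_truth = 150L, seed = 21)
  ts <- simulate_truth(cfg)
  expect_equal(length(ts$truth), 150L)
  expect_equal(anyDuplicated(variant_keys(ts$truth)), 0L)
  expect_equal(length(restrict(ts$truth, ts$regions)), 150L)  # all in-region
  expect_true(all(nchar(ts$truth$calls$ref) == 1L))
  ts2 <- simulate_truth(cfg)
  expect_equal(variant_keys(ts2$truth), variant_keys(ts$truth))
  expect_equal(ts2$truth$calls$vaf, ts$truth$calls$vaf)
  # default truth size matches the benchmark's 1159 high-confidence SNVs
  expect_equal(study_config()$n_truth, 1159L)
  # region too small to host the requested sites
  tiny <- small_config(chroms = "chr1", intervals_per_chrom = 2L,
                       interval_width = 30L, n_truth = 100L)
  expect_error(simulate_truth(tiny), "too small")
})

test_that("truth VAFs follow the configured mixture (KS distance < 0.05)", {
  cfg <- study_config(seed = 2)
  set.seed(1)
  draws <- rvaf(1e4, cfg)
  ks <- suppressWarnings(stats::ks.test(draws, function(q) pvaf(q, cfg)))
  expect_lt(unname(ks$statistic), 0.05)
  expect_true(all(draws > 0 & draws < 1))
})

test_that("a perfect caller with zero FP rates reproduces the truth exactly", {
  cfg <- noiseless_config(n_truth = 200L, chroms = paste0("chr", 1:4),
                          chrom_length = 5e5L, seed = 3)
  b <- simulate_study(cfg)
  tk <- variant_keys(b$truth)
  for (cs in b$callsets) expect_setequal(variant_keys(cs), tk)
})

test_that("with sensitivity zero the call-set size is the private FP draw", {
  # intercept -Inf => detection probability 0; only Poisson private FPs remain
  lambda <- 30
  sizes <- vapply(1:200, function(s) {
    cfg <- small_config(
      n_truth = 20L, seed = s,
      centers = list(A = center_profile(1L, 50)),
      callers = list(mutect = caller_profile(0, -Inf, fp_private = lambda)),
      difficult_fraction = 0)
    length(simulate_study(cfg)$callsets[[1L]])
  }, numeric(1))
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(sizes) - lambda), 3 * se)
})

test_that("center pools are shared within, and only within, a center", {
  overlaps_within <- overlaps_between <- caller_shared <- c()
  for (s in 1:40) {
    cfg <- small_config(
      n_truth = 30L, seed = s,
      centers = list(A = center_profile(2L, 50, 20L, 0.8),
                     B = center_profile(2L, 50, 20L, 0.8)),
      callers = list(mutect = caller_profile(0, -Inf, fp_private = 0,
                                             artifact_sites = 10L,
                                             artifact_incl = 0.7)),
      difficult_fraction = 0)
    b <- simulate_study(cfg)
    k <- lapply(b$callsets, variant_keys)
    tk <- variant_keys(b$truth)
    fp <- lapply(k, setdiff, y = tk)
    overlaps_within <- c(overlaps_within,
                         length(intersect(fp$A_1_bwa_mutect, fp$A_2_bwa_mutect)))
    # center-pool sites never cross centers; only caller-pool sites can
    shared_ab <- intersect(fp$A_1_bwa_mutect, fp$B_1_bwa_mutect)
    caller_shared <- c(caller_shared, length(shared_ab))
    overlaps_between <- c(overlaps_between, length(shared_ab))
  }
  # each center pool has 20 sites at inclusion 0.8 (expect ~12.8 shared) plus
  # 10 caller-pool sites at 0.7 (~4.9 shared)
  expect_gt(mean(overlaps_within), 12)
  expect_lt(mean(overlaps_within), 24)
  # cross-center sharing comes only from the 10-site caller pool (~4.9)
  expect_gt(mean(overlaps_between), 2.5)
  expect_lt(mean(overlaps_between), 8)
})

test_that("each call set has its own stream: adding a pipeline changes nothing", {
  cfg <- small_config(n_truth = 80L, seed = 9)
  b1 <- simulate_study(cfg)
  cfg2 <- small_config(
    n_truth = 80L, seed = 9,
    callers = list(mutect = caller_profile(0.45, -0.8, fp_private = 25,
                                           artifact_sites = 5L,
                                           artifact_incl = 0.7),
                   strelka = caller_profile(0.4, -1.0, fp_private = 40)))
  b2 <- simulate_study(cfg2)
  for (nm in names(b1$callsets)) {
    expect_equal(variant_keys(b2$callsets[[nm]]), variant_keys(b1$callsets[[nm]]))
  }
  expect_gt(length(b2$callsets), length(b1$callsets))
})

test_that("a materialized study round-trips through the VCF/BED readers", {
  cfg <- small_config(n_truth = 60L, seed = 30)
  b <- simulate_study(cfg)
  dir <- tempfile()
  write_study(b, dir)
  back <- read_study(dir)
  expect_setequal(variant_keys(back$truth), variant_keys(b$truth))
  expect_equal(as.data.frame(back$regions), as.data.frame(b$regions))
  expect_equal(nrow(back$manifest), nrow(b$manifest))
  for (nm in names(b$callsets)) {
    expect_setequal(variant_keys(back$callsets[[nm]]),
                    variant_keys(b$callsets[[nm]]))
  }
  # rerun materialization is byte-identical (seeded determinism)
  dir2 <- tempfile()
  write_study(simulate_study(cfg), dir2)
  f <- "A_1_bwa_mutect.vcf"
  expect_equal(readLines(file.path(dir2, f)), readLines(file.path(dir, f)))
  expect_equal(readLines(file.path(dir2, "truth.vcf")),
               readLines(file.path(dir, "truth.vcf")))
})

test_that("estimate_profile recovers configured sensitivity and FP rate", {
  # perfect caller: sensitivity exactly 1, FP rate exactly 0
  b0 <- simulate_study(noiseless_config(n_truth = 100L, seed = 4))
  ep0 <- estimate_profile(b0)
  expect_equal(ep0$sensitivity, rep(1, nrow(ep0)))
  expect_equal(ep0$fp_rate, rep(0, nrow(ep0)))
  # constant sensitivity 0.8 with lambda = 40 private FPs, a quick single-seed check
  cfg <- small_config(
    n_truth = 400L, seed = 8,
    centers = list(A = center_profile(3L, 60), B = center_profile(3L, 60)),
    callers = list(mutect = caller_profile(0, qlogis(0.8), fp_private = 40,
                                           artifact_sites = 0L)),
    difficult_fraction = 0)
  ep <- estimate_profile(simulate_study(cfg))
  expect_lt(abs(ep$sensitivity - 0.8), 0.03)
  expect_lt(abs(ep$fp_rate - 40), 3 * sqrt(40 / ep$n_callsets))
})

test_that("shared pools separate the grouping schemes; removing them equalizes", {
  # isolated pool effect: center-shared artifacts survive within-center voting
  # but not cross-center voting, so they depress within-center precision
  f1_m2 <- function(cfg_fun, scheme, seeds) {
    vapply(seeds, function(s) {
      b <- simulate_study(cfg_fun(s))
      res <- suppressMessages(run_consensus(
        b, out_dir = tempfile(), schemes = scheme, quiet = TRUE))
      mean(vapply(res[[scheme]], function(sw) sw$f1[sw$m == 2], numeric(1)))
    }, numeric(1))
  }
  pools_on <- function(s) small_config(
    n_truth = 200L, seed = s,
    centers = list(A = center_profile(3L, 60, 25L, 0.9),
                   B = center_profile(3L, 60, 25L, 0.9),
                   C = center_profile(3L, 60, 25L, 0.9)),
    callers = list(mutect = caller_profile(0, qlogis(0.85), fp_private = 30)),
    difficult_fraction = 0)
  pools_off <- function(s) small_config(
    n_truth = 200L, seed = s,
    centers = list(A = center_profile(3L, 60), B = center_profile(3L, 60),
                   C = center_profile(3L, 60)),
    callers = list(mutect = caller_profile(0, qlogis(0.85), fp_private = 30)),
    difficult_fraction = 0, center_site_sd = 0)
  seeds <- 1:30
  w_on <- f1_m2(pools_on, "within_center", seeds)
  x_on <- f1_m2(pools_on, "cross_center", seeds)
  expect_lt(t.test(w_on, x_on, paired = TRUE)$p.value, 0.01)
  expect_lt(mean(w_on), mean(x_on))  # direction set by the center pools
  w_off <- f1_m2(pools_off, "within_center", seeds)
  x_off <- f1_m2(pools_off, "cross_center", seeds)
  # identical exchangeable centers: no detectable scheme difference
  expect_lt(abs(mean(w_off) - mean(x_off)), 0.01)
})
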