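callers3 <- function(sets) {
  # name three call sets as the three callers of one replicate
  names(sets) <- c("mutect", "strelka", "ss")[seq_along(sets)]
  sets
}

test_that("candidate features encode per-caller membership", {
  sets <- callers3(list(mk_cs(1L, caller = "mutect"),
                        mk_cs(1:2, caller = "strelka"),
                        mk_cs(1L, caller = "ss")))
  cand <- build_candidates(sets)
  expect_equal(nrow(cand), 2L)
  v1 <- cand[cand$pos == 1L, ]; v2 <- cand[cand$pos == 2L, ]
  expect_equal(unlist(v1[, c("det_mutect", "det_strelka", "det_ss")]),
               c(det_mutect = 1, det_strelka = 1, det_ss = 1))
  expect_equal(unlist(v2[, c("det_mutect", "det_strelka", "det_ss")]),
               c(det_mutect = 0, det_strelka = 1, det_ss = 0))
  # absent qualities imputed to 0 with missingness indicator set
  expect_equal(v2$qual_mutect, 0)
  expect_equal(v2$qual_mutect_missing, 1)
  expect_error(build_candidates(list()), "non-empty")
})

test_that("candidate flags agree with detection_counts on random sets", {
  set.seed(12)
  for (trial in 1:10) {
    sets <- callers3(replicate(3, rand_cs(40L, n_universe = 60L),
                               simplify = FALSE))
    cand <- build_candidates(sets)
    flags <- rowSums(cand[, c("det_mutect", "det_strelka", "det_ss")])
    counts <- detection_counts(unname(sets), allow_mixed = TRUE)
    keys <- paste(cand$chrom, cand$pos, cand$ref, cand$alt, sep = ":")
    expect_equal(unname(flags), unname(as.numeric(counts[keys])))
  }
})

test_that("negative sampling respects the ratio and avoids called sites", {
  rs <- region_set("chr1", 0L, 5000L)
  sets <- callers3(list(mk_cs(1:30), mk_cs(10:40), mk_cs(5:25)))
  cand0 <- build_candidates(sets, negatives_per_positive = 0)
  expect_equal(nrow(cand0), 40L)  # exactly the union
  cand1 <- build_candidates(sets, negatives_per_positive = 1, regions = rs,
                            seed = 3)
  expect_equal(nrow(cand1), 80L)
  negs <- cand1[rowSums(cand1[, grep("^det_", names(cand1))]) == 0, ]
  expect_equal(nrow(negs), 40L)
  expect_false(any(negs$pos %in% 1:40))
  expect_true(all(negs$vaf_missing == 1))
  expect_error(build_candidates(sets, negatives_per_positive = 1), "regions")
})

test_that("labels follow set membership with containment across m", {
  sets <- callers3(replicate(3, rand_cs(50L, n_universe = 80L),
                             simplify = FALSE))
  cand <- build_candidates(sets)
  reps <- replicate(3, rand_cs(40L, n_universe = 80L), simplify = FALSE)
  lab2 <- assign_labels(cand, consensus(reps, 2), "consensus_m2")
  lab3 <- assign_labels(cand, consensus(reps, 3), "consensus_m3")
  expect_true(all(lab3$label <= lab2$label))  # positives nest downward in m
  keys <- paste(cand$chrom, cand$pos, cand$ref, cand$alt, sep = ":")
  expect_equal(lab2$label,
               as.integer(keys %in% variant_keys(consensus(reps, 2))))
  expect_equal(unique(lab2$label_source), "consensus_m2")
})

test_that("chromosome split is a true partition with clear failure modes", {
  set.seed(44)
  chroms <- paste0("chr", 1:7)
  cand <- call_set(sample(chroms, 100, replace = TRUE), sample.int(9999L, 100),
                   "A", "T")$calls
  cand$label <- rbinom(100, 1, 0.5)
  attr(cand, "feature_cols") <- character(0)
  sp <- split_by_chromosome(cand, paste0("chr", 1:3))
  expect_equal(nrow(sp$train) + nrow(sp$test), 100L)
  expect_length(intersect(unique(sp$train$chrom), unique(sp$test$chrom)), 0L)
  expect_true(all(sp$train$chrom %in% paste0("chr", 1:3)))
  one <- cand[cand$chrom == cand$chrom[1], ]
  expect_error(split_by_chromosome(one, unique(one$chrom)), "empty test")
  expect_error(split_by_chromosome(one, "chrZZ"), "empty training")
  expect_error(split_by_chromosome(one, character(0)), "non-empty")
})

test_that("classifier training is seeded-deterministic and fits separable data", {
  set.seed(2)
  n <- 400L
  cand <- data.frame(chrom = rep(c("chr1", "chr2"), each = n / 2),
                     pos = 1:n, ref = "A", alt = "T",
                     signal = c(rnorm(n / 2, 3), rnorm(n / 2, 3)),
                     stringsAsFactors = FALSE)
  cand$label <- as.integer(cand$signal > 3)
  cand$signal <- cand$signal + cand$label * 10  # force wide margin
  cand$label_source <- "toy"
  attr(cand, "feature_cols") <- "signal"
  sp <- split_by_chromosome(cand, "chr1")
  model <- train_classifier(sp$train, seed = 9)
  pred <- predict(model, sp$train)
  expect_equal(as.integer(pred >= 0.5), sp$train$label)  # separable: exact fit
  model2 <- train_classifier(sp$train, seed = 9)
  expect_equal(predict(model2, sp$test), predict(model, sp$test))
  # single-class refusal
  onecls <- sp$train; onecls$label <- 1L
  attr(onecls, "feature_cols") <- "signal"
  expect_error(train_classifier(onecls), "single-class")
})

test_that("evaluation scores against truth membership, not training labels", {
  truth <- mk_cs(seq(2L, 40L, by = 2L))
  cand <- data.frame(chrom = "chr1", pos = 1:40, ref = "A", alt = "T",
                     x = as.numeric(1:40 %% 2 == 0), stringsAsFactors = FALSE)
  cand$label <- cand$x  # labels match truth parity
  cand$label_source <- "toy"
  attr(cand, "feature_cols") <- "x"
  model <- train_classifier(cand, nrounds = 10)
  # threshold 0: everything predicted positive -> recall 1
  mt0 <- evaluate_model(model, cand, truth, threshold = 0)
  expect_equal(mt0$recall, 1)
  mt <- evaluate_model(model, truth$calls |> transform(x = 1) |>
                         (\(d) { attr(d, "feature_cols") <- "x"; d })(),
                       truth)
  expect_equal(mt$precision, 1)
  bad <- cand; names(bad)[names(bad) == "x"] <- "y"
  expect_error(evaluate_model(model, bad, truth), "feature-order mismatch")
})

test_that("a label-shuffled model scores near the class prior", {
  set.seed(14)
  b <- simulate_study(small_config(n_truth = 200L, seed = 3))
  sets <- list(mutect = b$callsets[["A_1_bwa_mutect"]])
  cand <- build_candidates(sets, negatives_per_positive = 1,
                           regions = b$regions, seed = 1)
  lab <- assign_labels(cand, b$truth, "truth")
  lab$label <- sample(lab$label)  # destroy the feature-label link
  sp <- split_by_chromosome(lab, paste0("chr", 1:3))
  model <- train_classifier(sp$train, seed = 1)
  mt <- evaluate_model(model, sp$test, b$truth)
  prior <- mean(sp$test$label)
  # with no usable signal, F1 cannot approach the truth-trained regime
  expect_lt(mt$f1, 0.8)
  expect_gt(prior, 0)  # both classes present in the test fold
})

test_that("truth-labeled classifier beats the best single caller on held-out chromosomes", {
  b <- simulate_study(study_config(n_truth = 600L, seed = 13))
  man <- b$manifest
  feat_names <- man$name[man$center == "FD" & man$replicate == 1 &
                           man$mapper == "bwa"]
  sets <- b$callsets[feat_names]
  names(sets) <- man$caller[match(feat_names, man$name)]
  cand <- build_candidates(sets, negatives_per_positive = 1,
                           regions = b$regions, seed = 2)
  lab <- assign_labels(cand, b$truth, "truth")
  sp <- split_by_chromosome(lab, paste0("chr", 1:5))
  model <- train_classifier(sp$train, seed = 2)
  model_f1 <- evaluate_model(model, sp$test, b$truth)$f1
  test_chroms <- setdiff(unique(b$truth$calls$chrom), paste0("chr", 1:5))
  callset_on <- function(cs) {
    part <- cs$calls[cs$calls$chrom %in% test_chroms, ]
    call_set(part$chrom, part$pos, part$ref, part$alt)
  }
  tt <- callset_on(b$truth)
  single_f1 <- vapply(sets, function(cs)
    metrics(confusion(callset_on(cs), tt))$f1, numeric(1))
  expect_gt(model_f1, max(single_f1))
})

test_that("label experiment table has the documented shape and is seed-stable", {
  b <- simulate_study(small_config(n_truth = 250L, seed = 6,
                                   chroms = paste0("chr", 1:6)))
  tab <- label_quality_experiment(b, scheme = "within_center", m_values = 1:3,
                                  seeds = 1L, nrounds = 20)
  expect_equal(nrow(tab), 4L)  # three m rows plus the ground-truth row
  expect_setequal(tab$label_source,
                  c("consensus_m1", "consensus_m2", "consensus_m3", "truth"))
  expect_true(all(tab$test_f1 >= 0 & tab$test_f1 <= 1))
  tab2 <- label_quality_experiment(b, scheme = "within_center", m_values = 1:3,
                                   seeds = 1L, nrounds = 20)
  expect_equal(tab, tab2)
})
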