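#' Build candidate variants with per-caller features
#'
#' Candidates are the union of the caller call sets (typically the three
#' callers run on one replicate's BAM — the feature source replicate), plus
#' optionally sampled negative sites: in-region positions called by no
#' caller, at `negatives_per_positive` times the number of called
#' candidates. Each candidate carries, per caller, a detection flag and the
#' caller's quality score, plus VAF and tumor/normal depth pooled
#' first-available across callers. Missing numeric values are imputed to 0
#' with a paired missingness indicator, so "absent from this caller" is
#' distinguishable from "quality 0".
#'
#' When `labeling_callsets` is supplied, a `detection_count` feature (how
#' many of those replicates contain the candidate) is added. It is off by
#' default: when labels themselves come from a consensus over the same
#' replicates, that count is the label function and would leak it.
#'
#' @param feature_callsets Named-or-not list of `CallSet`s, one per caller,
#'   from a single replicate.
#' @param negatives_per_positive Ratio of sampled negative sites to called
#'   candidates (0 disables sampling; requires `regions` when > 0).
#' @param regions `RegionSet` to sample negatives from.
#' @param seed Integer seed for negative sampling.
#' @param labeling_callsets Optional list of `CallSet`s for the
#'   `detection_count` feature.
#' @return Data frame with key columns (`chrom`, `pos`, `ref`, `alt`) and
#'   numeric feature columns (recorded in `attr(, "feature_cols")`).
#' @export
build_candidates <- function(feature_callsets, negatives_per_positive = 0,
                             regions = NULL, seed = 1L,
                             labeling_callsets = NULL) {
  if (!is.list(feature_callsets) || length(feature_callsets) == 0L ||
      !all(vapply(feature_callsets, inherits, logical(1), "CallSet")))
    stop("feature_callsets must be a non-empty list of CallSet objects")
  caller_names <- names(feature_callsets)
  if (is.null(caller_names) || any(!nzchar(caller_names)))
    caller_names <- vapply(seq_along(feature_callsets), function(i) {
      ck <- feature_callsets[[i]]$provenance$caller
      if (is.na(ck %||% NA)) paste0("caller", i) else ck
    }, character(1))
  names(feature_callsets) <- caller_names

  union_calls <- bind_first_wins(feature_callsets)
  if (nrow(union_calls) == 0L) stop("empty caller union; no candidates to build")
  keys <- make_keys(union_calls)
  df <- union_calls[, c("chrom", "pos", "ref", "alt")]

  feats <- list()
  for (ck in caller_names) {
    cs <- feature_callsets[[ck]]
    idx <- match(keys, variant_keys(cs))
    feats[[paste0("det_", ck)]] <- as.numeric(!is.na(idx))
    q <- cs$calls$qual[idx]
    feats[[paste0("qual_", ck)]] <- ifelse(is.na(q), 0, q)
    feats[[paste0("qual_", ck, "_missing")]] <- as.numeric(is.na(q))
  }
  pool_first <- function(col) {
    out <- rep(NA_real_, length(keys))
    for (cs in feature_callsets) {
      idx <- match(keys, variant_keys(cs))
      v <- as.numeric(cs$calls[[col]][idx])
      out <- ifelse(is.na(out), v, out)
    }
    out
  }
  for (col in c("vaf", "tumor_depth", "normal_depth")) {
    v <- pool_first(col)
    feats[[col]] <- ifelse(is.na(v), 0, v)
    feats[[paste0(col, "_missing")]] <- as.numeric(is.na(v))
  }
  if (!is.null(labeling_callsets)) {
    counts <- detection_counts(labeling_callsets, allow_mixed = TRUE)
    idx <- match(keys, names(counts))
    feats$detection_count <- ifelse(is.na(idx), 0, as.numeric(counts[idx]))
  }
  out <- cbind(df, as.data.frame(feats))

  if (negatives_per_positive > 0) {
    if (is.null(regions))
      stop("regions are required to sample negative candidates")
    n_neg <- round(negatives_per_positive * nrow(out))
    if (n_neg > 0L) {
      set.seed(as.integer(seed))
      sites <- sample_sites(n_neg, regions,
                            exclude = paste(df$chrom, df$pos, sep = ":"))
      al <- random_alleles(n_neg)
      neg <- data.frame(chrom = sites$chrom, pos = sites$pos,
                        ref = al$ref, alt = al$alt, stringsAsFactors = FALSE)
      zero <- as.data.frame(lapply(feats, function(x) rep(0, n_neg)))
      for (nm in grep("_missing$", names(zero), value = TRUE)) zero[[nm]] <- 1
      out <- rbind(out, cbind(neg, zero))
    }
  }
  rownames(out) <- NULL
  attr(out, "feature_cols") <- names(feats)
  out
}

#' Label candidates from a truth or consensus set
#'
#' `label = 1` iff the candidate key is a member of `label_set`; the label
#' provenance (`"truth"`, `"consensus_m2"`, ...) is recorded per row.
#'
#' @param candidates Candidate data frame from [build_candidates()].
#' @param label_set A `CallSet` whose keys define the positives.
#' @param source_tag Character tag recorded in `label_source`.
#' @return The candidates with `label` (0/1) and `label_source` columns.
#' @export
assign_labels <- function(candidates, label_set, source_tag) {
  stopifnot(inherits(label_set, "CallSet"))
  keys <- paste(candidates$chrom, candidates$pos, candidates$ref,
                candidates$alt, sep = ":")
  out <- candidates
  out$label <- as.integer(keys %in% variant_keys(label_set))
  out$label_source <- source_tag
  attr(out, "feature_cols") <- attr(candidates, "feature_cols")
  out
}

#' Chromosome-holdout train/test split
#'
#' Partitions labeled candidates by chromosome (the replicate-study analogue
#' of a held-out sample: all replicates describe the same tumor, so a
#' chromosome split is the only split that avoids leakage). Every candidate
#' lands in exactly one side.
#'
#' @param labeled Labeled candidates from [assign_labels()].
#' @param train_chroms Character vector of training chromosome labels; the
#'   complement within the data is the test side.
#' @return List with `train` and `test` data frames.
#' @export
split_by_chromosome <- function(labeled, train_chroms) {
  if (length(train_chroms) == 0L) stop("train_chroms must be non-empty")
  in_train <- labeled$chrom %in% train_chroms
  census <- table(labeled$chrom)
  if (!any(in_train))
    stop("empty training partition; chromosome census: ",
         paste(names(census), census, sep = "=", collapse = ", "))
  if (all(in_train))
    stop("empty test partition; chromosome census: ",
         paste(names(census), census, sep = "=", collapse = ", "))
  fc <- attr(labeled, "feature_cols")
  train <- labeled[in_train, , drop = FALSE]
  test <- labeled[!in_train, , drop = FALSE]
  attr(train, "feature_cols") <- fc
  attr(test, "feature_cols") <- fc
  list(train = train, test = test)
}

#' Train the tabular variant classifier
#'
#' A seeded gradient-boosted tree ensemble (xgboost, logistic objective)
#' over the candidate features. This stands in for read-level deep models:
#' the question the package asks — how well consensus-derived labels
#' substitute for validated truth labels — is about label quality, not
#' architecture.
#'
#' @param train Labeled training candidates (must contain both classes).
#' @param params Named list of xgboost parameter overrides.
#' @param nrounds Number of boosting rounds.
#' @param seed Integer seed (training is deterministic given it).
#' @return An object of class `variant_classifier` carrying the booster,
#'   the feature ordering and training metadata.
#' @export
train_classifier <- function(train, params = list(), nrounds = 60L, seed = 1L) {
  fc <- attr(train, "feature_cols")
  if (is.null(fc)) stop("training set lacks feature metadata; build it with build_candidates()")
  if (is.null(train$label)) stop("training set is unlabeled; run assign_labels() first")
  y <- train$label
  if (length(unique(y)) < 2L)
    stop("single-class training set (all labels ", y[1L], "); cannot train")
  x <- as.matrix(train[, fc, drop = FALSE])
  defaults <- list(objective = "binary:logistic", max_depth = 4L, eta = 0.3,
                   subsample = 1, colsample_bytree = 1, nthread = 1L,
                   eval_metric = "logloss")
  p <- utils::modifyList(defaults, params)
  set.seed(as.integer(seed))
  booster <- xgboost::xgb.train(params = p,
                                data = xgboost::xgb.DMatrix(x, label = y),
                                nrounds = as.integer(nrounds), verbose = 0)
  structure(list(booster = booster, feature_cols = fc,
                 meta = list(n_train = nrow(train), nrounds = nrounds,
                             seed = as.integer(seed),
                             label_source = unique(train$label_source),
                             params = p)),
            class = "variant_classifier")
}

#' @export
print.variant_classifier <- function(x, ...) {
  cat(sprintf("variant_classifier: %d features, %d rounds, trained on %d candidates (labels: %s)\n",
              length(x$feature_cols), x$meta$nrounds, x$meta$n_train,
              paste(x$meta$label_source, collapse = ",")))
  invisible(x)
}

#' @export
predict.variant_classifier <- function(object, newdata, ...) {
  fc <- attr(newdata, "feature_cols") %||% object$feature_cols
  if (!all(object$feature_cols %in% names(newdata)))
    stop("feature-order mismatch: candidate table lacks ",
         paste(setdiff(object$feature_cols, names(newdata)), collapse = ", "))
  x <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  predict(object$booster, xgboost::xgb.DMatrix(x))
}

#' Score a trained classifier against the truth set
#'
#' Predictions on the test candidates are thresholded (default 0.5) and the
#' confusion is computed against truth membership of the test keys — never
#' against the training labels. Truth variants absent from the candidate
#' union are out of reach of any model over these candidates and are not
#' counted (the candidate-recall ceiling).
#'
#' @param model A `variant_classifier`.
#' @param test Test candidates (non-empty).
#' @param truth Truth `CallSet`.
#' @param threshold Decision threshold on the predicted probability.
#' @return A `MetricTriple`, with the `ConfusionSummary` in
#'   `attr(, "confusion")`.
#' @export
evaluate_model <- function(model, test, truth, threshold = 0.5) {
  stopifnot(inherits(model, "variant_classifier"), inherits(truth, "CallSet"))
  if (nrow(test) == 0L) stop("empty test set")
  prob <- predict(model, test)
  pos <- prob >= threshold
  keys <- paste(test$chrom, test$pos, test$ref, test$alt, sep = ":")
  in_truth <- keys %in% variant_keys(truth)
  cf <- confusion_summary(tp = sum(pos & in_truth),
                          fp = sum(pos & !in_truth),
                          fn = sum(!pos & in_truth))
  out <- metrics(cf)
  attr(out, "confusion") <- cf
  out
}

#' Consensus-label vs truth-label training experiment
#'
#' The package's second experiment: train the variant classifier once per
#' consensus threshold `m` — using the within-center (or all-centers)
#' consensus of the labeling replicates as training labels — and once with
#' the truth labels, then score every model against the truth on held-out
#' chromosomes. Columns report both the quality of the labels themselves
#' (precision/recall of the label set vs truth on the training chromosomes)
#' and the resulting model's test metrics.
#'
#' @param bundle A `StudyBundle` from [simulate_study()] or [read_study()].
#' @param scheme `"within_center"` (label with one center's replicates) or
#'   `"all_centers"` (label with every replicate).
#' @param m_values Consensus thresholds to use as label sources.
#' @param seeds Integer vector; the experiment is repeated per seed
#'   (negative sampling and training are re-seeded) and all rows returned.
#' @param center Labeling center for `within_center` (default: first center
#'   with >= 3 replicates).
#' @param feature_mapper Mapper whose caller call sets provide features.
#' @param feature_replicate Replicate providing the features (default 1).
#' @param label_caller Caller whose replicate consensus provides labels.
#' @param train_chroms Training chromosomes (default: first five in
#'   karyotype order among the bundle's chromosomes).
#' @param negatives_per_positive Passed to [build_candidates()].
#' @param nrounds,params Passed to [train_classifier()].
#' @return Data frame, one row per (label source, seed): `label_source`,
#'   `m` (NA for the truth rows), `seed`, `label_precision`, `label_recall`,
#'   `test_precision`, `test_recall`, `test_f1`.
#' @export
label_quality_experiment <- function(bundle,
                                     scheme = c("within_center", "all_centers"),
                                     m_values = NULL, seeds = 1L,
                                     center = NULL,
                                     feature_mapper = NULL,
                                     feature_replicate = 1L,
                                     label_caller = NULL,
                                     train_chroms = NULL,
                                     negatives_per_positive = 1,
                                     nrounds = 60L, params = list()) {
  stopifnot(inherits(bundle, "StudyBundle"))
  scheme <- match.arg(scheme)
  man <- bundle$manifest
  feature_mapper <- feature_mapper %||% man$mapper[1L]
  label_caller <- label_caller %||% man$caller[1L]
  if (is.null(center)) {
    tab <- table(unique(man[, c("center", "replicate")])$center)
    ok <- names(tab)[tab >= 3L]
    if (length(ok) == 0L) stop("no center with >= 3 replicates for labeling")
    center <- ok[1L]
  }
  label_names <- switch(scheme,
    within_center = man$name[man$center == center & man$mapper == feature_mapper &
                               man$caller == label_caller],
    all_centers = man$name[man$mapper == feature_mapper & man$caller == label_caller])
  labeling <- bundle$callsets[label_names]
  if (length(labeling) < 3L)
    stop("need >= 3 labeling replicates; found ", length(labeling))
  if (is.null(m_values)) m_values <- seq_len(length(labeling))
  if (any(m_values < 1L | m_values > length(labeling)))
    stop("m_values must lie in 1..", length(labeling))

  feat_names <- man$name[man$center == center &
                           man$replicate == feature_replicate &
                           man$mapper == feature_mapper]
  feature_callsets <- bundle$callsets[feat_names]
  names(feature_callsets) <- man$caller[match(feat_names, man$name)]
  if (length(feature_callsets) == 0L) stop("no feature call sets found")

  chroms <- unique(c(bundle$truth$calls$chrom,
                     unlist(lapply(feature_callsets, function(cs) cs$calls$chrom))))
  chroms <- chroms[order(chrom_rank(chroms))]
  train_chroms <- train_chroms %||% chroms[seq_len(min(5L, length(chroms) - 1L))]

  label_sets <- lapply(m_values, function(m)
    consensus(labeling, m, label = sprintf("consensus_m%d", m)))
  names(label_sets) <- sprintf("consensus_m%d", m_values)
  label_sets$truth <- bundle$truth
  src_m <- c(m_values, NA_integer_)

  rows <- list()
  for (seed in seeds) {
    candidates <- build_candidates(feature_callsets,
                                   negatives_per_positive = negatives_per_positive,
                                   regions = bundle$regions, seed = seed)
    for (j in seq_along(label_sets)) {
      tag <- names(label_sets)[j]
      labeled <- assign_labels(candidates, label_sets[[j]], tag)
      sp <- split_by_chromosome(labeled, train_chroms)
      ## label quality on the training side, scored against truth
      tr_keys <- paste(sp$train$chrom, sp$train$pos, sp$train$ref,
                       sp$train$alt, sep = ":")
      tr_truth <- tr_keys %in% variant_keys(bundle$truth)
      lab_cf <- confusion_summary(sum(sp$train$label == 1L & tr_truth),
                                  sum(sp$train$label == 1L & !tr_truth),
                                  sum(sp$train$label == 0L & tr_truth))
      lab_mt <- metrics(lab_cf)
      model <- train_classifier(sp$train, params = params,
                                nrounds = nrounds, seed = seed)
      mt <- evaluate_model(model, sp$test, bundle$truth)
      rows[[length(rows) + 1L]] <- data.frame(
        label_source = tag, m = src_m[j], seed = seed,
        label_precision = lab_mt$precision, label_recall = lab_mt$recall,
        test_precision = mt$precision, test_recall = mt$recall,
        test_f1 = mt$f1, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
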