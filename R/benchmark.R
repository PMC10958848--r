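#' Confusion counts of a call set against a truth set
#'
#' Classifies every called key as a true positive (also in `truth`) or false
#' positive, and every truth key missing from `calls` as a false negative.
#' Matching is exact on the `(chrom, pos, ref, alt)` key. Both inputs are
#' expected to have been restricted to the same evaluable regions and
#' SNV-selected upstream; `expected_truth_size` lets callers assert the
#' benchmark size (e.g. 1159 high-confidence exome SNVs) and warns on
#' mismatch.
#'
#' @param calls,truth `CallSet` objects.
#' @param expected_truth_size Optional declared truth size; a differing
#'   `length(truth)` triggers a warning.
#' @return A list of class `ConfusionSummary` with integer elements `tp`,
#'   `fp`, `fn`.
#' @examples
#' truth <- call_set("chr1", c(2L, 3L, 5L), "A", "T")
#' calls <- call_set("chr1", c(2L, 4L), "A", "T")
#' confusion(calls, truth)  # tp 1, fp 1, fn 2
#' @export
confusion <- function(calls, truth, expected_truth_size = NULL) {
  stopifnot(inherits(calls, "CallSet"), inherits(truth, "CallSet"))
  if (!is.null(expected_truth_size) && length(truth) != expected_truth_size)
    warning("truth set has ", length(truth), " keys; expected ",
            expected_truth_size)
  ck <- variant_keys(calls)
  tk <- variant_keys(truth)
  tp <- sum(ck %in% tk)
  confusion_summary(tp = tp, fp = length(ck) - tp, fn = sum(!(tk %in% ck)))
}

#' @rdname confusion
#' @param tp,fp,fn Non-negative integer counts.
#' @export
confusion_summary <- function(tp, fp, fn) {
  counts <- c(tp = tp, fp = fp, fn = fn)
  if (anyNA(counts) || any(counts < 0))
    stop("confusion counts must be non-negative")
  structure(as.list(as.integer(counts)) |> setNames(c("tp", "fp", "fn")),
            class = "ConfusionSummary")
}

#' @export
print.ConfusionSummary <- function(x, ...) {
  cat(sprintf("ConfusionSummary: TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, and F1 their harmonic
#' mean, `2*P*R/(P+R)` — algebraically `2*TP/(2*TP+FP+FN)`. Degenerate
#' ratios (0/0) are reported as 0 with the corresponding `*_defined` flag set
#' to `FALSE`; F1 is 0 whenever `precision + recall = 0`.
#'
#' @param x A `ConfusionSummary` (or anything with `tp`, `fp`, `fn`).
#' @return A list of class `MetricTriple`: `precision`, `recall`, `f1`
#'   (unrounded), plus logical `precision_defined`, `recall_defined`.
#' @examples
#' metrics(confusion_summary(900, 2, 259))  # precision .998, recall .777, F1 .873
#' @export
metrics <- function(x) {
  tp <- x$tp; fp <- x$fp; fn <- x$fn
  if (any(c(tp, fp, fn) < 0)) stop("negative confusion counts")
  p_def <- (tp + fp) > 0
  r_def <- (tp + fn) > 0
  precision <- if (p_def) tp / (tp + fp) else 0
  recall <- if (r_def) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1,
                 precision_defined = p_def, recall_defined = r_def),
            class = "MetricTriple")
}

#' @export
print.MetricTriple <- function(x, ...) {
  cat(sprintf("MetricTriple: precision=%.3f%s recall=%.3f%s f1=%.3f\n",
              round(x$precision, 3), if (x$precision_defined) "" else "*",
              round(x$recall, 3), if (x$recall_defined) "" else "*",
              round(x$f1, 3)))
  if (!x$precision_defined || !x$recall_defined)
    cat("  (* degenerate 0/0 ratio reported as 0)\n")
  invisible(x)
}

#' Consensus m-sweep evaluation table
#'
#' For `m = 1..n` computes the m-of-n consensus of the call sets, scores it
#' against the truth set, and tabulates counts and metrics. Because the
#' consensus sets are nested (anti-monotone in `m`), TP is non-increasing
#' and FN non-decreasing down the table. The best-F1 row is flagged.
#'
#' @inheritParams detection_counts
#' @param truth Truth `CallSet` (already region-restricted and SNV-selected).
#' @param expected_truth_size Passed to [confusion()].
#' @return Data frame with columns `m`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `best` (logical).
#' @export
sweep_m <- function(callsets, truth, allow_mixed = FALSE,
                    expected_truth_size = NULL) {
  check_vote_input(callsets, allow_mixed)
  n <- length(callsets)
  counts <- detection_counts(callsets, allow_mixed = TRUE)
  tk <- variant_keys(truth)
  if (!is.null(expected_truth_size) && length(tk) != expected_truth_size)
    warning("truth set has ", length(tk), " keys; expected ", expected_truth_size)
  rows <- lapply(seq_len(n), function(m) {
    keys <- names(counts)[counts >= m]
    tp <- sum(keys %in% tk)
    cf <- confusion_summary(tp, length(keys) - tp, sum(!(tk %in% keys)))
    mt <- metrics(cf)
    data.frame(m = m, tp = cf$tp, fp = cf$fp, fn = cf$fn,
               precision = mt$precision, recall = mt$recall, f1 = mt$f1)
  })
  out <- do.call(rbind, rows)
  out$best <- seq_len(n) == which.max(out$f1)
  out
}

#' Render sweep results as fixed-format TSV report files
#'
#' Writes one TSV per grouping scheme with deterministic column order
#' (`group, m, TP, FP, FN, Precision, Recall, F1, best`) and metrics rounded
#' half-even to 3 decimals. An empty result list yields a header-only file.
#'
#' @param results Named list: scheme name -> named list of sweep tables
#'   (as returned by [sweep_m()]), one per group.
#' @param dir Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
report_tables <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (scheme in names(results)) {
    sweeps <- results[[scheme]]
    rows <- lapply(names(sweeps), function(g) {
      sw <- sweeps[[g]]
      data.frame(group = g, m = sw$m, TP = sw$tp, FP = sw$fp, FN = sw$fn,
                 Precision = format_metric(sw$precision),
                 Recall = format_metric(sw$recall),
                 F1 = format_metric(sw$f1),
                 best = sw$best, stringsAsFactors = FALSE)
    })
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(group = character(0), m = integer(0), TP = integer(0),
                 FP = integer(0), FN = integer(0), Precision = character(0),
                 Recall = character(0), F1 = character(0), best = logical(0))
    if (nrow(tab)) tab <- tab[order(tab$group, tab$m), , drop = FALSE]
    path <- file.path(dir, paste0(scheme, "_sweep.tsv"))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

## Half-even rounding to 3 decimals, fixed width (round() is IEC 60559
## round-half-to-even; sprintf alone re-rounds from the binary value).
format_metric <- function(x) sprintf("%.3f", round(x, 3))

#' Published FD within-center consensus benchmark counts
#'
#' Reference confusion counts and rounded metrics for the within-center
#' consensus sweep of the FD center's three biological replicates in the
#' SEQC2 somatic exome benchmark (two mappers by three callers, truth set of
#' 1159 high-confidence SNVs). Every row satisfies `TP + FN = 1159`, and
#' feeding the counts through [metrics()] reproduces the published
#' precision/recall/F1 at three decimals — the package's golden check.
#'
#' @return Data frame with columns `center`, `pipeline`, `m`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f1` (the published 3-decimal values).
#' @examples
#' ref <- fd_reference_counts()
#' all(ref$tp + ref$fn == 1159)
#' @export
fd_reference_counts <- function() {
  tab <- data.frame(
    center = "FD",
    pipeline = rep(c("bwa_mutect", "bowtie_mutect", "bwa_strelka",
                     "bowtie_strelka", "bwa_ss", "bowtie_ss"), each = 3L),
    m = rep(1:3, times = 6L),
    tp = c(1003L, 900L, 749L, 988L, 875L, 727L, 1037L, 927L, 785L,
           937L, 792L, 643L, 948L, 816L, 677L, 918L, 793L, 661L),
    fp = c(525L, 2L, 0L, 565L, 2L, 0L, 2808L, 20L, 3L,
           539L, 5L, 3L, 1013L, 96L, 9L, 1009L, 97L, 15L),
    fn = c(156L, 259L, 410L, 171L, 284L, 432L, 122L, 232L, 374L,
           222L, 367L, 516L, 211L, 343L, 482L, 241L, 366L, 498L),
    precision = c(0.656, 0.998, 1.000, 0.636, 0.998, 1.000, 0.270, 0.979, 0.996,
                  0.635, 0.994, 0.995, 0.483, 0.895, 0.987, 0.476, 0.891, 0.978),
    recall = c(0.865, 0.777, 0.646, 0.852, 0.755, 0.627, 0.895, 0.800, 0.677,
               0.808, 0.683, 0.555, 0.818, 0.704, 0.584, 0.792, 0.684, 0.570),
    f1 = c(0.747, 0.873, 0.785, 0.729, 0.860, 0.771, 0.414, 0.880, 0.806,
           0.711, 0.810, 0.712, 0.608, 0.788, 0.734, 0.595, 0.774, 0.720),
    stringsAsFactors = FALSE
  )
  tab
}
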