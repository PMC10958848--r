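#' Detection-count table over replicate call sets
#'
#' For every variant key in the union of the given call sets, counts the
#' number of call sets that contain it — the quantity `m` of the m-of-n
#' consensus. All call sets must come from the same mapper-by-caller
#' pipeline: a consensus vote is only meaningful across replicates of one
#' pipeline, never across different callers (set `allow_mixed = TRUE` to
#' override for exploratory use).
#'
#' @param callsets A non-empty list of `CallSet` objects.
#' @param allow_mixed Permit call sets from different pipelines?
#' @return Named integer vector: key -> detection count (each in
#'   `1..length(callsets)`), in first-appearance order.
#' @examples
#' a <- call_set("chr1", c(1L, 2L), "A", "T", mapper = "bwa", caller = "mutect")
#' b <- call_set("chr1", c(2L, 3L), "A", "T", mapper = "bwa", caller = "mutect")
#' detection_counts(list(a, b))
#' @export
detection_counts <- function(callsets, allow_mixed = FALSE) {
  check_vote_input(callsets, allow_mixed)
  key_list <- lapply(callsets, variant_keys)
  all_keys <- unlist(key_list, use.names = FALSE)
  uniq <- unique(all_keys)
  counts <- integer(length(uniq))
  names(counts) <- uniq
  for (k in key_list) {
    i <- match(k, uniq)
    counts[i] <- counts[i] + 1L
  }
  counts
}

check_vote_input <- function(callsets, allow_mixed) {
  if (!is.list(callsets) || length(callsets) == 0L ||
      !all(vapply(callsets, inherits, logical(1), "CallSet")))
    stop("callsets must be a non-empty list of CallSet objects")
  if (!allow_mixed) {
    pipes <- unique(vapply(callsets, pipeline_of, character(1)))
    pipes <- pipes[pipes != "NA_NA"]
    if (length(pipes) > 1L)
      stop("call sets come from different pipelines (", paste(pipes, collapse = ", "),
           "); consensus votes are per-pipeline. Use allow_mixed = TRUE to override.")
  }
  invisible(TRUE)
}

#' Detection matrix (candidates x call sets)
#'
#' The boolean incidence structure underlying consensus voting: one row per
#' candidate key (the union of all inputs), one column per call set.
#'
#' @inheritParams detection_counts
#' @return A list of class `DetectionMatrix` with elements `candidates`
#'   (character keys), `incidence` (logical matrix), and `sources` (list of
#'   provenance lists).
#' @export
detection_matrix <- function(callsets, allow_mixed = FALSE) {
  check_vote_input(callsets, allow_mixed)
  key_list <- lapply(callsets, variant_keys)
  uniq <- unique(unlist(key_list, use.names = FALSE))
  inc <- matrix(FALSE, nrow = length(uniq), ncol = length(callsets))
  for (j in seq_along(key_list)) inc[, j] <- uniq %in% key_list[[j]]
  colnames(inc) <- vapply(seq_along(callsets), function(i) {
    pv <- callsets[[i]]$provenance
    if (!is.na(pv$center %||% NA))
      sprintf("%s_%s_%s_%s", pv$center, pv$replicate, pv$mapper, pv$caller)
    else sprintf("callset_%d", i)
  }, character(1))
  structure(list(candidates = uniq, incidence = inc,
                 sources = lapply(callsets, function(cs) cs$provenance)),
            class = "DetectionMatrix")
}

#' @export
print.DetectionMatrix <- function(x, ...) {
  cat(sprintf("DetectionMatrix: %d candidate(s) x %d call set(s)\n",
              length(x$candidates), ncol(x$incidence)))
  invisible(x)
}

#' m-of-n consensus call set
#'
#' Returns the variants detected in at least `m` of the given replicate call
#' sets (threshold inclusive, the "m >= k" rule). `consensus(s, 1)` is the
#' union and `consensus(s, length(s))` the intersection. Attributes of a
#' consensus key are taken from the first contributing call set in list
#' order; provenance records the group label and `m`.
#'
#' @inheritParams detection_counts
#' @param m Minimum number of detections, `1 <= m <= length(callsets)`.
#' @param label Optional group label recorded in the result's provenance.
#' @return A `CallSet` of the multiply-detected variants.
#' @examples
#' a <- call_set("chr1", 1:2, "A", "T", mapper = "bwa", caller = "mutect")
#' b <- call_set("chr1", 2:3, "A", "T", mapper = "bwa", caller = "mutect")
#' c <- call_set("chr1", c(2L, 4L), "A", "T", mapper = "bwa", caller = "mutect")
#' length(consensus(list(a, b, c), m = 2))  # only chr1:2 seen twice+
#' @export
consensus <- function(callsets, m, allow_mixed = FALSE, label = NULL) {
  check_vote_input(callsets, allow_mixed)
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L || m > length(callsets))
    stop("m must be an integer in 1..", length(callsets))
  counts <- detection_counts(callsets, allow_mixed = TRUE)
  keep_keys <- names(counts)[counts >= m]
  calls <- bind_first_wins(callsets)
  calls <- calls[make_keys(calls) %in% keep_keys, , drop = FALSE]
  rownames(calls) <- NULL
  out <- callset_from_calls(calls, provenance = list(
    mapper = callsets[[1L]]$provenance$mapper,
    caller = callsets[[1L]]$provenance$caller,
    label = label %||% sprintf("consensus_m%d_of_%d", m, length(callsets)),
    m = m))
  out
}

#' All pairwise intersections of replicate call sets
#'
#' One intersection per unordered pair of call sets, `choose(n, 2)` results —
#' the "two replicates only" comparison for a triple-replicate group.
#'
#' @inheritParams detection_counts
#' @return Named list of `CallSet`s, names like `"1&2"` (list positions).
#' @export
pairwise_intersections <- function(callsets, allow_mixed = FALSE) {
  check_vote_input(callsets, allow_mixed)
  if (length(callsets) < 2L) stop("need at least 2 call sets for pairwise intersections")
  pairs <- utils::combn(length(callsets), 2L)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    consensus(callsets[c(i1, i2)], m = 2L, allow_mixed = TRUE,
              label = sprintf("pair_%d&%d", i1, i2))
  })
  names(out) <- apply(pairs, 2L, paste, collapse = "&")
  out
}

#' Build replicate voting groups from a manifest
#'
#' Turns a replicate manifest (one row per call set: `center`, `replicate`,
#' `mapper`, `caller`, plus any bookkeeping columns) into voting groups under
#' one of the three consensus schemes:
#'
#' * `within_center` — one group per (center, pipeline), voting across that
#'   center's biological replicates. Centers with fewer than `min_replicates`
#'   replicates are excluded with a message (a single replicate cannot vote).
#' * `cross_center` — one group per (replicate number, pipeline), voting
#'   across centers that share the replicate number.
#' * `all_centers` — one group per pipeline, voting across every
#'   center-by-replicate cell (e.g. 9 members for 3 centers x 3 replicates).
#'
#' @param manifest Data frame with columns `center`, `replicate`, `mapper`,
#'   `caller` (extra columns such as `vcf_path` pass through untouched).
#' @param scheme One of `"within_center"`, `"cross_center"`, `"all_centers"`.
#' @param min_replicates Minimum group size for a group to be emitted.
#' @return A list of class `GroupingScheme`: `name`, and `groups` — a named
#'   list of integer vectors of manifest row indices.
#' @export
build_groups <- function(manifest,
                         scheme = c("within_center", "cross_center", "all_centers"),
                         min_replicates = 2L) {
  scheme <- match.arg(scheme)
  need <- c("center", "replicate", "mapper", "caller")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  pipe <- paste(manifest$mapper, manifest$caller, sep = "_")
  key <- switch(scheme,
                within_center = paste(manifest$center, pipe, sep = "."),
                cross_center = paste0("rep", manifest$replicate, ".", pipe),
                all_centers = pipe)
  groups <- split(seq_len(nrow(manifest)), key)
  small <- lengths(groups) < max(2L, min_replicates)
  if (any(small)) {
    dropped <- names(groups)[small]
    message("excluding ", sum(small), " group(s) with fewer than ",
            max(2L, min_replicates), " members: ",
            paste(dropped, collapse = ", "))
    groups <- groups[!small]
  }
  if (scheme == "cross_center") {
    multi <- vapply(groups, function(i) length(unique(manifest$center[i])) > 1L,
                    logical(1))
    if (!all(multi)) {
      message("excluding ", sum(!multi), " cross-center group(s) spanning a single center")
      groups <- groups[multi]
    }
    if (length(groups) == 0L)
      stop("cross_center scheme produced no multi-center group; ",
           "is there more than one center in the manifest?")
  }
  if (length(groups) == 0L) stop("no voting groups could be formed under scheme ", scheme)
  structure(list(name = scheme, groups = groups, manifest = manifest),
            class = "GroupingScheme")
}

#' @export
print.GroupingScheme <- function(x, ...) {
  cat(sprintf("GroupingScheme '%s': %d group(s) of sizes %s\n", x$name,
              length(x$groups),
              paste(sort(unique(lengths(x$groups))), collapse = "/")))
  invisible(x)
}

#' Write a detection-count table as TSV
#'
#' One row per candidate key (chrom, pos, ref, alt, count, then one 0/1
#' column per source call set).
#'
#' @param dm A `DetectionMatrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detection_table <- function(dm, path) {
  stopifnot(inherits(dm, "DetectionMatrix"))
  parts <- strsplit(dm$candidates, ":", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    ref = vapply(parts, `[`, character(1), 3L),
    alt = vapply(parts, `[`, character(1), 4L),
    count = as.integer(rowSums(dm$incidence)),
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(dm$incidence + 0L))
  df <- df[order(chrom_rank(df$chrom), df$pos), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
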