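#' @importFrom stats rbinom rgamma rnorm rpois runif rbeta plogis pbeta setNames
#' @importFrom utils read.table write.table combn
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Construct a somatic call set
#'
#' A `CallSet` is one replicate-and-pipeline's deduplicated set of variant
#' keys — the identity `(chrom, pos, ref, alt)` used for all set algebra —
#' together with optional per-variant call attributes (quality, filter
#' status, variant allele frequency, tumor/normal depth) and provenance
#' (which center, biological replicate, mapper and caller produced it).
#'
#' Positions follow the VCF convention (1-based). Alleles are uppercased
#' nucleotide strings over `A,C,G,T,N`; `ref` must differ from `alt`.
#' Duplicate keys collapse to a single entry, keeping the first occurrence's
#' attributes.
#'
#' @param chrom Character vector of chromosome labels.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Character vectors of reference/alternate alleles.
#' @param qual Numeric caller quality scores (optional, `NA` allowed).
#' @param filter Character filter status labels (default `"."`).
#' @param vaf Numeric variant allele fractions in `[0, 1]` (optional).
#' @param tumor_depth,normal_depth Non-negative integer read depths (optional).
#' @param center,replicate,mapper,caller Provenance fields.
#' @param label Optional free-form provenance label (used for consensus sets).
#' @param m Optional consensus threshold recorded on consensus outputs.
#' @return An object of class `CallSet`.
#' @examples
#' cs <- call_set(c("chr1", "chr2"), c(100L, 5L), c("A", "C"), c("T", "G"),
#'                center = "FD", replicate = 1, mapper = "bwa", caller = "mutect")
#' length(cs)
#' variant_keys(cs)
#' @export
call_set <- function(chrom, pos, ref, alt,
                     qual = NA_real_, filter = ".", vaf = NA_real_,
                     tumor_depth = NA_integer_, normal_depth = NA_integer_,
                     center = NA_character_, replicate = NA_integer_,
                     mapper = NA_character_, caller = NA_character_,
                     label = NULL, m = NULL) {
  n <- length(chrom)
  calls <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    qual = rep_len(as.numeric(qual), n),
    filter = rep_len(as.character(filter), n),
    vaf = rep_len(as.numeric(vaf), n),
    tumor_depth = rep_len(as.integer(tumor_depth), n),
    normal_depth = rep_len(as.integer(normal_depth), n),
    stringsAsFactors = FALSE
  )
  validate_calls(calls)
  keys <- make_keys(calls)
  calls <- calls[!duplicated(keys), , drop = FALSE]
  rownames(calls) <- NULL
  structure(
    list(calls = calls,
         provenance = list(center = center,
                           replicate = if (is.null(replicate)) NA_integer_ else as.integer(replicate),
                           mapper = mapper, caller = caller,
                           label = label, m = m)),
    class = "CallSet"
  )
}

validate_calls <- function(calls) {
  if (nrow(calls) == 0L) return(invisible(TRUE))
  bad <- which(is.na(calls$pos) | calls$pos < 1L)
  if (length(bad)) stop("invalid position (must be integer >= 1) at record ", bad[1L])
  ok_allele <- function(x) {
    nzchar(x) & !is.na(x) &
      vapply(strsplit(x, ""), function(b) all(b %in% VALID_BASES), logical(1))
  }
  bad <- which(!ok_allele(calls$ref) | !ok_allele(calls$alt))
  if (length(bad)) stop("invalid allele (non-empty string over A,C,G,T,N required) at record ", bad[1L])
  bad <- which(calls$ref == calls$alt)
  if (length(bad)) stop("ref equals alt at record ", bad[1L])
  bad <- which(!is.na(calls$vaf) & (calls$vaf < 0 | calls$vaf > 1))
  if (length(bad)) stop("vaf outside [0, 1] at record ", bad[1L])
  bad <- which((!is.na(calls$tumor_depth) & calls$tumor_depth < 0L) |
                 (!is.na(calls$normal_depth) & calls$normal_depth < 0L))
  if (length(bad)) stop("negative read depth at record ", bad[1L])
  invisible(TRUE)
}

make_keys <- function(calls) {
  if (nrow(calls) == 0L) return(character(0))
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Variant keys of a call set
#'
#' Returns the canonical `"chrom:pos:ref:alt"` key strings; two variants are
#' the same call iff their keys are equal.
#'
#' @param cs A `CallSet`.
#' @return Character vector of keys, one per variant.
#' @export
variant_keys <- function(cs) {
  stopifnot(inherits(cs, "CallSet"))
  make_keys(cs$calls)
}

#' @export
length.CallSet <- function(x) nrow(x$calls)

#' @export
print.CallSet <- function(x, ...) {
  pv <- x$provenance
  src <- if (!is.na(pv$center %||% NA)) {
    sprintf("%s rep %s, %s_%s", pv$center, pv$replicate, pv$mapper, pv$caller)
  } else if (!is.null(pv$label)) pv$label else "unspecified source"
  cat(sprintf("CallSet: %d variant(s) [%s]\n", nrow(x$calls), src))
  if (nrow(x$calls)) print(utils::head(x$calls, 6L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
as.data.frame.CallSet <- function(x, ...) x$calls

## Subset a CallSet by row index, preserving attributes and provenance.
callset_slice <- function(cs, idx) {
  out <- cs
  out$calls <- cs$calls[idx, , drop = FALSE]
  rownames(out$calls) <- NULL
  out
}

## Pipeline label (mapper x caller) of a CallSet.
pipeline_of <- function(cs) {
  paste(cs$provenance$mapper, cs$provenance$caller, sep = "_")
}

## Bind call rows from several CallSets, first occurrence of a key wins.
bind_first_wins <- function(callsets) {
  calls <- do.call(rbind, lapply(callsets, function(cs) cs$calls))
  if (is.null(calls)) calls <- empty_calls_df()
  calls <- calls[!duplicated(make_keys(calls)), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

empty_calls_df <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), qual = numeric(0), filter = character(0),
             vaf = numeric(0), tumor_depth = integer(0),
             normal_depth = integer(0), stringsAsFactors = FALSE)
}

## CallSet from a calls data.frame (already validated shape).
callset_from_calls <- function(calls, provenance = list()) {
  cs <- call_set(calls$chrom, calls$pos, calls$ref, calls$alt,
                 qual = calls$qual, filter = calls$filter, vaf = calls$vaf,
                 tumor_depth = calls$tumor_depth,
                 normal_depth = calls$normal_depth)
  cs$provenance <- utils::modifyList(cs$provenance, provenance)
  cs
}

#' Construct an evaluable-region set
#'
#' A `RegionSet` holds the genomic intervals (BED convention: 0-based,
#' half-open) inside which calls and truth variants are comparable, e.g. the
#' intersection of an exome target BED with a high-confidence region BED.
#' Overlapping or book-ended intervals on the same chromosome are merged on
#' construction.
#'
#' @param chrom Character vector of chromosome labels.
#' @param start,end Integer interval bounds, 0-based half-open; `start < end`.
#' @return An object of class `RegionSet`.
#' @examples
#' rs <- region_set(c("chr1", "chr1"), c(0L, 50L), c(100L, 150L))
#' as.data.frame(rs)  # merged to chr1:[0,150)
#' @export
region_set <- function(chrom = character(0), start = integer(0), end = integer(0)) {
  if (any(start != floor(start)) || any(end != floor(end)))
    stop("region coordinates must be integers")
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L)) stop("region start must be >= 0")
  if (any(start >= end)) stop("empty or inverted region (start >= end)")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = start + 1L, end = end)  # to 1-based closed
  )
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  structure(list(gr = gr), class = "RegionSet")
}

#' @export
length.RegionSet <- function(x) length(x$gr)

#' @export
as.data.frame.RegionSet <- function(x, ...) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(x$gr)),
             start = GenomicRanges::start(x$gr) - 1L,   # back to BED half-open
             end = GenomicRanges::end(x$gr),
             stringsAsFactors = FALSE)
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet: %d merged interval(s), %s bp total\n",
              length(x$gr), format(sum(GenomicRanges::width(x$gr)), big.mark = ",")))
  invisible(x)
}

## Total covered length in bp.
region_total_width <- function(rs) sum(GenomicRanges::width(rs$gr))
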