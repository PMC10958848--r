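#' Read a somatic VCF into a call set
#'
#' Parses a VCF 4.x file (plain or gzip/bgzip compressed) into a [call_set()].
#' One variant key is produced per record and alternate allele: multi-allelic
#' records are split into one key per ALT, since the consensus set algebra
#' needs atomic keys. Records whose keys coincide collapse to one entry (the
#' first record's attributes are kept).
#'
#' When `pass_only = TRUE`, records whose FILTER is neither `PASS` nor `.`
#' are dropped. A missing FILTER (`.`) counts as passing because some somatic
#' callers (e.g. SomaticSniper) emit unfiltered records that carry no PASS
#' label and are used as-is.
#'
#' Per-call attributes are taken from QUAL, FILTER and, when present, the
#' INFO keys `VAF`, `TDP` (tumor depth) and `NDP` (normal depth) — the keys
#' written by [write_vcf()]. Provenance comes from the caller of this
#' function, not from the file.
#'
#' @param path Path to a VCF file.
#' @param pass_only Drop records whose FILTER is neither `PASS` nor `.`?
#' @param chrom_style One of `"preserve"` (default), `"add_chr"`,
#'   `"strip_chr"` — normalizes chromosome labels across VCF/BED dialects at
#'   read time.
#' @param center,replicate,mapper,caller Provenance attached to the result.
#' @return A `CallSet`.
#' @export
read_vcf <- function(path, pass_only = FALSE,
                     chrom_style = c("preserve", "add_chr", "strip_chr"),
                     center = NA_character_, replicate = NA_integer_,
                     mapper = NA_character_, caller = NA_character_) {
  chrom_style <- match.arg(chrom_style)
  if (!file.exists(path)) stop("cannot read VCF: no such file: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("cannot read VCF '", path, "': ",
                                           conditionMessage(e)))
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  n_meta <- length(vcf@meta)
  if (is.null(fix) || nrow(fix) == 0L) {
    return(call_set(character(0), integer(0), character(0), character(0),
                    center = center, replicate = replicate,
                    mapper = mapper, caller = caller))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)

  pos <- suppressWarnings(as.integer(fix$POS))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad)) {
    stop("malformed VCF record at line ", n_meta + 1L + bad[1L],
         " of ", path, ": invalid POS '", fix$POS[bad[1L]], "'")
  }

  filt <- fix$FILTER
  filt[is.na(filt)] <- "."
  if (pass_only) {
    keep <- filt == "PASS" | filt == "."
  } else {
    keep <- rep(TRUE, nrow(fix))
  }

  info <- fix$INFO
  vaf <- info_numeric(info, "VAF")
  tdp <- info_numeric(info, "TDP")
  ndp <- info_numeric(info, "NDP")
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  ## split multi-allelic ALT into one key per allele
  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  bad <- which(n_alt == 0L)
  if (length(bad)) {
    stop("malformed VCF record at line ", n_meta + 1L + bad[1L],
         " of ", path, ": missing ALT")
  }
  idx <- rep.int(seq_len(nrow(fix)), n_alt)
  chrom <- fix$CHROM[idx]
  chrom <- switch(chrom_style,
                  preserve = chrom,
                  add_chr = ifelse(startsWith(chrom, "chr"), chrom, paste0("chr", chrom)),
                  strip_chr = sub("^chr", "", chrom))
  keep_row <- keep[idx]

  cs <- tryCatch(
    call_set(chrom[keep_row], pos[idx][keep_row],
             fix$REF[idx][keep_row], unlist(alts)[keep_row],
             qual = qual[idx][keep_row], filter = filt[idx][keep_row],
             vaf = vaf[idx][keep_row],
             tumor_depth = as.integer(tdp[idx][keep_row]),
             normal_depth = as.integer(ndp[idx][keep_row]),
             center = center, replicate = replicate,
             mapper = mapper, caller = caller),
    error = function(e) {
      stop("malformed VCF record in ", path, " (after line ", n_meta + 1L,
           "): ", conditionMessage(e))
    })
  cs
}

## Extract a numeric INFO key (e.g. "VAF") from INFO strings; NA when absent.
info_numeric <- function(info, key) {
  out <- rep(NA_real_, length(info))
  if (is.null(info) || length(info) == 0L) return(out)
  safe <- ifelse(is.na(info), "", info)
  m <- regexpr(paste0("(^|;)", key, "=[^;]+"), safe)
  hit <- m > 0L
  if (any(hit)) {
    vals <- sub(paste0("^;?", key, "="), "", regmatches(safe, m))
    out[hit] <- suppressWarnings(as.numeric(vals))
  }
  out
}

#' Read a BED file of evaluable regions
#'
#' Reads a 3+ column BED (0-based, half-open) into a [region_set()];
#' overlapping intervals are merged and columns beyond the third are ignored.
#' `track`/`browser`/comment lines are skipped.
#'
#' @param path Path to a BED file.
#' @param chrom_style As in [read_vcf()].
#' @return A `RegionSet`.
#' @export
read_bed <- function(path, chrom_style = c("preserve", "add_chr", "strip_chr")) {
  chrom_style <- match.arg(chrom_style)
  if (!file.exists(path)) stop("cannot read BED: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  if (length(lines) == 0L) return(region_set())
  tab <- utils::read.table(text = lines, sep = "", header = FALSE,
                           colClasses = "character", fill = TRUE)
  if (ncol(tab) < 3L) stop("BED file must have at least 3 columns: ", path)
  start <- suppressWarnings(as.numeric(tab[[2L]]))
  end <- suppressWarnings(as.numeric(tab[[3L]]))
  if (anyNA(start) || anyNA(end) ||
      any(start != floor(start)) || any(end != floor(end)))
    stop("non-integer BED coordinates in ", path)
  chrom <- tab[[1L]]
  chrom <- switch(chrom_style,
                  preserve = chrom,
                  add_chr = ifelse(startsWith(chrom, "chr"), chrom, paste0("chr", chrom)),
                  strip_chr = sub("^chr", "", chrom))
  region_set(chrom, start, end)
}

#' Restrict a call set to evaluable regions
#'
#' Keeps exactly the variants whose position falls inside some interval of
#' `regions`. Positions are VCF 1-based; regions are BED 0-based half-open,
#' so a variant at `pos` is kept iff `pos - 1` lies in `[start, end)` of some
#' interval. Attributes and provenance are preserved. The operation is
#' idempotent and monotone in the region set.
#'
#' @param cs A `CallSet`.
#' @param regions A `RegionSet`.
#' @return The restricted `CallSet`.
#' @export
restrict <- function(cs, regions) {
  stopifnot(inherits(cs, "CallSet"), inherits(regions, "RegionSet"))
  if (length(cs) == 0L || length(regions) == 0L) return(callset_slice(cs, integer(0)))
  if (!any(unique(cs$calls$chrom) %in%
             as.character(GenomicRanges::seqnames(regions$gr)))) {
    warning("no chromosome labels shared between call set and regions; ",
            "check chrom_style ('chr' prefix) consistency")
    return(callset_slice(cs, integer(0)))
  }
  q <- GenomicRanges::GRanges(cs$calls$chrom,
                              IRanges::IRanges(cs$calls$pos, cs$calls$pos))
  hit <- IRanges::overlapsAny(q, regions$gr)
  callset_slice(cs, which(hit))
}

#' Keep only single-nucleotide variants
#'
#' Drops every key whose REF or ALT allele is longer than one base (indels,
#' MNVs), keeping attributes and provenance.
#'
#' @param cs A `CallSet`.
#' @return The SNV-only `CallSet`.
#' @export
select_snvs <- function(cs) {
  stopifnot(inherits(cs, "CallSet"))
  keep <- nchar(cs$calls$ref) == 1L & nchar(cs$calls$alt) == 1L
  callset_slice(cs, which(keep))
}

#' Write a call set as a minimal VCF 4.2
#'
#' Emits a sorted (chromosome, then position) VCF with the call attributes
#' in QUAL/FILTER and the INFO keys `VAF`, `TDP`, `NDP`. Reading the file
#' back with [read_vcf()] reproduces the call set's keys exactly.
#'
#' @param cs A `CallSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cs, path) {
  stopifnot(inherits(cs, "CallSet"))
  calls <- cs$calls
  ord <- order(chrom_rank(calls$chrom), calls$pos, calls$ref, calls$alt)
  calls <- calls[ord, , drop = FALSE]
  info <- vapply(seq_len(nrow(calls)), function(i) {
    parts <- character(0)
    if (!is.na(calls$vaf[i])) parts <- c(parts, sprintf("VAF=%.6g", calls$vaf[i]))
    if (!is.na(calls$tumor_depth[i])) parts <- c(parts, sprintf("TDP=%d", calls$tumor_depth[i]))
    if (!is.na(calls$normal_depth[i])) parts <- c(parts, sprintf("NDP=%d", calls$normal_depth[i]))
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=replicall",
    '##INFO=<ID=VAF,Number=1,Type=Float,Description="Variant allele fraction">',
    '##INFO=<ID=TDP,Number=1,Type=Integer,Description="Tumor read depth">',
    '##INFO=<ID=NDP,Number=1,Type=Integer,Description="Normal read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- if (nrow(calls)) {
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
          ifelse(is.na(calls$qual), ".", format(calls$qual, trim = TRUE, digits = 6)),
          ifelse(is.na(calls$filter) | calls$filter == "", ".", calls$filter),
          info, sep = "\t")
  } else character(0)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write VCF to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write a region set as BED
#'
#' @param rs A `RegionSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(rs, path) {
  stopifnot(inherits(rs, "RegionSet"))
  df <- as.data.frame(rs)
  df <- df[order(chrom_rank(df$chrom), df$start), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Karyotype-ish chromosome ordering: numeric chromosomes first (by value),
## then X, Y, M, then anything else alphabetically.
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(core))
  rank <- ifelse(!is.na(num), num,
                 ifelse(core == "X", 100L,
                        ifelse(core == "Y", 101L,
                               ifelse(core %in% c("M", "MT"), 102L, 200L))))
  ## stable tie-break for exotic labels
  rank + match(core, sort(unique(core))) / (length(unique(core)) + 1)
}
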