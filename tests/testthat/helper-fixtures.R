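# In-code fixtures shared across the suite: quick call-set builders, random
# generators, and a handwritten VCF emitter independent of write_vcf().

# CallSet at given positions on one chromosome, A>T throughout.
mk_cs <- function(pos, chrom = "chr1", mapper = "bwa", caller = "mutect",
                  center = NA_character_, replicate = NA_integer_, ...) {
  call_set(rep(chrom, length(pos)), as.integer(pos), "A", "T",
           mapper = mapper, caller = caller, center = center,
           replicate = replicate, ...)
}

# Random CallSet drawn from a universe of n_universe sites.
rand_cs <- function(n, n_universe = 500L, chrom = "chr1",
                    mapper = "bwa", caller = "mutect") {
  mk_cs(sample.int(n_universe, min(n, n_universe)), chrom = chrom,
        mapper = mapper, caller = caller)
}

# Write VCF lines by hand (bypasses write_vcf, for read_vcf unit tests).
raw_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                    extra_meta = character(0)) {
  writeLines(c("##fileformat=VCFv4.2", extra_meta,
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               records), path)
  path
}

# Tiny study config for fast simulation-backed tests; any study_config()
# argument can be overridden.
small_config <- function(n_truth = 120L, seed = 1L, ...) {
  defaults <- list(
    n_truth = n_truth,
    chroms = paste0("chr", 1:6),
    chrom_length = 4e5L, intervals_per_chrom = 40L, interval_width = 1200L,
    centers = list(A = center_profile(3L, 60, 6L, 0.8),
                   B = center_profile(3L, 90, 6L, 0.8)),
    mappers = c(bwa = 1.0),
    callers = list(mutect = caller_profile(0.45, -0.8, fp_private = 25,
                                           artifact_sites = 5L,
                                           artifact_incl = 0.7)),
    seed = seed)
  do.call(study_config, utils::modifyList(defaults, list(...)))
}

# Brute-force per-key membership counts (independent oracle).
oracle_counts <- function(callsets) {
  keys <- unique(unlist(lapply(callsets, variant_keys)))
  vapply(keys, function(k) {
    sum(vapply(callsets, function(cs) k %in% variant_keys(cs), logical(1)))
  }, integer(1))
}
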