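#' Caller profile for the study simulator
#'
#' Describes one somatic caller's behavior in the simulator: a logistic
#' sensitivity curve in expected alternate-read mass (`VAF x depth`), a
#' private false-positive rate, and a caller-shared systematic artifact pool
#' (sites re-called across centers by the same caller).
#'
#' Per-site detection probability for a truth variant is
#' `plogis(slope * mapper_mult * vaf * depth + intercept + u)`, where `u` is
#' a center-by-site library effect (see [study_config()]). `slope = 0` gives
#' a constant sensitivity `plogis(intercept)` — use `intercept = Inf` for a
#' perfect caller.
#'
#' @param slope,intercept Logistic sensitivity parameters (logit scale).
#' @param fp_private Expected number of private false-positive sites per
#'   call set (Poisson mean).
#' @param artifact_sites Number of caller-shared artifact sites in the study.
#' @param artifact_incl Per-call-set inclusion probability of each artifact
#'   site.
#' @param filter_label FILTER string stamped on this caller's records
#'   (`"PASS"` for filtered callers, `"."` for unfiltered ones).
#' @return A list of class `CallerProfile`.
#' @export
caller_profile <- function(slope, intercept, fp_private = 0,
                           artifact_sites = 0L, artifact_incl = 0,
                           filter_label = "PASS") {
  stopifnot(fp_private >= 0, artifact_sites >= 0,
            artifact_incl >= 0, artifact_incl <= 1)
  structure(list(slope = slope, intercept = intercept,
                 fp_private = fp_private,
                 artifact_sites = as.integer(artifact_sites),
                 artifact_incl = artifact_incl,
                 filter_label = filter_label),
            class = "CallerProfile")
}

#' Center profile for the study simulator
#'
#' One sequencing center: how many biological replicates it contributed, the
#' mean tumor coverage of each replicate, and the center-shared artifact
#' pool (sites re-called across that center's replicates and pipelines,
#' emulating library-preparation artifacts).
#'
#' @param n_replicates Number of biological replicates.
#' @param coverage_mean Numeric vector (recycled to `n_replicates`) of mean
#'   tumor depths.
#' @param artifact_sites Number of center-shared artifact sites.
#' @param artifact_incl Per-call-set inclusion probability of each site.
#' @return A list of class `CenterProfile`.
#' @export
center_profile <- function(n_replicates = 3L, coverage_mean = 80,
                           artifact_sites = 0L, artifact_incl = 0) {
  stopifnot(n_replicates >= 1L, all(coverage_mean > 0),
            artifact_sites >= 0, artifact_incl >= 0, artifact_incl <= 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 coverage_mean = rep_len(coverage_mean, n_replicates),
                 artifact_sites = as.integer(artifact_sites),
                 artifact_incl = artifact_incl),
            class = "CenterProfile")
}

#' Configuration of a simulated multi-center replicate study
#'
#' The default configuration emulates the shape of a multi-center somatic
#' exome benchmark: a truth set of 1159 SNVs with a clonal/subclonal VAF
#' mixture, three triple-replicate centers (one low-coverage, ~40x; one
#' high/very-high, 100-250x; one moderate, 80x), two mappers by three
#' callers (six pipelines), private-FP-dominated caller noise, and small
#' center-shared and caller-shared artifact pools that give within-center
#' and cross-center consensus their distinct error structure.
#'
#' @param n_truth Number of truth SNVs (default 1159).
#' @param chroms Chromosome labels of the simulated genome.
#' @param chrom_length Length of each chromosome in bp.
#' @param intervals_per_chrom,interval_width Evaluable-region layout: evenly
#'   spaced intervals per chromosome (an exome-like target).
#' @param vaf_mixture Beta-mixture spec for truth VAFs: list with `weights`,
#'   `shape1`, `shape2` (defaults: clonal peak near 0.5, a 0.25 peak, and a
#'   low-frequency subclonal tail).
#' @param centers Named list of [center_profile()]s.
#' @param mappers Named numeric vector of mapper sensitivity multipliers.
#' @param callers Named list of [caller_profile()]s.
#' @param depth_shape Gamma shape of per-site depth variation.
#' @param center_site_sd SD (logit scale) of the center-by-site library
#'   effect shared across a center's replicates; 0 disables it.
#' @param difficult_fraction Fraction of truth sites in hard-to-capture
#'   context (low mappability / poor capture efficiency); shared by all
#'   centers.
#' @param capture_prob Probability that a given center's library rescues a
#'   difficult site (capture is center-level: shared across that center's
#'   replicates; an uncaptured site yields no alternate reads and cannot be
#'   called). Values below 1/2 make difficult sites predominantly
#'   single-center discoveries, which within-center voting retains and
#'   cross-center voting discards.
#' @param seed Master seed; every call set derives an independent stream
#'   from it, so adding a pipeline or center never perturbs existing draws.
#' @return A list of class `StudyConfig`.
#' @export
study_config <- function(n_truth = 1159L,
                         chroms = paste0("chr", 1:8),
                         chrom_length = 2e6,
                         intervals_per_chrom = 150L,
                         interval_width = 1500L,
                         vaf_mixture = list(weights = c(0.35, 0.30, 0.35),
                                            shape1 = c(20, 10, 2),
                                            shape2 = c(20, 30, 12)),
                         centers = list(
                           FD = center_profile(3L, c(40, 38, 42), 25L, 0.8),
                           IL = center_profile(3L, c(100, 250, 100), 25L, 0.8),
                           NV = center_profile(3L, c(80, 80, 80), 25L, 0.8)),
                         mappers = c(bwa = 1.0, bowtie = 0.95),
                         callers = list(
                           mutect = caller_profile(0.45, -0.8, fp_private = 150,
                                                   artifact_sites = 25L,
                                                   artifact_incl = 0.7),
                           strelka = caller_profile(0.40, -1.0, fp_private = 300,
                                                    artifact_sites = 25L,
                                                    artifact_incl = 0.7),
                           ss = caller_profile(0.30, -0.6, fp_private = 450,
                                               artifact_sites = 30L,
                                               artifact_incl = 0.7,
                                               filter_label = ".")),
                         depth_shape = 6,
                         center_site_sd = 1.2,
                         difficult_fraction = 0.30,
                         capture_prob = 0.25,
                         seed = 1L) {
  stopifnot(n_truth >= 1L, chrom_length >= 1, length(chroms) >= 1L,
            interval_width >= 1L, intervals_per_chrom >= 1L,
            abs(sum(vaf_mixture$weights) - 1) < 1e-8,
            all(vaf_mixture$weights >= 0), length(mappers) >= 1L,
            length(callers) >= 1L, length(centers) >= 1L,
            center_site_sd >= 0, difficult_fraction >= 0,
            difficult_fraction <= 1, capture_prob >= 0, capture_prob <= 1)
  if (is.null(names(centers)) || is.null(names(callers)) || is.null(names(mappers)))
    stop("centers, callers and mappers must be named")
  structure(list(n_truth = as.integer(n_truth), chroms = chroms,
                 chrom_length = as.integer(chrom_length),
                 intervals_per_chrom = as.integer(intervals_per_chrom),
                 interval_width = as.integer(interval_width),
                 vaf_mixture = vaf_mixture, centers = centers,
                 mappers = mappers, callers = callers,
                 depth_shape = depth_shape, center_site_sd = center_site_sd,
                 difficult_fraction = difficult_fraction,
                 capture_prob = capture_prob,
                 seed = as.integer(seed)),
            class = "StudyConfig")
}

#' Noise-free study configuration
#'
#' Every caller detects every truth variant (constant sensitivity 1) and no
#' false positives of any kind are generated; consensus at any `m` equals
#' the truth set and all metrics are exactly 1.
#'
#' @param ... Overrides passed to [study_config()].
#' @return A `StudyConfig`.
#' @export
noiseless_config <- function(...) {
  study_config(
    centers = list(FD = center_profile(3L, 40), IL = center_profile(3L, 100),
                   NV = center_profile(3L, 80)),
    callers = list(mutect = caller_profile(0, Inf),
                   strelka = caller_profile(0, Inf),
                   ss = caller_profile(0, Inf, filter_label = ".")),
    center_site_sd = 0, difficult_fraction = 0,
    ...)
}

## ---- RNG streams -----------------------------------------------------------

## Deterministic 31-bit stream seed from the master seed and a label path.
## A fixed polynomial string hash keeps streams stable across sessions and
## independent of list ordering in the config.
stream_seed <- function(master, ...) {
  s <- paste(c(as.character(master), ...), collapse = "|")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

## ---- VAF mixture -----------------------------------------------------------

#' Draw truth variant allele fractions from the configured mixture
#'
#' @param n Number of draws.
#' @param cfg A `StudyConfig` (only `vaf_mixture` is used).
#' @return Numeric vector of VAFs in (0, 1).
#' @export
rvaf <- function(n, cfg) {
  mx <- cfg$vaf_mixture
  comp <- sample.int(length(mx$weights), n, replace = TRUE, prob = mx$weights)
  rbeta(n, mx$shape1[comp], mx$shape2[comp])
}

#' Theoretical CDF of the configured VAF mixture
#'
#' @param q Quantiles.
#' @param cfg A `StudyConfig`.
#' @return `P(VAF <= q)` under the mixture.
#' @export
pvaf <- function(q, cfg) {
  mx <- cfg$vaf_mixture
  out <- 0
  for (j in seq_along(mx$weights))
    out <- out + mx$weights[j] * pbeta(q, mx$shape1[j], mx$shape2[j])
  out
}

## ---- region / position machinery ------------------------------------------

## Evaluable regions are a deterministic function of the config: evenly
## spaced exome-like intervals on each chromosome.
config_regions <- function(cfg) {
  spacing <- cfg$chrom_length %/% cfg$intervals_per_chrom
  if (spacing <= cfg$interval_width)
    stop("config error: intervals overlap; increase chrom_length or reduce intervals")
  starts <- (seq_len(cfg$intervals_per_chrom) - 1L) * spacing
  region_set(rep(cfg$chroms, each = cfg$intervals_per_chrom),
             rep(starts, times = length(cfg$chroms)),
             rep(starts + cfg$interval_width, times = length(cfg$chroms)))
}

## Map offsets in 1..total_covered_width to (chrom, 1-based pos).
offset_to_site <- function(offsets, regions) {
  df <- as.data.frame(regions)
  w <- df$end - df$start
  cum <- cumsum(w)
  iv <- findInterval(offsets - 1L, c(0L, cum), rightmost.closed = FALSE)
  within <- offsets - c(0L, cum)[iv] - 1L          # 0-based offset in interval
  data.frame(chrom = df$chrom[iv], pos = df$start[iv] + within + 1L,
             stringsAsFactors = FALSE)
}

## Sample n distinct in-region sites, excluding the (encoded) sites in
## `exclude` (character "chrom:pos").
sample_sites <- function(n, regions, exclude = character(0)) {
  W <- region_total_width(regions)
  if (n > W - length(exclude)) stop("config error: region too small to host ",
                                    n, " distinct sites")
  if (n == 0L) return(data.frame(chrom = character(0), pos = integer(0)))
  got <- data.frame(chrom = character(0), pos = integer(0))
  tries <- 0L
  while (nrow(got) < n) {
    take <- sample.int(W, min(W, (n - nrow(got)) * 2L + 10L))
    sites <- offset_to_site(take, regions)
    enc <- paste(sites$chrom, sites$pos, sep = ":")
    keep <- !(enc %in% exclude) & !duplicated(enc)
    got <- rbind(got, sites[keep, , drop = FALSE])
    exclude <- c(exclude, enc[keep])
    tries <- tries + 1L
    if (tries > 50L) stop("could not place distinct sites; regions too dense")
  }
  got <- got[seq_len(n), , drop = FALSE]
  rownames(got) <- NULL
  got
}

random_alleles <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

## ---- truth -----------------------------------------------------------------

#' Simulate the truth set and evaluable regions of a study
#'
#' Places exactly `n_truth` distinct SNVs at uniform-random in-region
#' positions with VAFs drawn from the configured mixture. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg A [study_config()].
#' @return List with elements `truth` (a `CallSet` carrying VAF attributes)
#'   and `regions` (a `RegionSet`).
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "StudyConfig"))
  regions <- config_regions(cfg)
  set.seed(stream_seed(cfg$seed, "truth"))
  sites <- sample_sites(cfg$n_truth, regions)
  al <- random_alleles(cfg$n_truth)
  vaf <- rvaf(cfg$n_truth, cfg)
  truth <- call_set(sites$chrom, sites$pos, al$ref, al$alt, vaf = vaf,
                    label = "truth")
  ## keys sorted for stable downstream iteration
  ord <- order(chrom_rank(truth$calls$chrom), truth$calls$pos)
  truth <- callset_slice(truth, ord)
  list(truth = truth, regions = regions)
}

## ---- shared pools ----------------------------------------------------------

## Draw the center-shared and caller-shared artifact pools and the
## center-by-site library effects, each in its own stream.
build_pools <- function(cfg, truth, regions) {
  truth_enc <- paste(truth$calls$chrom, truth$calls$pos, sep = ":")
  taken <- truth_enc
  pools <- list(center = list(), caller = list(), center_fx = list(),
                capture = list())
  ## which truth sites sit in hard-to-capture context (shared by all centers)
  set.seed(stream_seed(cfg$seed, "difficulty"))
  pools$difficult <- runif(length(truth_enc)) < cfg$difficult_fraction
  for (cn in names(cfg$centers)) {
    prof <- cfg$centers[[cn]]
    set.seed(stream_seed(cfg$seed, "centerpool", cn))
    sites <- sample_sites(prof$artifact_sites, regions, exclude = taken)
    al <- random_alleles(nrow(sites))
    pools$center[[cn]] <- cbind(sites, ref = al$ref, alt = al$alt,
                                stringsAsFactors = FALSE)
    taken <- c(taken, paste(sites$chrom, sites$pos, sep = ":"))
    set.seed(stream_seed(cfg$seed, "centerfx", cn))
    pools$center_fx[[cn]] <- if (cfg$center_site_sd > 0)
      rnorm(length(truth_enc), 0, cfg$center_site_sd) else numeric(length(truth_enc))
    ## center-level capture of difficult sites (shared across replicates)
    pools$capture[[cn]] <- !pools$difficult |
      (runif(length(truth_enc)) < cfg$capture_prob)
  }
  for (ck in names(cfg$callers)) {
    prof <- cfg$callers[[ck]]
    set.seed(stream_seed(cfg$seed, "callerpool", ck))
    sites <- sample_sites(prof$artifact_sites, regions, exclude = taken)
    al <- random_alleles(nrow(sites))
    pools$caller[[ck]] <- cbind(sites, ref = al$ref, alt = al$alt,
                                stringsAsFactors = FALSE)
    taken <- c(taken, paste(sites$chrom, sites$pos, sep = ":"))
  }
  pools$truth_enc <- truth_enc
  pools
}

## Per-(center, replicate) site depths, one stream per replicate so both
## mappers and all callers of a replicate see the same sequencing depth.
replicate_depths <- function(cfg, center, rep_idx) {
  prof <- cfg$centers[[center]]
  set.seed(stream_seed(cfg$seed, "depth", center, rep_idx))
  mean_cov <- prof$coverage_mean[rep_idx]
  list(tumor = rgamma(cfg$n_truth, shape = cfg$depth_shape,
                      scale = mean_cov / cfg$depth_shape),
       normal_mean = mean_cov * 0.8)
}

## ---- one call set ----------------------------------------------------------

#' Simulate one replicate-by-pipeline call set
#'
#' Detects each truth variant independently with probability
#' `plogis(slope * mult * vaf * depth + intercept + u)` (the caller's
#' sensitivity curve at that site's depth, plus the center-by-site library
#' effect `u`), then adds false positives from three pools: the
#' center-shared artifact pool, the caller-shared artifact pool (each site
#' included with its configured probability) and fresh Poisson private
#' sites. Attributes (VAF, depths, quality) are filled consistently with
#' the generating draw. Deterministic given the config seed: each
#' `(center, replicate, mapper, caller)` cell has its own stream.
#'
#' @param cfg A `StudyConfig`.
#' @param truth Truth `CallSet` from [simulate_truth()].
#' @param regions Evaluable `RegionSet`.
#' @param pools Shared pools from the study setup (internal structure; built
#'   once per study).
#' @param center,rep_idx,mapper,caller Which cell to simulate.
#' @param depths Optional precomputed replicate depths (built if missing).
#' @return A `CallSet` with full provenance.
#' @export
simulate_replicate <- function(cfg, truth, regions, pools, center, rep_idx,
                               mapper, caller, depths = NULL) {
  stopifnot(inherits(cfg, "StudyConfig"))
  cprof <- cfg$centers[[center]]
  kprof <- cfg$callers[[caller]]
  mult <- cfg$mappers[[mapper]]
  if (is.null(cprof) || is.null(kprof) || is.null(mult))
    stop("unknown center/caller/mapper: ", center, "/", caller, "/", mapper)
  if (is.null(depths)) depths <- replicate_depths(cfg, center, rep_idx)

  set.seed(stream_seed(cfg$seed, "callset", center, rep_idx, mapper, caller))
  n <- length(truth)
  vaf <- truth$calls$vaf
  u <- pools$center_fx[[center]]
  p <- if (kprof$slope == 0) {
    rep(plogis(kprof$intercept), n)
  } else {
    plogis(kprof$slope * mult * vaf * depths$tumor + kprof$intercept + u)
  }
  ## uncaptured difficult sites yield no alternate reads at this center
  capture <- pools$capture[[center]] %||% rep(TRUE, n)
  p <- p * capture
  detected <- rbinom(n, 1L, p) == 1L

  ## observed attributes for detected truth sites
  td <- pmax(1L, round(depths$tumor))
  alt_reads <- rbinom(n, td, pmin(1, pmax(0, vaf)))
  obs_vaf <- ifelse(td > 0, alt_reads / td, 0)
  qual <- pmin(99, pmax(1, 2.5 * alt_reads + rnorm(n, 0, 3)))
  nd <- pmax(1L, round(rgamma(n, shape = cfg$depth_shape,
                              scale = depths$normal_mean / cfg$depth_shape)))
  tcalls <- data.frame(chrom = truth$calls$chrom[detected],
                       pos = truth$calls$pos[detected],
                       ref = truth$calls$ref[detected],
                       alt = truth$calls$alt[detected],
                       qual = round(qual[detected], 1),
                       filter = rep(kprof$filter_label, sum(detected)),
                       vaf = round(obs_vaf[detected], 4),
                       tumor_depth = td[detected],
                       normal_depth = nd[detected],
                       stringsAsFactors = FALSE)

  fp_frames <- list()
  ## center-shared artifact sites
  cp <- pools$center[[center]]
  if (nrow(cp)) {
    inc <- runif(nrow(cp)) < cprof$artifact_incl
    fp_frames$center <- cp[inc, , drop = FALSE]
  }
  ## caller-shared systematic sites
  kp <- pools$caller[[caller]]
  if (nrow(kp)) {
    inc <- runif(nrow(kp)) < kprof$artifact_incl
    fp_frames$caller <- kp[inc, , drop = FALSE]
  }
  ## private random sites
  n_priv <- rpois(1L, kprof$fp_private)
  if (n_priv > 0L) {
    sites <- sample_sites(n_priv, regions, exclude = pools$truth_enc)
    al <- random_alleles(n_priv)
    fp_frames$private <- cbind(sites, ref = al$ref, alt = al$alt,
                               stringsAsFactors = FALSE)
  }
  fp <- if (length(fp_frames)) do.call(rbind, fp_frames) else NULL
  if (!is.null(fp) && nrow(fp)) {
    nf <- nrow(fp)
    fp_td <- pmax(1L, round(rgamma(nf, shape = cfg$depth_shape,
                                   scale = cprof$coverage_mean[rep_idx] / cfg$depth_shape)))
    fp_alt <- 1L + rbinom(nf, fp_td, 0.03)
    fcalls <- data.frame(chrom = fp$chrom, pos = fp$pos, ref = fp$ref,
                         alt = fp$alt,
                         qual = round(pmin(99, pmax(1, 2.5 * fp_alt + rnorm(nf, 0, 3))), 1),
                         filter = kprof$filter_label,
                         vaf = round(pmin(1, fp_alt / fp_td), 4),
                         tumor_depth = fp_td,
                         normal_depth = pmax(1L, round(rgamma(nf, cfg$depth_shape,
                                                              scale = cprof$coverage_mean[rep_idx] * 0.8 / cfg$depth_shape))),
                         stringsAsFactors = FALSE)
    tcalls <- rbind(tcalls, fcalls)
  }
  cs <- callset_from_calls(tcalls, provenance = list(
    center = center, replicate = as.integer(rep_idx),
    mapper = mapper, caller = caller))
  cs
}

## ---- whole study -----------------------------------------------------------

#' Simulate a complete multi-center replicate study
#'
#' Generates the truth set, evaluable regions, all per-replicate
#' per-pipeline call sets and the replicate manifest. Under the default
#' configuration this yields 3 centers x 3 replicates x 6 pipelines = 54
#' call sets. Fully deterministic given `cfg$seed`; every call set draws
#' from its own stream, so adding centers, callers or mappers never changes
#' existing call sets.
#'
#' @param cfg A [study_config()].
#' @return A list of class `StudyBundle`: `truth`, `regions`, `manifest`
#'   (data frame with `center`, `replicate`, `mapper`, `caller`, `name`),
#'   `callsets` (named list keyed like `"FD_1_bwa_mutect"`), and `config`.
#' @examples
#' \donttest{
#' bundle <- simulate_study(study_config(n_truth = 50, seed = 7))
#' length(bundle$callsets)
#' }
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "StudyConfig"))
  ts <- simulate_truth(cfg)
  pools <- build_pools(cfg, ts$truth, ts$regions)
  manifest <- expand.grid(caller = names(cfg$callers),
                          mapper = names(cfg$mappers),
                          stringsAsFactors = FALSE)
  rows <- list(); callsets <- list()
  for (cn in names(cfg$centers)) {
    prof <- cfg$centers[[cn]]
    for (r in seq_len(prof$n_replicates)) {
      depths <- replicate_depths(cfg, cn, r)
      for (mp in names(cfg$mappers)) for (ck in names(cfg$callers)) {
        nm <- paste(cn, r, mp, ck, sep = "_")
        callsets[[nm]] <- simulate_replicate(cfg, ts$truth, ts$regions, pools,
                                             cn, r, mp, ck, depths = depths)
        rows[[nm]] <- data.frame(center = cn, replicate = r, mapper = mp,
                                 caller = ck, name = nm,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  structure(list(truth = ts$truth, regions = ts$regions, manifest = manifest,
                 callsets = callsets, config = cfg),
            class = "StudyBundle")
}

#' @export
print.StudyBundle <- function(x, ...) {
  cat(sprintf("StudyBundle: %d truth SNVs, %d call sets (%d centers x %d pipelines)\n",
              length(x$truth), length(x$callsets), length(x$config$centers),
              length(x$config$mappers) * length(x$config$callers)))
  invisible(x)
}

#' Materialize / reload a simulated study on disk
#'
#' `write_study()` writes `truth.vcf`, `regions.bed`, `manifest.tsv` (with
#' `vcf_path` and `pass_only` columns) and one VCF per call set under `dir`;
#' `read_study()` reads such a directory back into a `StudyBundle` whose
#' call-set and truth keys equal the original's.
#'
#' @param bundle A `StudyBundle`.
#' @param dir Directory to write to / read from.
#' @return `write_study()` returns `dir` invisibly; `read_study()` a
#'   `StudyBundle` (with `config = NULL`).
#' @export
write_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "StudyBundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(bundle$truth, file.path(dir, "truth.vcf"))
  write_bed(bundle$regions, file.path(dir, "regions.bed"))
  man <- bundle$manifest
  man$vcf_path <- paste0(man$name, ".vcf")
  man$pass_only <- vapply(bundle$callsets[man$name], function(cs)
    all(cs$calls$filter != "."), logical(1))
  for (nm in man$name)
    write_vcf(bundle$callsets[[nm]], file.path(dir, paste0(nm, ".vcf")))
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$config))
    jsonlite::write_json(list(seed = bundle$config$seed,
                              n_truth = bundle$config$n_truth),
                         file.path(dir, "study.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  truth <- read_vcf(file.path(dir, "truth.vcf"))
  truth$provenance$label <- "truth"
  regions <- read_bed(file.path(dir, "regions.bed"))
  callsets <- list()
  for (i in seq_len(nrow(man))) {
    callsets[[man$name[i]]] <- read_vcf(
      file.path(dir, man$vcf_path[i]), pass_only = man$pass_only[i],
      center = man$center[i], replicate = man$replicate[i],
      mapper = man$mapper[i], caller = man$caller[i])
  }
  structure(list(truth = truth, regions = regions,
                 manifest = man[, c("center", "replicate", "mapper", "caller",
                                    "name", "vcf_path", "pass_only")],
                 callsets = callsets, config = NULL),
            class = "StudyBundle")
}

#' Recover simulator parameters from a bundle with known truth
#'
#' Estimates each caller's mean sensitivity (fraction of truth variants
#' detected, averaged over that caller's call sets) and mean false-positive
#' count per call set. A validation utility for parameter-recovery checks.
#'
#' @param bundle A `StudyBundle`.
#' @return Data frame with columns `caller`, `sensitivity`, `fp_rate`,
#'   `n_callsets`.
#' @export
estimate_profile <- function(bundle) {
  stopifnot(inherits(bundle, "StudyBundle"))
  tk <- variant_keys(bundle$truth)
  callers <- unique(bundle$manifest$caller)
  rows <- lapply(callers, function(ck) {
    nms <- bundle$manifest$name[bundle$manifest$caller == ck]
    sens <- vapply(bundle$callsets[nms], function(cs)
      sum(variant_keys(cs) %in% tk) / length(tk), numeric(1))
    fp <- vapply(bundle$callsets[nms], function(cs)
      sum(!(variant_keys(cs) %in% tk)), numeric(1))
    data.frame(caller = ck, sensitivity = mean(sens), fp_rate = mean(fp),
               n_callsets = length(nms), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
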