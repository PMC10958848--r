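#' Simulate a study and materialize it on disk
#'
#' Runs [simulate_study()] and writes the bundle (truth VCF, region BED,
#' manifest, per-replicate VCFs) under `out_dir`, together with a
#' `MANIFEST.json` provenance block (seed, configuration hash, file list).
#' Byte-identical across reruns with the same configuration.
#'
#' @param cfg A [study_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages?
#' @return The `StudyBundle`, invisibly.
#' @export
run_simulate <- function(cfg, out_dir, quiet = FALSE) {
  bundle <- simulate_study(cfg)
  write_study(bundle, out_dir)
  prov <- list(command = "simulate", seed = cfg$seed,
               config_hash = provenance_hash(cfg),
               n_truth = cfg$n_truth,
               n_callsets = length(bundle$callsets),
               files = sort(list.files(out_dir)))
  jsonlite::write_json(prov, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!quiet) message("simulated ", length(bundle$callsets), " call sets (",
                      cfg$n_truth, " truth SNVs) -> ", out_dir)
  invisible(bundle)
}

#' Run the consensus evaluation pipeline
#'
#' For each requested grouping scheme: builds the voting groups from the
#' manifest, restricts every call set and the truth set to the evaluable
#' regions and to SNVs, computes the full m-sweep per group, and renders the
#' fixed-format TSV report tables plus consensus VCFs. The input is either a
#' `StudyBundle` or a directory produced by [run_simulate()]/[write_study()].
#'
#' @param x A `StudyBundle` or a study directory path.
#' @param out_dir Output directory for reports.
#' @param schemes Grouping schemes to evaluate.
#' @param expected_truth_size Optional declared truth size (warns on
#'   mismatch, see [confusion()]).
#' @param write_consensus_vcf Write one VCF per group at its best-F1 `m`?
#' @param quiet Suppress progress messages?
#' @return Named list (scheme -> group -> sweep table), invisibly.
#' @export
run_consensus <- function(x, out_dir,
                          schemes = c("within_center", "cross_center", "all_centers"),
                          expected_truth_size = NULL,
                          write_consensus_vcf = FALSE, quiet = FALSE) {
  bundle <- as_bundle(x)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- select_snvs(restrict(bundle$truth, bundle$regions))
  callsets <- lapply(bundle$callsets, function(cs)
    select_snvs(restrict(cs, bundle$regions)))
  results <- list()
  for (scheme in schemes) {
    gs <- build_groups(bundle$manifest, scheme)
    if (!quiet) message(scheme, ": ", length(gs$groups), " voting group(s)")
    sweeps <- lapply(gs$groups, function(idx) {
      members <- callsets[bundle$manifest$name[idx]]
      sweep_m(members, truth, expected_truth_size = expected_truth_size)
    })
    results[[scheme]] <- sweeps
    if (write_consensus_vcf) {
      for (g in names(gs$groups)) {
        sw <- sweeps[[g]]
        best_m <- sw$m[sw$best][1L]
        members <- callsets[bundle$manifest$name[gs$groups[[g]]]]
        cons <- consensus(members, best_m, label = g)
        write_vcf(cons, file.path(out_dir, sprintf("%s_m%d.vcf", g, best_m)))
      }
    }
  }
  report_tables(results, out_dir)
  prov <- list(command = "consensus", schemes = schemes,
               config_hash = provenance_hash(list(
                 manifest = bundle$manifest,
                 truth_keys = variant_keys(bundle$truth))),
               files = sort(list.files(out_dir)))
  jsonlite::write_json(prov, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Run the consensus-label training experiment end to end
#'
#' Wraps [label_quality_experiment()] over a bundle or study directory and
#' writes `label_experiment.tsv` (full-precision columns rounded to three
#' decimals for display) and a `MANIFEST.json` provenance block.
#'
#' @inheritParams run_consensus
#' @param ... Passed to [label_quality_experiment()].
#' @return The experiment table, invisibly.
#' @export
run_label_experiment <- function(x, out_dir, quiet = FALSE, ...) {
  bundle <- as_bundle(x)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- label_quality_experiment(bundle, ...)
  disp <- tab
  for (col in c("label_precision", "label_recall", "test_precision",
                "test_recall", "test_f1"))
    disp[[col]] <- format_metric(disp[[col]])
  utils::write.table(disp, file.path(out_dir, "label_experiment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(command = "label-experiment",
               config_hash = provenance_hash(list(
                 manifest = bundle$manifest,
                 args = list(...))),
               files = sort(list.files(out_dir)))
  jsonlite::write_json(prov, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!quiet) message("label experiment: ", nrow(tab), " row(s) -> ", out_dir)
  invisible(tab)
}

as_bundle <- function(x) {
  if (inherits(x, "StudyBundle")) return(x)
  if (is.character(x) && length(x) == 1L && dir.exists(x)) return(read_study(x))
  stop("expected a StudyBundle or a study directory path")
}

## Stable short hash of any plain-list configuration (for provenance blocks).
provenance_hash <- function(obj) {
  txt <- paste(deparse(obj), collapse = "\n")
  sprintf("%08x", stream_seed(0L, txt))
}
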