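#' Run the full hierarchical pipeline in memory
#'
#' Executes the complete workflow on raw matrices: design alignment, TMM
#' normalization, log transform, paired t-tests with BH-FDR feature
#' selection, the tumor/normal dependence diagnostic, the mechanistic lasso
#' submodel on significant features, the clinical lasso-logistic submodel,
#' and pair emission. Deterministic given `config$seed`.
#'
#' @param mrna,mirna Raw-scale `him_expr` objects.
#' @param design A `him_design` (incomplete pairs are dropped).
#' @param config A [him_config()].
#' @return A list of class `him_result` with every stage output: `design`,
#'   `mrna_log`/`mirna_log`, `mrna_diff`/`mirna_diff`,
#'   `mrna_dependence`/`mirna_dependence`, `sig_mrnas`/`sig_mirnas`,
#'   `mech`, `clinical_design`, `clinical_fit`, `pairset`, `manifest`.
#' @export
him_run <- function(mrna, mirna, design, config = him_config()) {
  al_g <- align_design(mrna, design)
  al_m <- align_design(mirna, al_g$design)
  design <- al_m$design
  # both matrices restricted to the common complete-pair sample set
  al_g <- align_design(al_g$expr, design)
  mrna_raw <- al_g$expr; mirna_raw <- al_m$expr
  mrna_log <- log_transform(normalize_tmm(mrna_raw),
                            config$log_base, config$pseudocount)
  mirna_log <- log_transform(normalize_tmm(mirna_raw),
                             config$log_base, config$pseudocount)
  mrna_diff <- paired_ttest(mrna_log, design, raw_expr = mrna_raw,
                            fdr_threshold = config$fdr_threshold)
  mirna_diff <- paired_ttest(mirna_log, design, raw_expr = mirna_raw,
                             fdr_threshold = config$fdr_threshold)
  dep_g <- dependence_report(mrna_log, design, config$dependence_threshold)
  dep_m <- dependence_report(mirna_log, design, config$dependence_threshold)
  sig_g <- select_significant(mrna_diff, config$fdr_threshold)
  sig_m <- select_significant(mirna_diff, config$fdr_threshold)
  sub <- function(expr, ids) {
    out <- expr; out$values <- expr$values[ids, , drop = FALSE]; out
  }
  mech <- fit_all(sub(mrna_log, sig_g), sub(mirna_log, sig_m),
                  config, design)
  cd <- build_design(mech, mrna_log, mirna_log, design)
  fit <- fit_clinical(cd, config)
  pairset <- emit_pairs(fit, mech)
  manifest <- build_manifest(design, mrna_diff, mirna_diff, sig_g, sig_m,
                             mech, pairset, config)
  structure(list(design = design, mrna_log = mrna_log, mirna_log = mirna_log,
                 mrna_diff = mrna_diff, mirna_diff = mirna_diff,
                 mrna_dependence = dep_g, mirna_dependence = dep_m,
                 sig_mrnas = sig_g, sig_mirnas = sig_m, mech = mech,
                 clinical_design = cd, clinical_fit = fit, pairset = pairset,
                 manifest = manifest),
            class = "him_result")
}

# Per-stage counts in the reporting convention "pairs (#mRNA) (#miRNA)";
# internally consistency-checked on every run.
build_manifest <- function(design, mrna_diff, mirna_diff, sig_g, sig_m,
                           mech, pairset, config, input_hashes = NULL) {
  man <- list(
    version = as.character(utils::packageVersion("himpair")),
    seed = config$seed,
    config = unclass(config),
    input_hashes = input_hashes,
    n_patients = length(unique(design$patient_id)),
    detected = list(mrna = nrow(mrna_diff), mirna = nrow(mirna_diff)),
    significant = list(mrna = length(sig_g), mirna = length(sig_m)),
    mechanistic = as.list(mech$summary),
    clinical = as.list(pairset$summary))
  check_manifest(man, mech, pairset)
  man
}

check_manifest <- function(man, mech, pairset) {
  stopifnot(
    identical(as.list(pair_counts(mech$candidate_pairs)), man$mechanistic),
    identical(as.list(pair_counts(pairset$pairs)), man$clinical),
    man$clinical$n_pairs <= max(man$mechanistic$n_pairs, 0),
    all(paste(pairset$pairs$mirna_id, pairset$pairs$mrna_id) %in%
          paste(mech$candidate_pairs$mirna_id, mech$candidate_pairs$mrna_id)))
  invisible(TRUE)
}

#' @export
print.him_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<him_result> %d patients; detected %d mRNA / %d miRNA; ",
                     "significant %d / %d; mechanistic %d pairs (%d) (%d); ",
                     "clinical %d pairs (%d) (%d)\n"),
              m$n_patients, m$detected$mrna, m$detected$mirna,
              m$significant$mrna, m$significant$mirna,
              m$mechanistic$n_pairs, m$mechanistic$n_distinct_mrna,
              m$mechanistic$n_distinct_mirna, m$clinical$n_pairs,
              m$clinical$n_distinct_mrna, m$clinical$n_distinct_mirna))
  invisible(x)
}

#' Run the pipeline on files
#'
#' File-level wrapper over [him_run()]: reads the matrices, design, and
#' optional config, executes every stage, and writes all intermediates plus
#' a run manifest under `outdir`. Re-running with the same inputs and seed
#' reproduces every output byte-identically.
#'
#' @param mrna_path,mirna_path Expression matrix files (see
#'   [read_expression()]).
#' @param design_path Design file (see [read_design()]).
#' @param outdir Output directory, created if needed.
#' @param config A [him_config()] or path to a YAML/JSON config file.
#' @return The [him_run()] result, invisibly; outputs on disk include
#'   `*_diff.tsv`, `dependence_*.tsv`, `mech_pairs.tsv`, `eta.tsv`,
#'   `resid.tsv`, orphan lists, `pairset.tsv`, `molecules.tsv`,
#'   `summary.json`, `manifest.json`, `run.log`.
#' @export
run_pipeline <- function(mrna_path, mirna_path, design_path, outdir,
                         config = him_config()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  logmsg <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                              sprintf(...), "\n", sep = "", file = logf,
                              append = TRUE)
  cat("", file = logf)
  stage <- "io"
  res <- tryCatch({
    logmsg("stage io: reading inputs")
    mrna <- read_expression(mrna_path, "mRNA")
    mirna <- read_expression(mirna_path, "miRNA")
    design <- read_design(design_path)
    hashes <- unname(tools::md5sum(c(mrna_path, mirna_path, design_path)))
    stage <- "pipeline"
    logmsg("stage pipeline: seed %d, fdr %g, lambda_rule %s, cv_folds %d",
           config$seed, config$fdr_threshold, config$lambda_rule,
           config$cv_folds)
    out <- him_run(mrna, mirna, design, config)
    out$manifest$input_hashes <- stats::setNames(
      hashes, c("mrna", "mirna", "design"))
    out
  }, error = function(e) {
    logmsg("ERROR in stage %s: %s", stage, conditionMessage(e))
    partial <- list(stage_failed = stage, error = conditionMessage(e),
                    seed = config$seed)
    jsonlite::write_json(partial, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  logmsg("stage report: writing outputs")
  wt <- function(df, name) utils::write.table(
    df, file.path(outdir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$mrna_diff, "mrna_diff.tsv")
  wt(res$mirna_diff, "mirna_diff.tsv")
  wt(res$mrna_dependence$table, "dependence_mrna.tsv")
  wt(res$mirna_dependence$table, "dependence_mirna.tsv")
  write_mechanistic(res$mech, outdir)
  write_pairs(res$pairset, outdir, config)
  jsonlite::write_json(res$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  logmsg("done: %d clinical pairs", res$pairset$summary["n_pairs"])
  invisible(res)
}

#' Simulate a dataset to files
#'
#' Thin wrapper over [simulation_truth()] + [simulate_dataset()] writing
#' `mrna.tsv`, `mirna.tsv`, `design.tsv`, `truth_pairs.tsv`, and
#' `truth.json` under `outdir`, ready for [run_pipeline()]. Deterministic:
#' the same preset and seed always produce identical files.
#'
#' @param preset `"null"`, `"easy"`, `"default"`, or `"hard"`.
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @return The simulated dataset, invisibly.
#' @export
simulate_command <- function(preset = "default", seed = 1, outdir) {
  truth <- simulation_truth(preset = preset, seed = seed)
  sim <- simulate_dataset(truth)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$mrna, file.path(outdir, "mrna.tsv"))
  write_expression(sim$mirna, file.path(outdir, "mirna.tsv"))
  write_design(sim$design, file.path(outdir, "design.tsv"))
  utils::write.table(truth_pairs(truth), file.path(outdir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  params <- truth[c("disease_eta_mrnas", "disease_resid_mrnas",
                    "disease_mirnas", "effect_size", "noise_sd",
                    "n_patients", "n_mrna", "n_mirna", "vary_libsize",
                    "seed")]
  jsonlite::write_json(params, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sim)
}
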