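#' Expression matrix container
#'
#' Wraps a numeric features x samples matrix together with its feature kind
#' (mRNA or miRNA) and scale provenance (raw counts/intensities, normalized,
#' or log-transformed). Feature and sample identifiers live in the dimnames
#' and must be unique.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   rownames (feature IDs) and colnames (sample IDs).
#' @param feature_kind `"mRNA"` or `"miRNA"`.
#' @param scale `"raw"`, `"normalized"`, or `"log"`. Raw and normalized
#'   values must be nonnegative.
#' @param allow_missing Permit `NA` cells (used only between reading and
#'   [drop_sparse_features()]); all values must otherwise be finite.
#' @return An object of class `him_expr`.
#' @export
expression_matrix <- function(values, feature_kind = c("mRNA", "miRNA"),
                              scale = c("raw", "normalized", "log"),
                              allow_missing = FALSE) {
  feature_kind <- match.arg(feature_kind)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (feature IDs) and colnames (sample IDs)")
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f))
    stop("duplicate feature IDs: ", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample IDs: ", paste(dup_s, collapse = ", "))
  if (allow_missing) {
    if (any(is.infinite(values))) stop("values must be finite")
  } else if (any(!is.finite(values))) {
    stop("values must be finite and non-missing")
  }
  if (scale != "log" && any(values < 0, na.rm = TRUE))
    stop(scale, "-scale values must be nonnegative")
  structure(list(values = values, feature_kind = feature_kind, scale = scale),
            class = "him_expr")
}

#' @export
print.him_expr <- function(x, ...) {
  cat(sprintf("<him_expr> %d %s features x %d samples [%s scale]\n",
              nrow(x$values), x$feature_kind, ncol(x$values), x$scale))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x A `him_expr` object.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Paired tumor/normal design
#'
#' Describes which samples belong to which patient and whether each is tumor
#' (status 1) or adjacent normal (status 0). A complete design has every
#' patient exactly twice, once per status; incomplete designs are only
#' allowed as raw input to [align_design()], which drops incomplete pairs.
#'
#' @param sample_id,patient_id Character vectors of equal length.
#' @param status Integer/numeric vector of 0 (normal) and 1 (tumor).
#' @param allow_incomplete Skip the each-patient-exactly-twice check.
#' @return A data frame of class `him_design` with columns `sample_id`,
#'   `patient_id`, `status`.
#' @export
paired_design <- function(sample_id, patient_id, status,
                          allow_incomplete = FALSE) {
  sample_id <- as.character(sample_id)
  patient_id <- as.character(patient_id)
  status <- as.integer(status)
  n <- length(sample_id)
  if (length(patient_id) != n || length(status) != n)
    stop("sample_id, patient_id, status must have equal length")
  if (anyDuplicated(sample_id))
    stop("duplicate sample IDs in design: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  if (!all(status %in% c(0L, 1L)))
    stop("status must be binary: 1 = tumor, 0 = adjacent normal")
  key <- paste(patient_id, status)
  if (anyDuplicated(key))
    stop("a patient has two samples with the same status: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!allow_incomplete) {
    tab <- table(patient_id)
    bad <- names(tab)[tab != 2L]
    if (length(bad))
      stop("patients without a complete tumor/normal pair: ",
           paste(bad, collapse = ", "))
  }
  structure(data.frame(sample_id = sample_id, patient_id = patient_id,
                       status = status, stringsAsFactors = FALSE),
            class = c("him_design", "data.frame"))
}

#' @export
print.him_design <- function(x, ...) {
  cat(sprintf("<him_design> %d samples, %d patients (%d tumor / %d normal)\n",
              nrow(x), length(unique(x$patient_id)),
              sum(x$status == 1), sum(x$status == 0)))
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one validated object.
#' All stochastic steps (cross-validation folds, simulation) derive their
#' randomness from `seed`, so a run is fully replayable.
#'
#' @param fdr_threshold FDR cutoff for the paired t-test feature selection;
#'   features pass when adjusted p is strictly below it.
#' @param log_base Base of the log transform applied before modeling.
#' @param pseudocount Added before taking logs of counts.
#' @param lambda_rule Penalty-selection rule for lasso fits: `"cv_min"`
#'   (lambda minimizing cross-validated error), `"cv_1se"` (largest lambda
#'   within one SE of the minimum), or `"fixed"` (use `lambda_fixed`).
#' @param cv_folds Number of cross-validation folds; folds are assigned at
#'   the patient level so a patient's tumor and normal samples never straddle
#'   a fold boundary.
#' @param seed Integer master seed.
#' @param correlation_threshold |r| cutoff of the pairwise-correlation
#'   baseline comparator.
#' @param dependence_threshold |r| cutoff of the tumor/normal dependence
#'   diagnostic.
#' @param max_missing_fraction Features missing in more than this fraction of
#'   samples are dropped by [drop_sparse_features()].
#' @param lambda_fixed Penalty value used when `lambda_rule = "fixed"`.
#' @param standardize Standardize predictors internally for penalized fits
#'   (coefficients are always reported on the original scale).
#' @param glmnet_thresh Convergence threshold forwarded to the coordinate
#'   descent solver; tight default so Karush-Kuhn-Tucker conditions hold to
#'   high precision.
#' @return A list of class `him_config`.
#' @export
him_config <- function(fdr_threshold = 0.05, log_base = 2, pseudocount = 1,
                       lambda_rule = c("cv_min", "cv_1se", "fixed"),
                       cv_folds = 10, seed = 1,
                       correlation_threshold = 0.5,
                       dependence_threshold = 0.3,
                       max_missing_fraction = 0.9,
                       lambda_fixed = NULL, standardize = TRUE,
                       glmnet_thresh = 1e-10) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1,
            log_base > 1, pseudocount >= 0,
            cv_folds >= 2, correlation_threshold >= 0,
            correlation_threshold <= 1,
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  if (lambda_rule == "fixed" &&
      (is.null(lambda_fixed) || lambda_fixed < 0))
    stop("lambda_rule = 'fixed' requires a nonnegative lambda_fixed")
  structure(list(fdr_threshold = fdr_threshold, log_base = log_base,
                 pseudocount = pseudocount, lambda_rule = lambda_rule,
                 cv_folds = as.integer(cv_folds), seed = seed,
                 correlation_threshold = correlation_threshold,
                 dependence_threshold = dependence_threshold,
                 max_missing_fraction = max_missing_fraction,
                 lambda_fixed = lambda_fixed, standardize = standardize,
                 glmnet_thresh = glmnet_thresh),
            class = "him_config")
}

# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so package internals never perturb user randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

# Stable 31-adic string hash into [0, 2^31-2]; used to derive per-mRNA CV
# seeds so fold assignment is independent of iteration order.
stable_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

derive_seed <- function(id, seed) {
  bitwXor(stable_hash(id), as.integer(seed %% 2147483647)) %% 2147483647L
}
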