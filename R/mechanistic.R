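# Nudge eta by at most one ulp so that eta + resid reproduces y bit-exactly:
# resid = fl(y - eta) is small relative to y on the log scale, so the second
# subtraction y - resid is exact (Sterbenz) and the decomposition closes.
reconcile_decomposition <- function(y, eta) {
  resid <- y - eta
  eta <- y - resid
  resid <- y - eta
  list(eta = eta, resid = resid)
}

# Patient-level CV fold assignment: patients are shuffled with a seeded RNG
# and dealt round-robin into folds; both samples of a patient share a fold,
# so paired samples never leak across the CV split.
make_foldid <- function(patients, nfolds, seed) {
  upat <- unique(patients)
  if (length(upat) < nfolds) nfolds <- length(upat)
  perm <- with_seed(seed, sample(upat))
  fold_of <- stats::setNames(rep_len(seq_len(nfolds), length(upat)), perm)
  unname(fold_of[patients])
}

#' Fit the mechanistic submodel for one mRNA
#'
#' Lasso-penalized linear regression of a single mRNA's log expression on
#' the log expression of all candidate miRNAs:
#' `mRNA_j = alpha_0 + sum_p alpha_p miRNA_jp + e_j`, where the fitted part
#' is the linear predictor `eta_j` and `e_j = y - eta_j`, so the
#' decomposition `y = eta + resid` is exact by construction. Predictors are
#' standardized internally; coefficients are reported on the original scale;
#' the intercept is never penalized. The penalty is chosen by seeded
#' patient-level k-fold cross-validation (`cv_min` or `cv_1se`), or fixed.
#'
#' @param y Numeric vector of log mRNA expression, one value per sample.
#' @param X Samples x miRNAs numeric matrix of log expression (column names
#'   are miRNA IDs).
#' @param config A [him_config()].
#' @param patients Optional patient ID per sample for patient-level folds;
#'   sample-level folds are used when absent.
#' @param seed Seed for fold assignment (defaults to `config$seed`).
#' @return A list of class `him_mech_fit`: `alpha0`, `alphas` (named vector
#'   of nonzero coefficients), `eta`, `resid`, `lambda_used`, `support`.
#'   With fewer samples than `2 * cv_folds`, falls back to leave-one-out CV
#'   on a deterministic fold assignment (message emitted). A zero-variance
#'   `y` yields an intercept-only fit.
#' @export
fit_one_mrna <- function(y, X, config = him_config(), patients = NULL,
                         seed = config$seed) {
  stopifnot(is.numeric(y), is.matrix(X), nrow(X) == length(y))
  n <- length(y)
  intercept_only <- function() {
    a0 <- mean(y)
    structure(c(list(alpha0 = a0,
                     alphas = stats::setNames(numeric(0), character(0))),
                reconcile_decomposition(y, rep(a0, n)),
                list(lambda_used = Inf, support = character(0))),
              class = "him_mech_fit")
  }
  if (ncol(X) == 0 || stats::sd(y) == 0) return(intercept_only())
  # glmnet needs >= 2 predictor columns; pad with an all-zero dummy
  Xfit <- X
  if (ncol(Xfit) == 1)
    Xfit <- cbind(Xfit, `.him_dummy` = 0)
  if (config$lambda_rule == "fixed") {
    fit <- glmnet::glmnet(Xfit, y, family = "gaussian",
                          standardize = config$standardize,
                          thresh = config$glmnet_thresh)
    lambda <- config$lambda_fixed
    cf <- glmnet::coef.glmnet(fit, s = lambda, exact = TRUE, x = Xfit, y = y,
                              standardize = config$standardize,
                              thresh = config$glmnet_thresh)
  } else {
    if (n < 2 * config$cv_folds) {
      message("n = ", n, " < 2 * cv_folds; using leave-one-out CV")
      foldid <- seq_len(n)
    } else if (!is.null(patients)) {
      foldid <- make_foldid(patients, config$cv_folds, seed)
    } else {
      foldid <- with_seed(seed, sample(rep_len(seq_len(config$cv_folds), n)))
    }
    # the oracle-grade threshold stalls the path at tiny lambdas on pure-noise
    # responses; 1e-8 keeps KKT residuals far below the 1e-6 tolerance
    cv <- with_seed(seed,
      glmnet::cv.glmnet(Xfit, y, family = "gaussian", foldid = foldid,
                        standardize = config$standardize,
                        thresh = max(config$glmnet_thresh, 1e-8)))
    lambda <- if (config$lambda_rule == "cv_min") cv$lambda.min else cv$lambda.1se
    cf <- glmnet::coef.glmnet(cv$glmnet.fit, s = lambda)
  }
  cf <- as.matrix(cf)[, 1]
  alpha0 <- cf["(Intercept)"]
  betas <- cf[setdiff(names(cf), c("(Intercept)", ".him_dummy"))]
  nz <- betas[betas != 0]
  eta <- drop(alpha0 + X[, names(betas), drop = FALSE] %*% betas)
  structure(c(list(alpha0 = unname(alpha0), alphas = nz),
              reconcile_decomposition(y, unname(eta)),
              list(lambda_used = lambda, support = names(nz))),
            class = "him_mech_fit")
}

#' Fit the mechanistic submodel for every significant mRNA
#'
#' Runs [fit_one_mrna()] for each mRNA against the full set of significant
#' miRNAs, then partitions molecules: mediated mRNAs (nonempty lasso
#' support), orphan mRNAs (significant but empty support), and orphan
#' miRNAs (significant but in no support set). Candidate pairs are every
#' (mRNA, miRNA) with the miRNA in that mRNA's support. Cross-validation
#' folds are seeded per mRNA from a stable hash of its ID xor the master
#' seed, so results do not depend on iteration order.
#'
#' @param mrna,mirna Log-scale `him_expr` objects restricted to significant
#'   features, column-aligned to the same samples.
#' @param config A [him_config()].
#' @param design Optional `him_design` enabling patient-level CV folds.
#' @return A list of class `him_mech` with elements `fits` (named list of
#'   `him_mech_fit`), `eta` and `resid` matrices (mRNAs x samples),
#'   `mediated_mrnas`, `orphan_mrnas`, `orphan_mirnas`, `candidate_pairs`
#'   (data frame mrna_id, mirna_id, alpha), and `summary`
#'   (n_pairs, n_distinct_mrna, n_distinct_mirna).
#' @export
fit_all <- function(mrna, mirna, config = him_config(), design = NULL) {
  if (!identical(sample_ids(mrna), sample_ids(mirna)))
    stop("mRNA and miRNA matrices are not aligned to the same samples")
  if (!is.null(design) && !identical(design$sample_id, sample_ids(mrna)))
    stop("design is not aligned to the expression matrices")
  patients <- if (!is.null(design)) design$patient_id else NULL
  X <- t(mirna$values)
  fits <- lapply(feature_ids(mrna), function(j) {
    fit_one_mrna(mrna$values[j, ], X, config, patients = patients,
                 seed = derive_seed(j, config$seed))
  })
  names(fits) <- feature_ids(mrna)
  supports <- lapply(fits, `[[`, "support")
  mediated <- names(fits)[lengths(supports) > 0]
  orphans_mrna <- setdiff(names(fits), mediated)
  used_mirnas <- unique(unlist(supports, use.names = FALSE))
  orphans_mirna <- setdiff(feature_ids(mirna), used_mirnas)
  pairs <- if (length(mediated)) {
    do.call(rbind, lapply(mediated, function(j)
      data.frame(mrna_id = j, mirna_id = supports[[j]],
                 alpha = unname(fits[[j]]$alphas[supports[[j]]]),
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(mrna_id = character(0), mirna_id = character(0),
               alpha = numeric(0), stringsAsFactors = FALSE)
  }
  eta <- do.call(rbind, lapply(fits, `[[`, "eta"))
  resid <- do.call(rbind, lapply(fits, `[[`, "resid"))
  if (!is.null(eta)) dimnames(eta) <- dimnames(resid) <-
      list(names(fits), sample_ids(mrna))
  structure(list(fits = fits, eta = eta, resid = resid,
                 mediated_mrnas = mediated, orphan_mrnas = orphans_mrna,
                 orphan_mirnas = orphans_mirna, candidate_pairs = pairs,
                 summary = pair_counts(pairs)),
            class = "him_mech")
}

# (total pairs, # distinct mRNAs, # distinct miRNAs) reporting convention
pair_counts <- function(pairs) {
  c(n_pairs = nrow(pairs),
    n_distinct_mrna = length(unique(pairs$mrna_id)),
    n_distinct_mirna = length(unique(pairs$mirna_id)))
}

#' @export
print.him_mech <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<him_mech> %d mRNA fits: %d pairs (%d mRNA) (%d miRNA); ",
                     "%d orphan mRNAs, %d orphan miRNAs\n"),
              length(x$fits), s["n_pairs"], s["n_distinct_mrna"],
              s["n_distinct_mirna"], length(x$orphan_mrnas),
              length(x$orphan_mirnas)))
  invisible(x)
}

#' Serialize a mechanistic result
#'
#' Writes the nonzero-coefficient pair list, the eta and residual matrices,
#' and the molecule partitions as plain text under `dir`.
#'
#' @param mech A `him_mech`.
#' @param dir Output directory (created if needed).
#' @export
write_mechanistic <- function(mech, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(mech$candidate_pairs, file.path(dir, "mech_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("eta", "resid")) {
    m <- mech[[nm]]
    if (is.null(m)) m <- matrix(0, 0, 0)
    df <- data.frame(mrna_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(mech$orphan_mrnas, file.path(dir, "orphan_mrnas.txt"))
  writeLines(mech$orphan_mirnas, file.path(dir, "orphan_mirnas.txt"))
  invisible(dir)
}
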