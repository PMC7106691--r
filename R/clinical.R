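#' Build the clinical design matrix
#'
#' Assembles the predictors of the clinical submodel
#' `logit P(Y=1) = beta_0 + sum beta_eta_j eta_j + sum beta_e_j e_j +
#'  sum beta_k mRNA_k + sum beta_l miRNA_l`:
#' one ETA and one RESID column per mediated mRNA (its miRNA-driven linear
#' predictor and residual from the mechanistic submodel), plus one column of
#' log expression per orphan mRNA and orphan miRNA. Column roles are kept as
#' metadata; standardization happens inside the penalized fit.
#'
#' @param mech A `him_mech`.
#' @param mrna,mirna Log-scale `him_expr` objects covering at least the
#'   orphan molecules, sample-aligned to `design`.
#' @param design A complete `him_design` supplying the outcome Y (status).
#' @return A list of class `him_clinical_design`: `x` (samples x columns),
#'   `roles` (data frame column, role, molecule_id), `y`, `patients`.
#' @export
build_design <- function(mech, mrna, mirna, design) {
  samples <- design$sample_id
  if (!all(samples %in% sample_ids(mrna)) ||
      !all(samples %in% sample_ids(mirna)))
    stop("expression matrices are missing design samples")
  blocks <- list(); roles <- list()
  if (length(mech$mediated_mrnas)) {
    miss <- setdiff(mech$mediated_mrnas, rownames(mech$eta))
    if (length(miss))
      stop("mediated mRNA(s) missing eta/resid vectors: ",
           paste(miss, collapse = ", "))
    eta <- t(mech$eta[mech$mediated_mrnas, samples, drop = FALSE])
    res <- t(mech$resid[mech$mediated_mrnas, samples, drop = FALSE])
    colnames(eta) <- paste0("eta:", mech$mediated_mrnas)
    colnames(res) <- paste0("resid:", mech$mediated_mrnas)
    blocks <- c(blocks, list(eta, res))
    roles <- c(roles,
               list(data.frame(column = colnames(eta), role = "ETA",
                               molecule_id = mech$mediated_mrnas),
                    data.frame(column = colnames(res), role = "RESID",
                               molecule_id = mech$mediated_mrnas)))
  }
  add_orphans <- function(ids, expr, role, prefix) {
    if (!length(ids)) return()
    m <- t(expr$values[ids, samples, drop = FALSE])
    colnames(m) <- paste0(prefix, ids)
    blocks[[length(blocks) + 1L]] <<- m
    roles[[length(roles) + 1L]] <<-
      data.frame(column = colnames(m), role = role, molecule_id = ids)
  }
  add_orphans(mech$orphan_mrnas, mrna, "ORPHAN_MRNA", "mrna:")
  add_orphans(mech$orphan_mirnas, mirna, "ORPHAN_MIRNA", "mirna:")
  x <- if (length(blocks)) do.call(cbind, blocks)
       else matrix(0, nrow = length(samples), 0,
                   dimnames = list(samples, NULL))
  rownames(x) <- samples
  roles <- if (length(roles)) do.call(rbind, roles)
           else data.frame(column = character(0), role = character(0),
                           molecule_id = character(0))
  structure(list(x = x, roles = roles, y = design$status,
                 patients = design$patient_id),
            class = "him_clinical_design")
}

#' Fit the clinical submodel
#'
#' Lasso-penalized logistic regression of disease status on the clinical
#' design matrix, the penalty chosen by seeded patient-level k-fold
#' cross-validation on the binomial deviance. The intercept is unpenalized;
#' eta, residual, and orphan-molecule columns share a single global penalty.
#' Samples are treated as independent (no conditional pairing): the
#' tumor/normal dependence diagnostic motivates this assumption.
#'
#' @param cd A `him_clinical_design` with both outcome classes present.
#' @param config A [him_config()].
#' @return A list of class `him_clinical_fit`: `beta0`, `coefficients`
#'   (data frame column, role, molecule_id, beta — all columns, zeros
#'   included), `lambda_used`.
#' @export
fit_clinical <- function(cd, config = him_config()) {
  if (length(unique(cd$y)) < 2)
    stop("outcome has a single class; logistic fit undefined")
  # the coordinate-descent threshold needed for high-precision KKT checks on
  # gaussian fits stalls the binomial path near saturation; 1e-8 is ample
  # for the 1e-5 KKT tolerance of the logistic fit
  thresh <- max(config$glmnet_thresh, 1e-8)
  empty <- function(lambda) {
    cf <- cd$roles
    cf$beta <- numeric(nrow(cf))
    p1 <- mean(cd$y)
    structure(list(beta0 = log(p1 / (1 - p1)), coefficients = cf,
                   lambda_used = lambda), class = "him_clinical_fit")
  }
  if (ncol(cd$x) == 0) return(empty(Inf))
  seed <- derive_seed("clinical", config$seed)
  X <- cd$x
  if (ncol(X) == 1) X <- cbind(X, `.him_dummy` = 0)
  if (config$lambda_rule == "fixed") {
    fit <- glmnet::glmnet(X, cd$y, family = "binomial",
                          standardize = config$standardize,
                          thresh = thresh)
    lambda <- config$lambda_fixed
    cf <- glmnet::coef.glmnet(fit, s = lambda, exact = TRUE, x = X, y = cd$y,
                              standardize = config$standardize,
                              thresh = thresh)
  } else {
    n <- nrow(X)
    if (n < 2 * config$cv_folds) {
      message("n = ", n, " < 2 * cv_folds; using leave-one-out CV")
      foldid <- seq_len(n)
    } else {
      foldid <- make_foldid(cd$patients, config$cv_folds, seed)
    }
    cv <- with_seed(seed,
      glmnet::cv.glmnet(X, cd$y, family = "binomial",
                        type.measure = "deviance", foldid = foldid,
                        standardize = config$standardize,
                        thresh = thresh))
    lambda <- if (config$lambda_rule == "cv_min") cv$lambda.min else cv$lambda.1se
    cf <- glmnet::coef.glmnet(cv$glmnet.fit, s = lambda)
  }
  cf <- as.matrix(cf)[, 1]
  out <- cd$roles
  out$beta <- unname(cf[out$column])
  structure(list(beta0 = unname(cf["(Intercept)"]), coefficients = out,
                 lambda_used = lambda),
            class = "him_clinical_fit")
}

#' Emit miRNA-mRNA pairs from the clinical fit
#'
#' Applies the pair-emission rule: whenever the clinical submodel selects
#' the linear predictor eta_j (nonzero beta), the mRNA_j and every miRNA in
#' its mechanistic support are emitted as disease-associated pairs. Selected
#' residuals mark mRNAs whose disease effect bypasses their miRNAs; selected
#' orphan molecules are disease-associated on their own and join no pair.
#'
#' @param fit A `him_clinical_fit`.
#' @param mech The `him_mech` the clinical design was built from.
#' @return A list of class `him_pairs`: `pairs` (data frame mirna_id,
#'   mrna_id, alpha, beta_eta), `selected_etas`, `selected_resids`,
#'   `selected_orphan_mrnas`, `selected_orphan_mirnas`, and `summary`
#'   (n_pairs, n_distinct_mrna, n_distinct_mirna).
#' @export
emit_pairs <- function(fit, mech) {
  cf <- fit$coefficients
  sel <- function(role) cf$molecule_id[cf$role == role & cf$beta != 0]
  etas <- sel("ETA")
  pairs <- if (length(etas)) {
    do.call(rbind, lapply(etas, function(j) {
      sup <- mech$fits[[j]]$support
      data.frame(mirna_id = sup, mrna_id = j,
                 alpha = unname(mech$fits[[j]]$alphas[sup]),
                 beta_eta = cf$beta[cf$role == "ETA" & cf$molecule_id == j],
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(mirna_id = character(0), mrna_id = character(0),
               alpha = numeric(0), beta_eta = numeric(0),
               stringsAsFactors = FALSE)
  }
  structure(list(pairs = pairs, selected_etas = etas,
                 selected_resids = sel("RESID"),
                 selected_orphan_mrnas = sel("ORPHAN_MRNA"),
                 selected_orphan_mirnas = sel("ORPHAN_MIRNA"),
                 summary = pair_counts(pairs)),
            class = "him_pairs")
}

#' @export
print.him_pairs <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<him_pairs> %d pairs (%d mRNA) (%d miRNA); %d residual-driven mRNAs, %d+%d orphan molecules selected\n",
              s["n_pairs"], s["n_distinct_mrna"], s["n_distinct_mirna"],
              length(x$selected_resids), length(x$selected_orphan_mrnas),
              length(x$selected_orphan_mirnas)))
  invisible(x)
}

#' Serialize an emitted pair set
#'
#' Writes `pairset.tsv` (mirna_id, mrna_id, alpha, beta_eta),
#' `molecules.tsv` (molecule_id, role for selected non-pair molecules), and
#' `summary.json`.
#'
#' @param pairset A `him_pairs`.
#' @param dir Output directory.
#' @param config Optional `him_config` echoed into the summary JSON.
#' @export
write_pairs <- function(pairset, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(pairset$pairs, file.path(dir, "pairset.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mol_block <- function(ids, role)
    data.frame(molecule_id = ids, role = rep(role, length(ids)),
               stringsAsFactors = FALSE)
  mol <- rbind(
    mol_block(pairset$selected_resids, "RESID"),
    mol_block(pairset$selected_orphan_mrnas, "ORPHAN_MRNA"),
    mol_block(pairset$selected_orphan_mirnas, "ORPHAN_MIRNA"))
  utils::write.table(mol, file.path(dir, "molecules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  s <- as.list(pairset$summary)
  if (!is.null(config)) s$config <- unclass(config)
  jsonlite::write_json(s, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Pairwise-correlation baseline comparator
#'
#' Screens every miRNA x mRNA pair by Pearson correlation across samples,
#' adjusts the correlation p-values by Benjamini-Hochberg over all pairs,
#' and keeps pairs with `|r| > correlation_threshold` and
#' `fdr < fdr_threshold`. This is the traditional correlation-screening
#' comparison to the hierarchical model's disease-anchored pair selection.
#'
#' @param mrna,mirna Log-scale `him_expr` objects restricted to significant
#'   features, sample-aligned.
#' @param config A [him_config()] supplying both thresholds.
#' @return Data frame with columns `mirna_id`, `mrna_id`, `r`, `p_value`,
#'   `fdr`, one row per kept pair; the total number of screened pairs is in
#'   attribute `n_tested`.
#' @export
correlation_baseline <- function(mrna, mirna, config = him_config()) {
  if (!identical(sample_ids(mrna), sample_ids(mirna)))
    stop("mRNA and miRNA matrices are not aligned to the same samples")
  n <- ncol(mrna$values)
  r <- stats::cor(t(mirna$values), t(mrna$values))  # miRNA x mRNA
  r[is.na(r)] <- 0   # zero-variance features carry no association signal
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  fdr <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p))
  keep <- which(abs(r) > config$correlation_threshold &
                fdr < config$fdr_threshold, arr.ind = TRUE)
  out <- data.frame(mirna_id = rownames(r)[keep[, 1]],
                    mrna_id = colnames(r)[keep[, 2]],
                    r = r[keep], p_value = p[keep], fdr = fdr[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$fdr, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- length(r)
  out
}

#' Overlap between two pair lists
#'
#' @param a,b `him_pairs` objects or data frames with `mirna_id`, `mrna_id`.
#' @return Named vector: `n_shared`, `n_a`, `n_b`.
#' @export
overlap_pairs <- function(a, b) {
  key <- function(x) {
    df <- if (inherits(x, "him_pairs")) x$pairs else x
    paste(df$mirna_id, df$mrna_id, sep = "\r")
  }
  ka <- key(a); kb <- key(b)
  c(n_shared = length(intersect(ka, kb)), n_a = length(ka), n_b = length(kb))
}
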