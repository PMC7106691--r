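# Independent oracles, coded from definitions (never from the package's own
# implementation paths), used to cross-check the pipeline.

# Benjamini-Hochberg step-up, literal: sort p ascending, adj_(i) =
# min_{j >= i} p_(j) * m / j, capped at 1, mapped back to input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, ps[i] * m / i)
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Trimmed mean of M-values, transcribed from the definition: reference =
# sample whose 75th percentile of library-scaled counts is closest to the
# mean such percentile; per sample, gene-wise M = log2 ratio of proportions
# vs reference and A = average log2 proportion, genes with a zero in either
# sample excluded; double trim (30% per tail on M, 5% per tail on A, by
# ranks); weighted mean of remaining M with inverse asymptotic binomial
# variance weights; factor = 2^mean; factors rescaled to geometric mean 1.
tmm_oracle <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- counts[, ref]
  nr <- lib[ref]
  fac <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    ys <- counts[, s]; ns <- lib[s]
    keep <- ys > 0 & yr > 0
    M <- log2((ys[keep] / ns) / (yr[keep] / nr))
    A <- 0.5 * log2((ys[keep] / ns) * (yr[keep] / nr))
    # asymptotic (delta-method) variance of M for binomial counts
    v <- (ns - ys[keep]) / (ns * ys[keep]) + (nr - yr[keep]) / (nr * yr[keep])
    if (max(abs(M)) < 1e-6) { fac[s] <- 1; next }
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f <- sum(M[keep2] / v[keep2]) / sum(1 / v[keep2])
    fac[s] <- 2^f
  }
  fac[!is.finite(fac) | fac == 0] <- 1
  fac / exp(mean(log(fac)))
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# ---- fixture builders -------------------------------------------------------

rand_counts <- function(n_feat, n_samp, seed = 1, lambda = 100,
                        prefix = "f") {
  set.seed(seed)
  m <- matrix(stats::rpois(n_feat * n_samp, lambda), n_feat, n_samp)
  dimnames(m) <- list(paste0(prefix, seq_len(n_feat)),
                      paste0("s", seq_len(n_samp)))
  m
}

mk_design <- function(n_pat, prefix = "P") {
  pats <- sprintf("%s%03d", prefix, seq_len(n_pat))
  paired_design(sample_id = c(paste0(pats, "_T"), paste0(pats, "_N")),
                patient_id = rep(pats, 2),
                status = rep(c(1L, 0L), each = n_pat))
}

# log-scale expression matrix with sample order matching mk_design(n_pat)
mk_log_expr <- function(vals, kind = "mRNA") {
  expression_matrix(vals, kind, "log")
}

# X with centered columns and crossprod(X) == n * I (orthonormal in the
# 1/n inner product), so the lasso solution has a closed form
orthonormal_X <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(X))[, seq_len(p), drop = FALSE]
  X <- Q * sqrt(n)
  colnames(X) <- paste0("mir", seq_len(p))
  X
}

# minimal him_mech built by hand, for clinical-module tests that need a
# mechanistic result with prescribed supports
mk_mech <- function(supports, orphan_mrnas = character(0),
                    orphan_mirnas = character(0), n_samp = 12,
                    sample_names = paste0("s", seq_len(n_samp)), seed = 1) {
  set.seed(seed)
  mediated <- names(supports)[lengths(supports) > 0]
  all_mrnas <- c(names(supports), orphan_mrnas)
  fits <- lapply(names(supports), function(j) {
    sup <- supports[[j]]
    alphas <- stats::setNames(stats::runif(length(sup), 0.5, 1.5), sup)
    eta <- stats::rnorm(n_samp)
    structure(list(alpha0 = 0, alphas = alphas, eta = eta,
                   resid = stats::rnorm(n_samp), lambda_used = 0.1,
                   support = sup), class = "him_mech_fit")
  })
  names(fits) <- names(supports)
  eta <- do.call(rbind, lapply(fits, `[[`, "eta"))
  resid <- do.call(rbind, lapply(fits, `[[`, "resid"))
  if (!is.null(eta)) dimnames(eta) <- dimnames(resid) <-
      list(names(fits), sample_names)
  pairs <- if (length(mediated)) do.call(rbind, lapply(mediated, function(j)
    data.frame(mrna_id = j, mirna_id = supports[[j]],
               alpha = unname(fits[[j]]$alphas), stringsAsFactors = FALSE)))
    else data.frame(mrna_id = character(0), mirna_id = character(0),
                    alpha = numeric(0))
  structure(list(fits = fits, eta = eta, resid = resid,
                 mediated_mrnas = mediated,
                 orphan_mrnas = c(setdiff(names(supports), mediated),
                                  orphan_mrnas),
                 orphan_mirnas = orphan_mirnas, candidate_pairs = pairs,
                 summary = c(n_pairs = nrow(pairs),
                             n_distinct_mrna = length(unique(pairs$mrna_id)),
                             n_distinct_mirna = length(unique(pairs$mirna_id)))),
            class = "him_mech")
}

# minimal him_clinical_fit with prescribed nonzero betas
mk_clin_fit <- function(roles_df, nonzero = character(0), betas = NULL) {
  roles_df$beta <- 0
  if (length(nonzero)) {
    if (is.null(betas)) betas <- rep(1, length(nonzero))
    roles_df$beta[match(nonzero, roles_df$column)] <- betas
  }
  structure(list(beta0 = 0, coefficients = roles_df, lambda_used = 0.05),
            class = "him_clinical_fit")
}
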