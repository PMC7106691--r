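#' TMM scaling factors
#'
#' Between-sample normalization factors by the trimmed mean of M-values
#' method: the reference sample is the column whose 75th percentile of
#' library-size-scaled counts is closest to the mean such percentile;
#' each sample's factor is the weighted trimmed mean of gene-wise
#' log2-fold-changes to the reference (30% trim on M, 5% on A,
#' inverse-asymptotic-variance weights, zero-count genes excluded), and the
#' factors are rescaled to geometric mean 1.
#'
#' @param expr A `him_expr` on the raw scale with at least two samples.
#' @return Named numeric vector of per-sample factors; multiplying each
#'   library size by its factor gives the effective library size.
#' @export
tmm_factors <- function(expr) {
  stopifnot(inherits(expr, "him_expr"))
  if (expr$scale != "raw") stop("TMM expects raw counts, got scale=", expr$scale)
  v <- expr$values
  if (ncol(v) < 2) stop("TMM needs at least 2 samples")
  zero <- colSums(v) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(v)[zero], collapse = ", "))
  f <- edgeR::calcNormFactors(v, method = "TMM")
  names(f) <- colnames(v)
  f
}

#' TMM-normalize a raw expression matrix
#'
#' Divides each column by its effective library size (library size times TMM
#' factor) and rescales to the geometric mean of the effective library sizes,
#' so normalized values stay on the magnitude of the input counts.
#'
#' @param expr A `him_expr` on the raw scale.
#' @param factors Optional precomputed [tmm_factors()]; computed if missing.
#' @return A `him_expr` with `scale = "normalized"`.
#' @export
normalize_tmm <- function(expr, factors = NULL) {
  if (is.null(factors)) factors <- tmm_factors(expr)
  eff <- colSums(expr$values) * factors[colnames(expr$values)]
  scale_to <- exp(mean(log(eff)))
  out <- expr
  out$values <- sweep(expr$values, 2, eff / scale_to, "/")
  out$scale <- "normalized"
  out
}

#' Log-transform expression values
#'
#' `value <- log_base(value + pseudocount)`, applied elementwise; renders
#' count distributions roughly symmetric ahead of linear modeling.
#'
#' @param expr A `him_expr` with nonnegative values.
#' @param log_base,pseudocount Transform parameters (defaults: base 2,
#'   pseudocount 1).
#' @return A `him_expr` with `scale = "log"`; the parameters are kept as
#'   attributes so [inverse_log_transform()] can invert exactly.
#' @export
log_transform <- function(expr, log_base = 2, pseudocount = 1) {
  if (any(expr$values < 0)) stop("log transform requires nonnegative values")
  if (expr$scale == "log") stop("matrix is already on the log scale")
  out <- expr
  out$values <- log(expr$values + pseudocount, base = log_base)
  out$scale <- "log"
  attr(out, "log_base") <- log_base
  attr(out, "pseudocount") <- pseudocount
  out
}

#' @rdname log_transform
#' @export
inverse_log_transform <- function(expr) {
  if (expr$scale != "log") stop("matrix is not on the log scale")
  b <- attr(expr, "log_base") %||% 2
  pc <- attr(expr, "pseudocount") %||% 1
  out <- expr
  out$values <- b^expr$values - pc
  out$values[abs(out$values) < 1e-12] <- abs(out$values[abs(out$values) < 1e-12])
  out$scale <- "raw"
  attr(out, "log_base") <- NULL
  attr(out, "pseudocount") <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split an aligned matrix into tumor and normal halves with matched
# patient columns; relies on the design being complete and aligned.
split_paired <- function(expr, design) {
  stopifnot(all(design$sample_id %in% sample_ids(expr)))
  tum <- design[design$status == 1, ]
  nor <- design[design$status == 0, ]
  nor <- nor[match(tum$patient_id, nor$patient_id), ]
  list(tumor = expr$values[, tum$sample_id, drop = FALSE],
       normal = expr$values[, nor$sample_id, drop = FALSE],
       patients = tum$patient_id)
}

#' Paired differential expression test
#'
#' For each feature, a paired t-test on within-patient tumor-minus-normal
#' differences of (log-scale) expression, with Benjamini-Hochberg adjustment
#' across all features of the matrix. Fold changes are computed from raw
#' medians — median(raw tumor) / median(raw normal) — when the raw-scale
#' matrix is supplied, honoring the convention that testing happens on
#' normalized log values while fold changes stay on the raw scale.
#'
#' @param expr A `him_expr` (log scale recommended), sample-aligned to
#'   `design`.
#' @param design A complete `him_design` with >= 3 pairs.
#' @param raw_expr Optional raw-scale `him_expr` with the same features and
#'   samples, used for fold changes; `NA` fold changes otherwise.
#' @param fdr_threshold Cutoff defining the `passes` flag (strict `<`).
#' @return A data frame of class `him_diff` with columns `feature_id`,
#'   `t_stat`, `p_value`, `fdr`, `fold_change`, `passes`, `degenerate`,
#'   `fc_undefined`. Features whose difference vector has zero variance are
#'   flagged degenerate with `p_value = 1` and never pass.
#' @export
paired_ttest <- function(expr, design, raw_expr = NULL,
                         fdr_threshold = 0.05) {
  sp <- split_paired(expr, design)
  n <- length(sp$patients)
  if (n < 3) stop("paired t-test needs at least 3 complete pairs")
  d <- sp$tumor - sp$normal
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  degen <- s == 0
  t_stat <- ifelse(degen, NA_real_, m / (s / sqrt(n)))
  p <- ifelse(degen, 1, 2 * stats::pt(-abs(t_stat), df = n - 1))
  fdr <- stats::p.adjust(p, method = "BH")
  fc <- rep(NA_real_, nrow(d))
  fc_undef <- rep(FALSE, nrow(d))
  if (!is.null(raw_expr)) {
    if (!setequal(feature_ids(raw_expr), feature_ids(expr)))
      stop("raw_expr features do not match expr features")
    spr <- split_paired(raw_expr, design)
    med_t <- apply(spr$tumor[feature_ids(expr), , drop = FALSE], 1, stats::median)
    med_n <- apply(spr$normal[feature_ids(expr), , drop = FALSE], 1, stats::median)
    fc <- med_t / med_n
    fc_undef <- med_n == 0
    fc[fc_undef & med_t > 0] <- Inf
    fc[fc_undef & med_t == 0] <- NA_real_
  }
  structure(data.frame(feature_id = feature_ids(expr), t_stat = t_stat,
                       p_value = p, fdr = fdr, fold_change = fc,
                       passes = fdr < fdr_threshold & !degen,
                       degenerate = degen, fc_undefined = fc_undef,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("him_diff", "data.frame"))
}

#' Select significant features from a differential table
#'
#' @param table A `him_diff`.
#' @param threshold FDR cutoff, strict inequality.
#' @return Character vector of feature IDs with `fdr < threshold` (excluding
#'   degenerate features), ordered by ascending FDR then feature ID.
#' @export
select_significant <- function(table, threshold = 0.05) {
  keep <- table[table$fdr < threshold & !table$degenerate, , drop = FALSE]
  keep <- keep[order(keep$fdr, keep$feature_id), , drop = FALSE]
  keep$feature_id
}

#' Drop features with too many missing cells
#'
#' Features whose missing fraction exceeds `max_missing_fraction` are
#' removed. Any missing cells that remain must be resolved explicitly:
#' `fill = "zero"` sets them to 0, the default `"error"` refuses.
#'
#' @param expr A `him_expr`, possibly with `NA` cells.
#' @param max_missing_fraction Tolerated missing fraction per feature.
#' @param fill `"error"` or `"zero"`.
#' @return A `him_expr` without missing cells.
#' @export
drop_sparse_features <- function(expr, max_missing_fraction = 0.9,
                                 fill = c("error", "zero")) {
  fill <- match.arg(fill)
  frac <- rowMeans(is.na(expr$values))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stop("all features exceed the missing-fraction threshold")
  out <- expr
  out$values <- expr$values[keep, , drop = FALSE]
  if (anyNA(out$values)) {
    if (fill == "error")
      stop("missing cells remain after feature dropping; set fill = 'zero' to zero-fill explicitly")
    out$values[is.na(out$values)] <- 0
  }
  out
}

#' Tumor/normal dependence diagnostic
#'
#' Per feature, the Pearson correlation between the tumor vector and the
#' matched normal vector across patients, and the fraction of features whose
#' |r| falls below a threshold. Low correlations justify modeling the two
#' tissue groups as independent rather than with per-patient random effects.
#'
#' @param expr A `him_expr` (log scale), aligned to `design`.
#' @param design A complete `him_design` with >= 3 pairs.
#' @param threshold |r| cutoff for `fraction_below`.
#' @return A list of class `him_dependence`: `table` (feature_id, r,
#'   degenerate) and `fraction_below`. Constant tumor or normal vectors get
#'   r recorded as 0 with a degeneracy flag and are excluded from the
#'   fraction.
#' @export
dependence_report <- function(expr, design, threshold = 0.3) {
  sp <- split_paired(expr, design)
  if (length(sp$patients) < 3) stop("dependence report needs >= 3 pairs")
  r <- vapply(seq_len(nrow(sp$tumor)), function(i) {
    x <- sp$tumor[i, ]; y <- sp$normal[i, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else stats::cor(x, y)
  }, numeric(1))
  degen <- is.na(r)
  tab <- data.frame(feature_id = feature_ids(expr),
                    r = ifelse(degen, 0, r), degenerate = degen,
                    stringsAsFactors = FALSE)
  frac <- if (all(degen)) NA_real_ else mean(abs(r[!degen]) < threshold)
  structure(list(table = tab, fraction_below = frac, threshold = threshold),
            class = "him_dependence")
}

#' @export
print.him_dependence <- function(x, ...) {
  cat(sprintf("<him_dependence> %d features; %.1f%% with |r| < %g\n",
              nrow(x$table), 100 * x$fraction_below, x$threshold))
  invisible(x)
}
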