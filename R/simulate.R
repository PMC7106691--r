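#' Ground truth for a simulated paired tumor/normal study
#'
#' Defines the generative structure the hierarchical model assumes: a sparse
#' mRNA x miRNA regulatory coefficient matrix A, three disjoint disease
#' channels — mRNAs whose tumor effect flows through their regulator miRNAs
#' (the eta channel), mRNAs with a direct residual-channel tumor shift, and
#' directly shifted miRNAs — plus effect sizes, noise level, and cohort
#' size. True pairs are the nonzero A entries of eta-channel mRNAs.
#'
#' Presets (all 200 mRNAs x 60 miRNAs, 30 patients; the non-null presets
#' carry 5 eta-channel mRNAs with 3 disjoint regulators each, i.e. 15 true
#' pairs, and no other disease channel):
#' \describe{
#'   \item{null}{no regulation, no disease effects — exchangeable groups.}
#'   \item{easy}{2.0 log2-unit shifts, noise sd 0.25.}
#'   \item{default}{1.5 log2-unit shifts, noise sd 0.5.}
#'   \item{hard}{0.75 log2-unit shifts, noise sd 0.75.}
#' }
#' The residual-channel and direct-miRNA channels are exercised through the
#' explicit parameters rather than the presets.
#'
#' Regulator miRNAs of eta-channel mRNAs receive tumor shifts whose sign
#' matches their regulatory coefficient, so every regulator pushes its mRNA
#' in the same direction in tumors (coherent dysregulation).
#'
#' @param preset One of `"null"`, `"easy"`, `"default"`, `"hard"`; or `NULL`
#'   to use the explicit parameters.
#' @param n_patients,n_mrna,n_mirna Cohort and panel sizes.
#' @param n_eta_mrnas Number of eta-channel mRNAs.
#' @param regulators_per_mrna True regulators per eta-channel mRNA
#'   (regulator sets are disjoint across mRNAs).
#' @param n_resid_mrnas,n_direct_mirnas Sizes of the other two channels.
#' @param effect_size Tumor shift in log2 units.
#' @param noise_sd Log2-scale Gaussian noise standard deviation.
#' @param coef_magnitude Magnitude of nonzero regulatory coefficients
#'   (signs drawn at random).
#' @param vary_libsize Draw per-sample library-size factors log-uniform in
#'   \[0.5, 2\] (so TMM has something to correct); `FALSE` fixes them at 1.
#' @param seed Integer seed; all structural draws and [simulate_dataset()]
#'   noise derive from it.
#' @return A list of class `him_truth`.
#' @export
simulation_truth <- function(preset = NULL, n_patients = 30, n_mrna = 200,
                             n_mirna = 60, n_eta_mrnas = 5,
                             regulators_per_mrna = 3, n_resid_mrnas = 0,
                             n_direct_mirnas = 0, effect_size = 1.5,
                             noise_sd = 0.5, coef_magnitude = 1,
                             vary_libsize = TRUE, seed = 1) {
  if (!is.null(preset)) {
    presets <- list(
      null    = list(n_eta_mrnas = 0, n_resid_mrnas = 0, n_direct_mirnas = 0,
                     effect_size = 0, noise_sd = 0.5),
      easy    = list(effect_size = 2.0, noise_sd = 0.25),
      default = list(),
      hard    = list(effect_size = 0.75, noise_sd = 0.75))
    if (!preset %in% names(presets))
      stop("unknown preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "))
    for (nm in names(presets[[preset]]))
      assign(nm, presets[[preset]][[nm]])
  }
  need_mirna <- n_eta_mrnas * regulators_per_mrna + n_direct_mirnas
  if (need_mirna > n_mirna)
    stop("channels need ", need_mirna, " miRNAs but panel has ", n_mirna)
  if (n_eta_mrnas + n_resid_mrnas > n_mrna)
    stop("channels need more mRNAs than the panel has")
  mrna_ids <- sprintf("gene%03d", seq_len(n_mrna))
  mirna_ids <- sprintf("mir%03d", seq_len(n_mirna))
  st <- with_seed(seed, {
    perm_g <- sample(mrna_ids)
    perm_m <- sample(mirna_ids)
    eta_mrnas <- sort(perm_g[seq_len(n_eta_mrnas)])
    resid_mrnas <- sort(perm_g[n_eta_mrnas + seq_len(n_resid_mrnas)])
    reg <- perm_m[seq_len(n_eta_mrnas * regulators_per_mrna)]
    direct <- sort(perm_m[n_eta_mrnas * regulators_per_mrna +
                            seq_len(n_direct_mirnas)])
    A <- matrix(0, n_mrna, n_mirna, dimnames = list(mrna_ids, mirna_ids))
    mirna_shift <- stats::setNames(numeric(n_mirna), mirna_ids)
    if (n_eta_mrnas > 0) {
      for (i in seq_len(n_eta_mrnas)) {
        regs <- reg[(i - 1) * regulators_per_mrna + seq_len(regulators_per_mrna)]
        signs <- sample(c(-1, 1), regulators_per_mrna, replace = TRUE)
        A[eta_mrnas[i], regs] <- coef_magnitude * signs
        mirna_shift[regs] <- effect_size * signs
      }
    }
    if (n_direct_mirnas > 0)
      mirna_shift[direct] <- effect_size *
        sample(c(-1, 1), n_direct_mirnas, replace = TRUE)
    resid_shift <- stats::setNames(numeric(n_mrna), mrna_ids)
    if (n_resid_mrnas > 0)
      resid_shift[resid_mrnas] <- effect_size *
        sample(c(-1, 1), n_resid_mrnas, replace = TRUE)
    list(eta_mrnas = eta_mrnas, resid_mrnas = resid_mrnas,
         direct_mirnas = direct, A = A, mirna_shift = mirna_shift,
         resid_shift = resid_shift)
  })
  structure(list(A = st$A, disease_eta_mrnas = st$eta_mrnas,
                 disease_resid_mrnas = st$resid_mrnas,
                 disease_mirnas = st$direct_mirnas,
                 mirna_shift = st$mirna_shift, resid_shift = st$resid_shift,
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_patients = n_patients, n_mrna = n_mrna,
                 n_mirna = n_mirna, vary_libsize = vary_libsize,
                 seed = as.integer(seed)),
            class = "him_truth")
}

#' True disease-associated pairs of a simulation truth
#'
#' @param truth A `him_truth`.
#' @return Data frame `mirna_id`, `mrna_id`, `alpha` — the nonzero A entries
#'   of eta-channel mRNAs.
#' @export
truth_pairs <- function(truth) {
  rows <- which(truth$A[truth$disease_eta_mrnas, , drop = FALSE] != 0,
                arr.ind = TRUE)
  data.frame(mirna_id = colnames(truth$A)[rows[, 2]],
             mrna_id = truth$disease_eta_mrnas[rows[, 1]],
             alpha = truth$A[truth$disease_eta_mrnas, , drop = FALSE][rows],
             stringsAsFactors = FALSE)
}

#' Simulate a paired tumor/normal expression dataset
#'
#' On the log2 scale: miRNA abundance = feature baseline (Uniform(4,10)) +
#' tumor shift (disease channels only) + Gaussian noise; mRNA abundance =
#' feature baseline + A x (centered miRNA abundance) + residual tumor shift
#' + Gaussian noise. Abundances are exponentiated, multiplied by per-sample
#' library-size factors (log-uniform in \[0.5, 2\]) and rounded to counts —
#' the lognormal layer plus rounding yields overdispersed, negative-
#' binomial-like counts while keeping the log-scale linear model exact.
#' Fully reproducible from `truth$seed`.
#'
#' @param truth A [simulation_truth()].
#' @return List with `mrna` and `mirna` (raw-scale `him_expr`), `design`
#'   (a `him_design`), and `truth`.
#' @export
simulate_dataset <- function(truth) {
  stopifnot(inherits(truth, "him_truth"))
  n_pat <- truth$n_patients
  n_s <- 2L * n_pat
  patients <- sprintf("P%03d", seq_len(n_pat))
  design <- paired_design(
    sample_id = c(paste0(patients, "_T"), paste0(patients, "_N")),
    patient_id = rep(patients, 2), status = rep(c(1L, 0L), each = n_pat))
  with_seed(truth$seed + 7L, {
    mu_mir <- stats::runif(truth$n_mirna, 4, 10)
    mu_g <- stats::runif(truth$n_mrna, 4, 10)
    tumor <- design$status
    z_mir <- matrix(mu_mir, truth$n_mirna, n_s) +
      outer(truth$mirna_shift, tumor) +
      matrix(stats::rnorm(truth$n_mirna * n_s, sd = truth$noise_sd),
             truth$n_mirna, n_s)
    rownames(z_mir) <- colnames(truth$A)
    z_g <- matrix(mu_g, truth$n_mrna, n_s) +
      truth$A %*% (z_mir - mu_mir) +
      outer(truth$resid_shift, tumor) +
      matrix(stats::rnorm(truth$n_mrna * n_s, sd = truth$noise_sd),
             truth$n_mrna, n_s)
    rownames(z_g) <- rownames(truth$A)
    lib <- if (truth$vary_libsize)
      exp(stats::runif(n_s, log(0.5), log(2))) else rep(1, n_s)
    mk <- function(z, kind) {
      counts <- round(sweep(2^z, 2, lib, "*"))
      colnames(counts) <- design$sample_id
      expression_matrix(counts, kind, "raw")
    }
    list(mrna = mk(z_g, "mRNA"), mirna = mk(z_mir, "miRNA"),
         design = design, truth = truth)
  })
}

#' Score recovery of true pairs
#'
#' Standard set-overlap metrics of an estimated pair set against the truth.
#' An empty estimate has precision 1 by convention (flagged via
#' `empty_estimate`); recall is then 0 unless the truth is empty too.
#'
#' @param estimated A `him_pairs` or data frame with `mirna_id`, `mrna_id`.
#' @param truth A `him_truth`.
#' @return Named list: `precision`, `recall`, `f1`, `n_estimated`, `n_true`,
#'   `mrna_recall`, `mirna_recall`, `empty_estimate`.
#' @export
score_recovery <- function(estimated, truth) {
  est <- if (inherits(estimated, "him_pairs")) estimated$pairs else estimated
  tp <- truth_pairs(truth)
  ke <- paste(est$mirna_id, est$mrna_id, sep = "\r")
  kt <- paste(tp$mirna_id, tp$mrna_id, sep = "\r")
  hits <- length(intersect(ke, kt))
  precision <- if (length(ke) == 0) 1 else hits / length(ke)
  recall <- if (length(kt) == 0) 1 else hits / length(kt)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_estimated = length(ke), n_true = length(kt),
       mrna_recall = if (nrow(tp)) length(intersect(unique(est$mrna_id),
                                                    unique(tp$mrna_id))) /
                       length(unique(tp$mrna_id)) else 1,
       mirna_recall = if (nrow(tp)) length(intersect(unique(est$mirna_id),
                                                     unique(tp$mirna_id))) /
                        length(unique(tp$mirna_id)) else 1,
       empty_estimate = length(ke) == 0)
}
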