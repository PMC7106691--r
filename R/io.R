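#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample IDs and a first column of feature IDs;
#' the body must be numeric. Field separator is taken from the file
#' extension (`.csv` = comma, otherwise tab) unless given explicitly.
#'
#' @param path File path.
#' @param feature_kind `"mRNA"` or `"miRNA"`.
#' @param sep Field separator; default inferred from extension.
#' @param na_strings Tokens treated as missing cells (only meaningful with
#'   `allow_missing = TRUE`).
#' @param allow_missing Permit missing cells, to be resolved by
#'   [drop_sparse_features()] before any modeling.
#' @return A `him_expr` with `scale = "raw"`, column order preserved.
#' @export
read_expression <- function(path, feature_kind = c("mRNA", "miRNA"),
                            sep = NULL, na_strings = c("", "NA"),
                            allow_missing = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("expression file needs a header and >=1 feature row")
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  # header may or may not carry a stub for the feature-ID column
  body_w <- widths[-1]
  if (length(unique(body_w)) != 1)
    stop("ragged rows: lines ", paste(which(body_w != body_w[1]) + 1, collapse = ", "),
         " have inconsistent field counts")
  n_samp <- body_w[1] - 1L
  header <- cells[[1]]
  samples <- if (widths[1] == body_w[1]) header[-1] else header
  if (length(samples) != n_samp)
    stop("header has ", length(samples), " sample IDs but rows have ",
         n_samp, " value fields")
  fids <- vapply(cells[-1], `[`, "", 1L)
  dup <- unique(fids[duplicated(fids)])
  if (length(dup))
    stop("duplicate feature IDs: ", paste(dup, collapse = ", "))
  vals <- matrix(NA_real_, nrow = length(fids), ncol = n_samp,
                 dimnames = list(fids, samples))
  for (i in seq_along(fids)) {
    raw <- cells[[i + 1L]][-1L]
    miss <- raw %in% na_strings
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !miss)
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d (feature '%s'), column %d (sample '%s'): '%s'",
                   i, fids[i], bad[1], samples[bad[1]], raw[bad[1]]))
    num[miss] <- NA_real_
    vals[i, ] <- num
  }
  if (!allow_missing && anyNA(vals))
    stop("missing cells found; re-read with allow_missing = TRUE and use drop_sparse_features()")
  expression_matrix(vals, feature_kind, "raw", allow_missing = allow_missing)
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression()] up to floating-point formatting (values
#' round-trip within 1e-12 relative tolerance).
#'
#' @param expr A `him_expr`.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(feature_id = rownames(expr$values),
                   expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a paired design table
#'
#' Tab-delimited with columns `sample_id`, `patient_id`, `status`
#' (1 = tumor, 0 = adjacent normal). Incomplete pairs are tolerated at read
#' time; [align_design()] resolves them.
#'
#' @param path File path.
#' @return A `him_design` (possibly incomplete).
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design file missing columns: ", paste(miss, collapse = ", "))
  paired_design(df$sample_id, df$patient_id, df$status,
                allow_incomplete = TRUE)
}

#' @rdname read_design
#' @param design A `him_design`.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path (`.json` parsed as JSON, anything else as YAML).
#' @return A `him_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(him_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(him_config, vals)
}

#' Align an expression matrix to a paired design
#'
#' Restricts to samples present in both, drops any patient lacking a
#' complete tumor/normal pair (both samples go together, with a warning),
#' and reorders columns to the design order.
#'
#' @param expr A `him_expr`.
#' @param design A `him_design`, possibly incomplete.
#' @return A list with elements `expr` (columns reordered) and `design`
#'   (complete, satisfying all pairing invariants).
#' @export
align_design <- function(expr, design) {
  common <- intersect(design$sample_id, sample_ids(expr))
  if (!length(common))
    stop("no sample IDs shared between expression matrix and design")
  d <- design[design$sample_id %in% common, , drop = FALSE]
  tab <- table(d$patient_id)
  incomplete <- names(tab)[tab != 2L]
  if (length(incomplete)) {
    dropped <- d$sample_id[d$patient_id %in% incomplete]
    warning("dropping samples without a complete tumor/normal pair: ",
            paste(dropped, collapse = ", "))
    d <- d[!d$patient_id %in% incomplete, , drop = FALSE]
  }
  if (length(unique(d$patient_id)) < 3)
    stop("fewer than 3 complete tumor/normal pairs remain after alignment")
  d <- paired_design(d$sample_id, d$patient_id, d$status)
  out <- expr
  out$values <- expr$values[, d$sample_id, drop = FALSE]
  list(expr = out, design = d)
}
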