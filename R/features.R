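#' Row-wise Z-score of a gene's value in one column
#'
#' Standardises the gene's value in the given column against the gene's own
#' row across all columns of the normalised cohort matrix:
#' `(V - mu_R) / sigma_R` with the population (divide-by-n) standard
#' deviation. A high row Z-score means the gene is abundant in this
#' population relative to its own levels elsewhere in the cohort -- the
#' quantity behind the Gene-Present / Gene-Absent notions.
#'
#' @param m_prime Normalised cohort matrix (see
#'   [trimmed_quantile_normalize()]).
#' @param gene Gene symbol.
#' @param column Column index or label.
#' @param strict With a constant row (`sigma_R = 0`), error when `TRUE`;
#'   otherwise (default) return 0 with a warning. All-zero imputed rows can
#'   occur for genes measured in only one study, so the lenient default
#'   keeps the pipeline total.
#' @return A single Z-score.
#' @export
row_zscore <- function(m_prime, gene, column, strict = FALSE) {
  v <- cohort_values(m_prime)
  if (!gene %in% rownames(v)) stop_ctap("gene '", gene, "' not in matrix")
  row <- v[gene, ]
  zscore_or_degenerate(row[[column]], mean(row), pop_sd(row),
                       sprintf("constant row for gene '%s'", gene), strict)
}

#' Column-wise Z-score of a gene's value in one column
#'
#' Standardises the gene's value against all genes of that column
#' (`(V - mu_C) / sigma_C`, population standard deviation): where the gene
#' sits in this population's overall intensity distribution.
#'
#' @inheritParams row_zscore
#' @export
col_zscore <- function(m_prime, gene, column, strict = FALSE) {
  v <- cohort_values(m_prime)
  if (!gene %in% rownames(v)) stop_ctap("gene '", gene, "' not in matrix")
  col <- v[, column]
  zscore_or_degenerate(col[[gene]], mean(col), pop_sd(col),
                       sprintf("constant column '%s'", as.character(column)),
                       strict)
}

zscore_or_degenerate <- function(x, mu, sigma, what, strict) {
  if (sigma > 0) return((x - mu) / sigma)
  if (strict) stop_ctap("degenerate Z-score: ", what)
  warning("degenerate Z-score (", what, "); returning 0", call. = FALSE)
  0
}

cohort_values <- function(m) if (inherits(m, "cohort_matrix")) m$values else m

#' Assemble the five-feature vector of a gene in one comparison pair
#'
#' The classifier's feature contract, in fixed order: (1) the CP's log2 fold
#' change, (2) column Z-score in the control column, (3) column Z-score in
#' the test column, (4) row Z-score at the control column, (5) row Z-score
#' at the test column.
#'
#' @param cp A `comparison_pair` (used for the log2 fold change; a gene
#'   absent from it is an error).
#' @param m_prime Normalised cohort matrix containing the CP's two columns.
#' @param gene Gene symbol.
#' @param strict Passed to the Z-score helpers.
#' @return Named numeric vector of length 5
#'   (`log2fc`, `z_col_control`, `z_col_test`, `z_row_control`,
#'   `z_row_test`).
#' @export
assemble_features <- function(cp, m_prime, gene, strict = FALSE) {
  stopifnot(inherits(cp, "comparison_pair"))
  if (!gene %in% names(cp$log2fc))
    stop_ctap("gene '", gene, "' absent from CP ", cp$cp_id, "'s log2fc")
  cols <- cp_columns(m_prime, cp$cp_id)
  c(log2fc = unname(cp$log2fc[[gene]]),
    z_col_control = col_zscore(m_prime, gene, cols[["control"]], strict),
    z_col_test = col_zscore(m_prime, gene, cols[["test"]], strict),
    z_row_control = row_zscore(m_prime, gene, cols[["control"]], strict),
    z_row_test = row_zscore(m_prime, gene, cols[["test"]], strict))
}

# vectorised feature assembly over genes x CPs; returns a data.frame with
# one row per (gene, cp). Precomputes row/column statistics once: the
# per-call operations above are the readable contract, this is the fast path.
feature_table <- function(cohort, genes, cp_ids = NULL) {
  stopifnot(inherits(cohort, "ctap_cohort"))
  v <- cohort$m_prime$values
  cp_ids <- cp_ids %||% cohort$m_prime$cp_ids
  row_mu <- rowMeans(v)
  row_sd <- apply(v, 1L, pop_sd)
  col_mu <- colMeans(v)
  col_sd <- apply(v, 2L, pop_sd)
  safe_z <- function(x, mu, s) {
    z <- (x - mu) / s
    z[rep_len(s <= 0, length(z))] <- 0  # degenerate rows/columns score 0
    z
  }
  out <- vector("list", length(cp_ids))
  for (i in seq_along(cp_ids)) {
    cp <- cohort$cps[[match(cp_ids[i], cohort$m_prime$cp_ids)]]
    cols <- cp_columns(cohort$m_prime, cp$cp_id)
    present <- genes %in% rownames(v)
    if (any(!present))
      stop_ctap("gene(s) not in cohort matrix: ",
                paste(genes[!present], collapse = ", "))
    fc <- ifelse(genes %in% names(cp$log2fc), cp$log2fc[genes], 0)
    out[[i]] <- data.frame(
      gene = genes, cp_id = cp$cp_id, context = cp$context,
      log2fc = unname(fc),
      z_col_control = safe_z(v[genes, cols[["control"]]],
                             col_mu[cols[["control"]]], col_sd[cols[["control"]]]),
      z_col_test = safe_z(v[genes, cols[["test"]]],
                          col_mu[cols[["test"]]], col_sd[cols[["test"]]]),
      z_row_control = safe_z(v[genes, cols[["control"]]],
                             row_mu[genes], row_sd[genes]),
      z_row_test = safe_z(v[genes, cols[["test"]]],
                          row_mu[genes], row_sd[genes]),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

feature_columns <- c("log2fc", "z_col_control", "z_col_test",
                     "z_row_control", "z_row_test")
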