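#' Decompose one column for trimmed quantile normalisation
#'
#' Stable-sorts a column (by value, then gene symbol, so the restoring
#' permutation is deterministic), cuts `trim_fraction` of the genes from each
#' tail, and computes the middle-part statistics used by the tail ramp:
#' mean, population standard deviation, middle Z-scores, and the counts of
#' middle genes with positive/negative Z.
#'
#' @param x Numeric column vector, named by gene symbol (names optional).
#' @param trim_fraction Fraction in (0, 0.5) trimmed from each tail; the
#'   number of genes cut per tail is `floor(trim_fraction * length(x))`.
#' @return A list of class `column_decomposition` with elements `order` (the
#'   sorting permutation), `small`, `middle`, `large` (sorted value blocks),
#'   `mu`, `sigma`, `z_m`, `n_pos`, `n_neg`, and `anchor` (index into the
#'   middle block of the gene whose Z-score is nearest 0, ties toward the
#'   lower index).
#' @export
decompose_column <- function(x, trim_fraction) {
  if (trim_fraction <= 0 || trim_fraction >= 0.5)
    stop_ctap("trim_fraction must lie in (0, 0.5)")
  n <- length(x)
  k <- floor(trim_fraction * n)
  if (n - 2L * k < 3L)
    stop_ctap("middle part smaller than 3 values after trimming")
  nm <- names(x) %||% as.character(seq_len(n))
  ord <- order(x, nm)  # stable tie-break by symbol
  sorted <- x[ord]
  small <- sorted[seq_len(k)]
  large <- if (k > 0L) sorted[seq.int(n - k + 1L, n)] else sorted[0L]
  middle <- sorted[seq.int(k + 1L, n - k)]
  mu <- mean(middle)
  sigma <- pop_sd(middle)
  z_m <- if (sigma > 0) (middle - mu) / sigma else rep(0, length(middle))
  structure(
    list(order = ord, small = small, middle = middle, large = large,
         mu = mu, sigma = sigma, z_m = z_m,
         n_pos = sum(z_m > 0), n_neg = sum(z_m < 0),
         anchor = which.min(abs(z_m))),
    class = "column_decomposition")
}

#' Revise a trimmed tail on the middle-part Z-ramp
#'
#' Replaces the trimmed tail values of one column by points on a linear ramp
#' that continues the middle part's Z-score range outward. The step per rank
#' is `|extreme(Z_m)| / N_side * sigma`, where the extreme is `max(Z_m)` for
#' the large tail (with `N_side = n_pos`) and `min(Z_m)` for the small tail
#' (`N_side = n_neg`). Ranks count outward from the middle gene whose
#' Z-score is nearest 0 (rank 0 at that anchor), so the innermost trimmed
#' gene sits at rank `N_side + 1` -- one step beyond the most extreme middle
#' gene -- and the ramp strictly preserves the column's ordering. Large-tail
#' replacements lie above the middle mean, small-tail replacements below it.
#'
#' @param decomp A `column_decomposition` computed on the
#'   quantile-normalised middle part.
#' @param side `"small"` or `"large"`.
#' @return Revised values in the same (ascending) order as the tail block;
#'   empty when the trim rounded to zero genes.
#' @export
revise_tail <- function(decomp, side = c("small", "large")) {
  side <- match.arg(side)
  stopifnot(inherits(decomp, "column_decomposition"))
  k <- length(decomp[[side]])
  if (k == 0L) return(numeric(0))
  n_side <- if (side == "large") decomp$n_pos else decomp$n_neg
  if (n_side == 0L)
    stop_ctap("one-sided middle part: no middle gene with ",
              if (side == "large") "positive" else "negative", " Z-score")
  extreme <- if (side == "large") max(decomp$z_m) else min(decomp$z_m)
  step <- abs(extreme) / n_side * decomp$sigma
  out_rank <- n_side + seq_len(k)  # rank distance from the Z ~ 0 anchor
  if (side == "large") decomp$mu + step * out_rank
  else rev(decomp$mu - step * out_rank)  # ascending, outermost first
}

#' Trimmed quantile normalisation of a cohort matrix
#'
#' Cross-platform normalisation robust to extreme values. Per column:
#' \enumerate{
#'   \item sort values ascending (remembering the gene order);
#'   \item cut `trim_fraction` of the genes from each tail;
#'   \item quantile-normalise the middle parts across columns (reference =
#'     per-rank mean), so every column shares the same sorted middle values;
#'   \item replace each trimmed tail by the [revise_tail()] Z-ramp computed
#'     from the normalised middle;
#'   \item restore the original gene order so each gene occupies one row.
#' }
#' Within each column, output preserves the input's rank order.
#'
#' @param m A [build_big_matrix()] result, or a plain numeric matrix with
#'   gene rownames.
#' @param trim_fraction Fraction trimmed per tail, in (0, 0.5); default 0.05.
#' @return The normalised matrix, same class and shape as the input.
#' @export
trimmed_quantile_normalize <- function(m, trim_fraction = 0.05) {
  is_cohort <- inherits(m, "cohort_matrix")
  v <- if (is_cohort) m$values else m
  if (!is.matrix(v) || !is.numeric(v)) stop_ctap("need a numeric matrix")
  n <- nrow(v)
  decomps <- lapply(seq_len(ncol(v)), function(j) {
    d <- decompose_column(setNames(v[, j], rownames(v)), trim_fraction)
    if (d$sigma <= 0)
      stop_ctap("degenerate middle part (sigma = 0) in column '",
                colnames(v)[j] %||% j, "'")
    d
  })
  # quantile-normalise middles: per-rank mean across columns
  mid <- vapply(decomps, `[[`, numeric(length(decomps[[1L]]$middle)), "middle")
  ref <- rowMeans(mid)
  out <- v
  for (j in seq_len(ncol(v))) {
    d <- decomps[[j]]
    k <- length(d$small)
    d$middle <- ref
    d$mu <- mean(ref)
    d$sigma <- pop_sd(ref)
    d$z_m <- (ref - d$mu) / d$sigma
    d$n_pos <- sum(d$z_m > 0)
    d$n_neg <- sum(d$z_m < 0)
    column <- c(if (k > 0L) revise_tail(d, "small"), ref,
                if (k > 0L) revise_tail(d, "large"))
    out[d$order, j] <- column
  }
  if (is_cohort) { m$values <- out; m } else out
}
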