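#' Assemble a normalised cohort from studies and CP specifications
#'
#' Runs the data-assembly stages in order: builds one comparison pair per
#' specification ([build_comparison_pair()]), stacks the population means
#' into the unnormalised big matrix ([build_big_matrix()]), and applies
#' trimmed quantile normalisation ([trimmed_quantile_normalize()]).
#'
#' @param studies List of [expression_study()] objects (matched to
#'   specifications by `study_id`).
#' @param cp_specs List of CP specifications (see [load_cohort_config()]).
#' @param trim_fraction Per-tail trim fraction for TQN; default 0.05.
#' @param fc_scale Scale on which comparison-pair log2 fold changes are
#'   computed: `"raw"` (default) uses the original intensities;
#'   `"normalized"` recomputes them from the TQN matrix (values clamped at 0
#'   before the Laplacian-corrected ratio, since the tail ramp can dip below
#'   zero).
#' @return An object of class `ctap_cohort` with elements `cps` (list of
#'   `comparison_pair`), `m` (unnormalised `cohort_matrix`), `m_prime`
#'   (normalised), `contexts`, and `trim_fraction`.
#' @export
build_cohort <- function(studies, cp_specs, trim_fraction = 0.05,
                         fc_scale = c("raw", "normalized")) {
  fc_scale <- match.arg(fc_scale)
  if (inherits(studies, "expression_study")) studies <- list(studies)
  ids <- vapply(studies, `[[`, "", "study_id")
  names(studies) <- ids
  cps <- lapply(cp_specs, function(spec) {
    if (!spec$study_id %in% ids)
      stop_ctap("no study '", spec$study_id, "' supplied for CP ", spec$cp_id)
    build_comparison_pair(studies[[spec$study_id]], spec)
  })
  m <- build_big_matrix(cps)
  m_prime <- trimmed_quantile_normalize(m, trim_fraction)
  if (fc_scale == "normalized") {
    for (i in seq_along(cps)) {
      cols <- cp_columns(m_prime, cps[[i]]$cp_id)
      g <- names(cps[[i]]$log2fc)
      cps[[i]]$log2fc <- setNames(
        log2_ratio(pmax(m_prime$values[g, cols[["test"]]], 0),
                   pmax(m_prime$values[g, cols[["control"]]], 0)), g)
    }
  }
  structure(
    list(cps = cps, m = m, m_prime = m_prime, contexts = m$contexts,
         trim_fraction = trim_fraction, fc_scale = fc_scale),
    class = "ctap_cohort")
}

#' @export
print.ctap_cohort <- function(x, ...) {
  cat(sprintf(
    "<ctap_cohort> %d CPs (%d OCU, %d OCD), %d genes, trim = %g, fc_scale = %s\n",
    length(x$cps), sum(x$contexts == "OCU"), sum(x$contexts == "OCD"),
    nrow(x$m$values), x$trim_fraction, x$fc_scale))
  invisible(x)
}

# log2fc of one gene across all CPs (NA when absent from a CP's study)
cohort_log2fc <- function(cohort, gene) {
  vapply(cohort$cps, function(cp)
    if (gene %in% names(cp$log2fc)) cp$log2fc[[gene]] else NA_real_, 0)
}
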