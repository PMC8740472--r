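#' Per-gene mean intensity over a sample population
#'
#' @param study An [expression_study()].
#' @param pop A population specification: a list with `sample_ids` (and
#'   optionally `label`), or a character vector of sample ids.
#' @return Named numeric vector of per-gene arithmetic means.
#' @export
population_mean <- function(study, pop) {
  stopifnot(inherits(study, "expression_study"))
  ids <- if (is.character(pop)) pop else pop$sample_ids
  if (length(ids) < 1L) stop_ctap("empty population")
  foreign <- setdiff(ids, study$sample_ids)
  if (length(foreign))
    stop_ctap("population references sample(s) absent from study '",
              study$study_id, "': ", paste(foreign, collapse = ", "))
  rowMeans(study$values[, ids, drop = FALSE])
}

#' Laplacian-corrected log2 expression ratio
#'
#' `log2((e_t + 0.01) / (e_c + 0.01))`. The 0.01 correction keeps the ratio
#' finite and damps the influence of very small intensities.
#'
#' @param e_t,e_c Non-negative test and control mean intensities
#'   (vectorised).
#' @return Finite log2 ratio(s); positive exactly when `e_t > e_c`.
#' @export
log2_ratio <- function(e_t, e_c) {
  if (any(e_t < 0) || any(e_c < 0))
    stop_ctap("log2_ratio: intensities must be non-negative")
  log2((e_t + 0.01) / (e_c + 0.01))
}

#' Build one comparison pair
#'
#' Summarises a test-versus-control contrast as population mean intensities
#' and per-gene Laplacian-corrected log2 ratios.
#'
#' @param study The [expression_study()] the CP is drawn from.
#' @param cp_spec A CP specification (see [load_cohort_config()]).
#' @return An object of class `comparison_pair` with fields `cp_id`,
#'   `context`, `study_id`, `control_mean`, `test_mean`, `log2fc`.
#' @export
build_comparison_pair <- function(study, cp_spec) {
  stopifnot(inherits(cp_spec, "cp_spec"))
  ec <- population_mean(study, cp_spec$control)
  et <- population_mean(study, cp_spec$test)
  structure(
    list(cp_id = cp_spec$cp_id, context = cp_spec$context,
         study_id = study$study_id,
         control_mean = ec, test_mean = et,
         log2fc = log2_ratio(et, ec)),
    class = "comparison_pair")
}

#' @export
print.comparison_pair <- function(x, ...) {
  cat(sprintf("<comparison_pair> CP %d (%s, %s): %d genes\n",
              x$cp_id, x$context, x$study_id, length(x$log2fc)))
  invisible(x)
}

#' Export a comparison pair as a two-column table
#'
#' Writes gene symbol and log2 ratio, tab-separated.
#'
#' @param cp A `comparison_pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_pair <- function(cp, path) {
  stopifnot(inherits(cp, "comparison_pair"))
  writeLines(c("gene\tlog2fc",
               paste(names(cp$log2fc),
                     format(cp$log2fc, digits = 15, trim = TRUE,
                            scientific = FALSE), sep = "\t")), path)
  invisible(path)
}

#' Assemble the unnormalised cohort matrix
#'
#' Stacks the population mean intensities of all comparison pairs into one
#' gene-by-column matrix: per CP one control column and one test column
#' (labelled `"<cp_id>:control"`, `"<cp_id>:test"`, in CP order). Rows cover
#' the union of all CP gene sets; a gene not measured in a CP's study is
#' imputed as 0 in both of that CP's columns.
#'
#' @param cps List of `comparison_pair` objects.
#' @return An object of class `cohort_matrix`: list with `values` (the
#'   matrix), `cp_ids`, and `contexts` (named by CP id).
#' @export
build_big_matrix <- function(cps) {
  if (length(cps) < 1L) stop_ctap("build_big_matrix: need at least one CP")
  stopifnot(all(vapply(cps, inherits, TRUE, "comparison_pair")))
  genes <- unique(unlist(lapply(cps, function(cp) names(cp$log2fc))))
  m <- matrix(0, nrow = length(genes), ncol = 2L * length(cps),
              dimnames = list(genes, NULL))
  labels <- character(2L * length(cps))
  for (i in seq_along(cps)) {
    cp <- cps[[i]]
    jc <- 2L * i - 1L
    labels[jc] <- paste0(cp$cp_id, ":control")
    labels[jc + 1L] <- paste0(cp$cp_id, ":test")
    m[names(cp$control_mean), jc] <- cp$control_mean
    m[names(cp$test_mean), jc + 1L] <- cp$test_mean
  }
  colnames(m) <- labels
  ids <- vapply(cps, function(cp) as.integer(cp$cp_id), 1L)
  structure(
    list(values = m, cp_ids = ids,
         contexts = setNames(vapply(cps, `[[`, "", "context"), ids)),
    class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("<cohort_matrix> %d genes x %d columns (%d CPs: %d OCU, %d OCD)\n",
              nrow(x$values), ncol(x$values), length(x$cp_ids),
              sum(x$contexts == "OCU"), sum(x$contexts == "OCD")))
  invisible(x)
}

# column indices of one CP's (control, test) pair
cp_columns <- function(m, cp_id) {
  idx <- match(paste0(cp_id, c(":control", ":test")), colnames(m$values))
  if (any(is.na(idx))) stop_ctap("CP ", cp_id, " not present in cohort matrix")
  setNames(idx, c("control", "test"))
}
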