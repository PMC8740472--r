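#' Per-CP regulation prediction for a candidate gene
#'
#' Applies a trained model (or the fold-change-only rule) to one candidate
#' gene in every comparison pair. Under the fold-change rule the prediction
#' is the sign of the CP's log2 ratio; a magnitude at or below
#' `fc_threshold` (default 0, i.e. only an exact zero) gives no signal,
#' recorded as 0, which counts as a mismatch under both calling hypotheses.
#'
#' @param model A `ctap_model`, or the string `"log2fc"` for the
#'   fold-change-only rule.
#' @param cohort A [build_cohort()] result.
#' @param gene Candidate gene symbol (uppercased internally). A gene absent
#'   from the cohort yields an empty result with a warning.
#' @param fc_threshold Minimum |log2fc| for the fold-change rule to emit a
#'   sign.
#' @return Named numeric vector of predictions (+1 / -1 / 0) by CP id.
#' @export
predict_candidate <- function(model, cohort, gene, fc_threshold = 0) {
  gene <- toupper(gene)
  cp_ids <- vapply(cohort$cps, `[[`, 1L, "cp_id")
  if (!gene %in% rownames(cohort$m$values)) {
    warning("candidate gene '", gene, "' absent from cohort; skipped",
            call. = FALSE)
    return(setNames(numeric(0), character(0)))
  }
  if (identical(model, "log2fc")) {
    fc <- vapply(cohort$cps, function(cp)
      if (gene %in% names(cp$log2fc)) cp$log2fc[[gene]] else 0, 0)
    pred <- ifelse(abs(fc) > fc_threshold, sign(fc), 0)
  } else {
    stopifnot(inherits(model, "ctap_model"))
    feats <- feature_table(cohort, gene)
    pred <- predict(model, feats)[order(match(feats$cp_id, cp_ids))]
  }
  setNames(pred, cp_ids)
}

#' Call a candidate's regulation direction under error tolerance
#'
#' Tests two hypotheses against the per-CP predictions: FOLLOW (the gene
#' moves with the TF's known direction in every CP) and OPPOSE (it moves
#' against it). The mismatch fraction of a hypothesis is the share of
#' in-scope CPs whose prediction disagrees (no-signal predictions of 0
#' disagree with both). The gene is called `Up` when only FOLLOW stays
#' within tolerance `t`, `Down` when only OPPOSE does, and `none` otherwise.
#'
#' @param per_cp_prediction Named vector of +1/-1/0 predictions by CP id.
#' @param contexts Named context vector (`"OCU"`/`"OCD"`) by CP id.
#' @param tf_direction Named vector giving the TF's expected direction per
#'   context, e.g. `c(OCU = -1, OCD = 1)`.
#' @param t Error tolerance rate in \[0, 0.5).
#' @param scope `"all_cps"` (default: one denominator over all CPs) or
#'   `"per_context"` (both contexts must pass separately).
#' @return List with `direction`, `mismatch_follow`, `mismatch_oppose`.
#' @export
call_direction <- function(per_cp_prediction, contexts, tf_direction,
                           t = 0.05, scope = c("all_cps", "per_context")) {
  scope <- match.arg(scope)
  if (t < 0 || t >= 0.5) stop_ctap("tolerance t must lie in [0, 0.5)")
  ids <- names(per_cp_prediction)
  if (length(ids) == 0L) stop_ctap("empty prediction scope")
  expected <- unname(tf_direction[contexts[ids]])
  mism <- function(target) per_cp_prediction != target
  if (scope == "all_cps") {
    mf <- mean(mism(expected))
    mo <- mean(mism(-expected))
    follow_ok <- mf <= t
    oppose_ok <- mo <= t
  } else {
    by_ctx <- split(seq_along(ids), contexts[ids])
    frac <- function(target) vapply(by_ctx, function(i)
      mean(per_cp_prediction[i] != target[i]), 0)
    mf_ctx <- frac(expected)
    mo_ctx <- frac(-expected)
    mf <- max(mf_ctx)
    mo <- max(mo_ctx)
    follow_ok <- all(mf_ctx <= t)
    oppose_ok <- all(mo_ctx <= t)
  }
  direction <- if (follow_ok && !oppose_ok) "Up"
               else if (oppose_ok && !follow_ok) "Down"
               else "none"
  list(direction = direction, mismatch_follow = mf, mismatch_oppose = mo)
}

#' GP/GA pattern annotation of one prediction
#'
#' Gene-Present-Sufficiently (GP): the model calls the gene up although its
#' fold change is negative -- its transcript abundance is judged high enough
#' to function. Gene-Absent-Insufficiently (GA): the model calls it down
#' although the fold change is positive -- the transcript is too scarce to
#' function. When a second model's prediction is supplied and disagrees,
#' the cell is `ambiguous`; anything else is `regular`.
#'
#' @param prediction Primary model prediction, +1 or -1.
#' @param log2fc The gene's log2 fold change in that CP.
#' @param co_model_prediction Optional second model's prediction.
#' @return One of `"GP"`, `"GA"`, `"regular"`, `"ambiguous"`.
#' @export
annotate_pattern <- function(prediction, log2fc, co_model_prediction = NULL) {
  if (!is.null(co_model_prediction) && co_model_prediction != prediction)
    return("ambiguous")
  if (prediction == 1 && log2fc < 0) return("GP")
  if (prediction == -1 && log2fc > 0) return("GA")
  "regular"
}

#' Call Up/Down targets of a TF from a candidate list
#'
#' Runs [predict_candidate()] and [call_direction()] over every candidate
#' gene and annotates each in-scope CP with its GP/GA pattern
#' ([annotate_pattern()]). Candidates absent from the cohort are collected
#' in the `skipped` attribute rather than silently dropped.
#'
#' @param model A `ctap_model` or `"log2fc"`.
#' @param cohort A [build_cohort()] result.
#' @param candidates Candidate list from [read_candidate_list()], or a
#'   character vector of gene symbols.
#' @param tf TF name; must match an entry of `tf_directions` when
#'   `candidates` is a plain vector.
#' @param tf_directions Named list of per-context directions (default
#'   [ctap_tf_directions()]).
#' @param t Error tolerance rate.
#' @param scope Tolerance scope, see [call_direction()].
#' @param co_model Optional second `ctap_model` used for the ambiguity
#'   annotation.
#' @param fc_threshold Passed to [predict_candidate()] for the fold-change
#'   rule.
#' @return A data frame of class `ctap_calls`: one row per scored candidate
#'   with `gene`, `direction`, the two mismatch fractions, and compact
#'   per-CP prediction/pattern strings; per-CP detail in the `predictions`
#'   and `patterns` attributes, skipped genes in `skipped`.
#' @export
call_targets <- function(model, cohort, candidates, tf = NULL,
                         tf_directions = ctap_tf_directions(), t = 0.05,
                         scope = "all_cps", co_model = NULL,
                         fc_threshold = 0) {
  if (is.character(candidates)) {
    if (is.null(tf)) stop_ctap("supply 'tf' with a plain candidate vector")
    candidates <- list(tf = tf, genes = toupper(candidates))
  }
  tf <- candidates$tf
  direction_tab <- tf_directions[[tf]]
  if (is.null(direction_tab))
    stop_ctap("no direction table for TF '", tf, "'")
  contexts <- cohort$contexts
  skipped <- character(0)
  rows <- list()
  pred_list <- list()
  patt_list <- list()
  for (gene in candidates$genes) {
    pred <- suppressWarnings(predict_candidate(model, cohort, gene,
                                               fc_threshold))
    if (length(pred) == 0L) { skipped <- c(skipped, gene); next }
    call <- call_direction(pred, contexts, direction_tab, t, scope)
    fc <- cohort_log2fc(cohort, gene)
    fc[is.na(fc)] <- 0
    co_pred <- if (!is.null(co_model))
      suppressWarnings(predict_candidate(co_model, cohort, gene)) else NULL
    patt <- vapply(seq_along(pred), function(i)
      annotate_pattern(pred[i], fc[i],
                       if (!is.null(co_pred)) co_pred[i] else NULL), "")
    names(patt) <- names(pred)
    rows[[gene]] <- data.frame(
      gene = gene, tf = tf, direction = call$direction,
      mismatch_follow = call$mismatch_follow,
      mismatch_oppose = call$mismatch_oppose,
      predictions = paste(ifelse(pred > 0, "+", ifelse(pred < 0, "-", "0")),
                          collapse = ""),
      patterns = paste(substr(patt, 1L, 2L), collapse = ","),
      stringsAsFactors = FALSE)
    pred_list[[gene]] <- pred
    patt_list[[gene]] <- patt
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene = character(0), tf = character(0),
                         direction = character(0))
  rownames(out) <- NULL
  structure(out, class = c("ctap_calls", "data.frame"),
            predictions = pred_list, patterns = patt_list,
            skipped = skipped, t = t, scope = scope)
}

#' @export
print.ctap_calls <- function(x, ...) {
  up <- sum(x$direction == "Up")
  down <- sum(x$direction == "Down")
  cat(sprintf("<ctap_calls> %d candidates scored (t = %g, %s): %d Up, %d Down, %d none; %d skipped\n",
              nrow(x), attr(x, "t"), attr(x, "scope"), up, down,
              sum(x$direction == "none"), length(attr(x, "skipped"))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 20L))
  invisible(x)
}

#' Overlap partition of call sets from several methods
#'
#' Computes, separately for Up and Down calls, the exact partition of the
#' union of called genes by method membership -- the set algebra behind a
#' Venn diagram, without the drawing.
#'
#' @param call_sets Named list of `ctap_calls` (or data frames with `gene`
#'   and `direction` columns), all over the same candidate list.
#' @return List with elements `Up` and `Down`; each is a list of gene-symbol
#'   vectors keyed by membership region (method names joined by `&`).
#' @export
compare_models <- function(call_sets) {
  if (length(call_sets) < 2L) stop_ctap("need at least two call sets")
  if (is.null(names(call_sets)))
    names(call_sets) <- paste0("method", seq_along(call_sets))
  partition_one <- function(direction) {
    sets <- lapply(call_sets, function(cs) cs$gene[cs$direction == direction])
    universe <- unique(unlist(sets))
    if (!length(universe)) return(list())
    member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
    member <- matrix(member, nrow = length(universe),
                     dimnames = list(universe, names(call_sets)))
    region <- apply(member, 1L, function(r)
      paste(names(call_sets)[r], collapse = " & "))
    split(universe, region)
  }
  list(Up = partition_one("Up"), Down = partition_one("Down"))
}
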