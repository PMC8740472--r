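#' Read a functional-group registry
#'
#' A functional group (FG) is a curated set of marker genes expected to be
#' collectively activated or collectively inhibited in a given comparison
#' context. The registry file is tab-separated with one row per (group, gene)
#' entry and columns `group`, `gene`, `OCU`, `OCD`; the context columns hold
#' `Activation` or `Inhibition` and must be constant within a group. A gene
#' may appear in several groups (each entry counts separately downstream) but
#' not twice within one group.
#'
#' @param path Path to the registry file.
#' @return An object of class `fg_registry`: a named list of groups, each
#'   with elements `name`, `genes` and `expected_state` (named character
#'   vector over contexts).
#' @export
read_fg_registry <- function(path) {
  tab <- read_tsv_strict(path)
  cols <- tab$header
  need <- c("group", "gene", "OCU", "OCD")
  if (length(setdiff(need, cols)))
    stop_ctap("FG registry '", path, "' lacks column(s): ",
              paste(setdiff(need, cols), collapse = ", "))
  df <- as.data.frame(do.call(rbind, tab$rows), stringsAsFactors = FALSE)
  names(df) <- cols
  df$gene <- toupper(df$gene)
  groups <- lapply(split(df, factor(df$group, levels = unique(df$group))),
                   function(g) {
    if (anyDuplicated(g$gene))
      stop_ctap("duplicate gene within group '", g$group[1L], "'")
    state <- c(OCU = unique(g$OCU), OCD = unique(g$OCD))
    if (length(state) != 2L || !all(state %in% c("Activation", "Inhibition")))
      stop_ctap("group '", g$group[1L],
                "' must declare one Activation/Inhibition state per context")
    list(name = g$group[1L], genes = g$gene, expected_state = state)
  })
  structure(groups, class = "fg_registry")
}

#' @export
print.fg_registry <- function(x, ...) {
  cat(sprintf("<fg_registry> %d groups, %d gene entries\n",
              length(x), sum(lengths(lapply(x, `[[`, "genes")))))
  for (g in x)
    cat(sprintf("  %-46s %2d genes  OCU=%s\n", g$name, length(g$genes),
                g$expected_state[["OCU"]]))
  invisible(x)
}

#' Bundled osteoclast-differentiation functional groups
#'
#' The 14 curated marker-gene groups (134 gene entries, counted with
#' multiplicity across groups) for the osteoclast-differentiation context,
#' shipped with the package.
#'
#' @return An `fg_registry` (see [read_fg_registry()]).
#' @export
ctap_fg_osteoclast <- function() {
  read_fg_registry(system.file("extdata", "osteoclast_fg.tsv",
                               package = "ctap", mustWork = TRUE))
}

#' Functional-group score
#'
#' The signed square of the mean log2 fold change over a group's member
#' genes: `(mean)^2` when the mean is non-negative, `-(mean)^2` otherwise.
#' The squaring stretches strong collective movement while the sign records
#' whether the group looks activated (positive) or inhibited (negative).
#'
#' @param log2fcs Numeric vector of member-gene log2 fold changes.
#' @return A single number, the group's score.
#' @export
fg_score <- function(log2fcs) {
  if (length(log2fcs) < 1L) stop_ctap("fg_score: empty member list")
  if (any(!is.finite(log2fcs))) stop_ctap("fg_score: non-finite log2 ratios")
  m <- mean(log2fcs)
  if (m >= 0) m^2 else -m^2
}

#' Does a functional-group score follow its expected state?
#'
#' A positive score signals activation and a negative score inhibition. A
#' score of exactly zero carries no directional evidence and follows neither
#' expectation.
#'
#' @param score Functional-group score (see [fg_score()]).
#' @param expected `"Activation"` or `"Inhibition"`.
#' @return `TRUE` if the score's direction matches the expectation.
#' @export
fg_state <- function(score, expected) {
  expected <- match.arg(expected, c("Activation", "Inhibition"))
  if (expected == "Activation") score > 0 else score < 0
}

#' Total functional-group score
#'
#' Counts, over all comparison pairs, the (CP, FG) cells whose functional
#' group followed its expected state. With two CPs in which 5 and 6 groups
#' follow expectation, the total is 11.
#'
#' @param states Logical matrix or data frame of follows-expectation flags,
#'   rows = comparison pairs, columns = functional groups.
#' @return A list of class `tfgs_result` with `count` (the total) and
#'   `per_cp_counts` (named integer vector by CP).
#' @export
tfgs <- function(states) {
  states <- as.matrix(states)
  if (!is.logical(states)) stop_ctap("tfgs: 'states' must be logical")
  if (any(is.na(states))) stop_ctap("tfgs: incomplete follows table")
  per_cp <- rowSums(states)
  structure(list(count = as.integer(sum(per_cp)),
                 per_cp_counts = setNames(as.integer(per_cp), rownames(states))),
            class = "tfgs_result")
}

#' @export
print.tfgs_result <- function(x, ...) {
  cat(sprintf("<tfgs_result> TFGS = %d over %d CPs\n",
              x$count, length(x$per_cp_counts)))
  invisible(x)
}

#' Expected training label of a functional group in a context
#'
#' @param fg One group from an `fg_registry`.
#' @param context `"OCU"` or `"OCD"`.
#' @return `+1` when the expected state is Activation (up-regulation),
#'   `-1` for Inhibition (down-regulation).
#' @export
expected_label <- function(fg, context) {
  if (!context %in% names(fg$expected_state))
    stop_ctap("context '", context, "' not declared for group '", fg$name, "'")
  if (fg$expected_state[[context]] == "Activation") 1 else -1
}

#' Fraction of member genes agreeing with the group direction
#'
#' Diagnostic companion to [fg_score()]: the share of member genes whose
#' log2 fold change points in the expected direction. Groups are rarely
#' unanimous in real data; a high agreement fraction (e.g. over 0.8) is
#' usually taken as sufficient collective behaviour.
#'
#' @param log2fcs Member-gene log2 fold changes.
#' @param expected `"Activation"` or `"Inhibition"`.
#' @return A fraction in \[0, 1\]; zero-valued members never agree.
#' @export
fg_agreement_fraction <- function(log2fcs, expected) {
  expected <- match.arg(expected, c("Activation", "Inhibition"))
  if (length(log2fcs) < 1L) stop_ctap("empty member list")
  if (expected == "Activation") mean(log2fcs > 0) else mean(log2fcs < 0)
}
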