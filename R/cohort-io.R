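#' Construct an expression study
#'
#' Container for one study's processed expression values: a gene-by-sample
#' intensity matrix keyed by uppercase official gene symbols.
#'
#' @param study_id Study identifier (e.g. a GEO series accession).
#' @param platform_id Platform identifier (e.g. a GEO platform accession).
#' @param values Numeric matrix, rows named by gene symbol, columns by sample
#'   id. Intensities must be finite and non-negative; symbols are
#'   uppercase-normalised and must be unique.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(study_id, platform_id = NA_character_, values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_ctap("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_ctap("'values' must have gene symbols as rownames and sample ids as colnames")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop_ctap("duplicate gene symbols in study '", study_id, "'")
  if (any(!is.finite(values)))
    stop_ctap("non-finite intensities in study '", study_id, "'")
  if (any(values < 0))
    stop_ctap("negative intensities in study '", study_id, "'")
  structure(
    list(study_id = as.character(study_id),
         platform_id = as.character(platform_id),
         sample_ids = colnames(values),
         values = values),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s (%s): %d genes x %d samples\n",
              x$study_id, x$platform_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# read a tab-separated table with '#' comment lines, strict rectangular check;
# returns list(header, rows); errors name the offending physical line
read_tsv_strict <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 1L) stop_ctap("empty file: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1L]])
  bad <- which(vapply(cells, length, 1L) != width)
  if (length(bad))
    stop_ctap(sprintf("parse error in '%s': line %d has %d fields, expected %d",
                      path, lineno[bad[1L]], length(cells[[bad[1L]]]), width))
  list(header = cells[[1L]], rows = cells[-1L], lineno = lineno[-1L])
}

#' Read a series-matrix-like expression table
#'
#' Reads a tab-separated expression table in the series-matrix dialect
#' (header row of sample identifiers, one row per probe, first column the
#' probe identifier), maps probe identifiers to official gene symbols through
#' a platform annotation, drops unmappable probes, and collapses multiple
#' probes per symbol by their arithmetic mean.
#'
#' @param path Path to the tab-separated expression file.
#' @param annotation Probe-to-symbol mapping: a named character vector
#'   (names = probe ids, values = gene symbols), a two-column data frame
#'   (probe id, gene symbol), or a path to a two-column tab-separated file.
#'   Probes mapped to an empty symbol are treated as unannotated.
#' @param study_id,platform_id Identifiers recorded on the result.
#' @param collapse How multiple probes mapping to one symbol are combined;
#'   only `"mean"` is provided.
#' @return An [expression_study()].
#' @export
read_series_matrix <- function(path, annotation, study_id = basename(path),
                               platform_id = NA_character_,
                               collapse = c("mean")) {
  collapse <- match.arg(collapse)
  annotation <- as_annotation(annotation)
  tab <- read_tsv_strict(path)
  samples <- tab$header[-1L]
  if (length(samples) < 1L) stop_ctap("no sample columns in '", path, "'")
  probes <- vapply(tab$rows, `[[`, "", 1L)
  vals <- lapply(seq_along(tab$rows), function(i) {
    v <- suppressWarnings(as.numeric(tab$rows[[i]][-1L]))
    if (any(is.na(v)))
      stop_ctap(sprintf("parse error in '%s': non-numeric or missing intensity at line %d",
                        path, tab$lineno[i]))
    v
  })
  m <- do.call(rbind, vals)
  colnames(m) <- samples
  sym <- toupper(unname(annotation[probes]))
  mapped <- !is.na(sym) & nzchar(sym)
  if (!any(mapped)) stop_ctap("no mappable probes in '", path, "'")
  m <- m[mapped, , drop = FALSE]
  sym <- sym[mapped]
  # mean-collapse: order-independent by construction
  collapsed <- rowsum(m, group = sym, reorder = TRUE) /
    as.vector(table(sym)[sort(unique(sym))])
  expression_study(study_id, platform_id, collapsed)
}

as_annotation <- function(annotation) {
  if (is.character(annotation) && is.null(names(annotation)) &&
      length(annotation) == 1L && file.exists(annotation)) {
    tab <- read_tsv_strict(annotation)
    rows <- c(list(tab$header), tab$rows)  # annotation files may be headerless
    if (identical(toupper(tab$header[1L]), "ID") ||
        identical(toupper(tab$header[1L]), "ID_REF"))
      rows <- tab$rows
    probe <- vapply(rows, `[[`, "", 1L)
    symbol <- vapply(rows, function(r) if (length(r) >= 2L) r[[2L]] else "", "")
    return(setNames(symbol, probe))
  }
  if (is.data.frame(annotation)) {
    if (ncol(annotation) < 2L) stop_ctap("annotation data frame needs 2 columns")
    return(setNames(as.character(annotation[[2L]]), as.character(annotation[[1L]])))
  }
  if (is.character(annotation) && !is.null(names(annotation)))
    return(annotation)
  stop_ctap("'annotation' must be a named character vector, data frame, or file path")
}

#' Write an expression study as a series-matrix-like table
#'
#' Inverse of [read_series_matrix()] under an identity annotation: gene
#' symbols are written in the probe-id column.
#'
#' @param study An [expression_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(study, path) {
  stopifnot(inherits(study, "expression_study"))
  header <- paste(c("ID_REF", study$sample_ids), collapse = "\t")
  body <- vapply(seq_len(nrow(study$values)), function(i)
    paste(c(rownames(study$values)[i],
            format(study$values[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

new_population <- function(label, sample_ids) {
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) < 1L) stop_ctap("empty population '", label, "'")
  list(label = as.character(label), sample_ids = sample_ids)
}

new_cp_spec <- function(cp_id, study_id, control, test, context) {
  if (!context %in% c("OCU", "OCD"))
    stop_ctap("unknown context label '", context, "' for CP ", cp_id,
              " (expected OCU or OCD)")
  if (length(intersect(control$sample_ids, test$sample_ids)))
    stop_ctap("control and test populations overlap for CP ", cp_id)
  structure(
    list(cp_id = as.integer(cp_id), study_id = as.character(study_id),
         control = control, test = test, context = context),
    class = "cp_spec")
}

#' Load a cohort configuration of comparison-pair specifications
#'
#' The configuration is a tab-separated table with one row per comparison
#' pair (CP) and columns `cp_id`, `study_id`, `control_samples`,
#' `test_samples` (semicolon-separated sample ids), `context` (`OCU` or
#' `OCD`), and optionally `control_label`, `test_label`, `platform_id`.
#' Lines starting with `#` are comments.
#'
#' @param path Path to the configuration file.
#' @return An ordered list of CP specifications (class `cp_spec`), one per
#'   row, with unique `cp_id`s.
#' @export
load_cohort_config <- function(path) {
  tab <- read_tsv_strict(path)
  cols <- tab$header
  need <- c("cp_id", "study_id", "control_samples", "test_samples", "context")
  missing <- setdiff(need, cols)
  if (length(missing))
    stop_ctap("cohort config '", path, "' lacks column(s): ",
              paste(missing, collapse = ", "))
  get <- function(row, name) {
    i <- match(name, cols)
    if (is.na(i)) NA_character_ else row[[i]]
  }
  specs <- lapply(tab$rows, function(r) {
    new_cp_spec(
      cp_id = as.integer(get(r, "cp_id")),
      study_id = get(r, "study_id"),
      control = new_population(get(r, "control_label") %||% "control",
                               strsplit(get(r, "control_samples"), ";")[[1L]]),
      test = new_population(get(r, "test_label") %||% "test",
                            strsplit(get(r, "test_samples"), ";")[[1L]]),
      context = get(r, "context"))
  })
  ids <- vapply(specs, `[[`, 1L, "cp_id")
  if (anyDuplicated(ids))
    stop_ctap("duplicate cp_id in cohort config: ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  specs
}

#' Read a candidate-target gene list
#'
#' One gene symbol per line; blank lines and `#` comments ignored. Symbols
#' are uppercase-normalised and de-duplicated (first occurrence kept).
#'
#' @param path Path to the list.
#' @param tf Name of the transcription factor the candidates belong to.
#' @return A list with elements `tf` and `genes`.
#' @export
read_candidate_list <- function(path, tf) {
  lines <- trimws(readLines(path, warn = FALSE))
  genes <- toupper(lines[nzchar(lines) & !startsWith(lines, "#")])
  genes <- genes[!duplicated(genes)]
  if (!length(genes)) stop_ctap("empty candidate list: ", path)
  list(tf = as.character(tf), genes = genes)
}

#' Bundled osteoclast-differentiation cohort design
#'
#' The 16-comparison-pair cohort design (8 OCU, 8 OCD) over 11 public
#' expression studies, shipped with the package.
#'
#' @return An ordered list of `cp_spec` objects (see [load_cohort_config()]).
#' @export
ctap_cp_osteoclast <- function() {
  load_cohort_config(system.file("extdata", "osteoclast_cps.tsv",
                                 package = "ctap", mustWork = TRUE))
}
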