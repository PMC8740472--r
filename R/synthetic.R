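#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the osteoclast-differentiation cohort design: 16
#' comparison pairs (8 per context) drawn from 8 studies with
#' platform-specific scale biases, triplicate populations, the bundled
#' 14-group marker registry driving context-consistent directed genes, the
#' two anchor TFs, and planted candidate targets per TF -- clean followers
#' and opposers plus GP/GA cases whose fold change opposes their abundance
#' pattern.
#'
#' @param n_studies Number of simulated studies; CPs are assigned
#'   round-robin, so studies carry 2 CPs each by default.
#' @param n_cps_per_context CPs per context (OCU and OCD alternate).
#' @param n_background_genes Undirected genes filling out the transcriptome.
#' @param replicates_per_population Samples per control/test population.
#' @param fg_registry Functional groups planted with context-consistent
#'   direction (default the bundled osteoclast registry). A gene listed in
#'   groups with conflicting expected states follows its first listing (the
#'   remaining listings become label noise, as in real curated groups).
#' @param tf_directions Anchor TFs and their per-context directions.
#' @param effect_size Mean |log2 fold change| of directed genes (log2
#'   units).
#' @param noise_sd Replicate-level noise standard deviation (log2 units).
#' @param platform_gain_range,platform_offset_range Per-study multiplicative
#'   gain and additive offset applied on the intensity scale.
#' @param planted_targets Per TF, counts of planted candidate genes by role:
#'   `follower`, `opposer`, `gp_case`, `ga_case`.
#' @param n_decoys Background genes added to each TF's candidate list as
#'   true negatives.
#' @param abundance_shift Log2 offset placing GP/GA genes in the
#'   top/bottom row quantile in their deciding CPs.
#' @param override_fc Magnitude of the (sign-opposing) log2 fold change of
#'   GP/GA genes in their deciding CPs.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A list of class `ctap_sim_config`.
#' @export
ctap_sim_config <- function(n_studies = 8, n_cps_per_context = 8,
                            n_background_genes = 2000,
                            replicates_per_population = 3,
                            fg_registry = ctap_fg_osteoclast(),
                            tf_directions = ctap_tf_directions(),
                            effect_size = 1, noise_sd = 0.25,
                            platform_gain_range = c(0.5, 2),
                            platform_offset_range = c(0, 10),
                            planted_targets = NULL, n_decoys = 20,
                            abundance_shift = 2, override_fc = 0.3,
                            seed = 1) {
  planted_targets <- planted_targets %||% lapply(tf_directions, function(d)
    c(follower = 10, opposer = 10, gp_case = 5, ga_case = 5))
  stopifnot(n_studies >= 1, n_cps_per_context >= 1, n_background_genes >= 0,
            replicates_per_population >= 1, effect_size > 0, noise_sd >= 0)
  structure(
    list(n_studies = n_studies, n_cps_per_context = n_cps_per_context,
         n_background_genes = n_background_genes,
         replicates_per_population = replicates_per_population,
         fg_registry = fg_registry, tf_directions = tf_directions,
         effect_size = effect_size, noise_sd = noise_sd,
         platform_gain_range = platform_gain_range,
         platform_offset_range = platform_offset_range,
         planted_targets = planted_targets, n_decoys = n_decoys,
         abundance_shift = abundance_shift, override_fc = override_fc,
         seed = seed),
    class = "ctap_sim_config")
}

#' Simulate a multi-study cohort with planted ground truth
#'
#' Baseline log2 abundances are normal (intensities log-normal); each study
#' applies its own multiplicative gain and additive offset, making trimmed
#' quantile normalisation non-trivial. Functional-group members and anchor
#' TFs shift their test populations by the context-directed effect size.
#' Planted candidate targets per TF: followers shift with the TF's
#' direction, opposers against it; GP cases carry a weakly negative fold
#' change everywhere but sit in the top abundance quantile of their row
#' exactly in the CPs whose follow-direction is up (and in the bottom
#' quantile, strongly down-regulated, elsewhere) -- recoverable as Up
#' targets only through the abundance features; GA cases mirror this as
#' Down targets with weakly positive fold changes.
#'
#' @param config A [ctap_sim_config()].
#' @return List with `studies` (list of [expression_study()]), `cp_specs`
#'   (list of CP specifications), `truth` (data frame: `gene`, `role`, `tf`,
#'   `true_direction`, `deciding_contexts`), `candidates` (per-TF candidate
#'   gene lists including decoys), and `config`.
#' @export
simulate_cohort <- function(config = ctap_sim_config()) {
  stopifnot(inherits(config, "ctap_sim_config"))
  cf <- config
  n_cp <- 2L * cf$n_cps_per_context
  contexts <- rep(c("OCU", "OCD"), cf$n_cps_per_context)
  study_of <- ((seq_len(n_cp) - 1L) %% cf$n_studies) + 1L

  fg_genes <- unique(unlist(lapply(cf$fg_registry, `[[`, "genes")))
  tf_genes <- toupper(names(cf$tf_directions))
  planted <- list()
  for (tf in names(cf$planted_targets)) {
    counts <- cf$planted_targets[[tf]]
    for (role in names(counts)) {
      k <- counts[[role]]
      if (k > 0L)
        planted[[paste(tf, role)]] <- data.frame(
          gene = sprintf("TGT_%s_%s%02d", toupper(tf), toupper(role),
                         seq_len(k)),
          role = role, tf = tf, stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(planted)) do.call(rbind, planted)
             else data.frame(gene = character(0), role = character(0),
                             tf = character(0))
  background <- sprintf("BG%05d", seq_len(cf$n_background_genes))
  genes <- c(fg_genes, setdiff(tf_genes, fg_genes), planted$gene, background)
  if (anyDuplicated(genes)) stop_ctap("gene name collision in simulation")
  n_genes <- length(genes)
  if (cf$n_background_genes < cf$n_decoys)
    stop_ctap("n_decoys exceeds the number of background genes")

  # expected direction of each FG gene per context (first listing wins)
  fg_dir <- list(OCU = numeric(0), OCD = numeric(0))
  for (ctx in c("OCU", "OCD")) {
    d <- setNames(rep(NA_real_, length(fg_genes)), fg_genes)
    for (g in cf$fg_registry)
      for (gene in g$genes)
        if (is.na(d[[gene]]))
          d[[gene]] <- if (g$expected_state[[ctx]] == "Activation") 1 else -1
    fg_dir[[ctx]] <- d
  }

  with_seed(cf$seed, {
    baseline <- setNames(rnorm(n_genes, mean = 6, sd = 1.5), genes)
    gain <- runif(cf$n_studies, cf$platform_gain_range[1L],
                  cf$platform_gain_range[2L])
    offset <- runif(cf$n_studies, cf$platform_offset_range[1L],
                    cf$platform_offset_range[2L])

    # per-CP log2 shifts of the directed genes (named vectors; 0 otherwise)
    shift <- lapply(seq_len(n_cp), function(i) {
      ctx <- contexts[i]
      dc <- setNames(numeric(0), character(0))  # control shifts
      dt <- cf$effect_size * fg_dir[[ctx]]      # test shifts, FG genes
      for (tf in names(cf$tf_directions))
        dt[[toupper(tf)]] <- cf$effect_size * cf$tf_directions[[tf]][[ctx]]
      if (nrow(planted)) for (r in seq_len(nrow(planted))) {
        gene <- planted$gene[r]
        d <- cf$tf_directions[[planted$tf[r]]][[ctx]]
        e <- cf$effect_size; a <- cf$abundance_shift; o <- cf$override_fc
        sh <- switch(planted$role[r],
          follower = c(0, d * e),
          opposer = c(0, -d * e),
          # GP: abundance-high + weak down where follow-direction is up
          gp_case = if (d > 0) c(a, a - o) else c(-a, -a - e),
          # GA: abundance-low + weak up where oppose-direction is down
          ga_case = if (d > 0) c(-a, -a + o) else c(a, a + e))
        dc[[gene]] <- sh[1L]
        dt[[gene]] <- sh[2L]
      }
      list(control = dc, test = dt)
    })

    studies <- lapply(seq_len(cf$n_studies), function(s) {
      cp_here <- which(study_of == s)
      cols <- list()
      for (i in cp_here) {
        for (role in c("control", "test")) {
          sh <- rep(0, n_genes)
          names(sh) <- genes
          sv <- shift[[i]][[role]]
          if (length(sv)) sh[names(sv)] <- sv
          for (r in seq_len(cf$replicates_per_population)) {
            v <- baseline + sh +
              if (cf$noise_sd > 0) rnorm(n_genes, sd = cf$noise_sd) else 0
            cols[[sprintf("cp%d_%s_r%d", i, substr(role, 1L, 4L), r)]] <-
              gain[s] * 2^v + offset[s]
          }
        }
      }
      m <- do.call(cbind, cols)
      rownames(m) <- genes
      expression_study(sprintf("SIM%02d", s), sprintf("SIMPL%02d", s), m)
    })

    cp_specs <- lapply(seq_len(n_cp), function(i) {
      reps <- seq_len(cf$replicates_per_population)
      new_cp_spec(
        cp_id = i, study_id = sprintf("SIM%02d", study_of[i]),
        control = new_population("control", sprintf("cp%d_cont_r%d", i, reps)),
        test = new_population("test", sprintf("cp%d_test_r%d", i, reps)),
        context = contexts[i])
    })

    decoys <- lapply(names(cf$planted_targets), function(tf)
      sample(background, cf$n_decoys))
    names(decoys) <- names(cf$planted_targets)
  })

  truth <- rbind(
    data.frame(gene = planted$gene, role = planted$role, tf = planted$tf,
               true_direction = c(follower = "Up", opposer = "Down",
                                  gp_case = "Up", ga_case = "Down")[planted$role],
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(decoys), function(tf)
      if (length(decoys[[tf]]))
        data.frame(gene = decoys[[tf]], role = "background", tf = tf,
                   true_direction = "none", stringsAsFactors = FALSE))))
  rownames(truth) <- NULL
  # CPs in which the GP/GA override pattern is planted
  truth$deciding_contexts <- ifelse(
    truth$role %in% c("gp_case", "ga_case"),
    vapply(seq_len(nrow(truth)), function(r) {
      d <- cf$tf_directions[[truth$tf[r]]]
      if (truth$role[r] %in% c("gp_case", "ga_case"))
        paste(names(d)[d > 0], collapse = ",") else ""
    }, ""), "")

  candidates <- lapply(names(cf$planted_targets), function(tf)
    list(tf = tf,
         genes = c(planted$gene[planted$tf == tf], decoys[[tf]])))
  names(candidates) <- names(cf$planted_targets)

  list(studies = studies, cp_specs = cp_specs, truth = truth,
       candidates = candidates, config = cf)
}

#' Score target calls against simulation truth
#'
#' Standard precision and recall per direction, judged against planted
#' roles (followers and GP cases are true Up targets; opposers and GA cases
#' true Down targets). With no calls in a direction, precision is reported
#' as 1 by convention and flagged.
#'
#' @param calls A [call_targets()] result (or data frame with `gene` and
#'   `direction`).
#' @param truth Truth table from [simulate_cohort()], restricted to one TF's
#'   candidates.
#' @return Data frame with one row per direction: `direction`, `n_true`,
#'   `n_called`, `precision`, `recall`, `precision_defined`.
#' @export
truth_evaluation <- function(calls, truth) {
  truth <- truth[truth$gene %in% c(calls$gene, truth$gene), , drop = FALSE]
  rows <- lapply(c("Up", "Down"), function(dir) {
    true_set <- truth$gene[truth$true_direction == dir]
    called <- calls$gene[calls$direction == dir]
    hit <- length(intersect(called, true_set))
    data.frame(
      direction = dir, n_true = length(true_set), n_called = length(called),
      precision = if (length(called)) hit / length(called) else 1,
      recall = if (length(true_set)) hit / length(true_set) else NA_real_,
      precision_defined = length(called) > 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
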