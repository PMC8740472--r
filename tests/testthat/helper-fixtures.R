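# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# default-condition synthetic cohort used across learning / calling tests
shared_sim <- function() cached("sim", function()
  simulate_cohort(ctap_sim_config(seed = 42)))

shared_cohort <- function() cached("cohort", function() {
  sim <- shared_sim()
  build_cohort(sim$studies, sim$cp_specs)
})

shared_training <- function() cached("training", function()
  build_training_set(shared_cohort(), ctap_fg_osteoclast()))

shared_model <- function(family) cached(paste0("model_", family), function()
  ctap_train(shared_training(), family, seed = 1))

# noiseless, bias-free small cohort for exact-limit checks
noiseless_sim <- function() cached("noiseless", function()
  simulate_cohort(ctap_sim_config(
    n_background_genes = 300, noise_sd = 0,
    platform_gain_range = c(1, 1), platform_offset_range = c(0, 0),
    seed = 7)))

noiseless_cohort <- function() cached("noiseless_cohort", function() {
  sim <- noiseless_sim()
  build_cohort(sim$studies, sim$cp_specs)
})

# small deterministic study: values[g, s] laid out explicitly
tiny_study <- function(values, study_id = "S1") {
  expression_study(study_id, "P1", values)
}

# minimal cohort carrying only per-CP log2 ratios (for the fold-change-only
# calling rule); fc is a gene x cp matrix, contexts a vector by cp
fc_only_cohort <- function(fc, contexts) {
  cps <- lapply(seq_len(ncol(fc)), function(i) {
    structure(list(cp_id = i, context = contexts[i], study_id = "fc",
                   control_mean = NULL, test_mean = NULL,
                   log2fc = setNames(fc[, i], rownames(fc))),
              class = "comparison_pair")
  })
  structure(list(cps = cps,
                 m = list(values = matrix(0, nrow(fc), 1,
                                          dimnames = list(rownames(fc), "x"))),
                 contexts = setNames(contexts, seq_len(ncol(fc)))),
            class = "ctap_cohort")
}

# the bundled worked-example fold changes (CASP1 across the 16 CPs)
casp1_fixture <- function() {
  path <- system.file("extdata", "casp1_log2fc.tsv", package = "ctap")
  read.delim(path, comment.char = "#")
}
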