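casp1_cohort <- function() {
  tab <- casp1_fixture()
  fc <- matrix(tab$log2fc, ncol = 16, byrow = TRUE,
               dimnames = list("CASP1", NULL))
  fc_only_cohort(fc, tab$context)
}

test_that("the fold-change rule reproduces the worked example's signs", {
  cohort <- casp1_cohort()
  pred <- predict_candidate("log2fc", cohort, "CASP1")
  expect_identical(unname(sign(pred)),
                   c(-1, -1, 1, -1, 1, -1, -1, 1, 1, 1, 1, 1, 1, -1, 1, 1))
  expect_identical(names(pred), as.character(1:16))
})

test_that("tolerance calling allows the worked example's two mismatches", {
  cohort <- casp1_cohort()
  pred <- predict_candidate("log2fc", cohort, "CASP1")
  call <- call_direction(pred, cohort$contexts, c(OCU = -1, OCD = 1),
                         t = 0.15)
  expect_equal(call$mismatch_follow, 2 / 16)
  expect_identical(call$direction, "Up")
  # the two disagreeing CPs are 5 and 16 (both OCU but up-regulated)
  expected <- c(OCU = -1, OCD = 1)[cohort$contexts]
  expect_identical(names(pred)[pred != expected], c("5", "16"))
  # a tolerance below 2/16 drops the call
  strict <- call_direction(pred, cohort$contexts, c(OCU = -1, OCD = 1),
                           t = 0.05)
  expect_identical(strict$direction, "none")
})

test_that("perfect agreement and perfect opposition call Up and Down", {
  contexts <- setNames(rep(c("OCU", "OCD"), 4), 1:8)
  d <- c(OCU = -1, OCD = 1)
  follow <- setNames(d[contexts], names(contexts))
  up <- call_direction(follow, contexts, d, t = 0)
  expect_identical(up$direction, "Up")
  expect_equal(up$mismatch_follow, 0)
  down <- call_direction(-follow, contexts, d, t = 0)
  expect_identical(down$direction, "Down")
  expect_equal(down$mismatch_oppose, 0)
  expect_error(call_direction(setNames(numeric(0), character(0)),
                              contexts, d), "empty")
  expect_error(call_direction(follow, contexts, d, t = 0.7), "0, 0.5")
})

test_that("the called-target set grows monotonically with tolerance", {
  set.seed(44)
  contexts <- setNames(rep(c("OCU", "OCD"), 8), 1:16)
  d <- c(OCU = -1, OCD = 1)
  fc <- matrix(rnorm(30 * 16), 30, 16,
               dimnames = list(sprintf("G%02d", 1:30), NULL))
  cohort <- fc_only_cohort(fc, unname(contexts))
  called <- lapply(c(0, 0.1, 0.2, 0.3, 0.45), function(t) {
    calls <- call_targets("log2fc", cohort, rownames(fc), tf = "IRF8", t = t)
    calls$gene[calls$direction != "none"]
  })
  for (i in seq_len(length(called) - 1L))
    expect_true(all(called[[i]] %in% called[[i + 1L]]))
  # direction exclusivity below t = 0.5: never both Up and Down
  for (t in c(0, 0.2, 0.45)) {
    calls <- call_targets("log2fc", cohort, rownames(fc), tf = "IRF8", t = t)
    tab <- table(calls$gene[calls$direction != "none"])
    expect_true(length(tab) == 0L || max(tab) <= 1L)
  }
})

test_that("GP/GA pattern annotation follows the override logic", {
  # model Up despite negative fold change: present sufficiently
  expect_identical(annotate_pattern(1, -0.4, 1), "GP")
  # model Down despite positive fold change: absent insufficiently
  expect_identical(annotate_pattern(-1, 0.4, -1), "GA")
  expect_identical(annotate_pattern(1, 0.4, 1), "regular")
  expect_identical(annotate_pattern(-1, -0.4), "regular")
  # co-model disagreement overrides everything
  expect_identical(annotate_pattern(-1, 0.4, 1), "ambiguous")
})

test_that("candidates absent from the cohort land in the skipped sidecar", {
  cohort <- casp1_cohort()
  expect_warning(pred <- predict_candidate("log2fc", cohort, "NOPE"),
                 "absent")
  expect_length(pred, 0L)
  suppressWarnings(
    calls <- call_targets("log2fc", cohort, c("CASP1", "NOPE"), tf = "IRF8",
                          t = 0.15))
  expect_identical(attr(calls, "skipped"), "NOPE")
  expect_equal(nrow(calls), 1L)
  expect_identical(calls$direction, "Up")
})

test_that("model calls equal fold-change calls when their signs agree", {
  sim <- shared_sim()
  cohort <- shared_cohort()
  model <- shared_model("svm")
  followers <- sim$truth$gene[sim$truth$role == "follower" &
                                sim$truth$tf == "IRF8"]
  m_calls <- call_targets(model, cohort, followers, tf = "IRF8", t = 0)
  f_calls <- call_targets("log2fc", cohort, followers, tf = "IRF8", t = 0)
  agree <- vapply(followers, function(g)
    identical(attr(m_calls, "predictions")[[g]],
              sign(attr(f_calls, "predictions")[[g]])), logical(1))
  expect_identical(m_calls$direction[agree], f_calls$direction[agree])
  expect_gt(sum(agree), 0L)
})

test_that("overlap partitions are exact set algebra", {
  mk <- function(up, down = character(0))
    data.frame(gene = c(up, down),
               direction = c(rep("Up", length(up)), rep("Down", length(down))))
  same <- compare_models(list(a = mk(c("X", "Y")), b = mk(c("X", "Y"))))
  expect_identical(same$Up, list(`a & b` = c("X", "Y")))
  disjoint <- compare_models(list(a = mk("X"), b = mk("Y")))
  expect_false("a & b" %in% names(disjoint$Up))
  three <- compare_models(list(s = mk(c("A", "B")), n = mk(c("B", "C")),
                               l = mk("B")))
  expect_identical(three$Up[["s & n & l"]], "B")
  expect_identical(three$Up[["s"]], "A")
  expect_identical(three$Up[["n"]], "C")
  # counts partition the union
  expect_equal(sum(lengths(three$Up)), 3L)
  expect_error(compare_models(list(mk("X"))), "at least two")
})
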