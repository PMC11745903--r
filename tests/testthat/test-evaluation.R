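# Split-plan invariants and ranking metrics.

check_plan_disjointness <- function(plan, samples) {
  pool <- setdiff(seq_len(nrow(samples)), plan$test)
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    expect_length(intersect(fold$train, fold$val), 0)
    expect_length(intersect(plan$test, c(fold$train, fold$val)), 0)
  }
  invisible(pool)
}

test_that("random/cline/drugcomb folds tile the pool as validation", {
  co <- tiny_cohort(n = 250)
  s <- co$samples
  for (strat in c("random", "cline", "drugcomb")) {
    plan <- make_splits(s, strat, k = 5, seed = 2)
    pool <- check_plan_disjointness(plan, s)
    vals <- unlist(lapply(plan$folds, `[[`, "val"))
    expect_setequal(vals, pool)          # covered exactly once
    expect_equal(anyDuplicated(vals), 0L)
    for (fold in plan$folds) {
      expect_setequal(c(fold$train, fold$val), pool)
    }
  }
})

test_that("cell-line folds hold out whole cell lines", {
  co <- tiny_cohort(n = 250)
  plan <- make_splits(co$samples, "cline", k = 5, test_fraction = 0,
                      seed = 4)
  # 5 cell lines in the tiny cohort: one validation cell line per fold
  for (fold in plan$folds) {
    vc <- unique(co$samples$cell_line[fold$val])
    tc <- unique(co$samples$cell_line[fold$train])
    expect_length(intersect(vc, tc), 0)
  }
  all_vc <- unlist(lapply(plan$folds, function(f)
    unique(co$samples$cell_line[f$val])))
  expect_setequal(all_vc, unique(co$samples$cell_line))
})

test_that("drug-combination folds never share an unordered pair", {
  co <- tiny_cohort(n = 250)
  s <- co$samples
  pair <- paste(pmin(s$drug_a, s$drug_b), pmax(s$drug_a, s$drug_b))
  plan <- make_splits(s, "drugcomb", k = 5, seed = 2)
  for (fold in plan$folds) {
    expect_length(intersect(pair[fold$train], pair[fold$val]), 0)
  }
})

test_that("novel-drug folds hold out exactly one or two drugs per sample", {
  co <- tiny_cohort(n = 250)
  s <- co$samples
  for (strat in c("drugsingle", "drugdouble")) {
    need <- if (strat == "drugsingle") 1L else 2L
    plan <- make_splits(s, strat, k = 5, seed = 2)
    check_plan_disjointness(plan, s)
    for (fold in plan$folds) {
      held <- setdiff(unique(c(s$drug_a[fold$val], s$drug_b[fold$val])),
                      unique(c(s$drug_a[fold$train], s$drug_b[fold$train])))
      n_held <- (s$drug_a %in% held) + (s$drug_b %in% held)
      expect_true(all(n_held[fold$val] == need))
      expect_true(all(n_held[fold$train] == 0L))
    }
  }
})

test_that("single- and double-novel validation sets are disjoint", {
  co <- tiny_cohort(n = 250)
  p1 <- make_splits(co$samples, "drugsingle", k = 5, seed = 2)
  p2 <- make_splits(co$samples, "drugdouble", k = 5, seed = 2)
  for (f in 1:5) {
    expect_length(intersect(p1$folds[[f]]$val, p2$folds[[f]]$val), 0)
  }
})

test_that("the two-pair toy example partitions as expected", {
  s <- data.frame(drug_a = c("A", "C"), drug_b = c("B", "D"),
                  cell_line = "c1", score = c(40, 40), label = 1L)
  plan <- make_splits(s, "drugdouble", k = 2, test_fraction = 0, seed = 1)
  vals <- sort(vapply(plan$folds, function(f) f$val[1], numeric(1)))
  expect_equal(vals, c(1, 2))  # each pair validates once, both drugs novel
  for (fold in plan$folds) expect_length(fold$train, 1)
})

test_that("fold membership is stable under sample reordering", {
  co <- tiny_cohort(n = 200)
  s <- co$samples
  plan <- make_splits(s, "cline", k = 3, seed = 9)
  perm <- sample(nrow(s))
  plan_p <- make_splits(s[perm, ], "cline", k = 3, seed = 9)
  cl_of_fold <- function(plan, s) lapply(plan$folds, function(f)
    sort(unique(s$cell_line[f$val])))
  expect_equal(cl_of_fold(plan, s), cl_of_fold(plan_p, s[perm, ]))
})

test_that("too few grouping units is an informative error", {
  s <- data.frame(drug_a = "A", drug_b = "B", cell_line = c("c1", "c2"),
                  score = 40, label = 1L)
  expect_error(make_splits(s, "cline", k = 5, test_fraction = 0), "units")
  expect_error(make_splits(s, "drugdouble", k = 5, test_fraction = 0),
               "drugs")
})

test_that("metrics match hand cases and the tie convention", {
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(m$auroc, 1); expect_equal(m$auprc, 1); expect_equal(m$f1, 1)

  expect_equal(compute_metrics(c(0, 1, 0, 1), c(0.1, 0.2, 0.3, 0.4))$auroc,
               0.75)
  expect_equal(compute_metrics(c(0, 1, 0, 1), rep(0.5, 4))$auroc, 0.5)
  expect_error(compute_metrics(c(1, 1), c(0.2, 0.3)), "both classes")

  # precision-recall: the 0.5-precision tail case
  m2 <- compute_metrics(c(0, 1), c(0.9, 0.1))
  expect_equal(m2$auprc, 0.5)
})

test_that("AUROC equals Wilcoxon pair counting on random vectors", {
  set.seed(51)
  for (trial in 1:25) {
    n <- sample(10:60, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), 2)   # rounding forces ties
    expect_lt(abs(compute_metrics(labels, scores)$auroc -
                    auroc_paircount(labels, scores)), 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  labels <- rbinom(80, 1, 0.4)
  labels[1:2] <- c(0, 1)
  scores <- rnorm(80)
  ref <- as.numeric(suppressMessages(
    pROC::auc(pROC::roc(labels, scores, direction = "<", quiet = TRUE))))
  expect_equal(compute_metrics(labels, scores)$auroc, ref,
               tolerance = 1e-12)
})

test_that("cross-validation bookkeeping is deterministic", {
  co <- tiny_cohort(n = 300)
  cfg <- tiny_config(max_epochs = 2)
  r1 <- run_cv(co, "random", config = cfg, k = 2, test_fraction = 0.1)
  expect_equal(nrow(r1$fold_metrics), 2)
  expect_equal(r1$summary$metric, c("auroc", "auprc", "f1"))
  expect_true(all(r1$fold_metrics$auroc >= 0 & r1$fold_metrics$auroc <= 1))
  expect_s3_class(r1$checkpoint, "synergy_checkpoint")
  r2 <- run_cv(co, "random", config = cfg, k = 2, test_fraction = 0.1)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$fold_metrics, r2$fold_metrics)
})
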