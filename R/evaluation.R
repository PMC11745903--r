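# Experimental protocol: held-out test split, k-fold cross-validation under
# five stratification strategies, and threshold-free ranking metrics.

#' Build a cross-validation split plan
#'
#' The data is first divided into a held-out test set (`test_fraction`) and
#' a training pool, then the pool is split into `k` folds. Both divisions
#' operate on the strategy's grouping unit so no unit leaks across sets:
#'
#' * `random` -- units are individual samples;
#' * `cline` -- units are cell lines: each fold's validation cell lines are
#'   absent from its training fold;
#' * `drugcomb` -- units are unordered drug pairs (individual drugs may
#'   still overlap);
#' * `drugsingle` -- drugs are partitioned; a fold validates on samples
#'   with exactly one held-out drug, trains on samples with none, and
#'   discards samples with two (shrinking the data);
#' * `drugdouble` -- as above but validation requires both drugs held out.
#'
#' Units are assigned to folds by a deterministic seed-keyed hash of their
#' id, so membership is stable under sample reordering.
#'
#' @param samples synergy sample data.frame.
#' @param strategy one of `"random"`, `"cline"`, `"drugcomb"`,
#'   `"drugsingle"`, `"drugdouble"`.
#' @param k number of folds (default 5).
#' @param test_fraction fraction of grouping units held out for final
#'   testing (default 0.10; 0 disables the test split).
#' @param seed integer seed keying the hash.
#' @return object of class `split_plan`: `folds` (list of `k` lists with
#'   integer `train` and `val` sample indices), `test` (integer indices),
#'   plus the strategy, `k` and seed.
#' @export
make_splits <- function(samples, strategy = c("random", "cline", "drugcomb",
                                              "drugsingle", "drugdouble"),
                        k = 5, test_fraction = 0.10, seed = 1) {
  strategy <- match.arg(strategy)
  n <- nrow(samples)
  drug_mode <- strategy %in% c("drugsingle", "drugdouble")

  unit_of <- switch(strategy,
    random = as.character(seq_len(n)),
    cline = samples$cell_line,
    drugcomb = paste(pmin(samples$drug_a, samples$drug_b),
                     pmax(samples$drug_a, samples$drug_b), sep = "\r"),
    drugsingle = ,
    drugdouble = NULL
  )

  if (!drug_mode) {
    units <- unique(unit_of)
    ord <- units[order(.hash_id(units, seed), units)]
    n_test <- floor(test_fraction * length(ord))
    test_units <- if (n_test > 0) ord[seq_len(n_test)] else character(0)
    pool_units <- setdiff(ord, test_units)
    if (length(pool_units) < k) {
      stop("only ", length(pool_units), " grouping units available for ",
           k, " folds (strategy ", strategy, ")", call. = FALSE)
    }
    fold_of_unit <- stats::setNames(
      rep_len(seq_len(k), length(pool_units)), pool_units)
    test_idx <- which(unit_of %in% test_units)
    pool_idx <- which(unit_of %in% pool_units)
    folds <- lapply(seq_len(k), function(f) {
      vu <- pool_units[fold_of_unit == f]
      val <- pool_idx[unit_of[pool_idx] %in% vu]
      list(train = setdiff(pool_idx, val), val = val)
    })
  } else {
    drugs <- unique(c(samples$drug_a, samples$drug_b))
    ord <- drugs[order(.hash_id(drugs, seed), drugs)]
    n_test <- floor(test_fraction * length(ord))
    test_drugs <- if (n_test > 0) ord[seq_len(n_test)] else character(0)
    pool_drugs <- setdiff(ord, test_drugs)
    if (length(pool_drugs) < k) {
      stop("only ", length(pool_drugs), " drugs available for ", k,
           " folds (strategy ", strategy, ")", call. = FALSE)
    }
    held_test <- (samples$drug_a %in% test_drugs) +
      (samples$drug_b %in% test_drugs)
    need <- if (strategy == "drugsingle") 1L else 2L
    test_idx <- which(held_test == need)
    pool_idx <- which(held_test == 0L)
    fold_of_drug <- stats::setNames(
      rep_len(seq_len(k), length(pool_drugs)), pool_drugs)
    folds <- lapply(seq_len(k), function(f) {
      held <- pool_drugs[fold_of_drug == f]
      n_held <- (samples$drug_a %in% held) + (samples$drug_b %in% held)
      list(train = pool_idx[n_held[pool_idx] == 0L],
           val = pool_idx[n_held[pool_idx] == need])
    })
  }

  structure(list(strategy = strategy, k = as.integer(k), seed = seed,
                 test_fraction = test_fraction, folds = folds,
                 test = test_idx),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> strategy=", x$strategy, ", k=", x$k, ", test=",
      length(x$test), " samples\n", sep = "")
  for (f in seq_along(x$folds)) {
    cat("  fold ", f, ": train=", length(x$folds[[f]]$train),
        " val=", length(x$folds[[f]]$val), "\n", sep = "")
  }
  invisible(x)
}

#' Ranking metrics for binary synergy classification
#'
#' AUROC is the probability that a random positive outranks a random
#' negative, with half credit for ties (the rank-statistic definition);
#' AUPRC is the area under the precision-recall curve by step
#' interpolation (tied scores processed as one block); F1 is computed at a
#' fixed probability threshold.
#'
#' @param labels 0/1 vector (both classes must be present).
#' @param scores numeric scores, higher = more likely positive.
#' @param f1_threshold probability threshold for F1 (default 0.5).
#' @return object of class `metric_set`: list with `auroc`, `auprc`, `f1`.
#' @export
compute_metrics <- function(labels, scores, f1_threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUROC/AUPRC",
         call. = FALSE)
  }
  r <- rank(scores)  # average ranks: ties get half credit
  auroc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  o <- order(scores, decreasing = TRUE)
  ls <- labels[o]
  ss <- scores[o]
  grp_last <- !duplicated(ss, fromLast = TRUE)  # block ends of tied scores
  tp <- cumsum(ls)[grp_last]
  np <- cumsum(rep(1, length(ls)))[grp_last]
  recall <- tp / n1
  precision <- tp / np
  auprc <- sum(diff(c(0, recall)) * precision)

  pred <- as.integer(scores >= f1_threshold)
  tp_f <- sum(pred == 1L & labels == 1L)
  prec_f <- if (sum(pred) > 0) tp_f / sum(pred) else 0
  rec_f <- tp_f / n1
  f1 <- if (prec_f + rec_f > 0) 2 * prec_f * rec_f / (prec_f + rec_f) else 0

  structure(list(auroc = auroc, auprc = auprc, f1 = f1),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> AUROC %.4f | AUPRC %.4f | F1 %.4f\n",
              x$auroc, x$auprc, x$f1))
  invisible(x)
}

#' Run k-fold cross-validation under a stratification strategy
#'
#' Trains one model per fold via [train_synergy_model()], collects per-fold
#' validation metrics and their mean/sd, and evaluates the best-validation
#' fold's model on the held-out test set (when present).
#'
#' @param cohort the cohort list (see [train_synergy_model()]).
#' @param strategy stratification strategy (see [make_splits()]).
#' @param config a [train_config()]; fold f trains with seed
#'   `config$seed + f` so folds differ in initialization while the whole
#'   run stays reproducible.
#' @param k folds (default 5).
#' @param test_fraction held-out test fraction (default 0.10).
#' @return list with `fold_metrics` (data.frame), `summary` (mean/sd),
#'   `test_metrics` (or `NULL`), `best_fold`, `checkpoint` (best fold's),
#'   `plan`, and per-fold training `reports`.
#' @export
run_cv <- function(cohort, strategy = "random", config = train_config(),
                   k = 5, test_fraction = 0.10) {
  samples <- .ensure_labels(cohort$samples, config$threshold)
  cohort$samples <- samples
  plan <- make_splits(samples, strategy, k = k,
                      test_fraction = test_fraction, seed = config$seed)
  graphs <- .build_drug_graphs(cohort$drugs)
  fold_metrics <- data.frame(fold = integer(0), auroc = numeric(0),
                             auprc = numeric(0), f1 = numeric(0))
  best <- list(auroc = -Inf, fold = NA_integer_, checkpoint = NULL)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    fit <- train_synergy_model(cohort, plan, fold = f, config = cfg_f,
                               graphs = graphs)
    val_idx <- plan$folds[[f]]$val
    val_prob <- predict_triplets(fit$checkpoint, cohort,
                                 samples[val_idx, , drop = FALSE],
                                 graphs = graphs)
    m <- compute_metrics(samples$label[val_idx], val_prob)
    fold_metrics <- rbind(fold_metrics,
                          data.frame(fold = f, auroc = m$auroc,
                                     auprc = m$auprc, f1 = m$f1))
    reports[[f]] <- fit$report
    if (m$auroc > best$auroc) {
      best <- list(auroc = m$auroc, fold = f, checkpoint = fit$checkpoint)
    }
  }
  summary_df <- data.frame(
    metric = c("auroc", "auprc", "f1"),
    mean = c(mean(fold_metrics$auroc), mean(fold_metrics$auprc),
             mean(fold_metrics$f1)),
    sd = c(stats::sd(fold_metrics$auroc), stats::sd(fold_metrics$auprc),
           stats::sd(fold_metrics$f1))
  )
  test_metrics <- NULL
  if (length(plan$test) > 0 &&
      length(unique(samples$label[plan$test])) == 2) {
    test_prob <- predict_triplets(best$checkpoint, cohort,
                                  samples[plan$test, , drop = FALSE],
                                  graphs = graphs)
    test_metrics <- compute_metrics(samples$label[plan$test], test_prob)
  }
  list(fold_metrics = fold_metrics, summary = summary_df,
       test_metrics = test_metrics, best_fold = best$fold,
       checkpoint = best$checkpoint, plan = plan, reports = reports)
}
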