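# Training-loop contracts on a deliberately small cohort and model.

make_split <- function(co, frac = 0.8, seed = 3) {
  n <- nrow(co$samples)
  set.seed(seed)
  tr <- sample(n, floor(frac * n))
  list(train = tr, val = setdiff(seq_len(n), tr))
}

test_that("training is bitwise reproducible under a fixed seed", {
  co <- tiny_cohort()
  sp <- make_split(co)
  cfg <- tiny_config(max_epochs = 3)
  f1 <- train_synergy_model(co, sp, config = cfg)
  f2 <- train_synergy_model(co, sp, config = cfg)
  expect_identical(f1$report$history$train_loss[1],
                   f2$report$history$train_loss[1])
  expect_identical(f1$report$epochs_run, f2$report$epochs_run)
  expect_identical(f1$checkpoint$params, f2$checkpoint$params)
})

test_that("zero learning rate freezes the parameters", {
  co <- tiny_cohort()
  sp <- make_split(co)
  cfg <- tiny_config(learning_rate = 0, max_epochs = 3)
  fit <- train_synergy_model(co, sp, config = cfg)
  set.seed(cfg$seed)
  ws <- hypersyn:::.build_workspace(
    co, cfg, hypersyn:::.ensure_labels(co$samples, 30)[sp$train, ])
  init <- hypersyn:::.init_params(cfg, ncol(ws$batch$A0), ncol(ws$expr),
                                  ncol(ws$emb))
  expect_equal(fit$checkpoint$params, init, tolerance = 1e-15,
               ignore_attr = TRUE)
  expect_equal(length(unique(fit$report$history$val_auroc)), 1L)
})

test_that("early stopping fires one patience window after the best epoch", {
  co <- tiny_cohort()
  sp <- make_split(co)
  cfg <- tiny_config(patience = 1, max_epochs = 30)
  fit <- train_synergy_model(co, sp, config = cfg)
  if (fit$report$stopping == "patience") {
    expect_equal(fit$report$epochs_run, fit$report$best_epoch + 1L)
  } else {
    expect_equal(fit$report$epochs_run, cfg$max_epochs)
  }
})

test_that("training rejects degenerate folds", {
  co <- tiny_cohort()
  expect_error(
    train_synergy_model(co, list(train = 1:100, val = integer(0)),
                        config = tiny_config()),
    "empty")
  expect_error(
    train_synergy_model(co, list(train = 1:100, val = 90:110),
                        config = tiny_config()),
    "overlap")
  co2 <- co
  co2$samples$label <- binarize_synergy(co2$samples$score)
  one_class <- which(co2$samples$label == 1L)[1:5]
  expect_error(
    train_synergy_model(co2, list(train = setdiff(1:200, one_class),
                                  val = one_class),
                        config = tiny_config()),
    "single class")
})

test_that("weight decay shrinks the weights under an identical schedule", {
  co <- tiny_cohort()
  sp <- make_split(co)
  l2_of <- function(wd) {
    fit <- train_synergy_model(
      co, sp, config = tiny_config(weight_decay = wd, max_epochs = 6,
                                   patience = 99))
    p <- fit$checkpoint$params
    sq <- 0
    walk <- function(x) {
      if (is.list(x)) lapply(x, walk) else sq <<- sq + sum(x^2)
      invisible(NULL)
    }
    walk(list(p$gtn, p$cell$weight, p$hgnn, p$pred))
    sq
  }
  expect_lt(l2_of(0.1), l2_of(0))
})

test_that("checkpoints round-trip through disk bit-faithfully enough", {
  co <- tiny_cohort()
  sp <- make_split(co)
  fit <- train_synergy_model(co, sp, config = tiny_config(max_epochs = 2))
  pred1 <- predict_triplets(fit$checkpoint, co, co$samples[1:20, ])
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit$checkpoint, path)
  ck <- load_checkpoint(path)
  pred2 <- predict_triplets(ck, co, co$samples[1:20, ])
  expect_equal(pred1, pred2, tolerance = 1e-7)
  not_ck <- tempfile(fileext = ".rds")
  saveRDS(list(1), not_ck)
  expect_error(load_checkpoint(not_ck), "checkpoint")
})

test_that("ablation switches produce runnable models", {
  co <- tiny_cohort()
  sp <- make_split(co)
  for (cfg in list(tiny_config(max_epochs = 2, use_transformer = FALSE),
                   tiny_config(max_epochs = 2, use_disease = FALSE),
                   tiny_config(max_epochs = 2,
                               residual_mode = "no_residual"),
                   tiny_config(max_epochs = 2,
                               residual_mode = "plain_residual"))) {
    fit <- train_synergy_model(co, sp, config = cfg)
    prob <- predict_triplets(fit$checkpoint, co, co$samples[1:10, ])
    expect_true(all(prob > 0 & prob < 1))
  }
})
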