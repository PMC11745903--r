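# Orchestration of a single training run and checkpoint round trips.

#' @keywords internal
.triplet_rows <- function(samples, index) {
  cbind(node_position(index, "drug", samples$drug_a),
        node_position(index, "drug", samples$drug_b),
        node_position(index, "cell_line", samples$cell_line))
}

#' @keywords internal
.ensure_labels <- function(samples, threshold) {
  if (all(is.na(samples$label))) {
    samples$label <- binarize_synergy(samples$score, threshold)
  }
  samples
}

#' @keywords internal
.ensure_preprocessed <- function(expr) {
  if (isTRUE(attr(expr, "preprocessed"))) expr else
    preprocess_expression(expr)
}

#' @keywords internal
.build_drug_graphs <- function(drugs) {
  graphs <- vector("list", nrow(drugs))
  for (k in seq_len(nrow(drugs))) {
    graphs[[k]] <- smiles_to_graph(drugs$smiles[k],
                                   drug_id = drugs$drug_id[k])
  }
  names(graphs) <- drugs$drug_id
  graphs
}

# Assemble the static per-fold workspace: packed molecular graphs, the
# preprocessed expression/embedding matrices, the node index, and the
# normalized propagation operator of the training-fold hypergraph.
#' @keywords internal
.build_workspace <- function(cohort, cfg, hyperedge_samples, graphs = NULL) {
  expr <- .ensure_preprocessed(cohort$expr)
  use_dis <- cfg$use_disease && !is.null(cohort$pairs) &&
    !is.null(cohort$embeddings) && nrow(cohort$embeddings) > 0
  emb <- if (use_dis) cohort$embeddings
  index <- build_node_index(
    cohort$drugs$drug_id, rownames(expr),
    if (use_dis) rownames(emb) else character(0)
  )
  if (is.null(graphs)) graphs <- .build_drug_graphs(cohort$drugs)
  batch <- .gtn_batch_from_graphs(graphs[index$drugs])
  hg <- build_hypergraph(hyperedge_samples,
                         if (use_dis) cohort$pairs else NULL,
                         index, cfg$interaction_weight,
                         positives_only = cfg$positives_only_hyperedges)
  list(batch = batch, expr = expr, emb = emb, P = .hg_operator(hg),
       index = index, hg = hg, n_drugs = length(index$drugs),
       graphs = graphs)
}

#' Train the synergy model on one cross-validation fold
#'
#' Runs the full pipeline -- molecular-graph encoding, cell-line/disease
#' encoders, hypergraph built from the training fold's positive triplets,
#' gated-residual refinement, triplet predictor -- and optimizes all
#' parameters jointly with AdamW on the cross-entropy loss. Training
#' batches receive symmetric permutation augmentation (each batch carries
#' both drug orders of its samples); validation AUROC is monitored every
#' epoch and training stops when it fails to improve for
#' `config$patience` epochs. Fully reproducible given `config$seed`.
#'
#' @param cohort list with `samples`, `drugs`, `expr`, and optionally
#'   `pairs` and `embeddings` (as produced by the readers,
#'   [filter_entities()], or [generate_cohort()]).
#' @param split a `split_plan` from [make_splits()], or a list with
#'   integer elements `train` and `val` indexing `cohort$samples`.
#' @param fold fold number within the split plan (default 1).
#' @param config a [train_config()].
#' @param graphs optional precomputed molecular graphs (named by drug id),
#'   to avoid re-parsing SMILES across folds.
#' @return list with `checkpoint` (class `synergy_checkpoint`) and
#'   `report` (per-epoch history, best epoch, stopping reason).
#' @export
train_synergy_model <- function(cohort, split, fold = 1,
                                config = train_config(), graphs = NULL) {
  cfg <- config
  samples <- .ensure_labels(cohort$samples, cfg$threshold)
  if (inherits(split, "split_plan")) {
    train_idx <- split$folds[[fold]]$train
    val_idx <- split$folds[[fold]]$val
  } else {
    train_idx <- split$train
    val_idx <- split$val
  }
  if (length(val_idx) == 0) stop("validation fold is empty", call. = FALSE)
  if (length(intersect(train_idx, val_idx)) > 0) {
    stop("train and validation folds overlap", call. = FALSE)
  }
  if (length(unique(samples$label[val_idx])) < 2) {
    stop("validation fold has a single class; AUROC undefined",
         call. = FALSE)
  }

  set.seed(cfg$seed)
  ws <- .build_workspace(cohort, cfg, samples[train_idx, , drop = FALSE],
                         graphs = graphs)
  params <- .init_params(cfg, in_dim_atoms = ncol(ws$batch$A0),
                         n_genes = ncol(ws$expr),
                         emb_dim = if (!is.null(ws$emb)) ncol(ws$emb))
  opt <- .adamw_init(params)

  val_rows <- .triplet_rows(samples[val_idx, , drop = FALSE], ws$index)
  val_labels <- samples$label[val_idx]

  # symmetric augmentation: every training batch carries both drug orders
  # of its samples, which actively pushes the scorer toward order
  # invariance within each optimizer step
  b0 <- if (cfg$augment) max(1L, cfg$batch_size %/% 2L) else cfg$batch_size
  lr <- cfg$learning_rate
  best <- list(auroc = -Inf, params = params, epoch = 0L)
  since_best <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auroc = numeric(0))
  reason <- "max_epochs"

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample(train_idx)
    losses <- numeric(0)
    sizes <- integer(0)
    for (start in seq(1, length(perm), by = b0)) {
      idx <- perm[start:min(start + b0 - 1L, length(perm))]
      bsamp <- samples[idx, , drop = FALSE]
      if (cfg$augment) bsamp <- augment_symmetric(bsamp)
      rows <- .triplet_rows(bsamp, ws$index)
      y <- bsamp$label
      fw <- .model_forward(params, ws, rows, cfg, train = TRUE,
                           keep_cache = TRUE)
      loss <- bce_loss(y, fw$prob)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch,
             " (batch starting at sample ", start, ")", call. = FALSE)
      }
      grads <- .model_backward(params, ws, rows, y, fw, cfg)
      upd <- .adamw_step(params, grads, opt, lr, cfg$weight_decay)
      params <- upd$params
      opt <- upd$state
      losses <- c(losses, loss)
      sizes <- c(sizes, length(y))
    }
    epoch_loss <- sum(losses * sizes) / sum(sizes)

    val_prob <- .model_forward(params, ws, val_rows, cfg,
                               train = FALSE)$prob
    val_auroc <- compute_metrics(val_labels, val_prob)$auroc
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss,
                                         val_auroc = val_auroc))
    if (val_auroc > best$auroc) {
      best <- list(auroc = val_auroc, params = params, epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience) {
        reason <- "patience"
        break
      }
      # reduce-on-plateau learning-rate schedule
      if (cfg$lr_decay_factor < 1 &&
          since_best %% cfg$lr_decay_patience == 0L) {
        lr <- lr * cfg$lr_decay_factor
      }
    }
  }

  checkpoint <- structure(
    list(params = best$params, config = cfg, index = ws$index,
         hypergraph = ws$hg, scheme = "convmol75",
         best_epoch = best$epoch, best_val_auroc = best$auroc,
         drug_smiles = stats::setNames(cohort$drugs$smiles,
                                       cohort$drugs$drug_id)),
    class = "synergy_checkpoint"
  )
  report <- list(history = history, best_epoch = best$epoch,
                 epochs_run = nrow(history), stopping = reason)
  list(checkpoint = checkpoint, report = report)
}

#' Score triplets with a trained checkpoint
#'
#' Rebuilds the deterministic forward pass (no dropout) from the
#' checkpoint's parameters and training-fold hypergraph, and scores each
#' (drug_a, drug_b, cell_line) row in its stored orientation.
#'
#' @param checkpoint a `synergy_checkpoint`.
#' @param cohort the cohort supplying expression, embeddings and SMILES.
#' @param triplets data.frame with `drug_a`, `drug_b`, `cell_line`
#'   (default: `cohort$samples`).
#' @param graphs optional precomputed molecular graphs named by drug id.
#' @return numeric vector of synergy probabilities.
#' @export
predict_triplets <- function(checkpoint, cohort, triplets = NULL,
                             graphs = NULL) {
  stopifnot(inherits(checkpoint, "synergy_checkpoint"))
  if (is.null(triplets)) triplets <- cohort$samples
  cfg <- checkpoint$config
  index <- checkpoint$index
  expr <- .ensure_preprocessed(cohort$expr)
  expr <- expr[index$cell_lines, , drop = FALSE]
  emb <- if (length(index$diseases) > 0) {
    cohort$embeddings[index$diseases, , drop = FALSE]
  }
  drugs <- data.frame(drug_id = index$drugs,
                      smiles = unname(checkpoint$drug_smiles[index$drugs]),
                      stringsAsFactors = FALSE)
  if (is.null(graphs)) graphs <- .build_drug_graphs(drugs)
  batch <- .gtn_batch_from_graphs(graphs[index$drugs])
  ws <- list(batch = batch, expr = expr, emb = emb,
             P = .hg_operator(checkpoint$hypergraph), index = index,
             n_drugs = length(index$drugs))
  rows <- .triplet_rows(triplets, index)
  .model_forward(checkpoint$params, ws, rows, cfg, train = FALSE)$prob
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing archive holding every parameter
#' matrix, the training configuration, the entity index, the training-fold
#' hypergraph, and the SMILES needed to rebuild drug graphs.
#'
#' @param checkpoint a `synergy_checkpoint`.
#' @param path file path.
#' @return `path` invisibly (save); the checkpoint (load).
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "synergy_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "synergy_checkpoint")) {
    stop("not a synergy checkpoint: ", path, call. = FALSE)
  }
  ck
}
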