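# Triplet predictor: an MLP over the concatenated refined features of
# (drug_a, drug_b, cell_line), with a sigmoid output unit. The default is
# the literal single affine layer; hidden layers are available by
# configuration.

#' Construct predictor parameters
#'
#' @param in_dim input dimension (3 x common feature dimension).
#' @param hidden integer vector of hidden layer widths (default none: a
#'   single affine layer plus sigmoid).
#' @param hidden_activation activation id for hidden layers.
#' @param init `"glorot"` (current RNG stream) or `"zero"`.
#' @return object of class `predictor_params`: `layers` is a list of
#'   `(weight, bias)` pairs ending in a scalar output unit.
#' @export
predictor_params <- function(in_dim, hidden = integer(0),
                             hidden_activation = "relu",
                             init = c("glorot", "zero")) {
  init <- match.arg(init)
  dims <- c(in_dim, hidden, 1L)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    W <- if (init == "zero") matrix(0, dims[l + 1], dims[l]) else
      .glorot(dims[l + 1], dims[l])
    layers[[l]] <- list(weight = W, bias = rep(0, dims[l + 1]))
  }
  structure(list(layers = layers, hidden_activation = hidden_activation),
            class = "predictor_params")
}

#' @keywords internal
.predictor_forward <- function(Z, pp) {
  act <- .get_activation(pp$hidden_activation)
  L <- length(pp$layers)
  pres <- vector("list", L)
  H <- Z
  hs <- vector("list", L)  # inputs to each layer
  for (l in seq_len(L)) {
    hs[[l]] <- H
    p <- pp$layers[[l]]
    pre <- H %*% t(p$weight) +
      matrix(p$bias, nrow(H), length(p$bias), byrow = TRUE)
    pres[[l]] <- pre
    H <- if (l < L) act$f(pre) else pre
  }
  prob <- .sigmoid(as.numeric(H))
  list(prob = prob, logit = as.numeric(H), pres = pres, inputs = hs)
}

# Backward from d(logit); returns layer gradients and dZ.
#' @keywords internal
.predictor_backward <- function(dlogit, fw, pp) {
  act <- .get_activation(pp$hidden_activation)
  L <- length(pp$layers)
  grads <- vector("list", L)
  dH <- matrix(dlogit, ncol = 1)
  for (l in rev(seq_len(L))) {
    p <- pp$layers[[l]]
    dPre <- if (l < L) {
      y <- act$f(fw$pres[[l]])
      dH * act$grad(fw$pres[[l]], y)
    } else dH
    grads[[l]] <- list(weight = t(dPre) %*% fw$inputs[[l]],
                       bias = colSums(dPre))
    dH <- dPre %*% p$weight
  }
  list(grads = grads, dZ = dH)
}

#' Vertically stack the per-modality feature blocks
#'
#' Stacks drugs, cell lines, and diseases (in node-index order) into the
#' global feature matrix.
#'
#' @param X_drug drugs x dim matrix.
#' @param X_cell cell lines x dim matrix.
#' @param X_dis diseases x dim matrix, or `NULL` for the disease-free
#'   ablation.
#' @return nodes x dim matrix.
#' @export
assemble_features <- function(X_drug, X_cell, X_dis = NULL) {
  blocks <- Filter(Negate(is.null), list(X_drug, X_cell, X_dis))
  dims <- vapply(blocks, ncol, integer(1))
  if (length(unique(dims)) != 1) {
    stop("feature blocks disagree on dimension: ",
         paste(dims, collapse = " vs "), call. = FALSE)
  }
  do.call(rbind, blocks)
}

#' Score one drug-drug-cell-line triplet
#'
#' Concatenates the refined features of drug_a, drug_b, and the cell line
#' (in that order), applies the predictor stack, and returns the sigmoid
#' probability of synergy. Architectural symmetry in the drug order is not
#' enforced; it is acquired through augmented training.
#'
#' @param refined nodes x dim refined feature matrix (node-index order).
#' @param triplet character vector `(drug_a, drug_b, cell_line)`.
#' @param index the `node_index`.
#' @param params a `predictor_params`.
#' @return probability in (0, 1).
#' @export
predict_synergy <- function(refined, triplet, index, params) {
  stopifnot(inherits(params, "predictor_params"), length(triplet) == 3)
  rows <- c(node_position(index, "drug", triplet[1]),
            node_position(index, "drug", triplet[2]),
            node_position(index, "cell_line", triplet[3]))
  z <- matrix(as.numeric(t(refined[rows, , drop = FALSE])), nrow = 1)
  .predictor_forward(z, params)$prob
}

#' Symmetric permutation augmentation of synergy samples
#'
#' Adds the drug-swapped twin of every sample, with the same score and
#' label, so the learned scorer becomes agnostic to drug order. Samples
#' whose swap is identical to the original (`drug_a == drug_b`) are not
#' duplicated.
#'
#' @param samples synergy sample data.frame.
#' @return augmented data.frame (originals first, twins after).
#' @export
augment_symmetric <- function(samples) {
  twins <- samples[samples$drug_a != samples$drug_b, , drop = FALSE]
  if (nrow(twins) > 0) {
    tmp <- twins$drug_a
    twins$drug_a <- twins$drug_b
    twins$drug_b <- tmp
  }
  out <- rbind(samples, twins)
  rownames(out) <- NULL
  out
}

#' Binary cross-entropy loss
#'
#' `-(1/N) sum( y log p + (1-y) log(1-p) )`, with probabilities clipped to
#' `[eps, 1-eps]` to stay finite.
#'
#' @param labels 0/1 vector.
#' @param probabilities predicted probabilities, same length.
#' @param eps clipping constant (default 1e-7).
#' @return the mean loss (scalar).
#' @export
bce_loss <- function(labels, probabilities, eps = 1e-7) {
  if (length(labels) != length(probabilities)) {
    stop("labels (", length(labels), ") and probabilities (",
         length(probabilities), ") differ in length", call. = FALSE)
  }
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}
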