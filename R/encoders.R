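# Single-layer perceptron encoders mapping cell-line expression rows and
# disease embedding rows into the common feature space shared with drugs.

#' Parameters of a single-layer perceptron encoder
#'
#' @param weight out_dim x in_dim numeric matrix.
#' @param bias out_dim numeric vector.
#' @param activation activation id (default `"relu"`).
#' @return object of class `mlp_params`.
#' @export
mlp_params <- function(weight, bias, activation = "relu") {
  weight <- as.matrix(weight)
  bias <- as.numeric(bias)
  if (length(bias) != nrow(weight)) {
    stop("bias length ", length(bias), " does not match weight rows ",
         nrow(weight), call. = FALSE)
  }
  .check_finite(weight, "encoder weight")
  .check_finite(bias, "encoder bias")
  structure(list(weight = weight, bias = bias, activation = activation),
            class = "mlp_params")
}

#' @keywords internal
.mlp_forward <- function(X, params) {
  act <- .get_activation(params$activation)
  pre <- X %*% t(params$weight) +
    matrix(params$bias, nrow(X), length(params$bias), byrow = TRUE)
  list(out = act$f(pre), pre = pre)
}

#' Encode cell lines into the common feature space
#'
#' Row k of the output is `activation(W c_k + b)` where `c_k` is the
#' preprocessed (log2, z-scored) expression profile of cell line k.
#'
#' @param expr preprocessed expression matrix (cell lines x genes).
#' @param params `mlp_params` whose `in_dim` equals the gene count.
#' @return cell lines x common-dim matrix with the input row names.
#' @export
encode_cell_lines <- function(expr, params) {
  stopifnot(inherits(params, "mlp_params"))
  if (ncol(expr) != ncol(params$weight)) {
    stop("encoder expects ", ncol(params$weight), " genes, got ",
         ncol(expr), call. = FALSE)
  }
  out <- .mlp_forward(expr, params)$out
  rownames(out) <- rownames(expr)
  out
}

#' Encode diseases into the common feature space
#'
#' Applies the same affine-plus-activation contract as
#' [encode_cell_lines()] to precomputed disease embedding vectors.
#'
#' @param embeddings disease embedding matrix (diseases x embedding dim).
#' @param params `mlp_params` whose `in_dim` equals the embedding length.
#' @return diseases x common-dim matrix with the input row names.
#' @export
encode_diseases <- function(embeddings, params) {
  stopifnot(inherits(params, "mlp_params"))
  if (ncol(embeddings) != ncol(params$weight)) {
    stop("encoder expects embedding length ", ncol(params$weight),
         ", got ", ncol(embeddings), call. = FALSE)
  }
  out <- .mlp_forward(embeddings, params)$out
  rownames(out) <- rownames(embeddings)
  out
}
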