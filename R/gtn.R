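# Multi-head graph-transformer layers over molecular graphs.
#
# Per layer, atom i is updated as
#   a'_i = sigma( W1 a_i + sum_{j in N(i)} alpha_ij W2 a_j ),
# where alpha_ij is a scaled dot-product attention coefficient
#   alpha_ij = softmax_j( (W3 a_i)' (W4 a_j) / sqrt(d) )
# computed per head and the per-head weighted sums are averaged. The final
# layer's atom features are max-pooled into one vector per drug.

.LOGIT_CLIP <- 30  # attention logits are clipped here before exp()

#' Parameters of one graph-transformer layer
#'
#' @param in_dim input feature dimension.
#' @param out_dim output feature dimension.
#' @param heads number of attention heads (default 4).
#' @param d per-head latent size; default `max(1, out_dim %/% heads)`.
#' @param init `"glorot"` (draws from the current RNG stream) or `"zero"`.
#' @return object of class `gtn_layer_params` with dense matrices `W1`, `W2`
#'   (out_dim x in_dim) and `W3`, `W4` (heads*d x in_dim).
#' @export
gtn_params <- function(in_dim, out_dim, heads = 4, d = NULL,
                       init = c("glorot", "zero")) {
  init <- match.arg(init)
  if (is.null(d)) d <- max(1L, out_dim %/% heads)
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc) else .glorot(nr, nc)
  }
  structure(
    list(W1 = mk(out_dim, in_dim), W2 = mk(out_dim, in_dim),
         W3 = mk(heads * d, in_dim), W4 = mk(heads * d, in_dim),
         heads = as.integer(heads), d = as.integer(d)),
    class = "gtn_layer_params"
  )
}

#' Multi-head attention coefficients of one atom over its neighbors
#'
#' For each head h, the coefficient over neighbor j is the softmax (over
#' `N(i)`) of the scaled dot product of the head's slices of `W3 a_i` and
#' `W4 a_j`, divided by `sqrt(d)`.
#'
#' @param graph a `molecular_graph`.
#' @param i atom index (1-based).
#' @param params a `gtn_layer_params`.
#' @return heads x |N(i)| matrix; every row sums to 1. Column names give the
#'   neighbor atom indices.
#' @export
attention_coefficients <- function(graph, i, params) {
  stopifnot(inherits(params, "gtn_layer_params"))
  if (i < 1 || i > graph$n_atoms) stop("atom index out of range: ", i,
                                       call. = FALSE)
  nb <- .mg_neighbors(graph)[[i]]
  if (length(nb) == 0) {
    stop("atom ", i, " has no neighbors; attention undefined", call. = FALSE)
  }
  A <- graph$atom_features
  d <- params$d; heads <- params$heads
  qi <- as.numeric(params$W3 %*% A[i, ])        # heads*d
  K <- A[nb, , drop = FALSE] %*% t(params$W4)   # |N| x heads*d
  out <- matrix(0, heads, length(nb),
                dimnames = list(NULL, as.character(nb)))
  for (h in seq_len(heads)) {
    sl <- (h - 1) * d + seq_len(d)
    logits <- as.numeric(K[, sl, drop = FALSE] %*% qi[sl]) / sqrt(d)
    logits <- pmin(pmax(logits, -.LOGIT_CLIP), .LOGIT_CLIP)
    e <- exp(logits - max(logits))
    out[h, ] <- e / sum(e)
  }
  out
}

#' Apply one graph-transformer layer to a molecular graph
#'
#' Each atom's feature becomes
#' `activation(W1 a_i + mean_h sum_j alpha_ij^h W2 a_j)`; isolated atoms get
#' `activation(W1 a_i)` (empty neighbor sum).
#'
#' @param graph a `molecular_graph` (or any object with `atom_features` and
#'   `bonds`).
#' @param params a `gtn_layer_params` whose `in_dim` matches the feature
#'   dimension.
#' @param activation activation id (default `"relu"`).
#' @return updated atom-feature matrix (atoms x out_dim).
#' @export
gtn_layer <- function(graph, params, activation = "relu") {
  batch <- .gtn_batch_from_graphs(list(graph))
  fw <- .gtn_forward(batch, list(params), activation = activation,
                     keep_cache = FALSE)
  fw$atom_features
}

#' Max-pooling readout of atom features into one drug vector
#'
#' @param atom_features atoms x dim numeric matrix (at least one row).
#' @return numeric vector of columnwise maxima.
#' @export
readout_max <- function(atom_features) {
  atom_features <- as.matrix(atom_features)
  if (nrow(atom_features) == 0) {
    stop("cannot max-pool a molecule with zero atoms", call. = FALSE)
  }
  apply(atom_features, 2, max)
}

# ---------------------------------------------------------------------------
# Batched engine: all drugs' molecular graphs are packed into one disjoint
# union so the whole drug set is encoded with a few dense matrix products.

#' @keywords internal
.gtn_batch_from_graphs <- function(graphs) {
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offs <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  A0 <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  ei <- integer(0); ej <- integer(0)
  for (k in seq_along(graphs)) {
    b <- graphs[[k]]$bonds
    if (nrow(b) > 0) {
      ei <- c(ei, b[, 1] + offs[k], b[, 2] + offs[k])
      ej <- c(ej, b[, 2] + offs[k], b[, 1] + offs[k])
    }
  }
  N <- sum(n_atoms)
  E <- length(ei)
  # aggregation matrices: Si rows collect edges by target, Sj by source
  Si <- Matrix::sparseMatrix(i = ei, j = seq_len(E), x = 1, dims = c(N, E))
  Sj <- Matrix::sparseMatrix(i = ej, j = seq_len(E), x = 1, dims = c(N, E))
  atom_of <- rep(seq_along(graphs), n_atoms)
  list(A0 = A0, ei = ei, ej = ej, Si = Si, Sj = Sj, n_graphs = length(graphs),
       graph_of_atom = atom_of,
       atoms_of_graph = split(seq_len(N), atom_of))
}

# Forward pass of a GTN stack over a packed batch; returns final atom
# features, per-graph max-pooled drug vectors, and (optionally) the cache
# needed for the backward pass.
#' @keywords internal
.gtn_forward <- function(batch, layers, activation = "relu",
                         keep_cache = TRUE, use_attention = TRUE) {
  act <- .get_activation(activation)
  A <- batch$A0
  E <- length(batch$ei)
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    p <- layers[[l]]
    heads <- p$heads; d <- p$d
    self_term <- A %*% t(p$W1)                  # N x out
    M <- A %*% t(p$W2)                          # N x out
    agg <- matrix(0, nrow(A), nrow(p$W1))
    cache_l <- NULL
    if (E > 0 && !use_attention) {
      # neighbor-mean ablation: uniform coefficients 1/|N(i)|
      deg <- as.numeric(batch$Si %*% rep(1, E))
      w_e <- 1 / deg[batch$ei]
      agg <- as.matrix(batch$Si %*% (w_e * M[batch$ej, , drop = FALSE]))
      if (keep_cache) cache_l <- list(A_in = A, M = M, w_e = w_e)
    } else if (E > 0) {
      Q <- A %*% t(p$W3)                        # N x heads*d
      K <- A %*% t(p$W4)
      QK <- Q[batch$ei, , drop = FALSE] * K[batch$ej, , drop = FALSE]
      # per-head logits: block row sums of QK
      L <- matrix(0, E, heads)
      for (h in seq_len(heads)) {
        sl <- (h - 1) * d + seq_len(d)
        L[, h] <- rowSums(QK[, sl, drop = FALSE]) / sqrt(d)
      }
      raw <- L
      L <- pmin(pmax(L, -.LOGIT_CLIP), .LOGIT_CLIP)
      expL <- exp(L)
      denom <- as.matrix(batch$Si %*% expL)     # N x heads
      alpha <- expL / pmax(denom[batch$ei, , drop = FALSE],
                           .Machine$double.xmin)
      for (h in seq_len(heads)) {
        agg <- agg + as.matrix(batch$Si %*%
                                 (alpha[, h] * M[batch$ej, , drop = FALSE]))
      }
      agg <- agg / heads
      if (keep_cache) {
        cache_l <- list(A_in = A, Q = Q, K = K, M = M, alpha = alpha,
                        raw = raw)
      }
    } else if (keep_cache) {
      cache_l <- list(A_in = A, M = M)
    }
    pre <- self_term + agg
    A <- act$f(pre)
    if (keep_cache) {
      cache_l$pre <- pre
      caches[[l]] <- cache_l
    }
  }
  # max-pool readout per graph
  dim_out <- ncol(A)
  drug_mat <- matrix(0, batch$n_graphs, dim_out)
  argmax <- matrix(0L, batch$n_graphs, dim_out)
  for (g in seq_len(batch$n_graphs)) {
    rows <- batch$atoms_of_graph[[g]]
    sub <- A[rows, , drop = FALSE]
    am <- max.col(t(sub), ties.method = "first")
    argmax[g, ] <- rows[am]
    drug_mat[g, ] <- sub[cbind(am, seq_len(dim_out))]
  }
  list(atom_features = A, drug_mat = drug_mat,
       cache = if (keep_cache) list(layers = caches, argmax = argmax))
}

# Backward pass: gradient of loss w.r.t. every layer's W1..W4 given the
# gradient at the pooled drug vectors. Atom inputs are constants, so no
# gradient flows past layer 1.
#' @keywords internal
.gtn_backward <- function(batch, layers, fw, dDrug, activation = "relu",
                          use_attention = TRUE) {
  act <- .get_activation(activation)
  A_last <- fw$atom_features
  dA <- matrix(0, nrow(A_last), ncol(A_last))
  am <- fw$cache$argmax
  for (g in seq_len(batch$n_graphs)) {
    idx <- cbind(am[g, ], seq_len(ncol(A_last)))
    dA[idx] <- dA[idx] + dDrug[g, ]
  }
  E <- length(batch$ei)
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    p <- layers[[l]]
    cc <- fw$cache$layers[[l]]
    heads <- p$heads; d <- p$d
    A_out <- act$f(cc$pre)
    dPre <- dA * act$grad(cc$pre, A_out)
    A_in <- cc$A_in
    gW1 <- t(dPre) %*% A_in
    dA_in <- dPre %*% p$W1
    gW2 <- matrix(0, nrow(p$W2), ncol(p$W2))
    gW3 <- matrix(0, nrow(p$W3), ncol(p$W3))
    gW4 <- matrix(0, nrow(p$W4), ncol(p$W4))
    if (E > 0 && !use_attention) {
      dM <- as.matrix(batch$Sj %*% (cc$w_e * dPre[batch$ei, , drop = FALSE]))
      gW2 <- t(dM) %*% A_in
      dA_in <- dA_in + dM %*% p$W2
    } else if (E > 0) {
      dAgg <- dPre / heads
      dM <- matrix(0, nrow(cc$M), ncol(cc$M))
      dQ <- matrix(0, nrow(cc$Q), ncol(cc$Q))
      dK <- matrix(0, nrow(cc$K), ncol(cc$K))
      G_e <- dAgg[batch$ei, , drop = FALSE]        # E x out
      Mj <- cc$M[batch$ej, , drop = FALSE]
      for (h in seq_len(heads)) {
        a_h <- cc$alpha[, h]
        dalpha <- rowSums(G_e * Mj)                # E
        dM <- dM + as.matrix(batch$Sj %*% (a_h * G_e))
        s <- as.matrix(batch$Si %*% (a_h * dalpha))  # N x 1
        dlogit <- a_h * (dalpha - s[batch$ei, 1])
        dlogit[abs(cc$raw[, h]) > .LOGIT_CLIP] <- 0
        sl <- (h - 1) * d + seq_len(d)
        Ksl <- cc$K[batch$ej, sl, drop = FALSE]
        Qsl <- cc$Q[batch$ei, sl, drop = FALSE]
        dQ[, sl] <- dQ[, sl] +
          as.matrix(batch$Si %*% (dlogit * Ksl)) / sqrt(d)
        dK[, sl] <- dK[, sl] +
          as.matrix(batch$Sj %*% (dlogit * Qsl)) / sqrt(d)
      }
      gW2 <- t(dM) %*% A_in
      gW3 <- t(dQ) %*% A_in
      gW4 <- t(dK) %*% A_in
      dA_in <- dA_in + dM %*% p$W2 + dQ %*% p$W3 + dK %*% p$W4
    }
    grads[[l]] <- list(W1 = gW1, W2 = gW2, W3 = gW3, W4 = gW4)
    dA <- dA_in
  }
  grads
}
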