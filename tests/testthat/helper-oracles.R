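# Independent reference implementations (nested loops, pair counting) and
# small fixture builders used across the suite.

# hand-built hypergraph from a dense incidence matrix and edge weights
make_hg <- function(H, w = rep(1, ncol(H))) {
  Hs <- Matrix::Matrix(H, sparse = TRUE)
  structure(
    list(H = Hs, edge_weights = w,
         node_degrees = as.numeric(Hs %*% w),
         edge_degrees = Matrix::colSums(Hs),
         edge_kinds = rep("triplet", ncol(H)), index = NULL),
    class = "hypergraph"
  )
}

# per-node double-loop oracle for the normalized hypergraph convolution
conv_oracle <- function(X, H, w, W6 = NULL, act = identity) {
  n <- nrow(H); m <- ncol(H)
  if (is.null(W6)) W6 <- diag(ncol(X))
  out <- matrix(0, n, ncol(X))
  edge_deg <- colSums(H)
  node_deg <- as.numeric(H %*% w)
  for (v in seq_len(n)) {
    acc <- rep(0, ncol(X))
    for (e in seq_len(m)) {
      if (H[v, e] == 0 || edge_deg[e] == 0) next
      s <- rep(0, ncol(X))
      for (u in seq_len(n)) if (H[u, e] == 1) s <- s + X[u, ]
      acc <- acc + w[e] * s / edge_deg[e]
    }
    out[v, ] <- if (node_deg[v] > 0) acc / node_deg[v] else 0
  }
  act(out %*% W6)
}

# per-atom / per-head loop oracle for one graph-transformer layer
gtn_oracle <- function(graph, params, act = function(x) pmax(x, 0)) {
  A <- graph$atom_features
  n <- nrow(A)
  nb <- vector("list", n)
  if (nrow(graph$bonds) > 0) {
    for (r in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds[r, 1]; j <- graph$bonds[r, 2]
      nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    }
  }
  heads <- params$heads; d <- params$d
  out <- matrix(0, n, nrow(params$W1))
  for (i in seq_len(n)) {
    pre <- as.numeric(params$W1 %*% A[i, ])
    if (length(nb[[i]]) > 0) {
      agg <- rep(0, nrow(params$W2))
      qi <- as.numeric(params$W3 %*% A[i, ])
      for (h in seq_len(heads)) {
        sl <- (h - 1) * d + seq_len(d)
        logits <- sapply(nb[[i]], function(j) {
          kj <- as.numeric(params$W4 %*% A[j, ])
          sum(qi[sl] * kj[sl]) / sqrt(d)
        })
        al <- exp(logits - max(logits)); al <- al / sum(al)
        for (t in seq_along(nb[[i]])) {
          agg <- agg + al[t] *
            as.numeric(params$W2 %*% A[nb[[i]][t], ])
        }
      }
      pre <- pre + agg / heads
    }
    out[i, ] <- act(pre)
  }
  out
}

# Wilcoxon-Mann-Whitney pair-counting AUROC (ties half credit)
auroc_paircount <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# random molecular-graph-like object (path graph) with given atoms/dim
random_path_graph <- function(n_atoms, feat_dim = 8) {
  n_atoms <- as.integer(n_atoms)
  bonds <- if (n_atoms > 1) cbind(seq_len(n_atoms - 1), 2:n_atoms) else
    matrix(integer(0), ncol = 2)
  colnames(bonds) <- c("i", "j")
  structure(
    list(atom_features = matrix(rnorm(n_atoms * feat_dim), n_atoms),
         bonds = bonds, n_atoms = n_atoms, scheme = "test",
         smiles = NA_character_),
    class = "molecular_graph"
  )
}

# tiny cohort + config for fast training tests (12 x 6 grid: up to 396
# distinct triplets)
tiny_cohort <- function(seed = 5, n = 300) {
  generate_cohort(synth_config(n_drugs = 12, n_cell_lines = 6,
                               n_diseases = 4, n_genes = 12,
                               embedding_dim = 6, n_samples = n,
                               seed = seed))
}

tiny_config <- function(...) {
  args <- list(common_dim = 8, gtn_layers = 1, refinement_layers = 1,
               heads = 2, batch_size = 64, max_epochs = 4, patience = 10,
               learning_rate = 3e-3, dropout = 0, seed = 11)
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}

# writes a small delimited file and returns its path
write_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
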