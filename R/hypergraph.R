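# Dual-relationship hypergraph: drug / cell-line / disease nodes, with
# order-3 synergy hyperedges (drug, drug, cell line) and order-2 indication
# hyperedges (drug, disease).

#' Build the global node index over drugs, cell lines and diseases
#'
#' Node positions are contiguous, drugs first, then cell lines, then
#' diseases (the vertical-concatenation order of the feature matrix), and
#' preserve the input order within each block. Entity namespaces are
#' distinct: the same id may appear as both a drug and a disease.
#'
#' @param drugs character vector of drug ids (deduplicated).
#' @param cell_lines character vector of cell-line ids.
#' @param diseases character vector of disease ids (may be empty for the
#'   disease-free ablation).
#' @return object of class `node_index`: list with the three id vectors,
#'   `n_nodes`, and a `position(type, id)`-style lookup via
#'   [node_position()].
#' @export
build_node_index <- function(drugs, cell_lines, diseases = character(0)) {
  for (ids in list(drugs, cell_lines, diseases)) {
    if (anyDuplicated(ids)) {
      stop("duplicate id within an entity type: ",
           ids[duplicated(ids)][1], call. = FALSE)
    }
  }
  drugs <- as.character(drugs)
  cell_lines <- as.character(cell_lines)
  diseases <- as.character(diseases)
  structure(
    list(drugs = drugs, cell_lines = cell_lines, diseases = diseases,
         n_nodes = length(drugs) + length(cell_lines) + length(diseases)),
    class = "node_index"
  )
}

#' Global node position of an entity id
#'
#' @param index a `node_index`.
#' @param type one of `"drug"`, `"cell_line"`, `"disease"`.
#' @param id entity id(s).
#' @return integer position(s) (1-based) in the global node ordering.
#' @export
node_position <- function(index, type = c("drug", "cell_line", "disease"),
                          id) {
  type <- match.arg(type)
  pos <- switch(type,
    drug = match(id, index$drugs),
    cell_line = length(index$drugs) + match(id, index$cell_lines),
    disease = length(index$drugs) + length(index$cell_lines) +
      match(id, index$diseases)
  )
  if (anyNA(pos)) {
    stop("unknown ", type, " id: ", id[which(is.na(match(id, switch(type,
      drug = index$drugs, cell_line = index$cell_lines,
      disease = index$diseases))))][1], call. = FALSE)
  }
  pos
}

#' @export
print.node_index <- function(x, ...) {
  cat("<node_index> ", length(x$drugs), " drugs + ", length(x$cell_lines),
      " cell lines + ", length(x$diseases), " diseases = ", x$n_nodes,
      " nodes\n", sep = "")
  invisible(x)
}

#' Build the dual-relationship hypergraph
#'
#' One order-3 hyperedge (weight 1) is created per unique unordered
#' (drug_a, drug_b, cell_line) among the supplied synergy samples --
#' by default only positive-label (synergistic) samples, which is what the
#' hyperedges represent; one order-2 hyperedge (weight `interaction_weight`)
#' per unique indication pair. Node degrees are weighted
#' (`deg(v) = sum_e w_e H[v,e]`); hyperedge degrees are unweighted
#' cardinalities. An `interaction_weight` of 0 makes indication hyperedges
#' inert in the convolution, reproducing the disease-free ablation.
#'
#' @param samples synergy sample data.frame; if `positives_only` the `label`
#'   column must be set (see [binarize_synergy()]).
#' @param pairs indication pair data.frame or `NULL`.
#' @param index a `node_index` resolving every referenced id.
#' @param interaction_weight non-negative weight of indication hyperedges
#'   (default 0.02).
#' @param positives_only keep only label-1 samples as hyperedges
#'   (default `TRUE`).
#' @return object of class `hypergraph`: sparse binary incidence `H`
#'   (nodes x hyperedges), `edge_weights`, `node_degrees`, `edge_degrees`,
#'   `edge_kinds` (`"triplet"`/`"indication"`), and the `index`.
#' @export
build_hypergraph <- function(samples, pairs, index, interaction_weight = 0.02,
                             positives_only = TRUE) {
  stopifnot(inherits(index, "node_index"))
  if (interaction_weight < 0) {
    stop("interaction_weight must be >= 0", call. = FALSE)
  }
  if (any(samples$drug_a == samples$drug_b)) {
    k <- which(samples$drug_a == samples$drug_b)[1]
    stop("triplet with identical drugs rejected: (", samples$drug_a[k], ", ",
         samples$drug_b[k], ", ", samples$cell_line[k], ")", call. = FALSE)
  }
  if (positives_only) {
    if (all(is.na(samples$label))) {
      stop("positives_only = TRUE requires binarized labels", call. = FALSE)
    }
    samples <- samples[samples$label == 1L, , drop = FALSE]
  }
  # unordered triplet key for deduplication
  key <- paste(pmin(samples$drug_a, samples$drug_b),
               pmax(samples$drug_a, samples$drug_b),
               samples$cell_line, sep = "\r")
  samples <- samples[!duplicated(key), , drop = FALSE]

  n_tri <- nrow(samples)
  n_ind <- if (is.null(pairs)) 0L else nrow(pairs)
  n_edges <- n_tri + n_ind
  ii <- integer(0); jj <- integer(0)
  if (n_tri > 0) {
    ii <- c(node_position(index, "drug", samples$drug_a),
            node_position(index, "drug", samples$drug_b),
            node_position(index, "cell_line", samples$cell_line))
    jj <- rep(seq_len(n_tri), 3L)
  }
  if (n_ind > 0) {
    ii <- c(ii, node_position(index, "drug", pairs$drug_id),
            node_position(index, "disease", pairs$disease_id))
    jj <- c(jj, rep(n_tri + seq_len(n_ind), 2L))
  }
  H <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(index$n_nodes, n_edges))
  edge_weights <- c(rep(1, n_tri), rep(interaction_weight, n_ind))
  edge_kinds <- c(rep("triplet", n_tri), rep("indication", n_ind))
  node_degrees <- as.numeric(H %*% edge_weights)
  edge_degrees <- Matrix::colSums(H)
  structure(
    list(H = H, edge_weights = edge_weights, node_degrees = node_degrees,
         edge_degrees = edge_degrees, edge_kinds = edge_kinds,
         index = index),
    class = "hypergraph"
  )
}

#' @export
print.hypergraph <- function(x, ...) {
  cat("<hypergraph> ", nrow(x$H), " nodes, ", ncol(x$H), " hyperedges (",
      sum(x$edge_kinds == "triplet"), " triplet, ",
      sum(x$edge_kinds == "indication"), " indication)\n", sep = "")
  invisible(x)
}

# Dense normalized propagation operator P = D^-1 H W_e E^-1 H^T with the
# zero-degree convention (1/0 := 0, so isolated nodes get zero input and
# survive via the residual path).
#' @keywords internal
.hg_operator <- function(hg) {
  Dinv <- ifelse(hg$node_degrees > 0, 1 / hg$node_degrees, 0)
  Einv <- ifelse(hg$edge_degrees > 0, 1 / hg$edge_degrees, 0)
  Hw <- hg$H %*% Matrix::Diagonal(x = hg$edge_weights * Einv)
  as.matrix(Matrix::Diagonal(x = Dinv) %*% Hw %*% Matrix::t(hg$H))
}

#' Dump the hypergraph incidence as a coordinate list
#'
#' Writes one `(node, hyperedge, weight)` row per incidence entry, for
#' debugging and fixtures.
#'
#' @param hg a `hypergraph`.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_hypergraph_coords <- function(hg, path) {
  co <- Matrix::summary(hg$H)
  df <- data.frame(node = co$i, hyperedge = co$j,
                   weight = hg$edge_weights[co$j])
  df <- df[order(df$hyperedge, df$node), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
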