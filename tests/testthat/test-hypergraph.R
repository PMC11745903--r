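test_that("node index uses block ordering: drugs, cells, diseases", {
  idx <- build_node_index(c("d1", "d2"), "c1", "dis1")
  expect_equal(node_position(idx, "drug", c("d1", "d2")), c(1L, 2L))
  expect_equal(node_position(idx, "cell_line", "c1"), 3L)
  expect_equal(node_position(idx, "disease", "dis1"), 4L)
  expect_equal(idx$n_nodes, 4L)

  # disease-free ablation mode
  idx2 <- build_node_index(c("d1", "d2"), "c1")
  expect_equal(idx2$n_nodes, 3L)

  # namespaced entities: same id as drug and disease is allowed
  idx3 <- build_node_index("x", "c1", "x")
  expect_equal(node_position(idx3, "drug", "x"), 1L)
  expect_equal(node_position(idx3, "disease", "x"), 3L)

  expect_error(build_node_index(c("d1", "d1"), "c1"), "duplicate")
  expect_error(node_position(idx, "drug", "zz"), "zz")
})

test_that("the dual-relationship hypergraph matches the hand example", {
  idx <- build_node_index(c("d1", "d2"), "c1", "dis1")
  samples <- data.frame(drug_a = "d1", drug_b = "d2", cell_line = "c1",
                        score = 50, label = 1L)
  pairs <- data.frame(drug_id = "d1", disease_id = "dis1")
  hg <- build_hypergraph(samples, pairs, idx, interaction_weight = 0.02)
  H <- as.matrix(hg$H)
  expect_equal(dim(H), c(4L, 2L))
  expect_equal(unname(H[, 1]), c(1, 1, 1, 0))
  expect_equal(unname(H[, 2]), c(1, 0, 0, 1))
  expect_equal(unname(hg$edge_degrees), c(3, 2))
  expect_equal(hg$node_degrees, c(1.02, 1, 1, 0.02))
  expect_equal(hg$edge_kinds, c("triplet", "indication"))
})

test_that("hyperedges deduplicate and validate", {
  idx <- build_node_index(c("d1", "d2"), "c1")
  s2 <- data.frame(drug_a = c("d1", "d2"), drug_b = c("d2", "d1"),
                   cell_line = "c1", score = 50, label = 1L)
  hg <- build_hypergraph(s2, NULL, idx)   # unordered duplicate collapses
  expect_equal(ncol(hg$H), 1L)
  expect_true(all(hg$node_degrees == round(hg$node_degrees)))

  bad <- data.frame(drug_a = "d1", drug_b = "d1", cell_line = "c1",
                    score = 50, label = 1L)
  expect_error(build_hypergraph(bad, NULL, idx), "identical drugs")

  # only positive-label samples become hyperedges by default
  s3 <- data.frame(drug_a = c("d1", "d1"), drug_b = c("d2", "d2"),
                   cell_line = c("c1", "c1"), score = c(50, 10),
                   label = c(1L, 0L))
  expect_equal(ncol(build_hypergraph(s3[2, ], NULL, idx,
                                     positives_only = FALSE)$H), 1L)
  expect_equal(ncol(build_hypergraph(s3, NULL, idx)$H), 1L)
})

test_that("weighted handshake identity holds exactly", {
  set.seed(31)
  co <- tiny_cohort()
  co$samples$label <- binarize_synergy(co$samples$score)
  idx <- build_node_index(co$drugs$drug_id, rownames(co$expr),
                          rownames(co$embeddings))
  hg <- build_hypergraph(co$samples, co$pairs, idx,
                         interaction_weight = 0.37)
  expect_equal(sum(hg$node_degrees),
               sum(hg$edge_weights * hg$edge_degrees))
})

test_that("construction is order-independent up to column permutation", {
  co <- tiny_cohort()
  co$samples$label <- binarize_synergy(co$samples$score)
  idx <- build_node_index(co$drugs$drug_id, rownames(co$expr),
                          rownames(co$embeddings))
  hg1 <- build_hypergraph(co$samples, co$pairs, idx)
  set.seed(8)
  perm <- sample(nrow(co$samples))
  hg2 <- build_hypergraph(co$samples[perm, ], co$pairs, idx)
  expect_equal(sort(hg1$node_degrees), sort(hg2$node_degrees))
  expect_equal(sort(hg1$edge_degrees), sort(hg2$edge_degrees))
  cols <- function(hg) sort(apply(as.matrix(hg$H), 2, paste, collapse = ""))
  expect_equal(cols(hg1), cols(hg2))
})

test_that("zero interaction weight reproduces the disease-free ablation", {
  co <- tiny_cohort()
  co$samples$label <- binarize_synergy(co$samples$score)
  idx <- build_node_index(co$drugs$drug_id, rownames(co$expr),
                          rownames(co$embeddings))
  hg0 <- build_hypergraph(co$samples, co$pairs, idx,
                          interaction_weight = 0)
  hg_no <- build_hypergraph(co$samples, NULL, idx)
  set.seed(6)
  X <- matrix(rnorm(idx$n_nodes * 4), idx$n_nodes, 4)
  expect_lt(max(abs(hgnn_convolve(X, hg0) - hgnn_convolve(X, hg_no))),
            1e-12)
})

test_that("incidence coordinate dump is written", {
  idx <- build_node_index(c("d1", "d2"), "c1")
  s <- data.frame(drug_a = "d1", drug_b = "d2", cell_line = "c1",
                  score = 50, label = 1L)
  hg <- build_hypergraph(s, NULL, idx)
  p <- tempfile(fileext = ".tsv")
  write_hypergraph_coords(hg, p)
  df <- read.delim(p)
  expect_equal(nrow(df), 3)
  expect_equal(df$weight, rep(1, 3))
})
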