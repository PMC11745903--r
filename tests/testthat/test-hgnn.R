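test_that("hypergraph convolution reproduces the worked 3-node example", {
  H <- cbind(c(1, 1, 1), c(1, 1, 0))
  hg <- make_hg(H)
  out <- hgnn_convolve(cbind(c(1, 2, 3)), hg)
  expect_equal(unname(out[, 1]), c(1.75, 1.75, 2.0))
})

test_that("single node in a single hyperedge is a fixed point", {
  hg <- make_hg(matrix(1, 1, 1))
  X <- cbind(c(3.2))
  expect_equal(hgnn_convolve(X, hg), X)
})

test_that("constant features are conserved for any positive weights", {
  set.seed(13)
  for (trial in 1:5) {
    n <- sample(4:12, 1); m <- sample(2:6, 1)
    H <- matrix(rbinom(n * m, 1, 0.5), n, m)
    w <- runif(m, 0.01, 3)
    hg <- make_hg(H, w)
    X <- matrix(rep(c(2.5, -1), each = n), n, 2)
    out <- hgnn_convolve(X, hg)
    active <- hg$node_degrees > 0
    expect_lt(max(abs(out[active, ] - X[active, ])), 1e-10)
    expect_true(all(out[!active, ] == 0))
  }
})

test_that("convolution agrees with the per-node double-loop oracle", {
  set.seed(17)
  for (trial in 1:20) {
    n <- sample(3:20, 1); m <- sample(2:10, 1)
    H <- matrix(rbinom(n * m, 1, 0.4), n, m)
    w <- runif(m, 0, 2)
    hg <- make_hg(H, w)
    X <- matrix(rnorm(n * 3), n, 3)
    W6 <- matrix(rnorm(9), 3, 3)
    got <- hgnn_convolve(X, hg, W6, activation = "relu")
    want <- conv_oracle(X, H, w, W6, act = function(x) pmax(x, 0))
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("dimension mismatches are reported", {
  hg <- make_hg(matrix(1, 2, 1))
  expect_error(hgnn_convolve(matrix(0, 3, 2), hg), "nodes")
  expect_error(hgnn_convolve(matrix(0, 2, 2), hg, W6 = matrix(0, 3, 2)),
               "columns")
})

test_that("saturated gates give identity or doubling", {
  set.seed(19)
  H <- cbind(c(1, 1, 0, 1), c(0, 1, 1, 1))
  hg <- make_hg(H)
  X <- matrix(rnorm(8), 4, 2)
  p_off <- hgnn_layer_params(diag(2), matrix(0, 2, 2), rep(-50, 2))
  expect_lt(max(abs(gated_residual_layer(X, hg, p_off) - X)), 1e-12)
  p_on <- hgnn_layer_params(diag(2), matrix(0, 2, 2), rep(50, 2))
  expect_lt(max(abs(gated_residual_layer(X, hg, p_on) - 2 * X)), 1e-12)
})

test_that("gated layer matches an elementwise scalar oracle", {
  set.seed(23)
  H <- cbind(c(1, 1, 0, 1), c(0, 1, 1, 1), c(1, 0, 1, 0))
  w <- c(1, 0.5, 2)
  hg <- make_hg(H, w)
  X <- matrix(rnorm(12), 4, 3)
  p <- hgnn_layer_params(matrix(rnorm(9), 3), matrix(rnorm(9), 3),
                         rnorm(3))
  C <- conv_oracle(X, H, w, p$conv_weight, act = function(x) pmax(x, 0))
  G <- matrix(0, 4, 3)
  for (v in 1:4) for (c0 in 1:3) {
    G[v, c0] <- 1 / (1 + exp(-(sum(p$gate_weight[c0, ] * C[v, ]) +
                                 p$gate_bias[c0])))
  }
  expect_lt(max(abs(gated_residual_layer(X, hg, p) - (X + G * X))), 1e-8)
  expect_lt(max(abs(gated_residual_layer(X, hg, p, gate_on = "conv") -
                      (X + G * C))), 1e-8)
})

test_that("equilibrium bias initialization makes layers near-identity", {
  p <- hgnn_layer_params(diag(3), matrix(1, 3, 3), rnorm(3))
  p5 <- init_gate_bias_ebi(p)
  expect_equal(p5$gate_bias, rep(-5, 3))
  expect_equal(unique(round(1 / (1 + exp(-p5$gate_bias)), 4)), 0.0067)
  p0 <- init_gate_bias_ebi(p, b0 = 0)
  expect_equal(1 / (1 + exp(-p0$gate_bias)), rep(0.5, 3))

  set.seed(29)
  H <- matrix(rbinom(60, 1, 0.4), 12, 5)
  hg <- make_hg(H)
  X <- matrix(rnorm(12 * 8), 12, 8)
  pr <- hypersyn:::.hgnn_layer_init(8, ebi_bias = -5)
  out <- gated_residual_layer(X, hg, pr)
  expect_lt(norm(out - X, "F") / norm(X, "F"), 0.01)
})

test_that("gate opening is monotone in its bias", {
  set.seed(37)
  H <- matrix(rbinom(40, 1, 0.5), 8, 5)
  hg <- make_hg(H)
  X <- matrix(rnorm(8 * 4), 8, 4)
  p <- hypersyn:::.hgnn_layer_init(4, ebi_bias = -3)
  f <- hypersyn:::.hgnn_layer_forward(X, hypersyn:::.hg_operator(hg), p)
  for (delta in c(0.5, 1, 2)) {
    p2 <- p; p2$gate_bias <- p$gate_bias + delta
    f2 <- hypersyn:::.hgnn_layer_forward(X, hypersyn:::.hg_operator(hg), p2)
    expect_true(all(f2$G >= f$G))
  }
})

test_that("refine composes layers and honors the ablation modes", {
  set.seed(41)
  H <- matrix(rbinom(50, 1, 0.4), 10, 5)
  hg <- make_hg(H)
  X <- matrix(rnorm(40), 10, 4)
  expect_equal(refine(X, hg, list()), X)

  p <- hypersyn:::.hgnn_layer_init(4)
  expect_equal(refine(X, hg, list(p)), gated_residual_layer(X, hg, p))

  C <- hgnn_convolve(X, hg, p$conv_weight, activation = "relu")
  expect_equal(refine(X, hg, list(p), mode = "no_residual"), C)
  expect_equal(refine(X, hg, list(p), mode = "plain_residual"), X + C)

  # three EBI layers stay close to the input before any training
  layers <- lapply(1:3, function(l) hypersyn:::.hgnn_layer_init(4))
  out3 <- refine(X, hg, layers)
  expect_lt(norm(out3 - X, "F") / norm(X, "F"), 0.03)
})
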