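test_that("synergy table reader parses rows losslessly", {
  p <- write_tmp(c("drug_a,drug_b,cell_line,score",
                   "A,B,c1,12.0", "B,C,c2,45.5", "A,C,c1,-3.0"))
  s <- read_synergy_table(p)
  expect_equal(nrow(s), 3)
  expect_equal(s$score, c(12.0, 45.5, -3.0))
  expect_true(all(is.na(s$label)))

  # duplicated rows are retained (no dedup at read)
  p2 <- write_tmp(c("drug_a,drug_b,cell_line,score",
                    "A,B,c1,31.2", "A,B,c1,31.2"))
  expect_equal(nrow(read_synergy_table(p2)), 2)
})

test_that("reader errors name the missing column and the bad row", {
  p <- write_tmp(c("drug1,drug_b,cell_line,score", "A,B,c1,1"))
  expect_error(read_synergy_table(p), "drug_a")
  p2 <- write_tmp(c("drug_a,drug_b,cell_line,score", "A,B,c1,oops"))
  expect_error(read_synergy_table(p2), "line 1")
})

test_that("all five tables survive a read-write-read round trip", {
  co <- tiny_cohort()
  d <- tempfile(); dir.create(d)
  write_cohort(co, d)
  co2 <- load_cohort(d)
  expect_equal(co2$samples[, 1:4], co$samples[, 1:4])
  expect_equal(co2$drugs, co$drugs)
  expect_equal(co2$expr, co$expr)
  expect_equal(co2$pairs, co$pairs)
  expect_equal(co2$embeddings, co$embeddings)
  # second round trip is exact
  d2 <- tempfile(); dir.create(d2)
  write_cohort(co2, d2)
  expect_equal(load_cohort(d2)$samples, co2$samples)
})

test_that("delimiter auto-detection can be overridden", {
  p <- write_tmp(c("drug_id\tsmiles", "A\tCCO"), ext = ".txt")
  expect_equal(read_drug_table(p)$smiles, "CCO")
  p2 <- write_tmp(c("drug_id;smiles", "A;CCO"), ext = ".csv")
  expect_equal(read_drug_table(p2, delim = ";")$smiles, "CCO")
})

test_that("entity filtering enforces the cross-table rules", {
  co <- tiny_cohort()
  # plant inconsistencies
  co$samples$cell_line[1] <- "CL99"          # no expression
  co$samples$drug_a[2] <- "D999"             # unknown drug
  co$pairs <- rbind(co$pairs,
                    data.frame(drug_id = "D999", disease_id = "DIS01"),
                    data.frame(drug_id = "D001", disease_id = "DISXX"))
  f <- filter_entities(co$samples, co$drugs, co$expr, co$pairs,
                       co$embeddings)
  expect_equal(unname(f$report["samples_missing_cell_line"]), 1L)
  expect_equal(unname(f$report["samples_missing_drug"]), 1L)
  expect_gte(unname(f$report["pairs_missing_drug"]), 1L)
  expect_gte(unname(f$report["pairs_missing_embedding"]), 1L)
  expect_false("CL99" %in% f$samples$cell_line)
  expect_false("D999" %in% c(f$samples$drug_a, f$pairs$drug_id))
  # every surviving reference resolves
  expect_true(all(f$samples$drug_a %in% f$drugs$drug_id))
  expect_true(all(f$samples$cell_line %in% rownames(f$expr)))
  expect_true(all(f$pairs$disease_id %in% rownames(f$embeddings)))
})

test_that("filtering a consistent cohort is a no-op and is idempotent", {
  co <- tiny_cohort()
  f1 <- filter_entities(co$samples, co$drugs, co$expr, co$pairs,
                        co$embeddings)
  expect_equal(nrow(f1$samples), nrow(co$samples))
  f2 <- filter_entities(f1$samples, f1$drugs, f1$expr, f1$pairs,
                        f1$embeddings)
  expect_equal(f2$samples, f1$samples)
  expect_equal(f2$expr, f1$expr)
  expect_equal(f2$pairs, f1$pairs)
  expect_true(all(f2$report == 0))
})

test_that("filtering that removes everything is a hard error", {
  co <- tiny_cohort()
  co$samples$cell_line <- "CL99"
  expect_error(filter_entities(co$samples, co$drugs, co$expr),
               "no synergy samples")
})

test_that("expression preprocessing is log2 then population z-score", {
  m <- cbind(g1 = c(1, 3), g2 = c(5, 5))
  rownames(m) <- c("a", "b")
  out <- preprocess_expression(m)
  expect_equal(out[, "g1"], c(a = -1, b = 1))     # log2 -> [1,2], pop sd 0.5
  expect_equal(out[, "g2"], c(a = 0, b = 0))      # constant -> zeros
  expect_equal(unname(preprocess_expression(cbind(c(0, 0, 0)))[, 1]),
               c(0, 0, 0))                        # zeros stay zero
  bad <- cbind(gX = c(-1, 2)); rownames(bad) <- c("cl1", "cl2")
  expect_error(preprocess_expression(bad), "gX")
  expect_error(preprocess_expression(bad), "cl1")
})

test_that("non-constant gene columns are exactly standardized", {
  set.seed(9)
  m <- matrix(rexp(200), 20, 10,
              dimnames = list(NULL, paste0("g", 1:10)))
  out <- preprocess_expression(m)
  expect_lt(max(abs(colMeans(out))), 1e-9)
  popvar <- colMeans(out^2) - colMeans(out)^2
  expect_lt(max(abs(popvar - 1)), 1e-9)
})

test_that("binarization is strict at the threshold", {
  expect_equal(binarize_synergy(c(45, 30, -10)), c(1L, 0L, 0L))
  expect_equal(binarize_synergy(30 + 1e-9), 1L)
  expect_error(binarize_synergy(c(1, NA)), "non-finite")
  expect_error(binarize_synergy(Inf), "non-finite")
})
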