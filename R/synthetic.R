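# Self-contained synthetic cohort with a plantable trilinear synergy
# signal. The generator emulates the five input tables at desk scale so
# the whole pipeline (readers, encoders, hypergraph, training, splits) is
# testable without any external download. Molecules come from a bundled
# vocabulary of small drug-like SMILES; drug latent traits are indexed by
# drug identity, not chemistry, so synthetic performance exercises the
# learning machinery rather than chemical validity.

# ~100 small drug-like molecules (all parse through smiles_to_graph)
.SMILES_VOCAB <- c(
  "CCO", "CC(=O)O", "c1ccccc1", "Cc1ccccc1", "CCN", "CCC", "CCCC",
  "CC(C)O", "CC(C)C", "C1CCCCC1", "C1CCCC1", "c1ccncc1", "c1ccoc1",
  "c1ccsc1", "c1cc[nH]c1", "CC(=O)Oc1ccccc1C(=O)O", "CC(=O)Nc1ccc(O)cc1",
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  "OC(=O)c1ccccc1O", "Nc1ccc(cc1)S(=O)(=O)N", "COc1ccccc1", "Oc1ccccc1",
  "Nc1ccccc1", "Clc1ccccc1", "Brc1ccccc1", "Fc1ccccc1", "C=C", "C#N",
  "CC#N", "CCOCC", "CCOC(=O)C", "OCC(O)CO", "OCCO", "NCCO", "NCCN",
  "OC(=O)CC(O)(CC(=O)O)C(=O)O", "CC(O)C(=O)O", "C1CCNCC1", "C1CCOC1",
  "C1CCNC1", "O=C1CCCCC1", "CC(=O)C", "CCC(=O)C", "CC=O", "OCc1ccccc1",
  "O=Cc1ccccc1", "CC(=O)c1ccccc1", "c1ccc2ccccc2c1", "c1ccc2[nH]ccc2c1",
  "CCCCCC", "CCCCCCO", "CC(C)(C)O", "CC(C)(C)C", "CCS", "CCSC",
  "CS(=O)C", "CC(N)C(=O)O", "NCC(=O)O", "CC(C)CC(N)C(=O)O",
  "OC(=O)CCC(=O)O", "OC(=O)C=CC(=O)O", "CCCCN", "CCCN", "CN(C)C",
  "CNC", "CN", "COC", "COC(=O)c1ccccc1", "CCOC(=O)c1ccccc1",
  "O=C(N)c1ccccc1", "N#Cc1ccccc1", "OC(=O)c1ccccc1", "CC(=O)N",
  "CC(=O)NC", "O=C(N)N", "Cn1ccnc1", "c1cnc[nH]1", "c1cncnc1",
  "c1ccc(cc1)c1ccccc1", "Oc1ccc(O)cc1", "Nc1ccc(N)cc1",
  "Clc1ccc(Cl)cc1", "Cc1ccc(C)cc1", "COc1ccc(OC)cc1", "CCc1ccccc1",
  "C=Cc1ccccc1", "C#Cc1ccccc1", "OCCN(CC)CC", "CCN(CC)CC",
  "CC(C)NCC(O)c1ccccc1", "CNCC(O)c1ccccc1", "OCC1CCCCC1",
  "NC1CCCCC1", "OC1CCCCC1", "O=C1CCCN1", "O=C1CCCCN1", "C1CN1",
  "C1CO1", "CC1CO1", "CC(Cl)C(=O)O", "FC(F)(F)c1ccccc1",
  "CC(=O)CC(=O)C", "CC(=O)OC", "O=S(=O)(O)c1ccccc1"
)

#' Synthetic cohort configuration
#'
#' Defaults define a desk-scale cohort: 30 drugs on 10 cell lines with 8
#' indication diseases, 60 genes, and 2000 sampled triplets. The planted
#' synergy signal for triplet (i, j, k) is
#' `signal_strength * (u_i (.) u_j)' v_k` over low-dimensional latent
#' traits -- symmetric in the drug pair and representable by the model
#' architecture. Scores are rescaled so that `positive_fraction` of the
#' cohort exceeds the conventional threshold of 30; label noise is planted
#' by reflecting a random subset of scores across the threshold (so a
#' sample's label always equals the thresholding of its score).
#'
#' @param n_drugs,n_cell_lines,n_diseases,n_genes,embedding_dim entity and
#'   dimension counts.
#' @param n_samples number of sampled (drug, drug, cell line) triplets
#'   (without replacement; at most `choose(n_drugs, 2) * n_cell_lines`).
#' @param signal_strength multiplier of the planted trilinear signal.
#' @param label_noise probability in `[0, 0.5)` that a sample's score is
#'   reflected across the threshold.
#' @param indication_density probability of each non-primary drug-disease
#'   indication pair.
#' @param positive_fraction target fraction of positive labels.
#' @param latent_dim dimension of the latent trait vectors.
#' @param score_noise_sd standard deviation of additive score noise on the
#'   latent scale (signal sd is about 2 at the defaults).
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_drugs = 30, n_cell_lines = 10, n_diseases = 8,
                         n_genes = 60, embedding_dim = 16, n_samples = 2000,
                         signal_strength = 1.0, label_noise = 0.05,
                         indication_density = 0.15, positive_fraction = 0.30,
                         latent_dim = 4, score_noise_sd = 0.2, seed = 1) {
  stopifnot(n_drugs >= 2, n_cell_lines >= 1, n_diseases >= 1, n_genes >= 1,
            embedding_dim >= 1, signal_strength >= 0,
            label_noise >= 0, label_noise < 0.5,
            indication_density >= 0, indication_density <= 1,
            positive_fraction > 0, positive_fraction < 1)
  max_n <- choose(n_drugs, 2) * n_cell_lines
  if (n_samples > max_n) {
    stop("n_samples (", n_samples, ") exceeds the number of distinct ",
         "triplets (", max_n, ")", call. = FALSE)
  }
  if (n_drugs > length(.SMILES_VOCAB)) {
    stop("at most ", length(.SMILES_VOCAB), " drugs supported (SMILES ",
         "vocabulary size)", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic cohort
#'
#' Produces the five input tables (synergy samples, drugs, expression,
#' indication pairs, disease embeddings) with the planted signal described
#' in [synth_config()]. Cell-line expression is a noisy linear lift of the
#' cell latent trait, exponentiated so that the standard log2 + z-score
#' preprocessing recovers it; drugs sharing a primary disease have
#' correlated latent traits, and the indication pairs expose that
#' structure to the hypergraph.
#'
#' @param cfg a [synth_config()].
#' @return a cohort list (`samples`, `drugs`, `expr`, `pairs`,
#'   `embeddings`) with a `manifest` attribute carrying the configuration
#'   and the noiseless planted scores (see [oracle_scores()]).
#' @export
generate_cohort <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  ndr <- cfg$n_drugs; ncl <- cfg$n_cell_lines; ndi <- cfg$n_diseases
  L <- cfg$latent_dim

  drug_ids <- sprintf("D%03d", seq_len(ndr))
  cell_ids <- sprintf("CL%02d", seq_len(ncl))
  dis_ids <- sprintf("DIS%02d", seq_len(ndi))
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))

  smiles <- sample(.SMILES_VOCAB, ndr)
  drugs <- data.frame(drug_id = drug_ids, smiles = smiles,
                      stringsAsFactors = FALSE)

  W_dis <- matrix(stats::rnorm(ndi * L), ndi, L)       # disease centers
  primary <- sample.int(ndi, ndr, replace = TRUE)
  U <- sqrt(0.5) * W_dis[primary, , drop = FALSE] +
    sqrt(0.5) * matrix(stats::rnorm(ndr * L), ndr, L)  # drug latents
  V <- matrix(stats::rnorm(ncl * L), ncl, L)           # cell latents

  load <- matrix(stats::rnorm(L * cfg$n_genes), L) / sqrt(L)
  E <- V %*% load + 0.1 * matrix(stats::rnorm(ncl * cfg$n_genes), ncl)
  expr <- pmax(2^(3 + E) - 1, 0)
  rownames(expr) <- cell_ids
  colnames(expr) <- gene_ids

  lift <- matrix(stats::rnorm(L * cfg$embedding_dim), L) / sqrt(L)
  emb <- W_dis %*% lift +
    0.05 * matrix(stats::rnorm(ndi * cfg$embedding_dim), ndi)
  rownames(emb) <- dis_ids
  colnames(emb) <- sprintf("e%02d", seq_len(cfg$embedding_dim))

  pairs <- data.frame(drug_id = drug_ids, disease_id = dis_ids[primary],
                      stringsAsFactors = FALSE)
  extra <- which(matrix(stats::runif(ndr * ndi), ndr, ndi) <
                   cfg$indication_density, arr.ind = TRUE)
  if (nrow(extra) > 0) {
    pairs <- rbind(pairs, data.frame(drug_id = drug_ids[extra[, 1]],
                                     disease_id = dis_ids[extra[, 2]],
                                     stringsAsFactors = FALSE))
  }
  pairs <- pairs[!duplicated(pairs), , drop = FALSE]
  rownames(pairs) <- NULL

  # sample distinct triplets (i < j, k) uniformly without replacement
  pair_grid <- which(upper.tri(matrix(0, ndr, ndr)), arr.ind = TRUE)
  n_grid <- nrow(pair_grid) * ncl
  pick <- sample.int(n_grid, cfg$n_samples)
  pr <- ((pick - 1) %% nrow(pair_grid)) + 1
  kk <- ((pick - 1) %/% nrow(pair_grid)) + 1
  ii <- pair_grid[pr, 1]; jj <- pair_grid[pr, 2]

  planted <- rowSums(U[ii, , drop = FALSE] * U[jj, , drop = FALSE] *
                       V[kk, , drop = FALSE])
  z <- cfg$signal_strength * planted +
    cfg$score_noise_sd * stats::rnorm(cfg$n_samples)
  thr <- stats::quantile(z, 1 - cfg$positive_fraction, names = FALSE)
  score <- 30 + 10 * (z - thr) / max(stats::sd(z), 1e-12)
  flip <- stats::runif(cfg$n_samples) < cfg$label_noise
  score[flip] <- 60 - score[flip]  # reflect across the threshold

  samples <- data.frame(
    drug_a = drug_ids[ii], drug_b = drug_ids[jj], cell_line = cell_ids[kk],
    score = score, label = NA_integer_, stringsAsFactors = FALSE
  )

  cohort <- list(samples = samples, drugs = drugs, expr = expr,
                 pairs = pairs, embeddings = emb)
  attr(cohort, "manifest") <- list(cfg = cfg, planted = planted,
                                   U = U, V = V)
  cohort
}

#' Noiseless planted synergy values of a generated cohort
#'
#' Returns the per-sample latent trilinear values before noise and
#' rescaling, giving the Bayes-optimal ranking (the data-processing upper
#' bound on any model's AUROC for the cohort).
#'
#' @param cfg the [synth_config()] the cohort was generated with.
#' @param cohort the cohort returned by [generate_cohort()].
#' @return numeric vector aligned with `cohort$samples`.
#' @export
oracle_scores <- function(cfg, cohort) {
  man <- attr(cohort, "manifest")
  if (is.null(man) || !identical(man$cfg, cfg)) {
    regen <- generate_cohort(cfg)
    if (!isTRUE(all.equal(regen$samples[, 1:4], cohort$samples[, 1:4]))) {
      stop("cohort does not match the supplied configuration/seed",
           call. = FALSE)
    }
    man <- attr(regen, "manifest")
  }
  man$planted
}

#' Write a cohort's five tables to a directory
#'
#' Writes `synergy.csv`, `drugs.csv`, `expression.csv`, `indications.csv`,
#' `disease_embeddings.csv`, plus `manifest.json` recording the generator
#' configuration. A cohort written with the same configuration and seed is
#' byte-identical.
#'
#' @param cohort a cohort list.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_file(cohort$samples, file.path(dir, "synergy.csv"))
  write_table_file(cohort$drugs, file.path(dir, "drugs.csv"))
  write_table_file(cohort$expr, file.path(dir, "expression.csv"),
                   id_name = "cell_line")
  if (!is.null(cohort$pairs)) {
    write_table_file(cohort$pairs, file.path(dir, "indications.csv"))
    write_table_file(cohort$embeddings,
                     file.path(dir, "disease_embeddings.csv"),
                     id_name = "disease_id")
  }
  man <- attr(cohort, "manifest")
  if (!is.null(man) && requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- man$cfg
    jsonlite::write_json(cfg[names(cfg) != "class"],
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a cohort directory written by [write_cohort()]
#'
#' @param dir directory path.
#' @return a cohort list.
#' @export
load_cohort <- function(dir) {
  pairs_path <- file.path(dir, "indications.csv")
  emb_path <- file.path(dir, "disease_embeddings.csv")
  list(
    samples = read_synergy_table(file.path(dir, "synergy.csv")),
    drugs = read_drug_table(file.path(dir, "drugs.csv")),
    expr = read_expression_matrix(file.path(dir, "expression.csv")),
    pairs = if (file.exists(pairs_path)) read_indication_pairs(pairs_path),
    embeddings = if (file.exists(emb_path)) read_disease_embeddings(emb_path)
  )
}
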