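#' Read a drug-synergy table
#'
#' Reads rows of (drug_a, drug_b, cell_line, score) from delimited text. The
#' score is a continuous synergy value (e.g. a Loewe score or ComboScore);
#' binary labels are left unset at read time (see [binarize_synergy()]).
#' The reader is lossless: duplicated rows are retained.
#'
#' @param path path to a CSV/TSV file with a header row naming the columns
#'   `drug_a`, `drug_b`, `cell_line`, `score`.
#' @param delim field delimiter; `NULL` (default) auto-detects from the file
#'   extension (`.csv` comma, anything else tab).
#' @return a data.frame with columns `drug_a`, `drug_b`, `cell_line`
#'   (character), `score` (numeric) and `label` (integer, all `NA`).
#' @seealso [read_drug_table()], [filter_entities()], [binarize_synergy()]
#' @export
read_synergy_table <- function(path, delim = NULL) {
  df <- .read_delim(path, delim)
  .require_columns(df, c("drug_a", "drug_b", "cell_line", "score"), path)
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score) & !is.na(df$score))
  if (length(bad) > 0) {
    stop("unparseable score at data line ", bad[1], " of ", path,
         " (value '", df$score[bad[1]], "')", call. = FALSE)
  }
  data.frame(
    drug_a = as.character(df$drug_a),
    drug_b = as.character(df$drug_b),
    cell_line = as.character(df$cell_line),
    score = score,
    label = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Read a drug table (drug_id, smiles)
#'
#' @inheritParams read_synergy_table
#' @return data.frame with character columns `drug_id` and `smiles`.
#' @export
read_drug_table <- function(path, delim = NULL) {
  df <- .read_delim(path, delim)
  .require_columns(df, c("drug_id", "smiles"), path)
  out <- data.frame(drug_id = as.character(df$drug_id),
                    smiles = as.character(df$smiles),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$drug_id)) {
    stop("duplicate drug_id in ", path, ": ",
         out$drug_id[duplicated(out$drug_id)][1], call. = FALSE)
  }
  out
}

#' Read drug-disease indication pairs
#'
#' @inheritParams read_synergy_table
#' @return data.frame with character columns `drug_id` and `disease_id`.
#' @export
read_indication_pairs <- function(path, delim = NULL) {
  df <- .read_delim(path, delim)
  .require_columns(df, c("drug_id", "disease_id"), path)
  data.frame(drug_id = as.character(df$drug_id),
             disease_id = as.character(df$disease_id),
             stringsAsFactors = FALSE)
}

#' Read a cell-line expression matrix
#'
#' Wide numeric table: first column holds the cell-line id, remaining columns
#' are genes.
#'
#' @inheritParams read_synergy_table
#' @return numeric matrix (cell lines x genes) with row/column names.
#' @export
read_expression_matrix <- function(path, delim = NULL) {
  .read_wide_matrix(path, delim, what = "expression")
}

#' Read a disease embedding table
#'
#' Wide numeric table: first column holds the disease id, remaining columns
#' are embedding dimensions. Embeddings are precomputed (e.g. by a medical
#' language model) and consumed as-is.
#'
#' @inheritParams read_synergy_table
#' @return numeric matrix (diseases x embedding dims) with row names.
#' @export
read_disease_embeddings <- function(path, delim = NULL) {
  .read_wide_matrix(path, delim, what = "disease embedding")
}

#' @keywords internal
.read_wide_matrix <- function(path, delim, what) {
  df <- .read_delim(path, delim)
  if (ncol(df) < 2) {
    stop(what, " table ", path, " needs an id column plus numeric columns",
         call. = FALSE)
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate id in ", what, " table ", path, ": ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    stop(what, " table ", path, " contains missing values", call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' @keywords internal
.read_delim <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

#' @keywords internal
.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Write any of the five input tables back to delimited text
#'
#' Inverse of the readers; a read -> write -> read round trip reproduces the
#' table. Matrices are written with the id as first column.
#'
#' @param x data.frame or matrix as returned by the readers.
#' @param path output path; delimiter auto-detected from extension unless
#'   `delim` is given.
#' @param delim optional explicit delimiter.
#' @param id_name name of the id column for wide matrices.
#' @return `path`, invisibly.
#' @export
write_table_file <- function(x, path, delim = NULL, id_name = "id") {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- id_name
    x <- df
  }
  if ("label" %in% names(x) && all(is.na(x$label))) {
    x <- x[, setdiff(names(x), "label"), drop = FALSE]
  }
  utils::write.table(x, path, sep = delim, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Cross-filter the five input tables to a consistent cohort
#'
#' Applies the standard entity-filtering rules: samples are dropped when a
#' referenced drug lacks a SMILES string or the cell line lacks an expression
#' profile; indication pairs are dropped when their drug is absent from the
#' (filtered) synergy data or their disease has no embedding; unreferenced
#' cell lines, drugs and diseases are pruned. The operation is idempotent.
#'
#' @param samples synergy sample data.frame ([read_synergy_table()]).
#' @param drugs drug table ([read_drug_table()]).
#' @param expr expression matrix ([read_expression_matrix()]).
#' @param pairs optional indication pairs ([read_indication_pairs()]).
#' @param embeddings optional disease embedding matrix.
#' @return list with filtered `samples`, `drugs`, `expr`, `pairs`,
#'   `embeddings`, and a `report` (named integer vector of counts removed
#'   per rule).
#' @export
filter_entities <- function(samples, drugs, expr, pairs = NULL,
                            embeddings = NULL) {
  report <- c(
    drugs_no_smiles = 0L, samples_missing_drug = 0L,
    samples_missing_cell_line = 0L, cell_lines_unreferenced = 0L,
    drugs_unreferenced = 0L, pairs_missing_drug = 0L,
    pairs_missing_embedding = 0L, pairs_duplicate = 0L,
    diseases_unreferenced = 0L
  )

  keep <- !is.na(drugs$smiles) & nzchar(drugs$smiles)
  report["drugs_no_smiles"] <- sum(!keep)
  drugs <- drugs[keep, , drop = FALSE]

  has_drug <- samples$drug_a %in% drugs$drug_id &
    samples$drug_b %in% drugs$drug_id
  report["samples_missing_drug"] <- sum(!has_drug)
  has_cell <- samples$cell_line %in% rownames(expr)
  report["samples_missing_cell_line"] <- sum(has_drug & !has_cell)
  samples <- samples[has_drug & has_cell, , drop = FALSE]
  if (nrow(samples) == 0) {
    stop("no synergy samples survive entity filtering", call. = FALSE)
  }

  used_cells <- rownames(expr) %in% samples$cell_line
  report["cell_lines_unreferenced"] <- sum(!used_cells)
  expr <- expr[used_cells, , drop = FALSE]

  used_drugs <- drugs$drug_id %in% c(samples$drug_a, samples$drug_b)
  report["drugs_unreferenced"] <- sum(!used_drugs)
  drugs <- drugs[used_drugs, , drop = FALSE]

  if (!is.null(pairs) && !is.null(embeddings)) {
    in_drugs <- pairs$drug_id %in% drugs$drug_id
    report["pairs_missing_drug"] <- sum(!in_drugs)
    in_emb <- pairs$disease_id %in% rownames(embeddings)
    report["pairs_missing_embedding"] <- sum(in_drugs & !in_emb)
    pairs <- pairs[in_drugs & in_emb, , drop = FALSE]
    dup <- duplicated(pairs[, c("drug_id", "disease_id")])
    report["pairs_duplicate"] <- sum(dup)
    pairs <- pairs[!dup, , drop = FALSE]

    used_dis <- rownames(embeddings) %in% pairs$disease_id
    report["diseases_unreferenced"] <- sum(!used_dis)
    embeddings <- embeddings[used_dis, , drop = FALSE]
  } else {
    pairs <- NULL
    embeddings <- NULL
  }

  rownames(samples) <- NULL
  rownames(drugs) <- NULL
  if (!is.null(pairs)) rownames(pairs) <- NULL
  list(samples = samples, drugs = drugs, expr = expr,
       pairs = pairs, embeddings = embeddings, report = report)
}

#' Log2-transform and z-score an expression matrix
#'
#' Each raw value x becomes log2(x + 1); each gene column is then centered
#' and scaled to population standard deviation 1 (divide-by-N). Constant
#' gene columns map to all zeros so downstream linear algebra stays finite.
#'
#' @param expr non-negative numeric matrix (cell lines x genes).
#' @return the preprocessed matrix, with attribute `preprocessed = TRUE`.
#' @export
preprocess_expression <- function(expr) {
  stopifnot(is.matrix(expr))
  if (any(expr < 0)) {
    idx <- which(expr < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value for gene '",
         colnames(expr)[idx["col"]] %||% idx["col"], "' in cell line '",
         rownames(expr)[idx["row"]] %||% idx["row"], "'", call. = FALSE)
  }
  x <- log2(expr + 1)
  mu <- colMeans(x)
  n <- nrow(x)
  sd_pop <- sqrt(colMeans(x^2) - mu^2)
  sd_pop[sd_pop < sqrt(.Machine$double.eps)] <- Inf  # constant genes -> 0
  out <- sweep(sweep(x, 2, mu, "-"), 2, sd_pop, "/")
  attr(out, "preprocessed") <- TRUE
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binarize a synergy score at a fixed threshold
#'
#' Scores strictly above the threshold are the positive (synergistic) class;
#' boundary and lower scores are negative. The conventional threshold for
#' Loewe scores / ComboScores is 30.
#'
#' @param score numeric vector of finite synergy scores.
#' @param threshold decision threshold (default 30).
#' @return integer vector of 0/1 labels.
#' @export
binarize_synergy <- function(score, threshold = 30) {
  if (!all(is.finite(score))) {
    stop("non-finite synergy score at position ",
         which(!is.finite(score))[1], call. = FALSE)
  }
  as.integer(score > threshold)
}
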