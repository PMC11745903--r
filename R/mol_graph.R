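# Molecular graphs from SMILES, with a ConvMol-style 75-length atom
# featurization computed from the perceived connection table.

# fixed element vocabulary for the one-hot block (final slot = "other")
.MG_ELEMENTS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb"
)

.MG_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
                 Cl = 1, Br = 1, I = 1)

# legacy V2000 atom-block charge codes
.MG_CHARGE_CODE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0,
                     `5` = -1, `6` = -2, `7` = -3)

# minimal V2000 atom-block read for molecules the SDF container rejects
# (no bonds); elements and formal charges only
#' @keywords internal
.parse_bondless_sdf <- function(smiles, who) {
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = smiles),
    error = function(e) stop("invalid SMILES for ", who, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  n_atoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  if (is.na(n_atoms) || n_atoms < 1) {
    stop("invalid SMILES for ", who, ": no atoms parsed", call. = FALSE)
  }
  atom_lines <- lines[4 + seq_len(n_atoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  charge <- unname(.MG_CHARGE_CODE[trimws(substr(atom_lines, 37, 39))])
  charge[is.na(charge)] <- 0
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (cl in chg_lines) {
    f <- as.numeric(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", cl)),
                             "\\s+")[[1]])
    if (length(f) >= 2) {
      idx <- f[seq(1, length(f), by = 2)]
      val <- f[seq(2, length(f), by = 2)]
      charge[idx] <- val
    }
  }
  list(elements = elements, charge = charge)
}

#' Convert a SMILES string to a featurized molecular graph
#'
#' Parses the SMILES with OpenBabel (via ChemmineR), drops explicit
#' hydrogens, and featurizes each heavy atom with the documented
#' `"convmol75"` scheme: element one-hot (44 incl. other), degree one-hot
#' (0-10), implicit-valence one-hot (0-6), formal charge, radical-electron
#' slot, hybridization one-hot (sp/sp2/sp3/sp3d/sp3d2), aromatic flag, and
#' total-hydrogen one-hot (0-4) -- 75 values per atom. Hydrogen counts and
#' hybridization are derived from standard valence rules on the kekulized
#' connection table; aromaticity from ring perception.
#'
#' @param smiles a single SMILES string.
#' @param scheme atom-feature scheme id; only `"convmol75"` is defined.
#' @param drug_id optional id used in error messages.
#' @return an object of class `molecular_graph`: list with `atom_features`
#'   (atoms x 75 matrix), `bonds` (two-column matrix of undirected atom index
#'   pairs, 1-based), `n_atoms`, `scheme`, `smiles`.
#' @examples
#' g <- smiles_to_graph("CCO")
#' g$n_atoms  # 3
#' @export
smiles_to_graph <- function(smiles, scheme = "convmol75", drug_id = NULL) {
  stopifnot(length(smiles) == 1)
  if (scheme != "convmol75") {
    stop("unknown atom-feature scheme: ", scheme, call. = FALSE)
  }
  who <- if (is.null(drug_id)) paste0("'", smiles, "'") else
    paste0("drug ", drug_id, " ('", smiles, "')")
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("invalid SMILES for ", who, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  sdf1 <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf1)
  if (is.null(ab) || nrow(ab) == 0) {
    stop("invalid SMILES for ", who, ": no atoms parsed", call. = FALSE)
  }
  if (ncol(ab) < 3) {
    # molecules without bonds confuse the SDF container; take the atom
    # block straight from the V2000 text instead
    fb <- .parse_bondless_sdf(smiles, who)
    elements <- fb$elements
    charge <- fb$charge
    bonds <- matrix(integer(0), ncol = 3)
  } else {
    elements <- sub("_.*$", "", rownames(ab))
    charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else
      rep(0, nrow(ab))
    charge <- unname(.MG_CHARGE_CODE[as.character(charge_code)])
    charge[is.na(charge)] <- 0

    bb <- ChemmineR::bondblock(sdf1)
    # zero-bond molecules yield a counts-line artifact with < 3 columns
    bonds <- if (is.null(bb) || nrow(bb) == 0 || ncol(bb) < 3) {
      matrix(integer(0), ncol = 3)
    } else {
      cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
    }
  }

  # aromaticity via ring perception on the full molecule
  n_all <- length(elements)
  arom_atoms <- character(0)
  has_ring <- nrow(bonds) >= n_all  # cyclomatic number > 0
  if (has_ring) {
    rr <- tryCatch(ChemmineR::rings(sdf1, upper = 10, type = "all",
                                    arom = TRUE),
                   error = function(e) NULL)
    if (!is.null(rr) && length(rr$RINGS) > 0) {
      arom <- which(rr$AROMATIC)
      arom_atoms <- unique(unlist(rr$RINGS[arom]))
    }
  }
  is_arom_full <- paste0(elements, "_", seq_len(n_all)) %in% arom_atoms

  # drop explicit hydrogens, crediting them to their heavy neighbor
  heavy <- which(elements != "H")
  new_idx <- rep(NA_integer_, n_all)
  new_idx[heavy] <- seq_along(heavy)
  explicit_h <- integer(length(heavy))
  keep_bonds <- matrix(integer(0), ncol = 3)
  if (nrow(bonds) > 0) {
    h1 <- elements[bonds[, 1]] == "H"
    h2 <- elements[bonds[, 2]] == "H"
    for (r in which(xor(h1, h2))) {
      hv <- if (h1[r]) bonds[r, 2] else bonds[r, 1]
      explicit_h[new_idx[hv]] <- explicit_h[new_idx[hv]] + 1L
    }
    keep <- !h1 & !h2
    keep_bonds <- bonds[keep, , drop = FALSE]
    keep_bonds[, 1] <- new_idx[keep_bonds[, 1]]
    keep_bonds[, 2] <- new_idx[keep_bonds[, 2]]
  }
  if (any(keep_bonds[, 1] == keep_bonds[, 2])) {
    stop("self-bond in molecule for ", who, call. = FALSE)
  }

  n <- length(heavy)
  el <- elements[heavy]
  chg <- charge[heavy]
  is_arom <- is_arom_full[heavy]

  degree <- integer(n)
  bondsum <- numeric(n)
  n_double <- integer(n)
  n_triple <- integer(n)
  if (nrow(keep_bonds) > 0) {
    for (r in seq_len(nrow(keep_bonds))) {
      i <- keep_bonds[r, 1]; j <- keep_bonds[r, 2]
      o <- keep_bonds[r, 3]
      ord <- if (o == 4) 1.5 else o  # order-4 = aromatic bond notation
      degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
      bondsum[i] <- bondsum[i] + ord; bondsum[j] <- bondsum[j] + ord
      if (o == 2) { n_double[i] <- n_double[i] + 1L; n_double[j] <- n_double[j] + 1L }
      if (o == 3) { n_triple[i] <- n_triple[i] + 1L; n_triple[j] <- n_triple[j] + 1L }
    }
  }
  bondsum <- bondsum + explicit_h

  # implicit hydrogens from standard valences with a charge adjustment
  base_val <- .MG_VALENCE[el]
  base_val[is.na(base_val)] <- 0
  eff_val <- ifelse(el %in% c("N", "P", "O", "S"),
                    base_val + chg, base_val - abs(chg))
  implicit_h <- pmax(0L, as.integer(round(eff_val - ceiling(bondsum))))
  total_h <- implicit_h + explicit_h

  hyb <- ifelse(
    bondsum > 5.5, "sp3d2",
    ifelse(bondsum > 4.5 & degree >= 5, "sp3d",
      ifelse(n_triple > 0 | n_double >= 2, "sp",
        ifelse(is_arom | n_double > 0, "sp2", "sp3"))))

  feats <- matrix(0, nrow = n, ncol = 75)
  el_slot <- match(el, .MG_ELEMENTS)
  el_slot[is.na(el_slot)] <- length(.MG_ELEMENTS) + 1L  # "other"
  feats[cbind(seq_len(n), el_slot)] <- 1
  off <- 44
  feats[cbind(seq_len(n), off + pmin(degree, 10L) + 1L)] <- 1
  off <- off + 11
  feats[cbind(seq_len(n), off + pmin(implicit_h, 6L) + 1L)] <- 1
  off <- off + 7
  feats[, off + 1] <- chg
  # off + 2: radical electrons (not perceived; zero)
  off <- off + 2
  hyb_slot <- match(hyb, c("sp", "sp2", "sp3", "sp3d", "sp3d2"))
  feats[cbind(seq_len(n), off + hyb_slot)] <- 1
  off <- off + 5
  feats[, off + 1] <- as.numeric(is_arom)
  off <- off + 1
  feats[cbind(seq_len(n), off + pmin(total_h, 4L) + 1L)] <- 1

  bonds_out <- if (nrow(keep_bonds) > 0) {
    b <- cbind(pmin(keep_bonds[, 1], keep_bonds[, 2]),
               pmax(keep_bonds[, 1], keep_bonds[, 2]))
    b[!duplicated(b), , drop = FALSE]
  } else {
    matrix(integer(0), ncol = 2)
  }
  colnames(bonds_out) <- c("i", "j")

  structure(
    list(atom_features = feats, bonds = bonds_out, n_atoms = n,
         scheme = scheme, smiles = smiles,
         elements = el, aromatic = is_arom),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", x$smiles, ": ", x$n_atoms, " atoms, ",
      nrow(x$bonds), " bonds (scheme ", x$scheme, ")\n", sep = "")
  invisible(x)
}

# adjacency list (1-based neighbor indices per atom)
#' @keywords internal
.mg_neighbors <- function(graph) {
  nb <- vector("list", graph$n_atoms)
  if (nrow(graph$bonds) > 0) {
    for (r in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds[r, 1]; j <- graph$bonds[r, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

#' Dump / load a molecular graph as delimited text
#'
#' Deterministic plain-text round trip of the atom feature matrix and bond
#' list, used for fixtures.
#'
#' @param graph a `molecular_graph`.
#' @param path output path.
#' @return `path` invisibly (write); a `molecular_graph` (read).
#' @export
write_molecular_graph <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# molecular_graph\t%s\t%d\t%d\t%s", graph$scheme,
                     graph$n_atoms, nrow(graph$bonds), graph$smiles), con)
  utils::write.table(graph$atom_features, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (nrow(graph$bonds) > 0) {
    utils::write.table(graph$bonds, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_molecular_graph
#' @export
read_molecular_graph <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# molecular_graph\t", "", lines[1]), "\t")[[1]]
  scheme <- hdr[1]
  n_atoms <- as.integer(hdr[2])
  n_bonds <- as.integer(hdr[3])
  smiles <- hdr[4]
  feats <- do.call(rbind, lapply(lines[1 + seq_len(n_atoms)], function(l)
    as.numeric(strsplit(l, "\t")[[1]])))
  bonds <- if (n_bonds > 0) {
    do.call(rbind, lapply(lines[1 + n_atoms + seq_len(n_bonds)], function(l)
      as.integer(strsplit(l, "\t")[[1]])))
  } else matrix(integer(0), ncol = 2)
  colnames(bonds) <- c("i", "j")
  structure(
    list(atom_features = feats, bonds = bonds, n_atoms = n_atoms,
         scheme = scheme, smiles = smiles),
    class = "molecular_graph"
  )
}
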