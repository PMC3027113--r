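#' Parse a protein structure into a residue model
#'
#' Reads ATOM records for one chain of a PDB file and reduces each residue to
#' a single point: the unweighted centroid of its side-chain heavy atoms, or
#' the C-alpha position for glycine. The resulting model is the input for
#' residue contact-network construction.
#'
#' Rules applied while parsing:
#' \itemize{
#'   \item Only the requested model of a multi-model file is used
#'     (default: the first).
#'   \item HETATM records and waters are skipped, except selenomethionine
#'     (MSE), which is mapped to MET.
#'   \item For alternate-location residues the conformer with the highest
#'     summed occupancy is kept (ties: the one listed first).
#'   \item Non-standard residues are dropped with a warning; hydrogens are
#'     ignored.
#'   \item A non-glycine residue with no side-chain heavy atoms falls back to
#'     its C-alpha position (with a warning) so sequence indexing stays
#'     aligned; a residue with no usable atoms at all is dropped.
#' }
#'
#' @param pdb_source Path to a PDB file.
#' @param chain Chain identifier. `NULL` (default) selects the first chain
#'   that appears in the file.
#' @param model_index Which model of a multi-model file to use (1-based).
#' @param protein_id Identifier stored in the result; defaults to the file
#'   name without extension.
#'
#' @return An object of class `structure_model`: a list with `protein_id`,
#'   `chain_id`, `residues` (data frame with `chain_id`, `seq_index`,
#'   `resnum`, `aa`, `x`, `y`, `z`), `atoms` (heavy-atom table used for
#'   accessibility calculations) and `n_residues`.
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' cfg <- sim_config(n_proteins = 1, residues_range = c(12, 12))
#' gen_structure(cfg, n_res = 12, path = pdb, seed = 7)
#' m <- parse_structure(pdb)
#' m$n_residues
parse_structure <- function(pdb_source, chain = NULL, model_index = 1,
                            protein_id = NULL) {
  if (!file.exists(pdb_source)) {
    stop("structure file not found: ", pdb_source)
  }
  protein_id <- protein_id %||%
    sub("\\.(pdb|ent|cif)$", "", basename(pdb_source), ignore.case = TRUE)

  pdb <- suppressWarnings(bio3d::read.pdb(pdb_source, multi = TRUE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (model_index > 1) {
    if (nrow(pdb$xyz) < model_index) {
      stop("model_index ", model_index, " requested but file has only ",
           nrow(pdb$xyz), " model(s)")
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }

  # keep ATOM records plus MSE (selenomethionine -> MET); drop waters
  keep <- (at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")) &
    !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", pdb_source)

  # drop hydrogens / deuteriums
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == "")) {
    elesy <- substr(gsub("^[0-9]", "", at$elety), 1, 1)
  }
  at <- at[!(toupper(elesy) %in% c("H", "D")), , drop = FALSE]

  chains <- unique(at$chain)
  if (is.null(chain)) chain <- chains[1]
  if (!chain %in% chains) {
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  }
  at <- at[at$chain == chain, , drop = FALSE]
  at$resid[at$resid == "MSE"] <- "MET"

  # residue keys in file order
  ins <- at$insert
  ins[is.na(ins)] <- ""
  rkey <- paste(at$resno, ins, sep = "|")
  rkey_order <- unique(rkey)

  res_list <- vector("list", length(rkey_order))
  atom_list <- vector("list", length(rkey_order))
  dropped <- character(0)
  ca_fallback <- character(0)
  idx <- 0L
  for (k in rkey_order) {
    ra <- at[rkey == k, , drop = FALSE]
    resid3 <- ra$resid[1]
    aa1 <- bio3d::aa321(resid3)
    label <- paste0(resid3, " ", sub("\\|", "", k))
    if (is.na(aa1) || !aa1 %in% AA_PSSM) {
      dropped <- c(dropped, label)
      next
    }
    # alternate locations: keep highest summed occupancy conformer
    alts <- ra$alt
    alts[is.na(alts)] <- ""
    codes <- setdiff(unique(alts), "")
    if (length(codes) > 0L) {
      occ <- vapply(codes, function(a) sum(ra$o[alts == a], na.rm = TRUE),
                    numeric(1))
      best <- codes[which.max(occ)]  # which.max keeps the first on ties
      ra <- ra[alts == "" | alts == best, , drop = FALSE]
    }
    cen <- residue_centroid(ra[, c("elety", "x", "y", "z")], aa1)
    if (is.null(cen)) {
      dropped <- c(dropped, label)
      next
    }
    if (isTRUE(attr(cen, "ca_fallback"))) ca_fallback <- c(ca_fallback, label)
    idx <- idx + 1L
    res_list[[idx]] <- data.frame(
      chain_id = chain, seq_index = idx,
      resnum = trimws(paste0(ra$resno[1],
                             if (is.na(ra$insert[1])) "" else ra$insert[1])),
      aa = aa1, x = cen[1], y = cen[2], z = cen[3],
      stringsAsFactors = FALSE)
    atom_list[[idx]] <- data.frame(
      seq_index = idx, elety = ra$elety,
      x = ra$x, y = ra$y, z = ra$z, stringsAsFactors = FALSE)
  }
  if (idx == 0L) stop("chain '", chain, "' contains no standard residues")
  if (length(dropped) > 0L) {
    warning("dropped ", length(dropped), " non-standard/empty residue(s): ",
            paste(head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  }
  if (length(ca_fallback) > 0L) {
    warning("side chain missing, C-alpha used for: ",
            paste(head(ca_fallback, 5), collapse = ", "),
            if (length(ca_fallback) > 5) ", ...")
  }

  residues <- do.call(rbind, res_list[seq_len(idx)])
  rownames(residues) <- NULL
  out <- list(protein_id = protein_id, chain_id = chain,
              residues = residues,
              atoms = do.call(rbind, atom_list[seq_len(idx)]),
              n_residues = nrow(residues))
  class(out) <- "structure_model"
  out
}

#' Side-chain centroid of one residue
#'
#' The representative point of a residue is the arithmetic mean of its
#' side-chain heavy-atom coordinates; glycine, having no side chain, is
#' represented by its C-alpha. A non-glycine residue whose side-chain atoms
#' are all missing (disordered) falls back to C-alpha.
#'
#' @param atoms Data frame with columns `elety` (atom name), `x`, `y`, `z`.
#' @param aa One-letter amino-acid code of the residue.
#' @return Numeric length-3 vector, or `NULL` when no usable atom exists.
#'   The attribute `ca_fallback` is `TRUE` when a missing side chain forced
#'   the C-alpha fallback.
#' @export
residue_centroid <- function(atoms, aa) {
  if (nrow(atoms) == 0L) return(NULL)
  nm <- toupper(trimws(atoms$elety))
  ca <- which(nm == "CA")
  if (aa == "G") {
    if (length(ca) == 0L) return(NULL)
    return(c(atoms$x[ca[1]], atoms$y[ca[1]], atoms$z[ca[1]]))
  }
  side <- which(!(nm %in% BACKBONE_ATOMS))
  if (length(side) > 0L) {
    cen <- c(mean(atoms$x[side]), mean(atoms$y[side]), mean(atoms$z[side]))
    if (all(is.finite(cen))) return(cen)
  }
  if (length(ca) == 0L) return(NULL)
  cen <- c(atoms$x[ca[1]], atoms$y[ca[1]], atoms$z[ca[1]])
  attr(cen, "ca_fallback") <- TRUE
  cen
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", x$protein_id, " chain", x$chain_id,
      " (", x$n_residues, "residues )\n")
  invisible(x)
}

#' Write the parsed residue table to TSV
#'
#' @param model A `structure_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_residue_tsv <- function(model, path) {
  write.table(model$residues, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Map a variant-table position to a seq_index under the chosen convention.
resolve_position <- function(model, position, position_by = c("index", "author")) {
  position_by <- match.arg(position_by)
  if (position_by == "index") {
    pos <- as.integer(position)
    if (is.na(pos) || pos < 1L || pos > model$n_residues) return(NA_integer_)
    return(pos)
  }
  hit <- which(model$residues$resnum == as.character(position))
  if (length(hit) == 0L) return(NA_integer_)
  hit[1]
}
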