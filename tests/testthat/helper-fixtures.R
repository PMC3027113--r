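# Fixture builders: hand-written PDB records, toy profiles, and a small
# cached synthetic dataset shared by the slower tests.

pdb_line <- function(serial, name, resn, chain, resno, x, y, z,
                     occ = 1, alt = "", type = "ATOM", elem = "C") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, paste0(" ", name), alt, resn, chain, resno, "",
          x, y, z, occ, 0, elem)
}

write_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Three residues (SER, GLY, ALA) with known side-chain centroids
# (0,0,1), (5,0,0) [CA], (0,5,0).
toy3_pdb <- function() {
  write_pdb(c(
    pdb_line(1, "N", "SER", "A", 1, -1, 0, 0, elem = "N"),
    pdb_line(2, "CA", "SER", "A", 1, 0, 0, -1),
    pdb_line(3, "CB", "SER", "A", 1, 0, 0, 0),
    pdb_line(4, "OG", "SER", "A", 1, 0, 0, 2, elem = "O"),
    pdb_line(5, "CA", "GLY", "A", 2, 5, 0, 0),
    pdb_line(6, "CA", "ALA", "A", 3, 1, 5, 0),
    pdb_line(7, "CB", "ALA", "A", 3, 0, 5, 0)))
}

# A uniform-ish toy profile as profile_matrix via the TSV dialect.
toy_profile <- function(percent_rows, aa = NULL,
                        score_rows = NULL) {
  n <- nrow(percent_rows)
  aas <- psnsap:::AA_PSSM
  if (is.null(aa)) aa <- aas[max.col(percent_rows)]
  if (is.null(score_rows)) score_rows <- matrix(0L, n, 20)
  df <- data.frame(pos = seq_len(n), aa = aa)
  s <- as.data.frame(score_rows); names(s) <- paste0("s_", aas)
  p <- as.data.frame(percent_rows); names(p) <- paste0("p_", aas)
  path <- tempfile(fileext = ".pssm")
  write.table(cbind(df, s, p), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  parse_pssm(path)
}

# Profile with given per-position entropy ordering: percent mass split
# between the wild residue and alanine controls entropy smoothly.
profile_with_entropies <- function(wild_aa, conservedness) {
  aas <- psnsap:::AA_PSSM
  n <- length(wild_aa)
  pm <- matrix(0, n, 20)
  for (i in seq_len(n)) {
    wi <- match(wild_aa[i], aas)
    other <- if (wi == 1) 2 else 1
    pm[i, wi] <- round(100 * conservedness[i])
    pm[i, other] <- 100 - pm[i, wi]
  }
  toy_profile(pm, aa = wild_aa)
}

# Small synthetic dataset, generated once per test run and cached.
tiny_dataset_env <- new.env()
tiny_dataset <- function() {
  if (is.null(tiny_dataset_env$ds)) {
    dir <- file.path(tempdir(), "psnsap-tiny-ds")
    cfg <- sim_config(n_proteins = 5, residues_range = c(25, 40),
                      n_saps = 120)
    gen_dataset(cfg, dir, seed = 42)
    tiny_dataset_env$ds <- load_dataset(dir)
    tiny_dataset_env$fz <- featurize(tiny_dataset_env$ds$variants,
                                     tiny_dataset_env$ds$structures_dir,
                                     tiny_dataset_env$ds$profiles_dir,
                                     aux = tiny_dataset_env$ds$aux)
  }
  list(ds = tiny_dataset_env$ds, fz = tiny_dataset_env$fz)
}
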