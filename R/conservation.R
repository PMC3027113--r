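#' Parse a sequence profile (PSSM)
#'
#' Reads the ASCII position-specific scoring matrix produced by iterated
#' profile search (the `-Q` style output: one row per position carrying 20
#' log-odds scores followed by 20 weighted observed percentages), or a plain
#' TSV fallback with columns `pos`, `aa`, 20 score columns and 20 percent
#' columns.
#'
#' Per-position frequencies are derived from the observed percentages,
#' renormalized to sum to 1 (the ASCII output is rounded). Positions whose
#' percentages are all zero are flagged; their entropy is defined as 0.
#'
#' @param profile_source Path to the profile file.
#' @return A `profile_matrix`: list with `length`, `aa` (consensus residue
#'   per position), `scores` and `percents` (L x 20 matrices, columns in
#'   PSSM alphabet order), `frequencies` (renormalized), and `zero_row`
#'   (logical flag per position).
#' @export
parse_pssm <- function(profile_source) {
  if (!file.exists(profile_source)) {
    stop("profile file not found: ", profile_source)
  }
  lines <- readLines(profile_source, warn = FALSE)
  first <- lines[nzchar(trimws(lines))][1]
  if (!is.na(first) && grepl("^pos\t", first)) {
    return(parse_pssm_tsv(profile_source))
  }

  rows <- list()
  aa <- character(0)
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 42L) next
    if (!grepl("^[0-9]+$", tok[1]) || !tok[2] %in% AA_PSSM) next
    vals <- suppressWarnings(as.numeric(tok[3:42]))
    if (anyNA(vals)) {
      stop("malformed profile row at line ", ln, " of ", profile_source)
    }
    rows[[length(rows) + 1L]] <- vals
    aa <- c(aa, tok[2])
  }
  if (length(rows) == 0L) stop("no profile rows found in ", profile_source)
  m <- do.call(rbind, rows)
  new_profile_matrix(scores = m[, 1:20, drop = FALSE],
                     percents = m[, 21:40, drop = FALSE], aa = aa)
}

parse_pssm_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  score_cols <- paste0("s_", AA_PSSM)
  pct_cols <- paste0("p_", AA_PSSM)
  missing <- setdiff(c("pos", "aa", score_cols, pct_cols), names(df))
  if (length(missing) > 0L) {
    stop("profile TSV missing columns: ", paste(missing, collapse = ", "))
  }
  df <- df[order(df$pos), , drop = FALSE]
  new_profile_matrix(scores = as.matrix(df[, score_cols]),
                     percents = as.matrix(df[, pct_cols]),
                     aa = as.character(df$aa))
}

new_profile_matrix <- function(scores, percents, aa) {
  colnames(scores) <- AA_PSSM
  colnames(percents) <- AA_PSSM
  if (any(percents < 0)) stop("negative observed percentage in profile")
  rs <- rowSums(percents)
  zero_row <- rs == 0
  freq <- percents / ifelse(rs == 0, 1, rs)
  structure(list(length = nrow(scores), aa = aa, scores = scores,
                 percents = percents, frequencies = freq,
                 zero_row = zero_row),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", x$length, "positions",
      if (any(x$zero_row)) paste0("(", sum(x$zero_row), " all-zero)"), "\n")
  invisible(x)
}

#' Write a profile in the TSV fallback dialect
#'
#' @param profile A `profile_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pssm_tsv <- function(profile, path) {
  df <- data.frame(pos = seq_len(profile$length), aa = profile$aa)
  s <- as.data.frame(profile$scores); names(s) <- paste0("s_", AA_PSSM)
  p <- as.data.frame(profile$percents); names(p) <- paste0("p_", AA_PSSM)
  write.table(cbind(df, s, p), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Conservation score of a position (Shannon entropy)
#'
#' `-sum_j p_j log2 p_j` over the 20 amino-acid frequencies, with
#' `0 log2 0 := 0`. Lower values mean a more conserved position; the maximum
#' `log2 20` (about 4.32 bits) corresponds to a uniform position.
#'
#' @param freqs Numeric vector of 20 non-negative frequencies summing to at
#'   most 1 (small rounding overshoot tolerated).
#' @return Entropy in bits, in `[0, log2(20)]`.
#' @export
#' @examples
#' conservation_score(rep(1 / 20, 20))  # log2(20)
#' conservation_score(c(1, rep(0, 19)))  # 0
conservation_score <- function(freqs) {
  if (any(freqs < 0)) stop("negative frequency")
  if (sum(freqs) > 1 + 1e-6) {
    warning("frequencies sum to ", format(sum(freqs)), "; renormalizing")
    freqs <- freqs / sum(freqs)
  }
  p <- freqs[freqs > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

#' The seven conservation features of a substitution
#'
#' Profile-derived description of one mutation: the position-specific scores
#' and observed percentages of the wild-type and mutant residues, their
#' differences (mutant minus wild-type), and the position's conservation
#' score (entropy).
#'
#' @param profile A `profile_matrix`.
#' @param pos Position (1-based) in the profile.
#' @param wild,mutant One-letter amino-acid codes.
#' @return Named numeric vector of length 7: `pssm_wild`, `pssm_mutant`,
#'   `freq_wild`, `freq_mutant`, `det_pssm`, `det_freq`, `entropy`.
#'   Percent features are on the 0-100 scale of the profile output.
#' @export
conservation_features <- function(profile, pos, wild, mutant) {
  stopifnot(inherits(profile, "profile_matrix"))
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L || pos > profile$length) {
    stop("position ", pos, " outside profile of length ", profile$length)
  }
  if (!wild %in% AA_PSSM || !mutant %in% AA_PSSM) {
    stop("wild/mutant must be standard one-letter amino acids")
  }
  pw <- profile$scores[pos, wild]
  pm <- profile$scores[pos, mutant]
  fw <- profile$percents[pos, wild]
  fm <- profile$percents[pos, mutant]
  ent <- if (profile$zero_row[pos]) 0 else
    conservation_score(profile$frequencies[pos, ])
  c(pssm_wild = unname(pw), pssm_mutant = unname(pm),
    freq_wild = unname(fw), freq_mutant = unname(fm),
    det_pssm = unname(pm - pw), det_freq = unname(fm - fw),
    entropy = ent)
}

# Entropy of every profile position (0 for flagged all-zero rows).
profile_entropy <- function(profile) {
  ent <- as.numeric(apply(profile$frequencies, 1, conservation_score))
  ent[profile$zero_row] <- 0
  ent
}
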