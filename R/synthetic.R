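#' Configuration for the synthetic study generator
#'
#' The defaults define the package's desk-scale study conditions: 40
#' proteins of 50-90 residues, 2000 substitution records with a disease
#' fraction of 0.6 (mirroring the roughly 3:2 disease:neutral balance of
#' curated SAP collections), and a planted logistic disease signal that
#' increases with the site's closeness centrality and decreases with its
#' conservation entropy — the qualitative pattern the feature analysis is
#' expected to recover.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param residues_range Length range (inclusive) of each chain.
#' @param packing_density Relative compactness of the chain; larger values
#'   shrink the confinement radius and raise the contact network's mean
#'   degree.
#' @param conservation_concentration Dirichlet sharpness of profile
#'   columns: 1 gives flat (uninformative) columns, larger values
#'   concentrate mass on the wild-type residue (entropy to 0 in the limit).
#' @param conservation_coupling Strength of the link between a position's
#'   closeness and its profile sharpness (0 = independent).
#' @param effect_sizes Named coefficients (`closeness`, `entropy`,
#'   `degree`) of the logistic disease model on standardized features.
#' @param class_balance Target disease fraction of the labels.
#' @param n_saps Number of substitution records to sample.
#' @param cutoff Contact cutoff in angstroms.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 40, residues_range = c(50, 90),
                       packing_density = 1,
                       conservation_concentration = 10,
                       conservation_coupling = 0,
                       effect_sizes = c(closeness = 2, entropy = -1.5,
                                        degree = 0),
                       class_balance = 0.6, n_saps = 2000, cutoff = 6.5) {
  stopifnot(n_proteins >= 1, all(residues_range >= 3),
            packing_density > 0, conservation_concentration >= 1,
            class_balance > 0, class_balance < 1, n_saps >= 1)
  es <- c(closeness = 0, entropy = 0, degree = 0)
  es[names(effect_sizes)] <- effect_sizes
  structure(list(n_proteins = n_proteins, residues_range = residues_range,
                 packing_density = packing_density,
                 conservation_concentration = conservation_concentration,
                 conservation_coupling = conservation_coupling,
                 effect_sizes = es, class_balance = class_balance,
                 n_saps = n_saps, cutoff = cutoff),
            class = "sim_config")
}

unit_vec <- function(v) v / sqrt(sum(v^2))

#' Generate a synthetic protein structure
#'
#' Writes a compact self-avoiding random chain in PDB format: C-alpha atoms
#' on 3.8 A steps, confined to a sphere whose radius scales with
#' `n^(1/3) / packing_density^(1/3)`, with at least 4 A between
#' non-adjacent residues. Every non-glycine residue carries a single CB
#' pseudo-atom 1.5 A from its CA, so the parsed side-chain centroid is the
#' CB position exactly; glycines exercise the C-alpha rule.
#'
#' @param cfg A [sim_config()].
#' @param n_res Chain length.
#' @param path Output PDB path.
#' @param seed RNG seed; identical seeds give byte-identical files.
#' @param chain Chain identifier.
#' @return Invisibly, a list with `path`, the residue `aa` vector, and the
#'   intended `centroids` matrix (the parse oracle).
#' @export
gen_structure <- function(cfg, n_res, path, seed, chain = "A") {
  set.seed(seed)
  aa <- sample(AA_PSSM, n_res, replace = TRUE)
  r_conf <- 3.2 * n_res^(1 / 3) / cfg$packing_density^(1 / 3)
  pos <- matrix(0, n_res, 3)
  for (i in 2:n_res) {
    best <- NULL
    best_min <- -Inf
    for (try in 1:60) {
      dir <- rnorm(3)
      if (sqrt(sum(pos[i - 1, ]^2)) > r_conf) {
        dir <- dir - 1.5 * unit_vec(pos[i - 1, ])
      }
      cand <- pos[i - 1, ] + 3.8 * unit_vec(dir)
      min_d <- if (i > 2) {
        min(sqrt(rowSums((pos[1:(i - 2), , drop = FALSE] -
                            matrix(cand, i - 2, 3, byrow = TRUE))^2)))
      } else Inf
      if (min_d >= 4 && sqrt(sum(cand^2)) <= 1.25 * r_conf) {
        best <- cand
        break
      }
      if (min_d > best_min) {
        best_min <- min_d
        best <- cand
      }
    }
    pos[i, ] <- best
  }
  cb <- pos + t(vapply(seq_len(n_res), function(i) 1.5 * unit_vec(rnorm(3)),
                       numeric(3)))
  centroids <- ifelse(matrix(aa == "G", n_res, 3), pos, cb)

  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n_res)) {
    resn <- bio3d::aa123(aa[i])
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, " CA", "", resn, chain, i, "",
      pos[i, 1], pos[i, 2], pos[i, 3], 1, 0, "C"))
    if (aa[i] != "G") {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, " CB", "", resn, chain, i, "",
        cb[i, 1], cb[i, 2], cb[i, 3], 1, 0, "C"))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(list(path = path, aa = aa, centroids = centroids))
}

#' Generate a synthetic sequence profile
#'
#' Draws per-position amino-acid frequency vectors from a Dirichlet with
#' extra concentration on the wild-type residue, optionally sharpened at
#' positions of high closeness centrality (so conserved and central
#' positions co-locate), and writes them in the ASCII PSSM dialect that
#' [parse_pssm()] reads. Scores are rounded log-odds against a uniform
#' background; percentages are rounded to integers, as in real profile
#' output.
#'
#' @param cfg A [sim_config()].
#' @param model The `structure_model` the profile belongs to.
#' @param path Output file.
#' @param seed RNG seed.
#' @param closeness_z Optional standardized closeness vector (required only
#'   when `conservation_coupling` is nonzero and the caller has it
#'   precomputed; otherwise it is computed from the structure).
#' @return Invisibly, the true (unrounded) frequency matrix.
#' @export
gen_profile <- function(cfg, model, path, seed, closeness_z = NULL) {
  n <- model$n_residues
  conc <- rep(cfg$conservation_concentration, n)
  if (cfg$conservation_coupling != 0) {
    if (is.null(closeness_z)) {
      topo <- network_features(build_network(model, cfg$cutoff))
      closeness_z <- as.numeric(scale(topo$closeness))
      closeness_z[is.na(closeness_z)] <- 0
    }
    conc <- 1 + (cfg$conservation_concentration - 1) *
      exp(cfg$conservation_coupling * closeness_z)
  }
  set.seed(seed)
  p <- matrix(0, n, 20, dimnames = list(NULL, AA_PSSM))
  for (i in seq_len(n)) {
    alpha <- rep(1, 20)
    wi <- match(model$residues$aa[i], AA_PSSM)
    alpha[wi] <- alpha[wi] + (conc[i] - 1)
    g <- rgamma(20, shape = alpha)
    p[i, ] <- g / sum(g)
  }
  scores <- pmax(pmin(round(2 * log2((p + 1e-4) / 0.05)), 13), -12)
  percents <- round(100 * p)
  header <- paste0(
    "Last position-specific scoring matrix computed, weighted observed ",
    "percentages rounded down, information per position, and relative ",
    "weight of gapless real matches to pseudocounts")
  cols <- paste0("         ",
                 paste(sprintf("%4s", AA_PSSM), collapse = ""), " ",
                 paste(sprintf("%4s", AA_PSSM), collapse = ""))
  rows <- vapply(seq_len(n), function(i) {
    ent <- conservation_score(p[i, ])
    paste0(sprintf("%5d %s ", i, model$residues$aa[i]),
           paste(sprintf("%4d", scores[i, ]), collapse = ""), " ",
           paste(sprintf("%4d", percents[i, ]), collapse = ""),
           sprintf("  %5.2f %8.2f", log2(20) - ent, 1))
  }, character(1))
  writeLines(c(header, "", cols, rows, ""), path)
  invisible(p)
}

#' Generate a complete labeled synthetic dataset
#'
#' Produces everything the pipeline consumes: structures, profiles, a
#' variant table with disease/polymorphism labels, auxiliary aggregation
#' and HLA tables, and a ground-truth JSON. Substitution sites are sampled
#' across the proteins; the disease label of each site is drawn from a
#' logistic model on its standardized closeness, conservation entropy and
#' degree with the configured effect sizes, and the intercept is solved so
#' the expected disease fraction matches `class_balance`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed), with subdirectories
#'   `structures/` and `profiles/`.
#' @param seed RNG seed for the whole dataset.
#' @return Invisibly, a list with `dir`, the `variants` data frame, the
#'   `aux` list (aggregation table and HLA ids) and the `truth` list.
#' @export
gen_dataset <- function(cfg, dir, seed = 1) {
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "profiles"), showWarnings = FALSE)

  ids <- sprintf("P%04d", seq_len(cfg$n_proteins))
  set.seed(seed)
  lens <- sample(seq(cfg$residues_range[1], cfg$residues_range[2]),
                 cfg$n_proteins, replace = TRUE)

  site_tab <- vector("list", cfg$n_proteins)
  for (i in seq_len(cfg$n_proteins)) {
    spath <- file.path(dir, "structures", paste0(ids[i], ".pdb"))
    gen_structure(cfg, lens[i], spath, seed = seed + 97L * i)
    model <- parse_structure(spath, protein_id = ids[i])
    net <- build_network(model, cfg$cutoff)
    topo <- network_features(net)
    ppath <- file.path(dir, "profiles", paste0(ids[i], ".pssm"))
    cz <- as.numeric(scale(topo$closeness))
    cz[is.na(cz)] <- 0
    gen_profile(cfg, model, ppath, seed = seed + 97L * i + 31L,
                closeness_z = cz)
    profile <- parse_pssm(ppath)
    site_tab[[i]] <- data.frame(
      protein_id = ids[i],
      structure_file = paste0(ids[i], ".pdb"),
      chain = model$chain_id,
      position = topo$seq_index,
      wild = model$residues$aa,
      closeness = topo$closeness,
      degree = topo$degree,
      entropy = profile_entropy(profile),
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, site_tab)

  set.seed(seed + 7919L)
  take <- sample(nrow(sites), min(cfg$n_saps, nrow(sites)))
  sites <- sites[take, , drop = FALSE]
  sites$mutant <- vapply(sites$wild,
                         function(w) sample(setdiff(AA_PSSM, w), 1),
                         character(1))

  zs <- function(v) {
    s <- as.numeric(scale(v))
    s[is.na(s)] <- 0
    s
  }
  lp <- cfg$effect_sizes["closeness"] * zs(sites$closeness) +
    cfg$effect_sizes["entropy"] * zs(sites$entropy) +
    cfg$effect_sizes["degree"] * zs(sites$degree)
  b0 <- uniroot(function(b) mean(plogis(b + lp)) - cfg$class_balance,
                c(-30, 30))$root
  sites$label <- ifelse(rbinom(nrow(sites), 1, plogis(b0 + lp)) == 1,
                        "disease", "polymorphism")

  variants <- sites[, c("protein_id", "structure_file", "chain", "position",
                        "wild", "mutant", "label")]
  rownames(variants) <- NULL
  write.table(variants, file.path(dir, "variants.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  agg <- data.frame(protein_id = sites$protein_id,
                    position = sites$position,
                    agg_wild = round(rnorm(nrow(sites)), 4),
                    agg_mutant = round(rnorm(nrow(sites)), 4))
  write.table(agg, file.path(dir, "aux_agg.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  hla_ids <- ids[seq_len(max(1L, round(0.05 * cfg$n_proteins)))]
  writeLines(hla_ids, file.path(dir, "hla_ids.txt"))

  truth <- list(effect_sizes = as.list(cfg$effect_sizes), intercept = b0,
                class_balance = cfg$class_balance, seed = seed,
                planted_features = names(cfg$effect_sizes)[
                  cfg$effect_sizes != 0])
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir, variants = variants,
                 aux = list(agg = agg, hla_ids = hla_ids), truth = truth))
}

#' Load a generated dataset directory
#'
#' @param dir Directory written by [gen_dataset()] (or laid out the same
#'   way).
#' @return List with `variants`, `aux` (aggregation table + HLA ids, when
#'   present) and the `structures`/`profiles` subdirectory paths.
#' @export
load_dataset <- function(dir) {
  variants <- read.delim(file.path(dir, "variants.tsv"),
                         stringsAsFactors = FALSE, colClasses = "character")
  variants$position <- as.integer(variants$position)
  aux <- list()
  agg_path <- file.path(dir, "aux_agg.tsv")
  if (file.exists(agg_path)) aux$agg <- read.delim(agg_path)
  hla_path <- file.path(dir, "hla_ids.txt")
  if (file.exists(hla_path)) aux$hla_ids <- readLines(hla_path)
  list(variants = variants, aux = aux,
       structures_dir = file.path(dir, "structures"),
       profiles_dir = file.path(dir, "profiles"))
}
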