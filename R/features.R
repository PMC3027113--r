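#' Feature schema of the full SAP feature vector
#'
#' The fixed, documented order of the 42 features produced by [assemble()]:
#' 7 conservation features, 4 topological features of the mutation site,
#' 25 environment features (5 most conserved contact neighbors x 5 values
#' each), and 6 auxiliary features (PAM250 score, solvent accessibility,
#' aggregation propensities, HLA-family flag).
#'
#' @return Character vector of 42 unique feature names, with a `blocks`
#'   attribute giving the block of each feature.
#' @export
feature_schema <- function() {
  cons <- c("pssm_wild", "pssm_mutant", "freq_wild", "freq_mutant",
            "det_pssm", "det_freq", "entropy")
  topo <- c("degree", "clustering", "closeness", "betweenness")
  env <- as.vector(t(outer(paste0("env", 1:5),
                           c("degree", "clustering", "closeness",
                             "betweenness", "entropy"),
                           paste, sep = "_")))
  aux <- c("pam250", "sasa_wild", "agg_wild", "agg_mutant", "agg_change",
           "hla_flag")
  nm <- c(cons, topo, env, aux)
  attr(nm, "blocks") <- rep(c("conservation", "topology", "environment",
                              "auxiliary"),
                            c(length(cons), length(topo), length(env),
                              length(aux)))
  nm
}

# -- PAM250 ------------------------------------------------------------------

pam250_env <- new.env(parent = emptyenv())

load_pam250 <- function() {
  if (is.null(pam250_env$m)) {
    path <- system.file("extdata", "pam250.txt", package = "psnsap")
    m <- as.matrix(read.table(path, header = TRUE, row.names = 1,
                              comment.char = "#", check.names = FALSE))
    storage.mode(m) <- "double"
    pam250_env$m <- m
  }
  pam250_env$m
}

#' PAM250 substitution score
#'
#' Log-odds score of substituting `wild` by `mutant` under the PAM250
#' mutation model; the matrix is symmetric, so the direction does not
#' matter. The table is shipped with the package.
#'
#' @param wild,mutant One-letter amino-acid codes.
#' @return Numeric score.
#' @export
#' @examples
#' pam250_score("W", "W")  # 17, the most conserved diagonal entry
pam250_score <- function(wild, mutant) {
  m <- load_pam250()
  if (!wild %in% rownames(m) || !mutant %in% rownames(m)) {
    stop("non-standard amino acid: ", wild, "/", mutant)
  }
  m[wild, mutant]
}

# -- environment encoding ----------------------------------------------------

#' Environment encoding of a mutation site
#'
#' The contact neighbors of the site are ranked by conservation score
#' (ascending entropy; lower = more conserved; ties broken by ascending
#' sequence index) and the five most conserved are kept. Each contributes
#' its degree, clustering coefficient, closeness, scaled betweenness and
#' entropy, concatenated in rank order into a 25-dimensional vector. Sites
#' with fewer than five neighbors are padded with zeros.
#'
#' @param net A `contact_network`.
#' @param profile A `profile_matrix` covering the chain.
#' @param pos Vertex (sequence index) of the mutation site.
#' @param topo Optional precomputed [network_features()] table (avoids
#'   recomputation when encoding many sites on one protein).
#' @return Named numeric vector of length 25 (`env1_degree` ...
#'   `env5_entropy`).
#' @export
environment_features <- function(net, profile, pos, topo = NULL) {
  pos <- check_vertex(net, pos)
  if (net$n > profile$length) {
    stop("profile (", profile$length, " positions) shorter than network (",
         net$n, " vertices)")
  }
  if (is.null(topo)) topo <- network_features(net)
  nb <- neighbors(net, pos)
  schema <- feature_schema()
  env_names <- schema[attr(schema, "blocks") == "environment"]
  out <- setNames(numeric(25), env_names)
  if (length(nb) > 0L) {
    ent <- vapply(nb, function(j) {
      if (profile$zero_row[j]) 0 else
        conservation_score(profile$frequencies[j, ])
    }, numeric(1))
    sel <- nb[order(ent, nb)][seq_len(min(5L, length(nb)))]
    for (r in seq_along(sel)) {
      j <- sel[r]
      out[(r - 1L) * 5L + 1:5] <- c(topo$degree[j], topo$clustering[j],
                                    topo$closeness[j], topo$betweenness[j],
                                    ent[match(j, nb)])
    }
  }
  out
}

# -- solvent accessibility (rolling-probe fallback) --------------------------

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radius <- function(elety) {
  first <- substr(gsub("^[0-9]", "", toupper(trimws(elety))), 1, 1)
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  out <- r[first]
  out[is.na(out)] <- 1.70
  unname(out)
}

#' Solvent-accessible surface area per residue
#'
#' Rolling-probe (Shrake-Rupley) accessible surface area computed from the
#' heavy atoms retained by [parse_structure()], summed per residue. Used as
#' a fallback when no externally computed accessibility table is supplied.
#'
#' @param model A `structure_model`.
#' @param probe Probe radius in angstroms (water, 1.4 A).
#' @param n_points Sphere sample points per atom.
#' @return Numeric vector of per-residue areas (A^2), indexed by
#'   `seq_index`.
#' @export
sasa_residues <- function(model, probe = 1.4, n_points = 96) {
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- atom_radius(at$elety) + probe
  sphere <- fibonacci_sphere(n_points)
  n_at <- nrow(at)
  area <- numeric(n_at)
  for (a in seq_len(n_at)) {
    dvec <- sqrt(colSums((t(xyz) - xyz[a, ])^2))
    nbr <- which(dvec < rad[a] + rad & seq_len(n_at) != a)
    pts <- sphere * rad[a]
    pts <- sweep(pts, 2, xyz[a, ], "+")
    if (length(nbr) > 0L) {
      free <- rep(TRUE, n_points)
      for (b in nbr) {
        if (!any(free)) break
        d2 <- colSums((t(pts[free, , drop = FALSE]) - xyz[b, ])^2)
        free[free] <- d2 > rad[b]^2
      }
      frac <- sum(free) / n_points
    } else {
      frac <- 1
    }
    area[a] <- frac * 4 * pi * rad[a]^2
  }
  per_res <- tapply(area, at$seq_index, sum)
  out <- numeric(model$n_residues)
  out[as.integer(names(per_res))] <- per_res
  out
}

# -- auxiliary features ------------------------------------------------------

#' Auxiliary features of a substitution record
#'
#' Looks up externally computed per-residue accessibility and per-record
#' aggregation propensities from optional tables, and flags HLA-family
#' proteins from a configurable identifier list. When no accessibility
#' table is given, the internal rolling-probe area ([sasa_residues()]) is
#' used; absent aggregation values default to 0 with a missingness flag.
#'
#' @param record List or one-row data frame with `protein_id`, `position`
#'   (sequence index), `wild`, `mutant`.
#' @param model The `structure_model` of the record's protein.
#' @param aux Optional list with elements `sasa` (data frame: `protein_id`,
#'   `position`, `sasa`), `agg` (data frame: `protein_id`, `position`,
#'   `agg_wild`, `agg_mutant`) and `hla_ids` (character vector).
#' @param sasa_cache Optional precomputed [sasa_residues()] vector for the
#'   protein.
#' @return Named numeric vector `sasa_wild`, `agg_wild`, `agg_mutant`,
#'   `agg_change`, `hla_flag`, with attribute `agg_missing`.
#' @export
auxiliary_features <- function(record, model, aux = list(),
                               sasa_cache = NULL) {
  pos <- as.integer(record$position)
  pid <- as.character(record$protein_id)

  sasa <- NA_real_
  if (!is.null(aux$sasa)) {
    hit <- which(aux$sasa$protein_id == pid & aux$sasa$position == pos)
    if (length(hit) > 0L) {
      sasa <- aux$sasa$sasa[hit[1]]
    } else {
      warning("no accessibility entry for ", pid, " position ", pos,
              "; using internal fallback")
    }
  }
  if (is.na(sasa)) {
    if (is.null(sasa_cache)) sasa_cache <- sasa_residues(model)
    sasa <- sasa_cache[pos]
  }

  agg_w <- agg_m <- 0
  agg_missing <- TRUE
  if (!is.null(aux$agg)) {
    hit <- which(aux$agg$protein_id == pid & aux$agg$position == pos)
    if (length(hit) > 0L) {
      agg_w <- aux$agg$agg_wild[hit[1]]
      agg_m <- aux$agg$agg_mutant[hit[1]]
      agg_missing <- FALSE
    } else {
      warning("no aggregation entry for ", pid, " position ", pos,
              "; defaulting to 0")
    }
  }
  hla <- as.numeric(pid %in% (aux$hla_ids %||% character(0)))
  out <- c(sasa_wild = unname(sasa), agg_wild = agg_w, agg_mutant = agg_m,
           agg_change = agg_m - agg_w, hla_flag = hla)
  attr(out, "agg_missing") <- agg_missing
  out
}

# -- assembly ----------------------------------------------------------------

#' Assemble the full feature vector for one substitution
#'
#' Concatenates, in the fixed [feature_schema()] order, the 7 conservation
#' features, the 4 topological features of the site on the wild-type
#' structure, the 25-dimensional neighbor-environment encoding, and the 6
#' auxiliary features. The record's wild-type amino acid must match the
#' parsed residue at its position; a mismatch (an erroneous position record)
#' raises an error of class `psnsap_wild_mismatch`.
#'
#' @param record List or one-row data frame with `protein_id`, `position`
#'   (sequence index), `wild`, `mutant`.
#' @param model `structure_model` of the protein.
#' @param net `contact_network` built from `model`.
#' @param profile `profile_matrix` of the protein.
#' @param aux Optional auxiliary tables (see [auxiliary_features()]).
#' @param topo,sasa_cache Optional precomputed per-protein tables.
#' @return Named numeric vector of length 42.
#' @export
assemble <- function(record, model, net, profile, aux = list(),
                     topo = NULL, sasa_cache = NULL) {
  pos <- as.integer(record$position)
  if (is.na(pos) || pos < 1L || pos > model$n_residues) {
    stop("position ", record$position, " outside chain of length ",
         model$n_residues)
  }
  wild <- as.character(record$wild)
  mutant <- as.character(record$mutant)
  parsed_aa <- model$residues$aa[pos]
  if (parsed_aa != wild) {
    cond <- simpleError(paste0("wild-type mismatch for ", record$protein_id,
                               " position ", pos, ": table says ", wild,
                               ", structure has ", parsed_aa))
    class(cond) <- c("psnsap_wild_mismatch", class(cond))
    stop(cond)
  }
  if (is.null(topo)) topo <- network_features(net)

  cons <- conservation_features(profile, pos, wild, mutant)
  top <- c(degree = topo$degree[pos], clustering = topo$clustering[pos],
           closeness = topo$closeness[pos],
           betweenness = topo$betweenness[pos])
  env <- environment_features(net, profile, pos, topo = topo)
  auxv <- auxiliary_features(record, model, aux, sasa_cache = sasa_cache)
  out <- c(cons, top, env, pam250 = pam250_score(wild, mutant), auxv)
  schema <- feature_schema()
  stopifnot(identical(names(out), as.vector(schema)))
  out
}

#' Featurize a variant table
#'
#' Runs the whole feature pipeline over a table of substitutions: parses
#' each referenced structure once, builds its contact network and topology
#' table, loads its sequence profile, and assembles the 42-feature vector of
#' every record. Records whose wild-type amino acid does not match the
#' parsed structure (or whose position is out of range) are rejected and
#' reported, not silently dropped.
#'
#' @param variants Data frame with columns `protein_id`, `structure_file`,
#'   `chain`, `position`, `wild`, `mutant`, and optionally `label`
#'   (`disease` / `polymorphism`) and `profile_file`.
#' @param structures_dir,profiles_dir Directories that `structure_file` /
#'   profile files are resolved against. Profiles default to
#'   `<protein_id>.pssm`.
#' @param aux Optional auxiliary tables (see [auxiliary_features()]).
#' @param cutoff Contact cutoff in angstroms.
#' @param position_by `"index"` (1-based position in the parsed chain,
#'   default) or `"author"` (residue numbering of the structure file).
#' @return List with `features` (data frame: identifier columns, optional
#'   `label`, then the 42 feature columns) and `rejects` (data frame with a
#'   `reason` per rejected record).
#' @export
featurize <- function(variants, structures_dir = ".", profiles_dir = ".",
                      aux = list(), cutoff = 6.5,
                      position_by = c("index", "author")) {
  position_by <- match.arg(position_by)
  required <- c("protein_id", "structure_file", "chain", "position",
                "wild", "mutant")
  missing <- setdiff(required, names(variants))
  if (length(missing) > 0L) {
    stop("variant table missing columns: ", paste(missing, collapse = ", "))
  }
  schema <- feature_schema()
  has_label <- "label" %in% names(variants)

  feat_rows <- list()
  rej_rows <- list()
  key <- paste(variants$protein_id, variants$structure_file, variants$chain)
  for (k in unique(key)) {
    rows <- which(key == k)
    v1 <- variants[rows[1], ]
    ctx <- tryCatch({
      spath <- file.path(structures_dir, v1$structure_file)
      model <- parse_structure(spath, chain = as.character(v1$chain),
                               protein_id = as.character(v1$protein_id))
      ppath <- if ("profile_file" %in% names(variants) &&
                   nzchar(v1$profile_file %||% "")) {
        file.path(profiles_dir, v1$profile_file)
      } else {
        file.path(profiles_dir, paste0(v1$protein_id, ".pssm"))
      }
      profile <- parse_pssm(ppath)
      net <- build_network(model, cutoff = cutoff)
      list(model = model, profile = profile, net = net,
           topo = network_features(net),
           sasa = if (is.null(aux$sasa)) sasa_residues(model) else NULL)
    }, error = function(e) e)
    if (inherits(ctx, "error")) {
      for (r in rows) {
        rej_rows[[length(rej_rows) + 1L]] <-
          cbind(variants[r, required], reason = conditionMessage(ctx))
      }
      next
    }
    for (r in rows) {
      rec <- variants[r, ]
      pos <- resolve_position(ctx$model, rec$position, position_by)
      res <- if (is.na(pos)) {
        simpleError(paste0("position ", rec$position,
                           " not found in parsed chain"))
      } else {
        rec2 <- rec; rec2$position <- pos
        tryCatch(assemble(rec2, ctx$model, ctx$net, ctx$profile, aux,
                          topo = ctx$topo, sasa_cache = ctx$sasa),
                 error = function(e) e)
      }
      if (inherits(res, "error")) {
        rej_rows[[length(rej_rows) + 1L]] <-
          cbind(rec[, required], reason = conditionMessage(res))
      } else {
        base <- rec[, c("protein_id", "position", "wild", "mutant")]
        if (has_label) base$label <- rec$label
        feat_rows[[length(feat_rows) + 1L]] <-
          cbind(base, as.data.frame(as.list(res)))
      }
    }
  }
  empty_feat <- stats::setNames(
    as.data.frame(matrix(numeric(0), ncol = 4 + has_label + length(schema))),
    c("protein_id", "position", "wild", "mutant",
      if (has_label) "label", schema))
  features <- if (length(feat_rows)) do.call(rbind, feat_rows) else empty_feat
  rownames(features) <- NULL
  rejects <- if (length(rej_rows)) do.call(rbind, rej_rows) else
    stats::setNames(as.data.frame(matrix(character(0), ncol = 7)),
                    c(required, "reason"))
  rownames(rejects) <- NULL
  list(features = features, rejects = rejects)
}
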