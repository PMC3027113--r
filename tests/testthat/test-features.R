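test_that("feature schema is fixed: 42 unique names in documented blocks", {
  schema <- feature_schema()
  expect_length(schema, 42)
  expect_length(unique(schema), 42)
  blocks <- attr(schema, "blocks")
  expect_equal(as.vector(table(blocks)[c("conservation", "topology",
                                         "environment", "auxiliary")]),
               c(7L, 4L, 25L, 6L))
})

test_that("PAM250 lookups are symmetric and match the shipped asset", {
  expect_equal(pam250_score("W", "W"), 17)
  expect_equal(pam250_score("A", "R"), pam250_score("R", "A"))
  aas <- psnsap:::AA_PSSM
  m <- outer(aas, aas, Vectorize(pam250_score))
  expect_true(isSymmetric(m))
  # independent reparse of the asset file
  path <- system.file("extdata", "pam250.txt", package = "psnsap")
  ref <- as.matrix(read.table(path, header = TRUE, row.names = 1,
                              comment.char = "#", check.names = FALSE))
  expect_equal(unname(m), unname(ref[aas, aas]))
  expect_error(pam250_score("A", "X"), "non-standard")
})

test_that("PAM250 asset equals the reference matrix in Biostrings", {
  skip_if_not_installed("Biostrings")
  ref <- NULL
  utils::data("PAM250", package = "Biostrings", envir = environment())
  ref <- get("PAM250", envir = environment())
  aas <- psnsap:::AA_PSSM
  m <- outer(aas, aas, Vectorize(pam250_score))
  expect_equal(unname(m), unname(ref[aas, aas]))
})

test_that("environment encoding selects the five most conserved neighbors", {
  # star: site 1 contacts 2..9; residues 10..12 exist but are not neighbors
  adj <- matrix(0, 12, 12)
  adj[1, 2:9] <- 1
  net <- as_contact_network(adj)
  cons <- c(0.9, seq(0.55, 0.90, by = 0.05), 0.99, 0.99, 0.99)
  prof <- profile_with_entropies(rep("L", 12), cons)
  ent <- psnsap:::profile_entropy(prof)
  env <- environment_features(net, prof, 1)
  expect_length(env, 25)
  # sort oracle over all neighbors: 5 smallest entropies
  sel_ent <- env[paste0("env", 1:5, "_entropy")]
  expect_equal(unname(sel_ent), sort(ent[2:9])[1:5], tolerance = 1e-12)
  # each selected block carries the neighbor's own topology (leaf: degree 1)
  expect_equal(unname(env[paste0("env", 1:5, "_degree")]), rep(1, 5))
})

test_that("environment vectors pad with zeros below five neighbors", {
  adj <- matrix(0, 6, 6)
  adj[1, 2:4] <- 1          # 3 neighbors
  net <- as_contact_network(adj)
  prof <- profile_with_entropies(rep("K", 6), rep(0.8, 6))
  env3 <- environment_features(net, prof, 1)
  expect_length(env3, 25)
  expect_equal(unname(env3[16:25]), rep(0, 10))
  expect_true(all(env3[c("env1_degree", "env2_degree", "env3_degree")] == 1))
  # isolated site: all 25 zeros
  env0 <- environment_features(net, prof, 5)
  expect_equal(unname(env0), rep(0, 25))
})

test_that("environment ties break by ascending sequence index", {
  adj <- matrix(0, 8, 8)
  adj[1, 2:8] <- 1
  net <- as_contact_network(adj)
  prof <- profile_with_entropies(rep("D", 8), rep(0.7, 8))  # all tied
  env <- environment_features(net, prof, 1)
  ent <- psnsap:::profile_entropy(prof)
  expect_equal(unname(env[paste0("env", 1:5, "_entropy")]),
               unname(ent[2:6]), tolerance = 1e-12)
})

test_that("a buried residue has near-zero accessible area", {
  # center CB at origin enclosed by a 26-point shell of CB atoms 4 A away
  shell <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  shell <- shell[rowSums(abs(shell)) > 0, ]
  shell <- 4 * shell / sqrt(rowSums(shell^2))
  lines <- c(pdb_line(1, "CA", "ALA", "A", 1, 0.5, 0, 0),
             pdb_line(2, "CB", "ALA", "A", 1, 0, 0, 0))
  for (i in seq_len(nrow(shell))) {
    lines <- c(lines,
               pdb_line(2 + 2 * i - 1, "CA", "ALA", "A", 1 + i,
                        shell[i, 1] + 0.5, shell[i, 2], shell[i, 3]),
               pdb_line(2 + 2 * i, "CB", "ALA", "A", 1 + i,
                        shell[i, 1], shell[i, 2], shell[i, 3]))
  }
  m <- parse_structure(write_pdb(lines))
  areas <- sasa_residues(m)
  expect_lt(areas[1], 1)           # buried
  expect_gt(mean(areas[-1]), 20)   # shell residues face outward
})

test_that("auxiliary features read tables, default sensibly, and flag HLA", {
  fx <- tiny_dataset()
  ds <- fx$ds
  rec <- list(protein_id = ds$variants$protein_id[1],
              position = ds$variants$position[1],
              wild = ds$variants$wild[1], mutant = ds$variants$mutant[1])
  model <- parse_structure(
    file.path(ds$structures_dir, ds$variants$structure_file[1]),
    protein_id = rec$protein_id)
  a <- auxiliary_features(rec, model, ds$aux)
  row <- ds$aux$agg[ds$aux$agg$protein_id == rec$protein_id &
                      ds$aux$agg$position == rec$position, ]
  expect_equal(unname(a["agg_wild"]), row$agg_wild)
  expect_equal(unname(a["agg_change"]), row$agg_mutant - row$agg_wild)
  expect_false(attr(a, "agg_missing"))
  expect_equal(unname(a["hla_flag"]),
               as.numeric(rec$protein_id %in% ds$aux$hla_ids))
  # absent from aggregation table: zeros plus missingness flag
  rec2 <- rec; rec2$position <- -99
  expect_warning(
    a2 <- auxiliary_features(list(protein_id = rec$protein_id, position = 1,
                                  wild = "A", mutant = "V"),
                             model, list(agg = ds$aux$agg[0, ])),
    "no aggregation entry")
  expect_equal(unname(a2[c("agg_wild", "agg_mutant", "agg_change")]),
               c(0, 0, 0))
  expect_true(attr(a2, "agg_missing"))
})

test_that("assemble returns 42 named features and rejects mismatches", {
  fx <- tiny_dataset()
  feats <- fx$fz$features
  schema <- feature_schema()
  expect_true(all(schema %in% names(feats)))
  expect_equal(sum(names(feats) %in% schema), 42)
  # identities hold on every record
  expect_equal(feats$det_freq, feats$freq_mutant - feats$freq_wild)
  expect_equal(feats$det_pssm, feats$pssm_mutant - feats$pssm_wild)
  expect_equal(feats$agg_change, feats$agg_mutant - feats$agg_wild)

  ds <- fx$ds
  v <- ds$variants[1, ]
  model <- parse_structure(file.path(ds$structures_dir, v$structure_file),
                           protein_id = v$protein_id)
  net <- build_network(model)
  prof <- parse_pssm(file.path(ds$profiles_dir,
                               paste0(v$protein_id, ".pssm")))
  wrong <- v
  wrong$wild <- setdiff(psnsap:::AA_PSSM, model$residues$aa[v$position])[1]
  expect_error(assemble(wrong, model, net, prof), class = "psnsap_wild_mismatch")
  expect_error(assemble({v2 <- v; v2$position <- 10000; v2}, model, net,
                        prof), "outside chain")
})

test_that("structure-side features ignore the mutant amino acid", {
  fx <- tiny_dataset()
  ds <- fx$ds
  v <- ds$variants[1, ]
  model <- parse_structure(file.path(ds$structures_dir, v$structure_file),
                           protein_id = v$protein_id)
  net <- build_network(model)
  prof <- parse_pssm(file.path(ds$profiles_dir,
                               paste0(v$protein_id, ".pssm")))
  alt <- v
  alt$mutant <- setdiff(psnsap:::AA_PSSM, c(v$wild, v$mutant))[1]
  f1 <- assemble(v, model, net, prof, aux = ds$aux)
  f2 <- assemble(alt, model, net, prof, aux = ds$aux)
  shared <- c("degree", "clustering", "closeness", "betweenness",
              grep("^env", names(f1), value = TRUE),
              "sasa_wild", "entropy", "pssm_wild", "freq_wild", "hla_flag")
  expect_equal(f1[shared], f2[shared])
  expect_false(f1["pam250"] == f2["pam250"] &&
                 f1["pssm_mutant"] == f2["pssm_mutant"])
})

test_that("featurize rejects bad records and keeps the header on empty input", {
  fx <- tiny_dataset()
  ds <- fx$ds
  v <- ds$variants[1:3, ]
  v$wild[2] <- setdiff(psnsap:::AA_PSSM,
                       c(v$wild[2], v$mutant[2]))[1]  # force mismatch
  res <- featurize(v, ds$structures_dir, ds$profiles_dir, aux = ds$aux)
  expect_equal(nrow(res$features), 2)
  expect_equal(nrow(res$rejects), 1)
  expect_match(res$rejects$reason[1], "mismatch")

  empty <- featurize(v[0, ], ds$structures_dir, ds$profiles_dir)
  expect_equal(nrow(empty$features), 0)
  expect_true(all(feature_schema() %in% names(empty$features)))
})
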