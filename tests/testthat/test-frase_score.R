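test_that("atom typing follows the documented perception rules", {
  V <- ligand_type_vocab()
  expect_length(V, 29)
  expect_length(protein_type_vocab(), 13)

  tb <- type_atoms_ligand(benzene_mol())
  for (t in tb)
    expect_setequal(V[t], c("Aromatic", "Aromatic Carbon"))

  hx <- hexagon_xyz()
  fluoro <- fbmol(c(rep("C", 6), "F"), rbind(hx, c(2.72, 0, 0)),
                  rbind(cbind(1:6, c(2:6, 1), rep(c(2L, 1L), 3)),
                        c(1L, 7L, 1L)), name = "FBZ")
  tf <- type_atoms_ligand(fluoro)[[7]]
  expect_true(all(c("Halogen", "F", "Hetero") %in% V[tf]))

  # carboxylate oxygens: acceptor + negative ionizable + carboxylate
  bza <- fragment_palette()$benzoate
  to <- type_atoms_ligand(bza)
  for (i in which(bza$element == "O"))
    expect_true(all(c("H-bond Acceptor", "Carboxylate Oxygen",
                      "Negative Ionizable") %in% V[to[[i]]]))

  # protein side: ASP carboxylate, LYS amine, PHE ring
  pv <- protein_type_vocab()
  asp <- place_residue("ASP", "A", 1, c(0, 0, 0), rotation = diag(3))
  pt <- type_atoms_protein(list(asp))
  od1 <- which(asp$atom_names == "OD1")
  expect_true(all(c("H-bond Acceptor", "Carboxylate Oxygen",
                    "Negative Ionizable") %in% pv[pt$types[[od1]]]))
  lys <- place_residue("LYS", "A", 2, c(0, 0, 0), rotation = diag(3))
  nz <- which(lys$atom_names == "NZ")
  expect_true(all(c("Positive Ionizable", "H-bond Donor") %in%
                  pv[type_atoms_protein(list(lys))$types[[nz]]]))
})

test_that("the distance weight implements the capped Gaussian", {
  expect_equal(distance_weight(3), 1.0)
  expect_equal(distance_weight(4), exp(-1))
  expect_equal(distance_weight(10), exp(-49))
  expect_equal(distance_weight(10.01), 0)
  expect_equal(distance_weight(12), 0)
  expect_error(distance_weight(-0.1), "negative")
  # vectorised
  expect_equal(distance_weight(c(3, 11)), c(1, 0))
})

test_that("the interaction fingerprint is 377-long and matches hand cases", {
  # one single-typed pair at 3 A contributes exactly 1.0 to its cell
  frag <- fbmol("C", matrix(c(0, 0, 0), 1), name = "C1")
  res <- fb_residue("ALA", "A", 1, "CB", "C", matrix(c(3, 0, 0), 1))
  fr <- frase(frag, list(res), source = "t", label = "true", id = "t1")
  fp <- interaction_fingerprint(fr)
  expect_length(fp, 377)
  m <- match("Aliphatic Carbon", ligand_type_vocab())
  n <- match("Aliphatic Carbon", protein_type_vocab())
  expect_equal(unname(fp[(m - 1) * 13 + n]), 1.0)
  expect_equal(sum(fp), 1.0)

  # the same pair beyond the cap gives the zero vector
  res12 <- fb_residue("ALA", "A", 1, "CB", "C", matrix(c(12, 0, 0), 1))
  fr12 <- frase(frag, list(res12), source = "t", label = "true", id = "t2")
  expect_equal(sum(interaction_fingerprint(fr12)), 0)
  expect_true(all(interaction_fingerprint(fr12) >= 0))
})

test_that("fingerprints equal the brute-force double-loop oracle", {
  for (seed in c(61, 62, 63)) {
    fr <- make_toy_complex(fixture_spec(
      seed = seed,
      fragment_name = c("benzamide", "imidazole", "benzoate")[seed - 60]
    ))$truth$frase
    expect_equal(unname(interaction_fingerprint(fr)), oracle_fingerprint(fr),
                 tolerance = 1e-12)
  }
})

test_that("fingerprints are invariant under rigid motion", {
  fr <- make_toy_complex(fixture_spec(seed = 71))$truth$frase
  fp1 <- interaction_fingerprint(fr)
  R <- frasebot:::.rand_rotation()
  shift <- c(5, -9, 2)
  fr2 <- fr
  fr2$fragment$xyz <- sweep(fr2$fragment$xyz %*% t(R), 2, -shift)
  for (i in seq_along(fr2$environment))
    fr2$environment[[i]]$xyz <- sweep(fr2$environment[[i]]$xyz %*% t(R), 2,
                                      -shift)
  expect_equal(fp1, interaction_fingerprint(fr2), tolerance = 1e-9)
})

test_that("decoy generation swaps fragments deterministically", {
  frs <- make_frase_set(10, seed = 5)
  d <- make_decoys(frs, decoy_spec(2, seed = 9))
  expect_length(d, 20)
  expect_true(all(vapply(d, `[[`, character(1), "label") == "decoy"))
  # environments untouched; fragment centroid preserved
  for (k in seq_along(d)) {
    i <- ceiling(k / 2)
    expect_identical(d[[k]]$environment, frs[[i]]$environment)
    expect_equal(colMeans(d[[k]]$fragment$xyz),
                 colMeans(frs[[i]]$fragment$xyz), tolerance = 1e-9)
    expect_false(identical(d[[k]]$fragment$name, NULL))
  }
  # no self-draw: decoy fragment never comes from its own FRASE
  for (k in seq_along(d)) {
    i <- ceiling(k / 2)
    donor <- sub(".*<-", "", d[[k]]$id)
    expect_false(donor == frs[[i]]$id)
  }
  # byte-identical rerun under the same seed
  d2 <- make_decoys(frs, decoy_spec(2, seed = 9))
  expect_identical(lapply(d, `[[`, "fragment"), lapply(d2, `[[`, "fragment"))
  expect_error(make_decoys(frs[1], decoy_spec(2)), "fewer than 2")
})

test_that("train/validation splits are disjoint and exhaustive", {
  ids <- sprintf("f%05d", 1:5000)
  sp <- split_frase_ids(ids, 1200, seed = 4)
  expect_length(sp$train, 1200)
  expect_length(sp$validation, 3800)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), ids)
  expect_identical(split_frase_ids(ids, 1200, seed = 4)$train, sp$train)
})

test_that("the classifier learns planted signal and stays honest on null", {
  ds <- make_separable_training_set(300, n_signal = 5, effect = 3, seed = 17)
  expect_gte(ds$bayes_accuracy, 0.95)
  m <- train_model(ds$true[1:200, ], ds$decoy[1:400, ], epochs = 120,
                   seed = 3)
  p_true <- mlp_predict(m$net, ds$true[201:300, ])
  p_decoy <- mlp_predict(m$net, ds$decoy[401:600, ])
  expect_true(all(p_true > 0 & p_true < 1))
  expect_gt(mean(p_true), mean(p_decoy))
  acc <- mean(c(p_true > 0.5, p_decoy <= 0.5))
  expect_gte(acc, 0.8)   # quick schedule; the full schedule is exercised
                         # in the acceptance suite
  expect_error(train_model(ds$true[0, , drop = FALSE], ds$decoy), "per class")
})

test_that("scores are pose-sensitive and rigid-motion invariant", {
  fr <- make_toy_complex(fixture_spec(seed = 81))$truth$frase
  ds <- make_separable_training_set(150, seed = 19)
  m <- train_model(ds$true, ds$decoy, epochs = 60, seed = 2)
  s1 <- score_frase(m, fr)
  expect_gt(s1, 0); expect_lt(s1, 1)
  R <- frasebot:::.rand_rotation()
  fr2 <- fr
  fr2$fragment$xyz <- fr2$fragment$xyz %*% t(R)
  for (i in seq_along(fr2$environment))
    fr2$environment[[i]]$xyz <- fr2$environment[[i]]$xyz %*% t(R)
  expect_equal(as.numeric(s1), as.numeric(score_frase(m, fr2)),
               tolerance = 1e-9)
  # a fingerprint argument is accepted directly
  expect_equal(as.numeric(score_frase(m, interaction_fingerprint(fr))),
               as.numeric(s1), tolerance = 1e-12)
})

test_that("model serialisation round-trips predictions", {
  ds <- make_separable_training_set(80, seed = 23)
  m <- train_model(ds$true, ds$decoy, epochs = 30, seed = 5)
  path <- tempfile(fileext = ".json")
  mlp_save(m$net, path)
  back <- mlp_load(path)
  X <- rbind(ds$true[1:10, ], ds$decoy[1:10, ])
  expect_equal(mlp_predict(back, X), mlp_predict(m$net, X), tolerance = 1e-12)
})
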