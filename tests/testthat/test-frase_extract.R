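test_that("drug-likeness filter flags each violated rule", {
  # benzamide: small, clean -> passes everything
  ok <- filter_ligand(fragment_palette()$benzamide)
  expect_true(ok$pass)
  expect_length(ok$reasons, 0)

  ph <- filter_ligand(phosphate_mol())
  expect_false(ph$pass)
  expect_true("phosphorus" %in% ph$reasons)

  pep <- filter_ligand(tetrapeptide_mol())
  expect_false(pep$pass)
  expect_true("peptide" %in% pep$reasons)

  # inorganic element
  sil <- fbmol(c("Si", "O"), rbind(c(0, 0, 0), c(1.6, 0, 0)),
               cbind(1L, 2L, 1L), name = "SIO")
  expect_true("inorganic_element" %in% filter_ligand(sil)$reasons)

  # reactive-group rules fire on constructed groups
  acrolein <- fbmol(c("C", "C", "C", "O"),
                    cbind(c(0, 1.3, 2.6, 3.5), c(0, 0.8, 0, 0.8), 0),
                    rbind(c(1L, 2L, 2L), c(2L, 3L, 1L), c(3L, 4L, 2L)),
                    name = "ACR")
  r <- filter_ligand(acrolein)
  expect_true(any(grepl("reactive", r$reasons)))
})

test_that("fragmentation follows the acyclic-single-bond and alpha rules", {
  hx <- hexagon_xyz()
  rb <- cbind(1:6, c(2:6, 1), rep(c(2L, 1L), 3))
  # ethylbenzene: ring + alpha-CH2 survives the MW window; ethane piece dies
  eb <- fbmol(rep("C", 8), rbind(hx, c(2.9, 0, 0), c(4.4, 0, 0)),
              rbind(rb, c(1L, 7L, 1L), c(7L, 8L, 1L)), name = "EBZ")
  fr <- fragment_ligand(eb)
  sizes <- sort(vapply(fr, n_atoms, integer(1)))
  expect_equal(sizes, c(7L, 8L))              # toluene-like + whole molecule
  mws <- sort(vapply(fr, function(f) attr(f, "mw"), numeric(1)))
  expect_equal(round(mws[1], 1), 92.1)        # ring + CH2, H-capped

  # single ring, no breakable bonds -> exactly the whole molecule
  chx <- fragment_palette()$cyclohexane
  expect_length(fragment_ligand(chx), 1)
  expect_equal(n_atoms(fragment_ligand(chx)[[1]]), 6)

  # biphenyl: each ring keeps the alpha-carbon across the inter-ring bond
  hx2 <- sweep(hx %*% diag(c(-1, 1, 1)), 2, c(-(2.78 + 1.39), 0, 0))
  bp <- fbmol(rep("C", 12), rbind(hx, hx2),
              rbind(rb, cbind(7:12, c(8:12, 7), rep(c(2L, 1L), 3)),
                    c(1L, 7L, 1L)), name = "BIP")
  fb <- fragment_ligand(bp)
  expect_setequal(vapply(fb, n_atoms, integer(1)), c(12L, 7L, 7L))
})

test_that("fragmentation never breaks ring bonds (oracle check)", {
  mols <- c(fragment_palette()[c("benzamide", "toluene", "furan")],
            list(tetrapeptide_mol()))
  for (mol in mols) {
    rb <- ring_bonds(mol)
    for (k in seq_len(nrow(mol$bonds)))
      expect_equal(rb[k], oracle_is_ring_bond(mol, k))
    rings <- mol_rings(mol)
    for (f in fragment_ligand(mol)) {
      mw <- attr(f, "mw")
      expect_gte(mw, 50); expect_lte(mw, 300)
      # every parent ring sharing >1 atom with the fragment is wholly inside
      # (a single shared atom is an alpha-atom kept across a cut)
      parent <- attr(f, "parent_atoms")
      for (ring in rings) {
        overlap <- sum(ring %in% parent)
        expect_true(overlap <= 1 || overlap == length(ring))
      }
    }
  }
})

test_that("environment cut-out respects the inclusive 4.5 A boundary", {
  frag <- fbmol("C", matrix(c(0, 0, 0), 1), name = "ATM")
  at_45 <- fb_residue("GLY", "A", 1, "CA", "C", matrix(c(4.5, 0, 0), 1))
  beyond <- fb_residue("GLY", "A", 2, "CA", "C", matrix(c(4.5001, 0, 0), 1))
  expect_equal(environment_residues(frag, list(at_45, beyond)), 1L)
  expect_length(environment_residues(frag, list(at_45, beyond), 0), 0)
})

test_that("FRASE extraction matches planted ground truth", {
  tc <- make_toy_complex(fixture_spec(seed = 21))
  frs <- extract_frases(tc$complex)
  expect_length(frs, 1)
  expect_equal(sort(vapply(frs[[1]]$environment, `[[`, integer(1), "seq")),
               sort(vapply(tc$complex$residues[tc$truth$env_idx], `[[`,
                           integer(1), "seq")))
  expect_equal(frs[[1]]$label, "true")

  # far-only spec -> every fragment dropped
  far <- make_toy_complex(fixture_spec(n_env = 0, n_far = 4,
                                       triplet_side = NULL, seed = 5))
  expect_warning(none <- extract_frases(far$complex), "empty environment")
  expect_length(none, 0)
})

test_that("extraction is invariant under rigid motion of the complex", {
  tc <- make_toy_complex(fixture_spec(seed = 31))
  R <- diag(3)[c(2, 3, 1), ] * c(1, 1, 1)  # proper permutation rotation
  shift <- c(11, -7, 3)
  cx2 <- tc$complex
  cx2$ligands[[1]]$xyz <- sweep(cx2$ligands[[1]]$xyz %*% t(R), 2, -shift)
  for (i in seq_along(cx2$residues)) {
    cx2$residues[[i]]$xyz <- sweep(cx2$residues[[i]]$xyz %*% t(R), 2, -shift)
    cx2$residues[[i]]$ca <- as.numeric(R %*% cx2$residues[[i]]$ca) + shift
  }
  f1 <- extract_frases(tc$complex)
  f2 <- extract_frases(cx2)
  expect_equal(length(f1), length(f2))
  expect_equal(vapply(f1[[1]]$environment, `[[`, integer(1), "seq"),
               vapply(f2[[1]]$environment, `[[`, integer(1), "seq"))
})

test_that("the affinity filter keeps only sub-threshold complexes", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,affinity_nM", "cplx1,12", "cplx2,250", "cplx3,99.9"), csv)
  kept <- filter_high_affinity(c("cplx1", "cplx2", "cplx3", "cplx4"), csv)
  expect_equal(kept, c("cplx1", "cplx3"))
})
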