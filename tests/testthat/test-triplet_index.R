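test_that("residue bit strings reproduce the published property table", {
  expect_equal(attr(residue_bits("GLY"), "string"), "00000000000")
  trp <- residue_bits("TRP")
  expect_equal(unname(trp[c("vol1", "vol2", "vol3")]), c(1, 1, 1))
  expect_equal(unname(trp["hbd"]), 1)
  expect_equal(unname(trp["aromatic"]), 1)
  phe <- residue_bits("PHE")
  expect_equal(unname(phe["aromatic"]), 1)
  expect_equal(unname(phe[c("hyd1", "hyd2", "hyd3")]), c(1, 1, 1))
  expect_equal(unname(phe[c("vol1", "vol2", "vol3")]), c(1, 1, 1))
  # charge assignment: basics positive, acids negative
  for (code in c("ARG", "LYS", "HIS"))
    expect_equal(unname(residue_bits(code)["pos"]), 1)
  for (code in c("ASP", "GLU"))
    expect_equal(unname(residue_bits(code)["neg"]), 1)
  # every string is 11 characters
  for (code in template_residues())
    expect_equal(nchar(attr(residue_bits(code), "string")), 11)
  expect_error(residue_bits("MSE"), "untypable")
})

test_that("triplet enumeration applies the inclusive [8,12] edge window", {
  res <- function(i, ca) fb_residue("ALA", "A", i, c("N", "CA"), c("N", "C"),
                                    rbind(ca + c(-1.46, 0, 0), ca))
  eq <- list(res(1, c(0, 0, 0)), res(2, c(10, 0, 0)), res(3, c(5, 8.66, 0)))
  tt <- enumerate_triplets(eq)
  expect_length(tt, 1)
  expect_equal(sort(tt[[1]]$edges), c(9.998980, 9.998980, 10),
               tolerance = 1e-4)

  small <- list(res(1, c(0, 0, 0)), res(2, c(7, 0, 0)), res(3, c(3.5, 6.06, 0)))
  expect_length(enumerate_triplets(small), 0)

  # boundary: exactly 8 and exactly 12 qualify
  b <- list(res(1, c(0, 0, 0)), res(2, c(8, 0, 0)), res(3, c(4, 10.5830, 0)))
  expect_length(enumerate_triplets(b), 1)
})

test_that("triplet enumeration equals the exhaustive oracle on a lattice", {
  set.seed(42)
  residues <- list()
  k <- 0L
  for (ix in 0:2) for (iy in 0:2) {
    k <- k + 1L
    ca <- c(ix * 8.2, iy * 8.2, stats::runif(1, -0.5, 0.5))
    code <- sample(template_residues(), 1)
    residues[[k]] <- fb_residue(code, "A", k, "CA", "C", matrix(ca, 1))
  }
  fast <- enumerate_triplets(residues)
  brute <- brute_force_triplets(residues)
  expect_gt(length(brute), 0)
  expect_equal(length(fast), length(brute))
  expect_setequal(vapply(fast, function(t) paste(t$idx, collapse = "-"),
                         character(1)),
                  vapply(brute, paste, character(1), collapse = "-"))
})

test_that("triplet keys are order-invariant with the right multiplicity", {
  k1 <- triplet_key(c("ALA", "GLY", "TRP"))
  k2 <- triplet_key(c("TRP", "GLY", "ALA"))
  expect_equal(k1$canonical, k2$canonical)
  expect_equal(k1$fps, k2$fps)
  expect_equal(nchar(k1$canonical), 33)

  expect_length(triplet_key(c("GLY", "GLY", "GLY"))$fps, 1)
  expect_length(triplet_key(c("ALA", "PHE", "TRP"))$fps, 6)

  # property: canonical key invariant under all 3! orderings, random draws
  set.seed(7)
  for (rep in 1:25) {
    codes <- sample(template_residues(), 3, replace = TRUE)
    keys <- apply(rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                        c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)), 1,
                  function(p) triplet_key(codes[p])$canonical)
    expect_length(unique(keys), 1)
    expect_lte(length(triplet_key(codes)$fps), 6)
    expect_true(triplet_key(codes)$canonical %in% triplet_key(codes)$fps)
  }
})

test_that("index matching equals brute-force all-pairs comparison", {
  set.seed(13)
  db <- lapply(1:6, function(i) make_toy_complex(
    fixture_spec(seed = 100 + i,
                 fragment_name = sample(names(fragment_palette()), 1)))$truth$frase)
  idx <- build_index(db)

  target <- make_toy_complex(fixture_spec(seed = 200))$complex
  tt <- enumerate_triplets(target$residues)
  fast <- match_target(tt, idx)

  db_trips <- lapply(db, function(fr) enumerate_triplets(fr$environment))
  names(db_trips) <- vapply(db, `[[`, character(1), "id")
  expect_equal(length(fast), oracle_match(tt, db_trips))

  # self-match: a target holding a database environment matches its triplets
  self_cx <- fb_complex("SELF", db[[1]]$environment)
  st <- enumerate_triplets(self_cx$residues)
  sm <- match_target(st, idx)
  expect_gte(length(sm), length(enumerate_triplets(db[[1]]$environment)))

  # an index without all-GLY triplets yields no matches for an all-GLY target
  gly <- lapply(1:4, function(i)
    fb_residue("GLY", "A", i, "CA", "C",
               matrix(c(9 * cos(i), 9 * sin(i), i * 5), 1)))
  gt <- enumerate_triplets(gly)
  has_gly_key <- length(gt) > 0 &&
    any(vapply(gt, function(t) !is.null(idx$map[[triplet_key(t)$canonical]]),
               logical(1)))
  if (!has_gly_key) expect_length(match_target(gt, idx), 0)
})

test_that("index construction streams from SD files and counts triplets", {
  frs <- lapply(1:3, function(i)
    make_toy_complex(fixture_spec(seed = 300 + i))$truth$frase)
  path <- tempfile(fileext = ".sdf")
  write_frase_sdf(frs, path)
  idx_mem <- build_index(frs)
  idx_file <- build_index(path)
  expect_equal(idx_file$n_frases, 3)
  expect_equal(sort(idx_mem$triplet_counts), sort(idx_file$triplet_counts))
  expect_setequal(ls(idx_mem$map), ls(idx_file$map))

  empty <- build_index(list())
  expect_equal(empty$n_frases, 0)
  expect_length(ls(empty$map), 0)
})
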