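test_that("three-point superposition recovers constructed transforms", {
  P <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 8.66, 0))
  id <- superpose_triplet(P, P)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(id$rmsd, 0, tolerance = 1e-10)

  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Q <- sweep(P %*% t(Rz), 2, -c(1, 2, 3))
  tr <- superpose_triplet(P, Q)
  expect_equal(tr$rotation, Rz, tolerance = 1e-9)
  expect_equal(tr$translation, c(1, 2, 3), tolerance = 1e-9)
  expect_lt(tr$rmsd, 1e-9)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)

  expect_error(superpose_triplet(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), P),
               "degenerate")
})

test_that("superposition rmsd equals the grid+refine oracle", {
  set.seed(3)
  for (rep in 1:5) {
    P <- matrix(stats::rnorm(9, sd = 4), 3, 3)
    # guard against near-collinear draws
    if (sqrt(sum(frasebot:::.cross3(P[2, ] - P[1, ], P[3, ] - P[1, ])^2)) < 1)
      next
    Q <- sweep(P %*% t(frasebot:::.rand_rotation()), 2,
               -stats::rnorm(3, sd = 5)) +
      matrix(stats::rnorm(9, sd = 0.3), 3, 3)
    tr <- superpose_triplet(P, Q)
    expect_equal(tr$rmsd, oracle_superpose_rmsd(P, Q), tolerance = 1e-3)
  }
})

test_that("seeding computes clash and burial from the target, from scratch", {
  tc <- make_toy_complex(fixture_spec(seed = 41))
  fr <- tc$truth$frase
  ident <- superpose_triplet(diag(3), diag(3))

  # far placement: no protein atom within the burial radius
  far <- ident; far$translation <- c(50, 0, 0)
  sf_far <- seed_fragment(fr, far, tc$complex)
  expect_equal(sf_far$mean_burial, 0)
  expect_null(cut_target_frase(sf_far, tc$complex))

  # constructed near-contact: one atom exactly 0.5 A from a protein atom
  one_atom <- frase(fbmol("C", matrix(c(0, 0, 0), 1), name = "X"),
                    fr$environment, source = "t", label = "true", id = "x")
  res_atom <- fr$environment[[1]]$xyz[1, ]
  shift <- ident
  shift$translation <- res_atom - c(0.5, 0, 0)
  sf <- seed_fragment(one_atom, shift, tc$complex)
  expect_equal(sf$min_clash_dist, 0.5, tolerance = 1e-9)
})

test_that("self-seeding reproduces the original pose and environment", {
  tc <- make_toy_complex(fixture_spec(seed = 51, n_env = 8))
  fr <- extract_frases(tc$complex)[[1]]
  scr <- screen_target(tc$complex, list(fr))
  expect_gte(length(scr$survivors), 1)
  sf <- scr$survivors[[1]]
  expect_lt(sf$provenance$transform$rmsd, 1e-6)
  expect_lt(max(abs(sf$fragment$xyz - fr$fragment$xyz)), 1e-6)
  # the re-cut target FRASE recovers the same residue set
  expect_setequal(vapply(sf$target_frase$environment, `[[`, integer(1), "seq"),
                  vapply(fr$environment, `[[`, integer(1), "seq"))
  # and passes the geometric filters
  expect_gte(sf$min_clash_dist, 1.0)
  expect_gte(sf$mean_burial, 5.0)
})

test_that("filters apply the documented thresholds inclusively", {
  mk <- function(clash, burial, fitness) structure(
    list(fragment = NULL, provenance = list(frase_id = "f"),
         min_clash_dist = clash, mean_burial = burial, fitness = fitness),
    class = "fb_seeded")
  cfg <- filter_config()
  out <- filter_seeded(list(mk(0.5, 7, 0.9), mk(1.0, 7, 0.9),
                            mk(2, 4.9, 0.9), mk(2, 7, 0.39),
                            mk(2, 7, 0.4)), cfg)
  expect_length(out, 2)              # the two boundary-inclusive passes
  rej <- attr(out, "rejections")
  expect_equal(nrow(rej), 3)
  expect_true(any(grepl("collision", rej$reason)))
  expect_true(any(grepl("not_buried", rej$reason)))
  expect_true(any(grepl("low_fitness", rej$reason)))

  # burial arithmetic: counts (10, 4) over two atoms average to 7 >= 5
  expect_equal(mean(c(10, 4)), 7)
  expect_length(filter_seeded(list(mk(2, mean(c(10, 4)), 0.9)), cfg), 1)
})

test_that("raising the fitness threshold never enlarges the survivor set", {
  set.seed(8)
  sfs <- lapply(1:30, function(i) structure(
    list(provenance = list(frase_id = paste0("f", i)),
         min_clash_dist = stats::runif(1, 0.5, 3),
         mean_burial = stats::runif(1, 2, 9),
         fitness = stats::runif(1)), class = "fb_seeded"))
  prev <- Inf
  for (thr in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    n <- length(filter_seeded(sfs, filter_config(fitness_min = thr)))
    expect_lte(n, prev)
    prev <- n
  }
  # survivors under all filters are a subset of collision-only survivors
  all_f <- filter_seeded(sfs, filter_config(fitness_min = 0.5))
  coll <- Filter(function(s) s$min_clash_dist >= 1, sfs)
  expect_true(all(vapply(all_f, function(s) s$provenance$frase_id,
                         character(1)) %in%
                  vapply(coll, function(s) s$provenance$frase_id,
                         character(1))))
})
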