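test_that("feature perception places typed points where chemistry dictates", {
  # benzene: exactly one aromatic feature at the ring centroid
  fb <- perceive_features(benzene_mol())
  expect_equal(nrow(fb), 1)
  expect_equal(fb$ftype, "Ar")
  expect_equal(unlist(fb[, c("x", "y", "z")], use.names = FALSE), c(0, 0, 0),
               tolerance = 1e-9)

  # phenol: one Ar + one HBD + one HBA (the hydroxyl is both)
  fp <- perceive_features(fragment_palette()$phenol)
  tab <- table(fp$ftype)
  expect_equal(as.vector(tab[c("Ar", "HBA", "HBD")]), c(1L, 1L, 1L))

  # benzoate: a Neg feature at the carboxylate oxygen centroid
  fz <- perceive_features(fragment_palette()$benzoate)
  expect_equal(sum(fz$ftype == "Neg"), 1)
  bza <- fragment_palette()$benzoate
  o_centroid <- colMeans(bza$xyz[bza$element == "O", ])
  neg <- unlist(fz[fz$ftype == "Neg", c("x", "y", "z")], use.names = FALSE)
  expect_equal(neg, unname(o_centroid), tolerance = 1e-9)

  # cyclohexane: a single hydrophobic centroid, no polar features
  fc <- perceive_features(fragment_palette()$cyclohexane)
  expect_equal(fc$ftype, "Hyd")
})

test_that("clustering partitions features type-purely under the bound", {
  # five near-coincident same-type features form one cluster
  near <- data.frame(ftype = "HBA",
                     x = c(0, 0.3, -0.2, 0.5, 0.1),
                     y = c(0, 0.2, 0.4, -0.3, 0), z = 0,
                     source = "a", stringsAsFactors = FALSE)
  cl <- cluster_features(near)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 5)

  # two far features split into singletons
  far <- data.frame(ftype = "Ar", x = c(0, 10), y = 0, z = 0, source = "a",
                    stringsAsFactors = FALSE)
  expect_length(cluster_features(far), 2)

  # random fixture: partition property, purity, diameter bound
  set.seed(31)
  feats <- data.frame(
    ftype = sample(c("HBA", "HBD", "Ar", "Hyd"), 60, replace = TRUE),
    x = stats::rnorm(60, sd = 6), y = stats::rnorm(60, sd = 6),
    z = stats::rnorm(60, sd = 6), source = "r", stringsAsFactors = FALSE)
  cl <- cluster_features(feats, max_diameter = 3)
  expect_equal(sum(vapply(cl, `[[`, numeric(1), "size")), nrow(feats))
  members <- sort(unlist(lapply(cl, `[[`, "members")))
  expect_equal(members, seq_len(nrow(feats)))
  for (c_ in cl) {
    expect_true(all(feats$ftype[c_$members] == c_$ftype))
    xyz <- as.matrix(feats[c_$members, c("x", "y", "z")])
    expect_lte(max(c(0, stats::dist(xyz))), 3)
    expect_equal(c_$diameter, max(c(0, stats::dist(xyz))), tolerance = 1e-9)
  }
})

test_that("cluster ranking is a deterministic total order", {
  mk <- function(id, size, density) list(id = id, ftype = "HBA",
                                         members = seq_len(size),
                                         centroid = c(0, 0, 0), size = size,
                                         diameter = 1, density = density)
  cl <- list(mk(1, 7, 2.5), mk(2, 10, 1.0), mk(3, 7, 3.1), mk(4, 2, 9.9))
  r <- rank_clusters(cl)
  expect_equal(vapply(r, `[[`, numeric(1), "id"), c(2, 3, 1, 4))
  expect_equal(vapply(r, `[[`, numeric(1), "rank"), 1:4)
  # all-singleton ties resolve by density then id
  s <- list(mk(1, 1, 0.5), mk(2, 1, 0.9), mk(3, 1, 0.5))
  expect_equal(vapply(rank_clusters(s), `[[`, numeric(1), "id"), c(2, 1, 3))
})

test_that("query assembly records types, tolerances and provenance", {
  mk <- function(id, ftype) list(id = id, ftype = ftype, members = 1:3,
                                 centroid = c(id, 0, 0), size = 3,
                                 diameter = 1, density = 2, rank = id)
  cl <- list(mk(1, "HBA"), mk(2, "HBA"), mk(3, "Ar"), mk(4, "Ar"))
  q <- build_query(cl, picks = 1:4, tolerance = 1.0)
  expect_equal(sort(table(q$features$ftype), decreasing = TRUE),
               sort(table(c("HBA", "HBA", "Ar", "Ar")), decreasing = TRUE))
  expect_true(all(q$features$tolerance == 1.0))
  expect_error(build_query(cl, picks = integer(0)), "empty")

  single <- build_query(cl, picks = 2)
  expect_equal(nrow(single$features), 1)

  # JSON round-trip preserves positions to 1e-3
  path <- tempfile(fileext = ".json")
  write_query(q, path)
  back <- read_query(path)
  expect_equal(back$features$x, q$features$x, tolerance = 1e-3)
  expect_equal(back$features$ftype, q$features$ftype)

  # table export is one line per feature
  tpath <- tempfile(fileext = ".pml")
  write_query(q, tpath)
  expect_length(grep("^#", readLines(tpath), invert = TRUE), 4)
})
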