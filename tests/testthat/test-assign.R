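test_that("hamming distance counts mismatches over co-typed loci", {
  # cluster (0,1,2,NA,1) vs patient (0,2,2,1,0): co-typed 4, mismatch 2
  cl <- harmonize_loci(list(mk_profile("c0", 1:5, c(0, 1, 2, NA, 1)),
                            mk_profile("c1", 1:5, c(0, 2, 2, 1, 0))),
                       mode = "union")
  dm <- hamming_matrix(
    profile_matrix(cl$loci, cl$codes[, "c0", drop = FALSE]),
    profile_matrix(cl$loci, cl$codes[, "c1", drop = FALSE]),
    min_support = 1)
  expect_equal(dm$dist["c0", "c1"], 0.5)
  expect_equal(dm$support["c0", "c1"], 4L)
})

test_that("hamming distance has identity, complement and symmetry properties", {
  set.seed(3)
  codes <- matrix(sample(c(0:2, NA), 120, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), 60, 2,
                  dimnames = list(NULL, c("x", "y")))
  loci <- variant_keys(rep("1", 60), 1:60, rep("A", 60), rep("G", 60))
  pm <- profile_matrix(loci, codes)
  x <- profile_matrix(loci, codes[, "x", drop = FALSE])
  y <- profile_matrix(loci, codes[, "y", drop = FALSE])
  self <- hamming_matrix(x, x, min_support = 1)
  expect_equal(unname(self$dist[1, 1]), 0)
  expect_equal(unname(self$support[1, 1]), sum(!is.na(codes[, "x"])))
  xy <- hamming_matrix(x, y, min_support = 1)
  yx <- hamming_matrix(y, x, min_support = 1)
  expect_equal(xy$dist["x", "y"], yx$dist["y", "x"])
  # locus reordering does not change the distance
  perm <- sample(60)
  x2 <- profile_matrix(loci[perm, ], codes[perm, "x", drop = FALSE])
  expect_equal(hamming_matrix(x2, y, min_support = 1)$dist["x", "y"],
               xy$dist["x", "y"])
  # complement profile differs everywhere it is co-typed
  comp <- codes[, "x", drop = FALSE] + 1L
  comp[comp == 3L] <- 0L
  colnames(comp) <- "z"
  z <- profile_matrix(loci, comp)
  expect_equal(hamming_matrix(x, z, min_support = 1)$dist["x", "z"], 1)
})

test_that("support thresholds flag invalid pairs and dead clusters error", {
  loci <- variant_keys(rep("1", 10), 1:10, rep("A", 10), rep("G", 10))
  cl_codes <- matrix(c(rep(1L, 10), c(1L, rep(NA, 9))), 10, 2,
                     dimnames = list(NULL, c("c0", "c1")))
  bk_codes <- matrix(rep(c(1L, 0L), each = 10), 10, 2,
                     dimnames = list(NULL, c("p1", "p2")))
  dm <- hamming_matrix(profile_matrix(loci, cl_codes),
                       profile_matrix(loci, bk_codes), min_support = 1)
  expect_equal(unname(dm$support["c1", ]), c(1L, 1L))
  expect_equal(unname(dm$dist["c1", ]), c(0, 1))
  # with min_support 2 cluster c1 is invalid against every patient
  expect_error(
    hamming_matrix(profile_matrix(loci, cl_codes),
                   profile_matrix(loci, bk_codes), min_support = 2),
    "c1")
  disjoint_bulk <- profile_matrix(
    variant_keys(rep("1", 10), 11:20, rep("A", 10), rep("G", 10)), bk_codes)
  expect_error(hamming_matrix(profile_matrix(loci, cl_codes), disjoint_bulk),
               "no loci")
})

test_that("Kuhn-Munkres solves the documented examples", {
  # diagonal-zero square matrix: identity mapping at zero cost
  d <- matrix(1, 3, 3, dimnames = list(paste0("c", 0:2), paste0("p", 1:3)))
  diag(d) <- 0
  km <- kuhn_munkres(d)
  expect_equal(unname(km$mapping), c("p1", "p2", "p3"))
  expect_equal(km$total_cost, 0)
  # 3x3 case verified by brute force over all 6 permutations
  d <- matrix(c(0.4, 0.1, 0.9,
                0.2, 0.8, 0.3,
                0.7, 0.6, 0.1), 3, 3, byrow = TRUE,
              dimnames = list(paste0("c", 0:2), paste0("p", 0:2)))
  km <- kuhn_munkres(d)
  expect_equal(unname(km$mapping), c("p1", "p0", "p2"))
  expect_equal(km$total_cost, 0.4)
  expect_equal(km$total_cost, brute_min_assignment(d))
  # margins are second-best minus chosen, reported as-is
  expect_equal(unname(km$margin), c(0.4 - 0.1, 0.3 - 0.2, 0.6 - 0.1))
  # rectangular: 2 clusters x 3 patients leaves one patient unmatched
  d <- matrix(c(0, 1, 1,
                1, 1, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("c0", "c1"), c("p0", "p1", "p2")))
  km <- kuhn_munkres(d)
  expect_equal(unname(km$mapping), c("p0", "p2"))
  expect_equal(km$unmatched_patients, "p1")
  expect_error(kuhn_munkres(t(d)), "pool")
})

test_that("Kuhn-Munkres equals brute force on random rectangular matrices", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(2:5, 1)
    m <- sample(n:6, 1)
    cost <- matrix(round(stats::runif(n * m), 3), n, m)
    km <- kuhn_munkres(cost)
    expect_equal(km$total_cost, brute_min_assignment(cost), tolerance = 1e-12)
    expect_false(anyDuplicated(km$mapping) > 0)
  }
  # determinism: identical input, identical output
  cost <- matrix(stats::runif(12), 3, 4)
  expect_identical(kuhn_munkres(cost), kuhn_munkres(cost))
})

test_that("invalid pairs enter the assignment only via the penalty", {
  d <- structure(list(
    dist = matrix(c(0.1, NA, NA, 0.2), 2, 2,
                  dimnames = list(c("c0", "c1"), c("pA", "pB"))),
    support = matrix(c(100L, 10L, 10L, 100L), 2, 2),
    clusters = c("c0", "c1"), patients = c("pA", "pB"),
    min_support = 50L, n_loci = 100L), class = "distance_matrix")
  km <- kuhn_munkres(d)
  expect_equal(unname(km$mapping), c("pA", "pB"))
  expect_false(any(km$penalized))
  # force a penalized choice: both valid cells on one patient
  d$dist <- matrix(c(0.1, 0.2, NA, NA), 2, 2,
                   dimnames = dimnames(d$dist))
  km <- kuhn_munkres(d)
  expect_true(any(km$penalized))
  expect_equal(km$total_cost, 0.1 + 2)
})

test_that("cell label propagation preserves rows and statuses", {
  cells <- data.frame(
    barcode = sprintf("BC%02d-1", 1:10),
    status = c(rep("singlet", 7), "doublet", "doublet", "unassigned"),
    cluster = c(rep("0", 5), "1", "1", NA, NA, NA),
    stringsAsFactors = FALSE
  )
  mapping <- c(`0` = "patientB", `1` = "patientA")
  out <- assign_cells(mapping, cells)
  expect_equal(nrow(out), 10L)
  expect_equal(sum(out$patient %in% c("patientA", "patientB")), 7L)
  expect_equal(out$patient[1:5], rep("patientB", 5))
  expect_equal(out$patient[8:9], c("doublet", "doublet"))
  expect_equal(out$patient[10], "unassigned")
  expect_error(assign_cells(c(`5` = "patientX"), cells), "absent")
})

test_that("cluster-to-group assignment maximizes overlap with tie warning", {
  cells <- data.frame(
    barcode = sprintf("B%03d", 1:185),
    status = "singlet",
    cluster = c(rep("0", 100), rep("1", 85)),
    stringsAsFactors = FALSE
  )
  reference <- setNames(
    c(rep("CD4 T", 90), rep("B", 10), rep("B", 80), rep("CD4 T", 5)),
    cells$barcode)
  mapping <- assign_to_groups(cells, reference)
  expect_equal(unname(mapping[c("0", "1")]), c("CD4 T", "B"))
  expect_equal(sum(attr(mapping, "overlap")), 185L)
  # perfectly nested: identity-like mapping, overlap = singlet count
  ref2 <- setNames(ifelse(cells$cluster == "0", "g0", "g1"), cells$barcode)
  m2 <- assign_to_groups(cells, ref2)
  expect_equal(unname(m2[c("0", "1")]), c("g0", "g1"))
  # tie: two clusters with equal overlap against two groups
  cells3 <- data.frame(barcode = sprintf("C%02d", 1:4), status = "singlet",
                       cluster = c("0", "0", "1", "1"),
                       stringsAsFactors = FALSE)
  ref3 <- setNames(c("g1", "g2", "g1", "g2"), cells3$barcode)
  expect_warning(m3 <- assign_to_groups(cells3, ref3), "tie")
  expect_equal(anyDuplicated(m3), 0L)
  expect_error(assign_to_groups(cells3, c(ZZZ = "g1")), "no singlet")
})

test_that("permuting bulk sample order permutes the mapping consistently", {
  truth <- simulate_cohort(sim_config(n_patients = 4, n_loci = 800,
                                      n_cells = 10, seed = 21))
  dm1 <- hamming_matrix(truth$clusters, truth$bulk)
  km1 <- kuhn_munkres(dm1)
  perm <- c(3, 1, 4, 2)
  bulk2 <- profile_matrix(truth$bulk$loci,
                          truth$bulk$codes[, perm, drop = FALSE])
  km2 <- kuhn_munkres(hamming_matrix(truth$clusters, bulk2))
  expect_equal(km1$mapping, km2$mapping[names(km1$mapping)])
})
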