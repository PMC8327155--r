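test_that("tree slicing assigns leaves to the branch occupied at the slice age", {
  tr <- tree4()   # internal ages 1 ({A,B}) and 2 ({C,D}), root 3
  expect_equal(slice_tree(tr, 0)$n_clades, 4)
  expect_equal(slice_tree(tr, 3)$n_clades, 1)
  expect_equal(slice_tree(tr, 10)$n_clades, 1)
  s <- slice_tree(tr, 1.5)
  expect_equal(s$n_clades, 3)
  expect_equal(s$clade[["A"]], s$clade[["B"]])
  expect_false(s$clade[["C"]] == s$clade[["D"]])
  expect_error(slice_tree(tr, -1), "non-negative")
})

test_that("clade count never increases with age and collapse conserves totals", {
  tr <- simulate_calibrated_tree(40, 800, seed = 13)
  set.seed(14)
  tab <- abundance_table(matrix(rpois(6 * 40, 2), 6, 40,
    dimnames = list(paste0("h", 1:6), tr$tip.label)))
  ages <- seq(0, 800, by = 100)
  counts <- sapply(ages, function(a) slice_tree(tr, a)$n_clades)
  expect_true(all(diff(counts) <= 0))
  for (a in ages) {
    collapsed <- collapse_table(tab, slice_tree(tr, a))
    expect_equal(unname(rowSums(collapsed)), unname(rowSums(tab)))
  }
})

test_that("collapse handles identity, single-clade and hand-worked slices", {
  tr <- tree4()
  tab <- tab4()
  id <- collapse_table(tab, slice_tree(tr, 0))
  expect_equal(unname(unclass(id)), unname(unclass(tab)))
  one <- collapse_table(tab, slice_tree(tr, 3))
  expect_equal(unname(as.vector(one)), unname(rowSums(tab)))
  three <- collapse_table(tab, slice_tree(tr, 1.5))
  expect_setequal(unclass(three)["h1", ], c(5, 5, 0))   # A+B, C, D
  missing_taxon <- abundance_table(matrix(1, 1, 1, dimnames = list("h", "Z")))
  expect_error(collapse_table(missing_taxon, slice_tree(tr, 0)), "Z")
})

test_that("Sorensen handles identical, disjoint and partially shared sets", {
  hostA <- c(t1 = 1, t2 = 3, t3 = 2, t4 = 0)
  tabAA <- abundance_table(rbind(x = hostA, y = hostA))
  expect_equal(sorensen_matrix(tabAA)["x", "y"], 0)
  tabD <- abundance_table(rbind(x = c(t1 = 1, t2 = 1, t3 = 0, t4 = 0),
                                y = c(t1 = 0, t2 = 0, t3 = 2, t4 = 5)))
  expect_equal(sorensen_matrix(tabD)["x", "y"], 1)
  tabS <- abundance_table(rbind(x = c(t1 = 1, t2 = 1, t3 = 1, t4 = 0),
                                y = c(t1 = 0, t2 = 2, t3 = 4, t4 = 1)))
  expect_equal(sorensen_matrix(tabS)["x", "y"], 1 / 3)   # a=2, b=1, c=1
  expect_error(sorensen_matrix(abundance_table(
    matrix(0, 2, 2, dimnames = list(c("a", "b"), c("t", "u"))))), "all-zero")
})

test_that("Sorensen agrees with its set-operation oracle and vegan on random tables", {
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rbinom(8 * 15, 3, 0.4), 8, 15,
                dimnames = list(paste0("h", 1:8), paste0("t", 1:15)))
    m[rowSums(m) == 0, 1] <- 1
    tab <- abundance_table(m)
    got <- sorensen_matrix(tab)
    expect_equal(unclass(got)[1:8, 1:8], sorensen_oracle(tab), tolerance = 1e-9)
    veg <- as.matrix(vegan::vegdist(m, "bray", binary = TRUE))
    expect_equal(max(abs(got - veg[rownames(got), colnames(got)])), 0,
                 tolerance = 1e-9)
  }
})

test_that("unweighted UniFrac matches brute-force branch enumeration", {
  skip_if_not_installed("phangorn")
  # hand case: two hosts on one cherry, no shared branches
  cherry <- read_calibrated_tree("(A:1,B:1);")
  tabC <- abundance_table(rbind(x = c(A = 1, B = 0), y = c(A = 0, B = 1)))
  expect_equal(unweighted_unifrac(tabC, cherry)["x", "y"], 1)
  tabI <- abundance_table(rbind(x = c(A = 1, B = 1), y = c(A = 2, B = 3)))
  expect_equal(unweighted_unifrac(tabI, cherry)["x", "y"], 0)

  tr4 <- tree4()
  tab <- abundance_table(rbind(h1 = c(A = 1, B = 1, C = 0, D = 0),
                               h2 = c(A = 1, B = 0, C = 1, D = 0)))
  expect_equal(unclass(unweighted_unifrac(tab, tr4))[1:2, 1:2],
               unifrac_oracle(tab, tr4), tolerance = 1e-9)

  for (s in 1:5) {
    n <- sample(4:8, 1)
    tr <- simulate_calibrated_tree(n, 100, seed = 100 + s)
    set.seed(200 + s)
    m <- matrix(rbinom(4 * n, 1, 0.5), 4, n,
                dimnames = list(paste0("h", 1:4), tr$tip.label))
    m[rowSums(m) == 0, 1] <- 1
    tab <- abundance_table(m)
    expect_equal(unclass(unweighted_unifrac(tab, tr))[1:4, 1:4],
                 unifrac_oracle(tab, tr), tolerance = 1e-9)
  }
  expect_error(unweighted_unifrac(abundance_table(
    rbind(h1 = c(A = 0, B = 0), h2 = c(A = 1, B = 1))), cherry), "no taxa")
})

test_that("on an equal-branch star, Sorensen is the monotone UniFrac transform u/(2-u)", {
  # with unit branches the star UniFrac is (b+c)/(a+b+c) and Sorensen is
  # (b+c)/(2a+b+c), so so = uf / (2 - uf) exactly - a cross-check tying the
  # two dissimilarities together on shared presence data
  star <- read_calibrated_tree("(A:1,B:1,C:1,D:1,E:1);")
  set.seed(9)
  m <- matrix(rbinom(4 * 5, 1, 0.6), 4, 5,
              dimnames = list(paste0("h", 1:4), star$tip.label))
  m[rowSums(m) == 0, 1] <- 1
  tab <- abundance_table(m)
  uf <- unweighted_unifrac(tab, star)
  so <- sorensen_matrix(tab)
  expect_equal(unclass(so)[1:4, 1:4], uf / (2 - uf), tolerance = 1e-12)
})

test_that("Mantel statistic is exact under linear maps and matches vegan", {
  d1 <- random_host_dist(10, seed = 41)
  mt <- mantel_test(d1, 2 * d1, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_equal(mt$R2, 1, tolerance = 1e-12)
  down <- max(d1) - d1; diag(down) <- 0
  expect_equal(mantel_test(d1, down, n_perm = 99, seed = 1)$r, -1,
               tolerance = 1e-12)
  d2 <- random_host_dist(10, seed = 42)
  expect_equal(mantel_test(d1, d2, n_perm = 9, seed = 1)$r,
               unname(vegan::mantel(as.dist(d1), as.dist(d2),
                                    permutations = 9)$statistic),
               tolerance = 1e-12)
  const <- matrix(1, 10, 10, dimnames = dimnames(d1)); diag(const) <- 0
  expect_error(mantel_test(d1, const, 99, 1), "constant")
  # permutation p respects its floor and determinism
  mt2 <- mantel_test(d1, d2, n_perm = 199, seed = 5)
  expect_gte(mt2$p, 1 / 200)
  expect_identical(mt2, mantel_test(d1, d2, n_perm = 199, seed = 5))
})

test_that("envelopes are ordered, use min/max for few shuffles and quantiles for many", {
  d1 <- random_host_dist(8, seed = 51)
  d2 <- random_host_dist(8, seed = 52)
  env10 <- envelope_null(d1, d2, n_shuffles = 10, seed = 3)
  expect_lte(env10["lower"], env10["upper"])
  # reproduce the 10-shuffle band by hand: min/max of the shuffled R2
  set.seed(3)
  r2 <- replicate(10, {
    p <- sample.int(8)
    cor(d1[upper.tri(d1)], d2[p, p][upper.tri(d2)])^2
  })
  expect_equal(unname(env10), unname(range(r2)), tolerance = 1e-12)
  env1k <- envelope_null(d1, d2, n_shuffles = 1000, seed = 3)
  expect_lte(env1k["lower"], env1k["upper"])
  expect_error(envelope_null(d1, d2, n_shuffles = 1, seed = 1), "n_shuffles")
})

test_that("BDTT recovers the planted scale disparity on one scenario", {
  sc <- planted_scenario(3)
  prof <- bdtt_profile(sc$tree, sc$comm$table, sc$factors,
                       ages = c(0, 100, 250, 600, 750, 900),
                       n_perm = 199, n_shuffles = 200, seed = 4)$profile
  young_p <- prof[prof$factor == "phylogeny" & prof$age <= 250, ]
  old_e <- prof[prof$factor == "ecology" & prof$age >= 600, ]
  expect_true(any(young_p$R2 > young_p$env_hi, na.rm = TRUE))
  expect_true(any(old_e$R2 > old_e$env_hi, na.rm = TRUE))
  expect_true(all(prof$R2[!is.na(prof$R2)] == prof$r[!is.na(prof$r)]^2))
  expect_true(all(prof$p > 0 & prof$p <= 1, na.rm = TRUE))
})

test_that("leaf-slice Sorensen is congruent with UniFrac ordering", {
  sc <- planted_scenario(5, n_taxa = 64)
  sor <- sorensen_matrix(sc$comm$table)
  uf <- unweighted_unifrac(sc$comm$table, sc$tree)
  expect_lte(mantel_test(sor, uf, n_perm = 999, seed = 6)$p, 0.05)
})

test_that("leaf shuffling preserves age-0 correlations and degrades deep ones", {
  sc <- planted_scenario(11)
  ages <- c(0, 700)
  obs <- bdtt_profile(sc$tree, sc$comm$table, sc$factors, ages = ages,
                      n_perm = 199, n_shuffles = 50, seed = 12)$profile
  nul <- leaf_shuffle_null(sc$tree, sc$comm$table, sc$factors, ages = ages,
                           n_perm = 199, n_shuffles = 50, seed = 12)$profile
  expect_equal(nul$R2[nul$age == 0], obs$R2[obs$age == 0], tolerance = 1e-12)
  # the planted deep ecology signal must not survive the shuffle
  deep_obs <- obs$R2[obs$age == 700 & obs$factor == "ecology"]
  deep_nul <- nul$R2[nul$age == 700 & nul$factor == "ecology"]
  expect_lt(deep_nul, deep_obs)
})

test_that("per-lineage association flags a perfectly group-restricted clade", {
  meta <- canid_meta()
  eco <- ecology_distance_matrix(meta)
  tr <- simulate_calibrated_tree(12, 100, seed = 61)
  set.seed(62)
  m <- matrix(rbinom(10 * 12, 1, 0.5), 10, 12,
              dimnames = list(meta$host, tr$tip.label))
  m[, 1] <- as.numeric(meta$group == "wolf")   # wolf-only lineage
  m[, 2] <- 1                                  # constant lineage: skipped
  tab <- abundance_table(m)
  hits <- lineage_association(tr, tab, list(ecology = eco), ages = 0,
                              n_perm = 999, fdr_alpha = 0.1, seed = 63)
  wolf_row <- hits[grepl("_c1$", hits$clade), ]
  # with 10 hosts a random permutation occasionally re-creates the wolf
  # partition (probability 4!6!/10! per draw), so the attainable p floor
  # sits just above 1/(n_perm + 1)
  expect_lte(wolf_row$p, 10 / 1000)
  expect_true(wolf_row$hit)
  expect_true(all(hits$q >= hits$p))
  expect_true(any(grepl("_c2", attr(hits, "skipped"))))
})

test_that("Ward/Spearman clustering recovers planted lineage blocks", {
  hosts <- paste0("h", 1:8)
  set.seed(71)
  wolfish <- matrix(rep(c(5, 4, 6, 5, 0, 1, 0, 0), 4), 4, 8, byrow = TRUE) +
    matrix(runif(32, 0, 0.4), 4, 8)
  dogish <- matrix(rep(c(0, 1, 0, 0, 6, 5, 4, 6), 4), 4, 8, byrow = TRUE) +
    matrix(runif(32, 0, 0.4), 4, 8)
  prof <- rbind(wolfish, dogish)
  dimnames(prof) <- list(paste0("lin", 1:8), hosts)
  res <- ward_spearman_clustering(prof, k = 2)
  expect_equal(length(unique(res$clusters[1:4])), 1)
  expect_equal(length(unique(res$clusters[5:8])), 1)
  expect_false(res$clusters[1] == res$clusters[5])

  # identical profiles merge at height 0; anti-correlated ones sit at 2
  two <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  colnames(two) <- paste0("h", 1:4)
  res2 <- ward_spearman_clustering(two, k = 2)
  expect_equal(min(res2$tree$height), 0, tolerance = 1e-12)
  d <- 1 - cor(t(two), method = "spearman")
  expect_equal(d["a", "c"], 2, tolerance = 1e-12)
  expect_warning(
    ward_spearman_clustering(rbind(two, flat = c(1, 1, 1, 1)), k = 2),
    "constant")
})
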