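mk_reads <- function(codes_by_pos, edit = NULL) {
  # codes_by_pos: list of 10 character vectors (recycled), one per position
  n <- max(lengths(codes_by_pos))
  out <- data.frame(read_id = sprintf("r%d", seq_len(n)), length = 50,
                    strand = "+", stringsAsFactors = FALSE)
  for (i in 1:10) out[[paste0("pos", i)]] <- rep(codes_by_pos[[i]], length.out = n)
  out$edit_distance <- if (is.null(edit)) rep(0L, n) else edit
  out
}

test_that("damage profile is the per-position C->T fraction over C sites", {
  # 100 reads, 30 with C->T at position 1, all have reference C there
  codes <- c(rep("CT", 30), rep("CC", 70))
  reads <- mk_reads(c(list(codes), rep(list("AA"), 9)))
  prof <- fit_damage_profile(reads)
  expect_equal(prof$rate[1], 0.30)
  expect_equal(prof$c_sites[1], 100)
  expect_true(all(is.na(prof$rate[2:10])))   # no C sites elsewhere

  all_match <- mk_reads(rep(list("CC"), 10))
  expect_equal(fit_damage_profile(all_match)$rate, rep(0, 10))
  expect_error(fit_damage_profile(all_match[0, ]), "no reads")
})

test_that("degradation score is the closed-form log-likelihood ratio", {
  prof <- structure(list(rate = c(0.3, rep(NA, 9)),
                         c_sites = c(100, rep(0, 9)),
                         ct = c(30, rep(0, 9))), class = "damage_profile")
  # single C->T at position 1: log(0.3 / 0.01)
  r_ct <- mk_reads(c(list("CT"), rep(list("AA"), 9)), edit = 1L)
  expect_equal(degradation_score(r_ct, prof, baseline = 0.01),
               log(0.3 / 0.01), tolerance = 1e-12)
  expect_equal(log(0.3 / 0.01), 3.401197, tolerance = 1e-6)

  # no C sites at all: models identical, score 0
  r_none <- mk_reads(rep(list("AA"), 10))
  expect_equal(degradation_score(r_none, prof, baseline = 0.01), 0)

  # profile equal to baseline everywhere: score 0 for any read
  flat <- structure(list(rate = rep(0.01, 10), c_sites = rep(10, 10),
                         ct = rep(0, 10)), class = "damage_profile")
  r_any <- mk_reads(c(list("CT"), list("CC"), rep(list("GA"), 8)), edit = 9L)
  expect_equal(degradation_score(r_any, flat, baseline = 0.01), 0,
               tolerance = 1e-12)

  expect_error(degradation_score(r_ct, prof, baseline = 1.2), "baseline")
})

test_that("degradation score is additive over positions and antisymmetric under model swap", {
  prof <- structure(list(rate = c(0.3, 0.2, rep(NA, 8)),
                         c_sites = c(10, 10, rep(0, 8)),
                         ct = c(3, 2, rep(0, 8))), class = "damage_profile")
  both <- mk_reads(c(list("CT"), list("CT"), rep(list("AA"), 8)), edit = 2L)
  only1 <- mk_reads(c(list("CT"), rep(list("AA"), 9)), edit = 1L)
  only2 <- mk_reads(c(list("AA"), list("CT"), rep(list("AA"), 8)), edit = 1L)
  expect_equal(degradation_score(both, prof, 0.01),
               degradation_score(only1, prof, 0.01) +
                 degradation_score(only2, prof, 0.01), tolerance = 1e-12)
  # swapping damage model and null flips the sign: score under rates b
  # against baseline r equals -(score under r against baseline b) for a
  # single-position read
  swapped <- structure(list(rate = c(0.01, rep(NA, 9)), c_sites = c(10, rep(0, 9)),
                            ct = c(0, rep(0, 9))), class = "damage_profile")
  expect_equal(degradation_score(only1, swapped, baseline = 0.3),
               -degradation_score(only1, prof, baseline = 0.01),
               tolerance = 1e-12)
})

test_that("negative difference proportion matches hand sums and its oracle", {
  expect_equal(negative_difference_proportion(c(10, 5, 2, 1)), 1)
  expect_equal(negative_difference_proportion(c(1, 2, 3)), 0)
  expect_equal(negative_difference_proportion(c(5, 7, 3, 4)), 4 / 7)
  flat <- negative_difference_proportion(c(3, 3, 3))
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "flat"))
  expect_error(negative_difference_proportion(5), "two")
  expect_error(negative_difference_proportion(c(-1, 2)), "negative")

  set.seed(17)
  for (i in 1:50) {
    h <- rpois(sample(2:12, 1), 5)
    v <- as.numeric(negative_difference_proportion(h))
    expect_equal(v, ndp_oracle(h), tolerance = 1e-12)
    expect_gte(v, 0); expect_lte(v, 1)
    dec <- all(diff(h) <= 0) && any(diff(h) < 0)
    inc <- all(diff(h) >= 0) && any(diff(h) > 0)
    if (dec) expect_equal(v, 1)
    if (inc) expect_equal(v, 0)
  }
})

test_that("coverage statistics are direct arithmetic", {
  cs <- coverage_stats(rep(1, 100), 1000)
  expect_equal(cs$depth, 0.1)
  expect_equal(cs$breadth_pct, 10)
  expect_equal(coverage_stats(integer(0), 500), list(depth = 0, breadth_pct = 0))
  cs2 <- coverage_stats(rep(2, 800), 800)
  expect_equal(cs2$depth, 2)
  expect_equal(cs2$breadth_pct, 100)
  expect_error(coverage_stats(1:5, 0), "positive")
  expect_error(coverage_stats(1:5, 3), "covered positions")
})

test_that("screening applies the published thresholds with reasons on failure", {
  # reported screening rows for an authenticated gut bacterium and a
  # dietary eukaryote
  bif <- taxon_summary("Bifidobacterium adolescentis", 790, 177, 0.02, 1.9, 10.1, 1)
  expect_true(screen_taxon(bif, bacterial_rules())$pass)
  ovis <- taxon_summary("Ovis aries", 214, 6, 0.75, 59, 11.7, 1)
  expect_true(screen_taxon(ovis, dietary_rules())$pass)
  expect_false(screen_taxon(ovis, bacterial_rules())$pass)

  low <- taxon_summary("x", 400, 177, 0.02, 1.9, 10.1, 1)
  res <- screen_taxon(low, bacterial_rules())
  expect_false(res$pass)
  expect_identical(res$reasons, "reads")

  # boundary: exactly 50 score>1 reads passes (inclusive bound), 49 fails
  expect_true(screen_taxon(taxon_summary("y", 600, 50, 0.1, 1, 10, 1))$pass)
  expect_false(screen_taxon(taxon_summary("y", 600, 49, 0.1, 1, 10, 1))$pass)

  expect_error(screen_taxon(list(reads = 600, ndp = 1), bacterial_rules()),
               "lacks field")
})

test_that("the damage-supporting read fraction rises with the deamination amplitude", {
  frac <- sapply(c(0, 0.1, 0.3), function(p0) {
    rd <- simulate_reads(damage_sim_spec(n_reads = 8000, p0 = p0, seed = 77))
    prof <- fit_damage_profile(rd)
    mean(degradation_score(rd, prof, baseline = 0.01) > 1)
  })
  expect_true(all(diff(frac) > 0))
})

test_that("read records survive a TSV round-trip and inconsistent rows are rejected", {
  rd <- simulate_reads(damage_sim_spec(n_reads = 50, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_read_records(rd, path)
  back <- read_read_records(path)
  expect_equal(back$edit_distance, rd$edit_distance)
  expect_equal(back$pos1, rd$pos1)
  bad <- rd; bad$edit_distance <- 0L; bad$pos1 <- "CT"
  write_read_records(bad, path)
  expect_error(read_read_records(path), "edit distance")
})
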