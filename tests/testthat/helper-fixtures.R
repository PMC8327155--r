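# Shared fixture builders: tiny trees and tables with hand-checkable
# structure, plus brute-force oracles kept independent of the package's
# own computation paths.

tree4 <- function() read_calibrated_tree("((A:1,B:1):2,(C:2,D:2):1);")

tab4 <- function(h1 = c(A = 2, B = 3, C = 5, D = 0),
                 h2 = c(A = 1, B = 0, C = 1, D = 1)) {
  abundance_table(rbind(h1 = h1, h2 = h2))
}

canid_meta <- function(n_wolf = 4, n_dog = 5, n_ancient = 1) {
  host_meta(data.frame(
    host = c(sprintf("wolf%d", seq_len(n_wolf)),
             sprintf("dog%d", seq_len(n_dog)),
             sprintf("ancient%d", seq_len(n_ancient))),
    group = rep(c("wolf", "dog", "ancient"), c(n_wolf, n_dog, n_ancient)),
    stringsAsFactors = FALSE))
}

random_host_dist <- function(n, seed, dim = 2) {
  set.seed(seed)
  x <- matrix(runif(n * dim), n, dim)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("h", seq_len(n)), paste0("h", seq_len(n)))
  d
}

# Sorensen by explicit set operations, one pair at a time
sorensen_oracle <- function(table) {
  pa <- unclass(table) > 0
  n <- nrow(pa)
  d <- matrix(0, n, n, dimnames = list(rownames(pa), rownames(pa)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    si <- colnames(pa)[pa[i, ]]
    sj <- colnames(pa)[pa[j, ]]
    a <- length(intersect(si, sj))
    b <- length(setdiff(si, sj))
    cc <- length(setdiff(sj, si))
    d[i, j] <- if (2 * a + b + cc == 0) 0 else 1 - 2 * a / (2 * a + b + cc)
  }
  d
}

# unweighted UniFrac by explicit per-branch enumeration via phangorn
unifrac_oracle <- function(table, tree) {
  pa <- unclass(table) > 0
  n <- nrow(pa)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  d <- matrix(0, n, n, dimnames = list(rownames(pa), rownames(pa)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    uniq <- tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      tips <- tree$tip.label[desc[[e]]]
      tips <- intersect(tips, colnames(pa))
      in_i <- any(pa[i, tips])
      in_j <- any(pa[j, tips])
      if (in_i || in_j) tot <- tot + tree$edge.length[e]
      if (xor(in_i, in_j)) uniq <- uniq + tree$edge.length[e]
    }
    d[i, j] <- uniq / tot
  }
  d
}

# negative difference proportion, written out loop-wise
ndp_oracle <- function(h) {
  num <- den <- 0
  for (i in seq_len(length(h) - 1)) {
    step <- h[i] - h[i + 1]
    if (step > 0) num <- num + step
    den <- den + abs(step)
  }
  if (den == 0) 0 else num / den
}

# Wilson bounds as roots of the score equation, found numerically
wilson_oracle <- function(k, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p_hat <- k / n
  g <- function(p) (p_hat - p)^2 - z^2 * p * (1 - p) / n
  # endpoints nudged inward: at k = 0 or n the score equation has a
  # degenerate root at the boundary that uniroot would otherwise return
  lo <- if (k == 0) 0 else
    uniroot(g, c(1e-12, min(p_hat, 1 - 1e-9)), tol = 1e-14)$root
  hi <- if (k == n) 1 else
    uniroot(g, c(max(p_hat, 1e-9), 1 - 1e-12), tol = 1e-14)$root
  c(lower = lo, upper = hi)
}

# standard synthetic scenario used by several suites
planted_scenario <- function(seed, ...) {
  spec <- community_sim_spec(seed = seed, ...)
  tree <- simulate_calibrated_tree(spec$n_taxa, spec$tree_depth, seed = seed + 1000)
  host_tree <- simulate_calibrated_tree(
    spec$n_wolf + spec$n_dog + spec$n_ancient, 1, seed = seed + 2000)
  comm <- simulate_community(tree, host_tree, spec)
  list(spec = spec, tree = tree, comm = comm,
       factors = list(phylogeny = comm$host_distance,
                      ecology = ecology_distance_matrix(comm$meta)))
}
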