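# Beta-diversity through time: slice a time-calibrated bacterial tree at
# successive ages, collapse taxa into slice-defined clades, recompute
# between-host dissimilarity at each age, and correlate it with host
# factors under permutation nulls.

#' Slice a calibrated tree at a given age
#'
#' Each leaf is assigned to the clade defined by the branch its lineage
#' occupies at the slice age: the youngest ancestor (possibly the leaf
#' itself) whose parent is older than the slice. Age 0 yields one clade per
#' leaf; ages at or above the root age yield a single clade.
#'
#' @param tree a `calibrated_tree`.
#' @param age slice age (>= 0, same units as the tree).
#' @return a `slice_assignment`: list with `age`, `clade` (named integer
#'   vector, leaf -> contiguous clade id) and `n_clades`.
#' @export
slice_tree <- function(tree, age) {
  if (age < 0) stop("slice age must be non-negative")
  ages <- node_ages(tree)
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  node_for <- integer(ntip)
  for (leaf in seq_len(ntip)) {
    node <- leaf
    while (node != root && ages[parent[node]] <= age) node <- parent[node]
    node_for[leaf] <- if (node != root) node else root
  }
  ids <- match(node_for, sort(unique(node_for)))
  structure(list(age = age,
                 clade = setNames(ids, tree$tip.label),
                 n_clades = max(ids)),
            class = "slice_assignment")
}

#' Collapse an abundance table to slice clades
#'
#' Clade counts are the sums of member-leaf counts per host, so per-host
#' totals are conserved at every slice age.
#'
#' @param table hosts-by-taxa `abundance_table`.
#' @param assign a `slice_assignment` covering every table taxon.
#' @return hosts-by-clades `abundance_table` (columns `s<age>_c<id>`).
#' @export
collapse_table <- function(table, assign) {
  miss <- setdiff(colnames(table), names(assign$clade))
  if (length(miss))
    stop("taxa absent from slice assignment: ", paste(utils::head(miss, 5), collapse = ", "))
  grp <- assign$clade[colnames(table)]
  m <- t(rowsum(t(unclass(table)), group = grp))
  colnames(m) <- sprintf("s%s_c%s", format(assign$age, trim = TRUE), colnames(m))
  abundance_table(m)
}

#' Sorensen (binary Bray-Curtis) dissimilarity between hosts
#'
#' Counts are reduced to presence/absence and each pair scored
#' `1 - 2a / (2a + b + c)` with `a` shared and `b`, `c` unique taxa. A host
#' with an empty profile is at distance 1 from every non-empty host; empty
#' hosts are reported in the `"empty_hosts"` attribute.
#'
#' @param table hosts-by-taxa `abundance_table` with at least two hosts.
#' @return a host distance matrix in \[0, 1\].
#' @export
sorensen_matrix <- function(table) {
  if (nrow(table) < 2) stop("need at least two hosts")
  pa <- unclass(table) > 0
  if (!any(pa)) stop("all-zero abundance table")
  a <- pa %*% t(pa)
  rs <- rowSums(pa)
  denom <- outer(rs, rs, `+`)
  d <- 1 - 2 * a / denom
  d[denom == 0] <- 0          # two empty profiles: identical composition
  diag(d) <- 0
  out <- host_distance_matrix(d, "Sorensen matrix")
  if (any(rs == 0)) attr(out, "empty_hosts") <- rownames(table)[rs == 0]
  out
}

#' Unweighted UniFrac dissimilarity
#'
#' For each host pair, the branch length unique to either host's taxa
#' divided by the total branch length subtending the union of present taxa.
#'
#' @param table hosts-by-taxa `abundance_table`; taxa must be tree leaves
#'   and every host must contain at least one taxon.
#' @param tree a `calibrated_tree` (any phylo with branch lengths works).
#' @return a host distance matrix in \[0, 1\].
#' @export
unweighted_unifrac <- function(table, tree) {
  miss <- setdiff(colnames(table), tree$tip.label)
  if (length(miss)) stop("taxa not in tree: ", paste(utils::head(miss, 5), collapse = ", "))
  pa <- unclass(table) > 0
  empty <- rownames(table)[rowSums(pa) == 0]
  if (length(empty)) stop("host(s) with no taxa: ", paste(empty, collapse = ", "))
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  # leaves under each edge's child, by postorder accumulation
  under <- matrix(FALSE, nedge, ntip)
  po <- ape::reorder.phylo(tree, "postorder")
  child_rows <- split(seq_len(nedge), po$edge[, 1])
  for (e in seq_len(nedge)) {
    ch <- po$edge[e, 2]
    under[e, ] <- if (ch <= ntip) seq_len(ntip) == ch
      else Reduce(`|`, lapply(child_rows[[as.character(ch)]],
                              function(r) under[r, ]))
  }
  len <- po$edge.length
  # host x edge: does the host contain any leaf under the edge?
  pa_full <- matrix(FALSE, nrow(table), ntip,
                    dimnames = list(rownames(table), tree$tip.label))
  pa_full[, colnames(table)] <- pa
  hb <- pa_full %*% t(under * 1) > 0
  n <- nrow(table)
  d <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    un <- hb[i, ] | hb[j, ]
    uniq <- xor(hb[i, ], hb[j, ])
    d[i, j] <- d[j, i] <- sum(len[uniq]) / sum(len[un])
  }
  host_distance_matrix(d, "UniFrac matrix")
}

# ---- Mantel machinery -------------------------------------------------------

upper_vec <- function(m) m[upper.tri(m)]

align_to <- function(d, labels, what = "matrix") {
  if (!all(labels %in% rownames(d))) stop(what, " lacks some host labels")
  d[labels, labels, drop = FALSE]
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of upper-triangle entries, with significance from
#' joint row/column permutations of the second matrix. The default p-value
#' is two-sided on |r|; `alternative = "greater"` gives the one-sided test.
#'
#' @param d1,d2 host distance matrices over the same labels.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return list with `r`, `R2`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1,
                        alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) stop("n_perm must be >= 1")
  d2 <- align_to(d2, rownames(d1), "d2")
  x <- upper_vec(d1)
  y <- upper_vec(d2)
  if (sd(x) == 0 || sd(y) == 0) stop("constant distance matrix: Mantel r undefined")
  r <- cor(x, y)
  n <- nrow(d1)
  set.seed(as.integer(seed))
  tol <- 1e-12
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    rp <- cor(x, upper_vec(d2[p, p]))
    hit <- if (alternative == "two.sided") abs(rp) >= abs(r) - tol else rp >= r - tol
    hits <- hits + hit
  }
  pval <- (1 + hits) / (n_perm + 1)
  list(r = r, R2 = r^2, p = pval, n_perm = n_perm)
}

#' Permutation envelope for per-slice correlations
#'
#' Shuffles host labels of the factor matrix and recomputes the squared
#' Mantel correlation with the community dissimilarity, yielding a null
#' band of R-squared values. With fewer than 40 shuffles the band is the
#' min/max of the replicates (10 draws cannot resolve 2.5/97.5 percentiles,
#' so the historical 10-shuffle design reads as a range); otherwise the
#' empirical 2.5 and 97.5 percentiles are used.
#'
#' @param community host dissimilarity matrix for one slice.
#' @param factor_matrix host factor distance matrix.
#' @param n_shuffles number of label shuffles (>= 2; default 1000).
#' @param seed integer seed.
#' @return named vector `c(lower, upper)` of the null R-squared band.
#' @export
envelope_null <- function(community, factor_matrix, n_shuffles = 1000, seed = 1) {
  if (n_shuffles < 2) stop("n_shuffles must be >= 2")
  f <- align_to(factor_matrix, rownames(community), "factor matrix")
  x <- upper_vec(community)
  n <- nrow(community)
  set.seed(as.integer(seed))
  r2 <- numeric(n_shuffles)
  for (b in seq_len(n_shuffles)) {
    p <- sample.int(n)
    r2[b] <- cor(x, upper_vec(f[p, p]))^2
  }
  if (n_shuffles < 40) {
    c(lower = min(r2), upper = max(r2))
  } else {
    setNames(quantile(r2, c(0.025, 0.975), names = FALSE), c("lower", "upper"))
  }
}

#' Beta-diversity-through-time profile
#'
#' For each slice age: slice the tree, collapse the table, compute the
#' Sorensen dissimilarity, Mantel-test it against every factor matrix and
#' attach the permutation envelope of each factor.
#'
#' @param tree bacterial `calibrated_tree`.
#' @param table hosts-by-taxa `abundance_table` (taxa = tree leaves).
#' @param factors named list of host factor distance matrices (e.g.
#'   `list(phylogeny = ..., ecology = ...)`).
#' @param ages ascending slice ages; default an even 11-point grid from 0
#'   to the root age.
#' @param n_perm Mantel permutations per test.
#' @param n_shuffles envelope label shuffles per slice.
#' @param seed integer seed; sub-seeds are derived per slice and factor.
#' @return a `bdtt_profile`: list with `profile` (long data frame: age,
#'   factor, n_clades, r, R2, p, env_lo, env_hi), `ages` and
#'   `dissimilarity` (per-age Sorensen matrices).
#' @export
bdtt_profile <- function(tree, table, factors, ages = NULL,
                         n_perm = 999, n_shuffles = 1000, seed = 1) {
  if (is.null(ages)) ages <- seq(0, root_age(tree), length.out = 11)
  if (is.unsorted(ages)) stop("ages must be ascending")
  if (is.null(names(factors)) || any(names(factors) == ""))
    stop("factors must be a named list")
  seeds <- matrix(sub_seeds(seed, 2 * length(ages) * length(factors)),
                  nrow = length(ages))
  rows <- list()
  diss <- list()
  for (ai in seq_along(ages)) {
    assign <- slice_tree(tree, ages[ai])
    collapsed <- collapse_table(table, assign)
    sor <- sorensen_matrix(collapsed)
    diss[[as.character(ages[ai])]] <- sor
    degenerate <- sd(upper_vec(sor)) == 0
    for (fi in seq_along(factors)) {
      if (degenerate) {
        # all hosts equidistant (e.g. a single shared clade near the root):
        # the correlation is undefined, recorded as NA rather than an error
        mt <- list(r = NA_real_, R2 = NA_real_, p = NA_real_)
        env <- c(lower = NA_real_, upper = NA_real_)
      } else {
      mt <- mantel_test(sor, factors[[fi]], n_perm = n_perm,
                        seed = seeds[ai, 2 * fi - 1])
      env <- envelope_null(sor, factors[[fi]], n_shuffles = n_shuffles,
                           seed = seeds[ai, 2 * fi])
      }
      rows[[length(rows) + 1]] <- data.frame(
        age = ages[ai], factor = names(factors)[fi],
        n_clades = assign$n_clades, r = mt$r, R2 = mt$R2, p = mt$p,
        env_lo = env["lower"], env_hi = env["upper"],
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  structure(list(profile = do.call(rbind, rows), ages = ages,
                 dissimilarity = diss),
            class = "bdtt_profile")
}

#' @export
print.bdtt_profile <- function(x, ...) {
  cat("BDTT profile over", length(x$ages), "slice ages\n")
  print(x$profile, digits = 3)
  invisible(x)
}

#' Write a BDTT profile as long-format TSV
#' @param profile a `bdtt_profile`.
#' @param path output TSV.
#' @export
write_bdtt_profile <- function(profile, path) {
  write.table(format(profile$profile, digits = 10, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Leaf-shuffle null profile
#'
#' Re-runs the full profile on a tree whose leaf labels have been permuted.
#' This breaks the phylogenetic relationship between sequences while
#' keeping the tree shape and the leaf-level composition, so leaf-slice
#' (age 0) correlations are identical to the observed ones by construction
#' and deeper-slice correlations decay toward the null.
#'
#' @inheritParams bdtt_profile
#' @return a `bdtt_profile` for the shuffled tree.
#' @export
leaf_shuffle_null <- function(tree, table, factors, ages = NULL,
                              n_perm = 999, n_shuffles = 1000, seed = 1) {
  seeds <- sub_seeds(seed, 2)
  set.seed(seeds[1])
  shuffled <- tree
  shuffled$tip.label <- sample(tree$tip.label)
  attr(shuffled, "node_age") <- attr(tree, "node_age")
  bdtt_profile(shuffled, table, factors, ages = ages, n_perm = n_perm,
               n_shuffles = n_shuffles, seed = seeds[2])
}

# ---- per-lineage association ------------------------------------------------

# 0/1 presence mismatch distance for one clade's presence vector
presence_mismatch <- function(pres) {
  d <- outer(pres, pres, `!=`) * 1
  dimnames(d) <- list(names(pres), names(pres))
  d
}

#' Per-lineage association with host factors
#'
#' At each slice age, every clade's host presence/absence mismatch distance
#' is tested against each factor distance matrix with a permutational
#' pseudo-F (the factor matrix enters through its principal coordinates;
#' see [pseudo_f_dist()]), and p-values are Benjamini-Hochberg adjusted
#' within each slice-by-factor stratum. Clades present in no host or in all
#' hosts carry no variance and are skipped.
#'
#' @param tree bacterial `calibrated_tree`.
#' @param table hosts-by-taxa `abundance_table`.
#' @param factors named list of host factor distance matrices.
#' @param ages slice ages to test.
#' @param n_perm permutations per clade test.
#' @param fdr_alpha FDR level defining hits.
#' @param seed integer seed.
#' @return data frame of class `lineage_hits`: clade, age, factor,
#'   statistic, p, q, hit; skipped clades in the `"skipped"` attribute.
#' @export
lineage_association <- function(tree, table, factors, ages,
                                n_perm = 999, fdr_alpha = 0.05, seed = 1) {
  rows <- list()
  skipped <- character()
  seeds <- sub_seeds(seed, length(ages))
  for (ai in seq_along(ages)) {
    assign <- slice_tree(tree, ages[ai])
    collapsed <- collapse_table(table, assign)
    pa <- unclass(collapsed) > 0
    clade_seeds <- sub_seeds(seeds[ai], ncol(pa) * length(factors))
    k <- 0L
    for (ci in seq_len(ncol(pa))) {
      pres <- pa[, ci]
      if (all(pres) || !any(pres)) {
        skipped <- c(skipped, sprintf("%s@%s", colnames(pa)[ci], ages[ai]))
        k <- k + length(factors)
        next
      }
      dresp <- presence_mismatch(setNames(pres, rownames(pa)))
      for (fi in seq_along(factors)) {
        k <- k + 1L
        pf <- pseudo_f_dist(dresp, factors[[fi]], n_perm = n_perm,
                            seed = clade_seeds[k])
        rows[[length(rows) + 1]] <- data.frame(
          clade = colnames(pa)[ci], age = ages[ai],
          factor = names(factors)[fi], statistic = pf$pseudo_F, p = pf$p,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (s in split(seq_len(nrow(out)), list(out$age, out$factor), drop = TRUE)) {
    out$q[s] <- p.adjust(out$p[s], method = "BH")
  }
  out$q <- pmax(out$q, out$p)   # BH never reports q below the raw p
  out$hit <- out$q <= fdr_alpha
  attr(out, "skipped") <- skipped
  class(out) <- c("lineage_hits", class(out))
  out
}

#' Ward clustering of lineage abundance profiles on Spearman distance
#'
#' Lineages (rows) are clustered on `1 - Spearman rho` between their
#' relative-abundance profiles across hosts, with Ward linkage. Constant
#' profiles have undefined rank correlation and are dropped with a warning.
#' Coherence between the host-level structure of the retained lineages and
#' each factor matrix is evaluated by a Mantel test on the between-host
#' Spearman distance.
#'
#' @param profiles lineages-by-hosts numeric matrix (e.g. the hit-lineage
#'   rows of a collapsed table, transposed).
#' @param k number of flat clusters to cut.
#' @param factors optional named list of host factor matrices for the
#'   coherence Mantel tests.
#' @param n_perm,seed Mantel parameters for the coherence tests.
#' @return list with `tree` (hclust), `clusters` (named vector),
#'   `host_distance` and `coherence` (per-factor Mantel results).
#' @export
ward_spearman_clustering <- function(profiles, k = 2, factors = NULL,
                                     n_perm = 999, seed = 1) {
  profiles <- as.matrix(profiles)
  const <- apply(profiles, 1, function(z) sd(z) == 0)
  if (any(const)) {
    warning("dropping constant lineage profile(s): ",
            paste(rownames(profiles)[const], collapse = ", "))
    profiles <- profiles[!const, , drop = FALSE]
  }
  if (nrow(profiles) < 2) stop("need at least two non-constant lineages")
  d <- 1 - cor(t(profiles), method = "spearman")
  hc <- hclust(stats::as.dist(d), method = "ward.D2")
  clusters <- cutree(hc, k = k)
  host_ok <- apply(profiles, 2, sd) > 0
  coherence <- NULL
  host_d <- NULL
  if (sum(host_ok) >= 3) {
    host_d <- 1 - cor(profiles[, host_ok, drop = FALSE], method = "spearman")
    diag(host_d) <- 0
    host_d <- host_distance_matrix(pmax(host_d, 0) / 2, "host Spearman distance")
    if (!is.null(factors)) {
      seeds <- sub_seeds(seed, length(factors))
      coherence <- lapply(seq_along(factors), function(fi)
        mantel_test(host_d, align_to(factors[[fi]], rownames(host_d)),
                    n_perm = n_perm, seed = seeds[fi]))
      names(coherence) <- names(factors)
    }
  }
  list(tree = hc, clusters = clusters, host_distance = host_d,
       coherence = coherence)
}
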