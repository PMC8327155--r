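# Seeded generators producing data with the statistical structure the
# analysis stages assume: host-structured presence/absence at distinct
# phylogenetic depths, exponential-decay 5' C->T damage, declining
# edit-distance histograms, diet-linked occurrence, and Poisson region
# coverage at known copy number.

#' Derive independent sub-seeds from one global seed
#'
#' Composite scenarios draw from several random streams; deriving one
#' sub-seed per stream from the global seed keeps every stream reproducible
#' and decoupled from the order in which stages run.
#'
#' @param seed integer global seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each below `2^31 - 1`.
#' @export
sub_seeds <- function(seed, n) {
  stopifnot(is.finite(seed), n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate an ultrametric pure-birth tree
#'
#' A Yule tree rescaled to the requested root age. Only relative node ages
#' matter to time-sliced beta-diversity, so a pure-birth process is the
#' minimal adequate model for the bacterial phylogeny.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param depth root age in time units.
#' @param seed integer seed.
#' @return a `calibrated_tree`.
#' @export
simulate_calibrated_tree <- function(n_taxa, depth = 1000, seed = 1) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length * (depth / max(ape::node.depth.edgelength(tree)))
  tree$tip.label <- sprintf("t%03d", seq_len(n_taxa))
  as_calibrated_tree(tree)
}

#' Specification for a synthetic host-structured community
#'
#' Encodes the planted scale-disparity design: a fraction of deep clades
#' carries a host-phylogeny signal expressed at the leaf level only (shared
#' leaf presence decays with host cophenetic distance, while the clades
#' themselves are ubiquitous, so the signal dies out at old slices), a
#' second fraction carries a host-ecology signal expressed at depth (sparse
#' noisy leaf occupancy whose within-clade union separates wolf and dog
#' hosts, so the signal sharpens at old slices), and the remainder is
#' baseline noise.
#'
#' @param n_wolf,n_dog,n_ancient host counts per group (default 4/5/1, the
#'   canid comparative panel size).
#' @param n_taxa number of bacterial leaves.
#' @param tree_depth root age of the bacterial tree (time units).
#' @param phylo_cutoff age below which the phylogeny signal lives.
#' @param phylo_strength phylogeny effect strength in \[0, 1\].
#' @param eco_cutoff slice age defining the deep clades that carry roles.
#' @param eco_strength ecology effect strength in \[0, 1\].
#' @param baseline background occurrence probability.
#' @param occupancy within-group occurrence probability of ecology-role
#'   leaves at strength 1.
#' @param prop_phylo,prop_eco target fraction of leaves assigned to each
#'   signal role (deep clades are recruited largest-first until the target
#'   leaf mass is reached).
#' @param theta log-series parameter for abundances given occurrence.
#' @param seed integer seed (mandatory).
#' @return a `community_sim_spec` list.
#' @export
community_sim_spec <- function(n_wolf = 4, n_dog = 5, n_ancient = 1,
                               n_taxa = 128, tree_depth = 1000,
                               phylo_cutoff = 250, phylo_strength = 0.9,
                               eco_cutoff = 600, eco_strength = 0.9,
                               baseline = 0.10, occupancy = 0.4,
                               prop_phylo = 0.45, prop_eco = 0.45,
                               theta = 0.95, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(phylo_strength >= 0, phylo_strength <= 1,
            eco_strength >= 0, eco_strength <= 1,
            phylo_cutoff > 0, phylo_cutoff < tree_depth,
            eco_cutoff > 0, eco_cutoff < tree_depth,
            baseline > 0, baseline < 1, occupancy > 0, occupancy <= 1,
            prop_phylo + prop_eco <= 1)
  spec <- as.list(environment())
  class(spec) <- "community_sim_spec"
  spec
}

#' Simulate host metadata for a community spec
#' @param spec a `community_sim_spec`.
#' @return a `host_meta` data frame (wolves, dogs, then ancient hosts).
#' @export
simulate_host_meta <- function(spec) {
  host_meta(data.frame(
    host = c(sprintf("wolf%d", seq_len(spec$n_wolf)),
             sprintf("dog%d", seq_len(spec$n_dog)),
             sprintf("ancient%d", seq_len(spec$n_ancient))),
    group = rep(c("wolf", "dog", "ancient"),
                c(spec$n_wolf, spec$n_dog, spec$n_ancient)),
    stringsAsFactors = FALSE
  ))
}

# log-series abundance sampler: P(k) proportional to theta^k / k
rlogseries <- function(n, theta) {
  kmax <- 2000L
  k <- seq_len(kmax)
  p <- theta^k / k
  cdf <- cumsum(p) / sum(p)
  findInterval(runif(n), cdf) + 1L
}

#' Simulate a host-structured community
#'
#' Draws presence/absence for every (host, leaf) pair under the planted
#' design of [community_sim_spec()], then log-series abundances for present
#' cells. At strengths (0, 0) every leaf occurs i.i.d. at the baseline rate.
#'
#' @param tree bacterial `calibrated_tree` whose leaf count matches
#'   `spec$n_taxa`.
#' @param host_tree host `calibrated_tree` with one leaf per host.
#' @param spec a `community_sim_spec`.
#' @return list with `table` (abundance_table), `meta` (host_meta),
#'   `host_tree` (the host tree with group labels placed on its tips),
#'   `host_distance` (the normalised cophenetic matrix the generator used)
#'   and `roles` (per-leaf role labels, the simulation truth).
#' @export
simulate_community <- function(tree, host_tree, spec) {
  stopifnot(inherits(spec, "community_sim_spec"))
  if (spec$eco_cutoff >= root_age(tree) || spec$phylo_cutoff >= root_age(tree))
    stop("cutoffs must be younger than the bacterial root age")
  meta <- simulate_host_meta(spec)
  n_host <- nrow(meta)
  if (length(host_tree$tip.label) != n_host)
    stop("host tree must have one leaf per host")
  seeds <- sub_seeds(spec$seed, 4L)

  # host cophenetic distances, normalised to [0, 1]
  set.seed(seeds[1])
  host_tree$tip.label <- sample(meta$host)   # groups placed randomly on the host tree
  Dh <- cophenetic_distances(host_tree)[meta$host, meta$host]
  Dh <- Dh / max(Dh)

  taxa <- tree$tip.label
  n_taxa <- length(taxa)
  deep <- slice_tree(tree, spec$eco_cutoff)
  clade_of <- deep$clade[taxa]

  # assign roles to deep clades by leaf mass, largest first, so every seed
  # carries close to the requested fraction of signal leaves per role
  set.seed(seeds[2])
  K <- deep$n_clades
  sizes <- tabulate(clade_of, K)
  ord <- order(sizes + runif(K), decreasing = TRUE)   # random tie-break
  role <- rep("noise", K)
  want <- c(phylogeny = spec$prop_phylo, ecology = spec$prop_eco) * n_taxa
  got <- c(phylogeny = 0, ecology = 0)
  for (k in ord) {
    deficit <- want - got
    pick <- names(which.max(deficit))
    if (deficit[pick] <= 0) next
    role[k] <- pick
    got[pick] <- got[pick] + sizes[k]
  }
  if (spec$eco_strength > 0 && sum(role == "ecology") < 2) {
    # the wolf/dog contrast needs at least one clade per affiliation
    role[ord[which(role[ord] != "ecology")[1]]] <- "ecology"
  }
  if (spec$phylo_strength == 0) role[role == "phylogeny"] <- "noise"
  if (spec$eco_strength == 0) role[role == "ecology"] <- "noise"
  affil <- rep(NA_character_, K)
  affil[role == "ecology"] <- rep(c("wolf", "dog"), length.out = sum(role == "ecology"))
  leaf_role <- role[clade_of]
  leaf_affil <- affil[clade_of]

  # occurrence probabilities, blended so strength 0 collapses to baseline
  set.seed(seeds[3])
  P <- matrix(spec$baseline, n_host, n_taxa, dimnames = list(meta$host, taxa))
  s_p <- spec$phylo_strength; s_e <- spec$eco_strength
  focal <- sample.int(n_host, n_taxa, replace = TRUE)
  radius <- runif(n_taxa)   # phylogeny-role occupancy radius, host-tree units
  for (t in seq_len(n_taxa)) {
    if (leaf_role[t] == "phylogeny" && s_p > 0) {
      # nested-ball occupancy: the leaf occupies every host within a random
      # cophenetic radius of its focal host, so co-occurrence decays with
      # host distance; strength blends this with baseline noise
      ball <- as.numeric(Dh[, focal[t]] <= radius[t])
      P[, t] <- (1 - s_p) * spec$baseline + s_p * ball
    } else if (leaf_role[t] == "ecology" && s_e > 0) {
      target <- ifelse(meta$group == leaf_affil[t], spec$occupancy,
                       ifelse(meta$group == "ancient", spec$occupancy / 2, 0))
      P[, t] <- (1 - s_e) * spec$baseline + s_e * target
    }
  }
  occ <- matrix(runif(n_host * n_taxa) < P, n_host, n_taxa,
                dimnames = dimnames(P))

  # phylogeny-role clades are made ubiquitous so their signal is strictly
  # leaf-scale: any host missing a clade receives one random member leaf
  if (s_p > 0) {
    for (k in which(role == "phylogeny")) {
      members <- which(clade_of == k)
      for (h in which(rowSums(occ[, members, drop = FALSE]) == 0)) {
        occ[h, sample(members, 1)] <- TRUE
      }
    }
  }

  set.seed(seeds[4])
  counts <- matrix(0, n_host, n_taxa, dimnames = dimnames(P))
  counts[occ] <- rlogseries(sum(occ), spec$theta)
  list(table = abundance_table(counts), meta = meta,
       host_tree = host_tree, host_distance = Dh,
       roles = setNames(leaf_role, taxa))
}

# ---- damage / read simulation ----------------------------------------------

#' Specification for simulated aligned-read records
#'
#' @param n_reads number of reads.
#' @param p0 5' C->T deamination amplitude at position 1 (ancient reads).
#' @param lambda exponential decay rate of the damage signal per position.
#' @param baseline background per-site mismatch rate (modern and ancient).
#' @param ancient_fraction fraction of reads drawn from the damaged
#'   (ancient) population.
#' @param len_meanlog,len_sdlog log-normal read-length parameters (bp);
#'   defaults give the short fragments typical of degraded DNA (~30-120 bp).
#' @param gc genomic GC content (sets the chance a 5' site has reference C).
#' @param seed integer seed (mandatory).
#' @return a `damage_sim_spec` list.
#' @export
damage_sim_spec <- function(n_reads = 10000, p0 = 0.3, lambda = 0.5,
                            baseline = 0.01, ancient_fraction = 1,
                            len_meanlog = log(55), len_sdlog = 0.3,
                            gc = 0.42, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(p0 >= 0, p0 <= 1, lambda > 0, baseline >= 0, baseline < 1,
            ancient_fraction >= 0, ancient_fraction <= 1, n_reads >= 1)
  spec <- as.list(environment())
  class(spec) <- "damage_sim_spec"
  spec
}

#' Simulate per-read alignment summaries with 5' damage
#'
#' Each read carries reference->read codes for 5' positions 1..10 (two
#' letters, e.g. `"CC"` match, `"CT"` deamination) plus a total edit
#' distance. Ancient reads gain C->T mismatches at position i with
#' probability `p0 * exp(-lambda * (i - 1)) + baseline`; modern reads and
#' non-C sites mismatch at the baseline rate only. Body mismatches beyond
#' position 10 are binomial at the baseline rate, which yields the declining
#' edit-distance histograms expected of genuine assignments.
#'
#' @param spec a `damage_sim_spec`.
#' @return data frame of read records (`read_id`, `length`, `strand`,
#'   `pos1`..`pos10`, `edit_distance`, `ancient`).
#' @export
simulate_reads <- function(spec) {
  stopifnot(inherits(spec, "damage_sim_spec"))
  set.seed(as.integer(spec$seed))
  n <- spec$n_reads
  len <- pmax(30L, pmin(200L, round(rlnorm(n, spec$len_meanlog, spec$len_sdlog))))
  ancient <- runif(n) < spec$ancient_fraction
  bases <- c("A", "C", "G", "T")
  pbase <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
  codes <- matrix("", n, 10)
  mm5 <- integer(n)
  for (i in 1:10) {
    ref <- sample(bases, n, replace = TRUE, prob = pbase)
    p_ct <- ifelse(ancient, pmin(1, spec$p0 * exp(-spec$lambda * (i - 1)) + spec$baseline),
                   spec$baseline)
    u <- runif(n)
    is_c <- ref == "C"
    damaged <- is_c & u < p_ct
    other_mm <- !is_c & u < spec$baseline
    read <- ref
    read[damaged] <- "T"
    if (any(other_mm)) {
      read[other_mm] <- vapply(ref[other_mm],
                               function(b) sample(setdiff(bases, b), 1), "")
    }
    codes[, i] <- paste0(ref, read)
    mm5 <- mm5 + as.integer(damaged | other_mm)
  }
  body <- rbinom(n, pmax(len - 10L, 0L), spec$baseline)
  out <- data.frame(
    read_id = sprintf("r%06d", seq_len(n)),
    length = len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  for (i in 1:10) out[[paste0("pos", i)]] <- codes[, i]
  out$edit_distance <- mm5 + body
  out$ancient <- ancient
  out
}

# ---- coverage simulation ----------------------------------------------------

#' Specification for target/control region coverage
#'
#' Region geometry defaults to the amylase design: a ~75 kb target (gene
#' region plus unplaced duplicate contigs) against 75 random 1-kb control
#' windows. The default host panel is 4 wolves at diploid copy number 2,
#' 5 dogs at 8 and one ancient host at 2.
#'
#' @param copy_number named integer vector of true diploid copy numbers, or
#'   `NULL` for the default panel.
#' @param group named character vector of host groups (required when
#'   `copy_number` is supplied).
#' @param per_copy_depth expected mapped reads per bp per gene copy.
#' @param target_length target region length (bp).
#' @param control_windows,control_length control window count and size (bp).
#' @param seed integer seed (mandatory).
#' @return a `coverage_sim_spec` list.
#' @export
coverage_sim_spec <- function(copy_number = NULL, group = NULL,
                              per_copy_depth = 0.02, target_length = 75000,
                              control_windows = 75, control_length = 1000,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(copy_number)) {
    copy_number <- c(wolf1 = 2, wolf2 = 2, wolf3 = 2, wolf4 = 2,
                     dog1 = 8, dog2 = 8, dog3 = 8, dog4 = 8, dog5 = 8,
                     ancient1 = 2)
    group <- setNames(sub("[0-9]+$", "", names(copy_number)), names(copy_number))
  }
  stopifnot(all(copy_number >= 1), all(copy_number == round(copy_number)),
            per_copy_depth > 0, target_length > 0,
            control_windows > 0, control_length > 0,
            !is.null(group), identical(names(group), names(copy_number)))
  spec <- as.list(environment())
  class(spec) <- "coverage_sim_spec"
  spec
}

#' Simulate mapped-read counts for target and control regions
#'
#' Target reads are Poisson with mean `copy_number * per_copy_depth *
#' target_length`; control reads are Poisson with mean `2 * per_copy_depth *
#' control_windows * control_length` (the control genome is diploid).
#'
#' @param spec a `coverage_sim_spec`.
#' @return a `region_counts` data frame (`host`, `group`, `target_reads`,
#'   `control_reads`, `target_len`, `control_len`, `true_copy_number`).
#' @export
simulate_coverage <- function(spec) {
  stopifnot(inherits(spec, "coverage_sim_spec"))
  set.seed(as.integer(spec$seed))
  cn <- spec$copy_number
  lc <- spec$control_windows * spec$control_length
  data.frame(
    host = names(cn),
    group = unname(spec$group[names(cn)]),
    target_reads = rpois(length(cn), cn * spec$per_copy_depth * spec$target_length),
    control_reads = rpois(length(cn), 2 * spec$per_copy_depth * lc),
    target_len = spec$target_length,
    control_len = lc,
    true_copy_number = unname(cn),
    stringsAsFactors = FALSE
  )
}
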