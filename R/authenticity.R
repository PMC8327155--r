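# Ancient-origin statistics for metagenomic taxon assignments: 5' C->T
# deamination profiles, per-read post-mortem degradation scores, the
# negative difference proportion of edit-distance histograms, coverage
# summaries, and the screening rules combining them.

pos_cols <- paste0("pos", 1:10)

ref_base <- function(codes) substr(codes, 1, 1)
read_base <- function(codes) substr(codes, 2, 2)

#' Fit a 5' C->T damage profile
#'
#' For each of the first 10 read positions, the deamination rate is the
#' number of C->T observations divided by the number of reference-C sites.
#' Positions with no reference-C site are flagged undefined (`NA`).
#'
#' @param reads data frame of read records as produced by
#'   [simulate_reads()] or [read_read_records()].
#' @return a `damage_profile`: list with `rate` (length 10), `c_sites`
#'   (reference-C site counts) and `ct` (C->T counts).
#' @export
fit_damage_profile <- function(reads) {
  if (NROW(reads) == 0) stop("no reads")
  if (!all(pos_cols %in% names(reads))) stop("reads lack pos1..pos10 columns")
  c_sites <- ct <- integer(10)
  for (i in 1:10) {
    codes <- reads[[pos_cols[i]]]
    is_c <- ref_base(codes) == "C"
    c_sites[i] <- sum(is_c)
    ct[i] <- sum(codes == "CT")
  }
  rate <- ifelse(c_sites > 0, ct / c_sites, NA_real_)
  structure(list(rate = rate, c_sites = c_sites, ct = ct),
            class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat("5' C->T damage profile (positions 1..10):\n")
  print(round(x$rate, 4))
  invisible(x)
}

#' Estimate damage amplitude and decay from a fitted profile
#'
#' Fits `rate(i) = p0 * exp(-lambda * (i - 1)) + baseline` by least squares
#' on the excess rate over baseline, weighting positions by their
#' reference-C site counts (deep positions carry little signal and large
#' relative noise).
#'
#' @param profile a `damage_profile`.
#' @param baseline background mismatch rate subtracted before the fit.
#' @return list with `p0` and `lambda`.
#' @export
estimate_damage_decay <- function(profile, baseline = 0) {
  ex <- profile$rate - baseline
  pos <- which(!is.na(ex) & ex > 0)
  if (length(pos) < 3) stop("too few informative positions to fit a decay")
  w <- profile$c_sites[pos]
  fit <- stats::lm(log(ex[pos]) ~ I(pos - 1), weights = w * ex[pos]^2)
  # weights ~ c_sites * ex^2 approximate inverse variance of log(ex)
  list(p0 = unname(exp(coef(fit)[1])), lambda = unname(-coef(fit)[2]))
}

#' Per-read post-mortem degradation score
#'
#' Log-likelihood ratio of a read's 5' observations under the fitted damage
#' model (position-dependent C->T rate) versus an undamaged null with a
#' constant baseline substitution rate. Only reference-C sites in positions
#' 1..10 contribute: an observed C->T adds `log(rate_i / baseline)`, a
#' retained C adds `log((1 - rate_i) / (1 - baseline))`. Positive scores
#' support post-mortem damage; the score is additive over positions and 0
#' for reads without informative sites.
#'
#' @param reads data frame of read records.
#' @param profile a `damage_profile`.
#' @param baseline null substitution rate, in (0, 1).
#' @param eps rates are clamped to `[eps, 1 - eps]` to keep the ratio finite.
#' @return numeric vector of scores, one per read.
#' @export
degradation_score <- function(reads, profile, baseline = 0.01, eps = 1e-9) {
  if (baseline <= 0 || baseline >= 1) stop("baseline must lie in (0, 1)")
  rate <- pmin(pmax(profile$rate, eps), 1 - eps)
  score <- numeric(NROW(reads))
  for (i in 1:10) {
    if (is.na(profile$rate[i])) next
    codes <- reads[[pos_cols[i]]]
    is_c <- ref_base(codes) == "C"
    damaged <- codes == "CT"
    score <- score +
      ifelse(damaged, log(rate[i] / baseline),
             ifelse(is_c, log((1 - rate[i]) / (1 - baseline)), 0))
  }
  score
}

#' Negative difference proportion of an edit-distance histogram
#'
#' The proportion of declining steps among adjacent bins,
#' `sum(max(0, n_i - n_{i+1})) / sum(|n_i - n_{i+1}|)`. A value of 1 means a
#' monotonically declining histogram, the shape expected when most reads
#' match their reference closely; values above 0.9 are the conventional
#' ancient-profile threshold. A flat histogram has no steps and returns 0
#' with a `"flat"` attribute set.
#'
#' @param histogram non-negative counts indexed by edit distance 0..k.
#' @return the proportion in \[0, 1\].
#' @export
negative_difference_proportion <- function(histogram) {
  histogram <- as.numeric(histogram)
  if (length(histogram) < 2) stop("need at least two histogram bins")
  if (any(histogram < 0)) stop("negative counts")
  d <- diff(histogram)
  denom <- sum(abs(d))
  if (denom == 0) {
    return(structure(0, flat = TRUE))
  }
  sum(pmax(0, -d)) / denom
}

#' Edit-distance histogram of (optionally score-filtered) reads
#'
#' @param reads read records with an `edit_distance` column and, if
#'   filtering, a score vector.
#' @param score optional per-read degradation scores.
#' @param min_score keep reads with score strictly greater than this
#'   (default `-Inf`, no filter).
#' @param k largest edit distance bin (distances above are truncated into it).
#' @return integer counts for distances 0..k.
#' @export
edit_distance_histogram <- function(reads, score = NULL, min_score = -Inf, k = 10) {
  ed <- reads$edit_distance
  if (!is.null(score)) ed <- ed[score > min_score]
  ed <- pmin(ed, k)
  tabulate(ed + 1L, nbins = k + 1L)
}

#' Depth and breadth of coverage
#'
#' @param per_base_depths depths at covered positions (uncovered positions
#'   are implicit zeros).
#' @param genome_length reference length (> 0, at least the number of
#'   covered positions).
#' @return list with `depth` (fold coverage) and `breadth_pct` (percent of
#'   positions covered at >= 1x).
#' @export
coverage_stats <- function(per_base_depths, genome_length) {
  if (genome_length <= 0) stop("genome_length must be positive")
  if (length(per_base_depths) > genome_length)
    stop("more covered positions than genome_length")
  list(depth = sum(per_base_depths) / genome_length,
       breadth_pct = 100 * sum(per_base_depths >= 1) / genome_length)
}

# ---- taxon summaries and screening ------------------------------------------

#' Build a per-taxon authentication summary row
#'
#' @param taxon taxon id.
#' @param reads assigned read count.
#' @param pmds_gt1 number of reads with degradation score > 1.
#' @param depth fold depth of coverage.
#' @param breadth_pct percent of reference covered >= 1x.
#' @param ct5_pct C->T rate at 5' position 1, in percent.
#' @param ndp negative difference proportion in \[0, 1\].
#' @return one-row data frame of class `taxon_summary`.
#' @export
taxon_summary <- function(taxon, reads, pmds_gt1, depth, breadth_pct,
                          ct5_pct, ndp) {
  if (pmds_gt1 > reads) stop("score>1 count exceeds assigned reads")
  if (!is.na(breadth_pct) && (breadth_pct < 0 || breadth_pct > 100))
    stop("breadth must lie in [0, 100]")
  if (ndp < 0 || ndp > 1) stop("-Delta% must lie in [0, 1]")
  out <- data.frame(taxon = taxon, reads = reads, pmds_gt1 = pmds_gt1,
                    depth = depth, breadth_pct = breadth_pct,
                    ct5_pct = ct5_pct, ndp = ndp, stringsAsFactors = FALSE)
  class(out) <- c("taxon_summary", class(out))
  out
}

#' Screening rule-sets for ancient-origin calls
#'
#' `bacterial_rules()` implements the gut-bacteria criteria: more than 500
#' assigned reads, at least 50 reads with degradation score > 1 (the
#' published summaries contain a taxon with exactly 50 such reads, so the
#' bound is inclusive), negative difference proportion above 0.9, and an
#' observed 5' C->T signal. `dietary_rules()` is the relaxed variant for
#' eukaryotic dietary traces: more than 100 reads, no score-read bound.
#'
#' @param min_reads assigned-read threshold (strict `>`).
#' @param min_pmds_reads score>1 read threshold (`>=`), or `NA` to skip.
#' @param min_ndp negative-difference-proportion threshold (strict `>`).
#' @param min_ct5 minimum 5' position-1 C->T percent (strict `>`).
#' @return a named list of thresholds.
#' @export
screening_rules <- function(min_reads, min_pmds_reads = NA, min_ndp = 0.9,
                            min_ct5 = 0) {
  list(min_reads = min_reads, min_pmds_reads = min_pmds_reads,
       min_ndp = min_ndp, min_ct5 = min_ct5)
}

#' @rdname screening_rules
#' @export
bacterial_rules <- function() screening_rules(500, 50)

#' @rdname screening_rules
#' @export
dietary_rules <- function() screening_rules(100, NA)

#' Screen a taxon summary against a rule-set
#'
#' @param summary a `taxon_summary` row (or any list with the same fields).
#' @param rules a rule-set from [screening_rules()].
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed criteria, empty on pass).
#' @export
screen_taxon <- function(summary, rules = bacterial_rules()) {
  need <- c("reads", "ndp", "ct5_pct")
  if (!is.na(rules$min_pmds_reads)) need <- c(need, "pmds_gt1")
  miss <- need[!need %in% names(summary)]
  if (length(miss)) stop("summary lacks field(s): ", paste(miss, collapse = ", "))
  reasons <- character()
  if (!(summary$reads > rules$min_reads)) reasons <- c(reasons, "reads")
  if (!is.na(rules$min_pmds_reads) &&
      !(summary$pmds_gt1 >= rules$min_pmds_reads)) reasons <- c(reasons, "pmds_gt1")
  if (!(summary$ndp > rules$min_ndp)) reasons <- c(reasons, "ndp")
  if (!(summary$ct5_pct > rules$min_ct5)) reasons <- c(reasons, "ct5_pct")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Screen every row of a taxon summary table
#'
#' @param summaries data frame with `taxon_summary` columns.
#' @param rules rule-set.
#' @return the table with `pass` and `reasons` columns appended.
#' @export
screen_table <- function(summaries, rules = bacterial_rules()) {
  res <- lapply(seq_len(nrow(summaries)),
                function(i) screen_taxon(summaries[i, ], rules))
  summaries$pass <- vapply(res, `[[`, logical(1), "pass")
  summaries$reasons <- vapply(res, function(r)
    paste(r$reasons, collapse = ";"), "")
  summaries
}

# ---- tabular I/O ------------------------------------------------------------

#' Read/write per-read alignment summaries as TSV
#' @param path TSV with columns read_id, length, strand, pos1..pos10,
#'   edit_distance.
#' @return data frame of read records.
#' @export
read_read_records <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("read_id", "length", pos_cols, "edit_distance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  mm5 <- rowSums(vapply(pos_cols, function(p)
    ref_base(df[[p]]) != read_base(df[[p]]), logical(nrow(df))))
  if (any(df$edit_distance < mm5))
    stop("edit distance below the number of recorded 5' mismatches")
  df
}

#' @rdname read_read_records
#' @param reads read records to write.
#' @export
write_read_records <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxon-summary table (screening-table column order)
#'
#' Columns: taxon, reads, pmds_gt1, depth, breadth_pct, ct5_pct, ndp.
#' @param path TSV file.
#' @return data frame of per-taxon summaries.
#' @export
read_taxon_summaries <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("taxon", "reads", "pmds_gt1", "depth", "breadth_pct", "ct5_pct", "ndp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df
}
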