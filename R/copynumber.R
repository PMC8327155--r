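# Diploid gene copy-number estimation from target-vs-control mapped read
# counts: binomial read-count ratios with Wilson confidence intervals and
# anchor-group scaling (e.g. wolves anchored at amylase copy number 2).

#' Target read-count ratio
#'
#' `target / (target + control)`: the binomial proportion of mapped reads
#' falling in the target region, the quantity whose uncertainty the Wilson
#' interval describes.
#'
#' @param target_reads,control_reads non-negative integer counts (total
#'   must be positive).
#' @return the ratio in \[0, 1\].
#' @export
read_ratio <- function(target_reads, control_reads) {
  if (any(target_reads < 0) || any(control_reads < 0)) stop("negative counts")
  tot <- target_reads + control_reads
  if (any(tot == 0)) stop("zero total read count")
  target_reads / tot
}

#' Wilson score interval for the read-count ratio
#'
#' @param target_reads,control_reads counts as in [read_ratio()].
#' @param level confidence level in (0, 1).
#' @return matrix with columns `lower`, `upper` (one row per host).
#' @export
ratio_confidence <- function(target_reads, control_reads, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  n <- target_reads + control_reads
  if (any(n == 0)) stop("zero total read count")
  p <- target_reads / n
  z <- qnorm(1 - (1 - level) / 2)
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  cbind(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Scale read-count ratios to diploid copy numbers against an anchor group
#'
#' The anchor group (canonically wolves, copy number 2) defines one scaling
#' factor that maps the group mean onto the anchor value, so the anchor
#' group's mean estimate equals the anchor copy number exactly by
#' construction.
#'
#' Two conventions are available. `"rate"` (default) scales the
#' target:control rate ratio `target / control`, which is proportional to
#' the true copy number when read counts are proportional to copy number
#' times region length - so estimates stay unbiased arbitrarily far from
#' the anchor. `"proportion"` scales the bounded ratio
#' `target / (target + control)` directly; it is exact at the anchor but
#' compresses estimates away from it, and is retained for comparison with
#' the raw-proportion description of the original read-depth approach.
#'
#' Confidence intervals: the per-host Wilson interval is mapped through the
#' same transform, and by default the sampling noise of the anchor scaling
#' factor is propagated on the log scale (delta method); without
#' propagation the intervals under-cover whenever anchor and test hosts
#' have comparable depth.
#'
#' @param counts a `region_counts` data frame (`host`, `group`,
#'   `target_reads`, `control_reads`, ...).
#' @param anchor_group group whose true copy number is known.
#' @param anchor_cn the known diploid copy number of the anchor group.
#' @param level confidence level.
#' @param convention `"rate"` or `"proportion"` (see Details).
#' @param propagate_anchor include anchor-factor variance in the scaled
#'   intervals.
#' @param length_correction divide each host's rate by
#'   `target_len / control_len` before scaling, for designs where the two
#'   effective lengths differ (off by default: the canonical design uses
#'   matched ~75 kb regions).
#' @return data frame of class `copy_number_estimates`: host, group, ratio,
#'   ratio CI, copy number and scaled CI.
#' @export
scale_to_copies <- function(counts, anchor_group = "wolf", anchor_cn = 2,
                            level = 0.95,
                            convention = c("rate", "proportion"),
                            propagate_anchor = TRUE,
                            length_correction = FALSE) {
  convention <- match.arg(convention)
  need <- c("host", "group", "target_reads", "control_reads")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("counts lack column(s): ", paste(miss, collapse = ", "))
  anchor <- counts$group == anchor_group
  if (!any(anchor)) stop("anchor group '", anchor_group, "' is empty")
  t <- counts$target_reads
  c0 <- counts$control_reads
  ratio <- read_ratio(t, c0)
  ci <- ratio_confidence(t, c0, level)
  lenfac <- if (length_correction) counts$target_len / counts$control_len else 1
  stat <- switch(convention,
                 rate = (t / c0) / lenfac,
                 proportion = ratio / lenfac)
  stat_lo <- switch(convention,
                    rate = (ci[, "lower"] / (1 - ci[, "lower"])) / lenfac,
                    proportion = ci[, "lower"] / lenfac)
  stat_hi <- switch(convention,
                    rate = (ci[, "upper"] / (1 - ci[, "upper"])) / lenfac,
                    proportion = ci[, "upper"] / lenfac)
  anchor_mean <- mean(stat[anchor])
  if (anchor_mean <= 0) stop("anchor group has zero mean ratio")
  s <- anchor_cn / anchor_mean
  cn <- s * stat
  lo <- s * stat_lo
  hi <- s * stat_hi
  if (propagate_anchor) {
    # relative variance of the anchor mean (delta method on log scale),
    # added to each host's own interval width
    var_stat <- switch(convention,
                       rate = (t / c0)^2 * (1 / pmax(t, 0.5) + 1 / pmax(c0, 0.5)),
                       proportion = ratio * (1 - ratio) / (t + c0))
    rel_anchor <- sqrt(sum(var_stat[anchor])) / (sum(anchor) * anchor_mean)
    z <- qnorm(1 - (1 - level) / 2)
    own_rel <- (log(pmax(hi, 1e-12)) - log(pmax(lo, 1e-12))) / (2 * z)
    tot_rel <- sqrt(own_rel^2 + rel_anchor^2)
    lo <- cn * exp(-z * tot_rel)
    hi <- cn * exp(z * tot_rel)
  }
  out <- data.frame(host = counts$host, group = counts$group,
                    ratio = ratio,
                    ratio_lower = ci[, "lower"], ratio_upper = ci[, "upper"],
                    copy_number = cn, cn_lower = lo, cn_upper = hi,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "scaling_factor") <- s
  attr(out, "convention") <- convention
  class(out) <- c("copy_number_estimates", class(out))
  out
}

#' Read region counts from TSV
#'
#' Columns: host, group, target_reads, control_reads, target_len,
#' control_len.
#' @param path TSV file.
#' @return a `region_counts` data frame.
#' @export
read_region_counts <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("host", "group", "target_reads", "control_reads",
            "target_len", "control_len")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$target_reads < 0 | df$control_reads < 0)) stop("negative counts")
  if (any(df$target_len <= 0 | df$control_len <= 0)) stop("non-positive lengths")
  df
}
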