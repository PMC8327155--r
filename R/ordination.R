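# Ordination and distance-matrix inference: principal coordinates,
# permutational pseudo-F tests (grouped and distance-predictor forms) and
# the Procrustes non-randomness test.

gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers the squared distances and eigendecomposes. Axes with
#' positive eigenvalues are returned in decreasing order; negative
#' eigenvalues (non-Euclidean input) are reported, not silently dropped.
#'
#' @param d symmetric host distance matrix with at least 3 hosts.
#' @param tol eigenvalues below `tol * max(eig)` count as null.
#' @return list with `points` (hosts x axes), `eig` (all eigenvalues),
#'   `explained` (fraction of the positive eigenvalue sum per axis).
#' @export
pcoa <- function(d, tol = 1e-8) {
  d <- host_distance_matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 hosts")
  res <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- res$eig
  keep <- which(eig > tol * max(eig))
  pts <- res$points[, keep, drop = FALSE]
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("PCo", seq_along(keep))
  list(points = pts, eig = eig, explained = eig[keep] / sum(eig[eig > 0]))
}

# pseudo-F of a response Gower matrix against a hat matrix, with the
# trace identities tr(HGH) = tr(GH) and tr((I-H)G(I-H)) = tr(G) - tr(GH)
pseudo_f_perm <- function(G, H, m, n_perm, seed) {
  n <- nrow(G)
  if (n - m - 1 <= 0) stop("not enough residual degrees of freedom")
  f_of <- function(Gp) {
    num <- sum(Gp * H)
    tot <- sum(diag(Gp))
    resid <- tot - num
    # a partition explaining all variation leaves a residual of exactly 0;
    # floating-point noise can make it slightly negative, which must read
    # as an infinite F, not a huge negative one
    if (resid <= 1e-12 * max(abs(tot), 1)) return(Inf)
    (num / m) / (resid / (n - m - 1))
  }
  f_obs <- f_of(G)
  set.seed(as.integer(seed))
  tol <- 1e-12
  hits <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    hits <- hits + (f_of(G[p, p]) >= f_obs - tol)
  }
  list(pseudo_F = f_obs, p = (1 + hits) / (n_perm + 1))
}

hat_matrix <- function(X) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  list(H = tcrossprod(Q), m = qrX$rank)
}

#' Permutational pseudo-F of one distance matrix against another
#'
#' The predictor distance matrix enters through its principal coordinates
#' (all positive-eigenvalue axes), whose hat matrix partitions the
#' Gower-centered response into among- and within-model sums of squares;
#' significance comes from joint row/column permutation of the response.
#' This is the distance-matrix analogue of PERMANOVA used for per-lineage
#' association testing.
#'
#' @param d_resp response host distance matrix.
#' @param d_pred predictor host distance matrix.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `pseudo_F` and `p`.
#' @export
pseudo_f_dist <- function(d_resp, d_pred, n_perm = 999, seed = 1) {
  d_pred <- align_to(d_pred, rownames(d_resp), "predictor matrix")
  co <- pcoa_axes_all(d_pred)
  hm <- hat_matrix(co)
  G <- gower_center(d_resp)
  pseudo_f_perm(G, hm$H, hm$m, n_perm, seed)
}

# positive-eigenvalue principal coordinates without the n >= 3 guard
pcoa_axes_all <- function(d, tol = 1e-8) {
  e <- eigen(gower_center(as.matrix(d)), symmetric = TRUE)
  keep <- which(e$values > tol * max(abs(e$values)))
  sweep(e$vectors[, keep, drop = FALSE], 2, sqrt(e$values[keep]), `*`)
}

#' PERMANOVA: permutational pseudo-F for group differences
#'
#' Partitions the Gower-centered distance matrix into among- and
#' within-group sums of squares; the p-value comes from permuting group
#' labels (equivalently, jointly permuting rows/columns of the response).
#'
#' @param d host distance matrix.
#' @param groups group label per host (>= 2 groups).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `pseudo_F`, `p`, `df` (among, residual).
#' @export
permanova_groups <- function(d, groups, n_perm = 999, seed = 1) {
  d <- host_distance_matrix(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) stop("one group label per host required")
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  X <- stats::model.matrix(~ groups)[, -1, drop = FALSE]
  hm <- hat_matrix(X)
  G <- gower_center(d)
  res <- pseudo_f_perm(G, hm$H, hm$m, n_perm, seed)
  res$df <- c(among = hm$m, residual = nrow(d) - hm$m - 1)
  res
}

#' Procrustes non-randomness test between two ordinations
#'
#' Superimposes two configurations of the same hosts (translation, scaling,
#' rotation, reflection allowed) and tests the symmetric residual `m2`
#' against row-permutation nulls. Wraps [vegan::protest()] with an explicit
#' seed.
#'
#' @param coords1,coords2 host coordinate matrices with matching rows.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `m2` (minimized residual sum of squares), `p` and the
#'   underlying `protest` object.
#' @export
procrustes_test <- function(coords1, coords2, n_perm = 999, seed = 1) {
  coords1 <- as.matrix(coords1)
  coords2 <- as.matrix(coords2)
  if (nrow(coords1) != nrow(coords2)) stop("configurations must share hosts")
  if (nrow(coords1) < 3) stop("need at least 3 hosts")
  set.seed(as.integer(seed))
  pt <- vegan::protest(coords1, coords2, permutations = n_perm)
  list(m2 = pt$ss, p = pt$signif, protest = pt)
}
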