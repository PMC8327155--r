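# Microbiome-based dietary-niche prediction: diet distance construction,
# diet-correlated taxon selection, PCA ordination, binomial logistic
# classification, exhaustive leave-1/leave-2-out cross-validation and
# projection of a new (ancient) sample.

#' Euclidean diet distance matrix from consumption profiles
#'
#' @param profiles data frame with a `host` column and one numeric column
#'   per food category (consumption fractions in \[0, 1\]).
#' @return a host distance matrix.
#' @export
diet_distance <- function(profiles) {
  profiles <- as.data.frame(profiles)
  if (!"host" %in% names(profiles)) stop("profiles need a 'host' column")
  m <- as.matrix(profiles[setdiff(names(profiles), c("host", "group"))])
  if (!is.numeric(m) || ncol(m) < 1) stop("no numeric food-category columns")
  if (any(m < 0 | m > 1)) stop("consumption fractions must lie in [0, 1]")
  rownames(m) <- profiles$host
  host_distance_matrix(as.matrix(dist(m)), "diet matrix")
}

#' Select taxa whose occurrence tracks the diet distance matrix
#'
#' Each taxon's host-pair presence-mismatch distance is Mantel-tested
#' against the diet matrix; taxa with p <= alpha are retained. Constant
#' taxa (present everywhere or nowhere) carry no signal and are skipped.
#' Optional Benjamini-Hochberg adjustment is off by default: the selection
#' is a screening step and the downstream classifier is validated by
#' cross-validation, not by the selection p-values.
#'
#' @param table hosts-by-taxa `abundance_table`.
#' @param diet_d host diet distance matrix.
#' @param alpha retention threshold on the Mantel p-value.
#' @param n_perm Mantel permutations.
#' @param seed integer seed.
#' @param fdr apply BH adjustment before thresholding.
#' @return character vector of retained taxon ids, with the per-taxon test
#'   table in the `"tests"` attribute and skipped taxa in `"skipped"`.
#' @export
select_diet_taxa <- function(table, diet_d, alpha = 0.05, n_perm = 999,
                             seed = 1, fdr = FALSE) {
  diet_d <- align_to(diet_d, rownames(table), "diet matrix")
  pa <- unclass(table) > 0
  taxa <- colnames(pa)
  seeds <- sub_seeds(seed, length(taxa))
  keeprow <- list()
  skipped <- character()
  for (t in seq_along(taxa)) {
    pres <- pa[, t]
    if (all(pres) || !any(pres)) { skipped <- c(skipped, taxa[t]); next }
    mt <- mantel_test(presence_mismatch(setNames(pres, rownames(pa))),
                      diet_d, n_perm = n_perm, seed = seeds[t])
    keeprow[[length(keeprow) + 1]] <- data.frame(
      taxon = taxa[t], r = mt$r, p = mt$p, stringsAsFactors = FALSE)
  }
  tests <- if (length(keeprow)) do.call(rbind, keeprow) else
    data.frame(taxon = character(), r = numeric(), p = numeric())
  pv <- if (fdr) p.adjust(tests$p, "BH") else tests$p
  sel <- tests$taxon[pv <= alpha]
  structure(sel, tests = tests, skipped = skipped)
}

# ridge-penalized binomial logistic fit on one predictor; used when the
# two classes are perfectly separated and maximum likelihood diverges
ridge_logistic <- function(x, y, lambda = 1e-3) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    sum(log1p(exp(-(2 * y - 1) * eta))) + lambda * b[2]^2
  }
  opt <- stats::optim(c(0, 0), nll, method = "BFGS")
  opt$par
}

#' Fit the microbiome-based diet classifier
#'
#' Converts the selected-taxon table to presence/absence, maps hosts with a
#' column-centered (unscaled) PCA, and regresses the binary dietary niche
#' (0 = carnivorous/wolf-like, 1 = omnivorous/dog-like) on the first-axis
#' scores with a binomial logistic model. Perfect separation - likely with
#' a handful of hosts - switches the fit to a small ridge penalty, which
#' leaves threshold predictions unchanged while keeping coefficients
#' finite.
#'
#' @param table hosts-by-taxa `abundance_table` restricted to the selected
#'   taxa.
#' @param labels named vector of `"carnivorous"` / `"omnivorous"` (or
#'   0/1) per host; both classes must occur.
#' @param threshold decision threshold on the predicted probability.
#' @return a `diet_model`: selected taxa, centering vector, first-axis
#'   loadings, logistic intercept/slope, threshold, training scores.
#' @export
fit_diet_model <- function(table, labels, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  if (nrow(table) < 3) stop("need at least 3 hosts")
  y <- diet_label_to_binary(labels[rownames(table)])
  if (length(unique(y)) < 2) stop("both dietary classes must be present")
  pa <- (unclass(table) > 0) * 1
  pc <- prcomp(pa, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1]
  fit <- suppressWarnings(glm(y ~ scores, family = binomial()))
  separated <- !fit$converged || any(abs(coef(fit)) > 15)
  if (separated) {
    b <- ridge_logistic(scores, y)
  } else {
    b <- unname(coef(fit))
  }
  structure(list(taxa = colnames(table), center = pc$center,
                 loadings = pc$rotation[, 1], intercept = b[1],
                 slope = b[2], threshold = threshold,
                 train_scores = scores, train_labels = y,
                 ridge = separated),
            class = "diet_model")
}

diet_label_to_binary <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% 0:1)) stop("numeric labels must be 0/1")
    return(as.numeric(labels))
  }
  lab <- tolower(as.character(labels))
  if (!all(lab %in% c("carnivorous", "omnivorous", "wolf-like", "dog-like")))
    stop("labels must be carnivorous/omnivorous")
  as.numeric(lab %in% c("omnivorous", "dog-like"))
}

#' Predict the dietary niche of a new host
#'
#' The presence/absence profile is aligned to the model's taxon list
#' (missing taxa treated as absent and reported), centered and projected on
#' the stored first axis, and pushed through the logistic model. The
#' probability scale runs from 0 (wolf-like, carnivorous) to 1 (dog-like,
#' omnivorous); scores at exactly the threshold are called omnivorous (the
#' boundary is assigned to the positive class).
#'
#' @param model a `diet_model`.
#' @param profile named presence/absence (or count) vector for the new
#'   host, or a one-row abundance table.
#' @return list with `probability`, `class`, `score` (axis-1 coordinate),
#'   `missing_taxa` and `low_support` (no selected taxon observed).
#' @export
predict_diet <- function(model, profile) {
  if (is.matrix(profile)) profile <- profile[1, ]
  pres <- setNames(numeric(length(model$taxa)), model$taxa)
  overlap <- intersect(names(profile), model$taxa)
  if (length(overlap) == 0) stop("profile shares no taxa with the model")
  pres[overlap] <- as.numeric(profile[overlap] > 0)
  missing_taxa <- setdiff(model$taxa, names(profile))
  score <- sum((pres - model$center) * model$loadings)
  prob <- plogis(model$intercept + model$slope * score)
  list(probability = unname(prob),
       class = if (prob >= model$threshold) "omnivorous" else "carnivorous",
       score = unname(score),
       missing_taxa = missing_taxa,
       low_support = !any(pres > 0))
}

#' Exhaustive leave-1-out and leave-2-out cross-validation
#'
#' Enumerates every split that holds out 1 or 2 hosts (45 splits for nine
#' hosts), refits the full procedure on each training set - taxon selection
#' against the diet matrix inside the fold (no leakage), PCA, logistic
#' regression - and predicts the held-out hosts at the model threshold.
#' Training folds with a single class are skipped and reported. When a fold
#' selects no taxon, an intercept-only model (training class frequency) is
#' used. Setting `select_on_full = TRUE` reproduces the leakage-prone
#' variant that selects taxa once on the full data; it exists only for
#' comparison and inflates null accuracy.
#'
#' @param table hosts-by-taxa `abundance_table`.
#' @param diet_d host diet distance matrix (drives per-fold selection).
#' @param labels dietary niche labels per host.
#' @param split_sizes held-out set sizes (default `c(1, 2)`).
#' @param alpha,n_perm selection parameters per fold.
#' @param seed integer seed.
#' @param select_on_full disable fold-internal selection (leakage variant).
#' @return list with `accuracy` (mean over all held-out predictions),
#'   `splits` (per-prediction records) and `n_splits`.
#' @export
cross_validate <- function(table, diet_d, labels, split_sizes = c(1, 2),
                           alpha = 0.05, n_perm = 999, seed = 1,
                           select_on_full = FALSE) {
  hosts <- rownames(table)
  n <- length(hosts)
  if (n < 4) stop("need at least 4 hosts")
  y <- diet_label_to_binary(labels[hosts])
  names(y) <- hosts
  holdouts <- unlist(lapply(split_sizes, function(k)
    apply(combn(n, k), 2, identity, simplify = FALSE)), recursive = FALSE)
  seeds <- sub_seeds(seed, length(holdouts))
  full_sel <- if (select_on_full)
    select_diet_taxa(table, diet_d, alpha, n_perm, seed = sub_seeds(seed + 1, 1)) else NULL
  recs <- list()
  skipped <- 0L
  for (si in seq_along(holdouts)) {
    test_idx <- holdouts[[si]]
    train <- hosts[-test_idx]
    if (length(unique(y[train])) < 2) { skipped <- skipped + 1L; next }
    tr_tab <- abundance_table(unclass(table)[train, , drop = FALSE])
    sel <- if (select_on_full) full_sel else
      select_diet_taxa(tr_tab, diet_d[train, train], alpha, n_perm,
                       seed = seeds[si])
    if (length(sel) >= 1) {
      model <- fit_diet_model(
        abundance_table(unclass(tr_tab)[, sel, drop = FALSE]), y[train])
      preds <- lapply(hosts[test_idx], function(h)
        predict_diet(model, unclass(table)[h, ]))
      prob <- vapply(preds, `[[`, numeric(1), "probability")
    } else {
      prob <- rep(mean(y[train]), length(test_idx))   # intercept-only fallback
    }
    pred_class <- as.numeric(prob >= 0.5)
    recs[[length(recs) + 1]] <- data.frame(
      split = si, host = hosts[test_idx], held_out = length(test_idx),
      probability = prob, predicted = pred_class, truth = y[hosts[test_idx]],
      correct = pred_class == y[hosts[test_idx]],
      row.names = NULL, stringsAsFactors = FALSE)
  }
  splits <- do.call(rbind, recs)
  list(accuracy = mean(splits$correct), splits = splits,
       n_splits = length(holdouts), n_skipped = skipped)
}
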