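separable_diet_data <- function(seed = 5, n_noise = 20) {
  set.seed(seed)
  hosts <- c(paste0("wolf", 1:4), paste0("dog", 1:5))
  grp <- rep(c("wolf", "dog"), c(4, 5))
  noise <- matrix(rbinom(9 * n_noise, 1, 0.5), 9, n_noise,
                  dimnames = list(hosts, paste0("noise", seq_len(n_noise))))
  sig <- cbind(matrix(rep(c(1, 0), c(4, 5)), 9, 6),
               matrix(rep(c(0, 1), c(4, 5)), 9, 6))
  colnames(sig) <- paste0("diet", 1:12)
  meta <- host_meta(data.frame(host = hosts, group = grp))
  prof <- simulate_diet_profiles(meta, seed = seed + 1)
  list(table = abundance_table(cbind(sig, noise)),
       diet_d = diet_distance(prof),
       labels = setNames(ifelse(grp == "wolf", "carnivorous", "omnivorous"),
                         hosts))
}

test_that("diet distances are plain Euclidean distances on fraction vectors", {
  prof <- data.frame(host = c("a", "b", "c"),
                     meat = c(1, 0, 0.6), carb = c(0, 1, 0.4))
  d <- diet_distance(prof)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], sqrt(2), tolerance = 1e-12)
  expect_equal(diet_distance(data.frame(host = c("x", "y"),
                                        meat = c(0.6, 0.9),
                                        carb = c(0.4, 0.1)))["x", "y"],
               sqrt(0.09 + 0.09), tolerance = 1e-12)
  expect_error(diet_distance(data.frame(host = "x", meat = 1.4)), "fractions")
})

test_that("taxon selection keeps perfect diet trackers and skips constant taxa", {
  dat <- separable_diet_data()
  sel <- select_diet_taxa(dat$table, dat$diet_d, n_perm = 199, seed = 2)
  expect_true(all(paste0("diet", 1:12) %in% sel))
  tests <- attr(sel, "tests")
  expect_equal(min(tests$p[grepl("^diet", tests$taxon)]), 1 / 200)

  with_const <- abundance_table(cbind(unclass(dat$table),
                                      everywhere = rep(1, 9)))
  sel2 <- select_diet_taxa(with_const, dat$diet_d, n_perm = 99, seed = 3)
  expect_true("everywhere" %in% attr(sel2, "skipped"))
})

test_that("the classifier separates planted blocks and projects deterministically", {
  dat <- separable_diet_data()
  sel <- paste0("diet", 1:12)
  tab <- abundance_table(unclass(dat$table)[, sel])
  model <- fit_diet_model(tab, dat$labels)
  train_pred <- vapply(rownames(tab), function(h)
    predict_diet(model, unclass(dat$table)[h, ])$probability, numeric(1))
  expect_equal(unname(train_pred >= 0.5),
               unname(dat$labels[rownames(tab)] == "omnivorous"))

  # a duplicated host projects to the identical axis-1 score
  dup <- predict_diet(model, unclass(dat$table)["dog1", ])
  expect_equal(dup$score, unname(model$train_scores["dog1"]), tolerance = 1e-9)

  # probability is monotone in the axis score
  grid <- seq(min(model$train_scores), max(model$train_scores), length.out = 25)
  probs <- plogis(model$intercept + model$slope * grid)
  expect_true(all(diff(probs) > 0) || all(diff(probs) < 0))

  # all-absent profile: deterministic, flagged low-support
  empty <- setNames(rep(0, 12), sel)
  p0 <- predict_diet(model, empty)
  expect_true(p0$low_support)
  expect_equal(p0$probability, predict_diet(model, empty)$probability)
  expect_error(predict_diet(model, c(unrelated = 1)), "no taxa")
  expect_error(fit_diet_model(tab, setNames(rep("omnivorous", 9),
                                            rownames(tab))), "both")
})

test_that("exhaustive cross-validation enumerates 45 splits and is perfect when separable", {
  dat <- separable_diet_data()
  cv <- cross_validate(dat$table, dat$diet_d, dat$labels, alpha = 0.1,
                       n_perm = 199, seed = 4)
  expect_equal(cv$n_splits, choose(9, 1) + choose(9, 2))
  expect_equal(cv$accuracy, 1.0)
  # per-split outcomes reproduce exactly
  cv2 <- cross_validate(dat$table, dat$diet_d, dat$labels, alpha = 0.1,
                        n_perm = 199, seed = 4)
  expect_identical(cv$splits, cv2$splits)
})

test_that("label shuffling drives cross-validated accuracy to chance", {
  dat <- separable_diet_data(n_noise = 10)
  accs <- vapply(1:8, function(s) {
    set.seed(900 + s)
    shuffled <- setNames(sample(dat$labels), names(dat$labels))
    cross_validate(dat$table, dat$diet_d, shuffled, alpha = 0.1,
                   n_perm = 49, seed = s)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.3)
  expect_lt(mean(accs), 0.7)
})
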