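toy_training_set <- function(n_per_class = 10, n_noise = 9, sep = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm((1 + n_noise) * n), 1 + n_noise, n,
              dimnames = list(c("informative", paste0("noise", seq_len(n_noise))),
                              paste0("s", seq_len(n))))
  labels <- rep(c("one", "two"), each = n_per_class)
  X["informative", labels == "two"] <- X["informative", labels == "two"] + sep
  list(X = X, labels = labels)
}

test_that("delta = 0 reproduces the class means and matches the formula oracle", {
  toy <- toy_training_set()
  fit <- train_shrunken_centroids(toy$X, toy$labels, delta = 0)
  oc <- oracle_shrunken(toy$X, toy$labels, delta = 0)
  expect_equal(fit$shrunken_centroids, oc$centroids, tolerance = 1e-12)
  expect_equal(fit$d, oc$d, tolerance = 1e-12)
  expect_equal(fit$s, oc$s, tolerance = 1e-12)
  expect_equal(fit$s0, oc$s0, tolerance = 1e-12)
  expect_equal(sum(fit$priors), 1)
})

test_that("the shrinkage identity holds at arbitrary delta against the oracle", {
  set.seed(14)
  for (rep in 1:10) {
    n_f <- sample(3:12, 1)
    nlab <- sample(2:4, 1)
    labels <- rep(paste0("c", seq_len(nlab)), each = 5)
    X <- matrix(rnorm(n_f * length(labels)), n_f, length(labels),
                dimnames = list(paste0("f", seq_len(n_f)), NULL))
    colnames(X) <- paste0("s", seq_along(labels))
    delta <- runif(1, 0, 2)
    fit <- train_shrunken_centroids(X, labels, delta = delta)
    oc <- oracle_shrunken(X, labels, delta = delta)
    expect_equal(fit$shrunken_centroids, oc$shrunken, tolerance = 1e-10)
    # soft-threshold bound
    expect_true(all(abs(fit$d_shrunk) <= pmax(abs(fit$d) - delta, 0) + 1e-12))
  }
})

test_that("full shrinkage collapses to the overall centroid and the prior argmax", {
  toy <- toy_training_set()
  dmax <- max(abs(train_shrunken_centroids(toy$X, toy$labels, 0)$d))
  fit <- train_shrunken_centroids(toy$X, toy$labels, delta = dmax + 1,
                                  priors = c(one = 0.9, two = 0.1))
  expect_equal(fit$shrunken_centroids[, "one"], fit$overall_centroid,
               tolerance = 1e-12)
  expect_equal(fit$shrunken_centroids[, "two"], fit$overall_centroid,
               tolerance = 1e-12)
  pr <- predict(fit, toy$X)
  expect_true(all(pr$predicted == "one"))
})

test_that("an intermediate delta keeps only the informative feature", {
  toy <- toy_training_set()
  fit0 <- train_shrunken_centroids(toy$X, toy$labels, 0)
  d_noise <- max(abs(fit0$d[-1, ]))
  d_signal <- max(abs(fit0$d[1, ]))
  expect_gt(d_signal, d_noise)
  fit <- train_shrunken_centroids(toy$X, toy$labels,
                                  delta = (d_noise + d_signal) / 2)
  active <- rowSums(fit$d_shrunk != 0) > 0
  expect_identical(names(which(active)), "informative")
})

test_that("active-feature count is monotone non-increasing in delta", {
  toy <- toy_training_set(n_noise = 20, sep = 3, seed = 5)
  fit0 <- train_shrunken_centroids(toy$X, toy$labels, 0)
  grid <- seq(0, max(abs(fit0$d)) * 1.1, length.out = 25)
  counts <- vapply(grid, function(d)
    n_active_features(train_shrunken_centroids(toy$X, toy$labels, d)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0)
})

test_that("training validates classes and delta", {
  toy <- toy_training_set()
  expect_error(train_shrunken_centroids(toy$X, toy$labels, delta = -1),
               "non-negative")
  expect_error(train_shrunken_centroids(toy$X, rep("one", ncol(toy$X))),
               "2 classes")
  labels <- toy$labels; labels[1] <- "lonely"
  labels[labels == "one"][-1] <- "one"
  expect_error(train_shrunken_centroids(toy$X, labels), "lonely")
})

test_that("marker panels take the top |d'| per class with overlap handling", {
  toy <- toy_training_set(n_noise = 9)
  fit <- train_shrunken_centroids(toy$X, toy$labels, 0)
  mk <- select_subgroup_markers(fit, n_per_class = 1)
  # one informative feature dominates both classes -> union of size 1
  expect_identical(mk$panel, "informative")
  expect_identical(mk$per_class$one, "informative")
  expect_identical(mk$per_class$two, "informative")

  mk3 <- select_subgroup_markers(fit, n_per_class = 3)
  expect_lte(length(mk3$panel), 6)
  expect_error(select_subgroup_markers(fit, n_per_class = 99), "exceeds")
})

test_that("disjoint class signatures give a panel of exactly k * n_per_class", {
  sc <- generate_subtyped_cohort(subtyped_cohort_spec(
    n_samples = 60, k_true = 3, n_signature_genes_per_group = 10,
    n_noise_genes = 20, signature_effect = 4, noise_sd = 0.5,
    survival_scales_years = c(5, 10, 15), seed = 6))
  fit <- train_shrunken_centroids(sc$expr, sc$group, 0)
  mk <- select_subgroup_markers(fit, n_per_class = 5)
  expect_equal(length(mk$panel), 15)
})

test_that("posteriors are normalized and centroid samples classify to their class", {
  sc <- generate_subtyped_cohort(subtyped_cohort_spec(
    n_samples = 60, k_true = 3, n_signature_genes_per_group = 10,
    n_noise_genes = 10, signature_effect = 5, noise_sd = 0.5,
    survival_scales_years = c(5, 10, 15), seed = 7))
  fit <- train_shrunken_centroids(sc$expr, sc$group, 0)
  # samples placed exactly at the class centroids
  probes <- fit$shrunken_centroids
  colnames(probes) <- paste0("probe", seq_len(ncol(probes)))
  pr <- predict(fit, probes)
  expect_identical(pr$predicted, fit$classes)
  expect_true(all(pr$max_posterior > 0.99))

  set.seed(8)
  rnd <- matrix(rnorm(nrow(probes) * 1000, 0, 5), nrow(probes), 1000,
                dimnames = list(rownames(probes), paste0("r", 1:1000)))
  pr2 <- predict(fit, rnd)
  post <- as.matrix(pr2[, grep("^posterior_", colnames(pr2))])
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))
})

test_that("reduced model equals the Euclidean nearest-centroid oracle", {
  set.seed(9)
  for (rep in 1:25) {
    nf <- sample(3:8, 1)
    labels <- rep(c("a", "b", "c"), each = 6)
    X <- matrix(rnorm(nf * 18), nf, 18,
                dimnames = list(paste0("f", 1:nf), paste0("s", 1:18)))
    fit <- train_shrunken_centroids(X, labels, delta = 0, priors = "uniform")
    # force the reduced regime: equal dispersions, no offset
    fit$s[] <- 1; fit$s0 <- 0
    Y <- matrix(rnorm(nf * 10), nf, 10,
                dimnames = list(paste0("f", 1:nf), paste0("y", 1:10)))
    pr <- predict(fit, Y)
    oc <- oracle_nearest_centroid(Y, fit$class_centroids)
    expect_identical(unname(pr$predicted), unname(oc))
  }
})

test_that("cross-validated threshold is deterministic and prunes noise", {
  toy <- toy_training_set(n_per_class = 15, n_noise = 9, sep = 5, seed = 10)
  cv1 <- cross_validate_threshold(toy$X, toy$labels, folds = 3, seed = 2)
  cv2 <- cross_validate_threshold(toy$X, toy$labels, folds = 3, seed = 2)
  expect_identical(cv1, cv2)
  expect_equal(min(cv1$table$error), 0)
  fit <- train_shrunken_centroids(toy$X, toy$labels, delta = cv1$delta_star)
  active <- names(which(rowSums(fit$d_shrunk != 0) > 0))
  expect_identical(active, "informative")
  expect_error(cross_validate_threshold(toy$X, toy$labels, folds = 20),
               "folds")
})

test_that("classification tolerates small panel gaps but rejects large ones", {
  sc <- generate_subtyped_cohort(subtyped_cohort_spec(
    n_samples = 60, k_true = 3, n_signature_genes_per_group = 10,
    n_noise_genes = 20, signature_effect = 4, noise_sd = 0.5,
    survival_scales_years = c(5, 10, 15), seed = 11))
  fit <- train_shrunken_centroids(sc$expr, sc$group, 0)
  X <- sc$expr$values
  drop_few <- X[-(1:3), ] # 3 of 50 features missing: 6% <= 10%
  pr <- predict(fit, drop_few)
  expect_equal(attr(pr, "n_shared_features"), nrow(X) - 3)
  drop_many <- X[-(1:10), ]
  expect_error(predict(fit, drop_many), "missing")
})
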