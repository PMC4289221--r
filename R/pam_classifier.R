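#' Train a nearest-shrunken-centroid (PAM) subgroup classifier
#'
#' Computes, per feature `i` and class `k`, the standardized centroid
#' difference `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, where `xbar_i` is the overall centroid,
#' `xbar_ik` the class centroid, `s_i` the pooled within-class standard
#' deviation and `s0` the median of the `s_i` (a guard against near-zero
#' variance features). Differences are soft-thresholded by the shrinkage
#' parameter `delta`:
#' `d'_ik = sign(d_ik) * max(0, |d_ik| - delta)`, and the shrunken centroids
#' reconstructed as `xbar'_ik = xbar_i + m_k * (s_i + s0) * d'_ik`. With
#' `delta = 0` the shrunken centroids equal the class means; for `delta`
#' beyond `max |d_ik|` they all collapse to the overall centroid.
#'
#' @param X an [expr_matrix] or numeric matrix (features x samples).
#' @param labels class label per sample (coerced to factor); every class
#'   needs at least 2 samples.
#' @param delta non-negative shrinkage threshold.
#' @param priors class prior probabilities: `"class_frequency"` (default),
#'   `"uniform"`, or a named numeric vector summing to 1.
#' @return An object of class `shrunken_centroids`.
#' @export
train_shrunken_centroids <- function(X, labels, delta = 0,
                                     priors = "class_frequency") {
  if (inherits(X, "expr_matrix")) X <- X$values
  stopifnot(is.matrix(X), is.numeric(X))
  if (is.null(rownames(X))) rownames(X) <- sprintf("feature%d", seq_len(nrow(X)))
  if (delta < 0) stop("delta must be non-negative")
  labels <- factor(labels)
  if (length(labels) != ncol(X)) stop("one label per sample required")
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  n_k <- table(labels)
  if (any(n_k < 2))
    stop("every class needs >= 2 samples; offending: ",
         paste(names(n_k)[n_k < 2], collapse = ", "))

  n <- ncol(X)
  K <- nlevels(labels)
  classes <- levels(labels)

  overall <- rowMeans(X)
  centroids <- vapply(classes, function(cl) rowMeans(X[, labels == cl, drop = FALSE]),
                      numeric(nrow(X)))
  # pooled within-class variance, n - K denominator
  ss <- matrix(0, nrow(X), 1)
  for (cl in classes) {
    sub <- X[, labels == cl, drop = FALSE]
    ss <- ss + rowSums((sub - centroids[, cl])^2)
  }
  s_i <- sqrt(as.vector(ss) / (n - K))
  s0 <- stats::median(s_i)

  m_k <- sqrt(1 / as.numeric(n_k) - 1 / n)
  names(m_k) <- classes
  dimnames(centroids) <- list(rownames(X), classes)
  names(overall) <- names(s_i) <- rownames(X)
  denom <- outer(s_i + s0, m_k) # features x classes
  d_ik <- (centroids - overall) / denom
  d_shrunk <- sign(d_ik) * pmax(abs(d_ik) - delta, 0)
  shrunken <- overall + denom * d_shrunk

  if (identical(priors, "class_frequency")) {
    pri <- as.numeric(n_k) / n
  } else if (identical(priors, "uniform")) {
    pri <- rep(1 / K, K)
  } else {
    if (!is.numeric(priors) || length(priors) != K || abs(sum(priors) - 1) > 1e-8)
      stop("numeric priors must have one entry per class and sum to 1")
    pri <- as.numeric(priors[classes])
  }
  names(pri) <- classes

  structure(list(classes = classes,
                 feature_ids = rownames(X),
                 overall_centroid = overall,
                 class_centroids = centroids,
                 shrunken_centroids = shrunken,
                 d = d_ik,
                 d_shrunk = d_shrunk,
                 s = s_i, s0 = s0,
                 m_k = m_k, n_k = as.integer(n_k),
                 priors = pri, delta = delta),
            class = "shrunken_centroids")
}

#' @export
print.shrunken_centroids <- function(x, ...) {
  cat(sprintf("shrunken_centroids: %d classes, %d features, delta = %g\n",
              length(x$classes), length(x$feature_ids), x$delta))
  cat(sprintf("  features with a nonzero shrunken difference: %d\n",
              sum(rowSums(x$d_shrunk != 0) > 0)))
  invisible(x)
}

#' Number of features surviving shrinkage
#' @param model a `shrunken_centroids` fit.
#' @return Count of features with any nonzero shrunken difference.
#' @export
n_active_features <- function(model) {
  stopifnot(inherits(model, "shrunken_centroids"))
  sum(rowSums(model$d_shrunk != 0) > 0)
}

#' Extract subgroup marker panels from a shrunken-centroid model
#'
#' For each class, the `n_per_class` features with the largest absolute
#' shrunken difference `|d'_ik|` (ties broken lexicographically by feature
#' ID). Returns the union panel with per-class membership; a feature topping
#' the list for several classes appears once in the panel with all its
#' classes annotated, so the union can be smaller than
#' `n_per_class * n_classes`.
#'
#' @param model a `shrunken_centroids` fit.
#' @param n_per_class markers per class (default 50, giving the 300-feature
#'   panel for six subgroups).
#' @return List with `panel` (character vector of feature IDs) and
#'   `per_class` (named list of per-class marker vectors).
#' @export
select_subgroup_markers <- function(model, n_per_class = 50) {
  stopifnot(inherits(model, "shrunken_centroids"))
  if (n_per_class > length(model$feature_ids))
    stop("n_per_class exceeds the number of model features")
  per_class <- lapply(model$classes, function(cl) {
    score <- abs(model$d_shrunk[, cl])
    ord <- order(-score, model$feature_ids)
    model$feature_ids[ord[seq_len(n_per_class)]]
  })
  names(per_class) <- model$classes
  panel <- unique(unlist(per_class, use.names = FALSE))
  list(panel = panel, per_class = per_class)
}

#' Classify samples with a shrunken-centroid model
#'
#' The discriminant for class `k` is
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 * log pi_k`;
#' a sample is assigned to the class minimizing it, with posterior
#' probabilities `exp(-delta_k / 2)` normalized across classes (computed
#' stably by subtracting the minimum discriminant). A call is flagged
#' confident when its maximum posterior exceeds `confidence` (default 0.80).
#'
#' Model features missing from `X` are tolerated up to `max_missing`
#' (fraction of the panel, default 0.10) by dropping those terms from every
#' class discriminant symmetrically — cross-platform panels rarely match
#' perfectly.
#'
#' @param model a `shrunken_centroids` fit.
#' @param X an [expr_matrix] or numeric matrix with features in rows.
#' @param confidence posterior threshold for the confident flag.
#' @param max_missing maximum tolerated fraction of missing model features.
#' @param ... unused.
#' @return A data.frame of class `subgroup_calls`: `sample_id`,
#'   `predicted`, `posterior_<class>` columns, `max_posterior`, `confident`.
#' @export
predict.shrunken_centroids <- function(object, X, confidence = 0.80,
                                       max_missing = 0.10, ...) {
  model <- object
  if (inherits(X, "expr_matrix")) X <- X$values
  stopifnot(is.matrix(X), is.numeric(X))
  shared <- intersect(model$feature_ids, rownames(X))
  missing_frac <- 1 - length(shared) / length(model$feature_ids)
  if (missing_frac > max_missing)
    stop(sprintf("%.0f%% of model features missing from input (allowed %.0f%%)",
                 100 * missing_frac, 100 * max_missing))
  idx <- match(shared, model$feature_ids)
  Xs <- X[shared, , drop = FALSE]
  cent <- model$shrunken_centroids[idx, , drop = FALSE]
  sden <- (model$s[idx] + model$s0)^2

  K <- length(model$classes)
  disc <- matrix(NA_real_, ncol(Xs), K, dimnames = list(colnames(Xs), model$classes))
  for (k in seq_len(K)) {
    disc[, k] <- colSums((Xs - cent[, k])^2 / sden) - 2 * log(model$priors[k])
  }
  dmin <- apply(disc, 1, min)
  post <- exp(-(disc - dmin) / 2)
  post <- post / rowSums(post)
  pred <- model$classes[apply(disc, 1, which.min)]

  out <- data.frame(sample_id = colnames(Xs), predicted = pred,
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(post) <- paste0("posterior_", model$classes)
  out <- cbind(out, as.data.frame(post, row.names = NULL))
  out$max_posterior <- apply(post, 1, max)
  out$confident <- out$max_posterior > confidence
  attr(out, "n_shared_features") <- length(shared)
  class(out) <- c("subgroup_calls", "data.frame")
  out
}

#' Cross-validate the shrinkage threshold
#'
#' Stratified `folds`-fold cross-validation of the misclassification error
#' over a grid of shrinkage thresholds; returns the largest threshold whose
#' mean error is within one standard error of the minimum (the usual 1-SE
#' rule, favouring sparser models).
#'
#' @param X features-x-samples matrix or [expr_matrix].
#' @param labels class labels.
#' @param delta_grid thresholds to evaluate (default 30 values from 0 to the
#'   largest `|d_ik|` of a full-data fit).
#' @param folds number of folds (default 5); every class must have at least
#'   `folds` samples.
#' @param seed integer seed controlling fold assignment.
#' @return List with `delta_star`, `table` (delta, mean error, SE) and
#'   `folds`.
#' @export
cross_validate_threshold <- function(X, labels, delta_grid = NULL,
                                     folds = 5, seed = 1L) {
  if (inherits(X, "expr_matrix")) X <- X$values
  labels <- factor(labels)
  if (folds < 2) stop("folds must be >= 2")
  n_k <- table(labels)
  if (any(n_k < folds))
    stop("every class needs >= folds samples; offending: ",
         paste(names(n_k)[n_k < folds], collapse = ", "))
  if (is.null(delta_grid)) {
    full <- train_shrunken_centroids(X, labels, delta = 0)
    delta_grid <- seq(0, max(abs(full$d)), length.out = 30)
  }
  set.seed(seed)
  fold_of <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  err <- matrix(NA_real_, folds, length(delta_grid))
  for (f in seq_len(folds)) {
    train_idx <- fold_of != f
    for (d in seq_along(delta_grid)) {
      fit <- train_shrunken_centroids(X[, train_idx, drop = FALSE],
                                      labels[train_idx], delta = delta_grid[d])
      pr <- predict(fit, X[, !train_idx, drop = FALSE])
      err[f, d] <- mean(pr$predicted != as.character(labels[!train_idx]))
    }
  }
  mean_err <- colMeans(err)
  se_err <- apply(err, 2, stats::sd) / sqrt(folds)
  best <- which.min(mean_err)
  within <- which(mean_err <= mean_err[best] + se_err[best])
  delta_star <- max(delta_grid[within])
  list(delta_star = delta_star,
       table = data.frame(delta = delta_grid, error = mean_err, se = se_err),
       folds = folds)
}

#' Serialize a shrunken-centroid model as a flat tab-delimited bundle
#'
#' One block per component (scalars, priors, per-feature statistics,
#' centroid matrices), all plain text, so a trained classifier can be
#' shipped alongside the marker panel and reloaded elsewhere.
#'
#' @param model a `shrunken_centroids` fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shrunken_centroids <- function(model, path) {
  stopifnot(inherits(model, "shrunken_centroids"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#delta\t%.17g", model$delta), con)
  writeLines(sprintf("#s0\t%.17g", model$s0), con)
  writeLines(paste0("#classes\t", paste(model$classes, collapse = "\t")), con)
  writeLines(paste0("#n_k\t", paste(model$n_k, collapse = "\t")), con)
  writeLines(paste0("#priors\t",
                    paste(sprintf("%.17g", model$priors), collapse = "\t")), con)
  df <- data.frame(feature_id = model$feature_ids,
                   overall = model$overall_centroid,
                   s = model$s,
                   model$shrunken_centroids,
                   check.names = FALSE)
  colnames(df) <- c("feature_id", "overall", "s",
                    paste0("centroid_", model$classes))
  utils::write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reload a serialized shrunken-centroid model
#'
#' Restores the subset of the fit needed for classification (shrunken
#' centroids, dispersions, offset, priors, threshold).
#'
#' @param path path written by [write_shrunken_centroids()].
#' @return A `shrunken_centroids` object usable with [predict.shrunken_centroids()].
#' @export
read_shrunken_centroids <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "\t"))]
    strsplit(sub(paste0("^#", key, "\t"), "", ln), "\t")[[1]]
  }
  classes <- get("classes")
  df <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                          stringsAsFactors = FALSE)
  shrunken <- as.matrix(df[, paste0("centroid_", classes), drop = FALSE])
  dimnames(shrunken) <- list(df$feature_id, classes)
  structure(list(classes = classes,
                 feature_ids = df$feature_id,
                 overall_centroid = stats::setNames(df$overall, df$feature_id),
                 class_centroids = shrunken,
                 shrunken_centroids = shrunken,
                 d = NULL,
                 d_shrunk = NULL,
                 s = stats::setNames(df$s, df$feature_id),
                 s0 = as.numeric(get("s0")),
                 m_k = NULL,
                 n_k = as.integer(get("n_k")),
                 priors = stats::setNames(as.numeric(get("priors")), classes),
                 delta = as.numeric(get("delta"))),
            class = "shrunken_centroids")
}
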