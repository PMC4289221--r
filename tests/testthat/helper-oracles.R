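# Brute-force oracles kept deliberately naive and independent of the
# package's vectorized implementations.

# b/w decomposition: loops over tumors, explicit variance formulas
oracle_bw <- function(values, pre_ids, post_ids) {
  nt <- length(pre_ids)
  t(apply(values, 1, function(x) {
    pair_means <- numeric(nt)
    sq_half_diffs <- numeric(nt)
    for (i in seq_len(nt)) {
      p <- x[pre_ids[i]]; q <- x[post_ids[i]]
      pair_means[i] <- (p + q) / 2
      sq_half_diffs[i] <- (p - q)^2 / 2
    }
    mu <- sum(pair_means) / nt
    b <- sum((pair_means - mu)^2) / (nt - 1)
    w <- sum(sq_half_diffs) / nt
    c(b = b, w = w)
  }))
}

# shrunken-centroid statistics recomputed term by term from the definitions
oracle_shrunken <- function(X, labels, delta) {
  labels <- factor(labels)
  classes <- levels(labels)
  n <- ncol(X); K <- length(classes)
  overall <- apply(X, 1, mean)
  out <- list()
  s2 <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    acc <- 0
    for (cl in classes) {
      xi <- X[i, labels == cl]
      acc <- acc + sum((xi - mean(xi))^2)
    }
    s2[i] <- acc / (n - K)
  }
  s <- sqrt(s2)
  names(s) <- rownames(X)
  s0 <- stats::median(s)
  d <- matrix(0, nrow(X), K, dimnames = list(rownames(X), classes))
  shrunk <- d
  cent <- d
  for (cl in classes) {
    nk <- sum(labels == cl)
    mk <- sqrt(1 / nk - 1 / n)
    for (i in seq_len(nrow(X))) {
      cent[i, cl] <- mean(X[i, labels == cl])
      d[i, cl] <- (cent[i, cl] - overall[i]) / (mk * (s[i] + s0))
      dp <- sign(d[i, cl]) * max(abs(d[i, cl]) - delta, 0)
      shrunk[i, cl] <- overall[i] + mk * (s[i] + s0) * dp
    }
  }
  list(d = d, shrunken = shrunk, centroids = cent, s = s, s0 = s0)
}

# plain nearest-centroid by Euclidean distance
oracle_nearest_centroid <- function(X, centroids) {
  apply(X, 2, function(x) {
    dists <- apply(centroids, 2, function(cen) sum((x - cen)^2))
    colnames(centroids)[which.min(dists)]
  })
}

# hand-rolled product-limit estimator
oracle_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ev_times <- sort(unique(times[events == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ev_times, surv = surv)
}

# two-group log-rank O/E tabulation over explicit risk sets
oracle_logrank_oe <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O <- c(0, 0); E <- c(0, 0); V <- 0
  for (t in times) {
    n1 <- sum(t1 >= t); n2 <- sum(t2 >= t); n <- n1 + n2
    d1 <- sum(t1 == t & e1 == 1); d2 <- sum(t2 == t & e2 == 1); d <- d1 + d2
    O <- O + c(d1, d2)
    E <- E + d * c(n1, n2) / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V, chisq = (O[1] - E[1])^2 / V)
}

# exhaustive best 2-partition of samples by within-block KL divergence to
# the block mean profile
oracle_best_2partition <- function(V) {
  ns <- ncol(V)
  best <- NULL; best_obj <- Inf
  for (code in 1:(2^(ns - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:ns]
    if (length(unique(grp)) < 2) next
    obj <- 0
    for (g in unique(grp)) {
      block <- V[, grp == g, drop = FALSE]
      mu <- rowMeans(block)
      for (j in seq_len(ncol(block))) {
        v <- block[, j]
        ok <- v > 0 & mu > 0
        obj <- obj + sum(v[ok] * log(v[ok] / mu[ok]) - v[ok] + mu[ok]) +
          sum(mu[!ok])
      }
    }
    if (obj < best_obj) { best_obj <- obj; best <- grp }
  }
  best
}

rand_index_adjusted <- function(a, b) mclust::adjustedRandIndex(a, b)

expect_same_partition <- function(a, b) {
  expect_equal(rand_index_adjusted(a, b), 1)
}
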