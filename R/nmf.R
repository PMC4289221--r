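#' Non-negative matrix factorization by KL multiplicative updates
#'
#' Factorizes a non-negative matrix `V` (features x samples) as `W %*% H`
#' with `W >= 0` (features x k metagene basis) and `H >= 0` (k x samples
#' metagene expression), minimizing the generalized Kullback-Leibler
#' divergence `D(V || WH)` by Lee-Seung multiplicative updates. The update is
#' monotone: the recorded objective trace is non-increasing. Iteration stops
#' when the relative objective decrease over a 10-iteration window falls
#' below `tol`, or at `max_iter`. On return the columns of `W` are scaled to
#' unit sum with the inverse scaling applied to the rows of `H`.
#'
#' @param V non-negative numeric matrix (or [expr_matrix]) with finite
#'   entries.
#' @param k factorization rank; `2 <= k < min(dim(V))`.
#' @param seed integer seed for the random uniform initialization.
#' @param max_iter maximum iterations (default 2000).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param eval_every evaluate the objective every this many iterations
#'   (default 1, a full per-iteration trace; consensus runs use a coarser
#'   setting for speed).
#' @return An object of class `nmf_fit`: list with `W`, `H`,
#'   `objective_trace` (with `trace_iterations` giving the iteration of each
#'   entry), `iterations`, `converged`, `k`, `seed`.
#' @export
nmf_factorize <- function(V, k, seed = 1L, max_iter = 2000L, tol = 1e-6,
                          eval_every = 1L) {
  if (inherits(V, "expr_matrix")) V <- V$values
  if (!is.matrix(V) || !is.numeric(V)) stop("V must be a numeric matrix")
  if (!all(is.finite(V))) stop("V must be finite")
  if (any(V < 0)) stop("V has negative entries; NMF requires non-negative input ",
                       "(see nonneg_fold())")
  if (k < 2 || k >= min(dim(V))) stop("k must satisfy 2 <= k < min(dim(V))")

  set.seed(seed)
  f <- nrow(V); s <- ncol(V)
  # uniform init scaled so the product's mean matches the data mean
  sc <- sqrt(max(mean(V), 1e-12) / (k * 0.25))
  W0 <- matrix(stats::runif(f * k), f, k) * sc
  H0 <- matrix(stats::runif(k * s), k, s) * sc

  res <- nmf_kl_cpp(V, W0, H0, as.integer(max_iter), tol, 10L,
                    as.integer(eval_every))
  dimnames(res$W) <- list(rownames(V), paste0("metagene", seq_len(k)))
  dimnames(res$H) <- list(paste0("metagene", seq_len(k)), colnames(V))
  structure(c(res, list(k = as.integer(k), seed = as.integer(seed))),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("nmf_fit: rank %d, %d x %d, %d iterations (%s), final KL divergence %.6g\n",
              x$k, nrow(x$W), ncol(x$H), x$iterations,
              if (x$converged) "converged" else "max_iter reached",
              utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Metagene assignment of samples
#'
#' Assigns each sample to its dominant metagene (argmax over its column of
#' `H`); exact ties go to the lowest metagene index.
#'
#' @param f an `nmf_fit`.
#' @return Integer vector of metagene labels, one per sample.
#' @export
nmf_labels <- function(f) {
  stopifnot(inherits(f, "nmf_fit"))
  lab <- apply(f$H, 2, which.max) # which.max takes the first (lowest) index on ties
  as.integer(lab)
}

#' Connectivity matrix of an NMF run
#'
#' Binary sample-by-sample matrix with entry (i, j) = 1 iff samples i and j
#' share the same dominant metagene. Invariant to permutations of the
#' metagene labels.
#'
#' @param f an `nmf_fit`.
#' @return A 0/1 matrix with sample dimnames and unit diagonal.
#' @export
connectivity_matrix <- function(f) {
  lab <- nmf_labels(f)
  C <- outer(lab, lab, "==") * 1
  dimnames(C) <- list(colnames(f$H), colnames(f$H))
  C
}

#' Fold a signed matrix into a non-negative one
#'
#' Splits every feature into a positive and a negative half-feature
#' (`max(x, 0)` and `max(-x, 0)`), stacking the negative part below the
#' positive part. This is the standard device for running NMF on
#' standardized (signed) expression data.
#'
#' @param V numeric matrix or [expr_matrix].
#' @return Non-negative matrix with `2 * nrow(V)` rows (suffixes `.pos`,
#'   `.neg`).
#' @export
nonneg_fold <- function(V) {
  if (inherits(V, "expr_matrix")) V <- V$values
  pos <- pmax(V, 0)
  neg <- pmax(-V, 0)
  rownames(pos) <- paste0(rownames(V), ".pos")
  rownames(neg) <- paste0(rownames(V), ".neg")
  rbind(pos, neg)
}

#' Consensus NMF clustering with cophenetic rank selection
#'
#' For each candidate rank `k`, runs `n_runs` randomly initialized NMF
#' factorizations, averages their sample connectivity matrices into a
#' consensus matrix `C_k`, and summarizes the stability of the clustering by
#' the cophenetic coefficient: the Pearson correlation between the
#' consensus-derived distances `1 - C_k` and the cophenetic distances of
#' their average-linkage hierarchical clustering. Stable clusterings give
#' coefficients near 1. Final labels at each `k` are the `k`-cluster cut of
#' that tree.
#'
#' Signed input (e.g. standardized expression) is handled per `fold`: with
#' `"auto"` (default) the matrix is passed through [nonneg_fold()] only when
#' it contains negatives.
#'
#' Per-run seeds are drawn once from a generator seeded with `seed`, so the
#' full consensus is reproducible bit for bit from `(V, k_range, n_runs,
#' seed)`.
#'
#' @param V numeric matrix or [expr_matrix] (features x samples).
#' @param k_range integer vector of candidate ranks (default `2:10`).
#' @param n_runs NMF restarts per rank (default 50).
#' @param seed master seed.
#' @param max_iter,tol per-run convergence controls, see [nmf_factorize()].
#' @param fold `"auto"`, `"none"` or `"split"` (always fold).
#' @return An object of class `nmf_consensus`: list with `k_range`,
#'   `consensus` (list of `C_k`), `cophenetic` (named numeric, `NA` where the
#'   coefficient is undefined), `labels` (list of integer label vectors),
#'   `n_runs`, `seed`.
#' @export
consensus_cluster <- function(V, k_range = 2:10, n_runs = 50, seed = 1L,
                              max_iter = 2000L, tol = 1e-6,
                              fold = c("auto", "none", "split")) {
  fold <- match.arg(fold)
  if (inherits(V, "expr_matrix")) V <- V$values
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (length(k_range) < 1 || any(k_range < 2)) stop("ranks must be >= 2")
  if (fold == "split" || (fold == "auto" && any(V < 0))) V <- nonneg_fold(V)
  if (any(V < 0)) stop("V has negative entries; use fold = \"auto\" or \"split\"")
  if (max(k_range) >= min(dim(V))) stop("largest rank must be < min(dim(V))")

  k_range <- as.integer(sort(unique(k_range)))
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max, length(k_range) * n_runs),
                      nrow = n_runs, ncol = length(k_range))

  ns <- ncol(V)
  consensus <- vector("list", length(k_range))
  labels <- vector("list", length(k_range))
  coph <- rep(NA_real_, length(k_range))
  names(consensus) <- names(labels) <- names(coph) <- paste0("k", k_range)

  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    Csum <- matrix(0, ns, ns)
    for (r in seq_len(n_runs)) {
      fit <- nmf_factorize(V, k, seed = run_seeds[r, ki],
                           max_iter = max_iter, tol = tol, eval_every = 10L)
      Csum <- Csum + connectivity_matrix(fit)
    }
    C <- Csum / n_runs
    diag(C) <- 1
    dimnames(C) <- list(colnames(V), colnames(V))
    consensus[[ki]] <- C

    d <- stats::as.dist(1 - C)
    hc <- stats::hclust(d, method = "average")
    labels[[ki]] <- stats::cutree(hc, k = k)
    dv <- as.vector(d)
    cv <- as.vector(stats::cophenetic(hc))
    # all-equal consensus entries make the correlation undefined; report NA
    if (stats::sd(dv) > 0 && stats::sd(cv) > 0)
      coph[ki] <- stats::cor(dv, cv)
  }

  structure(list(k_range = k_range, consensus = consensus,
                 cophenetic = coph, labels = labels,
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "nmf_consensus")
}

#' @export
print.nmf_consensus <- function(x, ...) {
  cat(sprintf("nmf_consensus: ranks %s, %d runs per rank\n",
              paste(range(x$k_range), collapse = "-"), x$n_runs))
  tab <- data.frame(k = x$k_range, cophenetic = round(x$cophenetic, 4))
  print(tab, row.names = FALSE)
  defined <- !is.na(x$cophenetic)
  if (any(defined))
    cat(sprintf("selected k = %d\n", select_k(x)))
  invisible(x)
}

#' @export
plot.nmf_consensus <- function(x, ...) {
  plot(x$k_range, x$cophenetic, type = "b", pch = 19,
       xlab = "rank k", ylab = "cophenetic coefficient", ...)
  invisible(x)
}

#' Select the rank maximizing the cophenetic coefficient
#'
#' Ties go to the smallest rank. Ranks with an undefined coefficient are
#' ignored; if none is defined, this is an error.
#'
#' @param r an `nmf_consensus`.
#' @return The selected integer rank.
#' @export
select_k <- function(r) {
  stopifnot(inherits(r, "nmf_consensus"))
  ok <- !is.na(r$cophenetic)
  if (!any(ok)) stop("cophenetic coefficient undefined at every rank")
  ks <- r$k_range[ok]
  rho <- r$cophenetic[ok]
  ks[which.max(rho)] # which.max returns the first (smallest k) on ties
}

#' Consensus labels at a given rank
#' @param r an `nmf_consensus`.
#' @param k rank (default: [select_k()]).
#' @return Named integer vector of subgroup labels.
#' @export
consensus_labels <- function(r, k = select_k(r)) {
  stopifnot(inherits(r, "nmf_consensus"))
  i <- match(k, r$k_range)
  if (is.na(i)) stop("rank ", k, " not in the evaluated range")
  r$labels[[i]]
}
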