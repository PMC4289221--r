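#' Read a subtype centroid table
#'
#' Tab-delimited, header row of subtype names, leading column of feature IDs.
#' The published intrinsic-subtype centroid tables (e.g. the 50-gene
#' five-subtype scheme) are distributed as supplementary data by their
#' authors and are supplied here as an input artifact; the package ships only
#' a synthetic toy table for testing.
#'
#' @param path path to the centroid file.
#' @return An object of class `subtype_centroids`: list with `centroids`
#'   (features x subtypes matrix) and `subtypes`.
#' @export
load_subtype_centroids <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("centroid table must be numeric")
  if (ncol(m) < 2) stop("need at least 2 subtypes")
  structure(list(centroids = m, subtypes = colnames(m)),
            class = "subtype_centroids")
}

#' Assign molecular subtypes by nearest centroid (Pearson correlation)
#'
#' Correlates each sample with each subtype centroid over the features
#' shared between the expression matrix and the centroid table, and assigns
#' the subtype with the highest correlation. Pearson correlation makes the
#' assignment invariant to per-sample affine rescaling with positive slope.
#' The shared-feature count is reported: cross-platform intersections are
#' routinely incomplete (e.g. 43 of 50 centroid genes present on older
#' arrays). Samples with zero variance over the shared features are
#' unassignable and flagged.
#'
#' @param X an [expr_matrix] or numeric matrix (features x samples).
#' @param centroids a `subtype_centroids` object.
#' @return A data.frame: `sample_id`, `subtype` (NA when unassignable),
#'   `tied` flag (correlation tie, first subtype in column order kept), and
#'   one `cor_<subtype>` column per subtype; attribute `n_shared_features`.
#' @export
assign_subtype <- function(X, centroids) {
  if (inherits(X, "expr_matrix")) X <- X$values
  stopifnot(inherits(centroids, "subtype_centroids"))
  shared <- intersect(rownames(X), rownames(centroids$centroids))
  if (length(shared) < 3)
    stop("need >= 3 shared features between matrix and centroids (found ",
         length(shared), ")")
  Xs <- X[shared, , drop = FALSE]
  Cs <- centroids$centroids[shared, , drop = FALSE]

  nsub <- ncol(Cs)
  cors <- matrix(NA_real_, ncol(Xs), nsub,
                 dimnames = list(colnames(Xs), colnames(Cs)))
  sample_sd <- apply(Xs, 2, stats::sd)
  ok <- sample_sd > 0
  if (any(ok)) cors[ok, ] <- stats::cor(Xs[, ok, drop = FALSE], Cs)

  assigned <- rep(NA_character_, ncol(Xs))
  tied <- rep(FALSE, ncol(Xs))
  for (j in which(ok)) {
    best <- which(cors[j, ] == max(cors[j, ]))
    assigned[j] <- colnames(Cs)[best[1]]
    tied[j] <- length(best) > 1
  }
  out <- data.frame(sample_id = colnames(Xs), subtype = assigned, tied = tied,
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(cors) <- paste0("cor_", colnames(Cs))
  out <- cbind(out, as.data.frame(cors, row.names = NULL))
  attr(out, "n_shared_features") <- length(shared)
  out
}
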