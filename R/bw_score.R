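#' Paired pre/post-treatment design
#'
#' Maps each tumor to exactly one pre-treatment and one post-treatment sample.
#'
#' @param tumor_ids character vector of tumor identifiers.
#' @param pre_sample_id,post_sample_id character vectors, one sample ID each
#'   per tumor; all sample IDs must be distinct.
#' @return An object of class `paired_design` (a data.frame).
#' @export
paired_design <- function(tumor_ids, pre_sample_id, post_sample_id) {
  stopifnot(length(tumor_ids) == length(pre_sample_id),
            length(tumor_ids) == length(post_sample_id))
  if (anyDuplicated(tumor_ids)) stop("duplicate tumor IDs")
  all_samples <- c(pre_sample_id, post_sample_id)
  if (anyDuplicated(all_samples))
    stop("sample IDs must be distinct across pre and post: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  structure(data.frame(tumor_id = as.character(tumor_ids),
                       pre_sample_id = as.character(pre_sample_id),
                       post_sample_id = as.character(post_sample_id),
                       stringsAsFactors = FALSE),
            class = c("paired_design", "data.frame"))
}

#' Between/within (b/w) variation scores over treatment pairs
#'
#' For each feature, the between-tumor variation `b` is the sample variance
#' (n-1 denominator) across tumors of the per-tumor pair means, and the
#' within-pair variation `w` is the mean across tumors of the per-pair
#' variance, i.e. `mean((pre - post)^2) / 2`. The score is `b / w`: features
#' with high scores vary between tumors but are stable under treatment
#' (estrogen-independent); features with low scores respond to treatment.
#'
#' Degenerate cases use documented sentinels: `w = 0` with `b > 0` scores
#' `+Inf` (perfectly invariant yet variable, ranked first, internally by `b`
#' descending); `b = 0` scores 0 and is flagged degenerate (ranked last).
#' Scores are computed on the load-scale matrix; standardizing first would
#' flatten every feature's total variance to one and destroy the ratio's
#' meaning across features.
#'
#' @param m an [expr_matrix] (not standardized).
#' @param d a [paired_design()]; at least 3 tumors, all samples present in `m`.
#' @return A data.frame of class `bw_score_table` with columns `feature_id`,
#'   `b`, `w`, `score`, `degenerate`, `rank`, ordered by rank.
#' @export
compute_bw_scores <- function(m, d) {
  stopifnot(inherits(m, "expr_matrix"), inherits(d, "paired_design"))
  if (nrow(d) < 3) stop("need at least 3 tumors to estimate between-tumor variance")
  samp <- colnames(m$values)
  for (i in seq_len(nrow(d))) {
    if (!(d$pre_sample_id[i] %in% samp))
      stop("tumor '", d$tumor_id[i], "': pre-treatment sample '",
           d$pre_sample_id[i], "' not found in expression matrix")
    if (!(d$post_sample_id[i] %in% samp))
      stop("tumor '", d$tumor_id[i], "': post-treatment sample '",
           d$post_sample_id[i], "' not found in expression matrix")
  }
  pre <- m$values[, d$pre_sample_id, drop = FALSE]
  post <- m$values[, d$post_sample_id, drop = FALSE]

  pair_means <- (pre + post) / 2
  b <- rowSums((pair_means - rowMeans(pair_means))^2) / (ncol(pair_means) - 1)
  w <- rowMeans((pre - post)^2) / 2

  score <- b / w
  degenerate <- (b == 0) | (w == 0 & b == 0)
  score[w == 0 & b > 0] <- Inf
  score[b == 0] <- 0

  out <- data.frame(feature_id = rownames(m$values), b = b, w = w,
                    score = score, degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  # rank: score descending; Inf-score features ordered by b descending;
  # finite ties broken lexicographically by feature ID
  key_b <- ifelse(is.infinite(out$score), -out$b, 0)
  ord <- order(-out$score, key_b, out$feature_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("bw_score_table", "data.frame")
  out
}

#' Select the top-scoring invariant features
#'
#' Returns the `n` features with the highest b/w scores (the estrogen-
#' independent panel). Degenerate features (`b = 0`) are never selected.
#' Ties among finite scores break lexicographically by feature ID; infinite
#' scores rank first, ordered by `b` descending.
#'
#' @param t a `bw_score_table` from [compute_bw_scores()].
#' @param n panel size (default 1000, the discovery panel size).
#' @return Character vector of `n` feature IDs in rank order.
#' @export
select_top_features <- function(t, n = 1000) {
  stopifnot(inherits(t, "bw_score_table"))
  eligible <- t[!t$degenerate, , drop = FALSE]
  if (n > nrow(eligible))
    stop("requested ", n, " features but only ", nrow(eligible),
         " non-degenerate features are available")
  eligible$feature_id[seq_len(n)]
}

#' Write a b/w score table as tab-delimited text
#' @param t a `bw_score_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bw_table <- function(t, path) {
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
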