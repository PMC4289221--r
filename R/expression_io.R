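#' Expression matrix container
#'
#' A lightweight container for a features-by-samples expression matrix with a
#' scale tag. Feature IDs are the row names, sample IDs the column names; both
#' must be unique. All values must be finite.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   row and column names set.
#' @param scale one of `"log_intensity"`, `"normalized_count"`,
#'   `"standardized"`.
#' @param constant_features character vector of feature IDs whose row was
#'   constant when the matrix was standardized (empty otherwise). These are
#'   excluded from b/w ranking downstream.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `scale` and `constant_features`.
#' @export
expr_matrix <- function(values,
                        scale = c("log_intensity", "normalized_count", "standardized"),
                        constant_features = character()) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must be finite (resolve missing values at load time)")
  structure(list(values = values, scale = scale,
                 constant_features = as.character(constant_features)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (scale: %s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (length(x$constant_features))
    cat(sprintf("  %d constant feature(s) flagged\n", length(x$constant_features)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Feature and sample identifiers of an expression matrix
#' @param x an [expr_matrix]
#' @return character vector of IDs.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a tab-delimited expression matrix
#'
#' Expects one header row of sample IDs and a leading column of feature IDs
#' (`orientation = "features_in_rows"`), or the transpose. Duplicate feature
#' IDs are collapsed by keeping the row with the highest mean (a deterministic
#' probe-collapse rule); duplicate sample IDs are an error. Non-numeric cells
#' are reported with their (row, column) position.
#'
#' @param path path to a tab-delimited text file.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @param scale scale tag to attach, see [expr_matrix()].
#' @param impute if `TRUE`, missing cells (`NA`/empty) are imputed with the
#'   per-feature median; if `FALSE` (default) missing cells are an error.
#' @return An [expr_matrix].
#' @export
load_expression_matrix <- function(path,
                                   orientation = c("features_in_rows", "samples_in_rows"),
                                   scale = "log_intensity",
                                   impute = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("malformed header: expected an ID column plus data columns in ", path)
  ids <- raw[[1]]
  # `[.data.frame` silently uniquifies duplicated names, so check them first
  col_ids <- colnames(raw)[-1]
  dat <- raw[, -1, drop = FALSE]
  if (anyDuplicated(col_ids))
    stop("duplicate sample ID in header: ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))

  m <- matrix(NA_real_, nrow(dat), ncol(dat), dimnames = list(ids, col_ids))
  for (j in seq_len(ncol(dat))) {
    cell <- dat[[j]]
    cell[cell == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell at (row %d, column %d) [feature '%s', sample '%s']: '%s'",
                   bad[1], j, ids[bad[1]], col_ids[j], cell[bad[1]]))
    m[, j] <- num
  }
  if (orientation == "samples_in_rows") m <- t(m)

  if (anyNA(m)) {
    if (!impute)
      stop("missing values present; rerun with impute = TRUE to impute per-feature medians")
    for (i in which(rowSums(is.na(m)) > 0)) {
      med <- stats::median(m[i, ], na.rm = TRUE)
      if (is.na(med)) stop("feature '", rownames(m)[i], "' is entirely missing")
      m[i, is.na(m[i, ])] <- med
    }
  }

  if (anyDuplicated(rownames(m))) {
    # keep the duplicate row with the highest mean
    means <- rowMeans(m)
    ord <- order(rownames(m), -means)
    keep <- ord[!duplicated(rownames(m)[ord])]
    m <- m[sort(keep), , drop = FALSE]
  }
  expr_matrix(m, scale = scale)
}

#' Write an expression matrix as tab-delimited text
#'
#' Values are written at full precision so that a write/read round trip
#' preserves them.
#'
#' @param x an [expr_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature_id = rownames(x$values),
                   format(x$values, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(x$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-feature standardization and mean centering
#'
#' Z-scores every feature row: subtract the feature mean and divide by the
#' feature standard deviation (sample SD, n-1 denominator). Constant features
#' cannot be scaled; they are centered to zero and recorded in
#' `constant_features` so that downstream b/w ranking can exclude them.
#'
#' @param m an [expr_matrix] not already standardized.
#' @return An [expr_matrix] with `scale = "standardized"`.
#' @export
standardize_and_center <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale == "standardized") return(m)
  v <- m$values
  if (ncol(v) < 2) stop("standardization needs at least 2 samples (SD undefined)")
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  centered <- v - mu
  const <- sdv == 0
  out <- centered
  out[!const, ] <- centered[!const, , drop = FALSE] / sdv[!const]
  expr_matrix(out, scale = "standardized",
              constant_features = union(m$constant_features, rownames(v)[const]))
}

#' Merge standardized cohorts on their shared features
#'
#' Restricts each cohort to the intersection of feature IDs and concatenates
#' the sample columns. Sample IDs are prefixed with their cohort label to
#' guarantee uniqueness. Every cohort must already be standardized, so that
#' each feature row retains mean zero within each cohort block after merging.
#'
#' @param cohorts named list of standardized [expr_matrix] objects; names are
#'   the cohort labels used as sample-ID prefixes.
#' @return A merged [expr_matrix] with `scale = "standardized"`.
#' @export
merge_cohorts <- function(cohorts) {
  if (!is.list(cohorts) || length(cohorts) < 2)
    stop("need at least 2 cohorts to merge")
  if (is.null(names(cohorts)) || any(names(cohorts) == ""))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  for (nm in names(cohorts)) {
    if (!inherits(cohorts[[nm]], "expr_matrix"))
      stop("cohort '", nm, "' is not an expr_matrix")
    if (cohorts[[nm]]$scale != "standardized")
      stop("cohort '", nm, "' must be standardized before merging")
  }
  shared <- Reduce(intersect, lapply(cohorts, function(x) rownames(x$values)))
  if (length(shared) == 0) stop("empty feature intersection across cohorts")
  blocks <- lapply(names(cohorts), function(nm) {
    v <- cohorts[[nm]]$values[shared, , drop = FALSE]
    colnames(v) <- paste(nm, colnames(v), sep = ".")
    v
  })
  expr_matrix(do.call(cbind, blocks), scale = "standardized",
              constant_features = intersect(
                shared, unique(unlist(lapply(cohorts, `[[`, "constant_features")))))
}

#' ER status call from ESR1 expression
#'
#' Classifies a sample as estrogen-receptor positive when its ESR1 expression
#' meets the cutoff (default 250 normalized transcript counts, the convention
#' for RSEM-normalized RNA-seq). The boundary is inclusive: `expr >= cutoff`
#' is positive.
#'
#' @param expr non-negative numeric vector of ESR1 normalized counts.
#' @param cutoff non-negative scalar cutoff; default 250.
#' @return character vector, `"positive"` or `"negative"` per value.
#' @export
call_er_status <- function(expr, cutoff = 250) {
  if (any(!is.finite(expr)) || any(expr < 0)) stop("ESR1 expression must be non-negative")
  if (!is.finite(cutoff) || cutoff < 0) stop("cutoff must be non-negative")
  ifelse(expr >= cutoff, "positive", "negative")
}

#' Read a clinical table
#'
#' Tab-delimited with columns `sample_id`, `time_years`, `event`, `endpoint`
#' (`DFS` or `DMFS`), `endocrine_treated` and `er_positive` (logical or
#' `unknown`). One row per sample, non-negative times, events coded 0/1.
#'
#' @param path path to the file.
#' @return A data.frame with one validated row per sample.
#' @export
load_clinical_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  needed <- c("sample_id", "time_years", "event", "endpoint",
              "endocrine_treated", "er_positive")
  missing_cols <- setdiff(needed, colnames(df))
  if (length(missing_cols))
    stop("clinical table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df$time_years <- as.numeric(df$time_years)
  if (any(!is.finite(df$time_years)) || any(df$time_years < 0))
    stop("time_years must be finite and non-negative")
  df$event <- as.integer(df$event)
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  if (!all(df$endpoint %in% c("DFS", "DMFS")))
    stop("endpoint must be DFS or DMFS")
  df
}

#' Write a clinical table as tab-delimited text
#' @param df data.frame in the [load_clinical_table()] layout.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
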