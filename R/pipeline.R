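#' Pipeline configuration
#'
#' Bundles the constants of the discovery/validation workflows. The defaults
#' are the framework's canonical settings: a 1000-feature invariant panel,
#' candidate ranks 2-10, 50 markers per subgroup (a 300-feature classifier
#' for six subgroups), an 0.80 posterior-confidence rule, 10-year survival
#' horizon and 5-year landmark.
#'
#' @param n_top_features invariant-panel size.
#' @param k_min,k_max candidate rank range for consensus NMF.
#' @param n_runs NMF restarts per rank.
#' @param n_markers_per_class markers per subgroup.
#' @param confidence_threshold posterior threshold for confident calls.
#' @param horizon_years survival truncation horizon.
#' @param landmark_years landmark time.
#' @param nmf_max_iter,nmf_tol per-run NMF convergence controls.
#' @param retrain_on_panel retrain the classifier on the marker panel
#'   (default) rather than thresholding the full model.
#' @param seed master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_top_features = 1000,
                            k_min = 2, k_max = 10,
                            n_runs = 50,
                            n_markers_per_class = 50,
                            confidence_threshold = 0.80,
                            horizon_years = 10,
                            landmark_years = 5,
                            nmf_max_iter = 2000L,
                            nmf_tol = 1e-6,
                            retrain_on_panel = TRUE,
                            seed = 1L) {
  if (k_max < k_min) stop("k_max must be >= k_min")
  if (k_min < 2) stop("k_min must be >= 2")
  if (n_top_features < 1) stop("n_top_features must be positive")
  if (confidence_threshold <= 0 || confidence_threshold >= 1)
    stop("confidence_threshold must be in (0, 1)")
  structure(list(n_top_features = as.integer(n_top_features),
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_runs = as.integer(n_runs),
                 n_markers_per_class = as.integer(n_markers_per_class),
                 confidence_threshold = confidence_threshold,
                 horizon_years = horizon_years,
                 landmark_years = landmark_years,
                 nmf_max_iter = as.integer(nmf_max_iter),
                 nmf_tol = nmf_tol,
                 retrain_on_panel = isTRUE(retrain_on_panel),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_manifest <- function(config, path, extra = list()) {
  kv <- c(unclass(config), extra,
          list(package_version = as.character(utils::packageVersion("estroclass"))))
  lines <- vapply(names(kv), function(nm)
    paste0(nm, "=", paste(format(kv[[nm]], digits = 15), collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run the discovery workflow
#'
#' The class-discovery arm of the framework: score features on the paired
#' pre/post cohort, select the top invariant panel, run consensus NMF over
#' the candidate ranks on the discovery cohort restricted to that panel,
#' pick the rank by cophenetic coefficient, train a shrunken-centroid
#' classifier on the consensus labels and extract the per-subgroup marker
#' panel (by default retraining the classifier on the panel).
#'
#' @param paired_expr [expr_matrix] of the paired pre/post cohort (load
#'   scale).
#' @param design matching [paired_design()].
#' @param discovery_expr [expr_matrix] of the discovery cohort.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, all stage artifacts are
#'   written as tab-delimited files plus a `manifest.txt` sufficient to
#'   replay the run.
#' @return List of class `discovery_result`: `bw_table`, `panel`,
#'   `consensus`, `k`, `labels`, `model`, `markers`, `config`.
#' @export
run_discovery <- function(paired_expr, design, discovery_expr, config = pipeline_config(),
                          out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))

  bw <- compute_bw_scores(paired_expr, design)
  panel <- select_top_features(bw, n = config$n_top_features)

  missing_panel <- setdiff(panel, feature_ids(discovery_expr))
  if (length(missing_panel))
    stop("discovery stage: ", length(missing_panel),
         " panel features absent from the discovery cohort")
  V <- discovery_expr$values[panel, , drop = FALSE]

  cons <- consensus_cluster(V, k_range = config$k_min:config$k_max,
                            n_runs = config$n_runs, seed = config$seed,
                            max_iter = config$nmf_max_iter, tol = config$nmf_tol)
  k <- select_k(cons)
  labels <- consensus_labels(cons, k)
  names(labels) <- sample_ids(discovery_expr)

  # the classifier is trained on per-feature standardized data so that
  # standardized validation cohorts live on the same scale
  Vstd <- standardize_and_center(expr_matrix(V))$values
  model <- train_shrunken_centroids(Vstd, labels, delta = 0)
  markers <- select_subgroup_markers(model, n_per_class = config$n_markers_per_class)
  if (config$retrain_on_panel) {
    model <- train_shrunken_centroids(Vstd[markers$panel, , drop = FALSE],
                                      labels, delta = 0)
  }

  res <- structure(list(bw_table = bw, panel = panel, consensus = cons,
                        k = k, labels = labels, model = model,
                        markers = markers, config = config),
                   class = "discovery_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_bw_table(bw, file.path(out_dir, "bw_scores.tsv"))
    writeLines(panel, file.path(out_dir, "invariant_panel.txt"))
    utils::write.table(data.frame(k = cons$k_range, cophenetic = cons$cophenetic),
                       file.path(out_dir, "rank_selection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (ki in seq_along(cons$k_range))
      utils::write.table(cons$consensus[[ki]],
                         file.path(out_dir, sprintf("consensus_k%d.tsv", cons$k_range[ki])),
                         sep = "\t", quote = FALSE)
    utils::write.table(data.frame(sample_id = names(labels), subgroup = labels),
                       file.path(out_dir, "subgroup_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(markers$panel, file.path(out_dir, "marker_panel.txt"))
    write_shrunken_centroids(model, file.path(out_dir, "model.tsv"))
    write_manifest(config, file.path(out_dir, "manifest.txt"),
                   extra = list(stage = "discovery", selected_k = k,
                                n_panel = length(panel),
                                n_markers = length(markers$panel)))
  }
  res
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf("discovery: %d-feature invariant panel -> consensus NMF selected k = %d\n",
              length(x$panel), x$k))
  cat(sprintf("  marker panel: %d features (%d per subgroup requested)\n",
              length(x$markers$panel), x$config$n_markers_per_class))
  invisible(x)
}

#' Run the validation workflow
#'
#' Standardizes each validation cohort per feature, merges them on shared
#' features, classifies every tumor into the discovered subgroups with the
#' trained model, flags confident calls (posterior above the configured
#' threshold), and runs the subgroup survival comparison plus, when a
#' two-level treatment stratum is available, the landmark analysis within
#' each subgroup.
#'
#' @param model a `shrunken_centroids` fit from discovery.
#' @param cohorts named list of [expr_matrix] validation cohorts (load
#'   scale; standardized internally).
#' @param clinical clinical data.frame ([load_clinical_table()] layout) with
#'   `sample_id` values matching the prefixed merged IDs (or raw IDs of a
#'   single cohort).
#' @param config a [pipeline_config()].
#' @param out_dir optional artifact directory.
#' @return List of class `validation_result`: `calls` (classification
#'   table), `confident_fraction`, `survival` (a `subgroup_survival`),
#'   `landmark` (per-subgroup list or `NULL`), `config`.
#' @export
run_validation <- function(model, cohorts, clinical, config = pipeline_config(),
                           out_dir = NULL) {
  stopifnot(inherits(model, "shrunken_centroids"),
            inherits(config, "pipeline_config"))
  if (!is.list(cohorts) || length(cohorts) < 1) stop("need >= 1 validation cohort")

  if (is.null(names(cohorts)) || any(names(cohorts) == ""))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  std <- lapply(cohorts, standardize_and_center)
  merged <- if (length(std) >= 2) {
    merge_cohorts(std)
  } else {
    # single cohort: apply the same label prefix convention as merging
    one <- std[[1]]
    colnames(one$values) <- paste(names(std)[1], colnames(one$values), sep = ".")
    one
  }

  calls <- predict(model, merged, confidence = config$confidence_threshold)
  labels <- stats::setNames(calls$predicted, calls$sample_id)

  surv <- NULL
  landmark <- NULL
  hit <- clinical$sample_id %in% names(labels)
  if (any(hit)) {
    surv <- subgroup_survival(clinical, labels, horizon = config$horizon_years)
    cl <- clinical[hit & clinical$time_years > 0, , drop = FALSE]
    treated <- cl$endocrine_treated
    if (is.character(treated)) treated <- treated == "TRUE" | treated == "true"
    if (length(unique(treated[!is.na(treated)])) == 2) {
      lab_cl <- labels[cl$sample_id]
      landmark <- lapply(sort(unique(lab_cl)), function(g) {
        sel <- lab_cl == g
        landmark_compare(cl$time_years[sel], cl$event[sel],
                         strata = factor(ifelse(treated[sel], "treated", "untreated"),
                                         levels = c("treated", "untreated")),
                         landmark = config$landmark_years,
                         horizon = config$horizon_years)
      })
      names(landmark) <- sort(unique(lab_cl))
    }
  }

  res <- structure(list(calls = calls,
                        confident_fraction = mean(calls$confident),
                        survival = surv, landmark = landmark, config = config),
                   class = "validation_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(calls, file.path(out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(surv))
      utils::write.table(surv$per_group, file.path(out_dir, "subgroup_survival.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(config, file.path(out_dir, "manifest.txt"),
                   extra = list(stage = "validation",
                                n_samples = nrow(calls),
                                confident_fraction = res$confident_fraction))
  }
  res
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("validation: %d samples classified, %.1f%% confident (posterior > %.2f)\n",
              nrow(x$calls), 100 * x$confident_fraction,
              x$config$confidence_threshold))
  if (!is.null(x$survival)) print(x$survival)
  invisible(x)
}
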