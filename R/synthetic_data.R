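#' Specification of a synthetic paired pre/post-treatment cohort
#'
#' Describes a cohort of tumors each profiled before and after an
#' estrogen-deprivation treatment, with three gene blocks: treatment-invariant
#' genes that vary between tumors (a per-tumor baseline shared by the pre and
#' post sample), treatment-responsive genes (a per-gene pre-to-post shift
#' applied to all tumors) and pure-noise genes. Expression is Gaussian on the
#' log scale, emulating post-RMA microarray data.
#'
#' @param n_tumors number of tumors (each contributes a pre and a post sample).
#' @param n_invariant_genes,n_responsive_genes,n_noise_genes block sizes.
#' @param between_sd SD of the tumor-specific baselines of invariant genes
#'   (log-expression units).
#' @param treatment_shift_sd SD of the per-gene pre-to-post shift of
#'   responsive genes.
#' @param noise_sd residual SD added to every measurement.
#' @param baseline_log_expression constant added to every value (default 0:
#'   expression is generated relative to the gene-wise background; set to a
#'   typical log2 intensity, e.g. 7, to emulate raw RMA-scale output).
#' @param seed integer seed; identical specs give bitwise-identical cohorts.
#' @return A list of class `paired_cohort_spec`.
#' @export
paired_cohort_spec <- function(n_tumors = 58,
                               n_invariant_genes = 1000,
                               n_responsive_genes = 1000,
                               n_noise_genes = 8000,
                               between_sd = 2,
                               treatment_shift_sd = 2,
                               noise_sd = 0.5,
                               baseline_log_expression = 0,
                               seed = 1L) {
  # SDs of zero are allowed so that exact limit cases can be constructed
  stopifnot(n_tumors >= 2,
            n_invariant_genes >= 0, n_responsive_genes >= 0, n_noise_genes >= 0,
            between_sd > 0, treatment_shift_sd >= 0, noise_sd >= 0)
  structure(list(n_tumors = as.integer(n_tumors),
                 n_invariant_genes = as.integer(n_invariant_genes),
                 n_responsive_genes = as.integer(n_responsive_genes),
                 n_noise_genes = as.integer(n_noise_genes),
                 between_sd = between_sd,
                 treatment_shift_sd = treatment_shift_sd,
                 noise_sd = noise_sd,
                 baseline_log_expression = baseline_log_expression,
                 seed = as.integer(seed)),
            class = "paired_cohort_spec")
}

#' Generate a paired pre/post-treatment cohort
#'
#' @param spec a [paired_cohort_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{expr}{[expr_matrix] with `2 * n_tumors` samples
#'       (`<tumor>_pre`, `<tumor>_post`).}
#'     \item{design}{[paired_design] mapping each tumor to its pre and post
#'       sample.}
#'     \item{gene_truth}{character vector per feature:
#'       `"invariant"`, `"responsive"` or `"noise"`.}
#'   }
#' @export
generate_paired_cohort <- function(spec) {
  stopifnot(inherits(spec, "paired_cohort_spec"))
  if (spec$n_tumors < 2) stop("n_tumors must be >= 2")
  set.seed(spec$seed)
  nt <- spec$n_tumors
  n_inv <- spec$n_invariant_genes
  n_res <- spec$n_responsive_genes
  n_noi <- spec$n_noise_genes
  n_genes <- n_inv + n_res + n_noi

  tumor_ids <- sprintf("tumor%03d", seq_len(nt))
  pre_ids <- paste0(tumor_ids, "_pre")
  post_ids <- paste0(tumor_ids, "_post")

  gene_ids <- c(if (n_inv) sprintf("INV%05d", seq_len(n_inv)),
                if (n_res) sprintf("RSP%05d", seq_len(n_res)),
                if (n_noi) sprintf("NSE%05d", seq_len(n_noi)))
  truth <- rep(c("invariant", "responsive", "noise"), c(n_inv, n_res, n_noi))

  pre <- matrix(0, n_genes, nt)
  post <- matrix(0, n_genes, nt)
  if (n_inv) {
    baseline <- matrix(stats::rnorm(n_inv * nt, 0, spec$between_sd), n_inv, nt)
    pre[seq_len(n_inv), ] <- baseline
    post[seq_len(n_inv), ] <- baseline
  }
  if (n_res) {
    shift <- stats::rnorm(n_res, 0, spec$treatment_shift_sd)
    post[n_inv + seq_len(n_res), ] <- post[n_inv + seq_len(n_res), ] + shift
  }
  pre <- pre + matrix(stats::rnorm(n_genes * nt, 0, spec$noise_sd), n_genes, nt) +
    spec$baseline_log_expression
  post <- post + matrix(stats::rnorm(n_genes * nt, 0, spec$noise_sd), n_genes, nt) +
    spec$baseline_log_expression

  values <- cbind(pre, post)[, rep(seq_len(nt), each = 2) + c(0, nt), drop = FALSE]
  # interleave pre/post per tumor for readability
  colnames(values) <- as.vector(rbind(pre_ids, post_ids))
  rownames(values) <- gene_ids
  names(truth) <- gene_ids

  list(expr = expr_matrix(values, scale = "log_intensity"),
       design = paired_design(tumor_ids, pre_ids, post_ids),
       gene_truth = truth)
}

#' Specification of a synthetic subtyped cohort with survival
#'
#' Describes a single-timepoint cohort with `k_true` planted subgroups. Each
#' subgroup carries a distinct block of signature genes shifted by
#' `signature_effect` in its members only; everything else is Gaussian noise.
#' Event times are exponential with a per-group scale (mean event time in
#' years), administratively censored, and each patient carries an
#' endocrine-treatment flag.
#'
#' @param n_samples cohort size.
#' @param k_true number of planted subgroups (>= 2).
#' @param n_signature_genes_per_group signature block size per subgroup.
#' @param n_noise_genes additional pure-noise genes.
#' @param signature_effect mean shift of a group's signature genes in its
#'   members (log-expression units).
#' @param noise_sd residual SD.
#' @param survival_scales_years numeric of length `k_true`: per-group
#'   exponential scale (mean event time, years).
#' @param censor_time_years administrative censoring horizon (years).
#' @param treated_fraction probability a patient is endocrine treated.
#' @param baseline_log_expression constant added to every value (default 0;
#'   set to a typical log2 intensity to emulate raw RMA-scale output).
#' @param seed integer seed.
#' @return A list of class `subtyped_cohort_spec`.
#' @export
subtyped_cohort_spec <- function(n_samples = 240,
                                 k_true = 6,
                                 n_signature_genes_per_group = 20,
                                 n_noise_genes = 80,
                                 signature_effect = 2,
                                 noise_sd = 1,
                                 survival_scales_years = seq(6, 30, length.out = k_true),
                                 censor_time_years = 15,
                                 treated_fraction = 0.5,
                                 baseline_log_expression = 0,
                                 seed = 1L) {
  stopifnot(n_samples >= 1, k_true >= 2,
            n_signature_genes_per_group >= 1, n_noise_genes >= 0,
            noise_sd > 0, censor_time_years > 0,
            treated_fraction >= 0, treated_fraction <= 1)
  if (length(survival_scales_years) != k_true)
    stop("survival_scales_years must have length k_true")
  if (any(survival_scales_years <= 0))
    stop("survival scales must be positive")
  structure(list(n_samples = as.integer(n_samples),
                 k_true = as.integer(k_true),
                 n_signature_genes_per_group = as.integer(n_signature_genes_per_group),
                 n_noise_genes = as.integer(n_noise_genes),
                 signature_effect = signature_effect,
                 noise_sd = noise_sd,
                 survival_scales_years = as.numeric(survival_scales_years),
                 censor_time_years = censor_time_years,
                 treated_fraction = treated_fraction,
                 baseline_log_expression = baseline_log_expression,
                 seed = as.integer(seed)),
            class = "subtyped_cohort_spec")
}

#' Generate a subtyped cohort with planted subgroups and survival
#'
#' Group assignment is round-robin (sizes as equal as possible) then shuffled
#' under the seed. Signature genes sit at `signature_effect` above baseline in
#' their own group only. Event times are exponential per group and censored at
#' the administrative horizon (`event = 0` when censored).
#'
#' @param spec a [subtyped_cohort_spec()].
#' @return A list with elements `expr` ([expr_matrix]), `group` (integer
#'   vector of true subgroup labels, named by sample) and `clinical`
#'   (data.frame in the [load_clinical_table()] layout).
#' @export
generate_subtyped_cohort <- function(spec) {
  stopifnot(inherits(spec, "subtyped_cohort_spec"))
  if (spec$k_true > spec$n_samples) stop("k_true exceeds n_samples")
  set.seed(spec$seed)
  n <- spec$n_samples
  k <- spec$k_true
  gpg <- spec$n_signature_genes_per_group
  n_genes <- k * gpg + spec$n_noise_genes

  group <- sample(rep_len(seq_len(k), n))
  sample_idv <- sprintf("sample%04d", seq_len(n))
  names(group) <- sample_idv

  gene_ids <- c(sprintf("SIG%d_%03d", rep(seq_len(k), each = gpg),
                        rep(seq_len(gpg), k)),
                if (spec$n_noise_genes) sprintf("NSE%04d", seq_len(spec$n_noise_genes)))
  values <- matrix(stats::rnorm(n_genes * n, 0, spec$noise_sd), n_genes, n,
                   dimnames = list(gene_ids, sample_idv)) +
    spec$baseline_log_expression
  for (g in seq_len(k)) {
    rows <- (g - 1L) * gpg + seq_len(gpg)
    values[rows, group == g] <- values[rows, group == g] + spec$signature_effect
  }

  scales <- spec$survival_scales_years[group]
  t_event <- stats::rexp(n, rate = 1 / scales)
  censored <- t_event > spec$censor_time_years
  clinical <- data.frame(
    sample_id = sample_idv,
    time_years = pmin(t_event, spec$censor_time_years),
    event = as.integer(!censored),
    endpoint = "DMFS",
    endocrine_treated = stats::rbinom(n, 1, spec$treated_fraction) == 1,
    er_positive = TRUE,
    stringsAsFactors = FALSE)

  list(expr = expr_matrix(values, scale = "log_intensity"),
       group = group,
       clinical = clinical)
}
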