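#' Assemble the per-participant analysis table
#'
#' Joins the observed cohort with derived food groups and categories, the
#' WCRF and IV-weighted dietary scores (with empirical tertiles), a BMI
#' category, and - when genotypes are supplied - the three PRS variants with
#' their tertile and decile bins.  This is the table every model-fitting
#' function operates on.
#'
#' @param cohort observed participant table (see [simulate_cohort()]).
#' @param genotypes optional dosage matrix (participants x SNPs; rownames
#'   must match `cohort$participant_id`).
#' @param manifest curated variant manifest (required with `genotypes`).
#' @param weights diet weight table (default [default_diet_weights()]).
#' @param opts diet constants from [diet_options()].
#' @return data.frame: cohort columns plus derived quantities, `*_cat`
#'   factors, `wcrf_*`, `iv_diet_score`, `iv_diet_tertile`, `bmi_group`, and
#'   `prs_*` columns when genotypes are given.
#' @export
build_analysis_table <- function(cohort, genotypes = NULL, manifest = NULL,
                                 weights = default_diet_weights(),
                                 opts = diet_options()) {
  groups <- derive_food_groups(cohort, opts)
  wc <- wcrf_score(groups)
  iv <- iv_diet_score(groups, weights)
  out <- cbind(cohort, groups, wc)
  out$iv_diet_score <- as.numeric(iv)
  out$iv_diet_tertile <- bin_scores(iv, 3, tertile_labels)
  bg <- .bincode(out$bmi, c(-Inf, 25, 30, Inf), right = FALSE)
  out$bmi_group <- factor(c("<25", "25 to <30", ">=30")[bg],
                          levels = c("<25", "25 to <30", ">=30"))
  if (!is.null(genotypes)) {
    if (is.null(manifest)) stop("genotypes supplied without a manifest")
    idx <- match(as.character(cohort$participant_id), rownames(genotypes))
    if (anyNA(idx)) stop("genotype rownames do not cover all participants")
    prs <- bin_prs(compute_prs(genotypes[idx, , drop = FALSE], manifest))
    out <- cbind(out, prs)
  }
  out
}
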