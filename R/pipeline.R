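#' Analysis configuration
#'
#' One structured configuration drives the staged pipeline.  It can be built
#' in code or read from a YAML file ([read_analysis_config()]).
#'
#' @param out_dir directory where every stage reads and writes its tables.
#' @param n,seed,active_terms passed to [sim_config()] by the simulate stage.
#' @param adjust_diet adjustment set for dietary exposures (alcohol is added
#'   automatically for single-food exposures other than alcohol, mirroring
#'   the convention that alcohol is not adjusted for when an alcohol-
#'   containing score is the exposure).
#' @param adjust_prs adjustment set for PRS exposures.
#' @param adjust_joint adjustment set for joint/stratified/cumulative-risk
#'   models.
#' @param reestimate_weights if TRUE the IV-diet weight table is re-derived
#'   from the input cohort itself (statistically circular; provided to mirror
#'   in-sample score construction) instead of the bundled preset.
#' @param af_method "levin" or "miettinen" (see [attributable_fraction()]).
#' @return object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(out_dir, n = 20000, seed = 1,
                            active_terms = c("sex", "family_history_crc",
                                             "wcrf_group", "prs_iv_tertile"),
                            adjust_diet = c("sex", "family_history_crc", "smoking",
                                            "bmi_group", "activity"),
                            adjust_prs = c("sex", "family_history_crc"),
                            adjust_joint = c("sex", "family_history_crc", "income",
                                             "smoking", "bmi_group", "activity"),
                            reestimate_weights = FALSE,
                            af_method = "levin") {
  structure(list(out_dir = out_dir, n = n, seed = seed,
                 active_terms = active_terms, adjust_diet = adjust_diet,
                 adjust_prs = adjust_prs, adjust_joint = adjust_joint,
                 reestimate_weights = isTRUE(reestimate_weights),
                 af_method = af_method),
            class = "analysis_config")
}

#' @param path YAML file with the fields of [analysis_config()].
#' @rdname analysis_config
#' @export
read_analysis_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(analysis_config, v)
}

#' @param config configuration to write.
#' @rdname analysis_config
#' @export
write_analysis_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

cohort_factor_levels <- function() {
  c(list(sex = c("woman", "man"), family_history_crc = c("no", "yes"),
         income = c("low", "medium", "high"),
         smoking = c("never", "former", "current"),
         activity = c("insufficient", "sufficient"),
         milk_type = milk_types, alcohol_freq = alcohol_levels,
         event_subtype = c("none", "colon", "rectal")),
    stats::setNames(rep(list(freq_levels),
                        length(grep("_freq$", names(diet_item_defs()), value = TRUE)) - 1),
                    setdiff(grep("_freq$", names(diet_item_defs()), value = TRUE),
                            "alcohol_freq")))
}

#' Cohort table I/O
#'
#' CSV with one row per participant and the documented header of
#' [simulate_cohort()]'s `cohort`; factor vocabularies (including the
#' explicit "missing" level) are restored on read.
#' @param path file path.
#' @rdname cohort_io
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in names(cohort_factor_levels())) {
    if (nm %in% names(d)) {
      lv <- cohort_factor_levels()[[nm]]
      extra <- if (nm == "event_subtype") character() else "missing"
      d[[nm]] <- factor(d[[nm]], levels = unique(c(lv, extra, unique(d[[nm]]))))
    }
  }
  d
}

#' @param cohort cohort data.frame.
#' @rdname cohort_io
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

stage_file <- function(config, name) file.path(config$out_dir, name)

require_stage_file <- function(config, name, produced_by) {
  f <- stage_file(config, name)
  if (!file.exists(f)) {
    stop("dependency violation: '", name, "' not found in ", config$out_dir,
         "; run stage '", produced_by, "' first")
  }
  f
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the staged analysis pipeline
#'
#' Executes an ordered subset of the six stages, each reading its inputs
#' from, and writing its tabular outputs to, `config$out_dir`:
#' \describe{
#'   \item{simulate}{synthetic cohort -> `cohort.csv`, `dosages.tsv`,
#'     `manifest.tsv`}
#'   \item{score-diet}{food groups, WCRF and IV-weighted scores ->
#'     `diet_scores.csv`, `diet_weights.tsv`}
#'   \item{build-prs}{three PRS variants with bins -> `prs.csv`,
#'     `prs_boundaries.tsv`}
#'   \item{fit}{adjusted Cox models for the dietary scores, each food group
#'     and the PRS bins -> `fits.tsv`}
#'   \item{joint}{joint score-by-PRS-tertile tables with interaction LRTs ->
#'     `joint.tsv`}
#'   \item{report}{cumulative risk at 80 per joint cell, excess risks,
#'     attributable fractions -> `cumulative_risk.tsv`, `excess_risk.tsv`,
#'     `attributable_fraction.tsv`}
#' }
#' A machine-readable run log (`run_log.json`: seed, package version, per-
#' stage row/event counts) is rewritten at the end; re-running with the same
#' configuration reproduces every output byte for byte.
#'
#' @param config an [analysis_config()].
#' @param stages ordered subset of
#'   `c("simulate","score-diet","build-prs","fit","joint","report")`.
#' @return invisibly, the run log as a list.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "score-diet", "build-prs",
                                    "fit", "joint", "report")) {
  stopifnot(inherits(config, "analysis_config"))
  all_stages <- c("simulate", "score-diet", "build-prs", "fit", "joint", "report")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed, n = config$n,
              package_version = as.character(utils::packageVersion("dietprs")),
              stages = list())

  for (st in stages) {
    log$stages[[st]] <- switch(st,
      "simulate" = stage_simulate(config),
      "score-diet" = stage_score_diet(config),
      "build-prs" = stage_build_prs(config),
      "fit" = stage_fit(config),
      "joint" = stage_joint(config),
      "report" = stage_report(config))
  }
  jsonlite::write_json(log, stage_file(config, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(log)
}

stage_simulate <- function(config) {
  sc <- sim_config(config$n, seed = config$seed, active_terms = config$active_terms)
  sim <- simulate_cohort(sc)
  write_cohort_csv(sim$cohort, stage_file(config, "cohort.csv"))
  write_dosages_tsv(sim$genotypes, stage_file(config, "dosages.tsv"))
  write_variant_manifest(sim$manifest, stage_file(config, "manifest.tsv"))
  list(rows = nrow(sim$cohort), events = sum(sim$cohort$event),
       baseline_hazard_rate = sim$truth$baseline_hazard_rate)
}

stage_score_diet <- function(config) {
  cohort <- read_cohort_csv(require_stage_file(config, "cohort.csv", "simulate"))
  groups <- derive_food_groups(cohort)
  wc <- wcrf_score(groups)
  weights <- default_diet_weights()
  if (config$reestimate_weights) {
    weights <- reestimate_diet_weights(cohort, groups, config)
  }
  iv <- iv_diet_score(groups, weights)
  scores <- cbind(data.frame(participant_id = cohort$participant_id),
                  groups, wc,
                  data.frame(iv_diet_score = as.numeric(iv),
                             iv_diet_tertile = bin_scores(iv, 3, tertile_labels)))
  utils::write.csv(scores, stage_file(config, "diet_scores.csv"),
                   row.names = FALSE, quote = FALSE)
  write_tsv(weights, stage_file(config, "diet_weights.tsv"))
  list(rows = nrow(scores),
       complete_iv = sum(!is.na(scores$iv_diet_score)),
       complete_wcrf = sum(!is.na(scores$wcrf_score)))
}

## in-sample weight construction: refit the adjusted per-food Cox models on
## the supplied cohort and convert the HRs/CIs to ln(HR)/SE weights
reestimate_diet_weights <- function(cohort, groups, config) {
  d <- cbind(cohort, groups)
  d$bmi_group <- factor(c("<25", "25 to <30", ">=30")[
    .bincode(d$bmi, c(-Inf, 25, 30, Inf), right = FALSE)],
    levels = c("<25", "25 to <30", ">=30"))
  cp <- diet_cutpoints()
  rows <- lapply(names(cp), function(food) {
    adj <- config$adjust_diet
    if (food != "alcohol") adj <- unique(c(adj, "alcohol_cat"))
    fit <- fit_cox(d, paste0(food, "_cat"), adj)
    tt <- fit$terms[-1, ]
    data.frame(food = food, category = tt$level, hr = tt$hr,
               lower = tt$lower, upper = tt$upper)
  })
  derive_weight_table(do.call(rbind, rows))
}

read_scores_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  cp <- diet_cutpoints()
  for (food in names(cp)) {
    col <- paste0(food, "_cat")
    if (col %in% names(d)) d[[col]] <- factor(d[[col]], levels = cp[[food]]$labels)
  }
  if ("wcrf_group" %in% names(d)) d$wcrf_group <- factor(d$wcrf_group, c("2-3", "0-1"))
  if ("iv_diet_tertile" %in% names(d)) {
    d$iv_diet_tertile <- factor(d$iv_diet_tertile, tertile_labels)
  }
  for (col in grep("^prs_.*_tertile$", names(d), value = TRUE)) {
    d[[col]] <- factor(d[[col]], prs_tertile_labels)
  }
  for (col in grep("^prs_.*_decile$", names(d), value = TRUE)) {
    d[[col]] <- factor(d[[col]], decile_labels)
  }
  if ("alcohol" %in% names(d)) d$alcohol <- factor(d$alcohol, alcohol_levels)
  d
}

stage_build_prs <- function(config) {
  dos <- read_dosages_tsv(require_stage_file(config, "dosages.tsv", "simulate"))
  man <- read_variant_manifest(require_stage_file(config, "manifest.tsv", "simulate"))
  prs <- bin_prs(compute_prs(dos, man))
  bounds <- do.call(rbind, lapply(
    grep("tertile|decile", names(prs), value = TRUE), function(col) {
      b <- attr(prs[[col]], "breaks")
      data.frame(bin_set = col, boundary = b[is.finite(b)])
    }))
  out <- cbind(data.frame(participant_id = rownames(dos)), prs)
  utils::write.csv(out, stage_file(config, "prs.csv"), row.names = FALSE, quote = FALSE)
  write_tsv(bounds, stage_file(config, "prs_boundaries.tsv"))
  list(rows = nrow(out), snps = nrow(man))
}

## cohort + per-stage score files -> one analysis table
assemble_from_files <- function(config) {
  cohort <- read_cohort_csv(require_stage_file(config, "cohort.csv", "simulate"))
  diet <- read_scores_csv(require_stage_file(config, "diet_scores.csv", "score-diet"))
  prs <- read_scores_csv(require_stage_file(config, "prs.csv", "build-prs"))
  d <- merge(cohort, diet, by = "participant_id", sort = FALSE)
  d <- merge(d, prs, by = "participant_id", sort = FALSE)
  d <- d[order(d$participant_id), , drop = FALSE]
  d$bmi_group <- factor(c("<25", "25 to <30", ">=30")[
    .bincode(d$bmi, c(-Inf, 25, 30, Inf), right = FALSE)],
    levels = c("<25", "25 to <30", ">=30"))
  d
}

fit_rows <- function(fit, exposure_name) {
  tt <- fit$terms
  data.frame(exposure = exposure_name, level = tt$level, n = tt$n,
             events = tt$events, person_years = round(tt$person_years, 1),
             coef = tt$coef, se = tt$se, hr = tt$hr,
             lower = tt$lower, upper = tt$upper, p = tt$p)
}

stage_fit <- function(config) {
  d <- assemble_from_files(config)
  cp <- diet_cutpoints()
  out <- list()
  score_adj <- config$adjust_diet
  out$wcrf <- fit_rows(fit_cox(d, "wcrf_group", score_adj), "wcrf_group")
  out$ivd <- fit_rows(fit_cox(d, "iv_diet_tertile", score_adj), "iv_diet_tertile")
  for (food in names(cp)) {
    adj <- score_adj
    if (food != "alcohol") adj <- unique(c(adj, "alcohol_cat"))
    col <- paste0(food, "_cat")
    ft <- fit_cox(d, col, adj)
    rows <- fit_rows(ft, col)
    tr <- p_trend(d, col, adj)
    rows$p_trend <- c(tr$p, rep(NA, nrow(rows) - 1))
    out[[food]] <- rows
  }
  for (v in c("prs_unw", "prs_beta", "prs_iv")) {
    out[[paste0(v, "_t")]] <- fit_rows(
      fit_cox(d, paste0(v, "_tertile"), config$adjust_prs), paste0(v, "_tertile"))
    out[[paste0(v, "_d")]] <- fit_rows(
      fit_cox(d, paste0(v, "_decile"), config$adjust_prs), paste0(v, "_decile"))
  }
  out <- lapply(out, function(x) {
    if (!"p_trend" %in% names(x)) x$p_trend <- NA_real_
    x
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  write_tsv(tab, stage_file(config, "fits.tsv"))
  list(rows = nrow(tab), models = length(out))
}

stage_joint <- function(config) {
  d <- assemble_from_files(config)
  out <- list()
  for (sc in c("wcrf_group", "iv_diet_tertile")) {
    jt <- joint_effect_table(d, sc, "prs_iv_tertile", config$adjust_joint)
    lrt <- lrt_interaction(d, sc, "prs_iv_tertile", config$adjust_joint)
    rows <- fit_rows(jt, paste0(sc, " x prs_iv_tertile"))
    rows$diet_level <- jt$terms$diet_level
    rows$prs_level <- jt$terms$prs_level
    rows$p_interaction <- c(lrt$p, rep(NA, nrow(rows) - 1))
    out[[sc]] <- rows
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  write_tsv(tab, stage_file(config, "joint.tsv"))
  list(rows = nrow(tab))
}

stage_report <- function(config) {
  d <- assemble_from_files(config)
  cr_all <- list(); ex_all <- list(); af_all <- list()
  for (sc in c("wcrf_group", "iv_diet_tertile")) {
    f1 <- droplevels(factor(d[[sc]]))
    d$.joint <- interaction(f1, d$prs_iv_tertile, sep = " | ")
    cr <- cumulative_risk_at_80(d, ".joint", config$adjust_joint)
    parts <- strsplit(as.character(cr$cell), " | ", fixed = TRUE)
    cr <- data.frame(score = sc,
                     diet_level = vapply(parts, `[`, "", 1),
                     prs_level = vapply(parts, `[`, "", 2),
                     cr[, c("n", "events", "cr_percent")])
    cr_all[[sc]] <- cr
    ref <- cr$cr_percent[cr$diet_level == levels(f1)[1] & cr$prs_level == "low"]
    worst_diet <- levels(f1)[length(levels(f1))]
    ex_all[[sc]] <- data.frame(
      score = sc,
      contrast = c("diet_alone", "prs_alone"),
      excess_percent = c(
        excess_risk(cr$cr_percent[cr$diet_level == worst_diet & cr$prs_level == "low"], ref),
        excess_risk(cr$cr_percent[cr$diet_level == levels(f1)[1] & cr$prs_level == "high"], ref)))
    expo_lv <- worst_diet
    ft <- fit_cox(d, sc, config$adjust_joint)
    hr <- ft$terms$hr[ft$terms$level == expo_lv]
    prev <- mean(f1 == expo_lv, na.rm = TRUE)
    af_all[[sc]] <- data.frame(score = sc, exposure_level = expo_lv,
                               prevalence = round(prev, 4), hr = hr,
                               af = attributable_fraction(prev, hr, config$af_method))
  }
  ftp <- fit_cox(d, "prs_iv_tertile", config$adjust_prs)
  hrp <- ftp$terms$hr[ftp$terms$level == "high"]
  prevp <- mean(d$prs_iv_tertile == "high", na.rm = TRUE)
  af_all$prs <- data.frame(score = "prs_iv_tertile", exposure_level = "high",
                           prevalence = round(prevp, 4), hr = hrp,
                           af = attributable_fraction(prevp, hrp, config$af_method))
  write_tsv(do.call(rbind, cr_all), stage_file(config, "cumulative_risk.tsv"))
  write_tsv(do.call(rbind, ex_all), stage_file(config, "excess_risk.tsv"))
  af <- do.call(rbind, af_all); rownames(af) <- NULL
  write_tsv(af, stage_file(config, "attributable_fraction.tsv"))
  list(cr_rows = sum(vapply(cr_all, nrow, 0L)), af_rows = nrow(af))
}
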