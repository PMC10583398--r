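## row filter shared by all model-fitting functions: exposure must be
## observed (complete-case); categorical adjusters keep an explicit
## "missing" level; numeric adjusters are complete-case
model_frame <- function(data, vars_exposure, adjust, outcome, timescale = "followup") {
  d <- data
  for (v in vars_exposure) {
    x <- d[[v]]
    if (is.null(x)) stop("no such column: ", v)
    drop <- is.na(x) | (is.factor(x) & as.character(x) == "missing")
    d <- d[!drop, , drop = FALSE]
    if (is.factor(d[[v]])) d[[v]] <- droplevels(d[[v]])
  }
  for (v in adjust) {
    x <- d[[v]]
    if (is.null(x)) stop("no such adjustment column: ", v)
    if (is.numeric(x)) d <- d[!is.na(x), , drop = FALSE]
    else d[[v]] <- with_missing_level(x)
  }
  ev <- switch(outcome,
               crc = d$event,
               colon = as.integer(d$event == 1 & d$event_subtype == "colon"),
               rectal = as.integer(d$event == 1 & d$event_subtype == "rectal"),
               stop("outcome must be crc, colon or rectal"))
  d$.event <- ev   # other-subsite cases are censored at diagnosis
  d
}

cox_formula <- function(terms, timescale) {
  lhs <- if (timescale == "age") {
    "survival::Surv(enrollment_age, enrollment_age + followup_time, .event)"
  } else {
    "survival::Surv(followup_time, .event)"
  }
  stats::as.formula(paste(lhs, "~", paste(terms, collapse = " + ")))
}

#' Fit an adjusted Cox proportional-hazards model
#'
#' Maximum partial likelihood with Efron tie handling via
#' [survival::coxph()].  Rows with a missing exposure are dropped
#' (complete-case per model); categorical adjustment covariates carry their
#' "missing" answers as an explicit level; numeric adjusters are
#' complete-case.  An exposure level with zero events is flagged and its
#' estimate withheld.
#'
#' @param data analysis table from [build_analysis_table()].
#' @param exposure name of the exposure column (factor; first level is the
#'   reference unless `ref` is given).
#' @param adjust character vector of adjustment columns.
#' @param outcome "crc" (default), "colon" or "rectal"; subsite analyses
#'   censor the other subsite's cases at diagnosis.
#' @param ref optional reference level for the exposure.
#' @param timescale "followup" (time-on-study, default) or "age" (with
#'   delayed entry at enrollment age).
#' @return object of class `crc_cox_fit`: list with `terms` (tidy
#'   coefficient table: term, level, n, events, person_years, coef, se, hr,
#'   lower, upper, p), `loglik`, `n`, `n_events`, `converged`, `flags`, and
#'   the underlying `model`.
#' @export
fit_cox <- function(data, exposure, adjust = character(), outcome = "crc",
                    ref = NULL, timescale = "followup") {
  d <- model_frame(data, exposure, adjust, outcome, timescale)
  if (!is.factor(d[[exposure]])) d[[exposure]] <- factor(d[[exposure]])
  if (!is.null(ref)) d[[exposure]] <- stats::relevel(d[[exposure]], ref)
  if (nrow(d) == 0) stop("no complete-case rows left")
  per <- per_level_summary(d, exposure)
  if (any(per$events < 1)) {
    warning("exposure level(s) with zero events: estimates withheld")
  }
  fml <- cox_formula(c(exposure, adjust), timescale)
  fit <- survival::coxph(fml, data = d, ties = "efron")
  tidy <- tidy_cox(fit, exposure, d)
  tidy <- merge(per, tidy, by = "level", all.x = TRUE, sort = FALSE)
  zero <- tidy$events < 1 & tidy$level != levels(d[[exposure]])[1]
  tidy[zero, c("coef", "se", "hr", "lower", "upper", "p")] <- NA
  structure(list(terms = tidy, loglik = fit$loglik[length(fit$loglik)],
                 n = nrow(d), n_events = sum(d$.event),
                 converged = !any(is.na(stats::coef(fit))),
                 flags = if (any(zero)) "zero_event_level" else character(),
                 exposure = exposure, adjust = adjust, outcome = outcome,
                 timescale = timescale, model = fit),
            class = "crc_cox_fit")
}

per_level_summary <- function(d, exposure) {
  lv <- levels(d[[exposure]])
  data.frame(level = lv,
             n = as.integer(table(d[[exposure]])[lv]),
             events = as.integer(tapply(d$.event, d[[exposure]], sum)[lv]),
             person_years = as.numeric(tapply(d$followup_time, d[[exposure]], sum)[lv]))
}

tidy_cox <- function(fit, exposure, d) {
  cf <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  keep <- which(startsWith(names(cf), exposure))
  lv <- levels(d[[exposure]])
  out <- data.frame(level = lv, coef = 0, se = 0, hr = 1,
                    lower = NA_real_, upper = NA_real_, p = NA_real_)
  if (length(keep)) {
    lev_of <- substring(names(cf)[keep], nchar(exposure) + 1)
    i <- match(lev_of, out$level)
    out$coef[i] <- cf[keep]
    out$se[i] <- se[keep]
    out$hr[i] <- exp(cf[keep])
    out$lower[i] <- exp(cf[keep] - z975 * se[keep])
    out$upper[i] <- exp(cf[keep] + z975 * se[keep])
    out$p[i] <- 2 * stats::pnorm(-abs(cf[keep] / se[keep]))
  }
  out
}

#' @export
print.crc_cox_fit <- function(x, digits = 3, ...) {
  cat("Cox model (", x$timescale, " timescale, outcome ", x$outcome, "): ",
      x$exposure, "\n", sep = "")
  cat("n =", x$n, " events =", x$n_events, "\n")
  tt <- x$terms
  tt$hr_ci <- ifelse(is.na(tt$p) & tt$hr == 1, "1.00 (ref.)",
                     sprintf("%.2f (%.2f-%.2f)", tt$hr, tt$lower, tt$upper))
  print(tt[, c("level", "n", "events", "person_years", "hr_ci")],
        row.names = FALSE, digits = digits)
  invisible(x)
}

#' Trend test across ordered exposure categories
#'
#' Wald test of a single linear term obtained by replacing the categorical
#' exposure with integer codes 0, 1, 2, ... in the order of its levels,
#' keeping the same adjustment set.
#'
#' @inheritParams fit_cox
#' @return list with `coef`, `se`, `z`, `p`.
#' @export
p_trend <- function(data, exposure, adjust = character(), outcome = "crc",
                    timescale = "followup") {
  d <- model_frame(data, exposure, adjust, outcome, timescale)
  f <- droplevels(factor(d[[exposure]]))
  if (nlevels(f) < 3) stop("trend test needs an ordered exposure with >= 3 levels")
  d$.trend <- as.integer(f) - 1L
  fit <- survival::coxph(cox_formula(c(".trend", adjust), timescale),
                         data = d, ties = "efron")
  b <- stats::coef(fit)[".trend"]
  s <- sqrt(diag(fit$var))[which(names(stats::coef(fit)) == ".trend")]
  z <- b / s
  list(coef = unname(b), se = unname(s), z = unname(z),
       p = unname(2 * stats::pnorm(-abs(z))))
}

#' Likelihood-ratio test for a diet-by-PRS interaction
#'
#' Compares the adjusted model containing the two exposures with a model
#' additionally containing their product (categorical) interaction, on the
#' identical row set: statistic = 2 (ll_full - ll_reduced), chi-square with
#' df = number of interaction coefficients.
#'
#' @param data analysis table.
#' @param exposure,modifier names of the two categorical terms.
#' @inheritParams fit_cox
#' @return list with `statistic`, `df`, `p`, `n`, plus both fitted models.
#' @export
lrt_interaction <- function(data, exposure, modifier, adjust = character(),
                            outcome = "crc", timescale = "followup") {
  d <- model_frame(data, c(exposure, modifier), adjust, outcome, timescale)
  red <- survival::coxph(cox_formula(c(exposure, modifier, adjust), timescale),
                         data = d, ties = "efron")
  full <- survival::coxph(cox_formula(c(paste0(exposure, " * ", modifier), adjust),
                                      timescale), data = d, ties = "efron")
  if (red$n != full$n) stop("nested fits used different row sets: LRT invalid")
  df <- sum(!is.na(stats::coef(full))) - sum(!is.na(stats::coef(red)))
  stat <- max(0, 2 * (full$loglik[2] - red$loglik[2]))
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       n = full$n, reduced = red, full = full)
}

#' Joint diet-by-PRS category model
#'
#' Fits one categorical term over the cross-classification of a dietary
#' grouping and the PRS tertile, with joint reference (healthy diet, low
#' PRS), reporting per-cell n, events, person-years, HR and CI.
#'
#' @param data analysis table.
#' @param diet,prs names of the two factors; their first levels form the
#'   reference cell.
#' @inheritParams fit_cox
#' @return `crc_cox_fit` whose `terms` has one row per joint cell, with the
#'   two constituent labels in columns `diet_level` and `prs_level`.
#' @export
joint_effect_table <- function(data, diet, prs, adjust = character(),
                               outcome = "crc", timescale = "followup") {
  d <- model_frame(data, c(diet, prs), adjust, outcome, timescale)
  fd <- droplevels(factor(d[[diet]])); fp <- droplevels(factor(d[[prs]]))
  d$.joint <- interaction(fd, fp, sep = " | ", lex.order = FALSE)
  fit <- fit_cox(d, ".joint", adjust, outcome, timescale = timescale)
  parts <- strsplit(as.character(fit$terms$level), " | ", fixed = TRUE)
  fit$terms$diet_level <- vapply(parts, `[`, "", 1)
  fit$terms$prs_level <- vapply(parts, `[`, "", 2)
  fit$exposure <- paste0(diet, " x ", prs)
  fit
}

#' Per-stratum Cox fits
#'
#' Applies [fit_cox()] within each level of a stratifying factor (e.g. PRS
#' tertile or sex), or - with `strata = "subsite"` - to the colon and rectal
#' outcomes separately (the other subsite's cases censored at diagnosis).
#'
#' @param data analysis table.
#' @param strata name of the stratifying column, or "subsite".
#' @inheritParams fit_cox
#' @return named list of `crc_cox_fit` objects.
#' @export
stratified_fits <- function(data, exposure, adjust = character(),
                            strata, outcome = "crc", timescale = "followup") {
  if (identical(strata, "subsite")) {
    return(list(colon = fit_cox(data, exposure, adjust, "colon", timescale = timescale),
                rectal = fit_cox(data, exposure, adjust, "rectal", timescale = timescale)))
  }
  f <- data[[strata]]
  if (is.null(f)) stop("no such stratum column: ", strata)
  lv <- setdiff(levels(factor(f)), "missing")
  out <- lapply(lv, function(l) {
    fit_cox(data[!is.na(f) & f == l, , drop = FALSE], exposure, adjust,
            outcome, timescale = timescale)
  })
  names(out) <- lv
  out
}
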