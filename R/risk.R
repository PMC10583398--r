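#' Standardized cumulative risk from a cumulative hazard
#'
#' The marginal (directly standardized) risk implied by a baseline cumulative
#' hazard `H` and a set of individual linear predictors:
#' \eqn{1 - \mathrm{mean}_i\, \exp(-H e^{lp_i})}.  With no covariates
#' (`lp = 0`) this reduces to the closed form \eqn{1 - e^{-H}}.
#'
#' @param cumhaz baseline cumulative hazard at the target age (scalar).
#' @param lp numeric vector of uncentered linear predictors (default 0).
#' @return risk as a proportion in [0, 1].
#' @examples
#' cumulative_risk_from_cumhaz(80 * 0.001)  # constant hazard 0.001/yr to age 80
#' @export
cumulative_risk_from_cumhaz <- function(cumhaz, lp = 0) {
  stopifnot(length(cumhaz) == 1, cumhaz >= 0)
  1 - mean(exp(-cumhaz * exp(lp)))
}

#' Covariate-adjusted cumulative risk at age 80
#'
#' Fits a Cox model on the age timescale with delayed entry at enrollment
#' age, a single categorical cell term (e.g. the joint diet-by-PRS category)
#' and the adjustment covariates, then computes for each cell the
#' standardized risk \eqn{1 - \mathrm{mean}_i S_i(80)} over that cell's own
#' participants, where \eqn{S_i(80) = \exp(-H_0(80) e^{lp_i})} uses the
#' Breslow baseline cumulative hazard and participant i's covariate-specific
#' linear predictor (marginal standardization within cell).
#'
#' @param data analysis table with `enrollment_age`, `followup_time`, `event`.
#' @param cell name of the categorical cell column.
#' @param adjust adjustment covariates.
#' @param age target age (default 80).
#' @param outcome "crc", "colon" or "rectal".
#' @return data.frame with one row per cell: `cell`, `n`, `events`,
#'   `cr_percent` (0-100, two meaningful decimals at typical scales);
#'   `attr(, "extrapolated")` is TRUE when no event-time support reaches
#'   `age` and the last observed baseline hazard was carried forward.
#' @export
cumulative_risk_at_80 <- function(data, cell, adjust = character(), age = 80,
                                  outcome = "crc") {
  d <- model_frame(data, cell, adjust, outcome, timescale = "age")
  f <- droplevels(factor(d[[cell]]))
  d[[cell]] <- f
  fit <- survival::coxph(cox_formula(c(cell, adjust), "age"),
                         data = d, ties = "efron", model = TRUE)
  bh <- survival::basehaz(fit, centered = FALSE)
  extrapolated <- max(bh$time) < age
  H <- if (any(bh$time <= age)) max(bh$hazard[bh$time <= age]) else 0
  lp <- stats::predict(fit, newdata = d, type = "lp", reference = "zero")
  cr <- vapply(levels(f), function(l) {
    cumulative_risk_from_cumhaz(H, lp[f == l])
  }, numeric(1))
  out <- data.frame(cell = levels(f),
                    n = as.integer(table(f)[levels(f)]),
                    events = as.integer(tapply(d$.event, f, sum)[levels(f)]),
                    cr_percent = round(100 * cr, 4))
  attr(out, "extrapolated") <- extrapolated
  attr(out, "cumhaz_at_age") <- H
  out
}

#' Excess risk between cumulative-risk estimates
#'
#' Pairwise difference of cumulative risks sharing a reference cell, e.g.
#' the excess due to diet alone is CR(unhealthy diet, low PRS) minus
#' CR(healthy diet, low PRS).
#'
#' @param exposed,reference cumulative risks (same units, typically percent).
#' @return `exposed - reference`, vectorized.
#' @examples
#' excess_risk(2.56, 2.28)  # 0.28
#' @export
excess_risk <- function(exposed, reference) {
  exposed - reference
}

#' Population attributable fraction
#'
#' Levin's prevalence-based formula
#' \eqn{AF = p(HR - 1) / (1 + p(HR - 1))}: the proportional reduction in
#' incidence expected if the exposed had been unexposed, given exposure
#' prevalence `p` and adjusted hazard ratio `hr`.  `method = "miettinen"`
#' gives the case-based alternative \eqn{p_c (HR - 1)/HR} where `p` is then
#' the exposure prevalence among cases.
#'
#' @param p exposure prevalence in (0, 1) (among the population for Levin,
#'   among cases for Miettinen).
#' @param hr adjusted hazard ratio (> 0).
#' @param method "levin" (default) or "miettinen".
#' @return attributable fraction (a proportion, < 1; negative for protective
#'   exposures).
#' @examples
#' attributable_fraction(0.5, 2)  # 1/3
#' @export
attributable_fraction <- function(p, hr, method = c("levin", "miettinen")) {
  method <- match.arg(method)
  stopifnot(all(p > 0 & p < 1), all(hr > 0))
  if (method == "levin") {
    x <- p * (hr - 1)
    if (any(x <= -1)) stop("undefined attributable fraction: p*(HR-1) <= -1")
    x / (1 + x)
  } else {
    p * (hr - 1) / hr
  }
}
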