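# Independent oracles used across the test files.  None of these call the
# package's fitting path.

# Efron-tie partial log-likelihood for a single covariate, written directly
# from its definition: for each distinct event time with d tied events,
# sum over j = 0..d-1 of log(sum_{risk} r_i - (j/d) sum_{tied} r_i).
efron_loglik <- function(beta, time, status, x) {
  r <- exp(beta * x)
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    tied <- which(time == t & status == 1)
    risk <- which(time >= t)
    d <- length(tied)
    ll <- ll + sum(beta * x[tied])
    for (j in seq_len(d) - 1) {
      ll <- ll - log(sum(r[risk]) - (j / d) * sum(r[tied]))
    }
  }
  ll
}

# minimal exponential survival data with a binary or categorical exposure;
# hazard = rate0 * exp(sum of per-level log HRs), administrative censoring
make_surv_data <- function(n, loghr_by_level, rate0 = 0.1, horizon = 10,
                           levels = names(loghr_by_level)) {
  g <- factor(sample(levels, n, replace = TRUE), levels = levels)
  rate <- rate0 * exp(unname(loghr_by_level[as.character(g)]))
  te <- rexp(n) / rate
  time <- pmin(te, horizon)
  data.frame(followup_time = time, event = as.integer(te <= horizon),
             exposure = g,
             event_subtype = factor(ifelse(te <= horizon, "colon", "none"),
                                    levels = c("none", "colon", "rectal")))
}

# tiny curated manifest for PRS unit tests
toy_manifest <- function(betas, ses, eaf = NULL) {
  data.frame(snp_id = paste0("rs", seq_along(betas)), beta = betas, se = ses,
             available = TRUE, eaf = eaf %||% rep(0.5, length(betas)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reference-category assignments for all 11 foods (used to build category
# tables by hand)
reference_categories <- function(n = 1) {
  cp <- diet_cutpoints()
  out <- data.frame(row.names = seq_len(n))
  for (food in names(cp)) {
    labs <- cp[[food]]$labels
    out[[paste0(food, "_cat")]] <- factor(rep(labs[1], n), levels = labs)
  }
  out
}
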