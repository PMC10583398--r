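`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantile binning of a numeric score
#'
#' Assigns each value to one of `k` empirical quantile bins.  Breaks are
#' type-1 sample quantiles; intervals are right-closed so a value sitting
#' exactly on a break falls in the lower bin.
#'
#' @param x numeric vector (no NAs contribute to the breaks; NA in, NA out).
#' @param k number of bins (3 for tertiles, 10 for deciles).
#' @param labels optional character vector of length `k`.
#' @return factor of length `length(x)` with `k` levels; the numeric break
#'   points are attached as `attr(, "breaks")` (including -Inf/Inf ends).
#' @examples
#' bin_scores(1:9, 3)            # 1-3 / 4-6 / 7-9
#' bin_scores(runif(100), 10)
#' @export
bin_scores <- function(x, k = 3, labels = NULL) {
  ok <- !is.na(x)
  if (sum(ok) < k) stop("need at least k = ", k, " non-missing scores")
  qs <- stats::quantile(x[ok], probs = seq_len(k - 1) / k, type = 1, names = FALSE)
  if (anyDuplicated(qs) || length(unique(c(qs, range(x[ok])))) < k) {
    stop("degenerate score distribution: quantile breaks are not distinct")
  }
  labels <- labels %||% paste0("Q", seq_len(k))
  brk <- c(-Inf, qs, Inf)
  idx <- .bincode(x, breaks = brk, right = TRUE, include.lowest = TRUE)
  out <- factor(labels[idx], levels = labels)
  attr(out, "breaks") <- brk
  out
}

tertile_labels <- c("T1", "T2", "T3")
prs_tertile_labels <- c("low", "intermediate", "high")
decile_labels <- paste0("D", 1:10)

## factor with an explicit "missing" level replacing NA (used for adjustment
## covariates, mirroring questionnaire "missing" categories)
with_missing_level <- function(x) {
  f <- if (is.factor(x)) x else factor(x)
  if (anyNA(f) || "missing" %in% levels(f)) {
    lv <- c(setdiff(levels(f), "missing"), "missing")
    f <- factor(ifelse(is.na(as.character(f)), "missing", as.character(f)), levels = lv)
  }
  f
}

z975 <- 1.959964
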