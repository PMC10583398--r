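#' Synthetic CRC susceptibility variant manifest
#'
#' Builds a synthetic stand-in for a curated table of colorectal cancer
#' susceptibility SNPs with external per-allele log-odds weights.  The layout
#' mirrors the common curation situation: of 127 candidate loci, 78 are
#' directly available in the genotyping data, and 20 of the 49 unavailable
#' loci have a linkage-disequilibrium proxy with r-squared above 0.8, so that
#' 98 SNPs survive curation.  All identifiers, positions, weights and allele
#' frequencies are generated deterministically from `seed`; they are not real
#' GWAS estimates.
#'
#' @param n_candidates number of candidate rows (default 127).
#' @param n_available number of rows with `available = TRUE` (default 78).
#' @param n_good_proxies number of unavailable rows given a proxy with
#'   `proxy_r2 > 0.8` (default 20).
#' @param seed integer seed for the deterministic draw.
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `eaf` (effect-allele frequency),
#'   `available`, `ambiguous`, `duplicate_of`, `proxy_id`, `proxy_r2`.
#' @seealso [select_variants()]
#' @export
synthetic_variant_manifest <- function(n_candidates = 127, n_available = 78,
                                       n_good_proxies = 20, seed = 20) {
  stopifnot(n_available <= n_candidates,
            n_good_proxies <= n_candidates - n_available)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_candidates
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, n, replace = TRUE)
  oa <- vapply(ea, function(a) {
    # avoid strand-ambiguous A/T and G/C pairs: curation assumes them excluded
    sample(setdiff(alleles, c(a, chartr("ACGT", "TGCA", a))), 1)
  }, character(1))
  m <- data.frame(
    snp_id = sprintf("rs%07d", sample(1e6:9e6, n)),
    chrom = sample(1:22, n, replace = TRUE),
    pos = sample(1e5:2.4e8, n),
    effect_allele = ea,
    other_allele = oa,
    beta = round(stats::rnorm(n, 0.08, 0.04), 4),   # per-allele log-odds
    se = round(stats::runif(n, 0.012, 0.045), 4),
    eaf = round(stats::runif(n, 0.08, 0.92), 3),
    available = FALSE,
    ambiguous = FALSE,
    duplicate_of = NA_character_,
    proxy_id = NA_character_,
    proxy_r2 = NA_real_,
    stringsAsFactors = FALSE
  )
  m$available[seq_len(n_available)] <- TRUE
  unavail <- which(!m$available)
  good <- unavail[seq_len(n_good_proxies)]
  bad <- setdiff(unavail, good)
  m$proxy_id[good] <- sprintf("rs%07d", sample(1e4:9e5, length(good)))
  m$proxy_r2[good] <- round(stats::runif(length(good), 0.81, 0.99), 3)
  # some of the remaining unavailable rows have only a weak proxy, the rest none
  weak <- bad[seq_len(floor(length(bad) / 2))]
  m$proxy_id[weak] <- sprintf("rs%07d", sample(1e4:9e5, length(weak)))
  m$proxy_r2[weak] <- round(stats::runif(length(weak), 0.30, 0.80), 3)
  m[sample(n), , drop = FALSE]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Curate a variant manifest for PRS computation
#'
#' Applies the selection cascade used when assembling an external-weight PRS:
#' duplicate, strand-ambiguous and high-LD-flagged rows are dropped; available
#' rows are kept; an unavailable row is replaced by its LD proxy when
#' `proxy_r2 > 0.8` (strict), the proxy inheriting the index SNP's `beta` and
#' `se` unchanged; all other unavailable rows are dropped.
#'
#' @param manifest data.frame as returned by [synthetic_variant_manifest()] or
#'   [read_variant_manifest()].  An optional logical column `high_ld` marks
#'   rows to drop for within-panel LD.
#' @param r2_threshold proxies must exceed this r-squared (default 0.8).
#' @return data.frame of selected scoring SNPs (columns as the manifest plus
#'   `source` = "direct" or "proxy"); the per-step selection ledger is attached
#'   as `attr(, "ledger")`.
#' @export
select_variants <- function(manifest, r2_threshold = 0.8) {
  required <- c("snp_id", "beta", "se", "available")
  miss <- setdiff(required, names(manifest))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  n0 <- nrow(manifest)
  ledger <- data.frame(step = character(), removed = integer(), remaining = integer())
  note <- function(step, before, after) {
    rbind(ledger, data.frame(step = step, removed = before - after, remaining = after))
  }

  m <- manifest
  dup <- if ("duplicate_of" %in% names(m)) !is.na(m$duplicate_of) else rep(FALSE, nrow(m))
  m <- m[!dup, , drop = FALSE];            ledger <- note("duplicate", n0, nrow(m))
  amb <- if ("ambiguous" %in% names(m)) isTRUE_vec(m$ambiguous) else rep(FALSE, nrow(m))
  k <- nrow(m); m <- m[!amb, , drop = FALSE]; ledger <- note("ambiguous", k, nrow(m))
  hld <- if ("high_ld" %in% names(m)) isTRUE_vec(m$high_ld) else rep(FALSE, nrow(m))
  k <- nrow(m); m <- m[!hld, , drop = FALSE]; ledger <- note("high_ld", k, nrow(m))

  if (any(m$available & (is.na(m$se) | m$se <= 0))) {
    stop("usable manifest rows must have se > 0")
  }
  direct <- m[m$available, , drop = FALSE]
  direct$source <- "direct"
  unav <- m[!m$available, , drop = FALSE]
  has_proxy <- !is.na(unav$proxy_r2) & unav$proxy_r2 > r2_threshold &
    !is.na(unav$proxy_id)
  if ("proxy_available" %in% names(unav)) {
    # a nominated proxy that is itself absent from the data cannot rescue
    # its index SNP
    dead <- has_proxy & !isTRUE_vec(unav$proxy_available)
    if (any(dead)) {
      warning(sum(dead), " proxy SNP(s) unavailable: index variant(s) dropped")
      has_proxy <- has_proxy & !dead
    }
  }
  proxies <- unav[has_proxy, , drop = FALSE]
  if (nrow(proxies)) {
    proxies$snp_id <- proxies$proxy_id   # scored at the proxy locus,
    proxies$source <- "proxy"            # with the index SNP's beta and se
  }
  dropped <- unav[!has_proxy, , drop = FALSE]
  ledger <- rbind(ledger,
    data.frame(step = "unavailable_no_proxy", removed = nrow(dropped),
               remaining = nrow(direct) + nrow(proxies)))
  out <- rbind(direct, if (nrow(proxies)) proxies)
  rownames(out) <- NULL
  attr(out, "ledger") <- ledger
  attr(out, "dropped") <- dropped$snp_id
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Read / write a variant manifest as TSV
#' @param path file path.
#' @return `read_variant_manifest()` returns the manifest data.frame.
#' @rdname variant_manifest_io
#' @export
read_variant_manifest <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(snp_id = "character"))
}

#' @param manifest manifest data.frame.
#' @rdname variant_manifest_io
#' @export
write_variant_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
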