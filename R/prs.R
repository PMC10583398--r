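#' Compute the three polygenic risk score variants
#'
#' Given per-participant effect-allele dosages and a curated manifest, computes
#' \deqn{PRS_{unw} = \sum_i SNP_i, \quad
#'       PRS_{\beta} = \sum_i \beta_i SNP_i, \quad
#'       PRS_{IV} = \sum_i (\beta_i / SE_i) SNP_i,}
#' where \eqn{SNP_i} is the dosage (0-2, possibly fractional for imputed
#' genotypes) of the effect allele of variant i.  A participant with any
#' missing dosage over the manifest SNPs gets NA scores (complete-case).
#'
#' @param dosages numeric matrix, participants x SNPs, entries in [0, 2];
#'   column names must cover `manifest$snp_id`.
#' @param manifest curated manifest (see [select_variants()]) with `snp_id`,
#'   `beta`, `se`.
#' @param flip optional logical vector (named by snp_id or in manifest order):
#'   TRUE where the dosage file counts the *other* allele, in which case the
#'   dosage is reflected to `2 - d` before scoring.
#' @return data.frame with columns `prs_unw`, `prs_beta`, `prs_iv`, one row
#'   per participant (rownames carried over from `dosages`).
#' @examples
#' d <- rbind(c(1, 2))
#' colnames(d) <- c("rs1", "rs2")
#' m <- data.frame(snp_id = c("rs1", "rs2"), beta = c(0.1, -0.2), se = c(0.05, 0.1))
#' compute_prs(d, m)  # unw 3, beta -0.3, iv -2
#' @export
compute_prs <- function(dosages, manifest, flip = NULL) {
  stopifnot(is.matrix(dosages))
  miss <- setdiff(manifest$snp_id, colnames(dosages))
  if (length(miss)) {
    stop("no dosage column for manifest SNP(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  if (any(manifest$se <= 0 | is.na(manifest$se))) stop("manifest se must be > 0")
  d <- dosages[, manifest$snp_id, drop = FALSE]
  rng <- range(d, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (!is.null(flip)) {
    if (!is.null(names(flip))) flip <- flip[manifest$snp_id]
    stopifnot(length(flip) == nrow(manifest))
    flip[is.na(flip)] <- FALSE
    if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  }
  out <- data.frame(
    prs_unw = rowSums(d),
    prs_beta = as.vector(d %*% manifest$beta),
    prs_iv = as.vector(d %*% (manifest$beta / manifest$se))
  )
  rownames(out) <- rownames(dosages)
  out
}

#' Add tertile and decile bins to a PRS table
#'
#' Empirical tertiles (labelled low / intermediate / high) and deciles
#' (D1-D10) are computed over the analyzed cohort for each score variant;
#' break points are recorded in `attr(, "breaks")` of each bin column.
#'
#' @param prs data.frame from [compute_prs()].
#' @return the input with `<score>_tertile` and `<score>_decile` factor
#'   columns appended.
#' @export
bin_prs <- function(prs) {
  for (v in c("prs_unw", "prs_beta", "prs_iv")) {
    prs[[paste0(v, "_tertile")]] <- bin_scores(prs[[v]], 3, prs_tertile_labels)
    prs[[paste0(v, "_decile")]] <- bin_scores(prs[[v]], 10, decile_labels)
  }
  prs
}

#' Dosage matrix I/O
#'
#' TSV layout: first column `participant_id`, remaining columns one per SNP
#' (header = snp_id), entries in [0, 2].  The VCF reader takes per-sample
#' dosages from the `DS` FORMAT field when present, otherwise counts ALT
#' alleles in `GT`; the ALT allele is taken as the counted allele.
#'
#' @param path file path.
#' @return numeric matrix participants x SNPs with dimnames.
#' @rdname dosage_io
#' @export
read_dosages_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @param dosages matrix to write.
#' @rdname dosage_io
#' @export
write_dosages_tsv <- function(dosages, path) {
  df <- data.frame(participant_id = rownames(dosages) %||% seq_len(nrow(dosages)),
                   dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dosage_io
#' @export
read_dosages_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- v@fix[, "ID"]
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    m <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    m <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  rownames(m) <- ids
  t(m)   # participants x SNPs
}
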