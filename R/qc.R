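#' SNP quality filtering
#'
#' Removes SNPs with missing-data fraction strictly above `max_missing`,
#' heterozygote fraction strictly above `max_het`, or minor allele frequency
#' strictly below `min_maf`. Filters are applied in the order
#' missing -> het -> MAF so that each removed SNP has a single primary
#' reason. MAF is allele-based: heterozygotes contribute one allele of each
#' kind and missing calls are excluded from the denominator. The line set
#' is never changed.
#'
#' @param geno Lines x SNPs dosage matrix (0/1/2/NA), unimputed.
#' @param max_missing,max_het,min_maf Thresholds (defaults 0.10, 0.10, 0.01).
#' @return A list of class `qc_result` with elements `geno` (the filtered
#'   matrix) and `report` (tibble: `snp`, `missing_frac`, `het_frac`, `maf`,
#'   `pass`, `reason`).
#' @export
qc_filter <- function(geno, max_missing = 0.10, max_het = 0.10,
                      min_maf = 0.01) {
  if (is.null(dim(geno)) || nrow(geno) == 0 || ncol(geno) == 0) {
    stop("empty genotype matrix", call. = FALSE)
  }
  n <- nrow(geno)
  n_miss <- colSums(is.na(geno))
  n_obs <- n - n_miss
  n_het <- colSums(geno == 1, na.rm = TRUE)
  ref <- colSums(geno, na.rm = TRUE)
  freq <- ifelse(n_obs > 0, ref / (2 * n_obs), NA_real_)
  maf <- pmin(freq, 1 - freq)
  missing_frac <- n_miss / n
  het_frac <- ifelse(n_obs > 0, n_het / n_obs, NA_real_)
  reason <- rep(NA_character_, ncol(geno))
  reason[missing_frac > max_missing] <- "missing"
  reason[is.na(reason) & het_frac > max_het] <- "het"
  reason[is.na(reason) & (is.na(maf) | maf < min_maf)] <- "maf"
  pass <- is.na(reason)
  report <- tibble::tibble(
    snp = colnames(geno), missing_frac = missing_frac,
    het_frac = het_frac, maf = maf, pass = pass, reason = reason
  )
  structure(list(geno = geno[, pass, drop = FALSE], report = report),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> ", sum(x$report$pass), " of ", nrow(x$report),
      " SNPs retained\n", sep = "")
  if (any(!x$report$pass)) {
    tab <- table(x$report$reason)
    cat("  removed:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.qc_result <- function(x, ...) x$report

#' @exportS3Method generics::glance
glance.qc_result <- function(x, ...) {
  tibble::tibble(
    n_snps = nrow(x$report),
    n_retained = sum(x$report$pass),
    n_missing = sum(x$report$reason == "missing", na.rm = TRUE),
    n_het = sum(x$report$reason == "het", na.rm = TRUE),
    n_maf = sum(x$report$reason == "maf", na.rm = TRUE)
  )
}

#' Encode raw bi-allelic calls as IBS dosages of the reference allele
#'
#' Homozygous calls for the reference-founder allele become 2, homozygous
#' alternative calls 0, heterozygous calls 1; missing calls are preserved.
#' Raw calls are two-letter genotypes such as `"AA"`, `"AB"`, `"BB"` (order
#' of letters irrelevant).
#'
#' @param calls Lines x SNPs character matrix of genotype calls (NA for
#'   missing).
#' @param panel `founder_panel` defining the reference allele letter per SNP.
#' @return Lines x SNPs integer dosage matrix.
#' @export
encode_ibs <- function(calls, panel) {
  snps <- colnames(calls)
  missing <- setdiff(snps, names(panel$ref_allele))
  if (length(missing)) {
    stop("SNP absent from founder panel: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ref <- panel$ref_allele[snps]
  out <- matrix(NA_integer_, nrow(calls), ncol(calls),
                dimnames = dimnames(calls))
  a1 <- substr(calls, 1, 1)
  a2 <- substr(calls, 2, 2)
  d <- (a1 == rep(ref, each = nrow(calls))) +
    (a2 == rep(ref, each = nrow(calls)))
  out[] <- as.integer(d)
  out
}

#' Render IBS dosages as raw letter calls (inverse of [encode_ibs()])
#'
#' @param geno Lines x SNPs dosage matrix (0/1/2/NA).
#' @param panel `founder_panel` with per-SNP allele letters.
#' @return Character matrix of two-letter genotype calls.
#' @export
decode_ibs <- function(geno, panel) {
  snps <- colnames(geno)
  ref <- rep(panel$ref_allele[snps], each = nrow(geno))
  alt <- rep(panel$alt_allele[snps], each = nrow(geno))
  out <- matrix(NA_character_, nrow(geno), ncol(geno),
                dimnames = dimnames(geno))
  out[which(geno == 2)] <- paste0(ref, ref)[which(geno == 2)]
  out[which(geno == 1)] <- paste0(ref, alt)[which(geno == 1)]
  out[which(geno == 0)] <- paste0(alt, alt)[which(geno == 0)]
  out
}

#' Mean imputation of missing dosages
#'
#' Replaces each missing call by the SNP's mean dosage over non-missing
#' lines; observed calls are untouched, so per-SNP means are preserved
#' exactly.
#'
#' @param geno Lines x SNPs dosage matrix.
#' @return Numeric matrix with no missing values.
#' @export
impute_mean <- function(geno) {
  all_miss <- colSums(!is.na(geno)) == 0
  if (any(all_miss)) {
    stop("SNP(s) with no observed calls cannot be mean-imputed: ",
         paste(head(colnames(geno)[all_miss], 5), collapse = ", "),
         call. = FALSE)
  }
  out <- apply(geno, 2, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v
  })
  rownames(out) <- rownames(geno)
  out
}

#' Place unmapped SNPs by chi-square association with mapped anchors
#'
#' For each query SNP, builds the 2x2 contingency table of homozygous
#' dosage classes (query 0/2 vs anchor 0/2, heterozygous and missing calls
#' excluded) against every mapped SNP, and assigns the query to the
#' chromosome and position of the anchor with the largest chi-square
#' statistic (ties broken by smaller p-value, then map order). Queries whose
#' best association does not reach the significance floor stay unassigned.
#'
#' @param query Lines x SNPs dosage matrix of unmapped SNPs (a single SNP
#'   may be passed as a named one-column matrix).
#' @param mapped Lines x SNPs dosage matrix of mapped SNPs (same lines).
#' @param map Genetic map covering the mapped SNPs.
#' @param alpha Significance floor before Bonferroni correction across
#'   anchors (default 0.05; the per-anchor floor is `alpha / n_anchors`).
#' @return A tibble `snp`, `chr`, `pos`, `anchor`, `chi_square`, `p`
#'   with `NA` placement for unassigned queries.
#' @export
assign_unmapped <- function(query, mapped, map, alpha = 0.05) {
  stopifnot(nrow(query) == nrow(mapped))
  anchors <- intersect(colnames(mapped), map$snp)
  mapped <- mapped[, anchors, drop = FALSE]
  pos <- map$pos[match(anchors, map$snp)]
  chr <- map$chr[match(anchors, map$snp)]
  floor_p <- alpha / length(anchors)
  res <- purrr::map_dfr(colnames(query), function(s) {
    q <- query[, s]
    chi <- rep(NA_real_, length(anchors))
    for (j in seq_along(anchors)) {
      a <- mapped[, j]
      keep <- !is.na(q) & !is.na(a) & q != 1 & a != 1
      if (sum(keep) < 4) next
      tab <- table(factor(q[keep], c(0, 2)), factor(a[keep], c(0, 2)))
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      chi[j] <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
    }
    if (all(is.na(chi))) {
      return(tibble::tibble(snp = s, chr = NA_character_, pos = NA_real_,
                            anchor = NA_character_, chi_square = NA_real_,
                            p = NA_real_))
    }
    p <- pchisq(chi, df = 1, lower.tail = FALSE)
    best <- which(chi == max(chi, na.rm = TRUE))
    if (length(best) > 1) best <- best[which.min(p[best])]
    best <- best[1]
    if (is.na(p[best]) || p[best] > floor_p) {
      tibble::tibble(snp = s, chr = NA_character_, pos = NA_real_,
                     anchor = anchors[best], chi_square = chi[best],
                     p = p[best])
    } else {
      tibble::tibble(snp = s, chr = as.character(chr[best]), pos = pos[best],
                     anchor = anchors[best], chi_square = chi[best],
                     p = p[best])
    }
  })
  res
}
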