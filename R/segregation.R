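#' Assign SNPs to allele-frequency groups
#'
#' The allele-frequency group (AFG) of a SNP is the number k of founders
#' carrying the reference-founder allele; the expected reference-allele
#' frequency in the population is k/8. SNPs monomorphic among the founders
#' (k = 0 or 8) are excluded. For k = 1 the unique founder is the reference
#' founder itself; for k = 7 it is the sole non-carrier.
#'
#' @param panel A `founder_panel`.
#' @return A tibble `snp`, `afg`, `expected_freq`, `unique_founder`
#'   (`NA` unless `afg` is 1 or 7).
#' @export
assign_afg <- function(panel) {
  if (anyNA(panel$alleles)) stop("founder panel has missing calls", call. = FALSE)
  k <- colSums(panel$alleles)
  keep <- k >= 1 & k <= 7
  snps <- colnames(panel$alleles)[keep]
  kk <- k[keep]
  uf <- rep(NA_character_, length(kk))
  uf[kk == 1] <- panel$reference
  if (any(kk == 7)) {
    sub <- panel$alleles[, keep, drop = FALSE][, kk == 7, drop = FALSE]
    uf[kk == 7] <- apply(sub, 2, function(col) {
      rownames(panel$alleles)[col == 0]
    })
  }
  tibble::tibble(snp = snps, afg = unname(as.integer(kk)),
                 expected_freq = unname(kk / 8),
                 unique_founder = unname(uf))
}

#' Summarise unique-founder SNPs
#'
#' Unique SNPs are those in AFG 1 (reference-founder allele private to the
#' reference founder) or AFG 7 (alternative allele private to one
#' non-reference founder): their allele effects can be traced to a single
#' founder.
#'
#' @param afg AFG table from [assign_afg()].
#' @return A one-row tibble: `n_snps`, `n_afg1`, `n_afg7`, `n_unique`,
#'   `pct_unique` (percent of all classified SNPs).
#' @export
unique_snp_report <- function(afg) {
  n1 <- sum(afg$afg == 1)
  n7 <- sum(afg$afg == 7)
  tibble::tibble(
    n_snps = nrow(afg), n_afg1 = n1, n_afg7 = n7,
    n_unique = n1 + n7,
    pct_unique = 100 * (n1 + n7) / nrow(afg)
  )
}

#' AFG-specific segregation-distortion test
#'
#' Per SNP, a 1-df chi-square test of the observed reference-allele count
#' against the funnel expectation k/8 of its allele-frequency group;
#' missing calls are excluded per SNP and Bonferroni--Holm adjustment is
#' applied genome-wide across all tested SNPs.
#'
#' Counting two alleles per line overstates the information in an inbred
#' population: after g selfing generations the two alleles of a line are
#' identical with probability F = 1 - 2^-g, inflating the plain chi-square
#' by a factor 1 + F. By default the statistic is therefore divided by
#' (1 + F_hat), with F_hat the pooled genome-wide inbreeding coefficient
#' estimated from the heterozygote deficit, which restores the nominal
#' type-I error when lines are independent. `correct_inbreeding = FALSE`
#' gives the plain textbook allele-count test.
#'
#' @param geno Unimputed lines x SNPs dosage matrix (0/1/2/NA).
#' @param afg AFG table from [assign_afg()]; every tested SNP must appear.
#' @param correct_inbreeding Apply the 1 + F correction (default `TRUE`).
#' @return A tibble with `snp`, `afg`, `n_ref`, `n_total` (allele counts),
#'   `observed_freq`, `expected_freq`, `deviation`, `direction` (+1
#'   reference-allele excess, -1 deficit), `chi_square`, `p`, `p_adj`
#'   (Bonferroni--Holm); attribute `F_hat` carries the pooled inbreeding
#'   estimate.
#' @export
sd_test <- function(geno, afg, correct_inbreeding = TRUE) {
  snps <- colnames(geno)
  hit <- match(snps, afg$snp)
  if (anyNA(hit)) {
    stop("SNP absent from AFG table: ",
         paste(head(snps[is.na(hit)], 5), collapse = ", "), call. = FALSE)
  }
  k <- afg$afg[hit]
  p0 <- afg$expected_freq[hit]
  n_obs <- colSums(!is.na(geno))
  n_ref <- colSums(geno, na.rm = TRUE)
  n_tot <- 2 * n_obs
  phat <- n_ref / n_tot
  # pooled inbreeding coefficient from the heterozygote deficit
  h_obs <- colSums(geno == 1, na.rm = TRUE) / n_obs
  h_exp <- 2 * phat * (1 - phat)
  F_hat <- if (correct_inbreeding) {
    max(0, min(0.999, 1 - sum(h_obs * n_obs) / sum(h_exp * n_obs)))
  } else 0
  chi <- (n_ref - n_tot * p0)^2 / (n_tot * p0 * (1 - p0)) / (1 + F_hat)
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  out <- tibble::tibble(
    snp = snps, afg = k,
    n_ref = unname(n_ref), n_total = unname(n_tot),
    observed_freq = unname(phat), expected_freq = p0,
    deviation = unname(phat - p0),
    direction = unname(sign(phat - p0)),
    chi_square = unname(chi), p = unname(p),
    p_adj = unname(p.adjust(p, method = "holm"))
  )
  attr(out, "F_hat") <- F_hat
  out
}

#' Call segregation-distortion regions
#'
#' A region is a maximal run of at least `min_run` consecutive mapped SNPs
#' (map order within chromosome) whose adjusted p-values fall below
#' `alpha`. The direction of distortion is recorded per member but not
#' required to be uniform.
#'
#' @param sd_results Tibble from [sd_test()].
#' @param map Genetic map covering the tested SNPs.
#' @param min_run Minimum run length (default 3).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @return A tibble `chr`, `start`, `end` (cM), `n_snps`, `mean_deviation`,
#'   `snps` (list column of member SNP ids).
#' @export
detect_sdr <- function(sd_results, map, min_run = 3, alpha = 0.01) {
  dat <- map %>%
    dplyr::inner_join(sd_results, by = "snp") %>%
    arrange(.data$chr, .data$pos)
  out <- dat %>%
    group_by(.data$chr) %>%
    dplyr::group_modify(function(d, key) {
      sig <- d$p_adj < alpha
      r <- rle(sig)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      runs <- which(r$values & r$lengths >= min_run)
      if (!length(runs)) {
        return(tibble::tibble(start = numeric(0), end = numeric(0),
                              n_snps = integer(0),
                              mean_deviation = numeric(0), snps = list()))
      }
      purrr::map_dfr(runs, function(ri) {
        idx <- starts[ri]:ends[ri]
        tibble::tibble(start = min(d$pos[idx]), end = max(d$pos[idx]),
                       n_snps = length(idx),
                       mean_deviation = mean(d$deviation[idx]),
                       snps = list(d$snp[idx]))
      })
    }) %>%
    ungroup()
  out
}

#' Founder-specific selection events
#'
#' Among unique SNPs (AFG 1 and 7) with significant segregation distortion,
#' groups SNPs by chromosome, unique founder and the direction of change of
#' that founder's own allele frequency. For AFG 7 the unique founder is the
#' sole carrier of the *alternative* allele, so a reference-allele excess
#' means a deficit of that founder's allele (direction inverted). Groups
#' with strictly more than `min_snps` members are reported.
#'
#' @param sd_results Tibble from [sd_test()].
#' @param afg AFG table from [assign_afg()].
#' @param map Genetic map.
#' @param min_snps Strict lower bound on group size (default 10).
#' @param alpha Adjusted-p threshold for significance (default 0.01).
#' @return A tibble `chr`, `founder`, `direction` (+1 increase of the
#'   founder's allele, -1 decrease), `n_snps`.
#' @export
founder_selection_events <- function(sd_results, afg, map, min_snps = 10,
                                     alpha = 0.01) {
  dat <- sd_results %>%
    dplyr::inner_join(afg[, c("snp", "unique_founder")], by = "snp") %>%
    dplyr::inner_join(map[, c("snp", "chr")], by = "snp") %>%
    filter(.data$afg %in% c(1L, 7L), .data$p_adj < alpha,
           .data$direction != 0)
  if (!nrow(dat)) {
    return(tibble::tibble(chr = character(0), founder = character(0),
                          direction = numeric(0), n_snps = integer(0)))
  }
  dat <- dat %>%
    mutate(founder_direction = ifelse(.data$afg == 1L, .data$direction,
                                      -.data$direction))
  dat %>%
    group_by(.data$chr, founder = .data$unique_founder,
             direction = .data$founder_direction) %>%
    summarise(n_snps = dplyr::n(), .groups = "drop") %>%
    filter(.data$n_snps > min_snps)
}
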