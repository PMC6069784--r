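#' The eight founder cultivars and their funnel crossing positions
#'
#' Returns the default founder panel layout used throughout the package:
#' eight European winter-wheat cultivars assigned to crossing positions
#' A--H of the funnel (two-way crosses A x B, C x D, E x F, G x H). Julius
#' (position H) is the reference founder: identity-by-state dosages count
#' copies of the Julius allele.
#'
#' @return A tibble with columns `founder` and `position` (letters A--H).
#' @export
#' @examples
#' wm_founders()
wm_founders <- function() {
  tibble::tibble(
    founder  = c("Patras", "Meister", "Linus", "JB Asano",
                 "Tobak", "Bernstein", "Safari", "Julius"),
    position = LETTERS[1:8]
  )
}

#' Default chromosome lengths for the 21 wheat chromosomes
#'
#' Genetic lengths (cM) of chromosomes 1A--7D on the consensus-map scale:
#' total ~3588 cM, shortest 4B (114.9 cM), longest 7D (214.8 cM).
#'
#' @return A named numeric vector of 21 chromosome lengths in cM.
#' @export
wm_chr_lengths <- function() {
  chrs <- paste0(rep(1:7, each = 3), rep(c("A", "B", "D"), 7))
  len <- c(
    `1A` = 178.2, `1B` = 172.6, `1D` = 180.4,
    `2A` = 190.5, `2B` = 185.3, `2D` = 157.6,
    `3A` = 186.7, `3B` = 170.9, `3D` = 166.2,
    `4A` = 164.1, `4B` = 114.9, `4D` = 137.8,
    `5A` = 172.3, `5B` = 198.9, `5D` = 190.1,
    `6A` = 158.4, `6B` = 141.7, `6D` = 168.3,
    `7A` = 211.6, `7B` = 176.5, `7D` = 214.8
  )
  len[chrs]
}

#' Default allele-frequency-group weights
#'
#' Probabilities that a simulated SNP's reference (Julius) allele is carried
#' by k = 1..7 of the eight founders. The default weights
#' (260, 531, 877, 842, 1315, 1582, 2177 of 7,584) reproduce the skew
#' towards high-frequency reference alleles typical of an elite
#' eight-founder wheat array panel, where about a third of mapped SNPs are
#' private to a single founder (AFG 1 or 7).
#'
#' @return A numeric vector of length 7 summing to 1.
#' @export
wm_afg_weights <- function() {
  n <- c(260, 531, 877, 842, 1315, 1582, 2177)
  n / sum(n)
}

#' Reduced-height (Rht) locus layout used by the default simulations
#'
#' The two semi-dwarfing loci on chromosomes 4B and 4D. At `Rht-B1` the
#' dwarfing allele is carried by Tobak and Safari (so the Julius allele is
#' the tall allele, shared by six founders); at `Rht-D1` the dwarfing allele
#' is carried by Julius, Patras, Linus and JB Asano.
#'
#' @return A tibble with columns `snp`, `chr`, `pos`, `carriers` (list column
#'   of founders carrying the Julius allele) and `dwarf_founders` (list column
#'   of founders carrying the dwarfing allele).
#' @export
wm_rht_loci <- function() {
  tibble::tibble(
    snp  = c("Rht-B1", "Rht-D1"),
    chr  = c("4B", "4D"),
    pos  = c(56.0, 69.2),
    carriers = list(
      c("Patras", "Meister", "Linus", "JB Asano", "Bernstein", "Julius"),
      c("Julius", "Patras", "Linus", "JB Asano")
    ),
    dwarf_founders = list(
      c("Tobak", "Safari"),
      c("Julius", "Patras", "Linus", "JB Asano")
    )
  )
}

#' Fixed study loci for the default simulations
#'
#' The two Rht loci plus the two markers of the default epistatic pair on
#' chromosomes 2B and 7B. The epistatic markers are assigned balanced
#' founder carriage (Julius allele in 4 of 8 founders, split across both
#' sides of the funnel) so that the population allele frequency is close
#' to 1/2 and the product term of the pair is uncorrelated with either
#' main effect.
#'
#' @return A tibble with columns `snp`, `chr`, `pos`, `carriers` (list
#'   column of founders carrying the Julius allele).
#' @export
wm_study_loci <- function() {
  rht <- wm_rht_loci()[, c("snp", "chr", "pos", "carriers")]
  epi <- tibble::tibble(
    snp = c("Epi2B", "Epi7B"),
    chr = c("2B", "7B"),
    pos = c(157.2, 135.4),
    carriers = list(
      c("Julius", "Patras", "Linus", "Tobak"),
      c("Julius", "Meister", "Bernstein", "Safari")
    )
  )
  dplyr::bind_rows(rht, epi)
}

#' Simulate a genetic map
#'
#' Places SNPs uniformly at random along 21 chromosomes (or any supplied set
#' of chromosome lengths). Optionally inserts fixed marker loci (for example
#' the default Rht loci) at their stated positions.
#'
#' @param n_snps Total number of SNPs to place (before fixed loci are added).
#' @param chr_lengths Named numeric vector of chromosome lengths in cM.
#' @param fixed_loci Optional tibble with columns `snp`, `chr`, `pos` to add
#'   verbatim (e.g. [wm_rht_loci()]).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `snp`, `chr`, `pos`, sorted by chromosome
#'   and position; attribute `chr_lengths` carries the chromosome lengths.
#' @export
#' @examples
#' map <- sim_genetic_map(200, seed = 1)
#' head(map)
sim_genetic_map <- function(n_snps = 2000, chr_lengths = wm_chr_lengths(),
                            fixed_loci = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_snps > 0, all(chr_lengths > 0), !is.null(names(chr_lengths)))
  # apportion SNPs to chromosomes proportional to length
  n_chr <- round(n_snps * chr_lengths / sum(chr_lengths))
  n_chr[n_chr < 1] <- 1
  map <- purrr::map2_dfr(names(chr_lengths), n_chr, function(ch, k) {
    tibble::tibble(chr = ch, pos = sort(runif(k, 0, chr_lengths[[ch]])))
  })
  map <- map %>%
    group_by(.data$chr) %>%
    mutate(snp = sprintf("S%s_%03d", .data$chr, row_number())) %>%
    ungroup() %>%
    select("snp", "chr", "pos")
  if (!is.null(fixed_loci)) {
    map <- bind_rows(map, fixed_loci[, c("snp", "chr", "pos")])
  }
  map <- map %>%
    mutate(chr = factor(.data$chr, levels = names(chr_lengths))) %>%
    arrange(.data$chr, .data$pos) %>%
    mutate(chr = as.character(.data$chr))
  stopifnot(!anyDuplicated(map$snp))
  attr(map, "chr_lengths") <- chr_lengths
  map
}

map_chr_lengths <- function(map) {
  len <- attr(map, "chr_lengths")
  if (is.null(len)) {
    len <- tapply(map$pos, map$chr, max)
    len <- setNames(as.numeric(len), names(len))
  }
  len
}

#' Simulate a founder allele panel
#'
#' Draws, for every SNP on the map, the set of founders carrying the
#' reference (Julius) allele. The reference founder always carries its own
#' allele, so each SNP falls in allele-frequency group k = 1..7 (number of
#' carriers among the eight founders); k is drawn from `afg_weights`.
#' Fixed loci (e.g. the Rht loci) receive their stated carrier sets.
#'
#' @param map Genetic map tibble from [sim_genetic_map()].
#' @param afg_weights Probabilities for k = 1..7; default [wm_afg_weights()].
#' @param founders Founder layout tibble; default [wm_founders()].
#' @param reference Name of the reference founder (default `"Julius"`).
#' @param fixed_loci Optional tibble with `snp` and `carriers` list column
#'   giving reference-allele carriers for specific SNPs.
#' @param founder_ld_scale Optional haplotype-block scale in cM. When set,
#'   each SNP copies the carrier set of its left neighbour on the same
#'   chromosome with probability `exp(-d / founder_ld_scale)` (d = distance
#'   in cM), so founders share local haplotype blocks and tightly linked
#'   SNPs are in strong linkage disequilibrium in the derived population,
#'   as in real panels of related elite cultivars. `NULL` (default) assigns
#'   carriers independently per SNP.
#' @param seed Optional integer seed.
#' @return An object of class `founder_panel`: list with `founders` (tibble),
#'   `reference`, `alleles` (8 x n_snps 0/1 matrix of reference-allele
#'   carriage, rows named by founder), and per-SNP allele letters
#'   `ref_allele` / `alt_allele` used by the raw-call codec.
#' @export
sim_founder_panel <- function(map, afg_weights = wm_afg_weights(),
                              founders = wm_founders(), reference = "Julius",
                              fixed_loci = NULL, founder_ld_scale = NULL,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(founders) == 8, reference %in% founders$founder)
  m <- nrow(map)
  others <- setdiff(founders$founder, reference)
  k <- sample(1:7, m, replace = TRUE, prob = afg_weights)
  alleles <- matrix(0L, nrow = 8, ncol = m,
                    dimnames = list(founders$founder, map$snp))
  alleles[reference, ] <- 1L
  extra <- k - 1L
  copy_prev <- rep(FALSE, m)
  if (!is.null(founder_ld_scale)) {
    same_chr <- c(FALSE, map$chr[-1] == map$chr[-m])
    d <- c(Inf, diff(map$pos))
    copy_prev <- same_chr & (runif(m) < exp(-d / founder_ld_scale))
  }
  for (j in seq_len(m)) {
    if (copy_prev[j]) {
      alleles[, j] <- alleles[, j - 1]
    } else if (extra[j] > 0) {
      alleles[sample(others, extra[j]), j] <- 1L
    }
  }
  if (!is.null(fixed_loci)) {
    for (i in seq_len(nrow(fixed_loci))) {
      s <- fixed_loci$snp[i]
      stopifnot(s %in% map$snp)
      alleles[, s] <- 0L
      alleles[fixed_loci$carriers[[i]], s] <- 1L
    }
  }
  # bi-allelic letters: reference allele is randomly A or B per SNP
  ref_letter <- sample(c("A", "B"), m, replace = TRUE)
  structure(
    list(
      founders  = founders,
      reference = reference,
      alleles   = alleles,
      ref_allele = setNames(ref_letter, map$snp),
      alt_allele = setNames(ifelse(ref_letter == "A", "B", "A"), map$snp)
    ),
    class = "founder_panel"
  )
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("<founder_panel> ", nrow(x$alleles), " founders x ",
      ncol(x$alleles), " SNPs; reference: ", x$reference, "\n", sep = "")
  invisible(x)
}

#' Founder genotypes as IBS dosages
#'
#' Founders are fully inbred, so their dosage of the reference allele is
#' 0 or 2 according to the panel allele table.
#'
#' @param panel A `founder_panel`.
#' @return A founders x SNPs numeric matrix of dosages in \{0, 2\}.
#' @export
founder_genotypes <- function(panel) {
  2 * panel$alleles
}
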