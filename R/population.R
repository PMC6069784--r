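#' Simulation configuration for the eight-way funnel design
#'
#' Parameters of the crossing scheme: founders are crossed in four fixed
#' pairs (positions AB, CD, EF, GH), pairs are intercrossed into two
#' four-way crosses (ABCD, EFGH), four-way plants are intercrossed
#' (including reciprocals, modelled identically) into eight-way seeds, and
#' each eight-way plant contributes selfed F2 seeds that are advanced by
#' single-seed descent.
#'
#' @param n_eight_way_seeds Number of eight-way F1 seeds (default 141).
#' @param n_f2_per_plant Selfed F2 seeds per eight-way plant (default 15);
#'   together with `n_eight_way_seeds` this caps the line budget.
#' @param target_lines Number of inbred lines to return (default 910).
#' @param ssd_generations Selfing generations from the eight-way F1
#'   (default 3, i.e. F1 to F4).
#' @param four_way_plants Integer vector of length 2: number of distinct
#'   four-way F1 plants on the ABCD and EFGH sides (default `c(18, 85)`).
#'   `NULL` gives every eight-way seed its own freshly simulated four-way
#'   parents (fully independent funnels).
#' @param missing_rate,het_error_rate Per-call probabilities of a missing
#'   genotype and of a spurious heterozygous call in [genotype_lines()].
#' @param seed Optional integer seed used by [sim_population()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_eight_way_seeds = 141, n_f2_per_plant = 15,
                       target_lines = 910, ssd_generations = 3,
                       four_way_plants = c(18, 85),
                       missing_rate = 0, het_error_rate = 0, seed = NULL) {
  stopifnot(
    n_eight_way_seeds >= 1, n_f2_per_plant >= 1, target_lines >= 1,
    ssd_generations >= 0,
    missing_rate >= 0, missing_rate <= 1,
    het_error_rate >= 0, het_error_rate <= 1
  )
  structure(
    list(n_eight_way_seeds = n_eight_way_seeds,
         n_f2_per_plant = n_f2_per_plant,
         target_lines = target_lines,
         ssd_generations = ssd_generations,
         four_way_plants = four_way_plants,
         missing_rate = missing_rate,
         het_error_rate = het_error_rate,
         seed = seed),
    class = "sim_config"
  )
}

#' Simulate a MAGIC population through the eight-way funnel
#'
#' Executes the full crossing scheme: 2-way crosses of the four founder
#' pairs, 4-way crosses on each side of the funnel, eight-way intercrosses
#' of four-way plants (reciprocals modelled identically), and
#' `ssd_generations` rounds of single-seed descent. Lines are sampled
#' without replacement from the seed budget
#' (`n_eight_way_seeds * n_f2_per_plant` lineage slots), so each line is
#' tagged with its eight-way ancestor family.
#'
#' @param panel A `founder_panel` (used for founder names/order).
#' @param map Genetic map tibble; its `chr_lengths` attribute defines the
#'   chromosomes simulated.
#' @param config A [sim_config()].
#' @return An object of class `magic_pop`: list with `lines` (list of
#'   individuals, each two whole-genome haplotypes), `pedigree` (tibble:
#'   `line`, `family`, `abcd_parent`, `efgh_parent`), `chr_lengths`,
#'   `founders` (names in crossing-position order A--H) and `reference`.
#' @export
#' @examples
#' map <- sim_genetic_map(100, seed = 1)
#' panel <- sim_founder_panel(map, seed = 2)
#' pop <- sim_population(panel, map, sim_config(target_lines = 20, seed = 3))
#' pop
sim_population <- function(panel, map, config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  chr_lengths <- map_chr_lengths(map)
  founders <- panel$founders$founder[order(panel$founders$position)]
  budget <- config$n_eight_way_seeds * config$n_f2_per_plant
  if (config$target_lines > budget) {
    stop("target_lines (", config$target_lines,
         ") exceeds the seed budget of ", budget,
         " (n_eight_way_seeds * n_f2_per_plant)", call. = FALSE)
  }

  f1 <- function(i, j) {
    list(new_haplotype(chr_lengths, i), new_haplotype(chr_lengths, j))
  }
  cross <- function(mother, father) {
    list(simulate_meiosis(mother, chr_lengths),
         simulate_meiosis(father, chr_lengths))
  }
  ab <- f1(1L, 2L); cd <- f1(3L, 4L); ef <- f1(5L, 6L); gh <- f1(7L, 8L)

  n_seeds <- config$n_eight_way_seeds
  independent <- is.null(config$four_way_plants)
  if (!independent) {
    abcd_pool <- lapply(seq_len(config$four_way_plants[1]),
                        function(i) cross(ab, cd))
    efgh_pool <- lapply(seq_len(config$four_way_plants[2]),
                        function(i) cross(ef, gh))
    abcd_idx <- sample.int(length(abcd_pool), n_seeds, replace = TRUE)
    efgh_idx <- sample.int(length(efgh_pool), n_seeds, replace = TRUE)
  }
  eight_way <- vector("list", n_seeds)
  abcd_parent <- integer(n_seeds); efgh_parent <- integer(n_seeds)
  for (s in seq_len(n_seeds)) {
    if (independent) {
      pa <- cross(ab, cd); pe <- cross(ef, gh)
      abcd_parent[s] <- s; efgh_parent[s] <- s
    } else {
      pa <- abcd_pool[[abcd_idx[s]]]; pe <- efgh_pool[[efgh_idx[s]]]
      abcd_parent[s] <- abcd_idx[s]; efgh_parent[s] <- efgh_idx[s]
    }
    eight_way[[s]] <- cross(pa, pe)
  }

  slots <- rep(seq_len(n_seeds), each = config$n_f2_per_plant)
  fam <- sort(sample(slots, config$target_lines))
  lines <- vector("list", config$target_lines)
  for (i in seq_len(config$target_lines)) {
    ind <- eight_way[[fam[i]]]
    for (g in seq_len(config$ssd_generations)) {
      ind <- list(simulate_meiosis(ind, chr_lengths),
                  simulate_meiosis(ind, chr_lengths))
    }
    lines[[i]] <- ind
  }
  ids <- sprintf("WM%04d", seq_len(config$target_lines))
  names(lines) <- ids
  structure(
    list(lines = lines,
         pedigree = tibble::tibble(line = ids, family = fam,
                                   abcd_parent = abcd_parent[fam],
                                   efgh_parent = efgh_parent[fam]),
         chr_lengths = chr_lengths,
         founders = founders,
         reference = panel$reference),
    class = "magic_pop"
  )
}

#' @export
print.magic_pop <- function(x, ...) {
  cat("<magic_pop> ", length(x$lines), " lines, ",
      length(x$chr_lengths), " chromosomes, ",
      length(unique(x$pedigree$family)), " eight-way families\n", sep = "")
  invisible(x)
}

#' Founder genome shares of every line
#'
#' @param pop A `magic_pop`.
#' @return A tibble with columns `line`, `family`, `founder`, `share`;
#'   shares sum to 1 within each line.
#' @export
founder_shares <- function(pop) {
  nf <- length(pop$founders)
  sh <- t(vapply(pop$lines, genome_shares, numeric(nf), n_founders = nf))
  tibble::tibble(
    line = rep(names(pop$lines), each = nf),
    family = rep(pop$pedigree$family, each = nf),
    founder = rep(pop$founders, length(pop$lines)),
    share = as.numeric(t(sh))
  )
}

#' Remove double-dwarf lines
#'
#' Drops every line that is homozygous for a dwarf-founder origin at *both*
#' semi-dwarfing loci; lines dwarf at only one locus (or neither) are kept,
#' in their original order. Origins are read from the haplotype mosaics, so
#' selection acts on true founder descent, as with a diagnostic marker assay.
#'
#' @param pop A `magic_pop`.
#' @param map Genetic map (for locus lookup).
#' @param loci Tibble with columns `snp`, `chr`, `pos` and list column
#'   `dwarf_founders`; default [wm_rht_loci()]. The two loci must lie on
#'   distinct chromosomes.
#' @return A filtered `magic_pop`; attribute `n_removed` records the count.
#' @export
apply_dwarf_selection <- function(pop, map, loci = wm_rht_loci()) {
  stopifnot(nrow(loci) == 2)
  if (!all(loci$snp %in% map$snp)) {
    stop("selection locus not found in map: ",
         paste(setdiff(loci$snp, map$snp), collapse = ", "), call. = FALSE)
  }
  if (loci$chr[1] == loci$chr[2]) {
    stop("the two selection loci must map to distinct chromosomes",
         call. = FALSE)
  }
  dwarf_idx <- lapply(loci$dwarf_founders, function(f) {
    match(f, pop$founders)
  })
  is_dwarf_at <- function(ind, chr, pos, dwarf) {
    o1 <- origins_at(ind[[1]][[chr]], pos)
    o2 <- origins_at(ind[[2]][[chr]], pos)
    (o1 %in% dwarf) && (o2 %in% dwarf)
  }
  drop <- vapply(pop$lines, function(ind) {
    is_dwarf_at(ind, loci$chr[1], loci$pos[1], dwarf_idx[[1]]) &&
      is_dwarf_at(ind, loci$chr[2], loci$pos[2], dwarf_idx[[2]])
  }, logical(1))
  out <- pop
  out$lines <- pop$lines[!drop]
  out$pedigree <- pop$pedigree[!drop, ]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Derive IBS genotype calls from founder mosaics
#'
#' Each line x SNP dosage is the number of reference-founder alleles implied
#' by the founder origins of the line's two haplotypes at the SNP position.
#' Residual heterozygous loci yield dosage 1. Optionally injects missing
#' calls and spurious heterozygous calls at the configured rates.
#'
#' @param pop A `magic_pop`.
#' @param panel The `founder_panel` the population was simulated from.
#' @param map Genetic map tibble.
#' @param missing_rate,het_error_rate Per-call error rates (default 0).
#' @return A lines x SNPs integer matrix of dosages 0/1/2 with `NA` for
#'   missing calls.
#' @export
genotype_lines <- function(pop, panel, map, missing_rate = 0,
                           het_error_rate = 0) {
  founder_row <- match(pop$founders, rownames(panel$alleles))
  stopifnot(!anyNA(founder_row))
  n <- length(pop$lines)
  m <- nrow(map)
  geno <- matrix(NA_integer_, n, m,
                 dimnames = list(names(pop$lines), map$snp))
  by_chr <- split(seq_len(m), map$chr)
  for (ch in names(by_chr)) {
    idx <- by_chr[[ch]]
    pos <- map$pos[idx]
    for (i in seq_len(n)) {
      ind <- pop$lines[[i]]
      h1 <- ind[[1]][[ch]]; h2 <- ind[[2]][[ch]]
      # unrecombined chromosomes carry a single founder segment
      o1 <- if (length(h1$founder) == 1L) h1$founder else origins_at(h1, pos)
      o2 <- if (length(h2$founder) == 1L) h2$founder else origins_at(h2, pos)
      geno[i, idx] <- panel$alleles[cbind(founder_row[o1], idx)] +
        panel$alleles[cbind(founder_row[o2], idx)]
    }
  }
  if (het_error_rate > 0) {
    flip <- runif(length(geno)) < het_error_rate
    geno[flip] <- 1L
  }
  if (missing_rate > 0) {
    geno[runif(length(geno)) < missing_rate] <- NA_integer_
  }
  geno
}
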