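# Shared in-code fixtures. Everything is generated programmatically with
# fixed seeds; no data files.

# small generic map: a few chromosomes, uniform SNPs
make_map <- function(n_snps = 120, n_chr = 3, len = 100, seed = 1) {
  lens <- stats::setNames(rep(len, n_chr), paste0("C", seq_len(n_chr)))
  sim_genetic_map(n_snps, chr_lengths = lens, seed = seed)
}

# map of unlinked loci: one SNP per micro-chromosome
make_unlinked_map <- function(n_snps = 300, seed = 1) {
  lens <- stats::setNames(rep(0.01, n_snps), sprintf("U%04d", seq_len(n_snps)))
  sim_genetic_map(n_snps, chr_lengths = lens, seed = seed)
}

# population + genotypes in one go
make_pop <- function(map, panel, n_lines = 120, seed = 5,
                     independent = FALSE, ssd = 3) {
  cfg <- if (independent) {
    sim_config(n_eight_way_seeds = n_lines, n_f2_per_plant = 1,
               target_lines = n_lines, ssd_generations = ssd,
               four_way_plants = NULL, seed = seed)
  } else {
    sim_config(target_lines = n_lines, ssd_generations = ssd, seed = seed)
  }
  sim_population(panel, map, cfg)
}

# two-locus class-mean fixture: two lines per two-locus homozygous class,
# phenotype exactly the class mean
class_mean_fixture <- function(jj, nn, jn, nj) {
  d <- rbind(c(2, 2), c(0, 0), c(2, 0), c(0, 2))
  geno <- d[rep(1:4, each = 2), ]
  rownames(geno) <- paste0("L", 1:8)
  colnames(geno) <- c("m1", "m2")
  y <- stats::setNames(rep(c(jj, nn, jn, nj), each = 2), rownames(geno))
  list(geno = geno, y = y)
}

# fabricated gwas_scan for grouping tests
fake_scan <- function(snps, config = scan_config()) {
  structure(list(snps = snps, n_fits = 100, n_lines = 400, config = config,
                 final_model = NULL),
            class = "gwas_scan")
}
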