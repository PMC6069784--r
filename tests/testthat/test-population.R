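map <- make_map(n_snps = 90, n_chr = 3, seed = 101)
panel <- sim_founder_panel(map, seed = 102)

test_that("single-seed descent to F4 leaves ~1/8 residual heterozygosity", {
  pop <- make_pop(map, panel, n_lines = 250, seed = 103, independent = TRUE)
  # heterozygosity by founder origin, checked at the mapped positions
  pos_by_chr <- split(map$pos, map$chr)
  het <- vapply(pop$lines, function(ind) {
    tot <- 0; n <- 0
    for (ch in names(pos_by_chr)) {
      o1 <- magicpop:::origins_at(ind[[1]][[ch]], pos_by_chr[[ch]])
      o2 <- magicpop:::origins_at(ind[[2]][[ch]], pos_by_chr[[ch]])
      tot <- tot + sum(o1 != o2); n <- n + length(o1)
    }
    tot / n
  }, numeric(1))
  se <- sd(het) / sqrt(length(het))
  expect_lt(abs(mean(het) - 0.125), 3 * se + 0.005)
})

test_that("without selfing every locus is heterozygous across funnel sides", {
  pop <- make_pop(map, panel, n_lines = 25, seed = 104, independent = TRUE,
                  ssd = 0)
  pos_by_chr <- split(map$pos, map$chr)
  for (ind in pop$lines[1:10]) {
    for (ch in names(pos_by_chr)) {
      o1 <- magicpop:::origins_at(ind[[1]][[ch]], pos_by_chr[[ch]])
      o2 <- magicpop:::origins_at(ind[[2]][[ch]], pos_by_chr[[ch]])
      expect_true(all(o1 %in% 1:4))  # ABCD-side gamete
      expect_true(all(o2 %in% 5:8))  # EFGH-side gamete
    }
  }
})

test_that("line demand beyond the seed budget is a configuration error", {
  cfg <- sim_config(n_eight_way_seeds = 4, n_f2_per_plant = 3,
                    target_lines = 13, seed = 1)
  expect_error(sim_population(panel, map, cfg), "budget")
})

test_that("founder genome shares average 1/8 and sum to one per line", {
  pop <- make_pop(map, panel, n_lines = 200, seed = 105)
  sh <- founder_shares(pop)
  sums <- sh |> dplyr::group_by(line) |> dplyr::summarise(s = sum(share))
  expect_equal(sums$s, rep(1, nrow(sums)))
  per_founder <- sh |>
    dplyr::group_by(founder) |>
    dplyr::summarise(m = mean(share),
                     se = sd(share) / sqrt(dplyr::n_distinct(line)))
  # family structure inflates the naive SE; use the family-level spread
  fam <- sh |>
    dplyr::group_by(founder, family) |>
    dplyr::summarise(m = mean(share), .groups = "drop_last") |>
    dplyr::summarise(mean = mean(m), se = sd(m) / sqrt(dplyr::n()))
  expect_true(all(abs(fam$mean - 0.125) < 3 * fam$se + 0.002))
})

test_that("identical configuration and seed reproduce the population", {
  cfg <- sim_config(target_lines = 30, seed = 77)
  p1 <- sim_population(panel, map, cfg)
  p2 <- sim_population(panel, map, cfg)
  expect_identical(p1$lines, p2$lines)
  expect_identical(p1$pedigree, p2$pedigree)
  set.seed(1); g1 <- genotype_lines(p1, panel, map, missing_rate = 0.02)
  set.seed(1); g2 <- genotype_lines(p2, panel, map, missing_rate = 0.02)
  expect_identical(g1, g2)
})

test_that("neutral allele frequencies follow the k/8 law per AFG", {
  umap <- make_unlinked_map(n_snps = 300, seed = 106)
  upanel <- sim_founder_panel(umap, afg_weights = rep(1 / 7, 7), seed = 107)
  pop <- make_pop(umap, upanel, n_lines = 250, seed = 108, independent = TRUE)
  g <- genotype_lines(pop, upanel, umap)
  afg <- assign_afg(upanel)
  freq <- colMeans(g) / 2
  for (k in 1:7) {
    snps <- afg$snp[afg$afg == k]
    if (length(snps) < 10) next
    f <- freq[snps]
    se <- sd(f) / sqrt(length(f))
    expect_lt(abs(mean(f) - k / 8), 3 * se + 0.01)
  }
})

test_that("missingness and heterozygous-error injection match their rates", {
  pop <- make_pop(map, panel, n_lines = 150, seed = 109)
  set.seed(110)
  g <- genotype_lines(pop, panel, map, missing_rate = 0.05)
  n <- length(g)
  obs <- mean(is.na(g))
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(obs - 0.05), 3 * se)
  g0 <- genotype_lines(pop, panel, map)
  expect_false(anyNA(g0))
  expect_true(all(g0 %in% 0:2))
  set.seed(111)
  ge <- genotype_lines(pop, panel, map, het_error_rate = 0.2)
  expect_gt(mean(ge == 1), mean(g0 == 1) + 0.1)
})

test_that("double-dwarf selection removes only doubly homozygous lines", {
  map21 <- sim_genetic_map(150, fixed_loci = wm_rht_loci(), seed = 112)
  panel21 <- sim_founder_panel(map21, fixed_loci = wm_rht_loci(), seed = 113)
  pop <- sim_population(panel21, map21,
                        sim_config(target_lines = 600, seed = 114))
  g_before <- genotype_lines(pop, panel21, map21)
  sel <- apply_dwarf_selection(pop, map21)
  n_removed <- attr(sel, "n_removed")
  expect_gt(n_removed, 0)
  expect_equal(length(sel$lines) + n_removed, length(pop$lines))
  # retained lines keep their order
  expect_identical(names(sel$lines),
                   intersect(names(pop$lines), names(sel$lines)))
  g_after <- g_before[names(sel$lines), ]
  # dwarf-allele frequencies: Julius allele at Rht-D1 IS the dwarf allele;
  # at Rht-B1 the dwarf allele is the non-Julius allele
  f_D_before <- mean(g_before[, "Rht-D1"]) / 2
  f_D_after <- mean(g_after[, "Rht-D1"]) / 2
  f_B_before <- 1 - mean(g_before[, "Rht-B1"]) / 2
  f_B_after <- 1 - mean(g_after[, "Rht-B1"]) / 2
  deficit_D <- f_D_before - f_D_after
  deficit_B <- f_B_before - f_B_after
  expect_gt(deficit_D, 0)
  expect_gt(deficit_B, 0)
  # class-removal algebra: deficit 2k(1-p)/(2(n-k)) is larger at the
  # rarer dwarf allele (Rht-B1, 2 of 8 founders)
  expect_gt(deficit_B, deficit_D)
  # a population with no double dwarfs passes through unchanged
  again <- apply_dwarf_selection(sel, map21)
  expect_identical(names(again$lines), names(sel$lines))
  expect_equal(attr(again, "n_removed"), 0)
})

test_that("selection-locus lookup and chromosome checks error cleanly", {
  loci <- wm_rht_loci()
  loci$snp <- c("nope1", "nope2")
  pop <- make_pop(map, panel, n_lines = 10, seed = 115)
  expect_error(apply_dwarf_selection(pop, map, loci), "not found")
  c1 <- map[map$chr == "C1", ]
  loci2 <- wm_rht_loci()
  loci2$snp <- c1$snp[1:2]
  loci2$chr <- c1$chr[1:2]
  loci2$pos <- c1$pos[1:2]
  expect_error(apply_dwarf_selection(pop, map, loci2), "distinct")
})

test_that("phenotype simulation honours the trait model exactly when noiseless", {
  map21 <- sim_genetic_map(80, fixed_loci = wm_study_loci(), seed = 116)
  panel21 <- sim_founder_panel(map21, fixed_loci = wm_study_loci(), seed = 117)
  pop <- sim_population(panel21, map21,
                        sim_config(target_lines = 200, seed = 118))
  g <- genotype_lines(pop, panel21, map21)
  # no QTL, no noise: every record is the intercept
  m0 <- trait_model(intercept = 80)
  ph0 <- sim_phenotype(g, m0, seed = 1)
  expect_true(all(ph0$value == 80))
  # single epistatic pair, no noise: class-mean contrast returns aa exactly
  m1 <- trait_model(epistatic = tibble::tibble(snp1 = "Epi2B",
                                               snp2 = "Epi7B", aa = 13.7),
                    intercept = 80)
  ph1 <- sim_phenotype(g, m1, seed = 2)
  lm1 <- line_means(ph1)
  eff <- aa_effect(g, lm1, "Epi2B", "Epi7B")
  expect_equal(eff$aa, 13.7)
  expect_false(eff$na_rule_used)
  # unknown locus errors
  m2 <- trait_model(additive = tibble::tibble(snp = "missing_snp", a = 1))
  expect_error(sim_phenotype(g, m2), "not present")
})

test_that("realised heritability matches the plug-in formula", {
  map21 <- sim_genetic_map(80, fixed_loci = wm_study_loci(), seed = 119)
  panel21 <- sim_founder_panel(map21, fixed_loci = wm_study_loci(), seed = 120)
  pop <- sim_population(panel21, map21,
                        sim_config(target_lines = 400, seed = 121))
  g <- genotype_lines(pop, panel21, map21)
  tm <- wm_trait_model(map21)
  ph <- sim_phenotype(g, tm, seed = 122)
  gv <- attr(ph, "genetic_values")
  h2_expected <- heritability(var(gv), V_E = tm$gxy_var + tm$resid_var,
                              y = tm$n_years)
  vc <- variance_components(ph)
  expect_lt(abs(heritability(vc) - h2_expected), 0.05)
})
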