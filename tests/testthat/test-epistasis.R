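# shared simulated population with the fixed epistatic pair
epi_map <- sim_genetic_map(60, fixed_loci = wm_study_loci(), seed = 151)
epi_panel <- sim_founder_panel(epi_map, fixed_loci = wm_study_loci(),
                               seed = 152)
epi_pop <- sim_population(epi_panel, epi_map,
                          sim_config(target_lines = 300, seed = 153))
epi_geno <- genotype_lines(epi_pop, epi_panel, epi_map)

test_that("the single-marker prescreen keeps associated SNPs and drops noise", {
  set.seed(154)
  n <- 400; m <- 200
  X <- matrix(2 * rbinom(n * m, 1, 0.5), n, m,
              dimnames = list(paste0("L", 1:n), paste0("S", 1:m)))
  y <- setNames(X[, 1] * 2 + rnorm(n), rownames(X))
  kept <- prescreen_candidates(y, X, alpha = 0.15)
  expect_true("S1" %in% kept)
  # null SNPs are excluded at roughly rate 1 - alpha
  frac_null_kept <- mean(paste0("S", 2:m) %in% kept)
  expect_lt(abs(frac_null_kept - 0.15), 3 * sqrt(0.15 * 0.85 / (m - 1)))
  expect_equal(prescreen_candidates(y, X, alpha = 1), colnames(X))
})

test_that("interaction p-values are symmetric in the pair order", {
  tm <- trait_model(epistatic = tibble::tibble(snp1 = "Epi2B", snp2 = "Epi7B",
                                               aa = 10),
                    intercept = 80, resid_var = 9, year_var = 1)
  ph <- sim_phenotype(epi_geno, tm, seed = 155)
  means <- line_means(ph)
  p12 <- pairwise_interaction_scan(means, epi_geno, c("Epi2B", "Epi7B"))
  p21 <- pairwise_interaction_scan(means, epi_geno, c("Epi7B", "Epi2B"))
  expect_equal(p12$p, p21$p)
})

test_that("a noiseless simulated interaction is recovered exactly", {
  tm <- trait_model(epistatic = tibble::tibble(snp1 = "Epi2B", snp2 = "Epi7B",
                                               aa = 13.7),
                    intercept = 84)
  ph <- sim_phenotype(epi_geno, tm, seed = 156)
  means <- line_means(ph)
  eff <- aa_effect(epi_geno, means, "Epi2B", "Epi7B")
  expect_equal(eff$aa, 13.7)
  # swapping loci leaves aa unchanged
  eff_sw <- aa_effect(epi_geno, means, "Epi7B", "Epi2B")
  expect_equal(eff_sw$aa, eff$aa)
  # relabelling one locus flips the sign
  flipped <- epi_geno
  flipped[, "Epi2B"] <- 2 - flipped[, "Epi2B"]
  expect_equal(aa_effect(flipped, means, "Epi2B", "Epi7B")$aa, -13.7)
})

test_that("the mixed-class substitution rule engages only when one cell is empty", {
  fx <- class_mean_fixture(73.9, 77.7, 89.0, 0)
  keep <- fx$geno[, 1] != 0 | fx$geno[, 2] != 2  # drop the NJ class
  g <- fx$geno[keep, ]; y <- fx$y[keep]
  eff <- aa_effect(g, y, "m1", "m2")
  expect_true(eff$na_rule_used)
  expect_equal(eff$aa, (73.9 + 77.7) - 2 * 89.0)
  # an empty homozygous class is unrecoverable
  keep2 <- !(fx$geno[, 1] == 2 & fx$geno[, 2] == 2)
  expect_error(aa_effect(fx$geno[keep2, ], fx$y[keep2], "m1", "m2"),
               "homozygous")
})

test_that("epistatic variance is the interaction share of the class sum of squares", {
  fx <- class_mean_fixture(85, 85, 75, 75)  # pure interaction, balanced
  expect_equal(suppressWarnings(epistatic_variance(fx$geno, fx$y, "m1", "m2")), 100)
  fx2 <- class_mean_fixture(2, -2, 0, 0)    # purely additive
  expect_equal(suppressWarnings(epistatic_variance(fx2$geno, fx2$y, "m1", "m2")), 0)
  # known variance split is recovered
  tm <- trait_model(additive = tibble::tibble(snp = c("Epi2B", "Epi7B"),
                                              a = c(2, 2)),
                    epistatic = tibble::tibble(snp1 = "Epi2B",
                                               snp2 = "Epi7B", aa = 8),
                    intercept = 0)
  ph <- sim_phenotype(epi_geno, tm, seed = 157)
  means <- line_means(ph)
  r2 <- suppressWarnings(epistatic_variance(epi_geno, means, "Epi2B", "Epi7B"))
  # SS(interaction)/SS(classes) = (aa/4)^2 / (a1^2 + a2^2 + (aa/4)^2) = 1/3
  expect_lt(abs(r2 - 100 / 3), 6)
})

test_that("joint selection keeps one representative of a proxied interaction", {
  set.seed(158)
  n <- 400
  x1 <- 2 * rbinom(n, 1, 0.5)
  x2 <- 2 * rbinom(n, 1, 0.5)
  x1b <- x1
  flip <- sample(n, 8)                    # near-duplicate proxy of x1
  x1b[flip] <- 2 - x1b[flip]
  X <- cbind(P1 = x1, P1b = x1b, P2 = x2)
  rownames(X) <- paste0("L", 1:n)
  y <- setNames((x1 - 1) * (x2 - 1) * 3 + rnorm(n, 0, 1), rownames(X))
  pw <- pairwise_interaction_scan(y, X, colnames(X))
  expect_true(all(pw$significant[pw$snp2 == "P2"]))
  kept <- select_interactions(pw, y, X)
  expect_equal(nrow(kept), 1)
  expect_true(kept$snp1 %in% c("P1", "P1b"))
  # two genuinely independent interactions are both retained
  x3 <- 2 * rbinom(n, 1, 0.5); x4 <- 2 * rbinom(n, 1, 0.5)
  X2 <- cbind(A = x1, B = x2, C = x3, D = x4)
  rownames(X2) <- rownames(X)
  y2 <- setNames((x1 - 1) * (x2 - 1) * 3 + (x3 - 1) * (x4 - 1) * 3 +
                   rnorm(n, 0, 1), rownames(X2))
  pw2 <- pairwise_interaction_scan(y2, X2, colnames(X2))
  kept2 <- select_interactions(pw2, y2, X2)
  keys <- paste(kept2$snp1, kept2$snp2)
  expect_true("A B" %in% keys)
  expect_true("C D" %in% keys)
  # empty input passes through
  pw0 <- pw; pw0$significant <- FALSE
  expect_equal(nrow(select_interactions(pw0, y, X)), 0)
})

test_that("interaction grouping merges orientation-matched endpoint windows", {
  map <- tibble::tibble(
    snp = c("a1", "a2", "b1", "b2", "c1", "c2"),
    chr = c("C1", "C1", "C2", "C2", "C1", "C2"),
    pos = c(10, 16, 50, 55, 30, 80)
  )
  prs <- tibble::tibble(
    snp1 = c("a1", "a2", "c1"),
    snp2 = c("b1", "b2", "c2"),
    p_fdr = c(1e-5, 1e-3, 1e-4)
  )
  out <- group_interactions(prs, map)
  # a1-b1 and a2-b2: endpoints 6 and 5 cM apart -> merged
  expect_equal(out$group[1], out$group[2])
  expect_false(out$group[3] == out$group[1])
  expect_true(out$representative[1])   # smaller FDR p
  expect_false(out$representative[2])
  # identical pairs merge; 8 cM endpoints do not
  prs2 <- tibble::tibble(snp1 = c("a1", "a1"), snp2 = c("b1", "b1"),
                         p_fdr = c(0.1, 0.2))
  expect_equal(dplyr::n_distinct(group_interactions(prs2, map)$group), 1)
  map8 <- map; map8$pos[2] <- 18.1  # a2 now 8.1 cM from a1
  out8 <- group_interactions(prs, map8)
  expect_false(out8$group[1] == out8$group[2])
  # chain linkage: A-B within window of B-C endpoints merges all three
  mapc <- tibble::tibble(snp = c("x1", "x2", "x3", "y1", "y2", "y3"),
                         chr = c(rep("C1", 3), rep("C2", 3)),
                         pos = c(10, 15, 20, 40, 45, 50))
  prsc <- tibble::tibble(snp1 = c("x1", "x2", "x3"),
                         snp2 = c("y1", "y2", "y3"),
                         p_fdr = c(0.01, 0.02, 0.03))
  expect_equal(dplyr::n_distinct(group_interactions(prsc, mapc)$group), 1)
})

test_that("the FDR stays controlled under a purely additive trait", {
  set.seed(159)
  n <- 200; m <- 12
  X <- matrix(2 * rbinom(n * m, 1, 0.5), n, m,
              dimnames = list(paste0("L", 1:n), paste0("S", 1:m)))
  total_sig <- 0; total_pairs <- 0
  for (i in 1:100) {
    y <- setNames(X[, 1] - X[, 2] + rnorm(n), rownames(X))
    pw <- pairwise_interaction_scan(y, X, colnames(X))
    total_sig <- total_sig + sum(pw$significant)
    total_pairs <- total_pairs + nrow(pw)
  }
  expect_lt(total_sig / total_pairs, 0.005)
})
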