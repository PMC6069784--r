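# a tiny hand-built founder panel: 8 founders x 5 SNPs
toy_panel <- function() {
  founders <- wm_founders()
  alleles <- matrix(0L, 8, 5,
                    dimnames = list(founders$founder, paste0("S", 1:5)))
  alleles["Julius", ] <- 1L                          # reference always carries
  alleles[c("Patras", "Meister", "Linus"), "S2"] <- 1L   # k = 4
  alleles[setdiff(founders$founder, "Tobak"), "S3"] <- 1L # k = 7, unique Tobak
  alleles[, "S4"] <- 1L                              # k = 8 -> monomorphic
  alleles[c("Patras"), "S5"] <- 1L                   # k = 2
  list(founders = founders, reference = "Julius", alleles = alleles,
       ref_allele = setNames(rep("A", 5), colnames(alleles)),
       alt_allele = setNames(rep("B", 5), colnames(alleles))) |>
    structure(class = "founder_panel")
}

test_that("allele-frequency groups count reference-allele carriers", {
  afg <- assign_afg(toy_panel())
  expect_equal(afg$snp, c("S1", "S2", "S3", "S5"))  # S4 monomorphic, excluded
  expect_equal(afg$afg, c(1L, 4L, 7L, 2L))
  expect_equal(afg$expected_freq, c(0.125, 0.5, 0.875, 0.25))
  expect_equal(afg$unique_founder, c("Julius", NA, "Tobak", NA))
})

test_that("unique-SNP accounting reports AFG 1 + AFG 7 counts and percentage", {
  afg <- tibble::tibble(
    afg = rep(1:7, times = c(260, 531, 877, 842, 1315, 1582, 2177)),
    snp = paste0("S", 1:7584), expected_freq = afg / 8,
    unique_founder = NA_character_
  )
  rep_ <- unique_snp_report(afg)
  expect_equal(rep_$n_unique, 2437)
  expect_equal(round(rep_$pct_unique, 1), 32.1)
  expect_equal(rep_$n_snps, 7584)
})

test_that("the distortion chi-square matches a textbook computation on counts", {
  # 800 lines, AFG 1: observed reference frequency 0.135 vs expected 0.125,
  # i.e. 216 vs 1384 alleles; oracle: sum((O-E)^2/E), E = (200, 1400)
  g <- matrix(c(rep(2L, 108), rep(0L, 692)), ncol = 1,
              dimnames = list(paste0("L", 1:800), "s1"))
  afg <- tibble::tibble(snp = "s1", afg = 1L, expected_freq = 0.125,
                        unique_founder = "Julius")
  res <- sd_test(g, afg, correct_inbreeding = FALSE)
  oracle_chi <- (216 - 200)^2 / 200 + (1384 - 1400)^2 / 1400
  expect_equal(res$chi_square, oracle_chi)
  expect_equal(res$p, pchisq(oracle_chi, 1, lower.tail = FALSE))
  expect_equal(res$n_ref, 216)
  expect_equal(res$direction, 1)
})

test_that("balanced counts give zero distortion and missing calls are excluded", {
  g <- matrix(c(rep(2L, 50), rep(0L, 50), rep(NA, 10)), ncol = 1,
              dimnames = list(paste0("L", 1:110), "s1"))
  afg <- tibble::tibble(snp = "s1", afg = 4L, expected_freq = 0.5,
                        unique_founder = NA_character_)
  res <- sd_test(g, afg, correct_inbreeding = FALSE)
  expect_equal(res$chi_square, 0)
  expect_equal(res$p, 1)
  expect_equal(res$n_total, 200)  # 2 x 100 non-missing
  expect_error(sd_test(g, afg[0, ]), "absent")
})

test_that("Bonferroni-Holm adjustment is monotone and bounded below by raw p", {
  map <- make_unlinked_map(n_snps = 150, seed = 81)
  panel <- sim_founder_panel(map, seed = 82)
  pop <- make_pop(map, panel, n_lines = 150, seed = 83, independent = TRUE)
  g <- genotype_lines(pop, panel, map)
  res <- sd_test(g, assign_afg(panel))
  expect_true(all(res$p_adj >= res$p))
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
  expect_true(all(res$direction == sign(res$deviation)))
})

test_that("distortion regions are maximal runs of adjacent significant SNPs", {
  map <- tibble::tibble(snp = paste0("S", 1:6), chr = "C1", pos = 1:6 * 10)
  base <- tibble::tibble(
    snp = map$snp, afg = 4L, n_ref = 0L, n_total = 0L,
    observed_freq = 0.6, expected_freq = 0.5, deviation = 0.1,
    direction = 1, chi_square = 0, p = 0.5
  )
  # pattern: sig sig sig non sig sig  -> exactly one region of 3
  base$p_adj <- c(0.001, 0.001, 0.001, 0.5, 0.001, 0.001)
  reg <- detect_sdr(base, map)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$n_snps, 3)
  expect_equal(reg$start, 10); expect_equal(reg$end, 30)
  expect_equal(reg$snps[[1]], c("S1", "S2", "S3"))
  # two significant SNPs split by a gap form no region
  base$p_adj <- c(0.001, 0.5, 0.001, 0.5, 0.001, 0.5)
  expect_equal(nrow(detect_sdr(base, map)), 0)
  # nothing significant -> empty
  base$p_adj <- rep(0.5, 6)
  expect_equal(nrow(detect_sdr(base, map)), 0)
})

test_that("founder selection events group unique SNPs by chromosome and direction", {
  n1 <- 12
  map <- tibble::tibble(snp = paste0("S", 1:(n1 + 10)),
                        chr = c(rep("C1", n1), rep("C2", 10)),
                        pos = seq_len(n1 + 10))
  afg_tab <- tibble::tibble(snp = map$snp,
                        afg = c(rep(1L, n1), rep(7L, 10)),
                        expected_freq = c(rep(0.125, n1), rep(0.875, 10)),
                        unique_founder = c(rep("Julius", n1),
                                           rep("Tobak", 10)))
  res <- tibble::tibble(
    snp = map$snp, afg = afg_tab$afg, n_ref = 0L, n_total = 0L,
    observed_freq = 0.2, expected_freq = afg_tab$expected_freq,
    deviation = 0.05, direction = 1, chi_square = 10,
    p = 1e-4, p_adj = 1e-3
  )
  ev <- founder_selection_events(res, afg_tab, map)
  # 12 AFG-1 SNPs (> 10) qualify; reference-allele excess = Julius increase
  expect_equal(nrow(ev), 1)
  expect_equal(ev$founder, "Julius")
  expect_equal(ev$direction, 1)
  expect_equal(ev$n_snps, n1)
  # AFG-7 group has exactly 10 members: not reported (strict threshold);
  # with 11 members it is, with the direction inverted for the non-carrier
  map2 <- dplyr::bind_rows(map, tibble::tibble(snp = "S23", chr = "C2",
                                               pos = 23))
  afg2 <- dplyr::bind_rows(afg_tab, tibble::tibble(snp = "S23", afg = 7L,
                                               expected_freq = 0.875,
                                               unique_founder = "Tobak"))
  res2 <- dplyr::bind_rows(res, res[1, ] |>
                             dplyr::mutate(snp = "S23", afg = 7L,
                                           expected_freq = 0.875))
  ev2 <- founder_selection_events(res2, afg2, map2)
  tob <- ev2[ev2$founder == "Tobak", ]
  expect_equal(nrow(tob), 1)
  expect_equal(tob$direction, -1)  # reference excess = Tobak-allele deficit
  expect_equal(tob$n_snps, 11)
  # nothing significant -> empty
  res$p_adj <- 0.5
  expect_equal(nrow(founder_selection_events(res, afg_tab, map)), 0)
})
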