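#' Specify a quantitative trait model
#'
#' The simulated trait value of line i in year y, replicate r is
#' \deqn{v = \mu + \sum_j a_j x_{ij} + \sum_k (aa_k/4) x_{i,k1} x_{i,k2}
#'   + Y_y + GY_{iy} + e_{iyr}}
#' with \eqn{x = dosage - 1 \in \{-1, 0, +1\}} the centred count of the
#' reference-founder allele. `a` is half the homozygous contrast (the
#' difference between the two homozygous classes is `2a`), and the `aa/4`
#' parameterisation of the product term guarantees that the contrast of
#' two-locus homozygous class means `(JJ + NN) - (JN + NJ)` equals `aa` in
#' expectation.
#'
#' @param additive Tibble with columns `snp` and `a` (cm, half the
#'   homozygous contrast). May be empty.
#' @param epistatic Tibble with columns `snp1`, `snp2`, `aa` (cm). May be
#'   empty.
#' @param intercept Trait mean in cm (default 84).
#' @param year_var,gxy_var,resid_var Variance components (cm^2) of the year
#'   main effect, the genotype x year interaction and the residual.
#' @param n_years,n_reps Number of years and replicates per year.
#' @return A list of class `trait_model`.
#' @export
trait_model <- function(additive = tibble::tibble(snp = character(), a = numeric()),
                        epistatic = tibble::tibble(snp1 = character(),
                                                   snp2 = character(),
                                                   aa = numeric()),
                        intercept = 84, year_var = 0, gxy_var = 0,
                        resid_var = 0, n_years = 2, n_reps = 1) {
  stopifnot(year_var >= 0, gxy_var >= 0, resid_var >= 0,
            n_years >= 1, n_reps >= 1)
  structure(
    list(additive = additive, epistatic = epistatic, intercept = intercept,
         year_var = year_var, gxy_var = gxy_var, resid_var = resid_var,
         n_years = n_years, n_reps = n_reps),
    class = "trait_model"
  )
}

#' Default plant-height trait architecture
#'
#' Builds the plant-height model used as the package's reference study
#' condition: the two large-effect semi-dwarfing loci on 4B (+12.8 cm
#' homozygous Julius contrast) and 4D (-14.9 cm), nine small-effect loci
#' with homozygous contrasts of 2.4--5.3 cm placed near their reported map
#' positions, and one additive-by-additive epistatic pair (2B x 7B,
#' aa = +13.7 cm) whose member SNPs also carry small main effects. With the
#' default variance components (year 25, genotype x year 5, residual
#' 16 cm^2, two years, one replicate) the realised broad-sense heritability
#' of line means is about 0.9 and their standard deviation about 11 cm.
#'
#' Small QTL are attached to the mapped SNP nearest their target position
#' on the target chromosome; the large loci and the epistatic pair use the
#' fixed study loci, so the map must have been built with
#' `fixed_loci = wm_study_loci()` (and the founder panel likewise).
#'
#' @param map Genetic map tibble containing SNPs named `Rht-B1`, `Rht-D1`,
#'   `Epi2B` and `Epi7B`.
#' @return A `trait_model`.
#' @export
wm_trait_model <- function(map) {
  stopifnot(all(c("Rht-B1", "Rht-D1", "Epi2B", "Epi7B") %in% map$snp))
  nearest <- function(chr, pos) {
    cand <- map[map$chr == chr, ]
    stopifnot(nrow(cand) > 0)
    cand$snp[which.min(abs(cand$pos - pos))]
  }
  small <- tibble::tibble(
    chr = c("1B", "1D", "2A", "2D", "3A", "4A", "5A", "6A", "7B"),
    pos = c(117.8, 167.1, 148.8, 97.1, 61.1, 43.2, 67.0, 79.1, 155.4),
    contrast = c(3.8, -3.9, -2.4, -3.5, -2.9, 2.8, 5.3, 5.1, -4.3)
  )
  small$snp <- mapply(nearest, small$chr, small$pos)
  additive <- dplyr::bind_rows(
    tibble::tibble(snp = c("Rht-B1", "Rht-D1"), a = c(12.8, -14.9) / 2),
    tibble::tibble(snp = small$snp, a = small$contrast / 2),
    tibble::tibble(snp = c("Epi2B", "Epi7B"), a = c(3.0, -3.6) / 2)
  )
  trait_model(
    additive = additive,
    epistatic = tibble::tibble(snp1 = "Epi2B", snp2 = "Epi7B", aa = 13.7),
    intercept = 84, year_var = 25, gxy_var = 5, resid_var = 16,
    n_years = 2, n_reps = 1
  )
}

#' Simulate phenotype records from genotypes
#'
#' Applies a [trait_model()] to a genotype matrix and draws year, genotype x
#' year and residual effects. Missing dosages contribute no genetic effect
#' (their centred dosage is taken as 0); supply an error-free matrix for
#' exact genetic values.
#'
#' @param geno Lines x SNPs dosage matrix (0/1/2; values in `[0, 2]`
#'   accepted).
#' @param model A `trait_model`; every model SNP must be a column of `geno`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `line`, `year`, `rep`, `value` (cm).
#' @export
sim_phenotype <- function(geno, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  miss <- setdiff(c(model$additive$snp, model$epistatic$snp1,
                    model$epistatic$snp2), colnames(geno))
  if (length(miss)) {
    stop("trait model locus not present in genotype matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(geno)
  stopifnot(!is.null(rownames(geno)))
  g <- setNames(rep(model$intercept, n), rownames(geno))
  if (nrow(model$additive)) {
    x <- geno[, model$additive$snp, drop = FALSE] - 1
    x[is.na(x)] <- 0
    g <- g + drop(x %*% model$additive$a)
  }
  if (nrow(model$epistatic)) {
    for (k in seq_len(nrow(model$epistatic))) {
      x1 <- geno[, model$epistatic$snp1[k]] - 1
      x2 <- geno[, model$epistatic$snp2[k]] - 1
      x1[is.na(x1)] <- 0; x2[is.na(x2)] <- 0
      g <- g + (model$epistatic$aa[k] / 4) * x1 * x2
    }
  }
  yrs <- seq_len(model$n_years)
  year_eff <- rnorm(model$n_years, 0, sqrt(model$year_var))
  out <- tidyr::expand_grid(line = rownames(geno), year = yrs,
                            rep = seq_len(model$n_reps))
  gxy <- matrix(rnorm(n * model$n_years, 0, sqrt(model$gxy_var)),
                n, model$n_years)
  ri <- match(out$line, rownames(geno))
  out$value <- g[out$line] + year_eff[out$year] +
    gxy[cbind(ri, out$year)] +
    rnorm(nrow(out), 0, sqrt(model$resid_var))
  attr(out, "genetic_values") <- setNames(g, rownames(geno))
  out
}
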