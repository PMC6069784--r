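#' Simple-matching genetic similarity
#'
#' Similarity between two lines is the proportion of SNPs at which they
#' carry an identical dosage state (0, 1 and 2 compared exactly), among
#' SNPs non-missing in both lines.
#'
#' @param geno Lines x SNPs dosage matrix (0/1/2/NA).
#' @return A symmetric lines x lines matrix with unit diagonal. Pairs with
#'   no shared non-missing SNP are `NA`; such pairs are listed in the
#'   `undefined_pairs` attribute.
#' @export
genetic_similarity <- function(geno) {
  obs <- !is.na(geno)
  shared <- tcrossprod(obs * 1)
  match_ct <- matrix(0, nrow(geno), nrow(geno))
  for (s in 0:2) {
    m <- (geno == s) & obs
    m[is.na(m)] <- FALSE
    match_ct <- match_ct + tcrossprod(m * 1)
  }
  sim <- match_ct / shared
  sim[shared == 0] <- NA_real_
  diag(sim) <- 1
  dimnames(sim) <- list(rownames(geno), rownames(geno))
  und <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)
  if (nrow(und)) {
    attr(sim, "undefined_pairs") <- tibble::tibble(
      line1 = rownames(geno)[und[, 1]], line2 = rownames(geno)[und[, 2]]
    )
  }
  sim
}

#' Principal components of a genetic-similarity matrix
#'
#' Treats the similarity matrix as an observations x variables table,
#' column-centres it and extracts principal components by singular value
#' decomposition (no scaling).
#'
#' @param sim Symmetric similarity matrix from [genetic_similarity()].
#' @return An object of class `sim_pca`: list with `scores` (tibble: `line`,
#'   `PC1`, `PC2`, ...) and `var_frac` (fractions of variance, non-increasing,
#'   summing to 1).
#' @export
similarity_pca <- function(sim) {
  if (!isTRUE(all.equal(sim, t(sim), tolerance = 1e-8))) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  if (anyNA(sim)) {
    stop("similarity matrix has undefined entries; remove the affected lines",
         call. = FALSE)
  }
  pc <- stats::prcomp(sim, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  vf <- if (tot < 1e-12) rep(0, length(pc$sdev)) else pc$sdev^2 / tot
  scores <- tibble::as_tibble(pc$x, .name_repair = "minimal")
  scores <- dplyr::bind_cols(
    tibble::tibble(line = rownames(sim) %||% as.character(seq_len(nrow(sim)))),
    scores
  )
  structure(list(scores = scores, var_frac = vf), class = "sim_pca")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_pca <- function(x, ...) {
  cat("<sim_pca> ", nrow(x$scores), " lines; PC1/PC2 variance: ",
      sprintf("%.1f%% / %.1f%%", 100 * x$var_frac[1], 100 * x$var_frac[2]),
      "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sim_pca <- function(x, ...) x$scores

#' @exportS3Method generics::glance
glance.sim_pca <- function(x, ...) {
  tibble::tibble(pc1_frac = x$var_frac[1], pc2_frac = x$var_frac[2],
                 n = nrow(x$scores))
}

#' @exportS3Method ggplot2::autoplot
autoplot.sim_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_frac[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_frac[2])
    ) +
    ggplot2::theme_minimal()
}

#' Linkage-disequilibrium decay with a population-specific background
#'
#' Computes r-squared (squared Pearson correlation of dosages) for
#' intra-chromosomal SNP pairs against genetic distance, fits a
#' second-degree LOESS decay curve, and estimates the population-specific
#' background LD as a quantile (default the 95th percentile) of r-squared
#' among unlinked (inter-chromosomal) pairs. The decay distance is the
#' smallest distance at which the fitted curve first crosses
#' `reference_r2` from above. Monomorphic SNPs are excluded.
#'
#' @param geno Imputed lines x SNPs dosage matrix.
#' @param map Genetic map covering the SNP columns.
#' @param reference_r2 Reference level for the decay distance (default 0.2).
#' @param unlinked_quantile Quantile of the unlinked r-squared distribution
#'   used as background (default 0.95).
#' @param loess_span LOESS span (default 0.3, degree 2).
#' @param max_intra_pairs,max_unlinked_pairs Subsampling caps for the two
#'   pair sets (seeded by the session RNG).
#' @return An object of class `ld_result`: `pairs` (tibble `snp1`, `snp2`,
#'   `dist`, `r2`), `curve` (tibble `dist`, `r2_fit`), `background_r2`,
#'   `decay_distance`, `background_distance` and the parameters used.
#' @export
ld_decay <- function(geno, map, reference_r2 = 0.2, unlinked_quantile = 0.95,
                     loess_span = 0.3, max_intra_pairs = 2e5,
                     max_unlinked_pairs = 1e5) {
  snps <- intersect(colnames(geno), map$snp)
  geno <- geno[, snps, drop = FALSE]
  sds <- apply(geno, 2, sd)
  mono <- sds == 0 | is.na(sds)
  if (any(mono)) {
    message("excluding ", sum(mono), " monomorphic SNP(s) from LD analysis")
    geno <- geno[, !mono, drop = FALSE]
    snps <- colnames(geno)
  }
  info <- map[match(snps, map$snp), ]
  by_chr <- split(seq_along(snps), info$chr, drop = TRUE)
  pairs <- purrr::map_dfr(by_chr, function(idx) {
    if (length(idx) < 2) return(NULL)
    r <- cor(geno[, idx, drop = FALSE])
    ut <- which(upper.tri(r), arr.ind = TRUE)
    tibble::tibble(
      snp1 = snps[idx[ut[, 1]]], snp2 = snps[idx[ut[, 2]]],
      dist = abs(info$pos[idx[ut[, 2]]] - info$pos[idx[ut[, 1]]]),
      r2 = r[ut]^2
    )
  })
  if (nrow(pairs) > max_intra_pairs) {
    pairs <- pairs[sample.int(nrow(pairs), max_intra_pairs), ]
  }
  # unlinked background: inter-chromosomal pairs
  n_snp <- length(snps)
  n_bg <- min(max_unlinked_pairs, n_snp * (n_snp - 1))
  i <- sample.int(n_snp, n_bg, replace = TRUE)
  j <- sample.int(n_snp, n_bg, replace = TRUE)
  keep <- info$chr[i] != info$chr[j]
  i <- i[keep]; j <- j[keep]
  bg_r2 <- vapply(seq_along(i), function(k) {
    cor(geno[, i[k]], geno[, j[k]])^2
  }, numeric(1))
  background_r2 <- as.numeric(quantile(bg_r2, unlinked_quantile, na.rm = TRUE))
  fit <- loess(r2 ~ dist, data = pairs, span = loess_span, degree = 2)
  grid <- seq(0, max(pairs$dist), length.out = 512)
  r2_fit <- predict(fit, newdata = data.frame(dist = grid))
  curve <- tibble::tibble(dist = grid, r2_fit = r2_fit)
  cross_down <- function(level) {
    ok <- !is.na(r2_fit)
    g <- grid[ok]; f <- r2_fit[ok]
    if (!length(f) || f[1] <= level) return(NA_real_)
    below <- which(f <= level)
    if (!length(below)) return(NA_real_)
    k <- below[1]
    # linear interpolation between grid points k-1 and k
    g[k - 1] + (level - f[k - 1]) * (g[k] - g[k - 1]) / (f[k] - f[k - 1])
  }
  structure(
    list(pairs = pairs, curve = curve,
         background_r2 = background_r2,
         decay_distance = cross_down(reference_r2),
         background_distance = cross_down(background_r2),
         reference_r2 = reference_r2,
         unlinked_quantile = unlinked_quantile,
         loess_span = loess_span),
    class = "ld_result"
  )
}

#' @export
print.ld_result <- function(x, ...) {
  cat("<ld_result> ", nrow(x$pairs), " linked pairs; background r2 = ",
      signif(x$background_r2, 3), "; r2 = ", x$reference_r2, " at ",
      signif(x$decay_distance, 3), " cM\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ld_result <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.ld_result <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pairs),
    background_r2 = x$background_r2,
    decay_distance = x$decay_distance,
    background_distance = x$background_distance,
    reference_r2 = x$reference_r2
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.ld_result <- function(object, max_points = 20000, ...) {
  pr <- object$pairs
  if (nrow(pr) > max_points) pr <- pr[sample.int(nrow(pr), max_points), ]
  ggplot2::ggplot(pr, ggplot2::aes(.data$dist, .data$r2)) +
    ggplot2::geom_point(alpha = 0.1, size = 0.4) +
    ggplot2::geom_line(data = object$curve,
                       ggplot2::aes(.data$dist, .data$r2_fit),
                       colour = "red", linewidth = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$background_r2,
                        linetype = "dashed") +
    ggplot2::labs(x = "genetic distance (cM)", y = expression(r^2)) +
    ggplot2::theme_minimal()
}
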