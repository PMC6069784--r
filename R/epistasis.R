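#' Single-marker pre-screen for the epistasis scan
#'
#' Regresses the trait on each SNP dosage separately and retains SNPs with
#' a slope p-value below `alpha` as candidates for pairwise interaction
#' testing.
#'
#' @param means Line means (tibble `line`, `mean` or named vector).
#' @param geno Imputed lines x SNPs dosage matrix.
#' @param alpha Inclusion threshold (default 0.15).
#' @return Character vector of candidate SNP ids (column order preserved).
#' @export
prescreen_candidates <- function(means, geno, alpha = 0.15) {
  y <- align_means(means, geno)
  X <- geno[names(y), , drop = FALSE]
  n <- length(y)
  sds <- apply(X, 2, sd)
  r <- suppressWarnings(cor(X, y))
  r[sds == 0] <- 0
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  colnames(X)[!is.na(p) & p < alpha]
}

align_means <- function(means, geno) {
  if (is_tibble(means) || is.data.frame(means)) {
    y <- setNames(means$mean, means$line)
  } else {
    y <- means
  }
  lines <- intersect(rownames(geno), names(y))
  stopifnot(length(lines) > 3)
  setNames(as.numeric(y[lines]), lines)
}

#' Pairwise di-genic interaction scan
#'
#' For every unordered pair of candidate SNPs, fits
#' `trait ~ x1 + x2 + x1:x2` on centred dosages and records the p-value of
#' the interaction term; Benjamini--Hochberg FDR adjustment is applied
#' across all tested pairs, and pairs with adjusted p at most `q` are
#' flagged significant.
#'
#' @param means Line means.
#' @param geno Imputed lines x SNPs dosage matrix.
#' @param candidates Candidate SNP ids (e.g. from
#'   [prescreen_candidates()]).
#' @param q FDR significance threshold (default 0.01).
#' @return A tibble `snp1`, `snp2`, `p`, `p_fdr`, `significant`.
#' @export
pairwise_interaction_scan <- function(means, geno, candidates, q = 0.01) {
  stopifnot(length(candidates) >= 2)
  y <- align_means(means, geno)
  X <- scale(geno[names(y), candidates, drop = FALSE], scale = FALSE)
  n <- length(y)
  idx <- combn(length(candidates), 2)
  np <- ncol(idx)
  pvals <- numeric(np)
  for (k in seq_len(np)) {
    x1 <- X[, idx[1, k]]
    x2 <- X[, idx[2, k]]
    D <- cbind(1, x1, x2, x1 * x2)
    qrD <- qr(D)
    if (qrD$rank < 4) { pvals[k] <- NA_real_; next }
    beta <- qr.coef(qrD, y)
    res <- qr.resid(qrD, y)
    df <- n - 4
    s2 <- sum(res^2) / df
    R <- qr.R(qrD)
    inv <- chol2inv(R)
    d4 <- numeric(4); d4[qrD$pivot] <- diag(inv)
    tval <- beta[4] / sqrt(s2 * d4[4])
    pvals[k] <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  }
  out <- tibble::tibble(
    snp1 = candidates[idx[1, ]], snp2 = candidates[idx[2, ]],
    p = pvals, p_fdr = p.adjust(pvals, method = "BH")
  )
  out$significant <- !is.na(out$p_fdr) & out$p_fdr <= q
  out
}

#' Joint forward/backward selection of interaction terms
#'
#' Builds one joint model containing the main effects of every SNP involved
#' in the significant pairs, then forward-adds product terms by smallest
#' partial p-value (threshold `p_in`) and backward-drops terms whose
#' p-value rises above `p_out`, with deterministic tie-breaking by input
#' order. Collinear product terms are rejected when they enter.
#'
#' @param pairs Tibble from [pairwise_interaction_scan()] (only rows with
#'   `significant == TRUE` are considered).
#' @param means Line means.
#' @param geno Imputed lines x SNPs dosage matrix.
#' @param p_in,p_out Selection thresholds (default 0.01).
#' @return The retained subset of `pairs`, with the joint-model interaction
#'   p-value in column `p_joint`.
#' @export
select_interactions <- function(pairs, means, geno, p_in = 0.01,
                                p_out = 0.01) {
  sig <- pairs[which(pairs$significant), , drop = FALSE]
  if (!nrow(sig)) {
    return(tibble::tibble(snp1 = character(0), snp2 = character(0),
                          p = numeric(0), p_fdr = numeric(0),
                          significant = logical(0), p_joint = numeric(0)))
  }
  y <- align_means(means, geno)
  snps <- unique(c(sig$snp1, sig$snp2))
  Xm <- scale(geno[names(y), snps, drop = FALSE], scale = FALSE)
  P <- vapply(seq_len(nrow(sig)), function(k) {
    Xm[, sig$snp1[k]] * Xm[, sig$snp2[k]]
  }, numeric(length(y)))
  base <- cbind(1, Xm)
  sel <- stepwise_terms(y, base, P, p_in, p_out)
  out <- sig[sel$kept, , drop = FALSE]
  out$p_joint <- sel$p
  out
}

# forward/backward over columns of P given a fixed base design
stepwise_terms <- function(y, base, P, p_in, p_out, max_iter = 100) {
  n <- length(y)
  m <- ncol(P)
  sel <- integer(0)
  tol <- 1e-8
  iter <- 0
  repeat {
    iter <- iter + 1
    changed <- FALSE
    D <- cbind(base, P[, sel, drop = FALSE])
    qrD <- qr(D)
    Q <- qr.Q(qrD)
    resid <- y - Q %*% crossprod(Q, y)
    rss0 <- sum(resid^2)
    cand <- setdiff(seq_len(m), sel)
    df2 <- n - ncol(D) - 1
    if (length(cand) && rss0 > tol && df2 > 0) {
      Pc <- P[, cand, drop = FALSE]
      Pr <- Pc - Q %*% crossprod(Q, Pc)
      ss <- colSums(Pr^2)
      ok <- ss > tol * n
      if (any(ok)) {
        num <- drop(crossprod(Pr, resid))^2 / ifelse(ok, ss, Inf)
        Fst <- num / pmax(rss0 - num, .Machine$double.eps) * df2
        pv <- pf(Fst, 1, df2, lower.tail = FALSE)
        pv[!ok] <- Inf
        best <- which.min(pv)
        if (is.finite(pv[best]) && pv[best] <= p_in) {
          sel <- c(sel, cand[best])
          changed <- TRUE
        }
      }
    }
    repeat {
      if (!length(sel)) break
      st <- term_stats(y, base, P[, sel, drop = FALSE])
      if (length(st$dependent)) {
        message("dropping collinear interaction term")
        sel <- sel[-max(st$dependent)]
        changed <- TRUE
        next
      }
      worst <- which.max(st$p)
      if (st$p[worst] > p_out) {
        sel <- sel[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed || iter >= max_iter) break
  }
  if (length(sel)) {
    st <- term_stats(y, base, P[, sel, drop = FALSE])
    list(kept = sort(sel), p = st$p[match(sort(sel), sel)])
  } else {
    list(kept = integer(0), p = numeric(0))
  }
}

# p-values of the P-columns only, given base always in the model
term_stats <- function(y, base, Ps) {
  D <- cbind(base, Ps)
  qrD <- qr(D)
  k <- ncol(D)
  kb <- ncol(base)
  if (qrD$rank < k) {
    dep <- sort(qrD$pivot[(qrD$rank + 1):k]) - kb
    return(list(dependent = dep[dep >= 1]))
  }
  beta <- qr.coef(qrD, y)
  res <- qr.resid(qrD, y)
  df <- length(y) - k
  s2 <- sum(res^2) / df
  inv <- chol2inv(qr.R(qrD))
  d <- numeric(k); d[qrD$pivot] <- diag(inv)
  tval <- beta / sqrt(s2 * d)
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  list(dependent = integer(0), p = p[(kb + 1):k], beta = beta[(kb + 1):k])
}

#' Group interacting SNP pairs by map window
#'
#' Two pairs merge (single linkage) when the endpoints of one lie within
#' `window` cM of the corresponding endpoints of the other on the same
#' chromosomes; both endpoint orientations are tried. Each merged group is
#' represented by its member with the smallest FDR-adjusted p.
#'
#' @param pairs Tibble with `snp1`, `snp2`, `p_fdr` (e.g. from
#'   [select_interactions()]).
#' @param map Genetic map.
#' @param window Endpoint window in cM (default 7, strict).
#' @return `pairs` with added columns `chr1`, `pos1`, `chr2`, `pos2`,
#'   `group`, `representative`.
#' @export
group_interactions <- function(pairs, map, window = 7) {
  if (!nrow(pairs)) {
    return(dplyr::mutate(pairs, chr1 = character(0), pos1 = numeric(0),
                         chr2 = character(0), pos2 = numeric(0),
                         group = integer(0), representative = logical(0)))
  }
  loc <- function(s, what) map[[what]][match(s, map$snp)]
  pairs$chr1 <- as.character(loc(pairs$snp1, "chr"))
  pairs$pos1 <- loc(pairs$snp1, "pos")
  pairs$chr2 <- as.character(loc(pairs$snp2, "chr"))
  pairs$pos2 <- loc(pairs$snp2, "pos")
  np <- nrow(pairs)
  close_ends <- function(c1, p1, c2, p2, d1, q1, d2, q2) {
    (c1 == d1 && c2 == d2 && abs(p1 - q1) <= window && abs(p2 - q2) <= window) ||
      (c1 == d2 && c2 == d1 && abs(p1 - q2) <= window && abs(p2 - q1) <= window)
  }
  parent <- seq_len(np)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (np > 1) {
    for (i in 1:(np - 1)) for (j in (i + 1):np) {
      if (close_ends(pairs$chr1[i], pairs$pos1[i], pairs$chr2[i],
                     pairs$pos2[i], pairs$chr1[j], pairs$pos1[j],
                     pairs$chr2[j], pairs$pos2[j])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(np), find, integer(1))
  pairs$group <- as.integer(factor(root, levels = unique(root)))
  pairs <- pairs %>%
    group_by(.data$group) %>%
    mutate(representative = row_number() == which.min(.data$p_fdr)) %>%
    ungroup()
  pairs
}

#' Additive-by-additive epistatic effect from two-locus class means
#'
#' Lines are classified at each locus as homozygous reference (J, dosage
#' >= 1.5) or homozygous alternative (N, dosage <= 0.5); intermediate
#' dosages are excluded. The effect is
#' `aa = (JJ + NN) - (JN + NJ)` over the four class means. If exactly one
#' mixed class (JN or NJ) is empty, twice the mean of the other mixed
#' class is substituted for the missing sum term and `na_rule_used` is set;
#' an empty homozygous class leaves `aa` undefined (error).
#'
#' @param geno Dosage matrix.
#' @param means Line means.
#' @param snp1,snp2 SNP ids of the pair.
#' @return A one-row tibble `snp1`, `snp2`, `jj`, `nn`, `jn`, `nj`
#'   (class means, cm), `n_jj`, `n_nn`, `n_jn`, `n_nj`, `aa` (cm),
#'   `na_rule_used`.
#' @export
aa_effect <- function(geno, means, snp1, snp2) {
  y <- align_means(means, geno)
  d1 <- geno[names(y), snp1]
  d2 <- geno[names(y), snp2]
  cls <- function(d) ifelse(d >= 1.5, "J", ifelse(d <= 0.5, "N", NA))
  c1 <- cls(d1); c2 <- cls(d2)
  keep <- !is.na(c1) & !is.na(c2)
  cm <- function(a, b) {
    i <- keep & c1 == a & c2 == b
    c(mean = if (any(i)) mean(y[i]) else NA_real_, n = sum(i))
  }
  jj <- cm("J", "J"); nn <- cm("N", "N"); jn <- cm("J", "N"); nj <- cm("N", "J")
  if (is.na(jj["mean"]) || is.na(nn["mean"])) {
    stop("empty homozygous class (JJ or NN): aa undefined for ",
         snp1, " x ", snp2, call. = FALSE)
  }
  na_rule <- FALSE
  mixed_sum <- jn[["mean"]] + nj[["mean"]]
  if (is.na(jn["mean"]) && !is.na(nj["mean"])) {
    mixed_sum <- 2 * nj[["mean"]]; na_rule <- TRUE
  } else if (is.na(nj["mean"]) && !is.na(jn["mean"])) {
    mixed_sum <- 2 * jn[["mean"]]; na_rule <- TRUE
  } else if (is.na(jn["mean"]) && is.na(nj["mean"])) {
    stop("both mixed classes empty: aa undefined for ", snp1, " x ", snp2,
         call. = FALSE)
  }
  m_jj <- jj[["mean"]]; m_nn <- nn[["mean"]]
  m_jn <- jn[["mean"]]; m_nj <- nj[["mean"]]
  k_jj <- jj[["n"]]; k_nn <- nn[["n"]]; k_jn <- jn[["n"]]; k_nj <- nj[["n"]]
  tibble::tibble(
    snp1 = snp1, snp2 = snp2,
    jj = m_jj, nn = m_nn, jn = m_jn, nj = m_nj,
    n_jj = k_jj, n_nn = k_nn, n_jn = k_jn, n_nj = k_nj,
    aa = (m_jj + m_nn) - mixed_sum,
    na_rule_used = na_rule
  )
}

#' Share of between-class variance attributable to the interaction
#'
#' Two-way ANOVA on the homozygous-classified lines of a SNP pair:
#' 100 x SS(interaction) / SS(between the four genotype classes), with
#' main effects fitted before the interaction.
#'
#' @inheritParams aa_effect
#' @return Percentage in `[0, 100]`.
#' @export
epistatic_variance <- function(geno, means, snp1, snp2) {
  y <- align_means(means, geno)
  d1 <- geno[names(y), snp1]
  d2 <- geno[names(y), snp2]
  cls <- function(d) ifelse(d >= 1.5, "J", ifelse(d <= 0.5, "N", NA))
  f1 <- cls(d1); f2 <- cls(d2)
  keep <- !is.na(f1) & !is.na(f2)
  f1 <- factor(f1[keep], c("J", "N")); f2 <- factor(f2[keep], c("J", "N"))
  yy <- y[keep]
  if (nlevels(droplevels(f1)) < 2 || nlevels(droplevels(f2)) < 2 ||
      length(unique(paste(f1, f2))) < 4) {
    stop("degenerate two-locus classification for ", snp1, " x ", snp2,
         call. = FALSE)
  }
  an <- anova(lm(yy ~ f1 * f2))
  ss <- an[["Sum Sq"]]
  names(ss) <- rownames(an)
  100 * ss[["f1:f2"]] / (ss[["f1"]] + ss[["f2"]] + ss[["f1:f2"]])
}

#' Complete di-genic epistasis scan
#'
#' Convenience pipeline: pre-screen -> pairwise interaction scan with FDR
#' control -> joint forward/backward selection -> map-window grouping ->
#' aa-effect and epistatic-variance estimation for each retained pair.
#'
#' @param means Line means.
#' @param geno Imputed lines x SNPs dosage matrix.
#' @param map Genetic map.
#' @param prescreen_alpha Single-marker inclusion threshold (default 0.15).
#' @param q FDR threshold (default 0.01).
#' @param window Grouping window in cM (default 7).
#' @return A tibble, one row per retained pair, with map positions, FDR p,
#'   group/representative flags, class means, `aa` and `r2_epi`.
#' @export
epistasis_scan <- function(means, geno, map, prescreen_alpha = 0.15,
                           q = 0.01, window = 7) {
  cand <- prescreen_candidates(means, geno, prescreen_alpha)
  empty <- tibble::tibble(
    snp1 = character(0), snp2 = character(0), p = numeric(0),
    p_fdr = numeric(0), significant = logical(0), p_joint = numeric(0)
  )
  if (length(cand) < 2) return(empty)
  pw <- pairwise_interaction_scan(means, geno, cand, q = q)
  kept <- select_interactions(pw, means, geno, p_in = q, p_out = q)
  if (!nrow(kept)) return(empty)
  kept <- group_interactions(kept, map, window = window)
  est <- purrr::map_dfr(seq_len(nrow(kept)), function(i) {
    eff <- aa_effect(geno, means, kept$snp1[i], kept$snp2[i])
    eff$r2_epi <- tryCatch(
      epistatic_variance(geno, means, kept$snp1[i], kept$snp2[i]),
      error = function(e) NA_real_
    )
    eff[, c("jj", "nn", "jn", "nj", "aa", "na_rule_used", "r2_epi")]
  })
  dplyr::bind_cols(kept, est)
}
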