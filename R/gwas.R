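#' Configuration of the cross-validated stepwise association scan
#'
#' @param p_enter,p_stay Partial-F p-value thresholds for forward inclusion
#'   and backward retention (both default 0.001).
#' @param cv_repeats,cv_folds Cross-validation layout: `cv_repeats` times
#'   `cv_folds`-fold (default 20 x 5 = 100 model fits).
#' @param detection_threshold Minimum number of fits (of
#'   `cv_repeats * cv_folds`) that must select a SNP for it to qualify as a
#'   marker-trait association (default 35).
#' @param mta_alpha Bonferroni--Holm adjusted-p threshold (default 0.01).
#' @param qtl_window_cM Single-linkage grouping window for same-sign MTAs
#'   (default 5 cM).
#' @param seed Optional integer seed for the fold assignments.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(p_enter = 0.001, p_stay = 0.001, cv_repeats = 20,
                        cv_folds = 5, detection_threshold = 35,
                        mta_alpha = 0.01, qtl_window_cM = 5, seed = NULL) {
  stopifnot(p_enter > 0, p_enter < 1, p_stay > 0, p_stay < 1,
            cv_repeats >= 1, cv_folds >= 2,
            detection_threshold >= 1,
            detection_threshold <= cv_repeats * cv_folds,
            mta_alpha > 0, mta_alpha < 1, qtl_window_cM >= 0)
  structure(
    list(p_enter = p_enter, p_stay = p_stay, cv_repeats = cv_repeats,
         cv_folds = cv_folds, detection_threshold = detection_threshold,
         mta_alpha = mta_alpha, qtl_window_cM = qtl_window_cM, seed = seed),
    class = "scan_config"
  )
}

# t-based partial tests for every term of the model y ~ 1 + Xs.
# Returns NULL-free list; $dependent gives indices of collinear columns
# (1-based into Xs) that must be rejected.
coef_stats <- function(y, Xs) {
  D <- cbind(1, Xs)
  qrD <- qr(D)
  k <- ncol(D)
  if (qrD$rank < k) {
    dep <- sort(qrD$pivot[(qrD$rank + 1):k]) - 1L  # drop intercept offset
    return(list(dependent = dep[dep >= 1]))
  }
  beta <- qr.coef(qrD, y)
  res <- qr.resid(qrD, y)
  df <- length(y) - k
  if (df <= 0) return(list(dependent = integer(0), p = rep(0, k - 1),
                           beta = beta[-1], df = df))
  s2 <- sum(res^2) / df
  R <- qr.R(qrD)
  inv <- chol2inv(R)
  d <- numeric(k)
  d[qrD$pivot] <- diag(inv)
  se <- sqrt(s2 * d)
  tval <- beta / se
  p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  list(dependent = integer(0), beta = beta[-1], se = se[-1], p = p[-1],
       df = df, s2 = s2)
}

#' Stepwise forward/backward SNP selection
#'
#' Forward steps add the candidate SNP with the smallest partial-F p-value
#' if it is at most `p_enter`; backward steps remove any selected SNP whose
#' partial p-value rises above `p_stay`; steps alternate until a fixed
#' point. The procedure is deterministic for a given column order: ties are
#' resolved in favour of the earlier column, so callers should order the
#' columns by map position and SNP id. A candidate collinear with the
#' selected set is skipped (its residual norm is below tolerance), and a
#' later-entering SNP that makes the set collinear is rejected.
#'
#' @param y Numeric response (e.g. line means).
#' @param X Lines x SNPs numeric matrix of imputed dosages, columns in map
#'   order.
#' @param p_enter,p_stay Selection thresholds (default 0.001).
#' @param max_iter Safety cap on forward/backward sweeps.
#' @return A tibble `snp`, `estimate`, `p` for the selected SNPs (empty if
#'   none), with attribute `selected` (column indices in selection order).
#' @export
stepwise_fit <- function(y, X, p_enter = 0.001, p_stay = 0.001,
                         max_iter = 200) {
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (var(y) == 0) {
    out <- tibble::tibble(snp = character(0), estimate = numeric(0),
                          p = numeric(0))
    attr(out, "selected") <- integer(0)
    return(out)
  }
  tol <- 1e-8
  sel <- integer(0)
  iter <- 0
  repeat {
    iter <- iter + 1
    changed <- FALSE
    ## forward
    D <- cbind(1, X[, sel, drop = FALSE])
    qrD <- qr(D)
    Q <- qr.Q(qrD)
    resid <- y - Q %*% crossprod(Q, y)
    rss0 <- sum(resid^2)
    cand <- setdiff(seq_len(ncol(X)), sel)
    df2 <- n - ncol(D) - 1
    if (length(cand) && rss0 > tol && df2 > 0) {
      Xc <- X[, cand, drop = FALSE]
      Xr <- Xc - Q %*% crossprod(Q, Xc)
      ss <- colSums(Xr^2)
      ok <- ss > tol * n
      if (any(ok)) {
        num <- drop(crossprod(Xr, resid))^2 / ifelse(ok, ss, Inf)
        Fst <- num / pmax(rss0 - num, .Machine$double.eps) * df2
        pv <- pf(Fst, 1, df2, lower.tail = FALSE)
        pv[!ok] <- Inf
        best <- which.min(pv)
        if (is.finite(pv[best]) && pv[best] <= p_enter) {
          sel <- c(sel, cand[best])
          changed <- TRUE
        }
      }
    }
    ## backward
    repeat {
      if (!length(sel)) break
      st <- coef_stats(y, X[, sel, drop = FALSE])
      if (length(st$dependent)) {
        # reject the latest-entering collinear SNP
        drop_i <- max(st$dependent)
        message("dropping collinear SNP: ", colnames(X)[sel[drop_i]])
        sel <- sel[-drop_i]
        changed <- TRUE
        next
      }
      worst <- which.max(st$p)
      if (st$p[worst] > p_stay) {
        sel <- sel[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed || iter >= max_iter) break
  }
  if (length(sel)) {
    st <- coef_stats(y, X[, sel, drop = FALSE])
    out <- tibble::tibble(snp = colnames(X)[sel], estimate = st$beta,
                          p = st$p)
  } else {
    out <- tibble::tibble(snp = character(0), estimate = numeric(0),
                          p = numeric(0))
  }
  attr(out, "selected") <- sel
  out
}

#' Cross-validated stepwise association scan
#'
#' Runs [stepwise_fit()] on every training set of a repeated k-fold
#' cross-validation (`cv_repeats` x `cv_folds` fits). For each SNP it
#' records the detection count (number of fits whose final model contains
#' the SNP) and a validation R-squared: the reduction in held-out error sum
#' of squares when the SNP is added to the rest of that fit's model,
#' divided by the held-out total sum of squares, averaged over the fits
#' that selected the SNP. Final p-values come from one stepwise fit on all
#' lines, Bonferroni--Holm adjusted against the genome-wide family of all
#' tested SNPs. Additive
#' effects are hard-class contrasts: mean of lines with dosage >= 1.5 minus
#' mean of lines with dosage <= 0.5 (homozygous reference minus homozygous
#' alternative).
#'
#' @param means Line means: tibble with columns `line` and `mean` (e.g.
#'   from [line_means()]) or a named numeric vector.
#' @param geno Imputed lines x SNPs dosage matrix.
#' @param map Genetic map covering the SNP columns.
#' @param config A [scan_config()].
#' @return An object of class `gwas_scan`: `snps` tibble (`snp`, `chr`,
#'   `pos`, `detection`, `detection_rate`, `r2_val`, `effect`, `estimate`,
#'   `p_final`, `p_adj`), `n_fits`, `n_lines`, `config`, and the full-data
#'   `final_model` tibble.
#' @export
cv_gwas <- function(means, geno, map, config = scan_config()) {
  if (is_tibble(means) || is.data.frame(means)) {
    y_all <- setNames(means$mean, means$line)
  } else {
    y_all <- means
  }
  lines <- intersect(rownames(geno), names(y_all))
  stopifnot(length(lines) >= config$cv_folds)
  snp_order <- map %>%
    filter(.data$snp %in% colnames(geno)) %>%
    arrange(.data$chr, .data$pos, .data$snp)
  X <- geno[lines, snp_order$snp, drop = FALSE]
  y <- as.numeric(y_all[lines])
  n <- length(y); m <- ncol(X)
  if (!is.null(config$seed)) set.seed(config$seed)

  n_fits <- config$cv_repeats * config$cv_folds
  detection <- integer(m)
  r2_sum <- numeric(m)
  r2_cnt <- integer(m)
  fits_run <- 0
  for (rep_i in seq_len(config$cv_repeats)) {
    fold <- sample(rep_len(seq_len(config$cv_folds), n))
    for (f in seq_len(config$cv_folds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      fit <- stepwise_fit(y[train], X[train, , drop = FALSE],
                          config$p_enter, config$p_stay)
      sel <- attr(fit, "selected")
      fits_run <- fits_run + 1
      if (length(train) < 2 * (length(sel) + 1)) {
        message("fold skipped: ", length(train), " training lines for ",
                length(sel), " predictors")
        next
      }
      if (!length(sel)) next
      detection[sel] <- detection[sel] + 1L
      ## held-out semi-partial R2 per selected SNP
      y_tr <- y[train]; y_te <- y[test]
      D_full <- cbind(1, X[train, sel, drop = FALSE])
      T_full <- cbind(1, X[test, sel, drop = FALSE])
      beta_full <- qr.coef(qr(D_full), y_tr)
      sse_full <- sum((y_te - T_full %*% beta_full)^2)
      tss <- sum((y_te - mean(y_tr))^2)
      if (tss <= 0) next
      for (jj in seq_along(sel)) {
        Dr <- D_full[, -(jj + 1), drop = FALSE]
        Tr <- T_full[, -(jj + 1), drop = FALSE]
        beta_r <- qr.coef(qr(Dr), y_tr)
        sse_r <- sum((y_te - Tr %*% beta_r)^2)
        j <- sel[jj]
        r2_sum[j] <- r2_sum[j] + (sse_r - sse_full) / tss
        r2_cnt[j] <- r2_cnt[j] + 1L
      }
    }
  }
  final <- stepwise_fit(y, X, config$p_enter, config$p_stay)
  # Bonferroni-Holm against the genome-wide family of all tested SNPs
  final$p_adj <- p.adjust(final$p, method = "holm", n = max(m, nrow(final)))

  hi <- X >= 1.5; lo <- X <= 0.5
  effect <- vapply(seq_len(m), function(j) {
    nh <- sum(hi[, j]); nl <- sum(lo[, j])
    if (nh == 0 || nl == 0) return(NA_real_)
    sum(y[hi[, j]]) / nh - sum(y[lo[, j]]) / nl
  }, numeric(1))

  snps <- snp_order %>%
    mutate(
      detection = detection,
      detection_rate = 100 * detection / n_fits,
      r2_val = ifelse(r2_cnt > 0, 100 * r2_sum / pmax(r2_cnt, 1), NA_real_),
      effect = effect
    ) %>%
    dplyr::left_join(final, by = "snp") %>%
    dplyr::rename(p_final = "p")
  structure(
    list(snps = snps, n_fits = n_fits, n_lines = n,
         config = config, final_model = final),
    class = "gwas_scan"
  )
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat("<gwas_scan> ", nrow(x$snps), " SNPs, ", x$n_lines, " lines, ",
      x$n_fits, " CV fits; ", nrow(x$final_model),
      " SNPs in the full-data model\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gwas_scan <- function(x, ...) x$snps

#' @exportS3Method generics::glance
glance.gwas_scan <- function(x, ...) {
  tibble::tibble(n_snps = nrow(x$snps), n_lines = x$n_lines,
                 n_fits = x$n_fits,
                 n_final = nrow(x$final_model),
                 max_detection = max(x$snps$detection))
}

#' @exportS3Method ggplot2::autoplot
autoplot.gwas_scan <- function(object, ...) {
  ggplot2::ggplot(object$snps,
                  ggplot2::aes(.data$pos, .data$detection_rate)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::geom_hline(
      yintercept = object$config$detection_threshold * 100 / object$n_fits,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::facet_wrap(~chr, scales = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "detection rate (%)") +
    ggplot2::theme_minimal()
}

#' Call marker-trait associations and group them into QTL
#'
#' MTAs are SNPs detected in at least `detection_threshold` of the CV fits
#' with Bonferroni--Holm adjusted p below `mta_alpha` in the full-data
#' model. MTAs on the same chromosome within `qtl_window_cM` of each other
#' (single linkage) and with additive effects of the same sign are grouped
#' into one QTL, represented by the member with the smallest adjusted p.
#'
#' @param scan A `gwas_scan`.
#' @param config Optional [scan_config()]; defaults to the scan's own.
#' @return A tibble `qtl`, `snp`, `chr`, `pos`, `range_min`, `range_max`,
#'   `n_members`, `detection_rate`, `p_adj`, `effect`, `r2_val`, `members`
#'   (list column).
#' @export
call_qtl <- function(scan, config = scan$config) {
  mta <- scan$snps %>%
    filter(.data$detection >= config$detection_threshold,
           !is.na(.data$p_adj), .data$p_adj < config$mta_alpha,
           !is.na(.data$effect)) %>%
    arrange(.data$chr, .data$pos)
  if (!nrow(mta)) {
    return(tibble::tibble(qtl = character(0), snp = character(0),
                          chr = character(0), pos = numeric(0),
                          range_min = numeric(0), range_max = numeric(0),
                          n_members = integer(0), detection_rate = numeric(0),
                          p_adj = numeric(0), effect = numeric(0),
                          r2_val = numeric(0), members = list()))
  }
  mta <- mta %>%
    group_by(.data$chr) %>%
    mutate(.new = c(TRUE, diff(.data$pos) > config$qtl_window_cM |
                      sign(.data$effect[-1]) != sign(.data$effect[-dplyr::n()]))) %>%
    mutate(.grp = cumsum(.data$.new)) %>%
    ungroup()
  out <- mta %>%
    group_by(.data$chr, .data$.grp) %>%
    dplyr::group_modify(function(d, key) {
      rep_i <- which.min(d$p_adj)
      tibble::tibble(
        snp = d$snp[rep_i], pos = d$pos[rep_i],
        range_min = min(d$pos), range_max = max(d$pos),
        n_members = nrow(d),
        detection_rate = d$detection_rate[rep_i],
        p_adj = d$p_adj[rep_i], effect = d$effect[rep_i],
        r2_val = d$r2_val[rep_i], members = list(d$snp)
      )
    }) %>%
    ungroup() %>%
    arrange(.data$chr, .data$pos) %>%
    group_by(.data$chr) %>%
    mutate(.i = row_number(), .n = dplyr::n()) %>%
    ungroup() %>%
    mutate(qtl = ifelse(.data$.n > 1,
                        sprintf("Q.%s.%s", .data$chr, letters[.data$.i]),
                        sprintf("Q.%s", .data$chr))) %>%
    select("qtl", "snp", "chr", "pos", "range_min", "range_max",
           "n_members", "detection_rate", "p_adj", "effect", "r2_val",
           "members")
  out
}
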