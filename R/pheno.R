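#' Per-line trait means across years
#'
#' With one replicate per year and a balanced layout, the least-squares
#' genotype mean under fixed genotype / random year effects equals the
#' arithmetic mean over years, which is what is computed; replicates within
#' a year are averaged first, and lines missing a year use their available
#' years.
#'
#' @param pheno Tibble with columns `line`, `year`, `rep`, `value`.
#' @return A tibble `line`, `n_years`, `n_records`, `mean` (cm), ordered as
#'   first appearance in `pheno`.
#' @export
line_means <- function(pheno) {
  stopifnot(all(c("line", "year", "value") %in% names(pheno)))
  pheno %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$line, .data$year) %>%
    summarise(.yr_mean = mean(.data$value), .n = dplyr::n(),
              .groups = "drop_last") %>%
    summarise(n_years = dplyr::n(), n_records = sum(.data$.n),
              mean = mean(.data$.yr_mean), .groups = "drop") %>%
    dplyr::left_join(x = dplyr::distinct(pheno, .data$line), by = "line")
}

#' Variance components from the line x year layout
#'
#' Method-of-moments (expected mean squares) estimation on the two-way
#' classification. With replicates within year (`r >= 2`) the genotype,
#' genotype-x-year and residual components are separated; with a single
#' replicate per year the interaction and residual are confounded and a
#' pooled error component `V_E = V_GY + V_R` is estimated. Negative
#' solutions are truncated to zero with a warning.
#'
#' @param pheno Tibble with columns `line`, `year`, `rep`, `value`; at
#'   least two years are required.
#' @return An object of class `varcomp`: list with `V_G`, and either
#'   `V_GY` + `V_R` (`separate = TRUE`) or pooled `V_E`, plus `y` (years),
#'   `r` (replicates per year), `df_resid` and `ms_resid`.
#' @export
variance_components <- function(pheno) {
  stopifnot(all(c("line", "year", "value") %in% names(pheno)))
  pheno <- filter(pheno, !is.na(.data$value))
  y <- length(unique(pheno$year))
  if (y < 2) {
    stop("at least two years are required to estimate V_G", call. = FALSE)
  }
  counts <- pheno %>% dplyr::count(.data$line, .data$year)
  r <- mean(counts$n)
  pheno$line <- factor(pheno$line)
  pheno$year <- factor(pheno$year)
  n_lines <- nlevels(pheno$line)
  if (r >= 2) {
    fit <- aov(value ~ line + year + line:year, data = pheno)
    tab <- summary(fit)[[1]]
    ms <- setNames(tab[["Mean Sq"]], trimws(rownames(tab)))
    v_r <- ms[["Residuals"]]
    v_gy <- (ms[["line:year"]] - v_r) / r
    v_g <- (ms[["line"]] - ms[["line:year"]]) / (r * y)
    df_resid <- tab[["Df"]][[4]]
    comps <- list(V_G = v_g, V_GY = v_gy, V_R = v_r, separate = TRUE)
    ms_resid <- v_r
  } else {
    fit <- aov(value ~ line + year, data = pheno)
    tab <- summary(fit)[[1]]
    ms <- setNames(tab[["Mean Sq"]], trimws(rownames(tab)))
    v_e <- ms[["Residuals"]]
    v_g <- (ms[["line"]] - v_e) / y
    df_resid <- tab[["Df"]][[3]]
    comps <- list(V_G = v_g, V_E = v_e, separate = FALSE)
    ms_resid <- v_e
  }
  trunc <- vapply(comps[names(comps) != "separate"],
                  function(v) is.numeric(v) && v < 0, logical(1))
  if (any(trunc)) {
    warning("negative variance component estimate(s) truncated to 0: ",
            paste(names(trunc)[trunc], collapse = ", "), call. = FALSE)
    for (nm in names(trunc)[trunc]) comps[[nm]] <- 0
  }
  structure(
    c(comps, list(y = y, r = r, df_resid = df_resid, ms_resid = ms_resid,
                  n_lines = n_lines)),
    class = "varcomp"
  )
}

#' @export
print.varcomp <- function(x, ...) {
  cat("<varcomp> V_G =", signif(x$V_G, 4))
  if (isTRUE(x$separate)) {
    cat(", V_GY =", signif(x$V_GY, 4), ", V_R =", signif(x$V_R, 4))
  } else {
    cat(", V_E (pooled GY + residual) =", signif(x$V_E, 4))
  }
  cat("; y =", x$y, ", r =", round(x$r, 2),
      "; h2 =", signif(heritability(x), 3), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.varcomp <- function(x, ...) {
  if (isTRUE(x$separate)) {
    tibble::tibble(component = c("V_G", "V_GY", "V_R"),
                   estimate = c(x$V_G, x$V_GY, x$V_R))
  } else {
    tibble::tibble(component = c("V_G", "V_E"),
                   estimate = c(x$V_G, x$V_E))
  }
}

#' @exportS3Method generics::glance
glance.varcomp <- function(x, ...) {
  tibble::tibble(V_G = x$V_G,
                 V_GY = if (isTRUE(x$separate)) x$V_GY else NA_real_,
                 V_R = if (isTRUE(x$separate)) x$V_R else NA_real_,
                 V_E = if (isTRUE(x$separate)) x$V_GY + x$V_R else x$V_E,
                 y = x$y, r = x$r, h2 = heritability(x))
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \deqn{h^2 = V_G / (V_G + V_{GY}/y + V_R/(y r))}
#' When only a pooled error `V_E = V_GY + V_R` is available (single
#' replicate per year), the denominator uses `V_E / y`, which equals the
#' formula above at r = 1.
#'
#' @param x Either a `varcomp` object or the genotypic variance `V_G`.
#' @param V_GY,V_R,V_E Variance components (cm^2); supply either
#'   `V_GY` + `V_R` or pooled `V_E`.
#' @param y,r Number of years and replicates per year.
#' @param ... Unused.
#' @return Heritability in `[0, 1]`.
#' @export
#' @examples
#' heritability(9, V_GY = 1, V_R = 1, y = 2, r = 1)  # 0.9
heritability <- function(x, ...) UseMethod("heritability")

#' @rdname heritability
#' @export
heritability.varcomp <- function(x, ...) {
  if (isTRUE(x$separate)) {
    heritability(x$V_G, V_GY = x$V_GY, V_R = x$V_R, y = x$y, r = x$r)
  } else {
    heritability(x$V_G, V_E = x$V_E, y = x$y)
  }
}

#' @rdname heritability
#' @export
heritability.numeric <- function(x, V_GY = NULL, V_R = NULL, V_E = NULL,
                                 y = 2, r = 1, ...) {
  V_G <- x
  stopifnot(V_G >= 0)
  denom <- if (!is.null(V_E)) {
    V_G + V_E / y
  } else {
    V_G + (V_GY %||% 0) / y + (V_R %||% 0) / (y * r)
  }
  if (denom <= 0) {
    stop("all variance components are zero; heritability undefined",
         call. = FALSE)
  }
  V_G / denom
}

#' Count transgressive lines
#'
#' A line is transgressive-tall when its mean exceeds the largest founder
#' mean by more than the two-sided least significant difference computed
#' from the residual variance and the record counts behind the two means;
#' symmetrically for transgressive-short lines.
#'
#' @param lines Line means tibble from [line_means()] (MAGIC lines only).
#' @param founders Line means tibble for the founders.
#' @param vc A `varcomp` object supplying the error variance and residual
#'   degrees of freedom.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A one-row tibble `n_taller`, `n_shorter`, `lsd_tall`,
#'   `lsd_short`.
#' @export
transgressive_count <- function(lines, founders, vc, alpha = 0.05) {
  if (!nrow(founders) || anyNA(founders$mean)) {
    stop("founder means are missing", call. = FALSE)
  }
  v_err <- if (isTRUE(vc$separate)) vc$V_GY / vc$y + vc$V_R / (vc$y * vc$r) else vc$V_E / vc$y
  tcrit <- qt(1 - alpha / 2, vc$df_resid)
  i_max <- which.max(founders$mean)
  i_min <- which.min(founders$mean)
  # per-comparison LSD using the mean record count of the MAGIC lines
  n_bar <- mean(lines$n_years)
  lsd <- function(n_f) {
    tcrit * sqrt(v_err * vc$y * (1 / (n_bar) + 1 / n_f))
  }
  lsd_tall <- lsd(founders$n_years[i_max])
  lsd_short <- lsd(founders$n_years[i_min])
  tibble::tibble(
    n_taller = sum(lines$mean > founders$mean[i_max] + lsd_tall),
    n_shorter = sum(lines$mean < founders$mean[i_min] - lsd_short),
    lsd_tall = lsd_tall, lsd_short = lsd_short
  )
}
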