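# Founder haplotype mosaics and meiosis.
#
# A haplotype is represented per chromosome as an ordered run-length list:
# list(end = numeric vector of segment end positions (cM, strictly
# increasing, last element = chromosome length), founder = integer vector of
# founder indices). Segment j covers (end[j-1], end[j]] with an implicit
# start at 0. A whole-genome haplotype is a named list of these, one per
# chromosome; a plant/line is a list of two whole-genome haplotypes.

new_haplotype <- function(chr_lengths, founder) {
  lapply(chr_lengths, function(L) list(end = L, founder = as.integer(founder)))
}

#' Build a fully inbred founder individual
#'
#' @param founder Integer founder index (1--8).
#' @param chr_lengths Named numeric vector of chromosome lengths (cM).
#' @return A list of two identical whole-genome haplotypes.
#' @export
founder_individual <- function(founder, chr_lengths) {
  h <- new_haplotype(chr_lengths, founder)
  list(h, h)
}

# extract the piece of haplotype h covering (from, to]
hap_slice <- function(h, from, to) {
  end <- h$end
  n <- length(end)
  j1 <- findInterval(from, end) + 1L          # first segment with end > from
  j2 <- findInterval(to, end, left.open = TRUE) + 1L  # first with end >= to
  if (j1 > n) j1 <- n
  if (j2 > n) j2 <- n
  ends <- end[j1:j2]
  ends[length(ends)] <- to
  list(end = ends, founder = h$founder[j1:j2])
}

merge_runs <- function(end, founder) {
  n <- length(founder)
  if (n <= 1) return(list(end = end, founder = founder))
  keep <- c(founder[-n] != founder[-1], TRUE)
  list(end = end[keep], founder = founder[keep])
}

# one gamete for one chromosome with nx crossovers and a given starting
# chromatid (Haldane: breakpoints uniform, chromatids alternate)
meiosis_chr <- function(a, b, L, nx, start_a) {
  if (nx == 0) {
    return(if (start_a) a else b)
  }
  bounds <- c(0, sort(runif(nx, 0, L)), L)
  use_a <- start_a
  ends <- vector("list", length(bounds) - 1L)
  fnds <- vector("list", length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    src <- if (use_a) a else b
    piece <- hap_slice(src, bounds[i], bounds[i + 1L])
    ends[[i]] <- piece$end
    fnds[[i]] <- piece$founder
    use_a <- !use_a
  }
  merge_runs(unlist(ends), unlist(fnds))
}

#' Simulate one meiosis
#'
#' Produces a single gamete from a parent individual. Crossover counts per
#' chromosome are Poisson with mean length/100 (Haldane map function, no
#' interference); breakpoint positions are uniform; the starting chromatid
#' is chosen with probability 1/2 and chromatids alternate at breakpoints.
#'
#' @param parent A list of two whole-genome haplotypes covering the same
#'   chromosomes (e.g. from [founder_individual()] or [sim_population()]).
#' @param chr_lengths Named numeric vector of chromosome lengths in cM; must
#'   name the same chromosomes as the parent haplotypes.
#' @return A whole-genome haplotype (the gamete).
#' @export
simulate_meiosis <- function(parent, chr_lengths) {
  h1 <- parent[[1]]; h2 <- parent[[2]]
  if (!identical(names(h1), names(chr_lengths)) ||
      !identical(names(h2), names(chr_lengths))) {
    stop("parent haplotypes and chromosome lengths cover different chromosomes",
         call. = FALSE)
  }
  nchr <- length(chr_lengths)
  nx <- rpois(nchr, pmax(chr_lengths, 0) / 100)
  start_a <- runif(nchr) < 0.5
  out <- vector("list", nchr)
  names(out) <- names(chr_lengths)
  for (i in seq_len(nchr)) {
    out[[i]] <- if (nx[i] == 0L) {
      if (start_a[i]) h1[[i]] else h2[[i]]
    } else {
      meiosis_chr(h1[[i]], h2[[i]], chr_lengths[[i]], nx[i], start_a[i])
    }
  }
  out
}

# founder origin of haplotype h at positions pos (vectorised)
origins_at <- function(h, pos) {
  i <- findInterval(pos, h$end) + 1L
  n <- length(h$end)
  i[i > n] <- n
  h$founder[i]
}

# check that a haplotype tiles [0, L] exactly
hap_covers <- function(h, L) {
  length(h$end) >= 1 &&
    all(diff(c(0, h$end)) > 0 | (L == 0 & h$end == 0)) &&
    isTRUE(all.equal(h$end[length(h$end)], L))
}

#' Genome share of each founder in an individual
#'
#' @param ind A list of two whole-genome haplotypes.
#' @param n_founders Number of founders (default 8).
#' @return Numeric vector of length `n_founders` summing to 1.
#' @export
genome_shares <- function(ind, n_founders = 8) {
  tot <- 0
  acc <- numeric(n_founders)
  for (h in ind) {
    for (ch in h) {
      lens <- diff(c(0, ch$end))
      acc <- acc + vapply(seq_len(n_founders), function(f) {
        sum(lens[ch$founder == f])
      }, numeric(1))
      tot <- tot + sum(lens)
    }
  }
  acc / tot
}
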