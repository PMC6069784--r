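# CSV dialects shared by the simulator and the analysis functions:
# genotype matrix (first column `line`, then one column per SNP, values
# 0/1/2/NA), map (snp,chr,pos), founder alleles (founder + one column per
# SNP, 0/1 carriage of the reference allele), phenotype (line,year,rep,
# value), pedigree (line,family,...).

#' Write a simulated data set to CSV files
#'
#' @param dir Output directory (created if needed).
#' @param geno Lines x SNPs dosage matrix (optional).
#' @param map Genetic map tibble (optional).
#' @param panel `founder_panel` (optional).
#' @param pheno Phenotype tibble (optional).
#' @param pedigree Pedigree tibble (optional).
#' @return `dir`, invisibly.
#' @export
write_magic_csv <- function(dir, geno = NULL, map = NULL, panel = NULL,
                            pheno = NULL, pedigree = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(geno)) {
    readr::write_csv(
      dplyr::bind_cols(tibble::tibble(line = rownames(geno)),
                       tibble::as_tibble(geno)),
      file.path(dir, "genotypes.csv")
    )
  }
  if (!is.null(map)) readr::write_csv(map, file.path(dir, "map.csv"))
  if (!is.null(panel)) {
    readr::write_csv(
      dplyr::bind_cols(tibble::tibble(founder = rownames(panel$alleles)),
                       tibble::as_tibble(panel$alleles)),
      file.path(dir, "founder_alleles.csv")
    )
  }
  if (!is.null(pheno)) readr::write_csv(pheno, file.path(dir, "phenotypes.csv"))
  if (!is.null(pedigree)) {
    readr::write_csv(pedigree, file.path(dir, "pedigree.csv"))
  }
  invisible(dir)
}

#' Read a genotype matrix from CSV
#'
#' @param path CSV with a `line` column followed by one column per SNP.
#' @return Lines x SNPs numeric matrix with dimnames.
#' @export
read_geno_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1]])
  m
}

#' Read a genetic map from CSV
#'
#' @param path CSV with columns `snp`, `chr`, `pos`.
#' @return A map tibble sorted by chromosome and position.
#' @export
read_map_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(snp = "c", chr = "c", pos = "d")) %>%
    arrange(.data$chr, .data$pos)
}

#' Read a phenotype table from CSV
#'
#' @param path CSV with columns `line`, `year`, `rep`, `value`.
#' @return A tibble.
#' @export
read_pheno_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
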