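# Containers and plain-text I/O: genotype matrices (VCF / TSV dosage),
# long-format phenotype tables.

#' Construct a genotype matrix container
#'
#' @param dosage accessions x SNPs integer matrix in \{0, 1, 2, NA\}
#'   (NA = missing call), with accession rownames and SNP colnames.
#' @param map data.frame with columns `snp`, `chrom`, `pos` (1-based bp)
#'   and optionally `subgenome`; must be sorted by (chrom, pos) with
#'   positions unique within a chromosome.
#' @param chrom_length_bp optional chromosome length (scalar or named by
#'   chromosome) used for interval clipping and window construction.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, map, chrom_length_bp = NULL) {
  stopifnot(is.matrix(dosage), is.data.frame(map),
            all(c("snp", "chrom", "pos") %in% names(map)),
            ncol(dosage) == nrow(map))
  ok_vals <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok_vals)) stop("dosage values must be 0, 1, 2 or NA")
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    map <- map[ord, , drop = FALSE]
    dosage <- dosage[, ord, drop = FALSE]
  }
  if (anyDuplicated(map[c("chrom", "pos")]))
    stop("positions must be unique within a chromosome")
  if (is.null(colnames(dosage))) colnames(dosage) <- map$snp
  if (!("subgenome" %in% names(map)))
    map$subgenome <- substr(map$chrom, 1, 1)
  rownames(map) <- NULL
  structure(list(dosage = dosage, map = map,
                 chrom_length_bp = chrom_length_bp),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "accessions x",
      ncol(x$dosage), "SNPs on", length(unique(x$map$chrom)),
      "chromosome(s);",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# subset SNP columns, keeping map in step
subset_snps <- function(g, keep) {
  genotype_matrix(g$dosage[, keep, drop = FALSE],
                  g$map[keep, , drop = FALSE],
                  chrom_length_bp = g$chrom_length_bp)
}

#' Write genotypes as minimal VCFv4.2
#'
#' Emits only the GT FORMAT field (`0/0`, `0/1`, `1/1`, `./.`), 1-based
#' positions, REF `A` / ALT `T` placeholders (alleles are not modelled).
#'
#' @param g a `genotype_matrix`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=saltpanel",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(g$dosage)),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosage))) {
    d <- g$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(g$map$chrom[j], g$map$pos[j], g$map$snp[j],
                       "A", "T", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF of biallelic SNPs into a genotype matrix
#'
#' Parses the GT field via the vcfR package (other fields are ignored);
#' phased or unphased diploid calls are counted as alt-allele dosage.
#'
#' @param path VCF file (optionally gzipped).
#' @param chrom_length_bp passed to [genotype_matrix()].
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path, chrom_length_bp = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt_clean <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt_clean %in% c("0/0")] <- 0L
  dos[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos[gt_clean %in% c("1/1")] <- 2L
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  if (anyNA(ids)) ids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  map <- data.frame(snp = ids, chrom = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]),
                    stringsAsFactors = FALSE)
  genotype_matrix(t(dos), map, chrom_length_bp = chrom_length_bp)
}

#' Write / read a dosage TSV with its SNP map
#'
#' `write_dosage_tsv` writes two tab-separated files: `<path>` holding the
#' accession x SNP dosage matrix (missing as NA) and `<path>.map` holding
#' the SNP map. `read_dosage_tsv` reads them back.
#'
#' @param g a `genotype_matrix`.
#' @param path output TSV path.
#' @return the path (write) or a `genotype_matrix` (read), invisibly for
#'   the writer.
#' @export
write_dosage_tsv <- function(g, path) {
  df <- data.frame(accession = rownames(g$dosage), g$dosage,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(g$map, paste0(path, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  map <- read.delim(paste0(path, ".map"))
  dos <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(dos) <- "integer"
  rownames(dos) <- df$accession
  genotype_matrix(dos, map)
}

#' Write / read a long-format phenotype CSV
#'
#' The canonical dialect has header `accession,year,rep,treatment,trait,value`
#' with treatment in \{control, salt\}.
#'
#' @param pheno a phenotype table (data.frame in the long dialect).
#' @param path CSV path.
#' @export
write_phenotypes_csv <- function(pheno, path) {
  stopifnot(all(c("accession", "year", "rep", "treatment", "trait",
                  "value") %in% names(pheno)))
  write.csv(as.data.frame(pheno)[, c("accession", "year", "rep",
                                     "treatment", "trait", "value")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_csv
#' @export
read_phenotypes_csv <- function(path) {
  pheno <- read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(year = "character", rep = "character"))
  need <- c("accession", "year", "rep", "treatment", "trait", "value")
  if (!all(need %in% names(pheno)))
    stop("phenotype CSV must have columns ", paste(need, collapse = ", "))
  bad <- pheno$treatment == "control" & !(pheno$value > 0)
  if (any(bad)) stop("control measurements must be positive")
  class(pheno) <- c("phenotype_table", "data.frame")
  pheno
}
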