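#' Subset a genotype matrix to a set of individuals
#' @param genotypes A `genotype_matrix`.
#' @param ids Individual ids to keep (order preserved as given).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(genotypes, ids) {
  pos <- match(ids, genotypes$individual_ids)
  if (anyNA(pos)) stop("unknown individual ids: ",
                       paste(utils::head(ids[is.na(pos)]), collapse = ", "))
  out <- genotypes
  out$individual_ids <- genotypes$individual_ids[pos]
  out$dosages <- genotypes$dosages[pos, , drop = FALSE]
  out
}

#' Write genotype dosages to a VCF file
#'
#' Emits a minimal VCF v4.2 with one sample per individual and a `DS`
#' (dosage) FORMAT field; the ALT allele is the effect allele so the dosage
#' counts effect alleles. Dosages are written with 6 decimal digits.
#' @param genotypes A `genotype_matrix`.
#' @param path Output path (plain text `.vcf`).
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  m <- length(genotypes$variant_ids)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT (effect) allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$individual_ids), collapse = "\t")
  )
  ds <- apply(genotypes$dosages, 2, function(col) {
    paste(formatC(col, digits = 6, format = "f"), collapse = "\t")
  })
  body <- paste("1", seq_len(m), genotypes$variant_ids,
                genotypes$other_alleles, genotypes$effect_alleles,
                ".", "PASS", ".", "DS", ds, sep = "\t")
  writeLines(c(hdr, body), path)
}

#' Read genotype dosages from a VCF written by [write_genotypes_vcf()]
#' @param path VCF path.
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  samples <- strsplit(lines[hdr_i], "\t")[[1]][-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  parts <- strsplit(body, "\t")
  var_ids <- vapply(parts, `[[`, "", 3)
  ref <- vapply(parts, `[[`, "", 4)
  alt <- vapply(parts, `[[`, "", 5)
  dos <- matrix(vapply(parts, function(p) as.numeric(p[-(1:9)]),
                       numeric(length(samples))),
                nrow = length(samples), ncol = length(var_ids))
  dimnames(dos) <- list(samples, var_ids)
  structure(
    list(individual_ids = samples, variant_ids = var_ids, dosages = dos,
         effect_alleles = alt, other_alleles = ref, maf = colMeans(dos) / 2),
    class = "genotype_matrix"
  )
}

#' Write / read genotype dosages as TSV
#'
#' Individuals x variants table with an `individual_id` first column; effect
#' and other alleles are stored in two comment lines (`#effect_alleles`,
#' `#other_alleles`) so the round trip is lossless.
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#effect_alleles", genotypes$effect_alleles),
                   collapse = "\t"), con)
  writeLines(paste(c("#other_alleles", genotypes$other_alleles),
                   collapse = "\t"), con)
  df <- data.frame(individual_id = genotypes$individual_ids,
                   round(genotypes$dosages, 6), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  lines <- readLines(path, n = 2)
  eff <- strsplit(lines[1], "\t")[[1]][-1]
  oth <- strsplit(lines[2], "\t")[[1]][-1]
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2,
                          check.names = FALSE, stringsAsFactors = FALSE)
  dos <- as.matrix(df[, -1, drop = FALSE])
  rownames(dos) <- df$individual_id
  structure(
    list(individual_ids = df$individual_id, variant_ids = colnames(dos),
         dosages = dos, effect_alleles = eff, other_alleles = oth,
         maf = colMeans(dos) / 2),
    class = "genotype_matrix"
  )
}

#' Write / read a variant-weight scoring file
#'
#' Tab-separated with header `variant_id, effect_allele, weight, gwas_p`;
#' numeric columns carry full precision (round trip lossless at 6+ digits).
#' @param weights Weight data.frame.
#' @param path File path.
#' @export
write_weights_tsv <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
}

#' @rdname write_weights_tsv
#' @export
read_weights_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write / read a cohort table as CSV
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
}
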