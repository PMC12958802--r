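# Plain-text writers/readers for simulated datasets, with the generating
# seed recorded in a sidecar metadata file.

write_sidecar <- function(path, seed, what) {
  meta <- c(sprintf("file: %s", basename(path)),
            sprintf("content: %s", what),
            sprintf("seed: %s", seed),
            sprintf("written: %s", format(Sys.time(), "%Y-%m-%d")))
  writeLines(meta, paste0(path, ".meta"))
}

#' Write a genotype matrix as a tab-separated table
#'
#' @param G A `geno_matrix`.
#' @param path Output file.
#' @param seed Generating seed recorded in the `.meta` sidecar.
#' @export
write_genotypes <- function(G, path, seed = NA) {
  stopifnot(inherits(G, "geno_matrix"))
  utils::write.table(G$calls, path, sep = "\t", quote = FALSE, col.names = NA)
  write_sidecar(path, seed, "genotype calls (individuals x loci)")
  invisible(path)
}

#' Read a genotype matrix written by [write_genotypes()]
#' @param path Input file.
#' @return A `geno_matrix`.
#' @export
read_genotypes <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  geno_matrix(m)
}

#' Write genotypes as a minimal VCF with GT fields
#'
#' Emits an uncompressed VCFv4.2 with one record per locus on a synthetic
#' single-contig layout and unphased diploid GT calls (0/0, 0/1, 1/1).
#'
#' @param G A `geno_matrix` (calls in {0,1,2} counted as ALT dosage).
#' @param path Output file.
#' @export
write_vcf <- function(G, path) {
  stopifnot(inherits(G, "geno_matrix"))
  calls <- t(G$calls)  # loci x individuals
  gt <- matrix(c("0/0", "0/1", "1/1")[calls + 1L], nrow(calls), ncol(calls))
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=chrS,length=100000000>",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(G$calls)), collapse = "\t"))
  body <- paste("chrS", seq_len(nrow(calls)) * 100L, rownames(calls), "A", "T",
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a phenotype table as CSV
#' @param table A `pheno_table`.
#' @param path Output file.
#' @param seed Seed recorded in the sidecar.
#' @export
write_phenotypes <- function(table, path, seed = attr(table, "seed") %||% NA) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  write_sidecar(path, seed, "phenotype records (hybrid, site-year, yield bu/ac)")
  invisible(path)
}

#' Write soil covariates as CSV
#' @param trial A `trial_design`.
#' @param path Output file.
#' @param seed Seed recorded in the sidecar.
#' @export
write_soil <- function(trial, path, seed = NA) {
  utils::write.csv(data.frame(site = rownames(trial$soil), trial$soil,
                              check.names = FALSE), path, row.names = FALSE)
  write_sidecar(path, seed, "site-level soil covariates")
  invisible(path)
}

#' Write weather series as a long-format CSV
#'
#' Columns: `site_year`, `variable`, `day`, `value`.
#'
#' @param trial A `trial_design`.
#' @param path Output file.
#' @param seed Seed recorded in the sidecar.
#' @export
write_weather <- function(trial, path, seed = NA) {
  rows <- do.call(rbind, lapply(names(trial$weather), function(sy) {
    W <- trial$weather[[sy]]
    data.frame(site_year = sy,
               variable = rep(rownames(W), each = ncol(W)),
               day = rep(as.integer(colnames(W)), times = nrow(W)),
               value = as.vector(t(W)))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  write_sidecar(path, seed, "daily weather series (long format)")
  invisible(path)
}

#' Write a selected-SNP list as two-column TSV
#' @param selection A `gwas_selection`.
#' @param path Output file.
#' @export
write_selection <- function(selection, path) {
  stopifnot(inherits(selection, "gwas_selection"))
  df <- data.frame(locus_id = selection$selected,
                   combined_p = selection$combined_p[selection$selected])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a kernel as a labeled square CSV
#' @param K A `kernel_matrix`.
#' @param path Output file.
#' @export
write_kernel <- function(K, path) {
  utils::write.csv(as.data.frame(unclass(K)), path, row.names = TRUE)
  invisible(path)
}
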