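#' Write a simulated cohort to plain-text files
#'
#' Internal coordinates are 0-based half-open throughout the package; the VCF
#' writer converts to 1-based positions on output and [read_vcf_dosage()]
#' converts back on read.
#'
#' Files written: `dosage.tsv` (variants x samples), `genotypes.vcf` (GT:DS),
#' `expression.tsv` (genes x samples), `genes.bed` (BED6, TSS as a 1-bp
#' interval), `contacts.tsv` (chrom_a, bin_a, chrom_b, bin_b, freq),
#' `gwas.tsv`, `truth_effects.tsv`, `truth_hotspots.tsv`.
#'
#' @param cohort A `trans_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "trans_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    dosage = file.path(dir, "dosage.tsv"),
    vcf = file.path(dir, "genotypes.vcf"),
    expression = file.path(dir, "expression.tsv"),
    genes = file.path(dir, "genes.bed"),
    contacts = file.path(dir, "contacts.tsv"),
    gwas = file.path(dir, "gwas.tsv"),
    effects = file.path(dir, "truth_effects.tsv"),
    hotspots = file.path(dir, "truth_hotspots.tsv")
  )
  write_dosage_tsv(cohort$genotypes, paths["dosage"])
  write_vcf(cohort$genotypes, paths["vcf"])
  write_expression_tsv(cohort$expression, paths["expression"])
  write_genes_bed(cohort$expression$genes, paths["genes"])
  readr::write_tsv(as_tibble(cohort$contacts), paths["contacts"])
  readr::write_tsv(as_tibble(cohort$gwas), paths["gwas"])
  readr::write_tsv(cohort$truth$effects, paths["effects"])
  readr::write_tsv(tibble(variant_id = cohort$truth$hotspot_variants),
                   paths["hotspots"])
  invisible(paths)
}

write_dosage_tsv <- function(genotypes, path) {
  tab <- as_tibble(t(genotypes$dosage), rownames = "variant_id")
  readr::write_tsv(dplyr::bind_cols(genotypes$variants[, c("variant_id", "chrom", "pos")],
                                    tab[, -1]), path)
}

write_expression_tsv <- function(expr, path) {
  readr::write_tsv(as_tibble(expr$values, rownames = "gene_id"), path)
}

#' @rdname write_cohort
#' @param genotypes A `genotype_matrix`.
#' @param path Output file.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes$dosage)), collapse = "\t")
  ), con)
  body <- vapply(seq_len(nrow(v)), function(j) {
    ds <- genotypes$dosage[, j]
    cells <- paste0(gt_codes[round(pmin(pmax(ds, 0), 2)) + 1L], ":",
                    format(ds, trim = TRUE))
    paste(c(v$chrom[j], v$pos[j] + 1L, v$variant_id[j], v$ref[j], v$alt[j],
            ".", "PASS", ".", "GT:DS", cells), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

write_genes_bed <- function(genes, path) {
  bed <- tibble(
    chrom = genes$chrom, start = genes$tss, end = genes$tss + 1L,
    name = genes$gene_id, score = 0L, strand = genes$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
}

#' Read a dosage TSV written by [write_cohort()]
#'
#' @param path File with columns `variant_id`, `chrom`, `pos` then one column
#'   per sample.
#' @return A `genotype_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  variants <- tab[, c("variant_id", "chrom", "pos")]
  m <- t(as.matrix(tab[, -(1:3)]))
  colnames(m) <- variants$variant_id
  genotype_matrix(m, variants)
}

#' Read dosages from a VCF with a DS FORMAT field
#'
#' Positions are converted to the package's internal 0-based convention.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @return A `genotype_matrix`.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  variants <- tibble(
    variant_id = fix$ID,
    chrom = as.integer(fix$CHROM),
    pos = as.integer(fix$POS) - 1L,
    ref = fix$REF, alt = fix$ALT
  )
  m <- t(ds)
  colnames(m) <- variants$variant_id
  genotype_matrix(m, variants)
}

#' Read a genes-by-samples expression TSV
#'
#' @param path File with a `gene_id` column then one column per sample.
#' @param genes Tibble of gene coordinates (`gene_id`, `chrom`, `tss`,
#'   `strand`), e.g. from [read_genes_bed()].
#' @return An `expression_matrix`.
#' @export
read_expression_tsv <- function(path, genes) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$gene_id
  genes <- genes[match(tab$gene_id, genes$gene_id), ]
  expression_matrix(m, genes)
}

#' Read gene coordinates from a BED6 file (TSS intervals)
#'
#' @param path BED6 file; the interval start is the TSS (0-based).
#' @return Tibble `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_genes_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         show_col_types = FALSE)
  tibble(gene_id = bed$name, chrom = bed$chrom, tss = bed$start,
         strand = bed$strand)
}

#' Read a 5-column contact TSV
#'
#' @param path File with columns `chrom_a`, `bin_a`, `chrom_b`, `bin_b`,
#'   `freq`.
#' @param resolution_bp Bin size of the matrix.
#' @return A `contact_matrix`.
#' @export
read_contacts_tsv <- function(path, resolution_bp) {
  contact_matrix(readr::read_tsv(path, show_col_types = FALSE), resolution_bp)
}

#' Read GWAS summary statistics from TSV
#'
#' @param path File with columns `variant_id`, `chrom`, `pos`, `beta`, `se`,
#'   `p`, `n`.
#' @param trait Trait label attached to the result.
#' @return A `gwas_summary` tibble.
#' @export
read_gwas_tsv <- function(path, trait = "trait") {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  structure(tab, class = c("gwas_summary", class(tibble())), trait = trait)
}
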