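#' Per-gene annotation table
#'
#' Holds the gene-level facts the pipeline needs: chromosome (for the X/Y
#' ratio statistics), biotype (protein_coding / miRNA / other, for the coding
#' filter), mitochondrial flag (for the mito-fraction filter), exonic length
#' in bp (for FPKM) and whether the gene is chrX-unique, i.e. on chrX with no
#' chrY homolog (for the X-Ratio numerator).
#'
#' @param symbol,chromosome,biotype,is_mitochondrial,exonic_length_bp,is_chrX_unique
#'   equal-length per-gene vectors; `biotype` must be one of
#'   `"protein_coding"`, `"miRNA"`, `"other"`.
#' @return A `data.frame` of class `gene_annotation`, one row per gene.
#' @export
gene_annotation <- function(symbol, chromosome, biotype,
                            is_mitochondrial = chromosome == "chrM",
                            exonic_length_bp = 1000L,
                            is_chrX_unique = FALSE) {
  n <- length(symbol)
  ann <- data.frame(
    symbol = as.character(symbol),
    chromosome = as.character(chromosome),
    biotype = as.character(biotype),
    is_mitochondrial = rep_len(as.logical(is_mitochondrial), n),
    exonic_length_bp = rep_len(as.integer(exonic_length_bp), n),
    is_chrX_unique = rep_len(as.logical(is_chrX_unique), n),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(unique(ann$biotype), c("protein_coding", "miRNA", "other"))
  if (length(bad)) {
    stop_format("unknown biotype(s): %s (allowed: protein_coding, miRNA, other)",
                paste(bad, collapse = ", "))
  }
  if (anyDuplicated(ann$symbol)) stop_format("duplicate gene symbols in annotation")
  if (any(is.na(ann$exonic_length_bp)) || any(ann$exonic_length_bp < 1L)) {
    stop_format("exonic_length_bp must be a positive integer for every gene")
  }
  if (any(ann$is_chrX_unique & ann$chromosome != "chrX")) {
    stop_format("is_chrX_unique genes must be on chrX: %s",
                paste(ann$symbol[ann$is_chrX_unique & ann$chromosome != "chrX"],
                      collapse = ", "))
  }
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

#' Read a gene annotation TSV
#'
#' Expects a tab-separated file with a header and columns `symbol`,
#' `chromosome`, `biotype`, `is_mitochondrial`, `exonic_length_bp`,
#' `is_chrX_unique` (booleans as true/false).
#'
#' @param path path to the TSV file.
#' @return A [gene_annotation()] table.
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("symbol", "chromosome", "biotype", "is_mitochondrial",
            "exonic_length_bp", "is_chrX_unique")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_format("annotation file missing column(s): %s", paste(miss, collapse = ", "))
  }
  gene_annotation(tab$symbol, tab$chromosome, tab$biotype,
                  is_mitochondrial = .as_bool(tab$is_mitochondrial),
                  exonic_length_bp = tab$exonic_length_bp,
                  is_chrX_unique = .as_bool(tab$is_chrX_unique))
}

.as_bool <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Write a gene annotation table to TSV
#' @param ann a [gene_annotation()] table.
#' @param path output path.
#' @export
write_gene_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a one-symbol-per-line gene list
#'
#' Blank lines and lines starting with `#` are skipped; duplicates are
#' removed, keeping the first occurrence.
#'
#' @param path path to the text file.
#' @return Character vector of unique symbols in file order.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Per-sample metadata table
#'
#' @param sample_id unique sample identifiers.
#' @param species one of `"human"`, `"mouse"`, `"other"` per sample.
#' @param organ organ per sample.
#' @param declared_sex one of `"male"`, `"female"`, `"mixed"`, `"unknown"`.
#' @return A `data.frame` of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, species = "other", organ = "unknown",
                            declared_sex = "unknown") {
  n <- length(sample_id)
  md <- data.frame(sample_id = as.character(sample_id),
                   species = rep_len(as.character(species), n),
                   organ = rep_len(as.character(organ), n),
                   declared_sex = rep_len(as.character(declared_sex), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(md$sample_id)) stop_format("duplicate sample ids")
  bad <- setdiff(unique(md$declared_sex), c("male", "female", "mixed", "unknown"))
  if (length(bad)) {
    stop_format("declared_sex must be male/female/mixed/unknown, got: %s",
                paste(bad, collapse = ", "))
  }
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' Read a sample metadata TSV (columns sample_id, species, organ, declared_sex)
#' @param path path to the TSV file.
#' @return A [sample_metadata()] table.
#' @export
read_sample_metadata <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "species", "organ", "declared_sex")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_format("sample metadata missing column(s): %s", paste(miss, collapse = ", "))
  }
  sample_metadata(tab$sample_id, tab$species, tab$organ, tab$declared_sex)
}
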