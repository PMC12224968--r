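# Shared fixtures, built in code. The default synthetic corpus is expensive
# enough to cache per test run.

.fixture_cache <- new.env(parent = emptyenv())

default_corpus <- function(seed = 1) {
  key <- paste0("corpus", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_corpus(sim_config(seed = seed))
  }
  .fixture_cache[[key]]
}

default_clean <- function(seed = 1) {
  key <- paste0("clean", seed)
  if (is.null(.fixture_cache[[key]])) {
    corp <- default_corpus(seed)
    .fixture_cache[[key]] <- run_qc(corp$matrix, corp$annotation)$matrix
  }
  .fixture_cache[[key]]
}

# Small dense cell_matrix from a plain matrix.
make_cm <- function(counts, samples = "s1", organs = NULL, species = "human") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell%02d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("g%02d", seq_len(ncol(counts)))
  }
  cell_matrix(counts, sample_of_cell = rep_len(samples, nrow(counts)),
              organ_of_cell = if (is.null(organs)) NULL
                              else rep_len(organs, nrow(counts)),
              species = species)
}

# Annotation covering gene symbols with simple defaults.
make_ann <- function(symbols, chromosome = "chr1", biotype = "protein_coding",
                     mito = FALSE, length_bp = 1000, chrx_unique = FALSE) {
  gene_annotation(symbols, rep_len(chromosome, length(symbols)),
                  rep_len(biotype, length(symbols)),
                  is_mitochondrial = rep_len(mito, length(symbols)),
                  exonic_length_bp = rep_len(length_bp, length(symbols)),
                  is_chrX_unique = rep_len(chrx_unique, length(symbols)))
}
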