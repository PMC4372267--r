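#  Shared fixtures for the test suite. Everything is generated in code; the
#  small_config genome keeps routine tests fast, while acceptance checks on
#  the reference conditions use sim_config() defaults.

small_config <- function(seed = 7L, ...) {
  defaults <- list(seed = seed, n_chroms = 2L, chrom_length = 2e6,
                   segment_width = 2e5, genes_per_chrom = 100L,
                   n_new_intragenic_peaks = 4L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

#  tiny null genome for replicate-based checks (no planted peaks needed)
null_config <- function(seed) {
  zero_effect_config(seed = seed, n_chroms = 1L, chrom_length = 2e6,
                     segment_width = 2e5, genes_per_chrom = 60L,
                     n_new_intragenic_peaks = 0L)
}

#  a cached default-condition bundle (no FASTA) shared by tests that only
#  need tracks/expression/peaks; built once per test run
default_bundle_nofasta <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_bundle(sim_config(seed = 11L),
                                components = c("sites", "expression",
                                               "peaks", "luma", "truth"))
    cache
  }
})

#  tiny deterministic gene model: one "+" gene with 3 exons, one "-" gene
toy_models <- function() {
  genes <- data.frame(gene_id = c("gA", "gB"),
                      chrom = c("chr1", "chr1"),
                      strand = c("+", "-"),
                      biotype = c("coding", "lncRNA"),
                      stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    chrom = "chr1",
    start = c(1000L, 2000L, 3000L, 9000L, 9800L),
    end = c(1200L, 2300L, 3400L, 9500L, 10000L),
    stringsAsFactors = FALSE)
  gene_models(genes, exons)
}
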