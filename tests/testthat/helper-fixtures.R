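# small in-code fixtures shared across test files

tiny_matrix <- function(kind = "methylation_beta", nf = 3, ns = 2, seed = 42) {
  set.seed(seed)
  v <- if (kind == "methylation_beta")
    matrix(runif(nf * ns), nf, ns)
  else matrix(rnorm(nf * ns, 5), nf, ns)
  dimnames(v) <- list(paste0("f", seq_len(nf)), paste0("s", seq_len(ns)))
  omics_matrix(v, kind)
}

write_tsv_matrix <- function(x, path = tempfile(fileext = ".tsv")) {
  write_matrix(x, path)
  path
}

# simple annotation covering probes p* and genes g* laid out on one chromosome
toy_annotation <- function() {
  data.frame(
    feature_id = c("p1", "p2", "p3", "g1", "g2", "g3"),
    chrom = c("chr1", "chr1", "chr2", "chr1", "chr1", "chr2"),
    position = c(100000L, 2000000L, 500000L, 110000L, 2500000L, 400000L),
    nearest_gene = c("g1", "", "", "", "", ""),
    stringsAsFactors = FALSE)
}

# cohort small enough for fast tests but with enough samples for model fits
small_cohort <- function(seed = 9, n = 120, ...) {
  simulate_cohort(simulation_config(
    n_samples = n, n_probes = 40, n_genes = 40, n_m2eqtl = 8,
    n_prognostic_genes = 5, seed = seed, ...))
}
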