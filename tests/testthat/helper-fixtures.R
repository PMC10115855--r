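# Fixtures built in code: small random expression matrices and reduced
# synthetic study configurations used across the suite.

toy_matrix <- function(genes = 20L, samples = 10L, seed = 1L, sd = 1) {
  set.seed(seed)
  matrix(rnorm(genes * samples, mean = 7, sd = sd), genes, samples,
         dimnames = list(sprintf("g%03d", seq_len(genes)),
                         sprintf("s%03d", seq_len(samples))))
}

# A reduced synthetic study: same structure as the defaults, smaller
# dimensions, for fast unit tests.
small_config <- function(seed = 1L, n_clinical = 150L, ...) {
  synthetic_config(n_lines = 120L, n_genes = 300L, n_program_genes = 12L,
                   n_clinical = n_clinical, seed = seed, ...)
}

# A drug-response table with the given IC50 values.
toy_response <- function(ic50, ids = sprintf("s%03d", seq_along(ic50))) {
  data.frame(sample_id = ids, ic50 = ic50, stringsAsFactors = FALSE)
}
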