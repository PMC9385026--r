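# Shared builders for small in-code fixtures.

# A deterministic toy experiment: explicit FPKM values, no randomness.
toy_experiment <- function() {
  erg_experiment(
    gene_ids = c("A", "B", "C"),
    treated = matrix(c(4, 2, 1,
                       8, 2, 1,
                       4, 2, 1), nrow = 3,
                     dimnames = list(NULL, NULL)),
    control = matrix(c(1, 2, 4,
                       2, 2, 4,
                       1, 2, 4), nrow = 3))
}

# Small simulated experiment used across modules; fixed seed, scaled-down
# gene count with the default noise/effect structure.
small_simulation <- function(n_genes = 400, seed = 101) {
  sim_config(n_genes = n_genes, frac_stable_up = 0.075,
             frac_stable_down = 0.075, frac_unstable = 0.05, seed = seed)
}

# Random expression table for oracle-equivalence checks on select_panel.
random_profile_table <- function(n, seed) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n))
  data.frame(
    gene = genes,
    av = round(stats::rnorm(n, 0, 1.5), 3),
    cv = round(stats::runif(n, 0.01, 1), 3),
    cv_defined = stats::runif(n) > 0.05,
    p_value = round(stats::runif(n), 3),
    mean_control_fpkm = round(stats::runif(n, 0, 5), 3),
    stringsAsFactors = FALSE)
}

write_tsv_text <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
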