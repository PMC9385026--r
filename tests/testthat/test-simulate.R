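# The synthetic-data generators: determinism, the stated generative model,
# and recoverability of the planted structure.

test_that("identical config and seed reproduce identical outputs everywhere", {
  cfg <- small_simulation(n_genes = 200, seed = 11)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$experiment$treated, b$experiment$treated)
  expect_identical(a$experiment$control, b$experiment$control)
  expect_identical(a$truth, b$truth)

  ev_a <- simulate_peak_evidence(a$truth, seed = 3)
  ev_b <- simulate_peak_evidence(b$truth, seed = 3)
  expect_identical(ev_a, ev_b)

  gs_a <- simulate_gene_sets(a$truth, n_sets = 4, seed = 3)
  gs_b <- simulate_gene_sets(b$truth, n_sets = 4, seed = 3)
  expect_identical(gs_a, gs_b)
})

test_that("class counts follow the rounded fractions and config is validated", {
  cfg <- sim_config(n_genes = 1000, frac_stable_up = 0.1,
                    frac_stable_down = 0.1, frac_unstable = 0.1, seed = 1)
  tr <- simulate_experiment(cfg)$truth
  counts <- table(tr$class)[c("stable_up", "stable_down",
                              "unstable", "non_responder")]
  expect_identical(as.integer(counts), c(100L, 100L, 100L, 700L))
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(frac_stable_up = 0.9, frac_stable_down = 0.2),
               "fractions")
  expect_error(sim_config(stable_sigma = 0), "sigma")
})

test_that("the zero-noise limit gives constant ratios and vanishing CV", {
  cfg <- sim_config(n_genes = 50, frac_stable_up = 0.2, frac_stable_down = 0.2,
                    frac_unstable = 0, stable_sigma = 1e-12, seed = 4)
  sr <- simulate_experiment(cfg)
  rp <- response_profile(sr$experiment, pseudocount = 1e-9)
  st <- stability_table(rp)
  stable <- sr$truth$class %in% c("stable_up", "stable_down")
  spread <- apply(rp$ratios[stable, ], 1, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-6)
  expect_lt(max(st$cv[stable]), 1e-6)
})

test_that("non-responders have mean log2 ratio near zero (Monte-Carlo)", {
  cfg <- sim_config(n_genes = 3000, frac_stable_up = 0, frac_stable_down = 0,
                    frac_unstable = 0, stable_sigma = 0.1, seed = 13)
  sr <- simulate_experiment(cfg)
  rp <- response_profile(sr$experiment, pseudocount = 1e-9)
  ratios <- as.vector(rp$ratios)
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios)), 3 * se)
})

test_that("planted stable responders out-rank unstable responders by CV", {
  sr <- simulate_experiment(small_simulation(n_genes = 2000, seed = 42))
  st <- stability_table(response_profile(sr$experiment))
  st <- st[match(sr$truth$gene, st$gene), ]
  stable_cv <- st$cv[sr$truth$class %in% c("stable_up", "stable_down")]
  unstable_cv <- st$cv[sr$truth$class == "unstable"]
  frac_above <- mean(stable_cv < min(unstable_cv, na.rm = TRUE), na.rm = TRUE)
  expect_gte(frac_above, 0.95)
})

test_that("simulated peak evidence encodes the planted subtype by construction", {
  truth <- data.frame(gene = sprintf("g%d", 1:8),
                      subtype = rep(c("ERalpha", "ERbeta", "ERalpha/beta",
                                      "other"), 2),
                      stringsAsFactors = FALSE)
  ev <- simulate_peak_evidence(truth, seed = 2)
  ab <- ev[truth$subtype == "ERalpha/beta", ]
  expect_true(all(ab$q_plus > ab$q_minus & ab$sn_ratio > 1))
  oth <- ev[truth$subtype == "other", ]
  expect_true(all(oth$q_plus <= oth$q_minus & oth$sn_ratio <= 1))
  expect_error(simulate_peak_evidence(
    data.frame(gene = "g", subtype = "ERgamma"), 1), "unknown")
})

test_that("the classifier recovers planted labels from simulated evidence exactly", {
  sr <- simulate_experiment(small_simulation(n_genes = 600, seed = 8))
  ev <- simulate_peak_evidence(sr$truth, seed = 9)
  calls <- classify_panel(ev)$calls
  got <- calls$subtype[match(sr$truth$gene, calls$gene)]
  expect_identical(got, sr$truth$subtype)
})

test_that("gene-set simulation plants a recoverable enriched set", {
  sr <- simulate_experiment(small_simulation(n_genes = 500, seed = 21))
  # no enrichment: designated set's responder share is near background
  flat <- simulate_gene_sets(sr$truth, n_sets = 6, set_size = 100,
                             enrichment = 1, seed = 5)
  responders <- sr$truth$gene[sr$truth$class != "non_responder"]
  share <- mean(flat$planted_set %in% responders)
  background <- length(responders) / nrow(sr$truth)
  expect_lt(abs(share - background), 0.12)

  # strong enrichment: designated set attains the smallest ORA p
  rich <- simulate_gene_sets(sr$truth, n_sets = 6, set_size = 100,
                             enrichment = 30, seed = 5)
  res <- enrich_panel(responders, rich, sr$truth$gene)
  expect_identical(res$set[which.min(res$p)], "planted_set")
  expect_identical(res$set[1], "planted_set")

  expect_error(simulate_gene_sets(sr$truth, n_sets = 0), "n_sets")
  expect_error(simulate_gene_sets(sr$truth, n_sets = 2, enrichment = 0),
               "enrichment")
})
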