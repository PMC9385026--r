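# Log2 transformation, response ratios, Welch testing, volcano tables.

test_that("log2 transform with pseudocount matches hand values and guards inputs", {
  expect_equal(log2_with_pseudocount(1, 0), 0)
  expect_equal(log2_with_pseudocount(7, 1), 3)
  expect_equal(log2_with_pseudocount(0, 1), 0)
  expect_error(log2_with_pseudocount(-1, 1), ">= 0")
  expect_error(log2_with_pseudocount(0, 0), "strictly positive")
})

test_that("response ratios are zero for identical arms and constant for a fixed fold", {
  exp_id <- erg_experiment(c("A", "B"),
                           treated = matrix(c(3, 5, 3, 5), 2),
                           control = matrix(c(3, 5, 3, 5), 2))
  rp <- response_profile(exp_id, pseudocount = 1)
  expect_true(all(rp$ratios == 0))
  expect_equal(rp$summary$log2fc, c(0, 0))

  exp_fold <- erg_experiment("A",
                             treated = matrix(c(4, 8, 40), 1),
                             control = matrix(c(1, 2, 10), 1))
  rp0 <- response_profile(exp_fold, pseudocount = 1e-9)
  expect_equal(unname(rp0$ratios[1, ]), rep(2, 3), tolerance = 1e-6)
})

test_that("swapping arms negates every ratio and raising treated never lowers one", {
  sr <- simulate_experiment(small_simulation(n_genes = 60))
  e <- sr$experiment
  rp <- response_profile(e, 1)
  swapped <- erg_experiment(e$gene_ids, e$control, e$treated)
  rp_sw <- response_profile(swapped, 1)
  expect_equal(rp_sw$ratios, -rp$ratios)

  bumped <- e$treated
  bumped[3, 2] <- bumped[3, 2] + 5
  rp_b <- response_profile(erg_experiment(e$gene_ids, bumped, e$control), 1)
  expect_gt(rp_b$ratios[3, 2], rp$ratios[3, 2])
  expect_equal(rp_b$ratios[-3, ], rp$ratios[-3, ])
})

test_that("Welch p-values match the textbook formula on random inputs", {
  welch_oracle <- function(x, y) {
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    2 * pt(-abs(t), df)
  }
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(sample(3:8, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    expect_equal(per_gene_test(x, y), welch_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("degenerate Welch inputs follow the stated conventions", {
  expect_equal(per_gene_test(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(per_gene_test(c(2, 2, 2), c(1, 1, 1)), 0)
  expect_error(per_gene_test(1, c(1, 2)), "at least 2")
  set.seed(5)
  jitter <- rnorm(6, sd = 1e-3)
  expect_lt(per_gene_test(rep(0, 6), 2 + jitter), 0.001)
})

test_that("volcano records class genes by significance and sign", {
  exp <- erg_experiment(c("up", "down", "flat"),
                        treated = matrix(c(8, 8.2, 7.9, 8.1,
                                           1, 1.1, 0.9, 1.05,
                                           3, 3.1, 2.9, 3.05), 3, byrow = TRUE),
                        control = matrix(c(2, 2.05, 1.95, 2.1,
                                           4, 4.1, 3.9, 4.05,
                                           3.02, 3.08, 2.93, 3.04), 3, byrow = TRUE))
  rp <- response_profile(exp, 1)
  vt <- volcano_table(rp, "pvalue", alpha = 0.05)
  expect_identical(vt$class[vt$gene == "up"], "up")
  expect_identical(vt$class[vt$gene == "down"], "down")
  expect_identical(vt$class[vt$gene == "flat"], "not_significant")
  expect_equal(vt$y_value, -log10(rp$summary$p_value[match(vt$gene, rp$summary$gene)]))

  st <- stability_table(rp)
  vt_cv <- volcano_table(rp, "cv", 0.05, cv = setNames(st$cv, st$gene))
  expect_identical(vt_cv$y_kind[1], "cv")
  expect_error(volcano_table(rp, "cv", 0.05), "requires")
})
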