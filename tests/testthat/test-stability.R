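# The CV = |SD/Av| statistic, stability ranking, and panel selection.

test_that("cv_statistic matches hand arithmetic and guards degenerate input", {
  const <- cv_statistic(rep(1, 6))
  expect_equal(c(const$av, const$sd, const$cv), c(1, 0, 0))

  two <- cv_statistic(c(2, 4))
  expect_equal(two$av, 3)
  expect_equal(two$sd, sqrt(2))           # n - 1 denominator
  expect_equal(two$cv, sqrt(2) / 3, tolerance = 1e-12)

  zero_mean <- cv_statistic(c(-1, -1, -1, 1, 1, 1))
  expect_false(zero_mean$defined)
  expect_true(is.na(zero_mean$cv))

  expect_error(cv_statistic(1), "at least 2")
})

test_that("cv_statistic agrees with the formula oracle on random vectors", {
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(sample(2:10, 1), mean = runif(1, -3, 3), sd = runif(1, 0.1, 2))
    res <- cv_statistic(x)
    m <- sum(x) / length(x)
    s <- sqrt(sum((x - m)^2) / (length(x) - 1))
    expect_equal(res$av, m, tolerance = 1e-12)
    expect_equal(res$sd, s, tolerance = 1e-12)
    if (res$defined) expect_equal(res$cv, abs(s / m), tolerance = 1e-12)
  }
})

test_that("ranking is CV-ascending with |Av| then symbol tie-breaks", {
  recs <- data.frame(gene = c("A", "B", "C"), cv = c(0.3, 0.1, 0.2),
                     av = c(1, 1, 1), cv_defined = TRUE)
  expect_identical(rank_by_stability(recs)$gene, c("B", "C", "A"))

  ties <- data.frame(gene = c("A", "B", "C"), cv = c(0.2, 0.2, 0.2),
                     av = c(1, -2, 1.5), cv_defined = TRUE)
  expect_identical(rank_by_stability(ties)$gene, c("B", "C", "A"))

  with_undef <- data.frame(gene = c("A", "B"), cv = c(0.1, NA),
                           av = c(1, 0), cv_defined = c(TRUE, FALSE))
  expect_message(ranked <- rank_by_stability(with_undef), "undefined")
  expect_identical(ranked$gene, "A")
  expect_identical(ranked$rank, 1L)
})

test_that("the packaged 30-gene panel ranks and averages as printed", {
  ranked <- rank_by_stability(erg_panel30())
  expect_identical(ranked$gene[1], "LINC02593")
  expect_equal(ranked$cv[1], 0.058)
  m <- mean_cv_by_set(ranked, c(30, 1))
  expect_equal(m$mean_cv[m$set_size == 30], 3.449 / 30, tolerance = 1e-12)
  expect_equal(m$mean_cv[m$set_size == 1], 0.058)
  expect_equal(m$sd_cv[m$set_size == 1], 0)
  expect_error(mean_cv_by_set(ranked, 31), "31")
})

test_that("prefix means of a CV-ascending ranking are monotone in set size", {
  set.seed(9)
  recs <- data.frame(gene = sprintf("g%03d", 1:80),
                     cv = runif(80, 0, 2), av = rnorm(80), cv_defined = TRUE)
  ranked <- rank_by_stability(recs)
  sizes <- c(5, 10, 20, 40, 80)
  m <- mean_cv_by_set(ranked, sizes)
  expect_true(all(diff(m$mean_cv) >= 0))
})

test_that("panel selection applies the candidate filter then slices by CV", {
  # five-row table worked out by hand: E fails the fold-change floor
  s <- data.frame(
    gene = c("A", "B", "C", "D", "E"),
    av = c(2, 1.5, -2, -1, 0.1),
    sd = c(0.2, 0.75, 0.4, 0.3, 0.005),
    cv = c(0.1, 0.5, 0.2, 0.3, 0.05),
    cv_defined = TRUE, stringsAsFactors = FALSE)
  rp <- list(summary = data.frame(
    gene = s$gene, log2fc = s$av, sd_ratio = s$sd, p_value = 0.01,
    mean_treated_fpkm = 10, mean_control_fpkm = 10, stringsAsFactors = FALSE))
  cfg <- erg_config(n_up = 1, n_down = 1, top_k = 2, fc_threshold = 0.585,
                    expression_floor = 1, seed = 1)
  pan <- select_panel(rp, s, cfg)
  expect_identical(pan$up, "A")
  expect_identical(pan$down, "C")
  expect_identical(sort(pan$top_k), c("A", "C"))
  expect_false(any(pan$shortfall))
})

test_that("selection agrees with an exhaustive filter-sort-slice oracle", {
  oracle <- function(tab, cfg) {
    cand <- tab[tab$cv_defined & tab$p_value < cfg$alpha &
                  abs(tab$av) >= cfg$fc_threshold &
                  tab$mean_control_fpkm >= cfg$expression_floor, ]
    slice <- function(pool, n) {
      pool <- pool[order(pool$cv, -abs(pool$av), pool$gene), ]
      pool$gene[seq_len(min(n, nrow(pool)))]
    }
    up <- slice(cand[cand$av > 0, ], cfg$n_up)
    down <- slice(cand[cand$av < 0, ], cfg$n_down)
    un <- cand[cand$gene %in% c(up, down), ]
    list(up = up, down = down, top_k = slice(un, cfg$top_k))
  }
  for (seed in c(2, 3, 4, 5)) {
    tab <- random_profile_table(sample(10:50, 1), seed)
    tab$sd <- tab$cv * abs(tab$av)
    rp <- list(summary = data.frame(
      gene = tab$gene, log2fc = tab$av, sd_ratio = tab$sd,
      p_value = tab$p_value, mean_treated_fpkm = 1,
      mean_control_fpkm = tab$mean_control_fpkm, stringsAsFactors = FALSE))
    cfg <- erg_config(n_up = 4, n_down = 4, top_k = 3, fc_threshold = 0.5,
                      expression_floor = 1, alpha = 0.4, seed = seed)
    got <- suppressMessages(select_panel(rp, tab, cfg))
    want <- oracle(tab, cfg)
    expect_identical(got$up, want$up)
    expect_identical(got$down, want$down)
    expect_identical(got$top_k, want$top_k)
  }
})

test_that("a direction shortfall returns all qualifying genes with a flag", {
  tab <- data.frame(gene = c("A", "B", "C"), av = c(1, 2, -1),
                    sd = 0.1, cv = c(0.1, 0.05, 0.1), cv_defined = TRUE)
  rp <- list(summary = data.frame(
    gene = tab$gene, log2fc = tab$av, sd_ratio = tab$sd, p_value = 0.01,
    mean_treated_fpkm = 5, mean_control_fpkm = 5, stringsAsFactors = FALSE))
  cfg <- erg_config(n_up = 10, n_down = 10, top_k = 5, fc_threshold = 0.5,
                    expression_floor = 1, seed = 1)
  msgs <- capture_messages(pan <- select_panel(rp, tab, cfg))
  expect_match(msgs, "qualifying", all = TRUE)
  expect_identical(sort(pan$up), c("A", "B"))
  expect_identical(pan$down, "C")
  expect_true(all(pan$shortfall))
})

test_that("rescaling all FPKM leaves ratios, CV and selection unchanged", {
  sr <- simulate_experiment(small_simulation(n_genes = 120))
  e <- sr$experiment
  pc <- 1e-9  # vanishing pseudocount: exact scale invariance of the ratios
  scaled <- erg_experiment(e$gene_ids, e$treated * 37, e$control * 37)
  rp1 <- response_profile(e, pc)
  rp2 <- response_profile(scaled, pc)
  expect_equal(rp1$ratios, rp2$ratios, tolerance = 1e-9)
  st1 <- stability_table(rp1)
  st2 <- stability_table(rp2)
  expect_equal(st1$cv, st2$cv, tolerance = 1e-6)
  cfg <- erg_config(n_up = 9, n_down = 9, top_k = 5, expression_floor = 0,
                    seed = 1)
  p1 <- suppressMessages(select_panel(rp1, st1, cfg))
  p2 <- suppressMessages(select_panel(rp2, st2, cfg))
  expect_identical(p1$up, p2$up)
  expect_identical(p1$down, p2$down)
})

test_that("planted stable responders dominate the selected panel", {
  sr <- simulate_experiment(small_simulation(n_genes = 2000, seed = 42))
  rp <- response_profile(sr$experiment)
  st <- stability_table(rp)
  cfg <- erg_config(n_up = 150, n_down = 150, top_k = 30, seed = 42)
  pan <- suppressMessages(select_panel(rp, st, cfg))
  stable <- sr$truth$gene[sr$truth$class %in% c("stable_up", "stable_down")]
  recovery <- mean(stable %in% c(pan$up, pan$down))
  expect_gte(recovery, 0.95)
})
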