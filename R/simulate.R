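# Synthetic-data generators. The expression generator plants four gene
# classes -- stable up-responders, stable down-responders, unstable
# responders, and non-responders -- under a log-normal FPKM model in which
# the noise sits additively on the log2 scale, so the CV of the log2
# response ratios is directly controlled by the class sigma. The evidence
# and gene-set generators plant subtype labels and an enriched category
# that the downstream classifier and ORA must recover.

#' Run code with a local RNG seed, restoring the caller's state
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

GENE_CLASSES <- c("stable_up", "stable_down", "unstable", "non_responder")

#' Configuration for the expression simulator
#'
#' Defaults mirror the emulated study design: 6 paired replicates and 150
#' stable up- plus 150 stable down-responders among roughly 26,000 genes.
#' The planted effect is a mean |log2 ratio| of 2 (a 4-fold response, the
#' scale of a strong estrogen response) with spread 0.5; stable responders
#' carry per-replicate log2 noise of SD 0.1 and unstable responders SD 1.0,
#' so the two are separated by the CV statistic. Tests use the same model
#' scaled down in gene count.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Number of paired replicates (>= 2).
#' @param frac_stable_up,frac_stable_down,frac_unstable Class fractions;
#'   the remainder are non-responders. Must sum to <= 1.
#' @param effect_size Mean |log2 ratio| planted in responders.
#' @param effect_spread SD of the planted |log2 ratio| around
#'   \code{effect_size}.
#' @param stable_sigma SD of per-replicate log2 ratio noise for stable
#'   responders (and the technical noise of non-responders).
#' @param unstable_sigma SD of per-replicate log2 ratio noise for unstable
#'   responders.
#' @param baseline_mean,baseline_sd Mean and SD of the per-gene baseline
#'   log2 FPKM.
#' @param seed Integer seed; identical configs give identical output.
#' @return Validated list of class \code{"erg_sim_config"}.
#' @export
sim_config <- function(n_genes = 26000L,
                       n_replicates = 6L,
                       frac_stable_up = 150 / 26000,
                       frac_stable_down = 150 / 26000,
                       frac_unstable = 0.05,
                       effect_size = 2,
                       effect_spread = 0.5,
                       stable_sigma = 0.1,
                       unstable_sigma = 1.0,
                       baseline_mean = 5,
                       baseline_sd = 2,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              frac_stable_up = frac_stable_up,
              frac_stable_down = frac_stable_down,
              frac_unstable = frac_unstable,
              effect_size = effect_size, effect_spread = effect_spread,
              stable_sigma = stable_sigma, unstable_sigma = unstable_sigma,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) abort("'n_genes' must be >= 1")
  if (cfg$n_replicates < 2L) abort("'n_replicates' must be >= 2")
  fracs <- c(cfg$frac_stable_up, cfg$frac_stable_down, cfg$frac_unstable)
  if (any(fracs < 0) || sum(fracs) > 1) {
    abort("class fractions must be >= 0 and sum to <= 1")
  }
  if (cfg$stable_sigma <= 0 || cfg$unstable_sigma <= 0) {
    abort("noise sigmas must be > 0")
  }
  if (cfg$effect_size <= 0) abort("'effect_size' must be > 0")
  if (cfg$effect_spread < 0) abort("'effect_spread' must be >= 0")
  if (cfg$baseline_sd < 0) abort("'baseline_sd' must be >= 0")
  structure(cfg, class = "erg_sim_config")
}

#' Simulate a paired treated/control expression experiment
#'
#' Generative model: each gene gets a constant baseline log2 FPKM drawn from
#' Normal(baseline_mean, baseline_sd), which both control replicates and the
#' treated arm share; each treated replicate adds the gene's true log2
#' effect plus Normal(0, class sigma) noise. FPKM values are 2^(log2 value),
#' i.e. log-normal. Class membership is assigned to the first genes in
#' order (counts are the rounded fractions), then gene order is left as
#' generated -- gene identifiers encode nothing about class.
#'
#' @param config An [sim_config()].
#' @return List with \code{experiment} (an [erg_experiment()]) and
#'   \code{truth}: data frame \code{gene}, \code{class},
#'   \code{true_effect}, \code{subtype}.
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "erg_sim_config")) config <- do.call(sim_config, config)
  n <- config$n_genes
  reps <- config$n_replicates
  n_up <- round(config$frac_stable_up * n)
  n_down <- round(config$frac_stable_down * n)
  n_unst <- round(config$frac_unstable * n)
  if (n_up + n_down + n_unst > n) abort("class counts exceed gene count")
  classes <- rep(GENE_CLASSES,
                 c(n_up, n_down, n_unst, n - n_up - n_down - n_unst))
  genes <- sprintf("gene%0*d", nchar(as.character(n)), seq_len(n))
  with_seed(config$seed, {
    baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    magnitude <- abs(stats::rnorm(n, config$effect_size, config$effect_spread))
    eff_sign <- ifelse(classes == "stable_up", 1,
                       ifelse(classes == "stable_down", -1,
                              ifelse(classes == "unstable",
                                     sample(c(-1, 1), n, replace = TRUE), 0)))
    effect <- eff_sign * magnitude
    sigma <- ifelse(classes == "unstable", config$unstable_sigma,
                    config$stable_sigma)
    noise <- matrix(stats::rnorm(n * reps), n, reps) * sigma
    log2_treated <- baseline + effect + noise
    log2_control <- matrix(baseline, n, reps)
    responder <- classes != "non_responder"
    subtype <- rep("other", n)
    subtype[responder] <- sample(SUBTYPE_LEVELS, sum(responder),
                                 replace = TRUE, prob = c(10, 2, 14, 3) / 29)
    truth <- data.frame(gene = genes, class = classes, true_effect = effect,
                        subtype = subtype, stringsAsFactors = FALSE)
    experiment <- erg_experiment(genes, 2^log2_treated, 2^log2_control)
    list(experiment = experiment, truth = truth)
  })
}

#' Simulate ChIP peak evidence consistent with planted subtype labels
#'
#' For each gene, scores are drawn so that the rule-based classifier must
#' recover the planted label: ER-alpha-bound genes get a strictly larger
#' peak score with estradiol than without, ER-beta-bound genes a
#' signal-to-noise ratio strictly above 1.0, and the magnitudes span the
#' ranges seen in real peak-evidence tables (scores up to a few thousand,
#' ratios up to the low tens).
#'
#' @param truth Ground-truth data frame with columns \code{gene},
#'   \code{subtype} (labels among \code{"ERalpha"}, \code{"ERbeta"},
#'   \code{"ERalpha/beta"}, \code{"other"}).
#' @param seed Integer seed.
#' @return Peak-evidence data frame \code{gene}, \code{q_minus},
#'   \code{q_plus}, \code{sn_ratio}.
#' @export
simulate_peak_evidence <- function(truth, seed = 1L) {
  if (!all(c("gene", "subtype") %in% names(truth))) {
    abort("truth must have 'gene' and 'subtype' columns")
  }
  unknown <- setdiff(unique(truth$subtype), SUBTYPE_LEVELS)
  if (length(unknown) > 0L) {
    abort("unknown subtype label(s): ", paste(unknown, collapse = ", "))
  }
  n <- nrow(truth)
  with_seed(seed, {
    alpha_pos <- truth$subtype %in% c("ERalpha", "ERalpha/beta")
    beta_pos <- truth$subtype %in% c("ERbeta", "ERalpha/beta")
    q_minus <- sample(0:1400, n, replace = TRUE)
    gap <- sample(30:3000, n, replace = TRUE)
    # negatives draw q_plus uniformly on 0..q_minus, so q_plus <= q_minus
    q_plus <- ifelse(alpha_pos, q_minus + gap,
                     floor(stats::runif(n) * (q_minus + 1)))
    sn <- ifelse(beta_pos, stats::runif(n, 1.05, 33), stats::runif(n, 0, 1))
    data.frame(gene = truth$gene, q_minus = as.numeric(q_minus),
               q_plus = as.numeric(q_plus), sn_ratio = sn,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' The first (designated) set samples genes with responder genes weighted
#' by \code{enrichment}; the remaining sets sample uniformly. With
#' \code{enrichment = 1} the designated set is indistinguishable from the
#' rest; large values make it the clear top hit of an over-representation
#' analysis of the responder panel.
#'
#' @param truth Ground-truth data frame with \code{gene} and \code{class}.
#' @param n_sets Number of sets (>= 1).
#' @param set_size Genes per set (default 50, capped at the gene count).
#' @param enrichment Sampling-weight multiplier for responder genes in the
#'   designated set (> 0; 1 = no enrichment).
#' @param seed Integer seed.
#' @return Named list of character vectors; the designated set is named
#'   \code{"planted_set"}.
#' @export
simulate_gene_sets <- function(truth, n_sets, set_size = 50L,
                               enrichment = 1, seed = 1L) {
  if (n_sets < 1L) abort("'n_sets' must be >= 1")
  if (!is_scalar_number(enrichment) || enrichment <= 0) {
    abort("'enrichment' must be a positive number (1 = no enrichment)")
  }
  genes <- truth$gene
  set_size <- min(as.integer(set_size), length(genes))
  if (set_size < 1L) abort("'set_size' must be >= 1")
  responder <- truth$class != "non_responder"
  with_seed(seed, {
    weights <- ifelse(responder, enrichment, 1)
    sets <- vector("list", n_sets)
    sets[[1L]] <- sort(sample(genes, set_size, prob = weights))
    if (n_sets > 1L) {
      for (i in 2:n_sets) sets[[i]] <- sort(sample(genes, set_size))
    }
    names(sets) <- c("planted_set",
                     if (n_sets > 1L) sprintf("random_set_%02d", seq_len(n_sets - 1L)))
    sets
  })
}
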