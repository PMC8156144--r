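#' Configuration for a synthetic cohort
#'
#' Defines the statistical structure of a simulated neoadjuvant-chemotherapy
#' cohort: log2 expression of `n_genes` genes over `n_samples` tumors, a
#' designated pathway gene set of `pathway_size` genes of which the first
#' `n_de_genes` are planted response-associated genes (mean shift `de_log2fc`
#' in responders), a binary pathological-complete-response label at prevalence
#' `pcr_prevalence`, a treatment arm flag, and exponential survival whose
#' hazard depends on the true composite-score tertile group only through the
#' arm-specific hazard ratios.
#'
#' Defaults mirror a typical array-based training cohort: 170 samples with a
#' responder prevalence of 57/170, a 200-gene pathway inside a 500-gene
#' matrix, three planted genes at log2 fold changes 0.8 / 0.6 / 0.4 against
#' unit log2 noise, an even treatment split, a halved hazard for high-score
#' tumors in the treated arm only, and month-scale exponential event and
#' censoring rates.
#'
#' @param n_samples Number of samples.
#' @param n_genes Total number of genes in the matrix.
#' @param pathway_size Number of genes assigned to the designated pathway set.
#' @param n_de_genes Number of planted response-associated genes (first genes
#'   of the pathway set); must equal `length(de_log2fc)`.
#' @param de_log2fc Per-gene planted effect sizes, log2 units
#'   (responder minus non-responder mean).
#' @param pcr_prevalence Probability a sample is a responder.
#' @param noise_sd Standard deviation of the Gaussian log2 noise.
#' @param baseline_mean Baseline log2 expression level.
#' @param chemo_fraction Probability a sample is in the treated arm.
#' @param hazard_ratio_high_vs_low_chemo Hazard ratio (high- vs low-score
#'   group) in the treated arm.
#' @param hazard_ratio_high_vs_low_nochemo Same, untreated arm (default 1:
#'   no score effect without treatment).
#' @param baseline_hazard Event rate per month for the low-score group.
#' @param censor_rate Censoring rate per month.
#' @param follow_up_max Administrative censoring horizon, months.
#' @param pathway_name Name given to the simulated pathway gene set.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 170,
                          n_genes = 500,
                          pathway_size = 200,
                          n_de_genes = 3,
                          de_log2fc = c(0.8, 0.6, 0.4),
                          pcr_prevalence = 57 / 170,
                          noise_sd = 1,
                          baseline_mean = 8,
                          chemo_fraction = 0.5,
                          hazard_ratio_high_vs_low_chemo = 0.5,
                          hazard_ratio_high_vs_low_nochemo = 1.0,
                          baseline_hazard = 0.01,
                          censor_rate = 0.005,
                          follow_up_max = 240,
                          pathway_name = "SIM_PATHWAY",
                          seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              pathway_size = as.integer(pathway_size),
              n_de_genes = as.integer(n_de_genes),
              de_log2fc = as.numeric(de_log2fc),
              pcr_prevalence = pcr_prevalence, noise_sd = noise_sd,
              baseline_mean = baseline_mean, chemo_fraction = chemo_fraction,
              hazard_ratio_high_vs_low_chemo = hazard_ratio_high_vs_low_chemo,
              hazard_ratio_high_vs_low_nochemo = hazard_ratio_high_vs_low_nochemo,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              follow_up_max = follow_up_max,
              pathway_name = as.character(pathway_name),
              seed = as.integer(seed))
  stopifnot(cfg$n_samples >= 1L, cfg$n_genes >= 1L,
            cfg$pathway_size >= 1L, cfg$pathway_size <= cfg$n_genes,
            cfg$n_de_genes >= 0L, cfg$n_de_genes <= cfg$pathway_size,
            length(cfg$de_log2fc) == cfg$n_de_genes,
            cfg$pcr_prevalence > 0, cfg$pcr_prevalence < 1,
            cfg$noise_sd > 0,
            cfg$chemo_fraction >= 0, cfg$chemo_fraction <= 1,
            cfg$hazard_ratio_high_vs_low_chemo > 0,
            cfg$hazard_ratio_high_vs_low_nochemo > 0,
            cfg$baseline_hazard > 0, cfg$censor_rate > 0,
            cfg$follow_up_max > 0)
  class(cfg) <- "cohort_config"
  cfg
}

#' Read a cohort configuration from YAML
#'
#' @param path YAML file whose keys are [cohort_config()] arguments.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  do.call(cohort_config, yaml::read_yaml(path))
}

#' Simulate a cohort with planted response-associated genes
#'
#' Generates (expression, clinical, gene sets) with the structure the
#' derivation-validation workflow assumes:
#' \itemize{
#'   \item response drawn Bernoulli(`pcr_prevalence`); regenerated (bounded
#'     retries) if a degenerate single-class draw occurs;
#'   \item log2 expression of gene g in sample s =
#'     `baseline_mean` + (`de_log2fc[g]` if g is planted and s a responder)
#'     + Normal(0, `noise_sd`);
#'   \item the pathway set = planted genes plus filler pathway genes;
#'   \item treatment arm drawn Bernoulli(`chemo_fraction`);
#'   \item for each endpoint (OS/DFS/DSS), event times are exponential with
#'     rate `baseline_hazard` times the arm-specific hazard ratio for samples
#'     in the top third of the *true* planted score (the `de_log2fc`-weighted
#'     sum of planted-gene expression); censoring times exponential at
#'     `censor_rate`, truncated at `follow_up_max`.
#' }
#' Fully reproducible from `config$seed`; per-stage random sub-streams are
#' derived deterministically from it so that, e.g., the expression draw does
#' not depend on how many response retries occurred.
#'
#' @param config A [cohort_config()].
#' @param max_retries Retries allowed for a degenerate all-one-class response
#'   draw before erroring.
#' @return A list with elements `expression` (matrix), `clinical`
#'   (data.frame), `gene_sets` (`gene_set_collection`), and `truth` (planted
#'   gene ids, weights, true score and group).
#' @export
simulate_cohort <- function(config, max_retries = 10L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 4L)

  n <- config$n_samples
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  sample_ids <- sprintf("S%04d", seq_len(n))
  pathway_genes <- gene_ids[seq_len(config$pathway_size)]
  planted <- gene_ids[seq_len(config$n_de_genes)]

  # response labels (retry degenerate draws at tiny n)
  set.seed(stage_seeds[[1L]])
  response <- NULL
  for (i in seq_len(max_retries + 1L)) {
    draw <- stats::rbinom(n, 1L, config$pcr_prevalence)
    if (n < 2L || length(unique(draw)) == 2L) {
      response <- draw
      break
    }
  }
  if (is.null(response)) {
    stop("degenerate response draw (single class) after ", max_retries,
         " retries; increase n_samples or adjust pcr_prevalence")
  }

  # expression: baseline + planted shift in responders + Gaussian noise
  set.seed(stage_seeds[[2L]])
  expr <- matrix(stats::rnorm(config$n_genes * n, mean = config$baseline_mean,
                              sd = config$noise_sd),
                 nrow = config$n_genes, ncol = n,
                 dimnames = list(gene_ids, sample_ids))
  if (config$n_de_genes > 0L && any(response == 1L)) {
    expr[planted, response == 1L] <-
      expr[planted, response == 1L, drop = FALSE] + config$de_log2fc
  }
  attr(expr, "log2_transformed") <- TRUE

  # treatment arm
  set.seed(stage_seeds[[3L]])
  chemo <- stats::rbinom(n, 1L, config$chemo_fraction)

  # true planted score and its tertile group drive the survival hazard
  true_score <- if (config$n_de_genes > 0L) {
    as.vector(config$de_log2fc %*% expr[planted, , drop = FALSE])
  } else {
    rep(0, n)
  }
  n_high <- round(n / 3)
  ord <- order(-true_score, sample_ids)
  high <- logical(n)
  high[ord[seq_len(n_high)]] <- TRUE

  hr <- ifelse(high,
               ifelse(chemo == 1L,
                      config$hazard_ratio_high_vs_low_chemo,
                      config$hazard_ratio_high_vs_low_nochemo),
               1)
  set.seed(stage_seeds[[4L]])
  clinical <- data.frame(
    sample_id = sample_ids,
    response = ifelse(response == 1L, "pCR", "non_pCR"),
    subtype = rep("TNBC", n),
    grade = rep("unknown", n),
    stage = rep("unknown", n),
    chemotherapy = ifelse(chemo == 1L, "yes", "no"),
    stringsAsFactors = FALSE
  )
  for (ep in .endpoints) {
    event_time <- stats::rexp(n, rate = config$baseline_hazard * hr)
    censor_time <- pmin(stats::rexp(n, rate = config$censor_rate),
                        config$follow_up_max)
    clinical[[paste0(ep, "_time")]] <- pmin(event_time, censor_time)
    clinical[[paste0(ep, "_event")]] <- as.numeric(event_time <= censor_time)
  }

  sets <- structure(stats::setNames(list(pathway_genes), config$pathway_name),
                    descriptions = stats::setNames("simulated pathway set",
                                                   config$pathway_name),
                    class = "gene_set_collection")

  list(expression = expr,
       clinical = clinical,
       gene_sets = sets,
       truth = list(planted_genes = planted, weights = config$de_log2fc,
                    true_score = stats::setNames(true_score, sample_ids),
                    high_group = stats::setNames(high, sample_ids)))
}

#' Simulate a null cohort
#'
#' Convenience wrapper around [simulate_cohort()] with all planted effect
#' sizes zero and both arm hazard ratios 1, i.e. no association between
#' expression, response, and survival.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param seed Integer seed.
#' @param ... Further arguments forwarded to [cohort_config()].
#' @return As [simulate_cohort()].
#' @export
simulate_null_cohort <- function(n_samples, n_genes, seed, ...) {
  cfg <- cohort_config(n_samples = n_samples, n_genes = n_genes,
                       pathway_size = min(n_genes, 200L),
                       n_de_genes = 0L, de_log2fc = numeric(0),
                       hazard_ratio_high_vs_low_chemo = 1,
                       hazard_ratio_high_vs_low_nochemo = 1,
                       seed = seed, ...)
  simulate_cohort(cfg)
}
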