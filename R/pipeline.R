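#' Derive a fold-change-weighted signature from a training cohort
#'
#' Runs the full derivation workflow: probe collapsing, restriction of the
#' differential-expression screen to the designated pathway set, moderated-t
#' testing of responders vs non-responders, the adjusted-p significance
#' screen, selection of the top-k genes with their log2 fold changes as
#' weights, per-sample scoring, top-tertile dichotomization, ROC-AUC of the
#' composite score, a paired DeLong comparison against the whole-pathway
#' single-sample enrichment score, and a per-gene AUC scan over the pathway.
#'
#' @param expression Log2 expression matrix, genes in rows (probes are
#'   collapsed internally).
#' @param clinical Clinical `data.frame` (canonical layout); samples with
#'   `response` `"unknown"` are excluded from the differential screen and ROC
#'   but still receive scores and a tertile group.
#' @param gene_sets A `gene_set_collection` (or named list of gene vectors).
#' @param pathway Name of the pathway set to restrict the screen to.
#' @param alpha Adjusted-p threshold of the significance screen.
#' @param k Number of signature genes.
#' @param fraction Top fraction labelled "high" (default one-third).
#' @param cohort_name Provenance label stored in the model.
#' @param out_dir Optional directory; when given, all intermediate tables,
#'   the serialized model, and a YAML manifest are written there.
#' @return A `derivation_result`: list with `model` (`signature_model`),
#'   `dgea`, `scores` (with tertile groups), `roc` (`roc_result`),
#'   `pathway_scores`, `roc_pathway`, `delong` (`sig_test`), `auc_scan`.
#' @export
run_derivation <- function(expression, clinical, gene_sets, pathway,
                           alpha = 0.05, k = 3L, fraction = 1 / 3,
                           cohort_name = "training", out_dir = NULL) {
  stopifnot(is.matrix(expression), is.data.frame(clinical))
  if (!pathway %in% names(gene_sets)) {
    stop("pathway set '", pathway, "' not found in the collection")
  }
  expression <- collapse_probes(expression)
  pathway_genes <- intersect(gene_sets[[pathway]], rownames(expression))
  if (length(pathway_genes) == 0L) {
    stop("derivation: no pathway gene present in the expression matrix")
  }
  labelled <- clinical[clinical$response %in% c("pCR", "non_pCR"), ,
                       drop = FALSE]
  labelled <- labelled[labelled$sample_id %in% colnames(expression), ,
                       drop = FALSE]
  if (sum(labelled$response == "pCR") < 3L ||
      sum(labelled$response == "non_pCR") < 3L) {
    stop("derivation: need at least 3 labelled samples per response class")
  }
  expr_lab <- expression[, labelled$sample_id, drop = FALSE]
  labels <- as.integer(labelled$response == "pCR")

  dgea <- moderated_t_test(expr_lab, labels, genes = pathway_genes)
  model <- select_signature(dgea, k = k, alpha = alpha,
                            training_cohort = cohort_name)

  scores <- dichotomize_top_fraction(compute_score(expression, model),
                                     fraction = fraction)
  sc_lab <- scores$score[match(labelled$sample_id, scores$sample_id)]
  roc <- roc_auc(sc_lab, labels)

  pathway_scores <- pathway_ssgsea_score(expression, pathway_genes)
  pw_lab <- pathway_scores$score[match(labelled$sample_id,
                                       pathway_scores$sample_id)]
  roc_pathway <- roc_auc(pw_lab, labels)
  delong <- delong_compare(sc_lab, pw_lab, labels)

  auc_scan <- per_gene_auc_scan(expr_lab, labels, genes = pathway_genes)

  result <- structure(list(model = model, dgea = dgea, scores = scores,
                           roc = roc, pathway_scores = pathway_scores,
                           roc_pathway = roc_pathway, delong = delong,
                           auc_scan = auc_scan, pathway = pathway,
                           cohort_name = cohort_name),
                      class = "derivation_result")
  if (!is.null(out_dir)) .write_derivation(result, out_dir)
  result
}

#' Validate a fixed signature on an independent cohort
#'
#' Applies the trained weights unchanged (no refitting): computes the
#' composite score, dichotomizes at the top tertile *within this cohort*,
#' and, where the clinical annotation allows, reports (a) the ROC-AUC against
#' response and the high-vs-low response-rate 2x2 Fisher test, and (b)
#' score-group survival per endpoint, overall and within each treatment
#' stratum. Missing analyses are skipped with a note; a cohort with neither
#' response nor survival annotation is an error.
#'
#' @param expression Log2 expression matrix of the validation cohort.
#' @param clinical Clinical `data.frame` (canonical layout).
#' @param model A `signature_model` with trained weights.
#' @param fraction Top fraction labelled "high".
#' @param endpoints Survival endpoints to attempt.
#' @param stratify Clinical column defining treatment strata (set `NULL` to
#'   skip stratified fits).
#' @param cohort_name Label used in the report.
#' @param out_dir Optional output directory (tables + manifest).
#' @return A `validation_result`: list with `scores`, `roc` (or NULL),
#'   `fisher` (or NULL), `pcr_table`, `survival` (named list of
#'   `survival_fit`s), `skipped` (character notes).
#' @export
run_validation <- function(expression, clinical, model, fraction = 1 / 3,
                           endpoints = c("OS", "DFS", "DSS"),
                           stratify = "chemotherapy",
                           cohort_name = "validation", out_dir = NULL) {
  stopifnot(is.matrix(expression), inherits(model, "signature_model"))
  expression <- collapse_probes(expression)
  scores <- dichotomize_top_fraction(compute_score(expression, model),
                                     fraction = fraction)
  skipped <- character(0)

  merged <- merge(scores, clinical, by = "sample_id")
  labelled <- merged[merged$response %in% c("pCR", "non_pCR"), , drop = FALSE]
  roc <- NULL
  fisher <- NULL
  pcr_table <- NULL
  if (nrow(labelled) > 0L && length(unique(labelled$response)) == 2L) {
    labels <- as.integer(labelled$response == "pCR")
    roc <- roc_auc(labelled$score, labels)
    tab <- table(group = factor(labelled$group, levels = c("high", "low")),
                 response = factor(labelled$response,
                                   levels = c("pCR", "non_pCR")))
    pcr_table <- tab
    fisher <- fisher_exact_2x2(tab["high", "pCR"], tab["high", "non_pCR"],
                               tab["low", "pCR"], tab["low", "non_pCR"])
  } else {
    skipped <- c(skipped, "response analysis (no two-class response labels)")
  }

  surv_fits <- list()
  strata <- if (is.null(stratify)) list(NULL) else {
    vals <- setdiff(unique(merged[[stratify]]), "unknown")
    c(list(NULL), as.list(sort(vals)))
  }
  for (ep in endpoints) {
    tc <- paste0(ep, "_time")
    if (!tc %in% colnames(clinical) || all(is.na(clinical[[tc]]))) {
      skipped <- c(skipped, paste0("survival endpoint ", ep, " (absent)"))
      next
    }
    for (st in strata) {
      key <- if (is.null(st)) ep else paste0(ep, ".", stratify, "=", st)
      fit <- tryCatch(
        stratified_survival_analysis(clinical, scores, ep, stratum = st,
                                     stratum_var = stratify),
        error = function(e) {
          skipped <<- c(skipped, paste0(key, " (", conditionMessage(e), ")"))
          NULL
        })
      if (!is.null(fit)) surv_fits[[key]] <- fit
    }
  }
  if (is.null(roc) && length(surv_fits) == 0L) {
    stop("validation cohort '", cohort_name,
         "' has neither usable response labels nor survival annotation")
  }
  for (s in skipped) message("validation [", cohort_name, "]: skipped ", s)

  result <- structure(list(scores = scores, roc = roc, fisher = fisher,
                           pcr_table = pcr_table, survival = surv_fits,
                           skipped = skipped, cohort_name = cohort_name,
                           model = model),
                      class = "validation_result")
  if (!is.null(out_dir)) .write_validation(result, out_dir)
  result
}

#' Run the full derivation + validation pipeline from a YAML config
#'
#' Config keys: `training` (list with `expression`, `clinical` paths, and
#' optional `dialect`), `validation` (list of such cohort entries, each with
#' a `name`), `gmt` (path), `pathway` (set name), and optional `alpha`, `k`,
#' `fraction`, `endpoints`, `stratify`, `out_dir`.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return List with `derivation` and `validations` (named by cohort).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$training), !is.null(config$gmt),
            !is.null(config$pathway))
  alpha <- config$alpha %||% 0.05
  k <- config$k %||% 3L
  fraction <- config$fraction %||% (1 / 3)
  endpoints <- config$endpoints %||% c("OS", "DFS", "DSS")
  stratify <- config$stratify %||% "chemotherapy"
  out_dir <- config$out_dir

  read_cohort <- function(entry) {
    dialect <- entry$dialect %||% "tsv"
    list(expression = read_expression_matrix(entry$expression, dialect),
         clinical = read_clinical(entry$clinical, dialect))
  }
  gene_sets <- read_gmt(config$gmt)
  training <- read_cohort(config$training)
  deriv <- run_derivation(training$expression, training$clinical, gene_sets,
                          config$pathway, alpha = alpha, k = k,
                          fraction = fraction,
                          cohort_name = config$training$name %||% "training",
                          out_dir = if (!is.null(out_dir))
                            file.path(out_dir, "derivation"))
  validations <- list()
  for (entry in config$validation %||% list()) {
    nm <- entry$name %||% paste0("validation", length(validations) + 1L)
    cohort <- read_cohort(entry)
    validations[[nm]] <- run_validation(
      cohort$expression, cohort$clinical, deriv$model, fraction = fraction,
      endpoints = endpoints, stratify = stratify, cohort_name = nm,
      out_dir = if (!is.null(out_dir)) file.path(out_dir, nm))
  }
  list(derivation = deriv, validations = validations)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @keywords internal
.write_manifest <- function(dir, stage, files) {
  checksums <- vapply(files, function(f) {
    unname(tools::md5sum(file.path(dir, f)))
  }, character(1L))
  yaml::write_yaml(list(stage = stage, files = as.list(checksums)),
                   file.path(dir, "manifest.yaml"))
}

#' @keywords internal
.write_derivation <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(result$dgea, file.path(out_dir, "dgea.tsv"))
  .write_tsv(result$scores, file.path(out_dir, "scores.tsv"))
  .write_tsv(result$auc_scan, file.path(out_dir, "auc_scan.tsv"))
  .write_tsv(result$roc$curve, file.path(out_dir, "roc_curve.tsv"))
  .write_tsv(data.frame(quantity = c("auc_signature", "auc_pathway",
                                     "delong_z", "delong_p"),
                        value = c(result$roc$auc, result$roc_pathway$auc,
                                  result$delong$statistic, result$delong$p)),
             file.path(out_dir, "evaluation.tsv"))
  write_signature_model(result$model, file.path(out_dir, "model.yaml"))
  .write_manifest(out_dir, "derivation",
                  c("dgea.tsv", "scores.tsv", "auc_scan.tsv", "roc_curve.tsv",
                    "evaluation.tsv", "model.yaml"))
  invisible(out_dir)
}

#' @keywords internal
.write_validation <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- "scores.tsv"
  .write_tsv(result$scores, file.path(out_dir, "scores.tsv"))
  if (!is.null(result$roc)) {
    rows <- data.frame(quantity = c("auc", "fisher_p", "odds_ratio"),
                       value = c(result$roc$auc, result$fisher$p,
                                 result$fisher$effect))
    .write_tsv(rows, file.path(out_dir, "response.tsv"))
    files <- c(files, "response.tsv")
  }
  if (length(result$survival)) {
    rows <- do.call(rbind, lapply(names(result$survival), function(k) {
      f <- result$survival[[k]]
      data.frame(analysis = k, n = f$n, chisq = f$log_rank$statistic,
                 p = f$log_rank$p)
    }))
    .write_tsv(rows, file.path(out_dir, "survival.tsv"))
    files <- c(files, "survival.tsv")
  }
  .write_manifest(out_dir, "validation", files)
  invisible(out_dir)
}
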