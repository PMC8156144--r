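#' Select a fold-change-weighted gene signature
#'
#' Takes the top `k` genes of the significance screen (adjusted p < `alpha`,
#' ordered by raw p, ties by |log2fc| then gene id) and uses their training
#' log2 fold changes as score weights. The screen is mandatory: if fewer than
#' `k` genes pass, an error suggests relaxing `alpha` rather than silently
#' taking an unscreened top-k.
#'
#' @param r Result of [moderated_t_test()] on the training cohort.
#' @param k Number of signature genes.
#' @param alpha Adjusted-p threshold for the significance screen.
#' @param name Signature name.
#' @param training_cohort Free-text provenance label for the training cohort.
#' @return A `signature_model`: list with `genes`, `weights` (named numeric),
#'   `name`, and `provenance` (training cohort, alpha, k, training statistics
#'   of the selected genes).
#' @export
select_signature <- function(r, k = 3L, alpha = 0.05,
                             name = "fc_weighted_signature",
                             training_cohort = "unspecified") {
  stopifnot(is.data.frame(r), k >= 1L)
  sig <- significant_genes(r, alpha)
  if (length(sig) < k) {
    stop("only ", length(sig), " genes pass the adjusted p < ", alpha,
         " screen but k = ", k,
         " were requested; consider relaxing alpha")
  }
  genes <- sig[seq_len(k)]
  rows <- r[match(genes, r$gene_id), , drop = FALSE]
  model <- list(genes = genes,
                weights = stats::setNames(rows$log2fc, genes),
                name = name,
                provenance = list(training_cohort = training_cohort,
                                  alpha = alpha, k = as.integer(k),
                                  training_stats = rows))
  class(model) <- "signature_model"
  model
}

#' Construct a signature model from explicit genes and weights
#'
#' For applying a published signature whose genes and weights are already
#' known (no training data needed).
#'
#' @param genes Character vector of gene ids (unique).
#' @param weights Numeric vector of per-gene weights, same length.
#' @param name Signature name.
#' @return A `signature_model`.
#' @export
signature_model <- function(genes, weights, name = "signature") {
  stopifnot(length(genes) == length(weights), !anyDuplicated(genes),
            is.numeric(weights))
  structure(list(genes = as.character(genes),
                 weights = stats::setNames(as.numeric(weights), genes),
                 name = name,
                 provenance = list(training_cohort = "external",
                                   alpha = NA_real_,
                                   k = length(genes))),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Signature model '", x$name, "' (", length(x$genes), " genes)\n",
      sep = "")
  print(round(x$weights, 6))
  invisible(x)
}

#' Serialize / deserialize a signature model as YAML
#'
#' @param model A `signature_model`.
#' @param path Output (input) path.
#' @return `path` invisibly (`write_signature_model`); a `signature_model`
#'   (`read_signature_model`).
#' @export
write_signature_model <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  yaml::write_yaml(list(name = model$name,
                        genes = as.list(model$genes),
                        weights = as.list(unname(model$weights)),
                        provenance = list(
                          training_cohort = model$provenance$training_cohort,
                          alpha = model$provenance$alpha,
                          k = model$provenance$k)),
                   path)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  y <- yaml::read_yaml(path)
  m <- signature_model(unlist(y$genes), unlist(y$weights), name = y$name)
  if (!is.null(y$provenance)) m$provenance <- utils::modifyList(m$provenance,
                                                                y$provenance)
  m
}

#' Compute per-sample composite signature scores
#'
#' The score of sample s is the weighted sum
#' \eqn{\sum_g w_g \, x_{gs}} over the model genes, applied to log2
#' expression exactly as supplied (no re-scaling). All model genes must be
#' present in the matrix (collapse probes first); nothing is imputed.
#'
#' @param m Numeric log2 expression matrix, genes in rows.
#' @param model A `signature_model`.
#' @param scale If `TRUE`, each signature gene is z-scaled across the samples
#'   of this matrix before weighting — useful when transferring a signature
#'   across platforms whose intensity scales differ. Off by default: the
#'   canonical score applies the raw coefficients to log2 expression as is.
#' @return A `data.frame` with columns `sample_id` and `score`.
#' @export
compute_score <- function(m, model, scale = FALSE) {
  stopifnot(is.matrix(m), inherits(model, "signature_model"))
  missing <- setdiff(model$genes, rownames(m))
  if (length(missing)) {
    stop("signature genes missing from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  sub <- m[model$genes, , drop = FALSE]
  if (scale) {
    mu <- rowMeans(sub)
    sdev <- apply(sub, 1L, stats::sd)
    if (any(sdev == 0)) {
      stop("cannot z-scale: zero variance in gene(s) ",
           paste(model$genes[sdev == 0], collapse = ", "))
    }
    sub <- (sub - mu) / sdev
  }
  score <- as.vector(model$weights[model$genes] %*% sub)
  data.frame(sample_id = colnames(m), score = score,
             stringsAsFactors = FALSE)
}

#' Dichotomize scores at the top fraction of a cohort
#'
#' Labels the `round(n * fraction)` highest-scoring samples "high" and the
#' rest "low" (default: the top one-third of the cohort). Ties at the cut are
#' resolved by sample id in lexicographic order, so the split is
#' deterministic.
#'
#' @param scores `data.frame` with `sample_id` and `score` columns (as from
#'   [compute_score()]).
#' @param fraction Fraction of the cohort labelled high, in (0, 1).
#' @return The input with an added `group` column, a factor with levels
#'   `low`, `high`.
#' @export
dichotomize_top_fraction <- function(scores, fraction = 1 / 3) {
  stopifnot(is.data.frame(scores),
            all(c("sample_id", "score") %in% colnames(scores)),
            fraction > 0, fraction < 1)
  n <- nrow(scores)
  if (n < 3L) stop("need at least 3 samples to dichotomize (got ", n, ")")
  n_high <- round(n * fraction)
  ord <- order(-scores$score, scores$sample_id)
  group <- rep("low", n)
  group[ord[seq_len(n_high)]] <- "high"
  scores$group <- factor(group, levels = c("low", "high"))
  scores
}

#' Single-sample rank-based pathway enrichment score
#'
#' Whole-pathway comparator score: for each sample, genes are ranked by
#' expression within the sample and a running-sum statistic walks down the
#' ranking, stepping up (by the rank weight raised to `weight_exponent`,
#' normalized) at in-set genes and down (by 1/(number of out-of-set genes))
#' at out-of-set genes. The score is the integrated difference over the whole
#' ranking; by construction it depends only on within-sample ranks. With
#' `normalize = TRUE`, scores are divided by the absolute range across the
#' samples of the matrix.
#'
#' @param m Numeric log2 expression matrix, genes in rows.
#' @param gene_set Character vector of set gene ids; at least one must be
#'   present in the matrix.
#' @param weight_exponent Exponent applied to the rank weights (default 0.25).
#' @param normalize Divide by the absolute score range across samples.
#' @return A `data.frame` with columns `sample_id` and `score`.
#' @export
pathway_ssgsea_score <- function(m, gene_set, weight_exponent = 0.25,
                                 normalize = TRUE) {
  stopifnot(is.matrix(m), is.character(gene_set))
  in_set <- rownames(m) %in% gene_set
  if (!any(in_set)) stop("no gene of the set is present in the matrix")
  n_genes <- nrow(m)
  n_out <- sum(!in_set)
  raw <- vapply(seq_len(ncol(m)), function(j) {
    if (n_out == 0L) return(0)  # set == all genes: running sum degenerate
    x <- m[, j]
    # walk ranks from highest expression down; ties broken by gene id for
    # determinism, but tie groups share a midrank weight so the score is a
    # function of ranks only
    ord <- order(-x, rownames(m))
    rk <- rank(x, ties.method = "average")  # high expression = high rank
    w <- rk[ord]^weight_exponent
    step_in <- ifelse(in_set[ord], w, 0)
    step_out <- ifelse(in_set[ord], 0, 1)
    p_in <- cumsum(step_in) / sum(step_in)
    p_out <- cumsum(step_out) / n_out
    sum(p_in - p_out)
  }, numeric(1L))
  score <- raw
  if (normalize && ncol(m) > 1L) {
    rng <- max(raw) - min(raw)
    if (rng > 0) score <- raw / rng
  }
  data.frame(sample_id = colnames(m), score = score,
             stringsAsFactors = FALSE)
}
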