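#' ROC curve and AUC
#'
#' The AUC is computed as the Mann-Whitney probability: the proportion of
#' (positive, negative) sample pairs in which the positive scores higher,
#' ties counted 1/2. The curve is obtained by thresholding at every distinct
#' score. The DeLong variance estimate of the AUC (structural components) is
#' returned alongside.
#'
#' @param scores Numeric per-sample scores (higher = more positive-like).
#' @param labels Binary labels (1/TRUE = positive class); both classes must
#'   be present.
#' @return A `roc_result`: list with `auc`, `curve` (data.frame of `fpr`,
#'   `tpr` from (0,0) to (1,1)), `n_pos`, `n_neg`, `variance`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- .binary_labels(labels, length(scores))
  stopifnot(is.numeric(scores), !anyNA(scores))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute an ROC curve")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last_of_tie <- which(!duplicated(s, fromLast = TRUE))
  curve <- data.frame(
    fpr = c(0, cumsum(1 - l)[last_of_tie] / n_neg),
    tpr = c(0, cumsum(l)[last_of_tie] / n_pos)
  )

  comp <- .delong_components(scores, labels)
  variance <- stats::var(comp$v10) / n_pos + stats::var(comp$v01) / n_neg

  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg,
                 variance = variance),
            class = "roc_result")
}

# DeLong structural components: v10[i] = mean_j psi(pos_i, neg_j),
# v01[j] = mean_i psi(pos_i, neg_j), psi = 1 / 0.5 / 0 for > / = / <.
# Computed via midranks (O(n log n)), the standard fast formulation.
#' @keywords internal
.delong_components <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01)
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Tests whether two scores computed on the same samples have equal AUC
#' against the same binary labels, using DeLong's structural-component
#' covariance estimate and a two-sided normal reference.
#'
#' @param scores_a,scores_b Paired numeric score vectors (same samples).
#' @param labels Binary labels; both classes must be present.
#' @return A `sig_test` list: `statistic` (z), `p`, `effect`
#'   (AUC_a - AUC_b), `method`, plus `auc_a`, `auc_b`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b))
  labels <- .binary_labels(labels, length(scores_a))
  roc_a <- roc_auc(scores_a, labels)
  roc_b <- roc_auc(scores_b, labels)
  ca <- .delong_components(scores_a, labels)
  cb <- .delong_components(scores_b, labels)
  n_pos <- roc_a$n_pos
  n_neg <- roc_a$n_neg
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n_pos +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n_neg
  diff <- roc_a$auc - roc_b$auc
  if (var_diff <= 0 || !is.finite(var_diff)) {
    z <- 0
    p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  .sig_test(z, p, effect = diff, method = "DeLong paired AUC comparison",
            extra = list(auc_a = roc_a$auc, auc_b = roc_b$auc,
                         var_diff = var_diff))
}

#' Per-gene AUC scan
#'
#' AUC of each gene's expression against the binary labels, plus the
#' orientation-free `auc_oriented = max(auc, 1 - auc)`; rows ordered by
#' `auc_oriented` descending (ties by gene id).
#'
#' @param m Numeric log2 expression matrix, genes in rows.
#' @param labels Binary per-sample labels.
#' @param genes Optional gene subset; at least one listed gene must be
#'   present, absent ones are dropped.
#' @return `data.frame` with columns `gene_id`, `auc`, `auc_oriented`.
#' @export
per_gene_auc_scan <- function(m, labels, genes = NULL) {
  stopifnot(is.matrix(m))
  labels <- .binary_labels(labels, ncol(m))
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(m))
    if (length(genes) == 0L) stop("no listed gene is present in the matrix")
    m <- m[genes, , drop = FALSE]
  }
  auc <- apply(m, 1L, function(x) roc_auc(x, labels)$auc)
  out <- data.frame(gene_id = rownames(m), auc = auc,
                    auc_oriented = pmax(auc, 1 - auc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$auc_oriented, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summing the hypergeometric probabilities of all tables
#' (conditional on the margins) as or less probable than the observed one —
#' the convention of [stats::fisher.test()], to which this delegates. The
#' effect is the sample odds ratio `(a*d)/(b*c)` (0/Inf allowed).
#'
#' @param a,b,c,d Non-negative integer counts, laid out as
#'   `rbind(c(a, b), c(c, d))`.
#' @return A `sig_test` with `statistic` (the count `a`), `p`, `effect`
#'   (odds ratio).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative")
  }
  if (sum(counts) == 0) stop("at least one margin must be positive")
  tab <- matrix(counts, nrow = 2L, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  or <- (a * d) / (b * c)
  .sig_test(a, p, effect = or, method = "Fisher's exact test (two-sided)")
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. Uses the exact null distribution when
#' the combined size is at most 12 and there are no ties; otherwise the
#' normal approximation with midrank ties, tie-corrected variance, and
#' continuity correction. Two-sided throughout. Delegates to
#' [stats::wilcox.test()]; a degenerate comparison (zero rank variance, all
#' observations identical) returns p = 1 by convention.
#'
#' @param x,y Numeric samples, both nonempty.
#' @return A `sig_test` with `statistic` (U for `x`), `p`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  ties <- anyDuplicated(c(x, y)) > 0L
  u <- sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  if (length(unique(c(x, y))) == 1L) {
    return(.sig_test(u, 1, method = "Mann-Whitney U test (degenerate)"))
  }
  exact <- !ties && (length(x) + length(y)) <= 12L
  res <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  .sig_test(u, res$p.value,
            method = if (exact) "Mann-Whitney U test (exact)" else
              "Mann-Whitney U test (normal approximation)")
}

#' Kruskal-Wallis rank test across two or more groups
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom, via [stats::kruskal.test()]. All observations identical yields
#' H = 0, p = 1 by convention.
#'
#' @param groups List of two or more nonempty numeric vectors.
#' @return A `sig_test` with `statistic` (H), `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(lengths(groups) >= 1L))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(.sig_test(0, 1, method = "Kruskal-Wallis test (degenerate)"))
  }
  res <- stats::kruskal.test(groups)
  .sig_test(unname(res$statistic), res$p.value,
            method = "Kruskal-Wallis test")
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks; the p-value uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom, two-sided. Errors when either vector has zero rank variance
#' (rho undefined).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A `sig_test` with `statistic` (t), `p`, `effect` (rho).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            !anyNA(x), !anyNA(y))
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("Spearman rho undefined: zero rank variance in one of the vectors")
  }
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (abs(rho) >= 1) {
    tstat <- sign(rho) * Inf
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  .sig_test(tstat, p, effect = rho,
            method = "Spearman rank correlation (t approximation)")
}

#' @keywords internal
.sig_test <- function(statistic, p, effect = NA_real_, method = "",
                      extra = NULL) {
  out <- c(list(statistic = unname(statistic), p = unname(p),
                effect = unname(effect), method = method), extra)
  class(out) <- "sig_test"
  out
}

#' @export
print.sig_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic),
      ", p = ", format(x$p), sep = "")
  if (!is.na(x$effect)) cat(", effect = ", format(x$effect), sep = "")
  cat("\n")
  invisible(x)
}
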