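#' Empirical-Bayes moderated two-group differential expression
#'
#' For each gene, computes the log2 fold change (group 1 minus group 0 mean),
#' a moderated t-statistic with empirical-Bayes shrunken variance, and raw and
#' Benjamini-Hochberg adjusted two-sided p-values. The pooled per-gene
#' residual variance \eqn{s_g^2} (with \eqn{d_g = n_0 + n_1 - 2} degrees of
#' freedom) is shrunk towards a prior \eqn{s_0^2} with prior degrees of
#' freedom \eqn{d_0}, both fitted by method of moments on
#' \eqn{\log s_g^2} across the tested genes (the standard scaled-F
#' hierarchical model for array variances):
#' \deqn{\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
#'       t_g = \frac{\bar{x}_{1g} - \bar{x}_{0g}}
#'                  {\tilde{s}_g \sqrt{1/n_0 + 1/n_1}},}
#' with p-values from a t distribution on \eqn{d_0 + d_g} degrees of freedom.
#' When the moment estimate of \eqn{d_0} is infinite, \eqn{\tilde{s}_g^2 =
#' s_0^2} for every gene and the reference distribution is normal.
#'
#' Zero-variance genes: when the shrunken standard error is exactly zero
#' (possible only if the prior variance is also degenerate), `t_mod` is 0 and
#' p is 1 for a zero fold change; a nonzero fold change against a zero
#' standard error yields an infinite statistic and p = 0.
#'
#' @param m Numeric log2 expression matrix, genes in rows.
#' @param labels Binary per-sample group labels (0/1, logical, or a two-level
#'   factor), aligned with `colnames(m)`; group 1 is the "responder" group.
#' @param genes Optional character vector restricting the test to a gene
#'   subset (e.g. a pathway); all requested genes must be present.
#' @param prior_df Optional override of the prior degrees of freedom
#'   \eqn{d_0}: `0` gives the ordinary pooled two-sample t-test, `Inf` fully
#'   shrinks every gene to the common prior variance. `NULL` (default) fits
#'   \eqn{d_0} from the data.
#' @return A `data.frame` (rows ordered by `p_raw` ascending, ties by
#'   |log2fc| descending then gene id) with columns `gene_id`, `log2fc`,
#'   `t_mod`, `df_total`, `p_raw`, `p_adj`, `mean0`, `mean1`, and attributes
#'   `df_prior` and `var_prior`.
#' @export
moderated_t_test <- function(m, labels, genes = NULL, prior_df = NULL) {
  stopifnot(is.matrix(m), is.numeric(m))
  labels <- .binary_labels(labels, ncol(m))
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      stop("genes not present in matrix: ", paste(missing, collapse = ", "))
    }
    m <- m[genes, , drop = FALSE]
  }
  n0 <- sum(labels == 0L)
  n1 <- sum(labels == 1L)
  if (n0 < 2L || n1 < 2L) {
    stop("each group needs at least 2 samples (got ", n0, " and ", n1, ")")
  }
  x0 <- m[, labels == 0L, drop = FALSE]
  x1 <- m[, labels == 1L, drop = FALSE]
  mean0 <- rowMeans(x0)
  mean1 <- rowMeans(x1)
  df_resid <- n0 + n1 - 2L
  s2 <- (rowSums((x0 - mean0)^2) + rowSums((x1 - mean1)^2)) / df_resid

  if (is.null(prior_df)) {
    fit <- .fit_scaled_f(s2, df_resid)
  } else {
    stopifnot(length(prior_df) == 1L, prior_df >= 0)
    fit <- list(df_prior = prior_df,
                var_prior = .prior_var_given_df(s2, df_resid, prior_df))
  }
  d0 <- fit$df_prior
  s02 <- fit$var_prior

  s2_post <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s02 + df_resid * s2) / (d0 + df_resid)
  }
  log2fc <- mean1 - mean0
  se <- sqrt(s2_post * (1 / n0 + 1 / n1))
  t_mod <- ifelse(se > 0, log2fc / se,
                  ifelse(log2fc == 0, 0, sign(log2fc) * Inf))
  df_total <- d0 + df_resid
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)

  out <- data.frame(gene_id = rownames(m), log2fc = log2fc, t_mod = t_mod,
                    df_total = rep(df_total, length(log2fc)),
                    p_raw = p_raw, p_adj = benjamini_hochberg(p_raw),
                    mean0 = mean0, mean1 = mean1,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, -abs(out$log2fc), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "df_prior") <- d0
  attr(out, "var_prior") <- s02
  out
}

# Method-of-moments fit of the scaled-F variance prior on log(s^2):
# s^2 ~ s0^2 F(d, d0), so with z = log s^2,
#   E[z]   = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)
#   Var[z] = trigamma(d/2) + trigamma(d0/2).
#' @keywords internal
.fit_scaled_f <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2L) {
    return(list(df_prior = Inf,
                var_prior = if (any(ok)) exp(.e_values(s2[ok], df)) else 0))
  }
  e <- .e_values(s2[ok], df)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    list(df_prior = Inf, var_prior = exp(emean))
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    list(df_prior = d0,
         var_prior = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' @keywords internal
.e_values <- function(s2, df) {
  log(s2) - digamma(df / 2) + log(df / 2)
}

#' @keywords internal
.prior_var_given_df <- function(s2, df, d0) {
  ok <- s2 > 0
  if (!any(ok)) return(0)
  emean <- mean(.e_values(s2[ok], df))
  if (is.infinite(d0)) exp(emean) else if (d0 == 0) NA_real_ else {
    exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
}

# Newton solve of trigamma(y) = x; monotone decreasing, so convergence is
# fast from the asymptotic start y ~ 0.5 + 1/x.
#' @keywords internal
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment: with order statistics \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, the adjusted value of \eqn{p_{(i)}} is
#' \eqn{\min_{j \ge i} \min(1, p_{(j)} m / j)}, returned in input order.
#' Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Significant genes from a differential-expression result
#'
#' Genes with adjusted p below `alpha`, ordered by raw p ascending; ties are
#' broken by |log2fc| descending, then gene id, so selection is deterministic.
#'
#' @param r Result of [moderated_t_test()].
#' @param alpha Adjusted-p significance threshold.
#' @return Character vector of gene ids (possibly empty).
#' @export
significant_genes <- function(r, alpha = 0.05) {
  stopifnot(is.data.frame(r), nrow(r) >= 1L)
  hits <- r[r$p_adj < alpha, , drop = FALSE]
  hits <- hits[order(hits$p_raw, -abs(hits$log2fc), hits$gene_id), ,
               drop = FALSE]
  hits$gene_id
}

#' @keywords internal
.binary_labels <- function(labels, n) {
  if (length(labels) != n) {
    stop("labels length (", length(labels), ") != number of samples (", n, ")")
  }
  if (is.factor(labels) || is.character(labels)) {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) > 2L) stop("labels must be binary; got levels: ",
                              paste(lv, collapse = ", "))
    labels <- as.integer(as.character(labels) == lv[length(lv)])
  }
  labels <- as.integer(as.logical(as.numeric(labels)))
  if (anyNA(labels)) stop("labels contain missing values")
  labels
}
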