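test_that("AUC handles perfect separation and all-tied scores", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC equals brute-force pair counting and the trapezoid area", {
  set.seed(20)
  for (rep in 1:20) {
    n <- 30
    labels <- c(rep(1, 10), rep(0, 20))
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties sometimes
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_pairs(scores, labels), tolerance = 1e-12)
    trap <- sum(diff(r$curve$fpr) *
                  (head(r$curve$tpr, -1) + tail(r$curve$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-10)
    expect_identical(c(r$curve$fpr[1], r$curve$tpr[1]), c(0, 0))
    expect_identical(c(tail(r$curve$fpr, 1), tail(r$curve$tpr, 1)), c(1, 1))
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
  }
})

test_that("AUC antisymmetry and monotone-transform invariance hold", {
  set.seed(21)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  expect_equal(roc_auc(scores, labels)$auc + roc_auc(-scores, labels)$auc, 1)
  expect_equal(roc_auc(scores, labels)$auc,
               roc_auc(plogis(scores) * 7 + 1, labels)$auc)
})

test_that("DeLong AUC and variance agree with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(22)
  labels <- rbinom(120, 1, 0.4)
  a <- labels + rnorm(120)
  b <- labels + rnorm(120)
  mine <- delong_compare(a, b, labels)
  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE),
                        pROC::roc(labels, b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_equal(abs(mine$statistic), abs(unname(ref$statistic)),
               tolerance = 1e-10)
  single <- roc_auc(a, labels)
  expect_equal(single$variance,
               unname(pROC::var(pROC::roc(labels, a, quiet = TRUE),
                                method = "delong")),
               tolerance = 1e-10)
})

test_that("identical paired scores give z = 0 and p = 1", {
  set.seed(23)
  s <- rnorm(30)
  lab <- rep(c(0, 1), 15)
  res <- delong_compare(s, s, lab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("DeLong variance is close to the bootstrap variance", {
  set.seed(24)
  n <- 200
  labels <- rep(c(0, 1), each = 100)
  scores <- labels * 0.8 + rnorm(n)
  r <- roc_auc(scores, labels)
  boot <- replicate(2000, {
    i <- c(sample(which(labels == 1), 100, TRUE),
           sample(which(labels == 0), 100, TRUE))
    roc_auc(scores[i], labels[i])$auc
  })
  expect_lt(abs(r$variance - var(boot)) / var(boot), 0.15)
})

test_that("per-gene AUC scan orients, orders, and ranks planted genes first", {
  m <- random_expression(6, 40, seed = 25)
  labels <- rep(c(0, 1), 20)
  m["G001", ] <- m["G001", ] + labels * 3   # strong up
  m["G002", ] <- m["G002", ] - labels * 3   # strong down
  scan <- per_gene_auc_scan(m, labels)
  expect_identical(sort(scan$gene_id[1:2]), c("G001", "G002"))
  expect_true(all(diff(scan$auc_oriented) <= 0))
  # a gene and its negation: auc_a + auc_b = 1 exactly
  m2 <- rbind(X = m["G001", ], NEGX = -m["G001", ])
  scan2 <- per_gene_auc_scan(m2, labels)
  expect_equal(sum(scan2$auc), 1)
  expect_equal(scan2$auc_oriented[1], scan2$auc_oriented[2])
})

test_that("Fisher exact matches the closed-form extreme-table cases", {
  expect_equal(fisher_exact_2x2(5, 0, 0, 5)$p, 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(3, 3, 3, 3)$p, 1)
  expect_equal(fisher_exact_2x2(6, 2, 1, 5)$effect, 15)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "positive")
})

test_that("Fisher exact equals hypergeometric enumeration on random tables", {
  set.seed(26)
  for (rep in 1:200) {
    tab <- rpois(4, lambda = sample(1:8, 1))
    if (sum(tab[1:2]) == 0 || sum(tab[3:4]) == 0 ||
        sum(tab[c(1, 3)]) == 0 || sum(tab[c(2, 4)]) == 0) next
    p <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])$p
    expect_equal(p, fisher_enumerate(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
  }
})

test_that("Fisher p is invariant under row and column swaps", {
  set.seed(27)
  for (rep in 1:25) {
    t4 <- rpois(4, 5) + 1
    p0 <- fisher_exact_2x2(t4[1], t4[2], t4[3], t4[4])$p
    expect_equal(fisher_exact_2x2(t4[3], t4[4], t4[1], t4[2])$p, p0)
    expect_equal(fisher_exact_2x2(t4[2], t4[1], t4[4], t4[3])$p, p0)
  }
})

test_that("Mann-Whitney U matches small-sample enumeration", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 2 / 6, tolerance = 1e-12)
  # identical samples: z ~ 0, p near 1
  expect_gt(mann_whitney_u(1:20, 1:20)$p, 0.95)
  expect_equal(mann_whitney_u(rep(1, 3), rep(1, 4))$p, 1)
})

test_that("Kruskal-Wallis is consistent with Mann-Whitney on two groups", {
  set.seed(28)
  for (rep in 1:20) {
    x <- rnorm(25)
    y <- rnorm(25, mean = runif(1, 0, 1))
    kw <- kruskal_wallis(list(x, y))
    mw <- mann_whitney_u(x, y)
    expect_lt(abs(kw$p - mw$p), 0.02)
  }
  expect_equal(kruskal_wallis(list(rep(1, 4), rep(1, 4)))$statistic, 0)
})

test_that("Kruskal-Wallis detects shifted groups", {
  set.seed(29)
  hits <- mean(replicate(40, {
    g <- lapply(0:2, function(k) rnorm(30, mean = k))
    kruskal_wallis(g)$p < 0.001
  }))
  expect_gte(hits, 0.95)
})

test_that("Spearman rho matches midrank Pearson with a t-approximation p", {
  expect_equal(spearman_rho(1:10, 1:10)$effect, 1)
  expect_equal(spearman_rho(1:10, 10:1)$effect, -1)
  set.seed(30)
  for (rep in 1:20) {
    x <- sample(1:8, 20, replace = TRUE)  # heavy ties
    y <- x + rnorm(20, sd = 2)
    res <- spearman_rho(x, y)
    rho <- cor(rank(x), rank(y))
    expect_equal(res$effect, rho, tolerance = 1e-12)
    tref <- rho * sqrt(18 / (1 - rho^2))
    expect_equal(res$p, 2 * pt(-abs(tref), 18), tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "zero rank variance")
})
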