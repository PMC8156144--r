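paper_weights <- c(CDKN2C = 0.539914, DEK = 0.487451, MCM3 = 0.313544)

test_that("selection recovers planted genes with weights near truth", {
  ok_genes <- 0
  ok_weights <- 0
  for (s in 1:30) {
    ch <- strong_cohort(seed = 200 + s)
    labels <- as.integer(ch$clinical$response == "pCR")
    d <- moderated_t_test(ch$expression, labels,
                          genes = ch$gene_sets$SIM_PATHWAY)
    model <- tryCatch(select_signature(d, k = 3, alpha = 0.05),
                      error = function(e) NULL)
    if (is.null(model)) next
    if (setequal(model$genes, ch$truth$planted_genes)) {
      ok_genes <- ok_genes + 1
      truth <- c(1.6, 1.2, 1.0)[match(model$genes, ch$truth$planted_genes)]
      n1 <- sum(labels == 1)
      n0 <- sum(labels == 0)
      se <- sqrt(1 / n0 + 1 / n1)  # noise sd is 1
      if (all(abs(model$weights - truth) < 3 * se)) {
        ok_weights <- ok_weights + 1
      }
    }
  }
  expect_gte(ok_genes, 27)
  expect_gte(ok_weights, 25)
})

test_that("selection refuses to bypass the significance screen", {
  ch <- simulate_null_cohort(60, 100, seed = 42)
  labels <- as.integer(ch$clinical$response == "pCR")
  d <- moderated_t_test(ch$expression, labels)
  expect_error(select_signature(d, k = 3, alpha = 0.05), "relaxing alpha")
})

test_that("selection tie-breaks are deterministic (|log2fc| then id)", {
  r <- data.frame(gene_id = c("Z", "A", "M"),
                  log2fc = c(0.9, 0.9, -1.2),
                  t_mod = 5, df_total = 10,
                  p_raw = c(0.001, 0.001, 0.001),
                  p_adj = c(0.003, 0.003, 0.003),
                  mean0 = 0, mean1 = 1)
  model <- select_signature(r, k = 3, alpha = 0.05)
  expect_identical(model$genes, c("M", "A", "Z"))
})

test_that("composite score is the printed-weight linear combination", {
  m <- matrix(1, nrow = 3, ncol = 2,
              dimnames = list(names(paper_weights), c("S1", "S2")))
  model <- signature_model(names(paper_weights), paper_weights)
  sc <- compute_score(m, model)
  expect_equal(sc$score, rep(1.340909, 2), tolerance = 1e-9)
  expect_equal(compute_score(m * 0, model)$score, c(0, 0))
})

test_that("compute_score matches a brute-force per-sample loop", {
  m <- random_expression(3, 10, seed = 14)
  w <- c(0.5, -0.25, 1.5)
  model <- signature_model(rownames(m), w)
  sc <- compute_score(m, model)
  manual <- vapply(seq_len(ncol(m)), function(j) sum(w * m[, j]), numeric(1))
  expect_equal(sc$score, manual, tolerance = 1e-12)
})

test_that("optional z-scaling standardizes genes before weighting", {
  m <- random_expression(4, 30, seed = 55)
  model <- signature_model(rownames(m)[1:2], c(2, -1))
  sc <- compute_score(m, model, scale = TRUE)
  z <- t(scale(t(m[1:2, ])))
  expect_equal(sc$score, as.vector(c(2, -1) %*% z), tolerance = 1e-12)
  flat <- m
  flat["G001", ] <- 5
  expect_error(compute_score(flat, model, scale = TRUE), "zero variance")
})

test_that("compute_score ignores gene order and extra matrix rows", {
  m <- random_expression(10, 5, seed = 15)
  model <- signature_model(c("G003", "G007", "G001"), c(1, 2, 3))
  shuffled <- signature_model(c("G001", "G003", "G007"), c(3, 1, 2))
  expect_equal(compute_score(m, model)$score,
               compute_score(m, shuffled)$score)
  expect_equal(compute_score(m, model)$score,
               compute_score(m[1:8, ], model)$score)
  expect_error(compute_score(m[4:10, ], model), "G001")
})

test_that("signature model round-trips through YAML", {
  model <- signature_model(names(paper_weights), paper_weights,
                           name = "three_gene")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_signature_model(model, path)
  back <- read_signature_model(path)
  expect_identical(back$genes, model$genes)
  expect_equal(back$weights, model$weights)
  expect_identical(back$name, "three_gene")
})

test_that("tertile dichotomization sizes and tie rules are exact", {
  sc <- data.frame(sample_id = c("S1", "S2", "S3"), score = c(1, 2, 3))
  out <- dichotomize_top_fraction(sc)
  expect_identical(as.character(out$group), c("low", "low", "high"))

  set.seed(16)
  sc170 <- data.frame(sample_id = sprintf("S%03d", 1:170), score = rnorm(170))
  expect_identical(sum(dichotomize_top_fraction(sc170)$group == "high"), 57L)

  ties <- data.frame(sample_id = sprintf("S%d", 9:1), score = rep(1, 9))
  out <- dichotomize_top_fraction(ties)
  expect_identical(sort(out$sample_id[out$group == "high"]),
                   c("S1", "S2", "S3"))
})

test_that("dichotomization is monotone in the score", {
  set.seed(17)
  sc <- data.frame(sample_id = sprintf("S%02d", 1:30), score = rnorm(30))
  base <- dichotomize_top_fraction(sc)
  for (i in c(1, 15, 30)) {
    bumped <- sc
    bumped$score[i] <- bumped$score[i] + 10
    out <- dichotomize_top_fraction(bumped)
    if (base$group[i] == "high") expect_identical(out$group[i], base$group[i])
    expect_identical(as.character(out$group[i]), "high")
  }
})

test_that("pathway score is maximal when set genes top the ranking", {
  genes <- sprintf("G%d", 1:8)
  set_genes <- genes[1:3]
  base <- matrix(8:1, ncol = 1, dimnames = list(genes, "S1"))
  best <- pathway_ssgsea_score(base, set_genes, normalize = FALSE)$score
  slots <- combn(8, 3)  # which rank slots (1 = top) the set genes occupy
  for (j in seq_len(ncol(slots))) {
    m <- matrix(0, nrow = 8, ncol = 1, dimnames = list(genes, "S1"))
    m[set_genes, 1] <- (8:1)[slots[, j]]
    m[setdiff(genes, set_genes), 1] <- (8:1)[-slots[, j]]
    sc <- pathway_ssgsea_score(m, set_genes, normalize = FALSE)$score
    expect_lte(sc, best + 1e-12)
  }
})

test_that("pathway score depends only on within-sample ranks", {
  m <- random_expression(20, 4, seed = 18)
  raw <- pathway_ssgsea_score(m, rownames(m)[1:5])
  mono <- pathway_ssgsea_score(exp(m / 3) + 2, rownames(m)[1:5])
  expect_equal(raw$score, mono$score, tolerance = 1e-12)
  # two samples with identical rank order score identically
  m2 <- cbind(m[, 1, drop = FALSE], S_dup = rank(m[, 1]) * 100)
  sc <- pathway_ssgsea_score(m2, rownames(m)[1:5], normalize = FALSE)
  expect_equal(sc$score[1], sc$score[2], tolerance = 1e-12)
})

test_that("pathway score degenerate cases follow the documented conventions", {
  m <- random_expression(6, 3, seed = 19)
  expect_equal(pathway_ssgsea_score(m, rownames(m))$score, rep(0, 3))
  expect_error(pathway_ssgsea_score(m, c("NOPE1", "NOPE2")), "no gene")
})
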