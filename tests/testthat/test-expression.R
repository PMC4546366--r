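make_matrix <- function(x, classes, genes = NULL, trait = NULL) {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(x)))
  rownames(x) <- sprintf("P%03d", seq_len(nrow(x)))
  expression_matrix(x, data.frame(probe_id = rownames(x),
                                  gene_symbol = genes),
                    classes = classes, trait = trait)
}

test_that("probe filtering applies the three rules and is idempotent", {
  set.seed(2)
  n <- 12
  cl <- rep(c("a", "b", "c"), each = 4)
  base <- matrix(exp(rnorm(50 * n, log(400), 0.5)), 50, n)
  x <- rbind(base,
             matrix(200, 2, n),                         # constant: fails (b)
             matrix(exp(rnorm(2 * n, log(50), 0.5)), 2, n),  # dim: fails (a)
             exp(rnorm(n, log(400), 0.1)))              # low-variance
  m <- make_matrix(x, cl)
  f <- filter_probes(m)
  aud <- f$filter_audit
  expect_gte(aud$n_fail_intensity, 2)
  expect_gte(aud$n_fail_logvar, 2)
  expect_false(any(c("P051", "P052", "P053", "P054") %in%
                     f$probes$probe_id))
  # idempotence via the stored reference variance
  f2 <- filter_probes(f)
  expect_identical(f$intensity, f2$intensity)
  expect_identical(f$probes, f2$probes)
})

test_that("the 33rd-percentile intensity gate is a strict boundary", {
  n <- 9
  lowq <- rep(300, n); lowq[1:4] <- 60     # 33rd percentile just below 125
  q <- unname(quantile(lowq, 0.33))
  expect_lt(q, 125)
  x <- rbind(matrix(rep(lowq, each = 1), 1, n, byrow = TRUE),
             matrix(exp(rnorm(30 * n, log(400), 0.6)), 30, n))
  m <- make_matrix(x, rep(c("a", "b", "c"), each = 3))
  f <- filter_probes(m)
  expect_false("P001" %in% f$probes$probe_id)
})

test_that("per-gene collapse keeps the most variable probe by IQR", {
  set.seed(4)
  n <- 9
  narrow <- exp(log(400) + rnorm(n, 0, 0.3))
  wide <- exp(log(400) + rnorm(n, 0, 1.5))
  filler <- matrix(exp(rnorm(40 * n, log(400), 0.6)), 40, n)
  x <- rbind(narrow, wide, filler)
  m <- make_matrix(x, rep(c("a", "b", "c"), each = 3),
                   genes = c("DUP", "DUP", sprintf("G%03d", 3:42)))
  f <- filter_probes(m)
  kept <- f$probes$probe_id[f$probes$gene_symbol == "DUP"]
  iqr1 <- IQR(log2(narrow)); iqr2 <- IQR(log2(wide))
  expect_equal(kept, if (iqr2 > iqr1) "P002" else "P001")
  expect_equal(sum(f$probes$gene_symbol == "DUP"), 1L)
})

test_that("class screen finds a separable signal and is seed-deterministic", {
  set.seed(6)
  n <- 6
  cl <- rep(c("a", "b"), each = 3)
  x <- matrix(exp(rnorm(100 * n, log(400), 0.2)), 100, n)
  x[1:5, cl == "b"] <- x[1:5, cl == "b"] * 50   # huge effect, 5 genes
  m <- make_matrix(x, cl)
  r1 <- multivariate_permutation_f(m, n_perm = 500, seed = 9)
  expect_setequal(r1$significant$gene, sprintf("G%03d", 1:5))
  r2 <- multivariate_permutation_f(m, n_perm = 500, seed = 9)
  expect_identical(r1$significant, r2$significant)
})

test_that("small class designs are enumerated exhaustively and reproducibly", {
  set.seed(8)
  cl <- rep(c("a", "b", "c"), each = 2)       # 6!/(2!2!2!) = 90 arrangements
  x <- matrix(exp(rnorm(10 * 6, log(300), 0.3)), 10, 6)
  m <- make_matrix(x, cl)
  r1 <- multivariate_permutation_f(m, n_perm = 1000, seed = 1)
  r2 <- multivariate_permutation_f(m, n_perm = 1000, seed = 999)
  expect_true(r1$exhaustive)
  expect_equal(r1$n_perm_used, 90)
  # enumeration makes the result seed-independent
  expect_identical(r1$significant, r2$significant)
  expect_identical(r1$stats$perm_p, r2$stats$perm_p)
})

test_that("the significant list is nested in fdr and confidence", {
  set.seed(10)
  cl <- rep(c("a", "b", "c"), each = 4)
  x <- matrix(exp(rnorm(80 * 12, log(300), 0.3)), 80, 12)
  x[1:10, cl == "b"] <- x[1:10, cl == "b"] * 3
  m <- make_matrix(x, cl)
  k1 <- multivariate_permutation_f(m, fdr = 0.05, n_perm = 300,
                                   seed = 2)$n_significant
  k2 <- multivariate_permutation_f(m, fdr = 0.20, n_perm = 300,
                                   seed = 2)$n_significant
  k3 <- multivariate_permutation_f(m, fdr = 0.05, conf = 0.5, n_perm = 300,
                                   seed = 2)$n_significant
  expect_gte(k2, k1)
  expect_gte(k3, k1)
})

test_that("pairwise fold-change gates match a direct rule evaluation", {
  set.seed(12)
  n_per <- 4
  cl <- rep(c("sham", "MI", "MI+Val"), each = n_per)
  x <- matrix(exp(rnorm(60 * 12, log(300), 0.15)), 60, 12)
  x[1, cl == "MI"] <- x[1, cl == "MI"] * 3        # strong, passes both gates
  x[2, cl == "MI"] <- x[2, cl == "MI"] * 1.12     # p small, FC below 1.2
  m <- make_matrix(x, cl)
  res <- pairwise_fc_filter(m, alpha = 0.01, fc = 1.2)

  # oracle: per-gene direct application of both gates
  lx <- log2(x)
  for (gene in c(1, 2, 7)) {
    pass <- FALSE
    for (cmp in list(c("MI", "sham"), c("MI", "MI+Val"))) {
      p <- t.test(lx[gene, cl == cmp[1]], lx[gene, cl == cmp[2]],
                  var.equal = TRUE)$p.value
      fcl <- mean(x[gene, cl == cmp[1]]) / mean(x[gene, cl == cmp[2]])
      fcs <- if (fcl >= 1) fcl else -1 / fcl
      pass <- pass || (p < 0.01 && abs(fcs) >= 1.2)
    }
    expect_equal(res$all$survives[gene], pass)
  }
  expect_true(res$all$survives[1])
  expect_false(res$all$survives[2])   # blocked by the FC gate

  # identical group means -> empty set
  m0 <- make_matrix(matrix(300, 20, 12), cl)
  expect_equal(nrow(pairwise_fc_filter(m0)$survivors), 0L)
  expect_error(pairwise_fc_filter(m, fc = 0.8), "fc")
})

test_that("trait screen returns exact linear genes and is deterministic", {
  set.seed(14)
  n <- 8
  trait <- c(70, 65, 30, 25, 20, 35, 60, 45)
  x <- matrix(exp(rnorm(50 * n, log(300), 0.3)), 50, n)
  x[1, ] <- exp(10 - 0.05 * trait)         # exact negative linear in log
  x[2, ] <- exp(2 + 0.04 * trait)          # exact positive
  m <- make_matrix(x, rep(c("a", "b"), each = 4), trait = trait)
  r <- quantitative_trait_corr(m, n_perm = 400, seed = 3)
  expect_true(all(c("G001", "G002") %in% r$significant$gene))
  expect_equal(r$stats$r[1], -1, tolerance = 1e-12)
  expect_equal(r$stats$r[2], 1, tolerance = 1e-12)
  r2 <- quantitative_trait_corr(m, n_perm = 400, seed = 3)
  expect_identical(r$significant, r2$significant)
  expect_error(quantitative_trait_corr(m, trait = rep(1, n)),
               "zero-variance")
})

test_that("expression TSV and annotation round-trip preserves the object", {
  set.seed(16)
  cl <- rep(c("sham", "MI"), each = 3)
  m <- generate_expression(cl, n_genes = 30, n_class_effect = 5,
                           n_trait = 0, n_dup_genes = 3, seed = 20)
  mat_path <- withr::local_tempfile(fileext = ".tsv")
  ann_path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(probe_id = m$probes$probe_id,
                   gene_symbol = m$probes$gene_symbol,
                   m$intensity, check.names = FALSE)
  utils::write.table(df, mat_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(data.frame(sample = colnames(m$intensity),
                              class = as.character(m$classes)),
                   ann_path, row.names = FALSE)
  rt <- read_expression_tsv(mat_path, ann_path)
  expect_equal(rt$intensity, m$intensity, tolerance = 1e-10)
  expect_equal(as.character(rt$classes), as.character(m$classes))
})

test_that("GEO series-matrix parsing extracts the expression table", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "!Series_title\t\"synthetic example\"",
    "!series_matrix_table_begin",
    paste("ID_REF", "GSM1", "GSM2", "GSM3", "GSM4", sep = "\t"),
    paste("p1", "10", "12", "30", "31", sep = "\t"),
    paste("p2", "5", "6", "5", "6", sep = "\t"),
    "!series_matrix_table_end"), path)
  m <- read_series_matrix(path, classes = c("x", "x", "y", "y"))
  expect_equal(dim(m$intensity), c(2L, 4L))
  expect_equal(unname(m$intensity["p1", ]), c(10, 12, 30, 31))
})
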