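# Cross-genome comparison statistics.

test_that("column scaling gives mean 0 / sample sd 1 and is idempotent", {
  expect_equal(unname(scale_columns(matrix(c(1, 2, 3), ncol = 1))[, 1]),
               c(-1, 0, 1))
  set.seed(21)
  m <- matrix(rnorm(60, 5, 3), nrow = 12,
              dimnames = list(NULL, paste0("m", 1:5)))
  m[3, 2] <- NA   # missing entries ignored and preserved
  s <- scale_columns(m)
  for (j in 1:5) {
    v <- s[, j][!is.na(s[, j])]
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(stats::sd(v), 1, tolerance = 1e-9)
  }
  expect_true(is.na(s[3, 2]))
  expect_equal(scale_columns(s), s, tolerance = 1e-12)   # idempotent
  mc <- m; mc[, 3] <- 7
  expect_error(scale_columns(mc), "m3")
})

test_that("line fitting matches the closed-form normal-equations oracle", {
  f <- fit_line(1:5, 2 * (1:5) + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  fc <- fit_line(1:5, rep(3, 5))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)

  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(10); y <- 1.5 * x + rnorm(10, sd = 0.6)
    f <- fit_line(x, y)
    # oracle: explicit normal equations + incomplete-beta p-value
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    sst <- sum((y - mean(y))^2); ssr <- sum(res^2)
    s2 <- ssr / (length(x) - 2)
    se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
    tt <- beta[2] / se
    df <- length(x) - 2
    p_oracle <- stats::pbeta(df / (df + tt^2), df / 2, 1 / 2)
    expect_equal(f$slope, beta[2], tolerance = 1e-9)
    expect_equal(f$intercept, beta[1], tolerance = 1e-9)
    expect_equal(f$r_squared, 1 - ssr / sst, tolerance = 1e-9)
    expect_equal(f$p_value, p_oracle, tolerance = 1e-9)
    expect_equal(f$stderr, se, tolerance = 1e-9)
  }
  expect_error(fit_line(rep(1, 5), 1:5), "constant")
  expect_error(fit_line(1:2, 1:2), "at least 3")
})

test_that("fit_line is equivariant under scaling of y", {
  set.seed(4)
  x <- rnorm(20); y <- 2 * x + rnorm(20)
  f1 <- fit_line(x, y)
  f2 <- fit_line(x, 10 * y)
  expect_equal(f2$slope, 10 * f1$slope, tolerance = 1e-9)
  expect_equal(f2$intercept, 10 * f1$intercept, tolerance = 1e-9)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-12)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-12)
})

test_that("PCA loadings are orthonormal and reconstruct the input", {
  set.seed(31)
  base <- rnorm(20)
  m <- scale_columns(cbind(a = base + rnorm(20, sd = 1e-9), b = base,
                           c = rnorm(20)))
  p <- pca_measures(m, 3)
  expect_equal(unname(t(p$loadings) %*% p$loadings), diag(3),
               tolerance = 1e-9)
  expect_true(all(diff(p$variance_fractions) <= 1e-12))
  expect_lte(sum(p$variance_fractions), 1 + 1e-12)
  # two perfectly correlated columns: first component of their pair
  m2 <- scale_columns(cbind(x = base, y = 3 * base + 2))
  p2 <- pca_measures(m2, 2)
  expect_equal(p2$variance_fractions[1], 1, tolerance = 1e-9)
  # full-rank reconstruction
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon, m, tolerance = 1e-8)
  # sign convention
  for (j in 1:3) {
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }
  expect_error(pca_measures(m, 4), "exceeds")
})

test_that("PCA variance fractions are invariant under genome reordering", {
  set.seed(12)
  m <- scale_columns(matrix(rnorm(50), nrow = 10))
  p1 <- pca_measures(m, 3)
  p2 <- pca_measures(m[sample(10), ], 3)
  expect_equal(p1$variance_fractions, p2$variance_fractions,
               tolerance = 1e-9)
})

test_that("average-linkage clustering merges identical items first", {
  m <- matrix(c(0, 0, 0.001, 0.002, 5, 5), ncol = 2, byrow = TRUE,
              dimnames = list(c("a", "b", "far"), NULL))
  hc <- hier_cluster(m, "genomes")$hclust
  # first merge joins the near-identical pair
  expect_equal(sort(-hc$merge[1, ]), c(1, 2))
  expect_true(all(diff(hc$height) >= -1e-12))   # nondecreasing heights
})

test_that("clustering recovers a planted two-cluster structure", {
  set.seed(9)
  m <- rbind(matrix(rnorm(9, 0, 0.1), ncol = 3),
             matrix(rnorm(9, 10, 0.1), ncol = 3))
  rownames(m) <- paste0("g", 1:6)
  hc <- hier_cluster(scale_columns(m), "genomes")$hclust
  top <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(top[1:3])), 1)
  expect_equal(length(unique(top[4:6])), 1)
  expect_false(top[1] == top[4])
  # oracle: brute-force all-pairs single merge of the two planted groups
  d <- as.matrix(stats::dist(scale_columns(m)))
  within <- max(d[1:3, 1:3], d[4:6, 4:6])
  between <- min(d[1:3, 4:6])
  expect_gt(between, within)
})

test_that("outlier flagging marks exactly the planted extreme cells", {
  m <- matrix(c(0, 0, 0, 10), ncol = 1, dimnames = list(paste0("g", 1:4), "x"))
  # 10 is >1.49 sd away; use threshold below its z-score
  s <- scale_columns(m)
  f <- flag_outliers(s, z_threshold = 1.4)
  expect_equal(f$replicon, "g4")
  expect_equal(f$rule_id, "OUTLIER001")
  expect_equal(nrow(flag_outliers(s, z_threshold = 3)), 0)
  # planted single-outlier cohort
  set.seed(14)
  cohort <- matrix(rnorm(40 * 3), nrow = 40,
                   dimnames = list(paste0("g", 1:40), c("a", "b", "c")))
  cohort[17, 2] <- 50
  fo <- flag_outliers(scale_columns(cohort), z_threshold = 3)
  expect_equal(unique(fo$replicon), "g17")
})

test_that("measure matrices round-trip through TSV", {
  rows <- lapply(1:3, function(s) {
    compute_metrics(generate_genome(genome_spec(seed = s,
                                                n_proteins = 10L))$record)
  })
  m <- metrics_to_matrix(rows)
  expect_equal(nrow(m), 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_measure_tsv(m, path)
  back <- read_measure_tsv(path)
  expect_equal(unname(back), unname(m), tolerance = 1e-9)
})

test_that("slope of protein count vs length is recovered on a synthetic cohort", {
  set.seed(77)
  a <- 0.9                       # proteins per kbp
  len_kbp <- runif(30, 1500, 8000)
  count <- a * len_kbp + rnorm(30, sd = 120)
  f <- fit_line(len_kbp, count)
  expect_lt(abs(f$slope - a), 3 * f$stderr)
  expect_gt(f$r_squared, 0.9)
})
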