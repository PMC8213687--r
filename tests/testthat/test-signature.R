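sig_norm <- function(extra = 4, n = 10, seed = 12, mt_fold = rep(1, n),
                     tmm = FALSE) {
  # 8 MT genes plus `extra` background genes, optional per-sample MT fold;
  # background carries most of the library so composition does not swamp
  # the block, and TMM (tmm = TRUE) corrects what remains
  set.seed(seed)
  mt <- t(sapply(seq_len(8), function(g)
    rnbinom(n, mu = 5000 * mt_fold, size = 30)))
  bg <- matrix(rnbinom(extra * n, mu = 4000, size = 10), nrow = extra)
  counts <- rbind(mt, bg)
  dimnames(counts) <- list(c(mt_gene_set(), paste0("G", seq_len(extra))),
                           paste0("S", seq_len(n)))
  cpm_normalize(counts, if (tmm) NULL else rep(1, n))
}

test_that("signature_score is an exact, additive column sum", {
  norm <- sig_norm()
  s <- signature_score(norm)
  expect_equal(s, colSums(norm$cpm[mt_gene_set(), ]))
  # additivity over a disjoint partition of the set
  a <- signature_score(norm, mt_gene_set()[1:3])
  b <- signature_score(norm, mt_gene_set()[4:8])
  expect_equal(a + b, s)
  expect_error(signature_score(norm, c("MT-CO2", "NOT_A_GENE")), "NOT_A_GENE")
  expect_error(signature_score(norm, character(0)), "empty")
  # 8 genes at 1000 cpm each -> score 8000
  flat <- norm; flat$cpm[mt_gene_set(), ] <- 1000
  expect_equal(unname(signature_score(flat)), rep(8000, 10))
})

test_that("a doubled MT block doubles the subgroup mean score (approx)", {
  fold <- rep(c(1, 2), each = 10)
  norm <- sig_norm(extra = 40, n = 20, mt_fold = fold, seed = 99, tmm = TRUE)
  s <- signature_score(norm)
  ratio <- mean(s[11:20]) / mean(s[1:10])
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("wilcoxon: exact branch, ties, and approx parity with base R", {
  r <- compare_groups_wilcoxon(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$p_value, 0.1)     # 2/20 most extreme among C(6,3)
  expect_identical(r$method, "exact_enumeration")
  expect_equal(compare_groups_wilcoxon(c(5, 5), c(5, 5))$p_value, 1)
  expect_error(compare_groups_wilcoxon(numeric(0), 1:3), "non-empty")

  # exact branch agrees with wilcox.test exact p (no ties)
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(7)
    expect_equal(compare_groups_wilcoxon(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # approx branch matches the tie-corrected continuity-corrected normal
  for (i in 1:5) {
    x <- sample(1:8, 15, replace = TRUE); y <- sample(1:8, 18, replace = TRUE)
    expect_equal(compare_groups_wilcoxon(x, y)$p_value,
                 suppressWarnings(
                   wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value))
  }
})

test_that("large-n null Wilcoxon p-values are approximately uniform", {
  set.seed(10)
  ps <- replicate(200, compare_groups_wilcoxon(rnorm(25), rnorm(25))$p_value)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("clustering recovers well-separated synthetic blocks", {
  fold <- rep(c(1, 3), each = 8)
  norm <- sig_norm(extra = 40, n = 16, mt_fold = fold, seed = 31, tmm = TRUE)
  cl <- cluster_mt_signature(norm, samples = colnames(norm$cpm))
  expect_setequal(cl$assignments$cluster[9:16], "high")
  expect_setequal(cl$assignments$cluster[1:8], "low")
  # invariant to sample order
  perm <- sample(16)
  cl2 <- cluster_mt_signature(norm, samples = colnames(norm$cpm)[perm])
  m1 <- setNames(cl$assignments$cluster, cl$assignments$sample_id)
  m2 <- setNames(cl2$assignments$cluster, cl2$assignments$sample_id)
  expect_identical(m1[names(m2)], m2)
  # invariant to per-gene affine rescaling (z-scoring removes it)
  resc <- norm; resc$cpm[1, ] <- resc$cpm[1, ] * 50 + 7
  cl3 <- cluster_mt_signature(resc, samples = colnames(norm$cpm))
  expect_identical(cl3$assignments$cluster, cl$assignments$cluster)

  # degenerate inputs
  flat <- norm; flat$cpm[mt_gene_set(), ] <- 5
  expect_error(suppressWarnings(
    cluster_mt_signature(flat, samples = colnames(norm$cpm))), "degenerate")
  one_flat <- norm; one_flat$cpm["MT-ND3", ] <- 5
  expect_warning(cluster_mt_signature(one_flat, samples = colnames(norm$cpm)),
                 "MT-ND3")
  expect_error(cluster_mt_signature(norm, samples = paste0("S", 1:3)),
               "at least 4")
})

test_that("extreme_score_samples picks the k most extreme", {
  s <- setNames(c(5, 1, 9, 3, 7, 2), paste0("S", 1:6))
  ex <- extreme_score_samples(s, k = 2)
  expect_setequal(ex$very_high, c("S3", "S5"))
  expect_setequal(ex$very_low, c("S2", "S6"))
  expect_error(extreme_score_samples(s, k = 4))
})

test_that("fisher_exact_2x2: closed forms, symmetry, oracle agreement", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(1, 9, 9, 1), 2)), 202 / 184756)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  # brute-force oracle over all margin-fixed tables, totals <= 30
  set.seed(6)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 3), 2)
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(m, k)
    probs <- vapply(support, function(a) {
      t2 <- matrix(c(a, k - a, m - a, n - k + a), 2)
      prod(choose(c(m, n), t2[, 1])) / choose(m + n, k)
    }, numeric(1))
    oracle <- sum(probs[probs <= probs[support == tab[1, 1]] * (1 + 1e-7)])
    expect_equal(fisher_exact_2x2(tab), min(1, oracle))
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("spearman_assoc: monotone pairs, exact enumeration, approx", {
  expect_equal(spearman_assoc(1:5, c(10, 20, 30, 40, 50))$rho, 1)
  expect_equal(spearman_assoc(1:5, 5:1)$rho, -1)
  expect_error(spearman_assoc(1:4, rep(2, 4)), "constant")
  expect_error(spearman_assoc(1:2, 1:2), "at least 3")

  # n = 5: matches an independent recursive brute force over 120 permutations
  brute <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    rho <- cor(rx, ry)
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    }
    all_rho <- vapply(perms(seq_along(y)), function(idx) cor(rx, ry[idx]),
                      numeric(1))
    mean(abs(all_rho) >= abs(rho) - 1e-9)
  }
  set.seed(3)
  for (i in 1:4) {
    x <- rnorm(5); y <- rnorm(5)
    got <- spearman_assoc(x, y)
    expect_identical(got$method, "exact_enumeration")
    expect_equal(got$p_value, brute(x, y))
  }
  # approx branch against the t-statistic route of cor.test
  x <- rnorm(30); y <- x + rnorm(30)
  got <- spearman_assoc(x, y)
  expect_equal(got$p_value,
               cor.test(x, y, method = "spearman", exact = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("linear_assoc finds signed slopes with BH across covariates", {
  set.seed(20)
  score <- rnorm(40, 100, 10)
  covs <- data.frame(pos = 2 * score + rnorm(40, 0, 1e-4),
                     neg = -0.5 * score + rnorm(40, 0, 1e-4),
                     null1 = rnorm(40), null2 = rnorm(40))
  covs$neg[3] <- NA   # pairwise dropping
  out <- linear_assoc(score, covs)
  expect_equal(out$slope_sign[out$covariate == "pos"], 1)
  expect_equal(out$slope_sign[out$covariate == "neg"], -1)
  expect_lt(max(out$fdr[out$covariate %in% c("pos", "neg")]), 1e-10)
  expect_equal(out$n[out$covariate == "neg"], 39)
  expect_equal(out$fdr, bh_fdr(out$p_value))
  expect_error(linear_assoc(score, data.frame(flat = rep(1, 40))), "constant")

  # n = 3 on an exact line: slope exact, t with 1 df
  out3 <- linear_assoc(c(1, 2, 3), data.frame(v = c(2, 4, 6.001)))
  expect_equal(out3$slope, 2.0005, tolerance = 1e-6)
})

test_that("null covariates give approximately uniform p-values", {
  set.seed(77)
  ps <- replicate(150, {
    s <- rnorm(25)
    linear_assoc(s, data.frame(v = rnorm(25)))$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("delta-Ct arithmetic and genomic copy ratios", {
  expect_equal(ddct_fold(16, 24), 256)
  expect_equal(ddct_fold(24, 16), 256)   # absolute difference
  expect_equal(ddct_fold(20, 20), 1)
  # inverse of the log2 formula is the identity
  folds <- c(1.5, 2, 379, 440, 1000)
  expect_equal(ddct_fold(24 - log2(folds), 24), folds, tolerance = 1e-9)
  expect_error(ddct_fold(NA, 20), "finite")

  expect_equal(round(genomic_copy_ratio(440, 379), 1), 1.2)
  expect_equal(genomic_copy_ratio(7, 7), 1)
  expect_equal(genomic_copy_ratio(200, 100), 2)
  expect_error(genomic_copy_ratio(0, 5), "positive")
})
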