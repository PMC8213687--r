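# helper: build a results table row
res_row <- function(gene, level, q1, q2, fdr, p = fdr) {
  data.frame(gene_id = gene, level = level,
             quantile_level = c(q1 = 0.25, median = 0.5, q3 = 0.75)[[level]],
             q_group1 = q1, q_group2 = q2, y_obs = abs(q2 - q1),
             p_value = p, fdr = fdr, stringsAsFactors = FALSE)
}

test_that("fold_change reproduces the published worked examples", {
  fc <- fold_change(81.20, 421.79)
  expect_equal(round(fc$ratio, 2), 5.19)
  expect_identical(fc$direction, "up")
  expect_equal(round(fold_change(5.02, 24.15)$ratio, 2), 4.81)
  expect_equal(round(fold_change(32.77, 115.12)$ratio, 2), 3.51)
  same <- fold_change(7, 7)
  expect_equal(same$ratio, 1)
  expect_identical(same$direction, "none")
  down <- fold_change(50, 20)
  expect_equal(down$ratio, 2.5)
  expect_identical(down$direction, "down")
  zero <- fold_change(0, 12)
  expect_identical(zero$ratio, Inf)
  expect_identical(zero$direction, "up")
  expect_error(fold_change(-1, 5), "non-negative")
})

test_that("call_degs applies all three criteria simultaneously per level", {
  thr <- deg_thresholds()
  res <- rbind(
    res_row("gA", "median", 50, 100, 0.01),   # all pass
    res_row("gB", "median", 5, 10, 0.01),     # diff 5 < 10 cpm
    res_row("gC", "median", 500, 700, 0.01),  # FC 1.4 < 1.5
    res_row("gD", "median", 50, 100, 0.06),   # FDR fails
    # gE passes at q3 only; median row fails FC
    res_row("gE", "median", 200, 205, 0.30),
    res_row("gE", "q3", 100, 400, 0.02))
  degs <- call_degs(res, thr)
  expect_setequal(degs$gene_id, c("gA", "gE"))
  ge <- degs[degs$gene_id == "gE", ]
  expect_identical(ge$level, "q3")
  expect_identical(ge$qualifying_levels, "q3")
  expect_equal(ge$cpm_ctl, 100)
  expect_equal(ge$cpm_case, 400)
  expect_equal(ge$ratio, 4)

  # criteria are evaluated at the same level jointly: a gene whose FDR
  # passes at the median but whose diff passes only at q3 (where FDR fails)
  # is not called
  res2 <- rbind(res_row("gF", "median", 100, 104, 0.01),
                res_row("gF", "q3", 100, 300, 0.50))
  expect_equal(nrow(call_degs(res2, thr)), 0)
})

test_that("reporting level is lowest FDR with median > q3 > q1 tie-break", {
  res <- rbind(res_row("g", "q1", 10, 40, 0.02),
               res_row("g", "median", 20, 80, 0.01),
               res_row("g", "q3", 30, 120, 0.01))
  deg <- call_degs(res)
  expect_identical(deg$level, "median")
  expect_identical(deg$qualifying_levels, "q1,median,q3")
  expect_equal(deg$fdr, 0.01)
})

test_that("raising any threshold never adds a DEG (monotonicity property)", {
  set.seed(8)
  for (i in 1:25) {
    n <- 40
    res <- do.call(rbind, lapply(seq_len(n), function(g) {
      lv <- sample(c("q1", "median", "q3"), 1)
      res_row(paste0("g", g), lv, rlnorm(1, log(50), 1), rlnorm(1, log(50), 1),
              runif(1))
    }))
    base <- deg_thresholds()
    loose <- call_degs(res, base)$gene_id
    tighter <- list(
      deg_thresholds(fdr_max = base$fdr_max / 2),
      deg_thresholds(min_abs_diff_cpm = base$min_abs_diff_cpm * 2),
      deg_thresholds(min_fold_change = base$min_fold_change * 1.5))
    for (thr in tighter)
      expect_true(all(call_degs(res, thr)$gene_id %in% loose))
  }
})

test_that("call_degs is invariant to row and sample order", {
  co <- small_cohort(n_genes = 15, n1 = 4, n2 = 4, seed = 77)
  res <- test_all_genes(co$norm, co$g1, co$g2, seed = 1)
  thr <- deg_thresholds(fdr_max = 0.9, min_abs_diff_cpm = 5,
                        min_fold_change = 1.1)  # permissive so calls exist
  a <- call_degs(res, thr)
  expect_gt(nrow(a), 0)
  # permute result rows
  b <- call_degs(res[sample(nrow(res)), ], thr)
  expect_equal(a, b)
  # permute sample columns upstream
  perm <- sample(ncol(co$norm$cpm))
  normp <- co$norm; normp$cpm <- normp$cpm[, perm]
  resp <- test_all_genes(normp, co$g1, co$g2, seed = 1)
  expect_equal(call_degs(resp, thr), a)
})

test_that("unique_degs implements the one-and-not-the-other rule", {
  deg <- function(ids) {
    k <- length(ids)
    data.frame(
      gene_id = ids, gene_name = ids, cpm_ctl = rep(10, k),
      cpm_case = rep(30, k), ratio = rep(3, k), direction = rep("up", k),
      fdr = rep(0.01, k), level = rep("median", k),
      qualifying_levels = rep("median", k), stringsAsFactors = FALSE)
  }
  u <- unique_degs(ctl_vs_E = deg(c("g1", "g2")),
                   ctl_vs_Eex = deg(c("g2", "g3")),
                   ctl_vs_A = deg(c("g2", "g4")),
                   ctl_vs_Aex = deg("g5"))
  # g1 only in E; g3 only in Eex; g2 significant on both sides -> excluded
  expect_setequal(u$E$gene_id, c("g1", "g3"))
  expect_setequal(u$A$gene_id, c("g4", "g5"))
  expect_length(intersect(u$E$gene_id, u$A$gene_id), 0)
  expect_identical(u$E$provenance[u$E$gene_id == "g3"], "ctl_vs_Eex")

  # empty A side: every E DEG is unique
  u2 <- unique_degs(deg(c("g1", "g2")), deg("g2"), deg(character(0)),
                    deg(character(0)))
  expect_setequal(u2$E$gene_id, c("g1", "g2"))
  expect_equal(nrow(u2$A), 0)
})

test_that("shared_and_exclusive partitions exactly", {
  p <- shared_and_exclusive(c("a", "b", "c"), c("b", "c", "d"))
  expect_identical(p, list(shared = c("b", "c"), only1 = "a", only2 = "d"))
  expect_length(shared_and_exclusive("x", "y")$shared, 0)
  p2 <- shared_and_exclusive(c("a", "b"), c("b", "a"))
  expect_setequal(p2$shared, c("a", "b"))
  expect_length(p2$only1, 0)
})

test_that("confirmation concordance recovers direction agreement", {
  # identical cohorts: trivially concordant
  co <- small_cohort(n_genes = 10, n1 = 5, n2 = 5, seed = 3)
  res <- test_all_genes(co$norm, co$g1, co$g2, seed = 1)
  degs <- call_degs(res, deg_thresholds(fdr_max = 1, min_abs_diff_cpm = 1,
                                        min_fold_change = 1.01))
  expect_gt(nrow(degs), 0)
  conc <- confirmation_concordance(degs, co$norm, co$g1, co$g2)
  expect_equal(conc$concordant_fraction, 1)

  # a fresh draw from the same generative model stays concordant for
  # strongly spiked genes; permuted labels sit near 1/2
  set.seed(55)
  n_gene <- 40; n_per <- 15
  mu <- rlnorm(n_gene, log(100), 0.8)
  spike <- rep(c(4, 1), c(10, n_gene - 10))
  draw <- function(fold) sapply(seq_len(n_per), function(i)
    rnbinom(n_gene, mu = mu * fold, size = 8))
  counts <- cbind(draw(1), draw(spike), draw(spike), draw(1))
  rownames(counts) <- paste0("G", seq_len(n_gene))
  colnames(counts) <- paste0("S", seq_len(4 * n_per))
  norm <- cpm_normalize(counts, rep(1, ncol(counts)))
  ctl <- paste0("S", 1:n_per)
  disc <- paste0("S", n_per + 1:n_per)
  conf <- paste0("S", 2 * n_per + 1:n_per)
  conf_null <- paste0("S", 3 * n_per + 1:n_per)   # no effect: coin-flip signs
  res2 <- test_all_genes(norm, ctl, disc, seed = 2, n_perm = 2000,
                         budget = 1e4)
  degs2 <- call_degs(res2)
  expect_gt(nrow(degs2), 5)
  good <- confirmation_concordance(degs2, norm, ctl, conf)
  expect_gte(good$concordant_fraction, 0.9)
  null <- confirmation_concordance(degs2, norm, ctl, conf_null)
  expect_gt(null$concordant_fraction, 0.1)   # ~ 0.5 under the null
  expect_lt(null$concordant_fraction, 0.9)

  expect_error(confirmation_concordance(degs2[0, ], norm, ctl, conf),
               "no discovery DEGs")
  bad <- degs2; bad$gene_id[1] <- "missing_gene"
  expect_error(confirmation_concordance(bad, norm, ctl, conf), "absent")
})
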