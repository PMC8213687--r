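## Mitochondrial signature scoring, clustering, enrichment and association
## statistics, and qPCR delta-Ct arithmetic.

#' The eight-gene mitochondrial signature
#'
#' The mitochondria-encoded oxidative-phosphorylation genes whose summed
#' expression forms the emphysema-associated signature: NADH dehydrogenase
#' subunits ND1/2/3/5, cytochrome c oxidase subunits CO1/2/3 and ATP
#' synthase subunit 6.
#'
#' @return character vector of the eight gene names.
#' @export
mt_gene_set <- function() {
  c("MT-ND1", "MT-ND2", "MT-ND3", "MT-ND5",
    "MT-CO1", "MT-CO2", "MT-CO3", "MT-ATP6")
}

.resolve_genes <- function(norm, gene_set) {
  ids <- rownames(norm$cpm)
  idx <- match(gene_set, ids)
  # version-stripped alias lookup for unversioned queries
  if (anyNA(idx)) {
    alias <- match(strip_gene_version(gene_set)[is.na(idx)],
                   strip_gene_version(ids))
    idx[is.na(idx)] <- alias
  }
  if (anyNA(idx))
    stop("gene set member(s) not in matrix: ",
         paste(gene_set[is.na(idx)], collapse = ", "))
  ids[idx]
}

#' Per-sample signature score: sum of cpm over a gene set
#'
#' @param norm \code{cpm_matrix}.
#' @param gene_set character vector of gene ids/names; all must resolve in
#'   the matrix (version-stripped aliases are tried).
#' @return named numeric vector, one exact column sum per sample.
#' @export
signature_score <- function(norm, gene_set = mt_gene_set()) {
  stopifnot(inherits(norm, "cpm_matrix"))
  if (length(gene_set) == 0) stop("empty gene set")
  genes <- .resolve_genes(norm, gene_set)
  colSums(norm$cpm[genes, , drop = FALSE])
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' For combined n <= 20 the null distribution of the rank sum is obtained
#' by full enumeration of the \code{choose(n, n1)} group assignments (exact
#' even under ties, since average ranks are enumerated); larger samples use
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors (both non-empty), e.g. signature scores of
#'   two subgroups.
#' @return list with \code{p_value}, rank-sum statistic \code{w} (of
#'   \code{x}) and \code{method}.
#' @export
compare_groups_wilcoxon <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n <= 20) {
    combs <- combn(n, n1)
    ws <- colSums(matrix(r[combs], nrow = n1))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(ws <= w + eps), mean(ws >= w - eps)))
    return(list(p_value = p, w = w, method = "exact_enumeration"))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(p_value = 1, w = w, method = "normal_approx"))
  z <- w - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)  # continuity correction
  list(p_value = 2 * pnorm(-abs(z)), w = w, method = "normal_approx")
}

#' Unsupervised hierarchical clustering of a signature into two groups
#'
#' Each gene row of the cpm sub-matrix is z-scored across the selected
#' samples (row scaling, as in standard expression heatmaps); samples are
#' clustered on Euclidean distance with complete linkage and the tree is
#' cut into two clusters. The cluster with the higher mean signature score
#' is labelled \code{"high"}. Zero-variance gene rows are dropped with a
#' warning; if no informative gene remains the samples cannot be clustered
#' and an error is raised.
#'
#' @param norm \code{cpm_matrix}.
#' @param gene_set signature genes (default \code{\link{mt_gene_set}}).
#' @param samples sample ids to cluster (>= 4).
#' @return list with \code{assignments} (data.frame: sample_id, cluster),
#'   \code{tree} (the hclust object) and \code{scores}.
#' @export
cluster_mt_signature <- function(norm, gene_set = mt_gene_set(), samples) {
  stopifnot(inherits(norm, "cpm_matrix"))
  if (length(samples) < 4) stop("need at least 4 samples to cluster")
  genes <- .resolve_genes(norm, gene_set)
  m <- norm$cpm[genes, samples, drop = FALSE]
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance gene row(s): ",
            paste(rownames(m)[sds == 0], collapse = ", "))
    m <- m[sds > 0, , drop = FALSE]
  }
  if (nrow(m) == 0)
    stop("all signature genes have zero variance across the samples; degenerate input")
  z <- t(scale(t(m)))
  tree <- hclust(dist(t(z), method = "euclidean"), method = "complete")
  cl <- cutree(tree, k = 2)
  scores <- signature_score(norm, gene_set)[samples]
  means <- tapply(scores, cl, mean)
  high_cluster <- as.integer(names(means)[which.max(means)])
  assignments <- data.frame(
    sample_id = samples,
    cluster = ifelse(cl == high_cluster, "high", "low"),
    stringsAsFactors = FALSE, row.names = NULL)
  list(assignments = assignments, tree = tree, scores = scores)
}

#' The k most extreme samples by signature score
#'
#' Convenience selector for surrogate-marker comparisons in cohorts without
#' imaging labels: the k samples with the highest and the k with the lowest
#' signature score.
#'
#' @param scores named numeric vector from \code{\link{signature_score}}.
#' @param k number of samples per extreme (default 5).
#' @return list with \code{very_high} and \code{very_low} sample ids.
#' @export
extreme_score_samples <- function(scores, k = 5) {
  stopifnot(k >= 1, 2 * k <= length(scores))
  o <- order(scores)
  list(very_high = names(scores)[rev(o)][seq_len(k)],
       very_low = names(scores)[o][seq_len(k)])
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditions on the margins and sums the hypergeometric probabilities of
#' all tables at most as probable as the observed one (with the customary
#' relative tolerance for ties in probability).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties averaged). For n <= 9
#' the two-sided p-value is exact, by enumeration of all n! rank
#' permutations (proportion with |rho| >= |rho_obs|); for larger n the
#' t-distribution approximation with n - 2 degrees of freedom is used.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{rho}, \code{p_value} and \code{method}.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9) {
    perms <- .all_perms(n)
    rhos <- apply(perms, 2, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-9)
    return(list(rho = rho, p_value = p, method = "exact_enumeration"))
  }
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * pt(-abs(t_stat), df = n - 2),
       method = "t_approx")
}

# all permutations of 1..n as an n x n! matrix (n <= 9): insert n at every
# position of every permutation of 1..(n-1)
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0
  for (pos in seq_len(n)) {
    for (j in seq_len(ncol(sub))) {
      col <- col + 1
      out[, col] <- append(sub[, j], n, after = pos - 1)
    }
  }
  out
}

#' Linear association of signature scores with clinical covariates
#'
#' Ordinary least-squares regression of each covariate on the signature
#' score (missing values dropped pairwise), with the two-sided slope
#' p-value and Benjamini-Hochberg adjustment across the covariates tested.
#'
#' @param scores named numeric vector of signature scores.
#' @param covariates data.frame of numeric covariates, rows aligned with
#'   \code{scores}.
#' @return data.frame: covariate, n, slope, slope_sign, p_value, fdr.
#' @export
linear_assoc <- function(scores, covariates) {
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(scores))
  rows <- lapply(names(covariates), function(nm) {
    yy <- as.numeric(covariates[[nm]])
    ok <- complete.cases(scores, yy)
    if (sum(ok) < 3) stop("covariate '", nm, "': fewer than 3 complete pairs")
    if (sd(yy[ok]) == 0) stop("covariate '", nm, "' is constant")
    fit <- summary(lm(yy[ok] ~ scores[ok]))
    data.frame(covariate = nm, n = sum(ok),
               slope = fit$coefficients[2, 1],
               slope_sign = sign(fit$coefficients[2, 1]),
               p_value = fit$coefficients[2, 4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out
}

#' qPCR delta-Ct fold enrichment
#'
#' The reference-gene cycle threshold is subtracted from the target gene's
#' and the absolute difference is raised to the power of 2:
#' \code{fold = 2^|ct_gene - ct_reference|}.
#'
#' @param ct_gene,ct_reference finite cycle-threshold values (vectorized).
#' @return fold enrichment.
#' @export
ddct_fold <- function(ct_gene, ct_reference) {
  if (any(!is.finite(ct_gene)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite")
  2^abs(ct_gene - ct_reference)
}

#' Ratio of two genomic fold enrichments
#'
#' Compares mitochondrial-genome copy-number proxies between two groups:
#' the ratio of their delta-Ct fold enrichments (display convention: one
#' decimal).
#'
#' @param fold_group1,fold_group2 positive fold enrichments.
#' @return \code{fold_group1 / fold_group2}.
#' @export
genomic_copy_ratio <- function(fold_group1, fold_group2) {
  if (any(fold_group1 <= 0) || any(fold_group2 <= 0))
    stop("fold enrichments must be positive")
  fold_group1 / fold_group2
}
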