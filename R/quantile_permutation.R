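## The core statistic: Y = |q(group1) - q(group2)| for a quantile level in
## {0.25, 0.5, 0.75}, with an exact permutation null (full enumeration of
## label assignments) or a seeded Monte-Carlo approximation when the
## enumeration budget is exceeded.

.QUANTILE_LEVELS <- c(q1 = 0.25, median = 0.5, q3 = 0.75)

.level_label <- function(level) {
  names(.QUANTILE_LEVELS)[match(level, .QUANTILE_LEVELS)]
}

.check_levels <- function(levels) {
  if (!all(levels %in% .QUANTILE_LEVELS))
    stop("quantile level must be one of 0.25 (q1), 0.5 (median), 0.75 (q3)")
  levels
}

#' Group quantile (type-7 / linear interpolation)
#'
#' For sorted values v(1..m), \code{h = level * (m - 1)} and the result is
#' \code{v(floor(h)+1) + (h - floor(h)) * (v(floor(h)+2) - v(floor(h)+1))}:
#' linear interpolation between order statistics, so the median of an even
#' sample is the mean of the two middle values. This is the convention all
#' quantile statistics in the package use.
#'
#' @param values non-empty numeric vector.
#' @param level quantile level in \{0.25, 0.5, 0.75\}.
#' @return the quantile, a scalar.
#' @export
group_quantile <- function(values, level) {
  if (length(values) == 0) stop("empty vector")
  .check_levels(level)
  v <- sort(values)
  m <- length(v)
  h <- level * (m - 1)
  lo <- floor(h)
  if (lo >= m - 1) return(v[m])
  v[lo + 1] + (h - lo) * (v[lo + 2] - v[lo + 1])
}

.perm_result <- function(gene_id, level, res, engine, n_used, p) {
  data.frame(gene_id = gene_id,
             level = .level_label(level),
             quantile_level = level,
             q_group1 = res$q1, q_group2 = res$q2,
             y_obs = res$y_obs,
             p_value = p,
             engine = engine,
             n_permutations_used = n_used,
             stringsAsFactors = FALSE)
}

#' Exact permutation p-value for a quantile difference
#'
#' Enumerates every assignment of \code{length(group1)} labels among the
#' pooled values and reports \code{p = P(Y >= y_obs)}, the proportion of
#' assignments whose absolute quantile difference is at least the observed
#' one. The observed assignment is part of the enumerated set, so p > 0 and
#' the denominator is \code{choose(n1 + n2, n1)}. Ties are handled
#' implicitly: assignments are over positions of the pooled multiset.
#'
#' @param group1,group2 numeric cpm vectors.
#' @param level quantile level in \{0.25, 0.5, 0.75\}; may be a vector.
#' @param budget maximum number of assignments to enumerate (default 2e5).
#' @param gene_id identifier used in the result row.
#' @return data.frame with one row per level: observed group quantiles,
#'   \code{y_obs}, \code{p_value}, engine and permutation count.
#' @export
exact_perm_pvalue <- function(group1, group2, level = 0.5, budget = 2e5,
                              gene_id = NA_character_) {
  .check_levels(level)
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  n_comb <- choose(n1 + n2, n1)
  if (n_comb > budget)
    stop(sprintf(
      "C(%d, %d) = %g exceeds the enumeration budget (%g); use the monte_carlo engine",
      n1 + n2, n1, n_comb, budget))
  res <- perm_quantile_test_cpp(c(group1, group2), n1, level,
                                "exact", 0, 0, 0)
  .perm_result(gene_id, level, res, "exact_enumeration", res$total,
               res$count_ge / res$total)
}

#' Seeded Monte-Carlo permutation p-value for a quantile difference
#'
#' Samples \code{n_perm} random label assignments and uses the add-one
#' estimator \code{p = (1 + #\{Y >= y_obs\}) / (n_perm + 1)}, which is never
#' zero. Identical seed and inputs give an identical p-value.
#'
#' @inheritParams exact_perm_pvalue
#' @param n_perm number of sampled assignments (>= 1000).
#' @param seed integer seed (mandatory: reproducibility contract).
#' @param counter per-gene stream offset; the (seed, counter) pair selects
#'   an independent random stream, so results do not depend on the order in
#'   which genes are processed.
#' @return data.frame as in \code{\link{exact_perm_pvalue}} with engine
#'   \code{"monte_carlo"}.
#' @export
monte_carlo_perm_pvalue <- function(group1, group2, level = 0.5,
                                    n_perm = 1e5, seed, counter = 0,
                                    gene_id = NA_character_) {
  .check_levels(level)
  if (missing(seed)) stop("seed is required for the monte_carlo engine")
  if (n_perm < 1000) stop("n_perm must be >= 1000")
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  res <- perm_quantile_test_cpp(c(group1, group2), n1, level,
                                "mc", n_perm, seed, counter)
  .perm_result(gene_id, level, res, "monte_carlo", res$total,
               (1 + res$count_ge) / (res$total + 1))
}

#' Permutation tests for every gene at the requested quantile levels
#'
#' For each gene, the cpm values of the two sample groups are compared with
#' the quantile-difference permutation test; the engine is exact
#' enumeration when \code{choose(n1 + n2, n1) <= budget} and seeded
#' Monte-Carlo otherwise. Benjamini-Hochberg FDR is attached per quantile
#' level (default) or jointly across levels.
#'
#' @param norm \code{cpm_matrix} from \code{\link{cpm_normalize}}.
#' @param group1,group2 character vectors of sample ids (e.g. from
#'   \code{\link{select_samples}}); conventionally group1 = controls.
#' @param levels quantile levels to test (default all three).
#' @param budget enumeration budget (default 2e5 assignments).
#' @param n_perm Monte-Carlo permutation count (default 1e5).
#' @param seed integer seed; expanded to independent per-gene streams.
#' @param fdr_scope \code{"per_level"} (default) corrects across genes
#'   within each quantile level; \code{"joint"} corrects across genes x
#'   levels together.
#' @return data.frame with one row per gene per level: \code{gene_id},
#'   \code{level} label, \code{quantile_level}, group quantiles,
#'   \code{y_obs}, \code{p_value}, \code{fdr}, \code{engine},
#'   \code{n_permutations_used}.
#' @export
test_all_genes <- function(norm, group1, group2,
                           levels = c(0.25, 0.5, 0.75),
                           budget = 2e5, n_perm = 1e5, seed = 1,
                           fdr_scope = c("per_level", "joint")) {
  fdr_scope <- match.arg(fdr_scope)
  .check_levels(levels)
  stopifnot(inherits(norm, "cpm_matrix"))
  miss <- setdiff(c(group1, group2), colnames(norm$cpm))
  if (length(miss) > 0)
    stop("sample(s) not in matrix: ", paste(head(miss, 5), collapse = ", "))
  if (length(group1) == 0 || length(group2) == 0)
    stop("selector matched no samples for one of the groups")
  n1 <- length(group1); n2 <- length(group2)
  exact <- is.finite(choose(n1 + n2, n1)) && choose(n1 + n2, n1) <= budget
  m1 <- norm$cpm[, group1, drop = FALSE]
  m2 <- norm$cpm[, group2, drop = FALSE]
  genes <- rownames(norm$cpm)
  rows <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    if (exact) {
      res <- perm_quantile_test_cpp(c(m1[g, ], m2[g, ]), n1, levels,
                                    "exact", 0, 0, 0)
      rows[[g]] <- .perm_result(genes[g], levels, res, "exact_enumeration",
                                res$total, res$count_ge / res$total)
    } else {
      res <- perm_quantile_test_cpp(c(m1[g, ], m2[g, ]), n1, levels,
                                    "mc", n_perm, seed, g - 1)
      rows[[g]] <- .perm_result(genes[g], levels, res, "monte_carlo",
                                res$total, (1 + res$count_ge) / (res$total + 1))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (fdr_scope == "joint") {
    out$fdr <- bh_fdr(out$p_value)
  } else {
    out$fdr <- NA_real_
    for (lv in unique(out$level)) {
      sel <- out$level == lv
      out$fdr[sel] <- bh_fdr(out$p_value[sel])
    }
  }
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values vector of p-values in (0, 1].
#' @return adjusted values, same order as the input; each adjusted value is
#'   at least its raw p-value and monotone in the sorted order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}
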