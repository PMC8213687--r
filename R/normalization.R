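## TMM normalization, implemented from the published definition (trimmed
## mean of M-values with precision weights) rather than by calling an
## external package; the test suite checks it against edgeR as an oracle.

#' TMM scaling factors
#'
#' Computes one trimmed-mean-of-M-values scaling factor per sample. For each
#' sample against a reference, per-gene log2 expression ratios (M) and mean
#' log2 abundances (A) are formed from library-size-normalized counts; genes
#' with a zero count in either member of the pair are excluded. The most
#' extreme \code{trim_logfc} fraction of M values on each side and the most
#' extreme \code{trim_abundance} fraction of A values on each side are
#' trimmed, and the factor is the weighted mean of the surviving M values
#' with inverse asymptotic-variance (precision) weights. Factors are
#' rescaled so their geometric mean is 1. The reference sample is the one
#' whose upper-quartile count fraction is closest to the mean upper-quartile
#' fraction.
#'
#' @param counts validated count matrix (genes x samples), >= 2 samples.
#' @param trim_logfc two-sided trim fraction on M values (default 0.30).
#' @param trim_abundance two-sided trim fraction on A values (default 0.05).
#' @return named numeric vector of positive scaling factors, one per sample.
#' @export
tmm_factors <- function(counts, trim_logfc = 0.30, trim_abundance = 0.05) {
  validate_counts(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  zero <- which(lib == 0)
  if (length(zero) > 0)
    stop("all-zero sample(s): ", paste(colnames(counts)[zero], collapse = ", "))

  # reference: upper-quartile count fraction closest to the mean fraction
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75, names = FALSE)) / lib
  if (all(f75 < 1e-20)) {
    ref <- which.max(colSums(sqrt(counts)))
  } else {
    ref <- which.min(abs(f75 - mean(f75)))
  }

  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
              trim_logfc, trim_abundance)
  }, numeric(1))
  f <- f / exp(mean(log(f)))       # geometric mean 1
  names(f) <- colnames(counts)
  f
}

# one sample against the reference; doubly trimmed weighted mean of M values
.tmm_pair <- function(obs, ref, lib_obs, lib_ref, trim_logfc, trim_abundance) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  if (length(obs) == 0) return(1)
  logR <- log2((obs / lib_obs) / (ref / lib_ref))
  absE <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  v <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_logfc) + 1; hiL <- n + 1 - loL
  loS <- floor(n * trim_abundance) + 1; hiS <- n + 1 - loS
  rL <- rank(logR); rS <- rank(absE)
  keep <- rL >= loL & rL <= hiL & rS >= loS & rS <= hiS
  fval <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(fval)) fval <- 0
  2^fval
}

#' TMM-adjusted counts per million
#'
#' \code{cpm[g, s] = counts[g, s] / (library_size[s] * factor[s]) * 1e6},
#' with library size the column sum of raw counts. With \code{factors =
#' NULL} the TMM factors are computed from the matrix; pass a vector of
#' ones for plain (unscaled) cpm. Zeros in counts stay exactly zero.
#'
#' @param counts validated count matrix.
#' @param factors per-sample scaling factors, or NULL to compute TMM.
#' @return an object of class \code{"cpm_matrix"}: list with \code{cpm}
#'   (genes x samples matrix), \code{factors} and \code{lib_sizes}.
#' @export
cpm_normalize <- function(counts, factors = NULL) {
  validate_counts(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  if (length(factors) != ncol(counts))
    stop("need one scaling factor per sample")
  if (any(!is.finite(factors) | factors <= 0))
    stop("scaling factors must be finite and > 0")
  lib <- colSums(counts)
  cpm <- sweep(counts, 2, lib * factors, "/") * 1e6
  structure(list(cpm = cpm,
                 factors = stats::setNames(as.numeric(factors), colnames(counts)),
                 lib_sizes = lib),
            class = "cpm_matrix")
}

#' @export
print.cpm_matrix <- function(x, ...) {
  cat("cpm_matrix:", nrow(x$cpm), "genes x", ncol(x$cpm), "samples\n")
  cat("TMM factors: ", paste(sprintf("%.3f", head(x$factors, 6)), collapse = " "),
      if (length(x$factors) > 6) "..." else "", "\n")
  invisible(x)
}
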