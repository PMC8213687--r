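# Shared fixtures, built in code.

# small deterministic count matrix
toy_counts <- function(n_genes = 6, n_samples = 4, seed = 11) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = 50, size = 5),
              nrow = n_genes,
              dimnames = list(sprintf("ENSG%08d.%d", seq_len(n_genes),
                                      rep_len(1:2, n_genes)),
                              paste0("S", seq_len(n_samples))))
  m
}

write_counts_tsv <- function(counts, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_metadata <- function() {
  data.frame(
    sample_id = paste0("S", 1:8),
    disease_status = rep(c("control", "case"), each = 4),
    sex = rep(c("male", "female"), 4),
    subphenotype = c(rep("none", 4), "E", "Eex", "A", "Aex"),
    cohort = "discovery",
    fev1_fvc = c(0.80, 0.76, 0.75, NA, 0.45, 0.50, 0.55, 0.60),
    tlco_va = runif(8, 3, 6),
    tlc = runif(8, 5, 8),
    stringsAsFactors = FALSE)
}

write_metadata_tsv <- function(meta, path = tempfile(fileext = ".tsv")) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  path
}

# a small two-group cohort for pipeline tests: returns a cpm_matrix plus ids
small_cohort <- function(n_genes = 30, n1 = 6, n2 = 6, seed = 5) {
  set.seed(seed)
  counts <- matrix(rnbinom(n_genes * (n1 + n2), mu = 200, size = 4),
                   nrow = n_genes,
                   dimnames = list(paste0("G", seq_len(n_genes)),
                                   paste0("S", seq_len(n1 + n2))))
  list(norm = cpm_normalize(counts, rep(1, n1 + n2)),
       g1 = paste0("S", seq_len(n1)),
       g2 = paste0("S", n1 + seq_len(n2)))
}

# independent pure-R enumeration oracle for the quantile permutation test
oracle_exact_perm <- function(g1, g2, level) {
  pool <- c(g1, g2)
  n <- length(pool); n1 <- length(g1)
  qfun <- function(v) unname(quantile(v, level, type = 7))
  y_obs <- abs(qfun(g1) - qfun(g2))
  combs <- combn(n, n1)
  ys <- apply(combs, 2, function(idx) abs(qfun(pool[idx]) - qfun(pool[-idx])))
  mean(ys >= y_obs - 1e-9 * (1 + y_obs))
}
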