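## Synthetic cohort generator: negative-binomial counts with gene-specific
## baselines and dispersions, unequal library sizes, spiked DE genes
## (whole-distribution and upper-tail-only shifts), a co-expressed
## mitochondrial block elevated in emphysema-dominant samples, study-like
## group sizes, and lung-function covariates linked to the MT signature.

# run fn() under a temporary RNG state
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  fn()
}

#' Default per-sex group sizes of the emulated cohort
#'
#' Discovery-cohort sizes mirror the modelled study design (males: 145
#' controls, 50 emphysema-dominant of which 22 extreme, 32 airway-dominant
#' of which 16 extreme, with mixed/normal-CT cases filling the male case
#' total; females about half the male numbers with 73 controls and 86
#' cases); \code{confirmation} counts are cases without imaging labels.
#'
#' @return named list with \code{male} and \code{female} integer vectors.
#' @export
default_group_sizes <- function() {
  list(
    male = c(control = 145, E = 28, Eex = 22, A = 16, Aex = 16,
             mixed = 46, normalCT = 45, confirmation = 36),
    female = c(control = 73, E = 14, Eex = 11, A = 8, Aex = 8,
               mixed = 23, normalCT = 22, confirmation = 17))
}

#' Simulation configuration
#'
#' Defaults encode the cohort structure the analysis assumes: log-normal
#' baseline abundances, gamma-distributed per-gene negative-binomial
#' dispersions (shape 2, mean 0.2), spiked differential genes at moderate
#' baselines, and an eight-gene mitochondrial block at a high baseline
#' (~10,000 cpm) elevated in emphysema-dominant (E/Eex) males with
#' lung-function covariates linked to the resulting signature score.
#'
#' @param n_genes total number of genes (>= 8 + spiked genes).
#' @param group_sizes list as returned by \code{\link{default_group_sizes}}.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   null-gene baseline, in cpm units.
#' @param dispersion_shape,dispersion_mean gamma parameters of the per-gene
#'   NB dispersion.
#' @param lib_size_range uniform range of per-sample library sizes (reads).
#' @param de_genes optional data.frame(\code{gene}, \code{fold},
#'   \code{mode}, \code{sexes}, \code{subphenotypes}) describing spiked
#'   genes; \code{mode} is \code{"median_shift"} (fold applied to every
#'   affected sample) or \code{"upper_tail_shift"} (fold applied to a
#'   random \code{tail_fraction} of the affected group, leaving the group
#'   median roughly unchanged); \code{sexes}/\code{subphenotypes} are
#'   comma-joined tokens, \code{"all"} meaning every case. NULL builds the
#'   default spike-in set from the \code{n_de_*} arguments.
#' @param n_de_median,de_median_fold count and fold of default
#'   whole-distribution spike-ins (affecting all cases, both sexes).
#' @param n_de_tail,de_tail_fold,tail_fraction count, fold and affected
#'   fraction of default upper-tail spike-ins (E/Eex males).
#' @param de_baseline_cpm typical baseline of spiked genes, cpm.
#' @param mt_fold,mt_subphenotypes,mt_sexes mitochondrial-block elevation
#'   and affected subgroup.
#' @param mt_baseline_cpm baseline of each MT-block gene, cpm.
#' @param confirmation_mt_fraction fraction of confirmation cases carrying
#'   the MT elevation (emphysema-like cases without imaging labels).
#' @param covariate_model linear links from the z-scored MT signature to
#'   TLCO/Va (negative), TLC (positive) and case FEV1/FVC (negative), with
#'   Gaussian noise SDs.
#' @param seed mandatory integer seed.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 500,
                       group_sizes = default_group_sizes(),
                       baseline_meanlog = log(30), baseline_sdlog = 1.5,
                       dispersion_shape = 2, dispersion_mean = 0.2,
                       lib_size_range = c(8e5, 1.2e6),
                       de_genes = NULL,
                       n_de_median = 20, de_median_fold = 4,
                       n_de_tail = 10, de_tail_fold = 4, tail_fraction = 0.3,
                       de_baseline_cpm = 100,
                       mt_fold = 2, mt_subphenotypes = c("E", "Eex"),
                       mt_sexes = "male", mt_baseline_cpm = 1e4,
                       confirmation_mt_fraction = 0.4,
                       covariate_model = list(
                         tlco_intercept = 4.8, tlco_slope = 0.9, tlco_sd = 0.5,
                         tlc_intercept = 6.0, tlc_slope = 0.5, tlc_sd = 0.4,
                         fev_slope = 0.03, fev_sd = 0.05),
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  n_mt <- length(mt_gene_set())
  if (is.null(de_genes)) {
    idx <- n_mt + seq_len(n_de_median + n_de_tail)
    de_genes <- data.frame(
      gene = idx,
      fold = c(rep(de_median_fold, n_de_median), rep(de_tail_fold, n_de_tail)),
      mode = c(rep("median_shift", n_de_median),
               rep("upper_tail_shift", n_de_tail)),
      sexes = c(rep("all", n_de_median), rep("male", n_de_tail)),
      subphenotypes = c(rep("all", n_de_median), rep("E,Eex", n_de_tail)),
      stringsAsFactors = FALSE)
  }
  if (nrow(de_genes) > 0) {
    if (any(de_genes$gene < 1 | de_genes$gene > n_genes))
      stop("de gene index out of range")
    if (any(de_genes$fold <= 0)) stop("fold changes must be > 0")
    if (any(de_genes$gene <= n_mt))
      stop("gene indices 1..", n_mt, " are reserved for the MT block")
  }
  stopifnot(n_genes >= n_mt + nrow(de_genes),
            all(unlist(group_sizes) >= 0),
            mt_fold > 0, tail_fraction > 0, tail_fraction <= 1)
  structure(list(
    n_genes = n_genes, group_sizes = group_sizes,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    dispersion_shape = dispersion_shape, dispersion_mean = dispersion_mean,
    lib_size_range = lib_size_range, de_genes = de_genes,
    tail_fraction = tail_fraction, de_baseline_cpm = de_baseline_cpm,
    mt_fold = mt_fold, mt_subphenotypes = mt_subphenotypes,
    mt_sexes = mt_sexes, mt_baseline_cpm = mt_baseline_cpm,
    confirmation_mt_fraction = confirmation_mt_fraction,
    covariate_model = covariate_model, seed = as.integer(seed)),
    class = "sim_config")
}

.sim_metadata <- function(group_sizes) {
  rows <- list()
  for (sx in names(group_sizes)) {
    sizes <- group_sizes[[sx]]
    for (grp in names(sizes)) {
      n <- sizes[[grp]]
      if (n == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        sex = sx,
        disease_status = if (grp == "control") "control" else "case",
        subphenotype = if (grp %in% c("control", "confirmation")) "none" else grp,
        cohort = if (grp == "confirmation") "confirmation" else "discovery",
        stringsAsFactors = FALSE)[rep(1, n), ]
    }
  }
  meta <- do.call(rbind, rows)
  meta$sample_id <- sprintf("S%04d", seq_len(nrow(meta)))
  rownames(meta) <- NULL
  meta[, c("sample_id", "disease_status", "sex", "subphenotype", "cohort")]
}

.affected_samples <- function(meta, sexes, subphenotypes) {
  sx <- if (identical(sexes, "all")) c("male", "female") else
    strsplit(sexes, ",", fixed = TRUE)[[1]]
  is_case <- meta$disease_status == "case"
  if (identical(subphenotypes, "all")) {
    hit <- is_case
  } else {
    sp <- strsplit(subphenotypes, ",", fixed = TRUE)[[1]]
    hit <- is_case & meta$subphenotype %in% sp
  }
  which(hit & meta$sex %in% sx)
}

#' Simulate a CT-phenotyped case/control RNA-seq cohort
#'
#' Counts are drawn as \code{NB(mean = baseline x library-composition x
#' fold, dispersion)} per gene and sample. Whole-distribution
#' (\code{median_shift}) spike-ins multiply the mean of every affected
#' sample; \code{upper_tail_shift} spike-ins multiply the mean in a random
#' \code{tail_fraction} of the affected group only, so the group median
#' stays roughly unchanged while the upper quartile moves. The first eight
#' genes are the mitochondrial block (named as in
#' \code{\link{mt_gene_set}}), elevated in the configured subgroup and in a
#' random fraction of the confirmation cases; TLCO/Va, TLC and case
#' FEV1/FVC covariates are generated from the realized signature score.
#' Fully reproducible from \code{config$seed}.
#'
#' @param config \code{\link{sim_config}} object.
#' @return list with \code{counts} (validated integer matrix),
#'   \code{metadata} (validated data.frame), \code{ground_truth}
#'   (data.frame of non-null genes: gene_id, mode, fold, sexes,
#'   subphenotypes) and \code{mt_high_confirmation} (sample ids of
#'   MT-elevated confirmation cases).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, function() {
    n_mt <- length(mt_gene_set())
    ng <- config$n_genes
    gene_ids <- c(mt_gene_set(),
                  sprintf("ENSG%08d.%d", seq_len(ng - n_mt),
                          1 + (seq_len(ng - n_mt) %% 17)))
    meta <- .sim_metadata(config$group_sizes)
    ns <- nrow(meta)

    baseline <- rlnorm(ng, config$baseline_meanlog, config$baseline_sdlog)
    baseline[seq_len(n_mt)] <- rlnorm(n_mt, log(config$mt_baseline_cpm), 0.1)
    if (nrow(config$de_genes) > 0)
      baseline[config$de_genes$gene] <-
        rlnorm(nrow(config$de_genes), log(config$de_baseline_cpm), 0.3)
    # baselines are in cpm units: rescale the null genes so the library
    # totals 1e6 and the MT-block / spike-in baselines sit on the true cpm
    # scale (the nulls stand in for the rest of the transcriptome)
    fixed <- c(seq_len(n_mt), config$de_genes$gene)
    null_idx <- setdiff(seq_len(ng), fixed)
    spare <- 1e6 - sum(baseline[fixed])
    if (length(null_idx) > 0 && spare > 0)
      baseline[null_idx] <- baseline[null_idx] * spare / sum(baseline[null_idx])
    dispersion <- rgamma(ng, shape = config$dispersion_shape,
                         rate = config$dispersion_shape / config$dispersion_mean)
    lib <- runif(ns, config$lib_size_range[1], config$lib_size_range[2])

    fold <- matrix(1, nrow = ng, ncol = ns)
    truth <- list()
    for (i in seq_len(nrow(config$de_genes))) {
      de <- config$de_genes[i, ]
      hit <- .affected_samples(meta, de$sexes, de$subphenotypes)
      if (de$mode == "upper_tail_shift") {
        hit <- sample(hit, size = max(1, round(config$tail_fraction * length(hit))))
      }
      fold[de$gene, hit] <- de$fold
      truth[[length(truth) + 1]] <- data.frame(
        gene_id = gene_ids[de$gene], mode = de$mode, fold = de$fold,
        sexes = de$sexes, subphenotypes = de$subphenotypes,
        stringsAsFactors = FALSE)
    }
    mt_hit <- .affected_samples(meta,
                                paste(config$mt_sexes, collapse = ","),
                                paste(config$mt_subphenotypes, collapse = ","))
    conf_cases <- which(meta$cohort == "confirmation")
    mt_conf <- sort(sample(conf_cases,
                           size = round(config$confirmation_mt_fraction *
                                          length(conf_cases))))
    for (g in seq_len(n_mt)) {
      fold[g, c(mt_hit, mt_conf)] <- config$mt_fold
      truth[[length(truth) + 1]] <- data.frame(
        gene_id = gene_ids[g], mode = "mt_block", fold = config$mt_fold,
        sexes = paste(config$mt_sexes, collapse = ","),
        subphenotypes = paste(config$mt_subphenotypes, collapse = ","),
        stringsAsFactors = FALSE)
    }

    # sequencing draws a fixed depth from the perturbed composition
    w <- sweep(fold, 1, baseline, "*")
    w <- sweep(w, 2, colSums(w), "/")
    mu <- sweep(w, 2, lib, "*")
    counts <- matrix(rnbinom(ng * ns, mu = mu,
                             size = rep(1 / dispersion, ns)),
                     nrow = ng, ncol = ns,
                     dimnames = list(gene_ids, meta$sample_id))

    # covariates from the realized (plain-cpm) signature score
    cpm0 <- sweep(counts, 2, colSums(counts), "/") * 1e6
    score <- colSums(cpm0[seq_len(n_mt), , drop = FALSE])
    z <- as.numeric(scale(score))
    cm <- config$covariate_model
    is_ctl <- meta$disease_status == "control"
    meta$fev1_fvc <- ifelse(
      is_ctl, runif(ns, 0.755, 0.88),
      pmin(0.69, pmax(0.25, 0.55 - cm$fev_slope * z + rnorm(ns, 0, cm$fev_sd))))
    meta$tlco_va <- cm$tlco_intercept - cm$tlco_slope * z +
      rnorm(ns, 0, cm$tlco_sd)
    meta$tlc <- cm$tlc_intercept + cm$tlc_slope * z + rnorm(ns, 0, cm$tlc_sd)

    validate_counts(counts)
    list(counts = counts,
         metadata = validate_metadata(meta),
         ground_truth = if (length(truth) > 0) do.call(rbind, truth) else
           data.frame(gene_id = character(0), mode = character(0),
                      fold = numeric(0), sexes = character(0),
                      subphenotypes = character(0)),
         mt_high_confirmation = meta$sample_id[mt_conf])
  })
}

#' Simulate a qPCR delta-Ct table
#'
#' Cycle thresholds are generated so that \code{2^|ct_gene -
#' housekeeping_ct|} recovers the configured per-group fold enrichment, up
#' to Gaussian Ct noise.
#'
#' @param fold_by_group named vector of target fold enrichments per group
#'   (defaults emulate mitochondrial-genome copy-number assays in extreme
#'   emphysema vs extreme airway-disease samples).
#' @param n_per_group named integer vector of samples per group.
#' @param gene_name assayed gene.
#' @param housekeeping_mean,housekeeping_sd reference-gene Ct distribution.
#' @param ct_noise_sd Gaussian noise SD on the target Ct, cycles.
#' @param seed mandatory integer seed.
#' @return data.frame: sample_id, group, gene_name, ct, housekeeping_ct.
#' @export
simulate_qpcr <- function(fold_by_group = c(Eex = 440, Aex = 379),
                          n_per_group = c(Eex = 4, Aex = 3),
                          gene_name = "MT-CO2",
                          housekeeping_mean = 24, housekeeping_sd = 0.5,
                          ct_noise_sd = 0.2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(fold_by_group > 0),
            identical(sort(names(fold_by_group)), sort(names(n_per_group))))
  .with_seed(seed, function() {
    rows <- lapply(names(fold_by_group), function(grp) {
      n <- n_per_group[[grp]]
      hk <- rnorm(n, housekeeping_mean, housekeeping_sd)
      ct <- hk - log2(fold_by_group[[grp]]) + rnorm(n, 0, ct_noise_sd)
      data.frame(sample_id = paste0(grp, "_", seq_len(n)), group = grp,
                 gene_name = gene_name, ct = ct, housekeeping_ct = hk,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
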