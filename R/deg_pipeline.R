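## DEG calling (three criteria), sub-phenotype unique-DEG sets, Venn-style
## partitions and the confirmation-cohort direction-concordance check.

#' DEG calling thresholds
#'
#' A gene is differentially expressed when, at one of the tested quantile
#' levels, the multiple-testing-corrected permutation p-value is below
#' \code{fdr_max} (strict), the absolute quantile difference is at least
#' \code{min_abs_diff_cpm} cpm, and the fold change between the two group
#' quantiles is at least \code{min_fold_change}.
#'
#' @param fdr_max FDR cut-off (strict \code{<}), default 0.05.
#' @param min_abs_diff_cpm minimum absolute quantile difference, in cpm,
#'   default 10 (inclusive \code{>=}).
#' @param min_fold_change minimum fold change, default 1.5 (inclusive).
#' @return list of class \code{"deg_thresholds"}.
#' @export
deg_thresholds <- function(fdr_max = 0.05, min_abs_diff_cpm = 10,
                           min_fold_change = 1.5) {
  stopifnot(fdr_max > 0, fdr_max <= 1,
            min_abs_diff_cpm > 0, min_fold_change > 0)
  structure(list(fdr_max = fdr_max,
                 min_abs_diff_cpm = min_abs_diff_cpm,
                 min_fold_change = min_fold_change),
            class = "deg_thresholds")
}

#' Fold change between two group summaries
#'
#' The ratio is always reported \code{>= 1} (larger over smaller) with a
#' direction flag: \code{"up"} when the case summary exceeds the control
#' summary, \code{"down"} for the converse, \code{"none"} when equal. A
#' zero on one side gives an infinite ratio with the appropriate direction.
#'
#' @param cpm_ctl,cpm_case non-negative group summary values (vectorized).
#' @return list with numeric \code{ratio} and character \code{direction}.
#' @export
fold_change <- function(cpm_ctl, cpm_case) {
  if (any(cpm_ctl < 0) || any(cpm_case < 0))
    stop("group summaries must be non-negative")
  hi <- pmax(cpm_ctl, cpm_case)
  lo <- pmin(cpm_ctl, cpm_case)
  ratio <- ifelse(hi == lo, 1, hi / lo)   # 0/0 -> 1; x/0 -> Inf
  direction <- ifelse(cpm_case > cpm_ctl, "up",
                      ifelse(cpm_case < cpm_ctl, "down", "none"))
  list(ratio = as.numeric(ratio), direction = as.character(direction))
}

#' Call differentially expressed genes from permutation test results
#'
#' Applies the three-criterion rule per gene and quantile level; a gene is
#' called when at least one level passes all three criteria simultaneously
#' at that level's group quantiles. The reported cpm pair and ratio come
#' from the qualifying level with the smallest FDR (ties broken median >
#' upper quartile > lower quartile); \code{fdr} is the minimum FDR across
#' qualifying levels.
#'
#' @param results data.frame from \code{\link{test_all_genes}}, with group1
#'   = controls and group2 = cases.
#' @param thresholds \code{\link{deg_thresholds}} object.
#' @param gene_names optional named character vector mapping gene_id to a
#'   display name; defaults to the gene_id itself.
#' @return data.frame of DEG records: \code{gene_id}, \code{gene_name},
#'   \code{cpm_ctl}, \code{cpm_case}, \code{ratio}, \code{direction},
#'   \code{fdr}, \code{level} (reporting level) and
#'   \code{qualifying_levels} (comma-joined).
#' @export
call_degs <- function(results, thresholds = deg_thresholds(),
                      gene_names = NULL) {
  stopifnot(inherits(thresholds, "deg_thresholds"))
  need <- c("gene_id", "level", "q_group1", "q_group2", "y_obs", "fdr")
  miss <- setdiff(need, names(results))
  if (length(miss) > 0)
    stop("results missing column(s): ", paste(miss, collapse = ", "))
  fc <- fold_change(results$q_group1, results$q_group2)
  pass <- results$fdr < thresholds$fdr_max &
    results$y_obs >= thresholds$min_abs_diff_cpm &
    fc$ratio >= thresholds$min_fold_change
  hit <- results[pass, , drop = FALSE]
  if (nrow(hit) == 0) {
    return(data.frame(gene_id = character(0), gene_name = character(0),
                      cpm_ctl = numeric(0), cpm_case = numeric(0),
                      ratio = numeric(0), direction = character(0),
                      fdr = numeric(0), level = character(0),
                      qualifying_levels = character(0),
                      stringsAsFactors = FALSE))
  }
  hit$ratio <- fc$ratio[pass]
  hit$direction <- fc$direction[pass]
  # deterministic reporting level: smallest FDR, ties median > q3 > q1
  tie_rank <- match(hit$level, c("median", "q3", "q1"))
  ord <- order(hit$gene_id, hit$fdr, tie_rank)
  hit <- hit[ord, , drop = FALSE]
  first <- !duplicated(hit$gene_id)
  qual <- tapply(hit$level, hit$gene_id,
                 function(x) paste(intersect(c("q1", "median", "q3"), x),
                                   collapse = ","))
  rec <- hit[first, , drop = FALSE]
  # stable output order: by gene_id (row/column order invariance)
  rec <- rec[order(rec$gene_id), , drop = FALSE]
  nm <- if (is.null(gene_names)) rec$gene_id else {
    out <- gene_names[rec$gene_id]
    ifelse(is.na(out), rec$gene_id, out)
  }
  data.frame(gene_id = rec$gene_id,
             gene_name = as.character(nm),
             cpm_ctl = rec$q_group1,
             cpm_case = rec$q_group2,
             ratio = rec$ratio,
             direction = rec$direction,
             fdr = rec$fdr,
             level = rec$level,
             qualifying_levels = as.character(qual[rec$gene_id]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sub-phenotype unique DEG sets
#'
#' A gene is unique to emphysema-dominant disease when it is significant in
#' the control-vs-E or control-vs-Eex comparison but in neither of the
#' control-vs-A / control-vs-Aex comparisons — and symmetrically for
#' airway-disease-dominant. The two outputs are disjoint by construction
#' (asserted).
#'
#' @param ctl_vs_E,ctl_vs_Eex,ctl_vs_A,ctl_vs_Aex DEG data.frames from
#'   \code{\link{call_degs}}, all against the same control group.
#' @return list with elements \code{E} and \code{A}, each a DEG data.frame
#'   with an added \code{provenance} column listing the comparisons in
#'   which the gene was significant.
#' @export
unique_degs <- function(ctl_vs_E, ctl_vs_Eex, ctl_vs_A, ctl_vs_Aex) {
  sets <- list(ctl_vs_E = ctl_vs_E, ctl_vs_Eex = ctl_vs_Eex,
               ctl_vs_A = ctl_vs_A, ctl_vs_Aex = ctl_vs_Aex)
  ids <- lapply(sets, function(x) x$gene_id)
  e_ids <- setdiff(union(ids$ctl_vs_E, ids$ctl_vs_Eex),
                   union(ids$ctl_vs_A, ids$ctl_vs_Aex))
  a_ids <- setdiff(union(ids$ctl_vs_A, ids$ctl_vs_Aex),
                   union(ids$ctl_vs_E, ids$ctl_vs_Eex))
  stopifnot(length(intersect(e_ids, a_ids)) == 0)
  pick <- function(uids, primary, secondary) {
    rec <- rbind(primary[primary$gene_id %in% uids, , drop = FALSE],
                 secondary[secondary$gene_id %in% setdiff(uids, primary$gene_id),
                           , drop = FALSE])
    rec <- rec[order(rec$gene_id), , drop = FALSE]
    rec$provenance <- vapply(rec$gene_id, function(g) {
      paste(names(sets)[vapply(ids, function(v) g %in% v, logical(1))],
            collapse = ",")
    }, character(1))
    rownames(rec) <- NULL
    rec
  }
  list(E = pick(e_ids, ctl_vs_E, ctl_vs_Eex),
       A = pick(a_ids, ctl_vs_A, ctl_vs_Aex))
}

#' Venn-style partition of two DEG id sets
#'
#' @param set1,set2 character vectors of gene ids.
#' @return list with \code{shared}, \code{only1}, \code{only2}.
#' @export
shared_and_exclusive <- function(set1, set2) {
  set1 <- unique(set1); set2 <- unique(set2)
  list(shared = sort(intersect(set1, set2)),
       only1 = sort(setdiff(set1, set2)),
       only2 = sort(setdiff(set2, set1)))
}

#' Confirmation-cohort direction concordance
#'
#' For each discovery DEG, recomputes the group-quantile summary (at the
#' record's reporting level) for the same controls versus the confirmation
#' cases and reports whether the direction of change agrees. Descriptive
#' only — no significance testing.
#'
#' @param degs DEG data.frame from \code{\link{call_degs}}.
#' @param norm \code{cpm_matrix} containing both cohorts.
#' @param ctl_ids control sample ids (the discovery controls).
#' @param confirmation_ids confirmation-cohort case sample ids.
#' @return list with \code{table} (per-gene directions and agreement flag)
#'   and \code{concordant_fraction}.
#' @export
confirmation_concordance <- function(degs, norm, ctl_ids, confirmation_ids) {
  stopifnot(inherits(norm, "cpm_matrix"))
  if (length(confirmation_ids) == 0) stop("confirmation cohort is empty")
  if (nrow(degs) == 0) stop("no discovery DEGs supplied")
  miss <- setdiff(degs$gene_id, rownames(norm$cpm))
  if (length(miss) > 0)
    stop("DEG gene(s) absent from matrix: ", paste(head(miss, 5), collapse = ", "))
  lv <- .QUANTILE_LEVELS[degs$level]
  q_ctl <- q_conf <- numeric(nrow(degs))
  for (i in seq_len(nrow(degs))) {
    q_ctl[i] <- group_quantile(norm$cpm[degs$gene_id[i], ctl_ids], lv[[i]])
    q_conf[i] <- group_quantile(norm$cpm[degs$gene_id[i], confirmation_ids], lv[[i]])
  }
  dir_conf <- ifelse(q_conf > q_ctl, "up", ifelse(q_conf < q_ctl, "down", "none"))
  tab <- data.frame(gene_id = degs$gene_id,
                    level = degs$level,
                    direction_discovery = degs$direction,
                    direction_confirmation = dir_conf,
                    concordant = dir_conf == degs$direction,
                    stringsAsFactors = FALSE)
  list(table = tab, concordant_fraction = mean(tab$concordant))
}
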