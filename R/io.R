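## IO: count matrices, sample metadata, gene sets, qPCR tables, DEG tables.
## Counts are plain integer matrices (genes x samples) with dimnames; sample
## metadata is a data.frame. Validators enforce the domain invariants.

.SUBPHENOTYPES <- c("E", "A", "Eex", "Aex", "mixed", "normalCT", "none")
.META_COLS <- c("sample_id", "disease_status", "sex", "subphenotype",
                "cohort", "fev1_fvc", "tlco_va", "tlc")

#' Strip Ensembl-style version suffixes from gene identifiers
#'
#' Versioned identifiers (e.g. \code{"ENSG00000244734.18"}) are retained
#' verbatim as primary keys throughout the package; this helper builds the
#' version-stripped alias used for lookups against unversioned gene lists.
#'
#' @param ids character vector of gene identifiers.
#' @return character vector with a trailing \code{".<digits>"} removed.
#' @export
strip_gene_version <- function(ids) {
  sub("\\.[0-9]+$", "", ids)
}

#' Validate a gene-by-sample count matrix
#'
#' Checks the count-matrix invariants: a numeric matrix of non-negative
#' integers with unique, non-empty gene and sample identifiers in its
#' dimnames. Violations raise errors naming the offending cell or id.
#'
#' @param counts numeric matrix, genes in rows, samples in columns.
#' @return the matrix, invisibly, with storage mode coerced to integer-valued
#'   double left untouched.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (genes x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "invalid count at gene '%s', sample '%s': %s (must be a non-negative integer)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, 1], bad[1, 2]])))
  }
  invisible(counts)
}

#' Read a raw count matrix
#'
#' Reads either a tab-separated table (first column gene id, header row of
#' sample ids) or a MatrixMarket triplet file with side files listing row
#' (gene) and column (sample) names, one id per line.
#'
#' @param path path to the TSV file, or to the \code{.mtx} file.
#' @param format \code{"tsv"} or \code{"mtx"}.
#' @param genes_path,samples_path side files for \code{format = "mtx"};
#'   default \code{<path>.genes} and \code{<path>.samples}.
#' @return validated integer count matrix with gene/sample dimnames.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        genes_path = paste0(path, ".genes"),
                        samples_path = paste0(path, ".samples")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L)
      stop("malformed header at line 1 of ", path,
           ": expected gene-id column plus at least one sample column")
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = c("character", rep("numeric", length(header) - 1L)),
                      quote = "")
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab[[1]]
  } else {
    if (!file.exists(genes_path)) stop("missing gene side file: ", genes_path)
    if (!file.exists(samples_path)) stop("missing sample side file: ", samples_path)
    m <- Matrix::readMM(path)
    counts <- as.matrix(m)
    gids <- readLines(genes_path)
    sids <- readLines(samples_path)
    if (length(gids) != nrow(counts) || length(sids) != ncol(counts))
      stop("side-file lengths do not match matrix dimensions in ", path)
    rownames(counts) <- gids
    colnames(counts) <- sids
  }
  validate_counts(counts)
  counts
}

#' Read sample metadata
#'
#' Tab-separated table with columns \code{sample_id}, \code{disease_status}
#' (case/control), \code{sex} (male/female), \code{subphenotype} (one of E,
#' A, Eex, Aex, mixed, normalCT, none; blank is read as none), \code{cohort}
#' (discovery/confirmation) and optional numeric covariates
#' \code{fev1_fvc}, \code{tlco_va}, \code{tlc}.
#'
#' @param path path to the TSV file.
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE, quote = "")
  for (col in c("fev1_fvc", "tlco_va", "tlc"))
    if (!col %in% names(meta)) meta[[col]] <- NA_real_
  validate_metadata(meta)
}

#' Validate a sample metadata table
#'
#' @param meta data.frame with the columns described in
#'   \code{\link{read_metadata}}.
#' @return the validated (and token-normalized) data.frame.
#' @export
validate_metadata <- function(meta) {
  missing_cols <- setdiff(.META_COLS[1:5], names(meta))
  if (length(missing_cols) > 0)
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (anyDuplicated(meta$sample_id))
    stop("sample_id collision: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  sp <- as.character(meta$subphenotype)
  sp[is.na(sp) | sp == ""] <- "none"
  sp[sp %in% c("normal-CT", "normal_CT")] <- "normalCT"
  bad <- setdiff(unique(sp), .SUBPHENOTYPES)
  if (length(bad) > 0)
    stop("unknown subphenotype token(s): ", paste(bad, collapse = ", "))
  meta$subphenotype <- sp
  if (!all(meta$disease_status %in% c("case", "control")))
    stop("disease_status must be 'case' or 'control'")
  if (!all(meta$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (!all(meta$cohort %in% c("discovery", "confirmation")))
    stop("cohort must be 'discovery' or 'confirmation'")
  if (any(meta$disease_status == "control" & meta$subphenotype != "none"))
    stop("controls must have subphenotype 'none'")
  for (col in c("fev1_fvc", "tlco_va", "tlc"))
    meta[[col]] <- as.numeric(meta[[col]])
  rownames(meta) <- NULL
  meta
}

#' Keep only spirometrically eligible controls
#'
#' Controls are retained only when FEV1/FVC is strictly greater than the
#' threshold (default 0.75), excluding borderline samples with possible
#' airflow obstruction. Cases pass through unchanged. Controls with a
#' missing FEV1/FVC are excluded with a warning.
#'
#' @param meta metadata data.frame.
#' @param threshold FEV1/FVC cut-off (strict \code{>}).
#' @return filtered metadata data.frame.
#' @export
filter_eligible_controls <- function(meta, threshold = 0.75) {
  ctl <- meta$disease_status == "control"
  miss <- ctl & is.na(meta$fev1_fvc)
  if (any(miss))
    warning(sum(miss), " control(s) with missing FEV1/FVC excluded: ",
            paste(head(meta$sample_id[miss], 5), collapse = ", "))
  keep <- !ctl | (!is.na(meta$fev1_fvc) & meta$fev1_fvc > threshold)
  out <- meta[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select sample ids by metadata attributes
#'
#' Sub-phenotype selection follows the containment convention of the CT
#' phenotyping: requesting \code{"E"} also returns extreme-emphysema
#' (\code{"Eex"}) samples and requesting \code{"A"} also returns
#' \code{"Aex"} samples, because the extreme halves are subsets of the
#' dominant groups. Requesting \code{"Eex"}/\code{"Aex"} returns only the
#' extreme samples.
#'
#' @param meta metadata data.frame.
#' @param disease_status,sex,subphenotype,cohort optional filters; NULL
#'   means no restriction.
#' @return character vector of sample ids.
#' @export
select_samples <- function(meta, disease_status = NULL, sex = NULL,
                           subphenotype = NULL, cohort = NULL) {
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(disease_status)) keep <- keep & meta$disease_status %in% disease_status
  if (!is.null(sex)) keep <- keep & meta$sex %in% sex
  if (!is.null(subphenotype)) {
    expand <- unique(unlist(lapply(subphenotype, function(p) {
      switch(p, E = c("E", "Eex"), A = c("A", "Aex"), p)
    })))
    keep <- keep & meta$subphenotype %in% expand
  }
  if (!is.null(cohort)) keep <- keep & meta$cohort %in% cohort
  meta$sample_id[keep]
}

#' Read a gene set (one identifier per line)
#'
#' Blank lines and lines starting with \code{#} are ignored.
#'
#' @param path path to the text file.
#' @return character vector of gene identifiers.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (length(ids) == 0) stop("empty gene set: ", path)
  ids
}

#' Read a qPCR cycle-threshold table
#'
#' Tab-separated with columns \code{sample_id}, \code{gene_name}, \code{ct}
#' and \code{housekeeping_ct} (reference-gene cycle threshold); extra
#' columns are kept.
#'
#' @param path path to the TSV file.
#' @return data.frame of validated measurements.
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_name", "ct", "housekeeping_ct")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("qPCR table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(tab$ct)) || !all(is.finite(tab$housekeeping_ct)) ||
      any(tab$ct <= 0) || any(tab$housekeeping_ct <= 0))
    stop("Ct values must be finite and > 0")
  tab
}

#' Write a DEG table
#'
#' Six tab-separated columns mirroring the conventional published layout:
#' \code{gene_name}, \code{ensembl_id}, \code{cpm_ctl}, \code{cpm_case},
#' \code{Ratio}, \code{FDR}. Rows are ordered up-regulated before
#' down-regulated, descending ratio within direction. The ratio is printed
#' at 2-decimal display precision; cpm and FDR columns carry 6 significant
#' digits so a re-read (\code{\link{read_deg_table}}, which recomputes the
#' ratio from the cpm columns) round-trips the records.
#'
#' @param records DEG data.frame from \code{\link{call_degs}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_deg_table <- function(records, path) {
  cols <- c("gene_name", "gene_id", "cpm_ctl", "cpm_case", "ratio", "fdr",
            "direction")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0)
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "))
  ord <- order(factor(records$direction, levels = c("up", "none", "down")),
               -records$ratio, records$gene_id)
  rec <- records[ord, , drop = FALSE]
  out <- data.frame(
    gene_name = rec$gene_name,
    ensembl_id = rec$gene_id,
    cpm_ctl = signif(rec$cpm_ctl, 6),
    cpm_case = signif(rec$cpm_case, 6),
    Ratio = sprintf("%.2f", rec$ratio),
    FDR = signif(rec$fdr, 6),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DEG table written by \code{\link{write_deg_table}}
#'
#' The full-precision ratio and direction are recomputed from the cpm
#' columns (the printed Ratio column is display-rounded).
#'
#' @param path path to the TSV file.
#' @return DEG data.frame.
#' @export
read_deg_table <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  fc <- fold_change(tab$cpm_ctl, tab$cpm_case)
  data.frame(
    gene_id = tab$ensembl_id,
    gene_name = tab$gene_name,
    cpm_ctl = tab$cpm_ctl,
    cpm_case = tab$cpm_case,
    ratio = fc$ratio,
    direction = fc$direction,
    fdr = tab$FDR,
    stringsAsFactors = FALSE)
}
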