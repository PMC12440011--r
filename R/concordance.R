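#' Cell-level quality-control thresholds
#'
#' Defaults follow the stated filtering rules for the organoid single-cell
#' data: cells are kept when UMI count, detected-gene count, mitochondrial
#' fraction and ribosomal fraction are all strictly below their bounds.
#'
#' @param max_umi upper bound on total counts per cell (exclusive).
#' @param max_genes upper bound on detected genes per cell (exclusive).
#' @param max_mito_fraction upper bound on mitochondrial count fraction.
#' @param max_ribo_fraction upper bound on ribosomal count fraction.
#' @return an object of class `cell_qc_thresholds`
#' @export
cell_qc_thresholds <- function(max_umi = 40000, max_genes = 8500,
                               max_mito_fraction = 0.10,
                               max_ribo_fraction = 0.40) {
  stopifnot(max_umi > 0, max_genes > 0,
            max_mito_fraction > 0, max_mito_fraction <= 1,
            max_ribo_fraction > 0, max_ribo_fraction <= 1)
  structure(list(max_umi = max_umi, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction,
                 max_ribo_fraction = max_ribo_fraction),
            class = "cell_qc_thresholds")
}

#' Filter cells of a count matrix by the QC rules
#'
#' A cell is kept iff total counts < max_umi AND detected genes < max_genes
#' AND mitochondrial fraction < max_mito_fraction AND ribosomal fraction <
#' max_ribo_fraction (all strict inequalities). Mitochondrial and ribosomal
#' genes are identified by configurable rowname prefixes.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse) with gene
#'   rownames and cell colnames
#' @param thresholds a [cell_qc_thresholds()]
#' @param mito_prefix prefix of mitochondrial gene names
#' @param ribo_prefixes prefixes of ribosomal gene names
#' @return list with `kept` (character vector of kept cell names) and
#'   `report` (per-cell data.frame of the QC quantities and rule outcomes)
#' @export
qc_filter_cells <- function(counts, thresholds = cell_qc_thresholds(),
                            mito_prefix = "MT-",
                            ribo_prefixes = c("RPS", "RPL")) {
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  if (min(counts) < 0) stop("negative counts")
  genes <- rownames(counts)
  mito <- startsWith(genes, mito_prefix)
  ribo <- Reduce(`|`, lapply(ribo_prefixes, function(p) startsWith(genes, p)))
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mito_frac <- ifelse(total > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / total, 0)
  ribo_frac <- ifelse(total > 0, Matrix::colSums(counts[ribo, , drop = FALSE]) / total, 0)
  report <- data.frame(
    cell = colnames(counts) %||% as.character(seq_along(total)),
    total_umi = as.numeric(total), detected_genes = as.numeric(detected),
    mito_fraction = as.numeric(mito_frac), ribo_fraction = as.numeric(ribo_frac),
    pass_umi = as.numeric(total) < thresholds$max_umi,
    pass_genes = as.numeric(detected) < thresholds$max_genes,
    pass_mito = as.numeric(mito_frac) < thresholds$max_mito_fraction,
    pass_ribo = as.numeric(ribo_frac) < thresholds$max_ribo_fraction,
    stringsAsFactors = FALSE)
  report$kept <- report$pass_umi & report$pass_genes & report$pass_mito & report$pass_ribo
  list(kept = report$cell[report$kept], report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold a differential-expression table
#'
#' Keeps rows with adjusted p <= alpha and |log2FC| >= lfc_min (both bounds
#' inclusive).
#'
#' @param table data.frame with columns `gene`, `log2fc`, `padj`
#' @param alpha adjusted-p cutoff (default 0.05)
#' @param lfc_min minimum absolute log2 fold change (default 0.8)
#' @return the filtered data.frame
#' @export
filter_de <- function(table, alpha = 0.05, lfc_min = 0.8) {
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(table)),
            alpha > 0, alpha < 1, lfc_min >= 0)
  if (anyDuplicated(table$gene)) stop("duplicate gene IDs in DE table")
  if (any(table$padj < 0 | table$padj > 1)) stop("adjusted p outside [0, 1]")
  table[table$padj <= alpha & abs(table$log2fc) >= lfc_min, , drop = FALSE]
}

#' Overlap and directionality concordance of two DE tables
#'
#' Intersects two (pre-filtered) differential-expression gene sets and
#' classifies each shared gene by fold-change sign agreement. A zero log2FC
#' counts as discordant (with a warning). Both "fraction of reference"
#' referents are reported: the overlap as a fraction of each table.
#'
#' @param a reference DE table (data.frame: `gene`, `log2fc`, `padj`)
#' @param b comparison DE table
#' @param apply_filter apply [filter_de()] with the given `alpha`/`lfc_min`
#'   to both tables first
#' @param alpha,lfc_min thresholds used when `apply_filter = TRUE`
#' @return object of class `concordance_report`: counts (`n_overlap`,
#'   `n_concordant`, `n_up_both`, `n_down_both`, `n_discordant`), fractions
#'   of the overlap, overlap fractions of each table, and gene lists per
#'   category
#' @export
overlap_concordance <- function(a, b, apply_filter = FALSE,
                                alpha = 0.05, lfc_min = 0.8) {
  if (apply_filter) {
    a <- filter_de(a, alpha, lfc_min)
    b <- filter_de(b, alpha, lfc_min)
  }
  if (anyDuplicated(a$gene) || anyDuplicated(b$gene))
    stop("duplicate gene IDs in DE table")
  shared <- intersect(a$gene, b$gene)
  la <- a$log2fc[match(shared, a$gene)]
  lb <- b$log2fc[match(shared, b$gene)]
  if (length(shared) > 0 && any(la == 0 | lb == 0))
    warning("zero log2FC among shared genes; counted as discordant")
  up_both <- la > 0 & lb > 0
  down_both <- la < 0 & lb < 0
  conc <- up_both | down_both
  n <- length(shared)
  res <- list(
    n_overlap = n,
    n_concordant = sum(conc),
    n_up_both = sum(up_both),
    n_down_both = sum(down_both),
    n_discordant = n - sum(conc),
    concordant_fraction = if (n > 0) sum(conc) / n else NA_real_,
    up_both_fraction = if (n > 0) sum(up_both) / n else NA_real_,
    down_both_fraction = if (n > 0) sum(down_both) / n else NA_real_,
    overlap_fraction_of_a = if (nrow(a) > 0) n / nrow(a) else NA_real_,
    overlap_fraction_of_b = if (nrow(b) > 0) n / nrow(b) else NA_real_,
    genes = list(up_both = shared[up_both], down_both = shared[down_both],
                 discordant = shared[!conc]))
  class(res) <- "concordance_report"
  res
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Overlap: %d genes; concordant: %d (%.1f%%; %.1f%% up-in-both, %.1f%% down-in-both)\n",
              x$n_overlap, x$n_concordant, 100 * x$concordant_fraction,
              100 * x$up_both_fraction, 100 * x$down_both_fraction))
  invisible(x)
}
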