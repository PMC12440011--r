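#' Generate a pair of differential-expression tables with known overlap
#'
#' Builds two gene-level DE tables (gene, log2fc, padj) sharing exactly
#' `overlap` gene IDs, of which exactly `concordant_up` are upregulated in
#' both and `concordant_down` downregulated in both; the remaining shared
#' genes have opposite signs. Every row passes the significance cutoffs by
#' construction (padj <= alpha, |log2fc| >= lfc_min). The default
#' composition (56 shared genes, 15 up- and 21 down-concordant, i.e. 36/56
#' concordant) matches the organoid-versus-biopsy comparison the package's
#' concordance arithmetic is built for.
#'
#' @param n_genes_a,n_genes_b table sizes
#' @param overlap number of shared gene IDs
#' @param concordant_up shared genes upregulated in both tables
#' @param concordant_down shared genes downregulated in both tables
#' @param alpha,lfc_min cutoffs the generated rows must satisfy
#' @param seed integer seed
#' @return list with `a`, `b` (data.frames) and `truth` (the requested
#'   counts plus the shared gene list)
#' @export
make_de_pair <- function(n_genes_a = 120, n_genes_b = 190, overlap = 56,
                         concordant_up = 15, concordant_down = 21,
                         alpha = 0.05, lfc_min = 0.8, seed = 1) {
  if (concordant_up + concordant_down > overlap)
    stop("concordant_up + concordant_down must be <= overlap")
  if (overlap > min(n_genes_a, n_genes_b))
    stop("overlap must be <= min(n_genes_a, n_genes_b)")
  withr::with_seed(seed, {
    total <- n_genes_a + n_genes_b - overlap
    genes <- sprintf("GENE%05d", sample.int(10 * total, total))
    shared <- genes[seq_len(overlap)]
    only_a <- genes[overlap + seq_len(n_genes_a - overlap)]
    only_b <- genes[n_genes_a + seq_len(n_genes_b - overlap)]

    sign_a <- sign_b <- rep(NA_real_, overlap)
    idx <- sample.int(overlap)     # which shared genes get which role
    up <- idx[seq_len(concordant_up)]
    down <- idx[concordant_up + seq_len(concordant_down)]
    disc <- setdiff(idx, c(up, down))
    sign_a[up] <- 1; sign_b[up] <- 1
    sign_a[down] <- -1; sign_b[down] <- -1
    sign_a[disc] <- sample(c(-1, 1), length(disc), replace = TRUE)
    sign_b[disc] <- -sign_a[disc]

    draw_lfc <- function(n) runif(n, lfc_min, lfc_min + 3)
    draw_p <- function(n) runif(n, 0, alpha)
    a <- data.frame(
      gene = c(shared, only_a),
      log2fc = c(sign_a * draw_lfc(overlap),
                 sample(c(-1, 1), length(only_a), TRUE) * draw_lfc(length(only_a))),
      padj = draw_p(n_genes_a), stringsAsFactors = FALSE)
    b <- data.frame(
      gene = c(shared, only_b),
      log2fc = c(sign_b * draw_lfc(overlap),
                 sample(c(-1, 1), length(only_b), TRUE) * draw_lfc(length(only_b))),
      padj = draw_p(n_genes_b), stringsAsFactors = FALSE)
    a <- a[sample.int(nrow(a)), ]; rownames(a) <- NULL
    b <- b[sample.int(nrow(b)), ]; rownames(b) <- NULL
    list(a = a, b = b,
         truth = list(overlap = overlap, concordant = concordant_up + concordant_down,
                      concordant_up = concordant_up,
                      concordant_down = concordant_down,
                      shared_genes = shared))
  })
}

#' Generate a sparse cell-by-gene count matrix with planted QC violations
#'
#' Baseline cells satisfy all four QC rules with margin; a designated
#' fraction of cells is constructed to violate exactly one named rule
#' (`umi`, `genes`, `mito`, `ribo`) while passing the other three. Gene
#' labels include mitochondrial- (`MT-`) and ribosomal- (`RPS`/`RPL`)
#' prefixed names.
#'
#' @param n_cells,n_genes matrix dimensions
#' @param violate_fractions named numeric vector, rule -> fraction of cells
#'   violating exactly that rule (names among umi, genes, mito, ribo)
#' @param thresholds the [cell_qc_thresholds()] the violations are built
#'   against
#' @param seed integer seed
#' @return list with `counts` (a sparse `dgCMatrix`, genes x cells),
#'   `truth` (kept cell names and the planted rule per cell)
#' @export
make_count_matrix <- function(n_cells = 100, n_genes = 200,
                              violate_fractions = c(umi = 0.1),
                              thresholds = cell_qc_thresholds(
                                max_umi = 1000, max_genes = 100,
                                max_mito_fraction = 0.10,
                                max_ribo_fraction = 0.40),
                              seed = 1) {
  stopifnot(all(violate_fractions >= 0), all(violate_fractions <= 1),
            sum(violate_fractions) <= 1)
  bad <- setdiff(names(violate_fractions), c("umi", "genes", "mito", "ribo"))
  if (length(bad) > 0) stop("unknown QC rule: ", paste(bad, collapse = ", "))
  n_mito <- max(3L, round(0.05 * n_genes))
  n_ribo <- max(6L, round(0.10 * n_genes))
  if (n_genes < n_mito + n_ribo + 20)
    stop("n_genes too small to carry mitochondrial and ribosomal genes")
  if (n_genes - n_mito - n_ribo < thresholds$max_genes + 1 &&
      "genes" %in% names(violate_fractions))
    stop("n_genes too small to realize the detected-genes threshold")
  withr::with_seed(seed, {
    genes <- c(sprintf("MT-ND%d", seq_len(n_mito)),
               sprintf("RPS%d", seq_len(ceiling(n_ribo / 2))),
               sprintf("RPL%d", seq_len(floor(n_ribo / 2))),
               sprintf("GENE%04d", seq_len(n_genes - n_mito - n_ribo)))
    stopifnot(length(genes) == n_genes)
    cells <- sprintf("CELL%04d", seq_len(n_cells))
    is_mito <- startsWith(genes, "MT-")
    is_ribo <- startsWith(genes, "RPS") | startsWith(genes, "RPL")
    plain <- which(!is_mito & !is_ribo)

    n_violate <- round(violate_fractions * n_cells)
    rule_of <- rep("none", n_cells)
    pool <- sample.int(n_cells)
    off <- 0L
    for (rule in names(n_violate)) {
      if (n_violate[[rule]] == 0) next
      rule_of[pool[off + seq_len(n_violate[[rule]])]] <- rule
      off <- off + n_violate[[rule]]
    }

    # baseline target: comfortably inside every rule
    base_genes <- max(5L, floor(min(thresholds$max_genes, length(plain)) / 2))
    counts <- Matrix::Matrix(0, n_genes, n_cells, sparse = TRUE,
                             dimnames = list(genes, cells))
    for (ci in seq_len(n_cells)) {
      rule <- rule_of[ci]
      g <- sample(plain, base_genes)
      v <- rpois(base_genes, 3) + 1
      # keep baseline totals well under the UMI bound
      tot_cap <- floor(thresholds$max_umi / 2)
      if (sum(v) > tot_cap) v <- pmax(1, floor(v * tot_cap / sum(v)))
      col <- numeric(n_genes)
      col[g] <- v
      total <- sum(col)
      # a whiff of mito/ribo signal, far below the fraction bounds
      col[which(is_mito)[1]] <- floor(0.02 * total)
      col[which(is_ribo)[1]] <- floor(0.05 * total)
      total <- sum(col)
      if (rule == "umi") {
        bump <- ceiling(thresholds$max_umi) - total + sample(0:20, 1)
        col[g[1]] <- col[g[1]] + max(bump, 0)
      } else if (rule == "genes") {
        need <- ceiling(thresholds$max_genes) - sum(col > 0)
        if (need > 0) {
          extra <- setdiff(plain, g)[seq_len(need)]
          col[extra] <- 1
        }
      } else if (rule == "mito") {
        tgt <- thresholds$max_mito_fraction
        col[which(is_mito)[1]] <- ceiling((tgt * sum(col[!is_mito])) / (1 - tgt)) + 1
      } else if (rule == "ribo") {
        tgt <- thresholds$max_ribo_fraction
        col[which(is_ribo)[1]] <- ceiling((tgt * sum(col[!is_ribo])) / (1 - tgt)) + 1
      }
      counts[, ci] <- col
    }
    qc <- qc_filter_cells(counts, thresholds)
    planted_kept <- cells[rule_of == "none"]
    if (!setequal(qc$kept, planted_kept))
      stop("internal error: planted QC violations not realized")
    list(counts = counts, truth = list(kept = planted_kept, rule = rule_of,
                                       thresholds = thresholds))
  })
}
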