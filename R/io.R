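#' Write a multi-channel image as TIFF with a channel-map sidecar
#'
#' One TIFF page per channel per z-slice (16-bit, scaled by a stored
#' factor), plus a YAML sidecar (`<path>.channels.yaml`) recording channel
#' names, slice counts and the intensity scale, so the file round-trips
#' without guessing dialects.
#'
#' @param image a `multichannel_image`
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_multichannel_tiff <- function(image, path) {
  chans <- image$channels
  pages <- list()
  slices <- integer(0)
  for (ch in names(chans)) {
    g <- chans[[ch]]
    if (length(dim(g)) == 3) {
      for (z in seq_len(dim(g)[3])) pages[[length(pages) + 1L]] <- g[, , z]
      slices[ch] <- dim(g)[3]
    } else {
      pages[[length(pages) + 1L]] <- g
      slices[ch] <- 1L
    }
  }
  scale <- max(1, max(vapply(pages, max, numeric(1))))
  pages <- lapply(pages, function(p) p / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  yaml::write_yaml(list(channels = as.list(slices), intensity_scale = scale),
                   paste0(path, ".channels.yaml"))
  invisible(path)
}

#' Read a multi-channel TIFF written by [write_multichannel_tiff()]
#'
#' @param path TIFF path (expects the `.channels.yaml` sidecar next to it)
#' @return a `multichannel_image`
#' @export
read_multichannel_tiff <- function(path) {
  side <- paste0(path, ".channels.yaml")
  if (!file.exists(side)) stop("channel-map sidecar not found: ", side)
  meta <- yaml::read_yaml(side)
  pages <- tiff::readTIFF(path, all = TRUE)
  chans <- list()
  i <- 1L
  for (ch in names(meta$channels)) {
    nz <- meta$channels[[ch]]
    if (nz == 1) {
      chans[[ch]] <- pages[[i]] * meta$intensity_scale
      i <- i + 1L
    } else {
      arr <- array(0, dim = c(dim(pages[[i]]), nz))
      for (z in seq_len(nz)) { arr[, , z] <- pages[[i]] * meta$intensity_scale; i <- i + 1L }
      chans[[ch]] <- arr
    }
  }
  structure(list(channels = chans, pixel_size = NULL),
            class = "multichannel_image")
}

#' Write a DE table as CSV (gene, log2fc, padj)
#' @param table data.frame with columns `gene`, `log2fc`, `padj`
#' @param path output path
#' @export
write_de_table <- function(table, path) {
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(table)))
  write.csv(table[, c("gene", "log2fc", "padj")], path, row.names = FALSE)
  invisible(path)
}

#' Read a DE table from CSV with configurable column mapping
#' @param path CSV/TSV path
#' @param gene_col,log2fc_col,padj_col column names in the file
#' @param sep field separator
#' @export
read_de_table <- function(path, gene_col = "gene", log2fc_col = "log2fc",
                          padj_col = "padj", sep = ",") {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(c(gene_col, log2fc_col, padj_col), names(raw))
  if (length(miss) > 0)
    stop("columns not found in ", path, ": ", paste(miss, collapse = ", "))
  data.frame(gene = raw[[gene_col]], log2fc = raw[[log2fc_col]],
             padj = raw[[padj_col]], stringsAsFactors = FALSE)
}

#' Write a sparse count matrix as MTX with gene/barcode TSVs
#' @param counts genes x cells sparse matrix with dimnames
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`
#' @export
write_count_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read an MTX count matrix with gene/barcode TSVs
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  methods::as(m, "CsparseMatrix")
}
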