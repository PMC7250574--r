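#' Read and write BED6 peak files
#'
#' Peaks are carried as tibbles in BED convention: half-open, 0-based
#' `[start, end)` coordinates. `read_bed()` accepts 3-6 column BED; missing
#' names are filled with `chrom:start-end`, missing scores with 0 and missing
#' strands with `"."`.
#'
#' @param path File path.
#' @param intervals Tibble with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @return `read_bed()` returns a tibble with columns `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`; `write_bed()` returns `path` invisibly.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE, comment = "#")
  if (ncol(x) < 3L) abort(sprintf("BED file '%s' has fewer than 3 columns", path))
  x <- x[, seq_len(min(6L, ncol(x))), drop = FALSE]
  names(x) <- cols[seq_len(ncol(x))]
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (!"name" %in% names(x)) {
    x$name <- paste0(x$chrom, ":", x$start, "-", x$end)
  }
  if (!"score" %in% names(x)) x$score <- 0
  if (!"strand" %in% names(x)) x$strand <- "."
  bad <- which(x$start >= x$end | x$start < 0L)
  if (length(bad)) {
    abort(sprintf("malformed interval (start >= end or start < 0) in '%s' at line %s",
                  path, paste(bad, collapse = ", ")))
  }
  as_tibble(x)
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  col <- function(nm, default) {
    if (nm %in% names(intervals)) intervals[[nm]] else default
  }
  out <- tibble(
    chrom = intervals$chrom,
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = col("name", paste0(intervals$chrom, ":", intervals$start, "-",
                              intervals$end)),
    score = col("score", 0),
    strand = col("strand", ".")
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Extract TSS records from a GFF3 annotation
#'
#' Reads `gene` (or `mRNA`) features from a GFF3 file and returns one TSS per
#' feature: the feature start on the + strand, the feature end on the −
#' strand. GFF3 1-based closed coordinates are converted to 0-based.
#'
#' @param path GFF3 file.
#' @param feature_type Feature types to use (default `c("gene", "mRNA")`;
#'   genes win when both are present for the same ID).
#' @return Tibble with columns `chrom`, `pos` (0-based TSS coordinate),
#'   `gene_id`, `strand`.
#' @export
read_gff_tss <- function(path, feature_type = c("gene", "mRNA")) {
  x <- readr::read_tsv(
    path, col_names = c("seqid", "source", "type", "start", "end",
                        "score", "strand", "phase", "attributes"),
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character(),
                            start = readr::col_double(),
                            end = readr::col_double())
  )
  x <- x[x$type %in% feature_type, , drop = FALSE]
  if (nrow(x) == 0L) abort(sprintf("no '%s' features in '%s'",
                                   paste(feature_type, collapse = "/"), path))
  id <- stringr::str_match(x$attributes, "ID=([^;]+)")[, 2]
  id[is.na(id)] <- stringr::str_match(x$attributes, "Name=([^;]+)")[, 2][is.na(id)]
  tss0 <- ifelse(x$strand == "-", x$end - 1, x$start - 1)
  out <- tibble(chrom = x$seqid, pos = as.integer(tss0),
                gene_id = id, strand = x$strand)
  distinct(out, .data$gene_id, .keep_all = TRUE)
}

#' Read/write a peak-by-sample count matrix
#'
#' The TSV layout is a header row of sample names and a first column of
#' feature (peak) names.
#'
#' @param path File path.
#' @param counts Integer matrix with feature rownames and sample colnames.
#' @return `read_count_matrix()` returns an integer matrix.
#' @export
read_count_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(x[[1]])
  m
}

#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(counts, path) {
  df <- tibble(feature = rownames(counts))
  df <- dplyr::bind_cols(df, as_tibble(counts))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample`, `timepoint`, `condition`,
#'   `replicate`.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "timepoint", "condition", "replicate")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(sprintf("sample sheet missing columns: %s",
                                  paste(miss, collapse = ", ")))
  x
}

#' Read peak sequences from FASTA
#'
#' @param path FASTA file keyed by peak name.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_peak_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' @rdname read_peak_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_peak_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a sparse single-cell count matrix
#'
#' Expects MatrixMarket counts with genes as rows, plus a one-column gene TSV
#' and a cell metadata TSV (`cell`, `timepoint`, `cluster`).
#'
#' @param mtx,genes,cells File paths.
#' @return List with `counts` (dgCMatrix, genes x cells) and `meta` (tibble).
#' @export
read_sc_counts <- function(mtx, genes, cells) {
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  g <- readr::read_tsv(genes, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_tsv(cells, show_col_types = FALSE, progress = FALSE)
  if (nrow(g) != nrow(m)) abort("gene table does not match matrix rows")
  if (nrow(meta) != ncol(m)) abort("cell metadata does not match matrix columns")
  rownames(m) <- g[[1]]
  colnames(m) <- meta$cell
  list(counts = m, meta = meta)
}

#' Read per-timepoint bulk expression tables
#'
#' @param paths Named character vector, one TSV (`gene_id`, `cpm`) per
#'   timepoint; names are the timepoint labels.
#' @return Long tibble (`gene_id`, `timepoint`, `cpm`).
#' @export
read_bulk_expression <- function(paths) {
  stopifnot(!is.null(names(paths)), all(nzchar(names(paths))))
  purrr::imap_dfr(paths, function(p, tp) {
    x <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    tibble(gene_id = x$gene_id, timepoint = tp, cpm = x$cpm)
  })
}

#' Read a gene-list file (one symbol per line)
#' @param path File path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}
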