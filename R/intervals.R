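#' Merge overlapping and bookended intervals
#'
#' Produces a sorted, non-overlapping interval set covering exactly the bases
#' covered by the input. Intervals that overlap or are bookended
#' (`end == start`) are merged, which is what peak-set compilation across
#' libraries requires: the union of covered bases with a minimal number of
#' records.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (BED half-open,
#'   0-based).
#' @return Tibble (`chrom`, `start`, `end`, `name`) sorted by chromosome and
#'   start; names are `chrom:start-end`.
#' @export
merge_intervals <- function(intervals) {
  check_intervals(intervals)
  if (nrow(intervals) == 0L) {
    return(tibble(chrom = character(), start = integer(),
                  end = integer(), name = character()))
  }
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  )
  # min.gapwidth = 1 also merges bookended (adjacent) ranges
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 1L)
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red)
  )
  out <- arrange(out, .data$chrom, .data$start)
  out$name <- paste0(out$chrom, ":", out$start, "-", out$end)
  out
}

#' Partition two peak sets by overlap
#'
#' An interval is "shared" iff it overlaps any interval of the other set by at
#' least one base. Because several intervals on one side can hit one interval
#' on the other, shared counts are reported from each side; unique and shared
#' counts partition each input set.
#'
#' @param set_a,set_b Interval tibbles (`chrom`, `start`, `end`, optional
#'   `name`).
#' @return List with tibbles `unique_a`, `shared_a`, `shared_b`, `unique_b`
#'   and a `counts` tibble (`unique_a`, `shared_a`, `shared_b`, `unique_b`).
#' @export
overlap_sets <- function(set_a, set_b) {
  check_intervals(set_a); check_intervals(set_b)
  hit_a <- overlaps_any(set_a, set_b)
  hit_b <- overlaps_any(set_b, set_a)
  res <- list(
    unique_a = set_a[!hit_a, , drop = FALSE],
    shared_a = set_a[hit_a, , drop = FALSE],
    shared_b = set_b[hit_b, , drop = FALSE],
    unique_b = set_b[!hit_b, , drop = FALSE]
  )
  res$counts <- tibble(unique_a = sum(!hit_a), shared_a = sum(hit_a),
                       shared_b = sum(hit_b), unique_b = sum(!hit_b))
  res
}

overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  qr <- GenomicRanges::GRanges(query$chrom,
                               IRanges::IRanges(query$start + 1L, query$end))
  sr <- GenomicRanges::GRanges(subject$chrom,
                               IRanges::IRanges(subject$start + 1L, subject$end))
  IRanges::overlapsAny(qr, sr)
}

check_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(x$start >= x$end)
  if (length(bad)) {
    abort(sprintf("malformed interval (start >= end) at row %s",
                  paste(bad, collapse = ", ")))
  }
  invisible(x)
}

#' Annotate peaks with their nearest TSS
#'
#' Each peak is assigned the gene whose transcription start site lies closest
#' to the peak midpoint (`floor((start + end) / 2)`). The reported distance is
#' signed relative to the gene: midpoint minus TSS on the + strand and the
#' negation on the − strand, so that negative distances are upstream of the
#' gene. Ties on |distance| are broken by lexicographically smaller
#' `gene_id`, which makes annotation deterministic and independent of TSS
#' input order.
#'
#' @param peaks Interval tibble (`chrom`, `start`, `end`, `name`).
#' @param tss Tibble of TSS records (`chrom`, `pos`, `gene_id`, `strand`), as
#'   from [read_gff_tss()].
#' @return Tibble (`peak`, `gene_id`, `distance`, `status`); peaks on
#'   chromosomes with no TSS get `gene_id = NA` and `status = "no_tss"`.
#' @export
nearest_tss <- function(peaks, tss) {
  check_intervals(peaks)
  stopifnot(all(c("chrom", "pos", "gene_id", "strand") %in% names(tss)))
  if (nrow(peaks) == 0L) {
    return(tibble(peak = character(), gene_id = character(),
                  distance = integer(), status = character()))
  }
  name <- if ("name" %in% names(peaks)) peaks$name else
    paste0(peaks$chrom, ":", peaks$start, "-", peaks$end)
  mid <- (peaks$start + peaks$end) %/% 2L
  out_gene <- rep(NA_character_, nrow(peaks))
  out_dist <- rep(NA_integer_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    ts <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(ts) == 0L) next
    # stable candidate order: position, then gene_id (resolves ties)
    ts <- ts[order(ts$pos, ts$gene_id), , drop = FALSE]
    idx <- findInterval(mid[pi], ts$pos)
    for (j in seq_along(pi)) {
      m <- mid[pi[j]]
      cand <- unique(pmin(pmax(c(idx[j] - 1L, idx[j], idx[j] + 1L, idx[j] + 2L),
                                1L), nrow(ts)))
      d <- abs(m - ts$pos[cand])
      pick <- cand[order(d, ts$gene_id[cand])][1]
      signed <- m - ts$pos[pick]
      if (ts$strand[pick] == "-") signed <- -signed
      out_gene[pi[j]] <- ts$gene_id[pick]
      out_dist[pi[j]] <- signed
    }
  }
  tibble(peak = name, gene_id = out_gene, distance = out_dist,
         status = ifelse(is.na(out_gene), "no_tss", "ok"))
}

#' Distance-to-TSS profile
#'
#' Histogram of signed peak-to-TSS distances over `[-window, +window]`, plus
#' the fraction of peaks within a cutoff of a TSS (the proximal-peak share,
#' e.g. within 500 bp).
#'
#' @param annotations Output of [nearest_tss()].
#' @param bin_width Bin width in bp (default 100).
#' @param window Half-width of the profile in bp (default 5000).
#' @param within Proximity cutoff in bp for `fraction_within` (default 500).
#' @return List with `histogram` (tibble `bin_start`, `bin_end`, `count`) and
#'   `fraction_within` (scalar share with |distance| <= `within`).
#' @export
tss_distance_profile <- function(annotations, bin_width = 100, window = 5000,
                                 within = 500) {
  if (bin_width <= 0) abort("bin_width must be positive")
  d <- annotations$distance[annotations$status == "ok" &
                              !is.na(annotations$distance)]
  if (length(d) == 0L) abort("no annotated peaks to profile")
  breaks <- seq(-window, window, by = bin_width)
  if (tail(breaks, 1) < window) breaks <- c(breaks, window)
  dd <- d[d >= -window & d <= window]
  nb <- length(breaks) - 1L
  bin <- pmin(findInterval(dd, breaks, rightmost.closed = TRUE), nb)
  hist_tbl <- tibble(bin_start = head(breaks, -1), bin_end = breaks[-1],
                     count = tabulate(bin, nbins = nb))
  frac <- mean(abs(d) <= within)
  structure(
    list(histogram = hist_tbl, fraction_within = frac,
         within = within, n = length(d)),
    class = "tss_profile"
  )
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf("TSS distance profile over %d peaks; %.1f%% within %d bp of a TSS\n",
              x$n, 100 * x$fraction_within, x$within))
  invisible(x)
}
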