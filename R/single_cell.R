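#' Log-normalize single-cell counts
#'
#' Per-cell depth normalization followed by a log transform:
#' `x' = ln(1 + scale * x / libsize)`. Cells with zero total count are
#' dropped with a warning.
#'
#' @param counts Sparse or dense matrix, genes x cells.
#' @param scale Scale factor (default 1e4).
#' @return Matrix of the same type and shape (minus dropped cells).
#' @export
lognormalize <- function(counts, scale = 1e4) {
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) {
    warn(sprintf("dropping %d cell(s) with zero counts", sum(lib == 0)))
    counts <- counts[, lib > 0, drop = FALSE]
    lib <- lib[lib > 0]
  }
  if (inherits(counts, "sparseMatrix")) {
    x <- methods::as(counts, "CsparseMatrix")
    x@x <- log1p(scale * x@x / rep.int(lib, diff(x@p)))
    x
  } else {
    log1p(scale * sweep(counts, 2, lib, "/"))
  }
}

#' Gene-set module score per cell
#'
#' Scores each cell for a gene set against expression-matched controls:
#' genes are binned into `n_bins` equal-frequency bins by their average
#' normalized expression across cells; for every set gene, `n_ctrl` control
#' genes are sampled (seeded, without replacement, capped at the bin size)
#' from its bin excluding set genes; the score is the mean normalized
#' expression of the set minus that of the pooled controls, per cell.
#'
#' @param norm Normalized matrix (genes x cells), as from [lognormalize()].
#' @param gene_set Character vector of set genes.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Controls sampled per set gene (default 100).
#' @param seed Seed for the control draw (default 42).
#' @return Named numeric vector, one score per cell.
#' @export
module_score <- function(norm, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 42) {
  genes <- rownames(norm)
  set <- intersect(gene_set, genes)
  if (!length(set)) {
    abort(sprintf("no gene-set members in the matrix; missing: %s",
                  paste(head(gene_set, 10), collapse = ", ")))
  }
  avg <- Matrix::rowMeans(norm)
  n_bins <- min(n_bins, length(avg))
  # equal-frequency bins on average expression; ties split deterministically
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / length(avg))
  names(bin) <- genes
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(set, function(g) {
      # sorted pool => control draw depends only on gene identity and seed
      pool <- sort(setdiff(genes[bin == bin[g]], set))
      if (!length(pool)) return(character(0))
      sample(pool, size = min(n_ctrl, length(pool)), replace = FALSE)
    }))
  })
  set_mean <- Matrix::colMeans(norm[set, , drop = FALSE])
  ctrl_mean <- if (length(ctrl)) {
    # multiset mean: every set gene contributes its own draws, so the
    # control distribution mirrors the set's expression-bin distribution
    w <- table(ctrl)
    u <- names(w)
    as.numeric(crossprod(as.numeric(w),
                         as.matrix(norm[u, , drop = FALSE]))) / sum(w)
  } else {
    set_mean  # degenerate: controls collapse onto the set, score 0
  }
  setNames(as.numeric(set_mean - ctrl_mean), colnames(norm))
}

#' Assign a cell-cycle phase from S and G2M scores
#'
#' A cell is G1 when both scores are non-positive; otherwise it is assigned
#' the phase with the larger score (S only when strictly larger).
#'
#' @param s_score,g2m_score Numeric vectors of per-cell module scores.
#' @return Character vector in `{"S", "G2M", "G1"}`.
#' @export
assign_phase <- function(s_score, g2m_score) {
  stopifnot(length(s_score) == length(g2m_score),
            all(is.finite(s_score)), all(is.finite(g2m_score)))
  ifelse(s_score <= 0 & g2m_score <= 0, "G1",
         ifelse(s_score > g2m_score, "S", "G2M"))
}

#' Cell-cycle scoring
#'
#' Convenience wrapper: computes S and G2M module scores and assigns a
#' phase per cell.
#'
#' @inheritParams module_score
#' @param s_genes,g2m_genes Phase signature gene sets (must be disjoint).
#' @return Tibble (`cell`, `s_score`, `g2m_score`, `phase`).
#' @export
cell_cycle_scores <- function(norm, s_genes, g2m_genes, n_bins = 24,
                              n_ctrl = 100, seed = 42) {
  if (length(intersect(s_genes, g2m_genes))) {
    abort("S and G2M signature sets must be disjoint")
  }
  s <- module_score(norm, s_genes, n_bins, n_ctrl, seed)
  g <- module_score(norm, g2m_genes, n_bins, n_ctrl, seed + 1L)
  tibble(cell = colnames(norm), s_score = as.numeric(s),
         g2m_score = as.numeric(g), phase = assign_phase(s, g))
}

#' Composition tables of cell metadata
#'
#' Within-timepoint fractions of a category (cluster, phase, ...). The
#' fractions sum to 1 within each timepoint. When a `class_of` mapping is
#' given, a nested table (broad class, then cluster within class) is also
#' returned.
#'
#' @param meta Cell metadata tibble with a `timepoint` column.
#' @param by Category column name (default `"cluster"`).
#' @param class_of Optional named character vector mapping category levels
#'   to broad classes.
#' @return Tibble (`timepoint`, category, `n`, `fraction`); with `class_of`,
#'   a list with `flat` and `nested` tibbles.
#' @export
composition <- function(meta, by = "cluster", class_of = NULL) {
  if (nrow(meta) == 0L) abort("empty cell metadata")
  if (!by %in% names(meta)) abort(sprintf("no column '%s' in metadata", by))
  flat <- meta |>
    dplyr::count(.data$timepoint, .data[[by]], name = "n") |>
    group_by(.data$timepoint) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()
  if (is.null(class_of)) return(flat)
  unknown <- setdiff(unique(meta[[by]]), names(class_of))
  if (length(unknown)) {
    abort(sprintf("categories missing from class_of: %s",
                  paste(unknown, collapse = ", ")))
  }
  nested <- meta |>
    mutate(class = unname(class_of[.data[[by]]])) |>
    dplyr::count(.data$timepoint, .data$class, .data[[by]], name = "n") |>
    group_by(.data$timepoint) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    group_by(.data$timepoint, .data$class) |>
    mutate(fraction_within_class = .data$n / sum(.data$n)) |>
    ungroup()
  list(flat = flat, nested = nested)
}

rank_sum_p <- function(x, y, exact_max = 25L) {
  # two-sided Wilcoxon rank-sum; exact when small and tie-free, otherwise
  # tie-corrected normal approximation without continuity correction
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)]) - m * (m + 1) / 2  # Mann-Whitney U of group 1
  ties <- table(r)
  if (m <= exact_max && n <= exact_max && all(ties == 1L)) {
    lo <- stats::pwilcox(W, m, n)
    hi <- stats::pwilcox(W - 1, m, n, lower.tail = FALSE)
    return(min(1, 2 * min(lo, hi)))
  }
  mu <- m * n / 2
  sig2 <- m * n / 12 * (m + n + 1 - sum(ties^3 - ties) /
                          ((m + n) * (m + n - 1)))
  if (sig2 <= 0) return(1)
  z <- (W - mu) / sqrt(sig2)
  2 * pnorm(-abs(z))
}

#' Rank-sum marker / differential-expression test
#'
#' Two-sided Wilcoxon rank-sum tests on the normalized layer between two
#' cell groups, gene by gene. Genes are kept when detected (raw count > 0)
#' in at least `min_pct` of the cells of either group. The fold change is
#' `log2((mean(expm1(x1)) + 1) / (mean(expm1(x2)) + 1))`, and p-values are
#' Bonferroni-adjusted over the genes tested. With `only_pos`, genes with
#' non-positive fold change are dropped.
#'
#' @param norm Normalized matrix (genes x cells).
#' @param counts Raw count matrix (genes x cells), used for detection
#'   fractions.
#' @param labels Per-cell group labels (length `ncol(norm)`).
#' @param group_1 Label(s) of the first group.
#' @param group_2 Label(s) of the second group; when `NULL`, the complement
#'   of `group_1`.
#' @param min_pct Minimum detection fraction in either group (default 0.3).
#' @param only_pos Keep only positive fold changes (default FALSE).
#' @param logfc_threshold Keep genes with `|log2fc|` at or above this value
#'   (default 0, i.e. no fold-change prefilter; 0.25 is the common
#'   single-cell default and screens out small composition-driven shifts).
#' @return Tibble (`gene`, `log2fc`, `pct_1`, `pct_2`, `p_value`,
#'   `p_adjusted`) sorted by p-value.
#' @export
rank_sum_markers <- function(norm, counts, labels, group_1, group_2 = NULL,
                             min_pct = 0.3, only_pos = FALSE,
                             logfc_threshold = 0) {
  stopifnot(length(labels) == ncol(norm))
  i1 <- labels %in% group_1
  i2 <- if (is.null(group_2)) !i1 else labels %in% group_2
  if (sum(i1) < 3L || sum(i2) < 3L) {
    abort("both groups need at least 3 cells")
  }
  det1 <- Matrix::rowSums(counts[, i1, drop = FALSE] > 0) / sum(i1)
  det2 <- Matrix::rowSums(counts[, i2, drop = FALSE] > 0) / sum(i2)
  keep <- pmax(det1, det2) >= min_pct
  genes <- rownames(norm)[keep]
  if (!length(genes)) {
    return(tibble(gene = character(), log2fc = numeric(), pct_1 = numeric(),
                  pct_2 = numeric(), p_value = numeric(),
                  p_adjusted = numeric()))
  }
  m1 <- as.matrix(norm[genes, i1, drop = FALSE])
  m2 <- as.matrix(norm[genes, i2, drop = FALSE])
  l2fc <- log2((rowMeans(expm1(m1)) + 1) / (rowMeans(expm1(m2)) + 1))
  sel <- abs(l2fc) >= logfc_threshold
  genes <- genes[sel]
  m1 <- m1[sel, , drop = FALSE]; m2 <- m2[sel, , drop = FALSE]
  pv <- vapply(seq_along(genes), function(i) rank_sum_p(m1[i, ], m2[i, ]),
               numeric(1))
  out <- tibble(gene = genes, log2fc = l2fc[sel], pct_1 = det1[keep][sel],
                pct_2 = det2[keep][sel], p_value = pv,
                p_adjusted = pmin(1, pv * length(genes)))
  if (only_pos) out <- filter(out, .data$log2fc > 0)
  arrange(out, .data$p_value, .data$gene)
}
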