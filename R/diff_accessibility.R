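#' Filter a count matrix on counts-per-million
#'
#' Keeps features with at least `min_cpm` counts per million in at least
#' `n_samples - 1` samples (the "one CPM in n − 1 samples" rule), which
#' removes peaks whose counts hover at the detection threshold before
#' differential testing.
#'
#' @param counts Integer matrix, features x samples.
#' @param min_cpm Minimum CPM (default 1).
#' @param min_samples Number of samples required to pass; default
#'   `ncol(counts) - 1`.
#' @param lib_sizes Optional library sizes (default column sums).
#' @return The retained rows of `counts`; warns (not errors) when nothing
#'   survives.
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_samples = NULL,
                       lib_sizes = NULL) {
  lib_sizes <- lib_sizes %||% colSums(counts)
  if (any(lib_sizes <= 0)) abort("all library sizes must be positive")
  min_samples <- min_samples %||% (ncol(counts) - 1L)
  cpm <- t(t(counts) / lib_sizes) * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep)) warn("cpm_filter removed every feature")
  counts[keep, , drop = FALSE]
}

#' Counts per million
#' @inheritParams cpm_filter
#' @param log Return log2 CPM with a prior count.
#' @param prior_count Prior added (on the CPM scale scaled to library size)
#'   before taking logs; default 2.
#' @return Numeric matrix of (log2) CPM.
#' @export
cpm <- function(counts, lib_sizes = NULL, log = FALSE, prior_count = 2) {
  lib_sizes <- lib_sizes %||% colSums(counts)
  if (!log) return(t(t(counts) / lib_sizes) * 1e6)
  # prior scaled per sample so that logs are finite and depth-comparable
  pr <- prior_count * lib_sizes / mean(lib_sizes)
  log2(t((t(counts) + pr) / (lib_sizes + 2 * pr)) * 1e6)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: the reference sample is the one whose
#' 75th-percentile CPM is closest to the mean of those quantiles; each
#' sample's factor is the weighted mean of log2 ratios (M) against the
#' reference after discarding the 30% most extreme M and 5% most extreme A
#' values on each tail, with inverse asymptotic binomial variances as
#' weights. Factors are rescaled to geometric mean 1 so they are relative.
#'
#' @param counts Integer matrix, features x samples (>= 2 samples).
#' @param lib_sizes Optional library sizes.
#' @param logratio_trim,abs_trim Two-sided trim fractions for M and A
#'   (defaults 0.3 and 0.05).
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_sizes = NULL,
                        logratio_trim = 0.3, abs_trim = 0.05) {
  if (ncol(counts) < 2L) abort("TMM needs at least two samples")
  lib_sizes <- lib_sizes %||% colSums(counts)
  if (any(lib_sizes <= 0)) abort("sample with zero library size")
  f75 <- apply(counts, 2, function(y) quantile(y / sum(y), 0.75, names = FALSE))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib_sizes[j], lib_sizes[ref],
             logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  obs <- obs[keep]; ref <- ref[keep]
  p_o <- obs / n_obs
  p_r <- ref / n_ref
  M <- log2(p_o / p_r)
  A <- 0.5 * log2(p_o * p_r)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]
  obs <- obs[fin]; ref <- ref[fin]
  if (length(M) == 0L || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  # inverse of the asymptotic (delta-method binomial) variance of M
  w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))
  2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
}

#' Scale counts to a common effective library size
#'
#' Counts are linearly rescaled so every sample has the geometric-mean
#' effective library size (library size times normalization factor), then
#' rounded half to even. The exact test and the dispersion estimator both
#' assume this equalization.
#'
#' @param counts Integer matrix.
#' @param norm_factors Per-sample factors (default all 1).
#' @param lib_sizes Optional library sizes.
#' @return List: `counts` (equalized integer matrix), `common_lib` (scalar).
#' @export
equalize_counts <- function(counts, norm_factors = NULL, lib_sizes = NULL) {
  lib_sizes <- lib_sizes %||% colSums(counts)
  norm_factors <- norm_factors %||% rep(1, ncol(counts))
  eff <- lib_sizes * norm_factors
  common <- exp(mean(log(eff)))
  scaled <- round(t(t(counts) * (common / eff)))  # round half to even
  storage.mode(scaled) <- "integer"
  list(counts = scaled, common_lib = common)
}

cond_loglik <- function(counts, groups, phi) {
  # conditional log-likelihood of a common NB dispersion given within-group
  # totals, summed over features and groups (equalized library sizes)
  r <- 1 / phi
  ll <- 0
  for (g in unique(groups)) {
    y <- counts[, groups == g, drop = FALSE]
    n <- ncol(y)
    if (n < 2L) next
    z <- rowSums(y)
    use <- z > 0
    if (!any(use)) next
    y <- y[use, , drop = FALSE]; z <- z[use]
    ll <- ll + sum(lgamma(y + r)) - length(z) * n * lgamma(r) -
      sum(lgamma(z + n * r)) + length(z) * lgamma(n * r) +
      sum(lgamma(z + 1)) - sum(lgamma(y + 1))
  }
  ll
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the summed per-feature conditional log-likelihood (conditioning
#' on within-group totals at equalized library sizes) over a log-spaced grid
#' on `[1e-4, 10]`, refined by golden-section search. Features with zero
#' total in a group contribute nothing for that group.
#'
#' @param counts Integer matrix (pre-equalized; see [equalize_counts()]).
#' @param groups Group label per column.
#' @param grid_n Grid resolution (default 25).
#' @return List of class `dispersion_estimate`: `phi`, `method`.
#' @export
estimate_dispersion <- function(counts, groups, grid_n = 25) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (!any(tab >= 2L)) {
    abort("no group has replicates; supply a dispersion manually")
  }
  info <- any(rowSums(counts) > 0) &&
    any(vapply(unique(groups), function(g) {
      y <- counts[, groups == g, drop = FALSE]
      ncol(y) >= 2 && any(apply(y, 1, function(r) length(unique(r)) > 1))
    }, logical(1)))
  grid <- exp(seq(log(1e-4), log(10), length.out = grid_n))
  ll <- vapply(grid, function(p) cond_loglik(counts, groups, p), numeric(1))
  if (!info) {
    warn("counts carry no dispersion information; returning grid minimum")
    return(structure(list(phi = grid[1], method = "cml_grid_degenerate"),
                     class = "dispersion_estimate"))
  }
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  phi <- golden_max(function(p) cond_loglik(counts, groups, p), lo, hi)
  structure(list(phi = phi, method = "cml_grid_golden"),
            class = "dispersion_estimate")
}

golden_max <- function(f, lo, hi, tol = 1e-6, iter = 60) {
  gr <- (sqrt(5) - 1) / 2
  a <- log(lo); b <- log(hi)
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(exp(c_)); fd <- f(exp(d_))
  for (k in seq_len(iter)) {
    if (abs(b - a) < tol) break
    if (fc > fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- f(exp(c_))
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- f(exp(d_))
    }
  }
  exp((a + b) / 2)
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("Common NB dispersion phi = %.4g (%s); BCV = %.3f\n",
              x$phi, x$method, sqrt(x$phi)))
  invisible(x)
}

#' Negative-binomial exact test for a two-group count split
#'
#' Conditions on the total `t = sum(a) + sum(b)`. With each group sum
#' NB-distributed (size `n_g / phi`) at a common per-sample mean, the
#' conditional law of the group-1 sum given `t` is free of the mean; the
#' two-sided p-value sums the conditional probabilities of every split as or
#' less probable than the observed one. At `phi = 0` the conditional law is
#' binomial and the test reduces to the two-sided exact binomial test.
#'
#' @param a,b Count vectors for the two groups, pre-equalized to a common
#'   library size.
#' @param phi Common NB dispersion (>= 0).
#' @return Two-sided p-value.
#' @export
nb_exact_test <- function(a, b, phi) {
  if (phi < 0) abort("phi must be non-negative")
  s_a <- sum(a); t <- s_a + sum(b)
  if (t == 0) return(1)
  n_a <- length(a); n_b <- length(b)
  k <- 0:t
  if (phi == 0) {
    lp <- dbinom(k, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    r_a <- n_a / phi; r_b <- n_b / phi
    # any common success probability cancels after normalization
    lp <- dnbinom(k, size = r_a, prob = 0.5, log = TRUE) +
      dnbinom(t - k, size = r_b, prob = 0.5, log = TRUE)
    lp <- lp - max(lp)
    lp <- lp - log(sum(exp(lp)))
  }
  p_obs <- lp[s_a + 1L]
  min(1, sum(exp(lp[lp <= p_obs + 1e-10])))
}

#' Differential accessibility table for one contrast
#'
#' Runs the full pairwise testing path on a peak count matrix: CPM filtering,
#' TMM normalization, equalization to a common library size, common
#' dispersion estimation, a per-peak NB exact test, and
#' Benjamini-Hochberg adjustment. Direction is called at `fdr <= alpha`:
#' `up_in_2` when the peak is more accessible in `group2`, `up_in_1` when in
#' `group1`, otherwise `ns`.
#'
#' @param counts Integer matrix, peaks x samples.
#' @param sheet Sample sheet tibble (`sample`, `timepoint` or other grouping
#'   column, ...).
#' @param contrast Length-2 character vector `(group1, group2)` of levels of
#'   `group_col`.
#' @param group_col Column of `sheet` holding the grouping factor (default
#'   `"timepoint"`).
#' @param alpha FDR threshold for direction calls (default 0.05).
#' @param min_cpm,min_samples Passed to [cpm_filter()] (on the contrast's
#'   samples).
#' @param phi Optional fixed dispersion; estimated when `NULL`.
#' @return Tibble of class `da_table` (`feature`, `log2fc`, `log_cpm`,
#'   `p_value`, `fdr`, `direction`) sorted by p-value, with the dispersion,
#'   contrast, normalization factors and direction counts as attributes.
#' @export
da_table <- function(counts, sheet, contrast, group_col = "timepoint",
                     alpha = 0.05, min_cpm = 1, min_samples = NULL,
                     phi = NULL) {
  stopifnot(length(contrast) == 2L)
  grp <- sheet[[group_col]]
  if (is.null(grp)) abort(sprintf("sample sheet has no column '%s'", group_col))
  sel <- sheet$sample[grp %in% contrast]
  if (!all(contrast %in% grp)) {
    abort(sprintf("contrast group absent from sample sheet: %s",
                  paste(setdiff(contrast, grp), collapse = ", ")))
  }
  m <- counts[, sel, drop = FALSE]
  groups <- grp[match(sel, sheet$sample)]
  m <- cpm_filter(m, min_cpm = min_cpm, min_samples = min_samples)
  nf <- tmm_factors(m)
  eq <- equalize_counts(m, norm_factors = nf)
  disp <- if (is.null(phi)) estimate_dispersion(eq$counts, groups) else
    structure(list(phi = phi, method = "fixed"), class = "dispersion_estimate")
  i1 <- groups == contrast[1]
  i2 <- groups == contrast[2]
  y <- eq$counts
  pv <- vapply(seq_len(nrow(y)), function(i) {
    nb_exact_test(y[i, i1], y[i, i2], disp$phi)
  }, numeric(1))
  mean1 <- rowMeans(y[, i1, drop = FALSE])
  mean2 <- rowMeans(y[, i2, drop = FALSE])
  log2fc <- log2((mean2 + 0.5) / (mean1 + 0.5))
  log_cpm <- log2(((mean1 + mean2) / 2 + 0.5) / eq$common_lib * 1e6)
  fdr <- p.adjust(pv, method = "BH")
  direction <- dplyr::case_when(
    fdr <= alpha & log2fc > 0 ~ "up_in_2",
    fdr <= alpha & log2fc < 0 ~ "up_in_1",
    TRUE ~ "ns"
  )
  out <- tibble(feature = rownames(y), log2fc = log2fc, log_cpm = log_cpm,
                p_value = pv, fdr = fdr, direction = direction)
  out <- arrange(out, .data$p_value, .data$feature)
  structure(out,
            class = c("da_table", class(out)),
            dispersion = disp$phi, contrast = contrast, alpha = alpha,
            norm_factors = nf,
            direction_counts = c(up_in_1 = sum(direction == "up_in_1"),
                                 up_in_2 = sum(direction == "up_in_2"),
                                 ns = sum(direction == "ns")))
}

#' @export
glance.da_table <- function(x, ...) {
  dc <- attr(x, "direction_counts")
  ct <- attr(x, "contrast")
  tibble(group1 = ct[1], group2 = ct[2], n_tested = nrow(x),
         n_up_in_1 = unname(dc["up_in_1"]), n_up_in_2 = unname(dc["up_in_2"]),
         pct_up_in_1 = 100 * unname(dc["up_in_1"]) / max(1, dc["up_in_1"] + dc["up_in_2"]),
         pct_up_in_2 = 100 * unname(dc["up_in_2"]) / max(1, dc["up_in_1"] + dc["up_in_2"]),
         dispersion = attr(x, "dispersion"), alpha = attr(x, "alpha"))
}

#' @export
tidy.da_table <- function(x, ...) {
  as_tibble(unclass(x)[c("feature", "log2fc", "log_cpm", "p_value", "fdr",
                         "direction")])
}

#' Peaks uniquely or transiently accessible at a timepoint
#'
#' Compares the two differential-accessibility contrasts flanking a
#' timepoint `t` (`t` vs the earlier timepoint and `t` vs the later one).
#' Peaks up at `t` in both contrasts are "transient" — they gain
#' accessibility at `t` and lose it again; peaks up in exactly one contrast
#' are unique to that comparison.
#'
#' @param da_prev DA table of the contrast (earlier, t).
#' @param da_next DA table of the contrast (t, later).
#' @param up_prev,up_next Direction value meaning "up at t" in each table
#'   (defaults `"up_in_2"` and `"up_in_1"` per the contrast orientation
#'   above).
#' @return List of character vectors: `unique_prev_up`, `transient`,
#'   `unique_next_up`, and a `counts` tibble.
#' @export
timepoint_specific_peaks <- function(da_prev, da_next,
                                     up_prev = "up_in_2",
                                     up_next = "up_in_1") {
  a <- da_prev$feature[da_prev$direction == up_prev]
  b <- da_next$feature[da_next$direction == up_next]
  res <- list(unique_prev_up = sort(setdiff(a, b)),
              transient = sort(intersect(a, b)),
              unique_next_up = sort(setdiff(b, a)))
  res$counts <- tibble(unique_prev_up = length(res$unique_prev_up),
                       transient = length(res$transient),
                       unique_next_up = length(res$unique_next_up))
  res
}

#' Classical MDS embedding of samples
#'
#' Classical (metric) multidimensional scaling on Euclidean distances
#' between log2-CPM profiles restricted to the `top_n` most variable peaks.
#' Coordinates are centered at the origin; rank-deficient distance matrices
#' yield fewer informative axes, padded with zeros.
#'
#' @param counts Integer matrix, peaks x samples (>= 3 samples).
#' @param top_n Number of most-variable peaks to use (default 500).
#' @param k Number of dimensions (default 2).
#' @param prior_count Prior for the log-CPM transform.
#' @return Tibble of class `atac_mds` (`sample`, `dim1`, `dim2`, ...), with
#'   eigenvalues and the distance matrix as attributes.
#' @export
mds_embedding <- function(counts, top_n = 500, k = 2, prior_count = 2) {
  if (ncol(counts) < 3L) abort("MDS needs at least 3 samples")
  lc <- cpm(counts, log = TRUE, prior_count = prior_count)
  v <- apply(lc, 1, var)
  use <- head(order(v, decreasing = TRUE), min(top_n, nrow(lc)))
  d <- dist(t(lc[use, , drop = FALSE]))
  fit <- cmdscale(d, k = min(k, ncol(counts) - 1L), eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  colnames(pts) <- paste0("dim", seq_len(k))
  out <- dplyr::bind_cols(tibble(sample = colnames(counts)), as_tibble(pts))
  structure(out, class = c("atac_mds", class(out)),
            eig = fit$eig, dist = d)
}

#' @export
tidy.atac_mds <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.atac_mds <- function(x, ...) {
  eig <- attr(x, "eig")
  pos <- pmax(eig, 0)
  nd <- sum(startsWith(names(x), "dim"))
  tibble(n_samples = nrow(x), n_dims = nd,
         var_explained = sum(pos[seq_len(nd)]) / sum(pos))
}
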