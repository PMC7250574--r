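test_that("cpm_filter applies the one-CPM-in-n-minus-1 rule", {
  m <- rbind(a = c(0L, 0L, 2L, 3L), b = c(2L, 2L, 2L, 2L),
             c = c(0L, 0L, 0L, 0L))
  lib <- rep(1e6, 4)
  kept <- cpm_filter(m, lib_sizes = lib)
  expect_identical(rownames(kept), "b")

  set.seed(301)
  big <- matrix(rnbinom(1000 * 6, mu = 2, size = 1), 1000, 6)
  rownames(big) <- sprintf("f%04d", 1:1000)
  libs <- colSums(big)
  kept2 <- cpm_filter(big, lib_sizes = libs)
  cpm_mat <- t(t(big) / libs) * 1e6
  oracle <- rowSums(cpm_mat >= 1) >= 5
  expect_identical(rownames(kept2), rownames(big)[oracle])
  expect_warning(cpm_filter(matrix(0L, 2, 3, dimnames = list(c("x", "y"), NULL)),
                            lib_sizes = rep(10, 3)),
                 "every feature")
})

test_that("TMM factors are 1 for identical or purely depth-scaled samples", {
  set.seed(302)
  a <- rnbinom(2000, mu = 50, size = 10)
  m <- cbind(s1 = a, s2 = a)
  expect_equal(unname(tmm_factors(m)), c(1, 1), tolerance = 1e-12)
  m2 <- cbind(s1 = a, s2 = 2L * a)
  expect_equal(unname(tmm_factors(m2)), c(1, 1), tolerance = 1e-12)
  expect_error(tmm_factors(m[, 1, drop = FALSE]), "two samples")
})

test_that("TMM factors agree with the edgeR reference on perturbed data", {
  skip_if_not_installed("edgeR")
  set.seed(303)
  m <- matrix(rnbinom(3 * 2000, mu = 100, size = 10), ncol = 3)
  idx <- order(m[, 3], decreasing = TRUE)[1:100]  # inflate top features
  m[idx, 3] <- m[idx, 3] * 10L
  colnames(m) <- paste0("s", 1:3)
  mine <- tmm_factors(m)
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})

test_that("common dispersion is recovered from simulated counts", {
  sim <- simulate_peak_counts(2000, baseline_mean = 100, dispersion = 0.1,
                              seed = 304)
  est <- estimate_dispersion(sim$counts, sim$sheet$timepoint)
  expect_gt(est$phi, 0.08)
  expect_lt(est$phi, 0.12)

  pois <- simulate_peak_counts(2000, baseline_mean = 100, dispersion = 0,
                               seed = 305)
  est0 <- estimate_dispersion(pois$counts, pois$sheet$timepoint)
  expect_lte(est0$phi, 0.01)

  flat <- matrix(5L, 1, 6, dimnames = list("f1", paste0("s", 1:6)))
  expect_warning(
    estd <- estimate_dispersion(flat, rep(c("a", "b"), each = 3)),
    "no dispersion information")
  expect_equal(estd$phi, 1e-4, tolerance = 1e-8)
  expect_error(estimate_dispersion(flat, letters[1:6]), "replicates")
})

test_that("the NB exact test matches closed-form conditional enumeration", {
  # independent oracle: negative-hypergeometric conditional probabilities
  oracle_p <- function(sa, sb, na, nb, phi) {
    t <- sa + sb
    if (t == 0) return(1)
    k <- 0:t
    if (phi == 0) {
      q <- dbinom(k, t, na / (na + nb))
    } else {
      ra <- na / phi; rb <- nb / phi
      q <- choose(k + ra - 1, k) * choose(t - k + rb - 1, t - k) /
        choose(t + ra + rb - 1, t)
    }
    sum(q[q <= q[sa + 1] * (1 + 1e-10)])
  }
  expect_equal(nb_exact_test(c(3, 3), c(3, 3), 0.1), 1)
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), 0.5), 1)

  p <- nb_exact_test(c(5, 5), c(0, 0), 0.1)
  expect_equal(p, oracle_p(10, 0, 2, 2, 0.1), tolerance = 1e-12)

  for (phi in c(0, 0.1, 1)) {
    for (t in c(1, 7, 18, 30)) {
      for (sa in 0:t) {
        mine <- nb_exact_test(c(sa, 0), c(t - sa, 0), phi)
        expect_equal(mine, oracle_p(sa, t - sa, 2, 2, phi),
                     tolerance = 1e-10)
      }
    }
  }
  # Poisson limit equals the two-sided exact binomial test
  for (sa in c(0, 3, 9, 14)) {
    bt <- binom.test(sa, 20, p = 0.5)$p.value
    expect_equal(nb_exact_test(c(sa, 0), c(20 - sa, 0), 0), bt,
                 tolerance = 1e-12)
  }
  bt2 <- binom.test(7, 25, p = 3 / 5)$p.value
  expect_equal(nb_exact_test(c(7, 0, 0), c(18, 0), 0), bt2, tolerance = 1e-12)
  expect_error(nb_exact_test(c(1, 2), c(3, 4), -0.5), "non-negative")
})

test_that("da_table is antisymmetric in the contrast and controls FDR shape", {
  sim <- simulate_peak_counts(800, da_fraction = 0.1, seed = 306)
  d12 <- da_table(sim$counts, sim$sheet, c("g1", "g2"))
  d21 <- da_table(sim$counts, sim$sheet, c("g2", "g1"))
  j <- dplyr::inner_join(tidy(d12), tidy(d21), by = "feature",
                         suffix = c("_a", "_b"))
  expect_equal(j$log2fc_a, -j$log2fc_b, tolerance = 1e-10)
  expect_equal(j$p_value_a, j$p_value_b, tolerance = 1e-12)
  swapped <- c(up_in_2 = "up_in_1", up_in_1 = "up_in_2", ns = "ns")
  expect_identical(unname(swapped[j$direction_a]), j$direction_b)

  # BH adjustment: monotone in p, never below raw p
  expect_true(all(d12$fdr >= d12$p_value - 1e-15))
  expect_true(all(diff(d12$fdr[order(d12$p_value)]) >= -1e-12))
  g <- glance(d12)
  expect_equal(g$n_up_in_1 + g$n_up_in_2 + sum(d12$direction == "ns"),
               nrow(d12))
  expect_error(da_table(sim$counts, sim$sheet, c("g1", "nope")), "absent")
})

test_that("timepoint-specific peaks follow set algebra on direction flags", {
  set.seed(307)
  feats <- sprintf("p%04d", 1:1000)
  mk <- function(up) {
    structure(tibble::tibble(feature = feats,
                             direction = ifelse(feats %in% up, "up_in_2", "ns")),
              class = c("da_table", "tbl_df", "tbl", "data.frame"))
  }
  up_prev <- sample(feats, 300)
  up_next <- sample(feats, 250)
  prev <- mk(up_prev)
  nxt <- structure(tibble::tibble(
    feature = feats,
    direction = ifelse(feats %in% up_next, "up_in_1", "ns")),
    class = c("da_table", "tbl_df", "tbl", "data.frame"))
  res <- timepoint_specific_peaks(prev, nxt)
  expect_equal(res$transient, sort(intersect(up_prev, up_next)))
  expect_equal(res$unique_prev_up, sort(setdiff(up_prev, up_next)))
  expect_equal(res$unique_next_up, sort(setdiff(up_next, up_prev)))

  empty <- mk(character(0))
  res0 <- timepoint_specific_peaks(empty, empty)
  expect_equal(res0$counts$transient, 0L)
})

test_that("classical MDS preserves distances and sample duplicates collapse", {
  set.seed(308)
  m <- matrix(rnbinom(500 * 3, mu = 100, size = 10), 500, 3)
  colnames(m) <- paste0("s", 1:3)
  rownames(m) <- sprintf("f%03d", 1:500)
  emb <- mds_embedding(m, top_n = 500)
  d_in <- as.matrix(attr(emb, "dist"))
  pts <- as.matrix(tidy(emb)[, c("dim1", "dim2")])
  d_out <- as.matrix(dist(pts))
  expect_equal(unname(d_out), unname(d_in), tolerance = 1e-8)

  dup <- cbind(m, m)
  colnames(dup) <- paste0("s", 1:6)
  emb2 <- mds_embedding(dup)
  p2 <- as.matrix(tidy(emb2)[, c("dim1", "dim2")])
  expect_lt(max(abs(p2[1:3, ] - p2[4:6, ])), 1e-8)

  # order invariance up to rotation/reflection (Procrustes residual)
  perm <- c(3, 1, 2)
  emb3 <- mds_embedding(m[, perm], top_n = 500)
  p3 <- as.matrix(tidy(emb3)[, c("dim1", "dim2")])[order(perm), , drop = FALSE]
  p3 <- p3[match(colnames(m), tidy(emb3)$sample[order(perm)]), , drop = FALSE]
  a <- as.matrix(tidy(emb)[, c("dim1", "dim2")])
  b <- as.matrix(tidy(emb3)[match(tidy(emb)$sample, tidy(emb3)$sample),
                            c("dim1", "dim2")])
  s <- svd(t(b) %*% a)
  rot <- s$u %*% t(s$v)
  expect_lt(max(abs(b %*% rot - a)), 1e-6)
  expect_error(mds_embedding(m[, 1:2]), "3 samples")
})
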