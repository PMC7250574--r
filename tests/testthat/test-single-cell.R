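test_that("log-normalization follows ln(1 + scale * x / libsize)", {
  counts <- Matrix::Matrix(matrix(c(0, 1, 3, 0, 2, 4), nrow = 3,
                                  dimnames = list(paste0("g", 1:3),
                                                  c("c1", "c2"))),
                           sparse = TRUE)
  norm <- lognormalize(counts, scale = 1e4)
  lib <- Matrix::colSums(counts)
  expect_equal(norm[1, 1], 0)
  expect_equal(norm[2, 1], log1p(1e4 * 1 / lib[1]), ignore_attr = TRUE)

  # a cell with library size 1e4 and one count gives ln(2)
  c2 <- matrix(0, 2, 1, dimnames = list(c("a", "b"), "c"))
  c2[1, 1] <- 1; c2[2, 1] <- 1e4 - 1
  expect_equal(lognormalize(c2)[1, 1], log(2), ignore_attr = TRUE)

  set.seed(501)
  dense <- matrix(rpois(200, 2), 20, 10,
                  dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  n1 <- lognormalize(dense)
  expect_equal(n1, log1p(1e4 * sweep(dense, 2, colSums(dense), "/")))
  sp <- lognormalize(Matrix::Matrix(dense, sparse = TRUE))
  expect_equal(as.matrix(sp), n1, ignore_attr = TRUE)
  withzero <- cbind(dense, c0 = 0)
  expect_warning(lognormalize(withzero), "zero counts")
})

test_that("module scores recover a planted shift and respect invariances", {
  set.seed(502)
  n_genes <- 200; n_cells <- 400
  base <- rlnorm(n_genes, log(1), 0.4)
  mu <- matrix(base, n_genes, n_cells)
  set_idx <- 1:20
  hot <- 1:150  # planted cells
  mu[set_idx, hot] <- mu[set_idx, hot] * 8
  counts <- matrix(rpois(length(mu), mu), n_genes, n_cells,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   sprintf("c%03d", 1:n_cells)))
  norm <- lognormalize(counts)
  sc <- module_score(norm, rownames(counts)[set_idx], seed = 1)
  expect_gt(mean(sc[hot]) - mean(sc[-hot]), 1)

  # identical cells give identical scores
  same <- matrix(rep(counts[, 1], 5), n_genes,
                 dimnames = list(rownames(counts), paste0("s", 1:5)))
  sc_same <- module_score(lognormalize(same), rownames(counts)[set_idx])
  expect_lt(diff(range(sc_same)), 1e-12)

  # gene order invariance at fixed seed
  sc_perm <- module_score(norm[sample(n_genes), ], rownames(counts)[set_idx],
                          seed = 1)
  expect_equal(sc, sc_perm)
  expect_error(module_score(norm, c("absent1", "absent2")), "missing")
})

test_that("phase assignment applies the two-score decision rule", {
  expect_equal(assign_phase(0.5, -0.2), "S")
  expect_equal(assign_phase(-0.1, -0.3), "G1")
  expect_equal(assign_phase(0.2, 0.4), "G2M")
  expect_equal(assign_phase(0, 0), "G1")
  expect_equal(assign_phase(c(1, -1), c(0.5, -0.5)), c("S", "G1"))
  expect_error(cell_cycle_scores(matrix(1, 2, 2), "a", "a"), "disjoint")
})

test_that("composition fractions equal the counting oracle and sum to one", {
  meta <- tibble::tibble(cell = paste0("c", 1:10),
                         timepoint = "uninjured",
                         cluster = rep(c("A", "B"), c(4, 6)))
  comp <- composition(meta)
  expect_equal(comp$fraction[comp$cluster == "A"], 0.4)

  set.seed(503)
  big <- tibble::tibble(
    cell = sprintf("c%04d", 1:5000),
    timepoint = sample(c("uninjured", "24hpa"), 5000, replace = TRUE),
    cluster = sample(paste0("C", 1:7), 5000, replace = TRUE)
  )
  comp2 <- composition(big)
  oracle <- table(big$timepoint, big$cluster)
  for (i in seq_len(nrow(comp2))) {
    r <- comp2[i, ]
    expect_equal(r$n, unname(oracle[r$timepoint, r$cluster]))
    expect_equal(r$fraction,
                 unname(oracle[r$timepoint, r$cluster] /
                          sum(oracle[r$timepoint, ])))
  }
  sums <- dplyr::summarise(dplyr::group_by(comp2, timepoint),
                           s = sum(fraction))
  expect_equal(sums$s, rep(1, 2))

  one <- composition(meta[meta$timepoint == "uninjured", ])
  expect_false(any(is.na(one$fraction)))
  nested <- composition(big, class_of = setNames(rep(c("prog", "diff"),
                                                     c(3, 4)),
                                                 paste0("C", 1:7)))
  within <- dplyr::summarise(
    dplyr::group_by(nested$nested, timepoint, class),
    s = sum(fraction_within_class))
  expect_equal(within$s, rep(1, 4))
  expect_error(composition(big, class_of = c(C1 = "x")), "missing")
  expect_error(composition(meta[0, ]), "empty")
})

test_that("rank-sum p-values equal exact permutation enumeration for 5 vs 5", {
  set.seed(504)
  x <- c(1.2, 3.4, 0.7, 2.2, 5.1)
  y <- c(0.3, 0.9, 1.8, 0.1, 0.5)
  vals <- c(x, y)
  splits <- combn(10, 5)
  W_obs <- sum(rank(vals)[1:5]) - 15
  Ws <- apply(splits, 2, function(ix) sum(rank(vals)[ix]) - 15)
  p_enum <- min(1, 2 * min(mean(Ws <= W_obs), mean(Ws >= W_obs)))
  mine <- regenatac:::rank_sum_p(x, y)
  expect_equal(mine, p_enum, tolerance = 1e-12)
  expect_equal(mine, wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)

  # tie-corrected normal approximation path matches wilcox.test
  xt <- c(rep(1, 10), rep(2, 20), rep(4, 10))
  yt <- c(rep(1, 18), rep(2, 12), rep(3, 10))
  pt <- regenatac:::rank_sum_p(xt, yt)
  ref <- suppressWarnings(wilcox.test(xt, yt, exact = FALSE,
                                      correct = FALSE)$p.value)
  expect_equal(pt, ref, tolerance = 1e-12)
})

test_that("marker testing filters on detection, adjusts, and flags direction", {
  set.seed(505)
  n_genes <- 60; n1 <- 30; n2 <- 30
  mu <- matrix(2, n_genes, n1 + n2)
  mu[1, 1:n1] <- 20           # marker of group 1
  mu[2, ] <- 0.05             # barely detected anywhere
  counts <- matrix(rpois(length(mu), mu), n_genes, n1 + n2,
                   dimnames = list(sprintf("g%02d", 1:n_genes),
                                   sprintf("c%02d", 1:(n1 + n2))))
  labels <- rep(c("A", "B"), c(n1, n2))
  norm <- lognormalize(counts)
  res <- rank_sum_markers(norm, counts, labels, "A", "B")
  expect_false("g02" %in% res$gene)          # min.pct filter
  expect_equal(res$gene[1], "g01")           # planted marker ranks first
  expect_true(all(res$p_adjusted >= res$p_value))
  pos <- rank_sum_markers(norm, counts, labels, "A", "B", only_pos = TRUE)
  expect_true(all(pos$log2fc > 0))

  # identical groups: p ~ 1, log2fc ~ 0
  dup <- cbind(counts[, 1:10], counts[, 1:10])
  colnames(dup) <- paste0("c", 1:20)
  res_dup <- rank_sum_markers(lognormalize(dup), dup,
                              rep(c("A", "B"), each = 10), "A", "B")
  expect_true(all(abs(res_dup$log2fc) < 1e-12))
  expect_true(all(res_dup$p_value > 0.99))

  # complement is used when group_2 is omitted
  res_c <- rank_sum_markers(norm, counts, labels, "A")
  expect_equal(res_c$gene[1], "g01")
  expect_error(rank_sum_markers(norm, counts, c(labels[-1], "Z"), "Z"),
               "3 cells")
})
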