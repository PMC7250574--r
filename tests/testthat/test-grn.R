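# hand-built miniature stage tables used across the chaining tests ---------

mini_tf_map <- function() {
  tibble::tibble(tf_name = c("TF.a", "TF.b", "TF.z"),
                 gene_id = c("ga", "gb", "gz"),
                 motif_id = c("M.a", "M.b", "M.z"))
}

mini_da <- function(up_feats, all_feats = up_feats) {
  structure(tibble::tibble(
    feature = all_feats,
    log2fc = ifelse(all_feats %in% up_feats, 2, 0),
    log_cpm = 5,
    p_value = ifelse(all_feats %in% up_feats, 1e-6, 0.8),
    fdr = ifelse(all_feats %in% up_feats, 1e-5, 0.9),
    direction = ifelse(all_feats %in% up_feats, "up_in_2", "ns")),
    class = c("da_table", "tbl_df", "tbl", "data.frame"))
}

mini_hits <- function(peak, motif) {
  tibble::tibble(peak = peak, motif_id = motif,
                 tf_name = sub("^M", "TF", motif),
                 offset = 10L, strand = "+", score = 12)
}

mini_annot <- function(peak, gene) {
  tibble::tibble(peak = peak, gene_id = gene, distance = 0L, status = "ok")
}

mini_bulk <- function(genes, stages, cpm = 10) {
  tidyr::expand_grid(gene_id = genes, timepoint = stages) |>
    dplyr::mutate(cpm = cpm)
}

test_that("regulator tables are the three-way join restricted to up peaks", {
  da <- mini_da(c("p1"), c("p1", "p2"))
  hits <- mini_hits(c("p1", "p1", "p2"), c("M.a", "M.b", "M.a"))
  annot <- mini_annot(c("p1", "p2"), c("gx", "gy"))
  tab <- build_regulator_table(da, hits, annot, mini_tf_map(), "24hpa")
  expect_equal(nrow(tab), 2L)           # one DA peak, two motifs
  expect_setequal(tab$motif_id, c("M.a", "M.b"))
  expect_equal(unique(tab$nearest_gene), "gx")

  none <- build_regulator_table(mini_da(character(0), "p1"), hits, annot,
                                mini_tf_map(), "24hpa")
  expect_equal(nrow(none), 0L)
  expect_error(build_regulator_table(da, hits, mini_annot("p2", "gy"),
                                     mini_tf_map(), "24hpa"),
               "lack TSS annotation")
})

test_that("regulator tables equal a nested-loop join oracle on the study", {
  st <- default_study()
  res <- st$res
  stage <- "24hpa"
  da <- res$da[[stage]]
  up <- da$feature[da$direction == "up_in_2"]
  tab <- build_regulator_table(da, res$hits, res$annotations, res$tf_map,
                               stage)
  oracle <- list()
  for (p in up) {
    hh <- res$hits[res$hits$peak == p, ]
    for (m in unique(hh$motif_id)) {
      g <- res$annotations$gene_id[res$annotations$peak == p]
      oracle[[length(oracle) + 1]] <- c(p, m, g)
    }
  }
  expect_equal(nrow(tab), length(oracle))
  key_t <- paste(tab$peak, tab$motif_id, tab$nearest_gene)
  key_o <- vapply(oracle, paste, collapse = " ", FUN.VALUE = character(1))
  expect_setequal(key_t, key_o)
})

test_that("expression vetting drops rows whose TF or target is silent", {
  da <- mini_da("p1")
  tab <- build_regulator_table(da, mini_hits("p1", "M.a"),
                               mini_annot("p1", "gx"), mini_tf_map(), "24hpa")
  bulk_ok <- mini_bulk(c("ga", "gx"), "24hpa")
  expect_equal(nrow(filter_expressed(tab, bulk_ok)), 1L)
  # TF silent
  bulk_tf0 <- dplyr::mutate(bulk_ok, cpm = ifelse(gene_id == "ga", 0, 10))
  expect_equal(nrow(filter_expressed(tab, bulk_tf0)), 0L)
  # target silent
  bulk_tg0 <- dplyr::mutate(bulk_ok, cpm = ifelse(gene_id == "gx", 0, 10))
  expect_equal(nrow(filter_expressed(tab, bulk_tg0)), 0L)
  # missing gene treated as not expressed, with a message
  expect_message(out <- filter_expressed(tab, mini_bulk("ga", "24hpa")),
                 "not expressed")
  expect_equal(nrow(out), 0L)

  # random-table rule oracle
  set.seed(701)
  genes <- sprintf("g%02d", 1:20)
  tab2 <- tibble::tibble(
    stage = "24hpa", peak = sprintf("p%02d", 1:30),
    nearest_gene = sample(genes, 30, replace = TRUE),
    distance = 0L, da_log2fc = 2, da_fdr = 1e-4,
    motif_id = "M.a", tf_name = "TF.a", tf_gene = sample(genes, 30, TRUE),
    hit_score = 10)
  bulk2 <- tibble::tibble(gene_id = genes, timepoint = "24hpa",
                          cpm = round(runif(20, 0, 3), 2))
  kept <- filter_expressed(tab2, bulk2)
  expr <- setNames(bulk2$cpm, bulk2$gene_id)
  oracle <- expr[tab2$tf_gene] >= 1 & expr[tab2$nearest_gene] >= 1
  expect_equal(kept$peak, tab2$peak[oracle])
})

test_that("chaining links stages through TF-coding targets with early activity", {
  tfm <- mini_tf_map()
  act <- tibble::tibble(stage = "6hpa", peak = "p0", nearest_gene = "gaux",
                        distance = 0L, da_log2fc = 2, da_fdr = 1e-4,
                        motif_id = "M.a", tf_name = "TF.a", tf_gene = "ga",
                        hit_score = 10)
  e24 <- dplyr::mutate(act, stage = "24hpa", peak = "p1",
                       nearest_gene = "gb")
  e72 <- dplyr::mutate(act, stage = "72hpa", peak = "p2", motif_id = "M.b",
                       tf_name = "TF.b", tf_gene = "gb", nearest_gene = "gc")
  circ <- chain_circuits(list(`6hpa` = act, `24hpa` = e24, `72hpa` = e72),
                         tfm)
  expect_equal(length(unique(circ$circuit_id)), 1L)
  expect_equal(circ$stage, c("24hpa", "72hpa"))
  expect_equal(circ$tf_gene, c("ga", "gb"))
  expect_equal(circ$target_gene, c("gb", "gc"))

  # no activity evidence at 6hpa: the 24hpa edge cannot start a chain
  act_other <- dplyr::mutate(act, motif_id = "M.z", tf_name = "TF.z",
                             tf_gene = "gz")
  none <- chain_circuits(list(`6hpa` = act_other, `24hpa` = e24,
                              `72hpa` = e72), tfm)
  expect_equal(nrow(none), 0L)

  # dropping the 72hpa edge truncates the chain to length one
  short <- chain_circuits(list(`6hpa` = act, `24hpa` = e24,
                               `72hpa` = e72[0, ]), tfm)
  expect_equal(nrow(short), 1L)
  expect_equal(short$stage, "24hpa")

  # a self-targeting TF is flagged and never loops
  self24 <- dplyr::mutate(e24, nearest_gene = "ga")
  sl <- chain_circuits(list(`6hpa` = act, `24hpa` = self24,
                            `72hpa` = e72[0, ]), tfm)
  expect_true(all(sl$self_loop))
  expect_lte(nrow(sl), 2L)

  empty <- chain_circuits(list(`6hpa` = act[0, ], `24hpa` = e24[0, ],
                               `72hpa` = e72[0, ]), tfm)
  expect_equal(nrow(empty), 0L)
})

test_that("the single-cell DE filter keeps circuits with a DE node", {
  tfm <- mini_tf_map()
  circ <- structure(tibble::tibble(
    circuit_id = c(1L, 1L, 2L), step = c(1L, 2L, 1L),
    stage = c("24hpa", "72hpa", "24hpa"),
    tf_name = c("TF.a", "TF.b", "TF.z"),
    tf_gene = c("ga", "gb", "gz"),
    target_gene = c("gb", "gc", "gq"),
    peak = c("p1", "p2", "p3"), motif_id = c("M.a", "M.b", "M.z"),
    hit_score = 10, da_fdr = 1e-4, self_loop = FALSE),
    class = c("circuit_set", "tbl_df", "tbl", "data.frame"))
  de <- tibble::tibble(gene = c("gc", "gq"), log2fc = c(2, 0.1),
                       pct_1 = 1, pct_2 = 1,
                       p_value = c(1e-9, 0.4), p_adjusted = c(1e-7, 1))
  sc_genes <- c("ga", "gb", "gc", "gz", "gq")
  kept <- filter_by_sc_de(circ, de, sc_genes, alpha = 0.05)
  expect_equal(unique(kept$circuit_id), 1L)
  expect_true(kept$sc_de[kept$target_gene == "gc"])

  # alpha = 1 keeps everything present in the data
  all_kept <- filter_by_sc_de(circ, de, sc_genes, alpha = 1)
  expect_equal(sort(unique(all_kept$circuit_id)), c(1L, 2L))
  # nothing DE: all dropped
  none <- filter_by_sc_de(circ, dplyr::mutate(de, p_adjusted = 1), sc_genes)
  expect_equal(nrow(none), 0L)
  # a node absent from the single-cell data drops the circuit
  missing <- filter_by_sc_de(circ, de, setdiff(sc_genes, "gb"))
  expect_false(1L %in% missing$circuit_id)
  # strict mode requires every node DE
  strict <- filter_by_sc_de(circ, de, sc_genes, strict = TRUE)
  expect_equal(nrow(strict), 0L)
})

test_that("target overlap counts regions by motif membership", {
  tabs <- list(tibble::tibble(
    stage = "24hpa", peak = c("r1", "r2", "r2", "r3"),
    nearest_gene = "gx", distance = 0L, da_log2fc = 2, da_fdr = 1e-4,
    motif_id = c("M.a", "M.a", "M.b", "M.b"),
    tf_name = c("TF.a", "TF.a", "TF.b", "TF.b"),
    tf_gene = c("ga", "ga", "gb", "gb"), hit_score = 10))
  ov <- target_overlap("TF.a", "TF.b", tabs)
  expect_equal(c(ov$only_a, ov$shared, ov$only_b), c(1L, 1L, 1L))
  same <- target_overlap("TF.a", "TF.a", tabs)
  expect_equal(c(same$only_a, same$shared, same$only_b), c(0L, 2L, 0L))
  expect_error(target_overlap("TF.a", "TF.nope", tabs), "absent")
})

test_that("network export is deterministic and parses back", {
  st <- default_study()
  circ <- st$res$circuits
  e1 <- tempfile(fileext = ".tsv"); d1 <- tempfile(fileext = ".dot")
  e2 <- tempfile(fileext = ".tsv"); d2 <- tempfile(fileext = ".dot")
  edges <- export_network(circ, e1, d1)
  export_network(circ, e2, d2)
  expect_identical(readLines(e1), readLines(e2))
  expect_identical(readLines(d1), readLines(d2))
  dot <- readLines(d1)
  expect_equal(dot[1], "digraph regulatory_circuits {")
  expect_equal(dot[length(dot)], "}")
  arrows <- stringr::str_match(dot, "\"(\\S+)\" -> \"(\\S+)\"")
  arrows <- arrows[!is.na(arrows[, 1]), , drop = FALSE]
  expect_setequal(paste(arrows[, 2], arrows[, 3]),
                  unique(paste(edges$tf_gene, edges$target_gene)))

  mt <- circ[0, ]
  e0 <- tempfile(); d0 <- tempfile()
  out0 <- export_network(mt, e0, d0)
  expect_equal(nrow(out0), 0L)
  expect_equal(readLines(d0), c("digraph regulatory_circuits {", "}"))
})
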