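#' Run the integrative regulatory pipeline on a study directory
#'
#' Executes the full analysis on a directory laid out as
#' [generate_dataset()] writes it: differential accessibility between
#' consecutive timepoints, nearest-TSS annotation, motif scanning, term
#' enrichment per stage, single-cell composition / cell-cycle / DE
#' statistics, and temporal circuit chaining with bulk-expression vetting
#' and the single-cell DE filter.
#'
#' @param data_dir Input directory.
#' @param out_dir Optional output directory; when given, all result tables
#'   are written as TSV (plus a DOT graph) with deterministic content.
#' @param alpha FDR threshold for accessibility, enrichment and DE calls.
#' @param min_expr Bulk CPM threshold for expression vetting.
#' @param motif_threshold Fraction-of-maximum PWM score for motif hits.
#' @param strict_de Require every circuit node differentially expressed.
#' @param score_seed Seed for module-score control draws.
#' @return A list with every intermediate and final result (DA tables,
#'   annotations, hits, regulator tables, circuits, enrichment, single-cell
#'   statistics).
#' @export
run_pipeline <- function(data_dir, out_dir = NULL, alpha = 0.05,
                         min_expr = 1, motif_threshold = 0.8,
                         strict_de = FALSE, score_seed = 42) {
  path <- function(...) file.path(data_dir, ...)
  sheet <- read_sample_sheet(path("sample_sheet.tsv"))
  tp <- unique(sheet$timepoint)
  counts <- read_count_matrix(path("atac_counts.tsv"))
  peaks <- read_bed(path("master_peaks.bed"))
  tss <- read_gff_tss(path("annotation.gff3"))
  seqs <- read_peak_fasta(path("peaks.fasta"))
  lib <- read_meme(path("motifs.meme"))
  tf_map <- readr::read_tsv(path("tf_map.tsv"), show_col_types = FALSE,
                            progress = FALSE)
  bulk <- read_bulk_expression(setNames(path(paste0("bulk_", tp, ".tsv")), tp))
  sc <- read_sc_counts(path("sc_counts.mtx"), path("sc_genes.tsv"),
                       path("sc_cells.tsv"))
  s_genes <- read_gene_list(path("s_genes.txt"))
  g2m_genes <- read_gene_list(path("g2m_genes.txt"))
  ont <- ontology(readr::read_tsv(path("ontology_edges.tsv"),
                                  show_col_types = FALSE, progress = FALSE))
  ann_raw <- readr::read_tsv(path("gene2term.tsv"), show_col_types = FALSE,
                             progress = FALSE)

  ## chromatin side ---------------------------------------------------------
  annot <- nearest_tss(peaks, tss)
  hits <- scan_peakset(seqs, lib, threshold = motif_threshold)
  da <- list()
  for (k in 2:length(tp)) {
    da[[tp[k]]] <- da_table(counts, sheet, contrast = c(tp[k - 1], tp[k]),
                            alpha = alpha)
  }
  ann_map <- propagate(ont, ann_raw)
  stage_tables <- list()
  enrichment <- list()
  for (k in 2:length(tp)) {
    st <- tp[k]
    tab <- build_regulator_table(da[[st]], hits, annot, tf_map, stage = st)
    stage_tables[[st]] <- filter_expressed(tab, bulk, stage = st,
                                           min_expr = min_expr)
    up_genes <- annot$gene_id[annot$peak %in%
                                da[[st]]$feature[da[[st]]$direction == "up_in_2"]]
    up_genes <- intersect(unique(up_genes), ann_map$universe)
    enrichment[[st]] <- if (length(up_genes)) {
      enrich(up_genes, ann_map, alpha = alpha)
    } else {
      NULL
    }
  }
  mds <- mds_embedding(counts)

  ## single-cell side -------------------------------------------------------
  norm <- lognormalize(sc$counts)
  cc <- cell_cycle_scores(norm, s_genes, g2m_genes, seed = score_seed)
  meta <- left_join(sc$meta, cc, by = "cell")
  comp_cluster <- composition(meta, by = "cluster")
  comp_phase <- composition(meta, by = "phase")
  sc_tp <- unique(meta$timepoint)
  de <- rank_sum_markers(norm, sc$counts, meta$timepoint,
                         group_1 = sc_tp[1], group_2 = sc_tp[2],
                         logfc_threshold = 0.25)

  ## circuits ---------------------------------------------------------------
  circuits <- chain_circuits(stage_tables, tf_map)
  circuits <- filter_by_sc_de(circuits, de, sc_genes = rownames(sc$counts),
                              alpha = alpha, strict = strict_de)

  res <- list(timepoints = tp, da = da, annotations = annot, hits = hits,
              stage_tables = stage_tables, enrichment = enrichment,
              mds = mds, cell_meta = meta, composition_cluster = comp_cluster,
              composition_phase = comp_phase, sc_de = de,
              circuits = circuits, tf_map = tf_map)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f),
                                         progress = FALSE)
    for (st in names(da)) w(tidy(da[[st]]), paste0("da_", st, ".tsv"))
    w(annot, "annotations.tsv")
    w(hits, "motif_hits.tsv")
    for (st in names(stage_tables)) {
      w(stage_tables[[st]], paste0("regulators_", st, ".tsv"))
    }
    for (st in names(enrichment)) {
      if (!is.null(enrichment[[st]])) {
        e <- mutate(enrichment[[st]],
                    member_genes = purrr::map_chr(.data$member_genes,
                                                  paste, collapse = ","))
        w(e, paste0("enrichment_", st, ".tsv"))
      }
    }
    w(meta, "cell_metadata.tsv")
    w(comp_cluster, "composition_cluster.tsv")
    w(comp_phase, "composition_phase.tsv")
    w(de, "sc_de.tsv")
    w(as_tibble(circuits), "circuits.tsv")
    export_network(circuits, file.path(out_dir, "network_edges.tsv"),
                   file.path(out_dir, "network.dot"))
  }
  res
}
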