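#' Build a per-stage regulator table
#'
#' Joins the peaks that are more accessible at a stage with the motif hits
#' they contain and their nearest-gene annotation: one row per (peak, motif)
#' with the peak's nearest gene as the putative target and the motif's TF as
#' the putative regulator.
#'
#' @param da A [da_table()] for the contrast that defines accessibility at
#'   this stage.
#' @param hits Motif-hit table from [scan_peakset()].
#' @param annot Nearest-TSS annotations from [nearest_tss()].
#' @param tf_map Tibble (`tf_name`, `gene_id`, `motif_id`) mapping motifs to
#'   the genes encoding their TFs.
#' @param stage Timepoint label recorded on every row.
#' @param up Direction value in `da` meaning "more accessible at the stage"
#'   (default `"up_in_2"`).
#' @return Tibble (`stage`, `peak`, `nearest_gene`, `distance`,
#'   `da_log2fc`, `da_fdr`, `motif_id`, `tf_name`, `tf_gene`, `hit_score`);
#'   one row per (peak, motif), best-scoring hit kept.
#' @export
build_regulator_table <- function(da, hits, annot, tf_map, stage,
                                  up = "up_in_2") {
  up_peaks <- da$feature[da$direction == up]
  h <- filter(hits, .data$peak %in% up_peaks)
  missing <- setdiff(unique(h$peak), annot$peak)
  if (length(missing)) {
    abort(sprintf("peaks with motif hits lack TSS annotation: %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(h) == 0L) {
    return(tibble(stage = character(), peak = character(),
                  nearest_gene = character(), distance = integer(),
                  da_log2fc = numeric(), da_fdr = numeric(),
                  motif_id = character(), tf_name = character(),
                  tf_gene = character(), hit_score = numeric()))
  }
  h <- h |>
    group_by(.data$peak, .data$motif_id) |>
    summarise(hit_score = max(.data$score), .groups = "drop")
  out <- h |>
    inner_join(select(annot, "peak", nearest_gene = "gene_id", "distance"),
               by = "peak") |>
    inner_join(select(tidy(da), "feature", da_log2fc = "log2fc",
                      da_fdr = "fdr"),
               by = c(peak = "feature")) |>
    left_join(select(tf_map, "motif_id", "tf_name", tf_gene = "gene_id"),
              by = "motif_id") |>
    mutate(stage = stage) |>
    select("stage", "peak", "nearest_gene", "distance", "da_log2fc",
           "da_fdr", "motif_id", "tf_name", "tf_gene", "hit_score")
  arrange(out, .data$peak, .data$motif_id)
}

#' Vet a regulator table against bulk expression
#'
#' Retains rows whose TF gene *and* nearest (target) gene are expressed at
#' the stage in bulk RNA-seq (CPM at or above `min_expr`). Genes missing
#' from the bulk table are treated as not expressed and reported.
#'
#' @param table A regulator table from [build_regulator_table()].
#' @param bulk Long bulk-expression tibble (`gene_id`, `timepoint`, `cpm`),
#'   as from [read_bulk_expression()].
#' @param stage Timepoint to vet at; defaults to the table's stage.
#' @param min_expr CPM threshold (default 1).
#' @return The filtered regulator table.
#' @export
filter_expressed <- function(table, bulk, stage = NULL, min_expr = 1) {
  if (nrow(table) == 0L) return(table)
  stage <- stage %||% table$stage[1]
  b <- filter(bulk, .data$timepoint == stage)
  if (nrow(b) == 0L) abort(sprintf("bulk table has no timepoint '%s'", stage))
  expr <- setNames(b$cpm, b$gene_id)
  need <- unique(c(table$tf_gene, table$nearest_gene))
  miss <- setdiff(need, names(expr))
  if (length(miss)) {
    inform(sprintf("%d gene(s) absent from bulk at %s treated as not expressed",
                   length(miss), stage))
  }
  ok <- function(g) !is.na(g) & g %in% names(expr) & expr[g] >= min_expr
  filter(table, ok(.data$tf_gene) & ok(.data$nearest_gene))
}

#' Chain stage regulator tables into temporal circuits
#'
#' The first table in `tables` is the activity stage: its motifs establish
#' which TFs show accessibility evidence early, but it contributes no edges.
#' Edges come from the later stages; an edge at stage *k* can start a chain
#' only if its TF's motif occurs among the vetted peaks of stage *k − 1*
#' (for the first chaining stage that is the activity stage), and a chain
#' extends from stage *k* to *k + 1* when the earlier edge's target gene
#' encodes the later edge's TF. Every maximal chain is emitted; qualifying
#' edges that no chain extends are emitted as length-1 circuits.
#' Self-targeting TFs are allowed and flagged; chains cannot loop because
#' each stage is used once.
#'
#' @param tables Named list of regulator tables in temporal order (names are
#'   the stage labels); at least two.
#' @param tf_map Tibble (`tf_name`, `gene_id`, `motif_id`); a target can
#'   extend a chain only if it appears here.
#' @return Tibble of class `circuit_set`: one row per circuit edge, columns
#'   `circuit_id`, `step`, `stage`, `tf_name`, `tf_gene`, `target_gene`,
#'   `peak`, `motif_id`, `hit_score`, `da_fdr`, `self_loop`.
#' @export
chain_circuits <- function(tables, tf_map) {
  stopifnot(length(tables) >= 2L, !is.null(names(tables)))
  stages <- names(tables)
  edge_tabs <- lapply(tables, function(t) {
    distinct(t, .data$stage, .data$peak, .data$nearest_gene, .data$motif_id,
             .data$tf_name, .data$tf_gene, .data$hit_score, .data$da_fdr)
  })
  motifs_at <- lapply(edge_tabs, function(t) unique(t$motif_id))
  n_stage <- length(stages)
  # edge k at chaining stage j (j >= 2) is entry-qualified iff its TF's
  # motif occurs among stage j-1 vetted peaks
  qualified <- function(j, edges) {
    mm <- tf_map$motif_id[match(edges$tf_gene, tf_map$gene_id)]
    !is.na(mm) & mm %in% motifs_at[[j - 1L]]
  }
  circuits <- list()
  build <- function(j, edge_row, chain) {
    chain <- c(chain, list(edge_row))
    extended <- FALSE
    if (j < n_stage) {
      nxt <- edge_tabs[[j + 1L]]
      # a target extends the chain only if it encodes a TF in the library
      follow <- nxt[!is.na(nxt$tf_gene) &
                      nxt$tf_gene == edge_row$nearest_gene &
                      edge_row$nearest_gene %in% tf_map$gene_id, ,
                    drop = FALSE]
      if (nrow(follow)) {
        for (i in seq_len(nrow(follow))) {
          build(j + 1L, follow[i, , drop = FALSE], chain)
        }
        extended <- TRUE
      }
    }
    if (!extended) circuits[[length(circuits) + 1L]] <<- chain
  }
  for (j in 2:n_stage) {
    ed <- edge_tabs[[j]]
    if (nrow(ed) == 0L) next
    for (i in which(qualified(j, ed))) build(j, ed[i, , drop = FALSE], list())
  }
  # keep maximal chains only: drop any chain that is a suffix of a longer one
  edge_key <- function(e) paste(e$stage, e$peak, e$motif_id, e$nearest_gene,
                                sep = "|")
  keys <- vapply(circuits, function(ch) {
    paste(vapply(ch, edge_key, character(1)), collapse = "->")
  }, character(1))
  dup <- duplicated(keys)
  circuits <- circuits[!dup]; keys <- keys[!dup]
  is_suffix <- vapply(seq_along(keys), function(i) {
    any(endsWith(keys[-i], paste0(">", keys[i])))
  }, logical(1))
  circuits <- circuits[!is_suffix]
  rows <- purrr::imap(circuits, function(chain, id) {
    purrr::imap(chain, function(e, step) {
      tibble(circuit_id = id, step = step, stage = e$stage,
             tf_name = e$tf_name, tf_gene = e$tf_gene,
             target_gene = e$nearest_gene, peak = e$peak,
             motif_id = e$motif_id, hit_score = e$hit_score,
             da_fdr = e$da_fdr,
             self_loop = !is.na(e$tf_gene) & e$tf_gene == e$nearest_gene)
    })
  })
  out <- bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0L) {
    out <- tibble(circuit_id = integer(), step = integer(),
                  stage = character(), tf_name = character(),
                  tf_gene = character(), target_gene = character(),
                  peak = character(), motif_id = character(),
                  hit_score = numeric(), da_fdr = numeric(),
                  self_loop = logical())
  } else {
    # deterministic circuit numbering by chain content
    key <- out |>
      group_by(.data$circuit_id) |>
      summarise(key = paste(.data$stage, .data$tf_gene, .data$target_gene,
                            .data$peak, collapse = "|"), .groups = "drop") |>
      arrange(.data$key)
    out$circuit_id <- match(out$circuit_id, key$circuit_id)
    out <- arrange(out, .data$circuit_id, .data$step)
  }
  structure(out, class = c("circuit_set", class(out)))
}

#' Filter circuits by single-cell differential expression
#'
#' Keeps circuits in which every edge's TF gene and target gene are present
#' in the single-cell data, and at least one gene of the circuit is
#' differentially expressed between the timepoints at adjusted p <= `alpha`
#' (`strict = TRUE` requires every node to be DE). Per-edge `sc_de` evidence
#' flags mark whether the edge's target passed the DE filter.
#'
#' @param circuits A `circuit_set` from [chain_circuits()].
#' @param de_table Marker table from [rank_sum_markers()] for the
#'   uninjured-vs-regenerating contrast.
#' @param sc_genes Genes measured in the single-cell data.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param strict Require all nodes DE (default FALSE).
#' @return Filtered `circuit_set` with an `sc_de` column.
#' @export
filter_by_sc_de <- function(circuits, de_table, sc_genes, alpha = 0.05,
                            strict = FALSE) {
  de_genes <- de_table$gene[de_table$p_adjusted <= alpha]
  out <- mutate(circuits, sc_de = .data$target_gene %in% de_genes)
  keep <- out |>
    group_by(.data$circuit_id) |>
    summarise(
      present = all(c(.data$tf_gene, .data$target_gene) %in% sc_genes),
      n_de = sum(unique(c(.data$tf_gene, .data$target_gene)) %in% de_genes),
      n_nodes = dplyr::n_distinct(c(.data$tf_gene, .data$target_gene)),
      .groups = "drop"
    ) |>
    filter(.data$present,
           if (strict) .data$n_de == .data$n_nodes else .data$n_de >= 1L) |>
    pull(.data$circuit_id)
  out <- filter(out, .data$circuit_id %in% keep)
  structure(out, class = unique(c("circuit_set", class(out))))
}

#' Count regions hit by one, the other, or both of two TF motifs
#'
#' Over the union of differentially accessible regions across the stage
#' tables, counts regions containing only `tf_a`'s motif, both, or only
#' `tf_b`'s (regions with neither are not counted).
#'
#' @param tf_a,tf_b TF names.
#' @param tables List of regulator tables.
#' @return Tibble (`only_a`, `shared`, `only_b`).
#' @export
target_overlap <- function(tf_a, tf_b, tables) {
  all_rows <- bind_rows(tables)
  known <- unique(all_rows$tf_name)
  bad <- setdiff(c(tf_a, tf_b), known)
  if (length(bad)) {
    abort(sprintf("TF(s) absent from the regulator tables: %s",
                  paste(bad, collapse = ", ")))
  }
  pa <- unique(all_rows$peak[all_rows$tf_name == tf_a])
  pb <- unique(all_rows$peak[all_rows$tf_name == tf_b])
  tibble(only_a = length(setdiff(pa, pb)),
         shared = length(intersect(pa, pb)),
         only_b = length(setdiff(pb, pa)))
}

#' Export circuits as an edge list and a DOT graph
#'
#' @param circuits A `circuit_set`.
#' @param edge_path Output TSV path.
#' @param dot_path Output DOT path.
#' @return Invisibly, the edge tibble written.
#' @export
export_network <- function(circuits, edge_path, dot_path) {
  cols <- c("tf_name", "tf_gene", "target_gene", "stage", "peak",
            "motif_id", "hit_score", "da_fdr")
  if ("sc_de" %in% names(circuits)) cols <- c(cols, "sc_de")
  edges <- circuits |>
    as_tibble() |>
    select(dplyr::all_of(cols)) |>
    distinct() |>
    arrange(.data$stage, .data$tf_name, .data$target_gene, .data$peak)
  readr::write_tsv(edges, edge_path, progress = FALSE)
  nodes <- sort(unique(c(edges$tf_gene, edges$target_gene)))
  lines <- c("digraph regulatory_circuits {",
             "  rankdir=LR;",
             sprintf("  \"%s\";", nodes),
             sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                     edges$tf_gene, edges$target_gene, edges$stage),
             "}")
  if (nrow(edges) == 0L) {
    lines <- c("digraph regulatory_circuits {", "}")
  }
  writeLines(lines, dot_path)
  invisible(edges)
}

#' @export
print.circuit_set <- function(x, ...) {
  nc <- if (nrow(x) && "circuit_id" %in% names(x)) {
    length(unique(x$circuit_id))
  } else {
    0L
  }
  cat(sprintf("Circuit set: %d circuit(s), %d edge row(s)\n", nc, nrow(x)))
  if (nrow(x)) NextMethod()
  invisible(x)
}
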