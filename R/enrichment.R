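#' Build an ontology from a parent-edge table
#'
#' @param edges Tibble with columns `child`, `parent` (term ids) and
#'   optionally `name` (child's human-readable name).
#' @param names Optional tibble (`term_id`, `name`) supplying names for
#'   terms that never appear as a child (e.g. roots).
#' @return Object of class `ontology`: tibble of terms plus a parent
#'   adjacency list. Errors, listing the members, if the parent graph has a
#'   cycle.
#' @export
ontology <- function(edges, names = NULL) {
  stopifnot(all(c("child", "parent") %in% base::names(edges)))
  ids <- sort(unique(c(edges$child, edges$parent,
                       if (!is.null(names)) names$term_id)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$child, to = edges$parent),
    directed = TRUE, vertices = ids
  )
  if (!igraph::is_dag(g)) {
    members <- find_cycle_members(edges)
    abort(sprintf("ontology has a cycle involving: %s",
                  paste(members, collapse = " -> ")))
  }
  nm <- setNames(rep(NA_character_, length(ids)), ids)
  if ("name" %in% base::names(edges)) nm[edges$child] <- edges$name
  if (!is.null(names)) nm[names$term_id] <- names$name
  terms <- tibble(term_id = ids, name = unname(nm[ids]))
  structure(list(terms = terms, graph = g), class = "ontology")
}

find_cycle_members <- function(edges) {
  # Kahn's algorithm; whatever cannot be peeled belongs to a cycle
  nodes <- unique(c(edges$child, edges$parent))
  e <- edges[, c("child", "parent")]
  repeat {
    outdeg <- table(factor(e$child, levels = nodes))
    indeg <- table(factor(e$parent, levels = nodes))
    drop <- nodes[outdeg == 0 | indeg == 0]
    if (!length(drop)) break
    nodes <- setdiff(nodes, drop)
    e <- e[e$child %in% nodes & e$parent %in% nodes, , drop = FALSE]
    if (!nrow(e)) break
  }
  sort(nodes)
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("Ontology with %d terms, %d edges\n",
              nrow(x$terms), igraph::ecount(x$graph)))
  invisible(x)
}

ancestors_of <- function(ont, term) {
  # includes the term itself
  names(igraph::subcomponent(ont$graph, term, mode = "out"))
}

#' Propagate gene annotations to ancestor terms
#'
#' True-path propagation: a gene annotated to a term is annotated to every
#' ancestor of that term. Per-term frequencies `p(term)` are computed on the
#' propagated map against the annotated universe, so `p` is monotone
#' non-decreasing from leaves to roots and `p(root) = 1` for any root above
#' an annotated gene.
#'
#' @param ont An [ontology()].
#' @param annotations Tibble (`gene_id`, `term_id`) of raw (pre-propagation)
#'   annotations.
#' @param universe Optional gene universe; defaults to the annotated genes.
#' @return Object of class `annotation_map`: `gene_terms` and `term_genes`
#'   adjacency lists, per-term frequency `p`, and the `universe`.
#' @export
propagate <- function(ont, annotations, universe = NULL) {
  stopifnot(inherits(ont, "ontology"),
            all(c("gene_id", "term_id") %in% names(annotations)))
  unknown <- setdiff(unique(annotations$term_id), ont$terms$term_id)
  if (length(unknown)) {
    abort(sprintf("annotations reference unknown terms: %s",
                  paste(unknown, collapse = ", ")))
  }
  anc <- lapply(setNames(nm = unique(annotations$term_id)),
                function(t) ancestors_of(ont, t))
  long <- annotations |>
    mutate(term_id = anc[.data$term_id]) |>
    tidyr::unnest_longer("term_id") |>
    distinct(.data$gene_id, .data$term_id)
  universe <- universe %||% sort(unique(annotations$gene_id))
  term_genes <- split(long$gene_id, long$term_id)
  gene_terms <- split(long$term_id, long$gene_id)
  p <- vapply(term_genes, function(g) length(unique(g)), numeric(1)) /
    length(universe)
  structure(list(gene_terms = gene_terms, term_genes = term_genes,
                 p = p, universe = universe, ontology = ont),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("Annotation map: %d genes, %d terms (propagated)\n",
              length(x$gene_terms), length(x$term_genes)))
  invisible(x)
}

#' Hypergeometric term enrichment
#'
#' For each term with at least one annotated gene, tests over-representation
#' of the query in the term's gene set with the upper-tail hypergeometric
#' probability `P(X >= k)` given the universe size `N`, term size `K` and
#' query size `n`, followed by Benjamini-Hochberg adjustment across tested
#' terms.
#'
#' @param query Character vector of genes (must be a subset of the
#'   universe).
#' @param ann An [annotation_map][propagate()].
#' @param universe Optional universe override (defaults to the map's).
#' @param alpha Significance threshold recorded on the result (default
#'   0.05).
#' @return Tibble (`term_id`, `name`, `k`, `K`, `n`, `N`, `p_value`, `fdr`,
#'   `significant`, `member_genes`) sorted by p-value.
#' @export
enrich <- function(query, ann, universe = NULL, alpha = 0.05) {
  stopifnot(inherits(ann, "annotation_map"))
  universe <- universe %||% ann$universe
  query <- unique(query)
  out_of <- setdiff(query, universe)
  if (length(out_of)) {
    abort(sprintf("query genes outside the universe: %s",
                  paste(out_of, collapse = ", ")))
  }
  N <- length(universe)
  n <- length(query)
  terms <- names(ann$term_genes)
  rows <- purrr::map(terms, function(t) {
    genes <- intersect(ann$term_genes[[t]], universe)
    K <- length(genes)
    if (K == 0L) return(NULL)
    hit <- intersect(query, genes)
    k <- length(hit)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term_id = t, k = k, K = K, n = n, N = N, p_value = p,
           member_genes = list(sort(hit)))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) return(out)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr <= alpha
  out <- left_join(out, ann$ontology$terms, by = "term_id")
  out <- select(out, "term_id", "name", "k", "K", "n", "N", "p_value",
                "fdr", "significant", "member_genes")
  arrange(out, .data$p_value, .data$term_id)
}

#' SimRel semantic similarity between two terms
#'
#' Information content is `IC(t) = -ln p(t)` from the annotation map's
#' propagated frequencies. With MICA the common ancestor of maximal IC,
#' `simrel(a, b) = (2 IC(MICA) / (IC(a) + IC(b))) * (1 - p(MICA))`. The
#' similarity is 0 when the terms share no ancestor and defined as 0 when
#' `IC(a) + IC(b) = 0`; it lies in `[0, 1)` and `simrel(a, a) = 1 - p(a)`.
#'
#' @param a,b Term ids with positive annotation frequency.
#' @param ann An [annotation_map][propagate()].
#' @return Similarity in `[0, 1)`.
#' @export
simrel <- function(a, b, ann) {
  p <- ann$p
  if (is.na(p[a]) || is.na(p[b]) || p[a] <= 0 || p[b] <= 0) {
    abort("both terms must have positive annotation frequency")
  }
  ont <- ann$ontology
  common <- intersect(ancestors_of(ont, a), ancestors_of(ont, b))
  common <- common[common %in% names(p)]
  if (!length(common)) return(0)
  ic <- -log(p[common])
  mica <- common[which.max(ic)]
  denom <- (-log(p[a])) + (-log(p[b]))
  if (denom == 0) return(0)
  unname((2 * -log(p[mica]) / denom) * (1 - p[mica]))
}

#' Reduce enriched terms into semantic families
#'
#' Greedy redundancy reduction in the spirit of semantic-clustering tools:
#' terms are swept in ascending p-value order; a term founds a new family
#' (becomes a representative) iff its SimRel similarity to every existing
#' representative is at or below `cutoff`, and otherwise joins the family of
#' its most similar representative. The representative of each family is
#' therefore always its most significant member.
#'
#' @param results Enrichment tibble from [enrich()]; only rows with
#'   `significant` are clustered unless `significant_only = FALSE`.
#' @param ann The [annotation_map][propagate()] used for the enrichment.
#' @param cutoff Allowed similarity between representatives (default 0.4).
#' @param significant_only Cluster only significant terms (default TRUE).
#' @return Tibble of class `term_families` (`term_id`, `name`, `p_value`,
#'   `representative`, `similarity`, `family_rank`); the three-level tree
#'   (root -> families -> members) is attached as attribute `tree`.
#' @export
reduce_terms <- function(results, ann, cutoff = 0.4,
                         significant_only = TRUE) {
  x <- results
  if (significant_only && "significant" %in% names(x)) {
    x <- filter(x, .data$significant)
  }
  x <- distinct(x, .data$term_id, .keep_all = TRUE)
  x <- arrange(x, .data$p_value, .data$term_id)
  reps <- character(0)
  rep_of <- character(nrow(x))
  sim_to_rep <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    t <- x$term_id[i]
    if (!length(reps)) {
      reps <- t; rep_of[i] <- t; sim_to_rep[i] <- simrel(t, t, ann)
      next
    }
    sims <- vapply(reps, function(r) simrel(t, r, ann), numeric(1))
    if (all(sims <= cutoff)) {
      reps <- c(reps, t)
      rep_of[i] <- t
      sim_to_rep[i] <- simrel(t, t, ann)
    } else {
      j <- which.max(sims)
      rep_of[i] <- reps[j]
      sim_to_rep[i] <- sims[j]
    }
  }
  out <- tibble(term_id = x$term_id, name = x$name, p_value = x$p_value,
                representative = rep_of, similarity = sim_to_rep)
  out <- mutate(out, family_rank = match(.data$representative, reps))
  tree <- list(root = "all_terms",
               families = lapply(setNames(nm = reps), function(r) {
                 out$term_id[out$representative == r]
               }))
  structure(out, class = c("term_families", class(out)), tree = tree,
            cutoff = cutoff)
}

#' @export
glance.term_families <- function(x, ...) {
  tibble(n_terms = nrow(x),
         n_families = length(unique(x$representative)),
         cutoff = attr(x, "cutoff"))
}
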