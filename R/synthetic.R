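#' Configuration for the synthetic regeneration study
#'
#' Describes a complete synthetic multi-timepoint study: a toy genome and
#' gene annotation, ATAC peaks with planted accessibility changes and
#' negative-binomial replicate noise, peak sequences with planted motif
#' instances, per-timepoint bulk expression, clustered single-cell counts
#' with planted markers, timepoint composition shifts and cell-cycle
#' signatures, a motif library, a small ontology, and a planted regulatory
#' circuit with single-criterion decoys. One seed makes every emitted file
#' reproducible byte for byte.
#'
#' Decoy genes each violate exactly one circuit criterion: `non_da` (the
#' candidate peak loses rather than gains accessibility at the stage),
#' `no_motif` (accessible peak without the TF motif), `tf_unexpressed` (the
#' TF is silent in bulk at the stage) and `not_de` (the target is not
#' differentially expressed in the single-cell contrast).
#'
#' @param seed Integer seed; all randomness fans out from it per component.
#' @param genome_length Chromosome length in bp.
#' @param n_chroms Number of chromosomes.
#' @param n_genes Number of genes (>= 220 + 2 * sig_size + n_hk).
#' @param n_tfs Number of TF-coding genes, each paired with one PWM.
#' @param timepoints Ordered timepoint labels.
#' @param n_replicates ATAC replicates per timepoint.
#' @param n_peaks Total master peaks (>= decoys + circuit + activity peaks).
#' @param peak_width Peak width in bp.
#' @param baseline_mean Expected fragment count per peak per sample.
#' @param dispersion NB dispersion of ATAC counts.
#' @param da_fraction Fraction of background peaks planted differentially
#'   accessible.
#' @param da_log2fc Planted accessibility effect (log2).
#' @param n_cells Cells per single-cell timepoint.
#' @param n_clusters Number of cell clusters.
#' @param marker_log2fc Planted cluster-marker effect (log2).
#' @param cycle_fractions Named `(S, G2M, G1)` proportions applied to every
#'   cluster (or a list with one such vector per cluster). Constant across
#'   timepoints; the timepoints differ in cluster mix, not cycling rate.
#' @param sc_dispersion NB dispersion of single-cell counts.
#' @param cycle_shift Fold increase of signature genes in their phase.
#' @param sig_size Genes per cell-cycle signature set.
#' @param sig_base Baseline mean count of signature genes outside their
#'   phase.
#' @param n_hk High-expressed filler genes (they populate the expression
#'   bins that module scoring draws controls from).
#' @param de_log2fc Planted single-cell timepoint DE effect (log2).
#' @param motif_width,motif_prob PWM width and consensus-base probability.
#' @param n_decoys Decoy genes, split evenly over the four violation
#'   classes.
#' @param planted_circuit Tibble (`tf`, `target`, `stage`) of circuit edges;
#'   `tf` must be a TF-coding gene and `stage` a non-baseline timepoint.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             genome_length = 4e6,
                             n_chroms = 4,
                             n_genes = 1500,
                             n_tfs = 12,
                             timepoints = c("uninjured", "6hpa", "24hpa", "72hpa"),
                             n_replicates = 3,
                             n_peaks = 600,
                             peak_width = 200,
                             baseline_mean = 100,
                             dispersion = 0.1,
                             da_fraction = 0.1,
                             da_log2fc = 2,
                             n_cells = 400,
                             n_clusters = 7,
                             marker_log2fc = 3,
                             cycle_fractions = c(S = 0.24, G2M = 0.12,
                                                 G1 = 0.64),
                             sc_dispersion = 0.05,
                             cycle_shift = 50,
                             sig_size = 60,
                             sig_base = 3,
                             n_hk = 100,
                             de_log2fc = 2,
                             motif_width = 14,
                             motif_prob = 0.9,
                             n_decoys = 200,
                             planted_circuit = NULL) {
  cfg <- as.list(environment())
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  cfg$planted_circuit <- planted_circuit %||% tibble(
    tf = c("g001", "g002", "g002", "g002"),
    target = c("g002", "g013", "g014", "g015"),
    stage = c("24hpa", "72hpa", "72hpa", "72hpa")
  )
  stopifnot(n_tfs >= 12, n_chroms >= 1, length(timepoints) >= 2,
            n_replicates >= 2, peak_width > 0, baseline_mean > 0,
            dispersion >= 0, n_clusters >= 1)
  if (da_fraction < 0 || da_fraction > 1) abort("da_fraction must be in [0, 1]")
  if (!is.list(cfg$cycle_fractions)) {
    cfg$cycle_fractions <- rep(list(cfg$cycle_fractions), n_clusters)
  }
  if (length(cfg$cycle_fractions) != n_clusters) {
    abort("cycle_fractions must have one (S, G2M, G1) vector per cluster")
  }
  for (f in cfg$cycle_fractions) {
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      abort("cycle_fractions must be non-negative and sum to 1")
    }
  }
  if (n_genes < 220 + 2 * sig_size + n_hk) {
    abort("n_genes too small for the gene allocation")
  }
  pc <- cfg$planted_circuit
  tf_ids <- gene_ids[seq_len(n_tfs)]
  bad_tf <- setdiff(pc$tf, tf_ids)
  bad_target <- setdiff(pc$target, gene_ids)
  bad_stage <- setdiff(pc$stage, timepoints[-1])
  if (length(bad_tf)) abort(sprintf("circuit TF is not a declared TF gene: %s",
                                    paste(bad_tf, collapse = ", ")))
  if (length(bad_target)) abort(sprintf("circuit target is not a declared gene: %s",
                                        paste(bad_target, collapse = ", ")))
  if (length(bad_stage)) abort(sprintf("circuit stage is not a valid timepoint: %s",
                                       paste(bad_stage, collapse = ", ")))
  n_fixed <- nrow(pc) + 9 + n_decoys  # circuit + activity + decoy peaks
  if (n_peaks < n_fixed + 50) {
    abort(sprintf("n_peaks must be at least %d", n_fixed + 50))
  }
  structure(cfg, class = "synthetic_config")
}

seed_for <- function(cfg, k) {
  as.integer((as.numeric(cfg$seed) * 7919 + k * 104729) %% 2147483629)
}

#' Draw negative-binomial counts with a mean/dispersion parametrization
#'
#' `E[X] = mean`, `Var[X] = mean + dispersion * mean^2`; `dispersion = 0`
#' gives Poisson draws.
#'
#' @param mean Positive mean (scalar or vector recycled over `n`).
#' @param dispersion Dispersion `phi >= 0`.
#' @param n Number of draws.
#' @param seed Optional seed (restores RNG state afterwards).
#' @return Integer vector of length `n`.
#' @export
sample_nb_counts <- function(mean, dispersion, n, seed = NULL) {
  if (any(mean <= 0)) abort("mean must be positive")
  if (dispersion < 0) abort("dispersion must be non-negative")
  draw <- function() {
    if (dispersion == 0) rpois(n, lambda = mean)
    else rnbinom(n, mu = mean, size = 1 / dispersion)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# gene allocation: roles by index ------------------------------------------
gene_roles <- function(cfg) {
  ids <- sprintf("g%03d", seq_len(cfg$n_genes))
  role <- rep("spare", cfg$n_genes)
  role[1:cfg$n_tfs] <- "tf"
  role[13:15] <- "circuit_target"
  role[16:20] <- "aux"
  role[21:(20 + cfg$n_decoys)] <- "decoy"
  s0 <- 20 + cfg$n_decoys
  role[(s0 + 1):(s0 + cfg$sig_size)] <- "s_sig"
  role[(s0 + cfg$sig_size + 1):(s0 + 2 * cfg$sig_size)] <- "g2m_sig"
  h0 <- s0 + 2 * cfg$sig_size
  role[(h0 + 1):(h0 + cfg$n_hk)] <- "hk"
  tibble(gene_id = ids, role = role)
}

decoy_classes <- function(cfg) {
  classes <- rep(c("non_da", "no_motif", "tf_unexpressed", "not_de"),
                 length.out = cfg$n_decoys)
  tfs <- list(non_da = c("g005", "g006"), no_motif = c(NA_character_, NA),
              tf_unexpressed = c("g009", "g010"), not_de = c("g011", "g012"))
  tf_gene <- character(length(classes))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    tf_gene[idx] <- rep(tfs[[cl]], length.out = length(idx))
  }
  tibble(gene_id = sprintf("g%03d", 21:(20 + cfg$n_decoys)),
         class = classes, tf_gene = tf_gene)
}

random_consensus <- function(n, width, min_dist = 5) {
  out <- character(0)
  while (length(out) < n) {
    cand <- paste(sample(DNA, width, replace = TRUE), collapse = "")
    ok <- all(vapply(out, function(o) {
      sum(strsplit(cand, "")[[1]] != strsplit(o, "")[[1]]) >= min_dist
    }, logical(1)))
    if (ok) out <- c(out, cand)
  }
  out
}

make_pwm_library <- function(cfg) {
  tf_ids <- sprintf("g%03d", seq_len(cfg$n_tfs))
  cons <- withr::with_seed(seed_for(cfg, 2),
                           random_consensus(cfg$n_tfs, cfg$motif_width))
  lib <- purrr::map2(tf_ids, cons, function(g, cs) {
    m <- matrix((1 - cfg$motif_prob) / 3, nchar(cs), 4,
                dimnames = list(NULL, DNA))
    hit <- match(strsplit(cs, "")[[1]], DNA)
    m[cbind(seq_along(hit), hit)] <- cfg$motif_prob
    pwm(m, motif_id = paste0("M.", g), tf_name = paste0("TF.", g))
  })
  names(lib) <- paste0("M.", tf_ids)
  lib
}

plant_sequence <- function(seqs, peak, consensus, offset, strand) {
  ins <- if (strand == "-") revcomp(consensus) else consensus
  s <- seqs[[peak]]
  substr(s, offset + 1L, offset + nchar(ins)) <- ins
  seqs[[peak]] <- s
  seqs
}

#' Generate the complete synthetic study
#'
#' Writes every input the pipeline consumes plus a ground-truth ledger:
#' GFF3 gene annotation, master and per-timepoint peak BED files, peak
#' FASTA with planted motif instances, ATAC count matrix and sample sheet,
#' per-timepoint bulk expression tables, MatrixMarket single-cell counts
#' with gene and cell metadata, cell-cycle gene lists, a MEME-format motif
#' library, a TF-to-gene map, an ontology (parent edges + gene-to-term
#' annotations), and `truth.json`.
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Output directory (created if absent).
#' @return The truth ledger (class `truth_ledger`), invisibly; also written
#'   to `truth.json`.
#' @export
generate_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    abort(sprintf("output directory '%s' is not writable", out_dir))
  }
  tp <- cfg$timepoints
  roles <- gene_roles(cfg)
  decoys <- decoy_classes(cfg)

  ## genes ------------------------------------------------------------------
  genes <- withr::with_seed(seed_for(cfg, 1), {
    per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
    spacing <- floor(cfg$genome_length / (per_chrom + 1))
    chrom <- paste0("chr", ((seq_len(cfg$n_genes) - 1L) %% cfg$n_chroms) + 1L)
    slot <- ((seq_len(cfg$n_genes) - 1L) %/% cfg$n_chroms) + 1L
    tss <- as.integer(slot * spacing +
                        round(runif(cfg$n_genes, -500, 500)))
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    mutate(roles, chrom = chrom, tss = tss, strand = strand,
           is_tf = .data$role == "tf",
           tf_name = ifelse(.data$is_tf, paste0("TF.", .data$gene_id), NA),
           motif_id = ifelse(.data$is_tf, paste0("M.", .data$gene_id), NA))
  })
  write_gff3(genes, file.path(out_dir, "annotation.gff3"), cfg$genome_length)

  ## motif library ----------------------------------------------------------
  lib <- make_pwm_library(cfg)
  write_meme(lib, file.path(out_dir, "motifs.meme"))
  tf_map <- genes |>
    filter(.data$is_tf) |>
    select("tf_name", "gene_id", "motif_id")
  readr::write_tsv(tf_map, file.path(out_dir, "tf_map.tsv"), progress = FALSE)

  ## peaks ------------------------------------------------------------------
  pc <- cfg$planted_circuit
  # chain-start TFs need 6hpa activity evidence; decoy TFs always get it so
  # a decoy fails on its one planted violation only
  start_tfs <- setdiff(pc$tf, pc$target)
  activity_tfs <- sort(unique(c(start_tfs, stats::na.omit(decoys$tf_gene))))
  aux_ids <- roles$gene_id[roles$role == "aux"]
  gene_at <- function(id) genes[match(id, genes$gene_id), ]

  plan <- bind_rows(
    tibble(kind = "circuit", anchor = pc$target, stage = pc$stage,
           tf_gene = pc$tf, class = NA_character_),
    tibble(kind = "activity", anchor = rep_len(aux_ids, length(activity_tfs)),
           stage = tp[2], tf_gene = activity_tfs, class = NA_character_),
    tibble(kind = "decoy", anchor = decoys$gene_id, stage = "24hpa",
           tf_gene = decoys$tf_gene, class = decoys$class)
  )
  n_bg <- cfg$n_peaks - nrow(plan)
  bg_anchors <- withr::with_seed(seed_for(cfg, 3), {
    pool <- roles$gene_id[roles$role %in% c("hk", "spare", "s_sig", "g2m_sig")]
    sample(pool, n_bg, replace = TRUE)
  })
  plan <- bind_rows(plan, tibble(kind = "background", anchor = bg_anchors,
                                 stage = NA, tf_gene = NA, class = NA))

  peaks <- withr::with_seed(seed_for(cfg, 4), {
    g <- gene_at(plan$anchor)
    start <- as.integer(g$tss +
                          round(runif(nrow(plan), -1500, 1500 - cfg$peak_width)))
    start <- pmax(start, 0L)
    start <- pmin(start, as.integer(cfg$genome_length - cfg$peak_width))
    tibble(chrom = g$chrom, start = start,
           end = start + as.integer(cfg$peak_width),
           kind = plan$kind, anchor = plan$anchor, stage = plan$stage,
           tf_gene = plan$tf_gene, class = plan$class)
  })
  peaks <- arrange(peaks, .data$chrom, .data$start, .data$anchor)
  peaks$name <- sprintf("peak_%04d", seq_len(nrow(peaks)))

  ## planted accessibility --------------------------------------------------
  mult <- matrix(1, nrow(peaks), length(tp), dimnames = list(peaks$name, tp))
  up <- 2^cfg$da_log2fc
  da_rows <- list()
  plant_da <- function(peak, stage, dir) {
    mult[peak, stage] <<- if (dir == "up") up else 1 / up
    da_rows[[length(da_rows) + 1L]] <<-
      tibble(peak = peak, timepoint = stage, direction = dir,
             log2fc = if (dir == "up") cfg$da_log2fc else -cfg$da_log2fc)
  }
  for (i in seq_len(nrow(peaks))) {
    k <- peaks$kind[i]
    if (k %in% c("circuit", "activity")) {
      plant_da(peaks$name[i], peaks$stage[i], "up")
    } else if (k == "decoy") {
      if (peaks$class[i] == "non_da") plant_da(peaks$name[i], "24hpa", "down")
      else plant_da(peaks$name[i], "24hpa", "up")
    }
  }
  withr::with_seed(seed_for(cfg, 5), {
    bg <- which(peaks$kind == "background")
    n_da <- round(cfg$da_fraction * length(bg))
    if (n_da > 0) {
      pick <- sample(bg, n_da)
      stages <- sample(tp, n_da, replace = TRUE)
      dirs <- sample(c("up", "down"), n_da, replace = TRUE)
      for (j in seq_along(pick)) {
        plant_da(peaks$name[pick[j]], stages[j], dirs[j])
      }
    }
  })
  da_truth <- bind_rows(da_rows)

  ## ATAC counts ------------------------------------------------------------
  sheet <- tidyr::expand_grid(timepoint = tp,
                              replicate = seq_len(cfg$n_replicates)) |>
    mutate(sample = paste0(.data$timepoint, "_r", .data$replicate),
           condition = "pax6") |>
    select("sample", "timepoint", "condition", "replicate")
  counts <- withr::with_seed(seed_for(cfg, 6), {
    base_mu <- rlnorm(nrow(peaks), log(cfg$baseline_mean) - 0.125, 0.5)
    size_f <- rlnorm(nrow(sheet), 0, 0.1)
    m <- sapply(seq_len(nrow(sheet)), function(j) {
      mu <- base_mu * mult[, sheet$timepoint[j]] * size_f[j]
      sample_nb_counts(mu, cfg$dispersion, nrow(peaks))
    })
    rownames(m) <- peaks$name
    colnames(m) <- sheet$sample
    m
  })
  write_count_matrix(counts, file.path(out_dir, "atac_counts.tsv"))
  readr::write_tsv(sheet, file.path(out_dir, "sample_sheet.tsv"),
                   progress = FALSE)

  ## per-timepoint peak calls (BED) -----------------------------------------
  master <- select(peaks, "chrom", "start", "end", "name")
  write_bed(master, file.path(out_dir, "master_peaks.bed"))
  for (t in tp) {
    called <- master[mult[, t] >= 1, , drop = FALSE]
    write_bed(called, file.path(out_dir, paste0("peaks_", t, ".bed")))
  }

  ## sequences with planted motifs ------------------------------------------
  motif_rows <- list()
  seqs <- withr::with_seed(seed_for(cfg, 7), {
    s <- vapply(seq_len(nrow(peaks)), function(i) {
      paste(sample(DNA, cfg$peak_width, replace = TRUE), collapse = "")
    }, character(1))
    names(s) <- peaks$name
    plantable <- which(!is.na(peaks$tf_gene) &
                         !(peaks$kind == "decoy" & peaks$class == "no_motif"))
    offs <- sample(20:(cfg$peak_width - cfg$motif_width - 20),
                   length(plantable), replace = TRUE)
    strands <- sample(c("+", "-"), length(plantable), replace = TRUE)
    for (j in seq_along(plantable)) {
      i <- plantable[j]
      cs <- consensus(lib[[paste0("M.", peaks$tf_gene[i])]])
      s <- plant_sequence(s, peaks$name[i], cs, offs[j], strands[j])
      motif_rows[[length(motif_rows) + 1L]] <-
        tibble(peak = peaks$name[i],
               motif_id = paste0("M.", peaks$tf_gene[i]),
               offset = offs[j], strand = strands[j])
    }
    s
  })
  motif_truth <- bind_rows(motif_rows)
  write_peak_fasta(seqs, file.path(out_dir, "peaks.fasta"))

  ## bulk expression --------------------------------------------------------
  silent <- bind_rows(
    tidyr::expand_grid(gene_id = c("g003", "g004"), timepoint = tp),
    tibble(gene_id = c("g009", "g010"), timepoint = "24hpa")
  )
  bulk <- withr::with_seed(seed_for(cfg, 8), {
    purrr::map_dfr(tp, function(t) {
      cpm <- rlnorm(cfg$n_genes, log(30), 0.8)
      tibble(gene_id = genes$gene_id, timepoint = t, cpm = round(cpm, 3))
    })
  })
  bulk$cpm[paste(bulk$gene_id, bulk$timepoint) %in%
             paste(silent$gene_id, silent$timepoint)] <- 0
  for (t in tp) {
    readr::write_tsv(filter(bulk, .data$timepoint == t)[, c("gene_id", "cpm")],
                     file.path(out_dir, paste0("bulk_", t, ".tsv")),
                     progress = FALSE)
  }

  ## single-cell ------------------------------------------------------------
  sc_tp <- c(tp[1], tp[min(3L, length(tp))])
  circuit_nodes <- unique(c(pc$target))
  de_classes <- c("non_da", "no_motif", "tf_unexpressed")
  de_up <- sort(c(circuit_nodes,
                  decoys$gene_id[decoys$class %in% de_classes &
                                   seq_len(nrow(decoys)) %% 2 == 0]))
  de_down <- sort(decoys$gene_id[decoys$class %in% de_classes &
                                   seq_len(nrow(decoys)) %% 2 == 1])
  de_truth <- bind_rows(
    tibble(gene = de_up, direction = "up_24hpa"),
    tibble(gene = de_down, direction = "down_24hpa")
  )
  s_genes <- roles$gene_id[roles$role == "s_sig"]
  g2m_genes <- roles$gene_id[roles$role == "g2m_sig"]
  writeLines(s_genes, file.path(out_dir, "s_genes.txt"))
  writeLines(g2m_genes, file.path(out_dir, "g2m_genes.txt"))
  clus <- paste0("C", seq_len(cfg$n_clusters))
  comp <- cluster_proportions(cfg$n_clusters)
  hk_ids <- roles$gene_id[roles$role == "hk"]
  markers <- tibble(gene = hk_ids[seq_len(min(5 * cfg$n_clusters, length(hk_ids)))],
                    cluster = rep(clus, length.out =
                                    min(5 * cfg$n_clusters, length(hk_ids))))

  sc <- withr::with_seed(seed_for(cfg, 9), {
    base <- rlnorm(cfg$n_genes, log(1), 1.2)
    base[roles$role %in% c("tf", "circuit_target", "aux", "decoy")] <- 2
    # spread signature baselines so they share expression bins with
    # non-signature genes (module scoring needs non-empty control pools)
    n_sig <- sum(roles$role %in% c("s_sig", "g2m_sig"))
    base[roles$role %in% c("s_sig", "g2m_sig")] <-
      rlnorm(n_sig, log(cfg$sig_base), 0.5)
    base[roles$role == "hk"] <-
      exp(runif(sum(roles$role == "hk"), log(2), log(60)))
    names(base) <- roles$gene_id
    n_cells <- cfg$n_cells
    cells <- list()
    for (t in sc_tp) {
      cl <- sample(clus, n_cells, replace = TRUE, prob = comp[[
        if (t == sc_tp[1]) 1 else 2]])
      # cycling rate is a cluster property; timepoints differ in cluster mix
      ph <- vapply(cl, function(cc) {
        sample(c("S", "G2M", "G1"), 1,
               prob = cfg$cycle_fractions[[match(cc, clus)]])
      }, character(1))
      cells[[t]] <- tibble(timepoint = t, cluster = cl, phase = ph)
    }
    meta <- bind_rows(cells)
    meta$cell <- sprintf("cell_%05d", seq_len(nrow(meta)))
    mu <- matrix(base, cfg$n_genes, nrow(meta),
                 dimnames = list(roles$gene_id, meta$cell))
    for (i in seq_len(nrow(markers))) {
      j <- meta$cluster == markers$cluster[i]
      mu[markers$gene[i], j] <- mu[markers$gene[i], j] * 2^cfg$marker_log2fc
    }
    j24 <- meta$timepoint == sc_tp[2]
    mu[de_up, j24] <- mu[de_up, j24] * 2^cfg$de_log2fc
    mu[de_down, !j24] <- mu[de_down, !j24] * 2^cfg$de_log2fc
    mu[s_genes, meta$phase == "S"] <- mu[s_genes, meta$phase == "S"] * cfg$cycle_shift
    mu[g2m_genes, meta$phase == "G2M"] <-
      mu[g2m_genes, meta$phase == "G2M"] * cfg$cycle_shift
    depth <- rlnorm(nrow(meta), 0, 0.3)
    mu <- sweep(mu, 2, depth, "*")
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / cfg$sc_dispersion),
      nrow(mu), ncol(mu), dimnames = dimnames(mu))
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
         meta = meta)
  })
  Matrix::writeMM(sc$counts, file.path(out_dir, "sc_counts.mtx"))
  readr::write_tsv(tibble(gene_id = rownames(sc$counts)),
                   file.path(out_dir, "sc_genes.tsv"), progress = FALSE)
  readr::write_tsv(sc$meta[, c("cell", "timepoint", "cluster")],
                   file.path(out_dir, "sc_cells.tsv"), progress = FALSE)

  ## ontology ---------------------------------------------------------------
  onto <- make_ontology_files(cfg, roles, out_dir)

  ## truth ledger -----------------------------------------------------------
  ledger <- structure(list(
    config = cfg[setdiff(names(cfg), "planted_circuit")],
    planted_circuit = pc,
    genes = select(genes, "gene_id", "role", "chrom", "tss", "strand",
                   "is_tf", "tf_name", "motif_id"),
    peaks = select(peaks, "name", "chrom", "start", "end", "kind",
                   "anchor", "stage", "tf_gene", "class"),
    da_truth = da_truth,
    motif_truth = motif_truth,
    circuit_truth = mutate(
      pc,
      peak = peaks$name[match(paste(pc$target, pc$stage),
                              paste(peaks$anchor, peaks$stage))]),
    activity_truth = tibble(
      tf_gene = activity_tfs, stage = tp[2],
      peak = peaks$name[match(paste("activity", activity_tfs),
                              paste(peaks$kind, peaks$tf_gene))]),
    decoy_truth = decoys,
    bulk_silent = silent,
    marker_truth = markers,
    de_truth = de_truth,
    phase_truth = select(sc$meta, "cell", "phase"),
    s_genes = s_genes,
    g2m_genes = g2m_genes
  ), class = "truth_ledger")
  write_truth_ledger(ledger, file.path(out_dir, "truth.json"))
  invisible(ledger)
}

cluster_proportions <- function(n_clusters) {
  # planted composition shift between the two single-cell timepoints:
  # progenitor-like clusters shrink, differentiated clusters expand
  un <- c(0.38, 0.20, 0.12, 0.10, 0.08, 0.07, 0.05)
  tw <- c(0.25, 0.10, 0.18, 0.15, 0.12, 0.11, 0.09)
  if (n_clusters <= 7) {
    list(un[seq_len(n_clusters)] / sum(un[seq_len(n_clusters)]),
         tw[seq_len(n_clusters)] / sum(tw[seq_len(n_clusters)]))
  } else {
    ex <- n_clusters - 7
    list(c(un, rep(0.02, ex)) / (1 + 0.02 * ex),
         c(tw, rep(0.02, ex)) / (1 + 0.02 * ex))
  }
}

write_gff3 <- function(genes, path, genome_length) {
  body_start <- ifelse(genes$strand == "+", genes$tss + 1L,
                       pmax(1L, genes$tss + 1L - 1000L))
  body_end <- ifelse(genes$strand == "+",
                     pmin(genome_length, genes$tss + 1L + 1000L),
                     genes$tss + 1L)
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
            genes$chrom, body_start, body_end, genes$strand,
            genes$gene_id, genes$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

make_ontology_files <- function(cfg, roles, out_dir) {
  edges <- tibble(
    child = c("T100", "T110", "T120", "T200", "T210", "T300", "T310"),
    parent = c("T000", "T100", "T100", "T000", "T200", "T000", "T300"),
    name = c("neurogenesis", "neuron differentiation",
             "neural precursor proliferation", "tissue morphogenesis",
             "tubule morphogenesis", "metabolic process",
             "biosynthetic process")
  )
  leaves <- c("T110", "T120", "T210", "T310")
  ann <- withr::with_seed(seed_for(cfg, 10), {
    n1 <- sample(leaves, cfg$n_genes, replace = TRUE)
    extra <- runif(cfg$n_genes) < 0.3
    n2 <- sample(leaves, cfg$n_genes, replace = TRUE)
    out <- bind_rows(tibble(gene_id = roles$gene_id, term_id = n1),
                     tibble(gene_id = roles$gene_id[extra],
                            term_id = n2[extra]))
    distinct(out)
  })
  # circuit genes all annotate to neuron differentiation
  circuit_ids <- c("g001", "g002", "g013", "g014", "g015")
  ann <- distinct(bind_rows(ann, tibble(gene_id = circuit_ids,
                                        term_id = "T110")))
  ann <- arrange(ann, .data$gene_id, .data$term_id)
  readr::write_tsv(edges, file.path(out_dir, "ontology_edges.tsv"),
                   progress = FALSE)
  readr::write_tsv(ann, file.path(out_dir, "gene2term.tsv"), progress = FALSE)
  list(edges = edges, annotations = ann)
}

#' Write / read the truth ledger
#'
#' The ledger round-trips losslessly through JSON (tibbles are serialized
#' as data frames of columns).
#'
#' @param ledger A `truth_ledger`.
#' @param path JSON path.
#' @return `read_truth_ledger()` returns the `truth_ledger`.
#' @export
write_truth_ledger <- function(ledger, path) {
  jsonlite::write_json(unclass(ledger), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_truth_ledger
#' @export
read_truth_ledger <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tabs <- c("planted_circuit", "genes", "peaks", "da_truth", "motif_truth",
            "circuit_truth", "activity_truth", "decoy_truth", "bulk_silent",
            "marker_truth", "de_truth", "phase_truth")
  for (t in tabs) if (!is.null(x[[t]])) x[[t]] <- as_tibble(x[[t]])
  structure(x, class = "truth_ledger")
}

#' Simulate a peak-count matrix with optional planted effects
#'
#' A lightweight two-group simulator for calibration and power studies of
#' the differential-accessibility tests: per-peak baselines are log-normal
#' around `baseline_mean`, replicate counts are negative binomial, and a
#' `da_fraction` of peaks receive a `±da_log2fc` shift in group 2 (half up,
#' half down).
#'
#' @param n_peaks Number of peaks.
#' @param n_per_group Replicates per group (default 3).
#' @param baseline_mean,dispersion NB parameters.
#' @param da_fraction Fraction of peaks planted differential.
#' @param da_log2fc Planted |log2 fold change|.
#' @param seed Seed.
#' @return List: `counts` (matrix), `sheet` (sample sheet tibble with
#'   `timepoint` in `{"g1", "g2"}`), `truth` (tibble `feature`,
#'   `direction` in `{"up_in_2", "up_in_1", "ns"}`).
#' @export
simulate_peak_counts <- function(n_peaks, n_per_group = 3,
                                 baseline_mean = 100, dispersion = 0.1,
                                 da_fraction = 0, da_log2fc = 2, seed = 1) {
  withr::with_seed(seed, {
    base <- rlnorm(n_peaks, log(baseline_mean) - 0.125, 0.5)
    dir <- rep("ns", n_peaks)
    n_da <- round(da_fraction * n_peaks)
    if (n_da > 0) {
      pick <- sample(n_peaks, n_da)
      dir[pick] <- rep(c("up_in_2", "up_in_1"), length.out = n_da)
    }
    mult2 <- ifelse(dir == "up_in_2", 2^da_log2fc,
                    ifelse(dir == "up_in_1", 2^-da_log2fc, 1))
    n_s <- 2 * n_per_group
    counts <- sapply(seq_len(n_s), function(j) {
      mu <- if (j > n_per_group) base * mult2 else base
      sample_nb_counts(mu, dispersion, n_peaks)
    })
    rownames(counts) <- sprintf("peak_%05d", seq_len(n_peaks))
    colnames(counts) <- c(paste0("g1_r", seq_len(n_per_group)),
                          paste0("g2_r", seq_len(n_per_group)))
    sheet <- tibble(sample = colnames(counts),
                    timepoint = rep(c("g1", "g2"), each = n_per_group),
                    condition = "sim",
                    replicate = rep(seq_len(n_per_group), 2))
    list(counts = counts, sheet = sheet,
         truth = tibble(feature = rownames(counts), direction = dir))
  })
}
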