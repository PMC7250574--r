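# shared fixtures, built in code and cached for the whole run

.fixtures <- new.env(parent = emptyenv())

# default synthetic study + full pipeline run, generated once
default_study <- function() {
  if (is.null(.fixtures$study)) {
    dir <- file.path(tempdir(), "regenatac-default-study")
    cfg <- synthetic_config(seed = 20240901)
    ledger <- generate_dataset(cfg, dir)
    out <- file.path(tempdir(), "regenatac-default-out")
    res <- suppressMessages(run_pipeline(dir, out_dir = out))
    .fixtures$study <- list(dir = dir, out = out, cfg = cfg,
                            ledger = ledger, res = res)
  }
  .fixtures$study
}

# a sharp test PWM: consensus bases at probability p, rest uniform
test_pwm <- function(consensus = "ACGTACGT", p = 0.85, id = "M.test",
                     tf = "TF.test", background = rep(0.25, 4)) {
  b <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - p) / 3, length(b), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(b), match(b, c("A", "C", "G", "T")))] <- p
  pwm(m, motif_id = id, tf_name = tf, background = background)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_interval_set <- function(n, span = 10000, max_width = 300,
                                chroms = c("chr1", "chr2")) {
  start <- sample.int(span, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + width,
                 name = sprintf("iv_%04d", seq_len(n)))
}

# brute-force per-window PWM scanner used as the independent oracle
oracle_scan <- function(seq, pw, threshold_frac = 0.8, pseudocount = 0.01) {
  lom <- log_odds(pw, pseudocount)
  thr <- threshold_frac * max_score(pw, pseudocount)
  w <- nrow(lom)
  chars <- strsplit(toupper(seq), "")[[1]]
  hits <- list()
  score_window <- function(sub) {
    idx <- match(sub, c("A", "C", "G", "T"))
    if (anyNA(idx)) return(-Inf)
    s <- 0
    for (j in seq_len(w)) s <- s + lom[j, idx[j]]
    s
  }
  for (o in 0:(length(chars) - w)) {
    sub <- chars[(o + 1):(o + w)]
    s_f <- score_window(sub)
    rc <- rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[sub])
    s_r <- score_window(unname(rc))
    if (is.finite(s_f) && s_f >= thr) {
      hits[[length(hits) + 1]] <- list(offset = o, strand = "+", score = s_f)
    }
    if (is.finite(s_r) && s_r >= thr) {
      hits[[length(hits) + 1]] <- list(offset = o, strand = "-", score = s_r)
    }
  }
  dplyr::bind_rows(hits)
}

# small hand-built ontology with a diamond, used by enrichment tests:
# R <- {A, B}; A <- {C, D}; B <- {E}; F <- {C, D}
make_test_ontology <- function() {
  edges <- tibble::tibble(
    child  = c("A", "B", "C", "D", "E", "F", "F"),
    parent = c("R", "R", "A", "A", "B", "C", "D"),
    name   = c("a", "b", "c", "d", "e", "f", "f")
  )
  ontology(edges, names = tibble::tibble(term_id = "R", name = "root"))
}

# propagated frequencies: C,D,B 3/8; E 2/8; F 1/8; A 4/8; R 1
make_test_map <- function() {
  ont <- make_test_ontology()
  ann <- tibble::tibble(
    gene_id = c("g1", "g2", "g2", "g3", "g4", "g5", "g6", "g7", "g8"),
    term_id = c("C", "C", "D", "D", "E", "E", "F", "B", "R")
  )
  propagate(ont, ann)
}
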