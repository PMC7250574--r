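DNA <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param matrix Numeric `width x 4` matrix of per-position base
#'   probabilities, columns A, C, G, T; each row must sum to 1 (tolerance
#'   1e-6).
#' @param motif_id,tf_name Identifier of the motif and the transcription
#'   factor that binds it.
#' @param background Length-4 background base probabilities (default
#'   uniform).
#' @return Object of class `pwm`.
#' @export
pwm <- function(matrix, motif_id, tf_name = motif_id,
                background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4L, nrow(matrix) >= 4L)
  colnames(matrix) <- DNA
  if (any(abs(rowSums(matrix) - 1) > 1e-6)) {
    abort(sprintf("PWM '%s': rows must sum to 1", motif_id))
  }
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  structure(list(motif_id = motif_id, tf_name = tf_name,
                 matrix = matrix, background = setNames(background, DNA)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (TF %s), width %d, consensus %s\n",
              x$motif_id, x$tf_name, nrow(x$matrix), consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (modal base per position)
#' @param x A `pwm` object.
#' @return Character scalar.
#' @export
consensus <- function(x) {
  paste(DNA[max.col(x$matrix, ties.method = "first")], collapse = "")
}

#' Log-odds score matrix of a PWM
#'
#' `score[i, b] = log2((p[i, b] + pseudocount * bg[b]) /
#' ((1 + pseudocount) * bg[b]))`, in bits. The pseudocount is spread in
#' proportion to the background so a zero probability scores finitely.
#'
#' @param x A `pwm`.
#' @param pseudocount Non-negative pseudocount mass (default 0.01).
#' @return `width x 4` numeric matrix (bits).
#' @export
log_odds <- function(x, pseudocount = 0.01) {
  stopifnot(inherits(x, "pwm"), pseudocount >= 0)
  if (any(x$background <= 0)) abort("background entries must be positive")
  bg <- matrix(x$background, nrow = nrow(x$matrix), ncol = 4, byrow = TRUE)
  s <- log2((x$matrix + pseudocount * bg) / ((1 + pseudocount) * bg))
  colnames(s) <- DNA
  s
}

#' Maximum attainable log-odds score of a PWM
#' @inheritParams log_odds
#' @return Scalar score in bits.
#' @export
max_score <- function(x, pseudocount = 0.01) {
  sum(apply(log_odds(x, pseudocount), 1, max))
}

#' Reverse-complement a DNA string
#' @param seq DNA string over A, C, G, T, N.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

encode_seq <- function(seq) {
  m <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA)
  m  # NA for N / anything else
}

# score every window of an encoded sequence against a log-odds matrix;
# windows touching an ambiguous base get -Inf
window_scores <- function(enc, lom) {
  w <- nrow(lom)
  L <- length(enc)
  n_win <- L - w + 1L
  if (n_win < 1L) return(numeric(0))
  sc <- numeric(n_win)
  bad <- logical(n_win)
  for (j in seq_len(w)) {
    b <- enc[j:(j + n_win - 1L)]
    bad <- bad | is.na(b)
    v <- unname(lom[j, ])[b]
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc[bad] <- -Inf
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Slides the log-odds matrix over every offset of the sequence (+ strand)
#' and of its reverse complement (− strand, with offsets reported on the
#' original sequence). Windows containing ambiguous bases are skipped. A hit
#' is any window scoring at or above the threshold.
#'
#' @param seq DNA string.
#' @param x A `pwm`.
#' @param threshold Detection threshold: with `type = "fraction"` (default)
#'   it is a fraction of [max_score()]; with `type = "bits"` an absolute
#'   score.
#' @param type `"fraction"` or `"bits"`.
#' @param pseudocount Passed to [log_odds()].
#' @param peak Optional peak name recorded in the output.
#' @return Tibble (`peak`, `motif_id`, `tf_name`, `offset`, `strand`,
#'   `score`), offsets 0-based on the forward sequence.
#' @export
scan_pwm <- function(seq, x, threshold = 0.8,
                     type = c("fraction", "bits"),
                     pseudocount = 0.01, peak = NA_character_) {
  type <- match.arg(type)
  stopifnot(inherits(x, "pwm"))
  lom <- log_odds(x, pseudocount)
  thr <- if (type == "fraction") threshold * max_score(x, pseudocount) else threshold
  w <- nrow(lom)
  enc <- encode_seq(seq)
  empty <- tibble(peak = character(), motif_id = character(),
                  tf_name = character(), offset = integer(),
                  strand = character(), score = numeric())
  if (length(enc) < w) return(empty)
  fwd <- window_scores(enc, lom)
  # minus strand: score the reverse-complemented matrix on the forward
  # sequence; row order reversed, A<->T and C<->G swapped
  rc_lom <- lom[rev(seq_len(w)), c(4L, 3L, 2L, 1L), drop = FALSE]
  rev_ <- window_scores(enc, rc_lom)
  hit_f <- which(fwd >= thr)
  hit_r <- which(rev_ >= thr)
  out <- tibble(
    peak = peak,
    motif_id = x$motif_id,
    tf_name = x$tf_name,
    offset = c(hit_f, hit_r) - 1L,
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(fwd[hit_f], rev_[hit_r])
  )
  arrange(out, .data$offset, .data$strand)
}

#' Scan a peak set with a motif library
#'
#' @param seqs Named character vector of peak sequences (names unique), as
#'   from [read_peak_fasta()].
#' @param library List of `pwm` objects.
#' @inheritParams scan_pwm
#' @return Motif-hit tibble keyed by (`peak`, `motif_id`, `offset`,
#'   `strand`).
#' @export
scan_peakset <- function(seqs, library, threshold = 0.8,
                         type = c("fraction", "bits"), pseudocount = 0.01) {
  type <- match.arg(type)
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup)) {
    abort(sprintf("duplicate peak names: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  if (length(library) == 0L || length(seqs) == 0L) {
    return(tibble(peak = character(), motif_id = character(),
                  tf_name = character(), offset = integer(),
                  strand = character(), score = numeric()))
  }
  enc <- lapply(seqs, encode_seq)
  acc <- list(peak = character(0), motif_id = character(0),
              tf_name = character(0), offset = integer(0),
              strand = character(0), score = numeric(0))
  for (m in library) {
    lom <- log_odds(m, pseudocount)
    w <- nrow(lom)
    thr <- if (type == "fraction") {
      threshold * sum(apply(lom, 1, max))
    } else {
      threshold
    }
    rc_lom <- lom[rev(seq_len(w)), c(4L, 3L, 2L, 1L), drop = FALSE]
    for (i in seq_along(enc)) {
      if (length(enc[[i]]) < w) next
      fwd <- window_scores(enc[[i]], lom)
      rev_ <- window_scores(enc[[i]], rc_lom)
      hf <- which(fwd >= thr); hr <- which(rev_ >= thr)
      nh <- length(hf) + length(hr)
      if (nh == 0L) next
      acc$peak <- c(acc$peak, rep(names(seqs)[i], nh))
      acc$motif_id <- c(acc$motif_id, rep(m$motif_id, nh))
      acc$tf_name <- c(acc$tf_name, rep(m$tf_name, nh))
      acc$offset <- c(acc$offset, c(hf, hr) - 1L)
      acc$strand <- c(acc$strand, rep(c("+", "-"), c(length(hf), length(hr))))
      acc$score <- c(acc$score, fwd[hf], rev_[hr])
    }
  }
  out <- as_tibble(acc)
  arrange(out, .data$peak, .data$motif_id, .data$offset, .data$strand)
}

#' Read and write motif libraries in MEME minimal format
#'
#' Only the minimal subset is handled: an optional background line and
#' `MOTIF id name` blocks followed by a `letter-probability matrix` header
#' and probability rows. The second word of the MOTIF line, when present, is
#' taken as the TF name.
#'
#' @param path File path.
#' @param library List of `pwm` objects.
#' @return `read_meme()` returns a named list of `pwm` objects (names are
#'   motif ids).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    bg <- vals[!is.na(vals)][1:4]
  }
  starts <- grep("^MOTIF\\s", lines)
  if (!length(starts)) abort(sprintf("no MOTIF blocks in '%s'", path))
  out <- list()
  for (s in starts) {
    toks <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    id <- toks[2]
    tf <- if (length(toks) >= 3) toks[3] else id
    h <- s + 1L
    while (h <= length(lines) && !grepl("letter-probability matrix", lines[h])) {
      h <- h + 1L
    }
    if (h > length(lines)) abort(sprintf("motif '%s': missing matrix header", id))
    w <- as.integer(stringr::str_match(lines[h], "w=\\s*(\\d+)")[, 2])
    rows <- lines[(h + 1L):(h + w)]
    mat <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])
    }))
    out[[id]] <- pwm(mat, motif_id = id, tf_name = tf, background = bg)
  }
  out
}

#' @rdname read_meme
#' @export
write_meme <- function(library, path) {
  bg <- library[[1]]$background
  con <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
    ""
  )
  for (m in library) {
    con <- c(con,
             sprintf("MOTIF %s %s", m$motif_id, m$tf_name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     nrow(m$matrix)),
             apply(m$matrix, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                                    r[1], r[2], r[3], r[4])),
             "")
  }
  writeLines(con, path)
  invisible(path)
}

#' Convert HOMER .motif probability files to `pwm` objects
#'
#' HOMER known-motif files carry a `>consensus name threshold` header
#' followed by one row of A/C/G/T probabilities per position.
#'
#' @param path HOMER `.motif` file (may contain several motifs).
#' @param background Background passed to each [pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_homer_motifs <- function(path, background = rep(0.25, 4)) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (!length(heads)) abort(sprintf("no motif headers in '%s'", path))
  bounds <- c(heads, length(lines) + 1L)
  out <- list()
  for (i in seq_along(heads)) {
    toks <- strsplit(sub("^>", "", lines[heads[i]]), "\\s+")[[1]]
    nm <- if (length(toks) >= 2) toks[2] else toks[1]
    # HOMER names look like "Oct4(POU,Homeobox)/..."; keep the leading token
    tf <- sub("[(/].*$", "", nm)
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    body <- body[nzchar(trimws(body))]
    mat <- do.call(rbind, lapply(body, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4])
    }))
    mat <- mat / rowSums(mat)
    out[[nm]] <- pwm(mat, motif_id = nm, tf_name = tf, background = background)
  }
  out
}

#' Write a motif-hit table
#' @param hits Tibble from [scan_peakset()].
#' @param path Output TSV.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits, path, progress = FALSE)
  invisible(path)
}
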