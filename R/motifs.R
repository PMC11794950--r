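DNA_BASES <- c("A", "C", "G", "T")

#' Construct a motif model from a position frequency matrix
#'
#' Stores the PFM together with the background base frequencies and the
#' pseudocount used to turn counts into log-odds scores. The pseudocount is
#' split across bases proportionally to the background (the common PWM
#' convention), so column `k` scores
#' `log(((pfm[b,k] + pc*bg[b]) / (colsum_k + pc)) / bg[b])`.
#'
#' @param name Motif name (used as list key and in hit tables).
#' @param pfm 4-by-L non-negative count matrix, rows A, C, G, T.
#' @param tf_name Transcription factor the motif belongs to (maps to an ADT
#'   name when applicable). Defaults to `name`.
#' @param background Base frequencies (A, C, G, T) summing to 1.
#' @param pseudocount Positive pseudocount.
#' @param id Optional accession id.
#' @return A list of class `phr_motif` with the PFM, the log-odds score
#'   matrix `score`, and the per-column score extremes used by
#'   [relative_score()].
#' @export
motif_model <- function(name, pfm, tf_name = name,
                        background = rep(0.25, 4), pseudocount = 0.8,
                        id = name) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4 || any(pfm < 0)) {
    abort("`pfm` must be a 4-row non-negative matrix (A, C, G, T).")
  }
  if (any(colSums(pfm) <= 0)) abort("Every PFM column needs a positive total.")
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9) {
    abort("`background` must be 4 positive frequencies summing to 1.")
  }
  if (pseudocount <= 0) abort("`pseudocount` must be positive.")
  rownames(pfm) <- DNA_BASES
  prob <- sweep(pfm + pseudocount * background,
                2, colSums(pfm) + pseudocount, "/")
  score <- log(prob / background)
  structure(
    list(name = name, tf_name = tf_name, id = id, pfm = pfm,
         background = background, pseudocount = pseudocount,
         score = score,
         col_min = apply(score, 2, min), col_max = apply(score, 2, max)),
    class = "phr_motif"
  )
}

#' @export
#' @method print phr_motif
print.phr_motif <- function(x, ...) {
  cat(sprintf("<phr_motif> %s (tf %s), length %d, consensus %s\n",
              x$name, x$tf_name, ncol(x$pfm), motif_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a motif (per-column maximal base)
#' @param motif A `phr_motif`.
#' @return A character scalar.
#' @export
motif_consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$pfm, 2, which.max)], collapse = "")
}

#' Reverse complement of DNA strings
#' @param seqs Character vector over the A/C/G/T/N alphabet.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(seqs) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seqs)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

# Encode equal-length sequences as an integer matrix (A=1..T=4, N=0).
encode_dna <- function(seqs) {
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) abort("Sequences must share a width.")
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt("N")] <- 0L; lut[utf8ToInt("n")] <- 0L
  codes <- utf8ToInt(paste(seqs, collapse = ""))
  if (any(lut[codes] == 0L & !(intToUtf8(codes, multiple = TRUE) %in%
                               c("N", "n")))) {
    abort("Invalid character in sequence (only A/C/G/T/N allowed).")
  }
  matrix(lut[codes], nrow = length(seqs), ncol = widths[1], byrow = TRUE)
}

#' JASPAR-style relative score of a sequence against a motif
#'
#' The log-odds sum over positions is min-max scaled to 0-1000 using the
#' per-column extreme path sums, so the consensus scores 1000 and the
#' anti-consensus 0. `N` bases contribute the background score (0 log-odds).
#'
#' @param motif A `phr_motif`.
#' @param seq Character scalar (or vector) of exactly the motif length.
#' @return Numeric relative score(s) in `[0, 1000]`.
#' @export
#' @examples
#' m <- motif_model("toy", rbind(A = c(4, 0), C = c(0, 4),
#'                               G = c(0, 0), T = c(0, 0)))
#' relative_score(m, "AC")
relative_score <- function(motif, seq) {
  L <- ncol(motif$pfm)
  if (any(nchar(seq) != L)) {
    abort(sprintf("Sequence length must equal motif length (%d).", L))
  }
  B <- encode_dna(seq)
  sc <- rbind(0, motif$score) # row 1 = N
  s <- numeric(length(seq))
  for (k in seq_len(L)) s <- s + sc[B[, k] + 1L, k]
  smin <- sum(motif$col_min)
  smax <- sum(motif$col_max)
  # clamp away float round-off so the bounds are exact
  unname(pmin(pmax(1000 * (s - smin) / (smax - smin), 0), 1000))
}

# Relative scores of every length-L window in an encoded matrix (cells = peaks).
# Returns n_seq x n_window matrix.
window_scores <- function(B, motif) {
  L <- ncol(motif$pfm)
  W <- ncol(B)
  if (W < L) return(NULL)
  nw <- W - L + 1L
  sc <- rbind(0, motif$score)
  s <- matrix(0, nrow(B), nw)
  for (k in seq_len(L)) {
    s <- s + matrix(sc[B[, k:(k + nw - 1L), drop = FALSE] + 1L, k],
                    nrow(B), nw)
  }
  smin <- sum(motif$col_min)
  smax <- sum(motif$col_max)
  pmin(pmax(1000 * (s - smin) / (smax - smin), 0), 1000)
}

# Motif with reverse-complemented PWM (for minus-strand scanning).
motif_revcomp <- function(motif) {
  pfm <- motif$pfm[4:1, ncol(motif$pfm):1, drop = FALSE]
  rownames(pfm) <- DNA_BASES
  motif_model(motif$name, pfm, tf_name = motif$tf_name,
              background = motif$background[4:1],
              pseudocount = motif$pseudocount, id = motif$id)
}

#' Scan peak sequences for motif hits
#'
#' Scores every window on both strands with [relative_score()] and reports
#' windows strictly above `cutoff` (default 400 on the 0-1000 scale), plus a
#' peak-by-motif logical membership matrix. Peaks shorter than a motif are
#' skipped for that motif with a warning.
#'
#' @param motifs A `phr_motif` or list of them.
#' @param seqs Named character vector of peak sequences (names = peak ids).
#' @param cutoff Minimum relative score (strict `>`).
#' @return A list of class `phr_hits`: `hits` tibble (`motif`, `peak_id`,
#'   `offset` from peak start, `strand`, `score`) and `membership`
#'   (peaks-by-motifs `lgCMatrix`).
#' @export
scan_peaks <- function(motifs, seqs, cutoff = 400) {
  if (inherits(motifs, "phr_motif")) motifs <- list(motifs)
  if (is.null(names(motifs))) {
    names(motifs) <- vapply(motifs, `[[`, "", "name")
  }
  if (is.null(names(seqs))) abort("`seqs` must be named by peak id.")
  widths <- nchar(seqs)
  hit_list <- list()
  for (w in unique(widths)) {
    idx <- which(widths == w)
    B <- encode_dna(seqs[idx])
    for (mname in names(motifs)) {
      m <- motifs[[mname]]
      L <- ncol(m$pfm)
      if (w < L) {
        warn(sprintf("%d peak(s) shorter than motif %s skipped.",
                     length(idx), mname))
        next
      }
      for (strand in c("+", "-")) {
        sm <- if (strand == "+") m else motif_revcomp(m)
        sc <- window_scores(B, sm)
        pass <- which(sc > cutoff, arr.ind = TRUE)
        if (nrow(pass)) {
          hit_list[[length(hit_list) + 1L]] <- tibble::tibble(
            motif = mname,
            peak_id = names(seqs)[idx[pass[, 1]]],
            offset = pass[, 2] - 1L,
            strand = strand,
            score = sc[pass]
          )
        }
      }
    }
  }
  hits <- if (length(hit_list)) {
    dplyr::arrange(dplyr::bind_rows(hit_list), .data$motif, .data$peak_id,
                   .data$offset, .data$strand)
  } else {
    tibble::tibble(motif = character(), peak_id = character(),
                   offset = integer(), strand = character(),
                   score = numeric())
  }
  membership <- Matrix::sparseMatrix(
    i = match(hits$peak_id, names(seqs)),
    j = match(hits$motif, names(motifs)),
    x = TRUE, dims = c(length(seqs), length(motifs)),
    dimnames = list(names(seqs), names(motifs))
  )
  structure(list(hits = hits, membership = membership, cutoff = cutoff),
            class = "phr_hits")
}

#' @export
#' @method print phr_hits
print.phr_hits <- function(x, ...) {
  cat(sprintf("<phr_hits> %d hits, %d motifs x %d peaks (cutoff > %g)\n",
              nrow(x$hits), ncol(x$membership), nrow(x$membership), x$cutoff))
  invisible(x)
}

#' GC fraction of sequences
#' @param seqs Character vector of DNA strings.
#' @return Numeric vector of G+C fractions.
#' @export
peak_gc <- function(seqs) {
  gc <- nchar(gsub("[^GCgc]", "", seqs))
  gc / nchar(seqs)
}
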