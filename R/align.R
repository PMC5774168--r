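#' Protein scoring scheme for translated local alignment
#'
#' Bundles a substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw alignment scores into
#' bit scores and E-values.  The defaults are the standard gapped
#' BLOSUM62 / gap 11,1 values (lambda = 0.267, K = 0.041).  A gap of
#' length L costs `gap_open + L * gap_extend`.
#'
#' @param matrix Symmetric integer substitution matrix with single-letter
#'   row/column names.  Defaults to [blosum62_matrix()].
#' @param gap_open,gap_extend Positive affine gap penalties.
#' @param lambda,K Karlin-Altschul statistical parameters (> 0).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(matrix = blosum62_matrix(), gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, K = 0.041) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            identical(rownames(matrix), colnames(matrix)),
            isTRUE(all(matrix == t(matrix))),
            gap_open > 0, gap_extend > 0, gap_extend <= gap_open,
            lambda > 0, K > 0)
  structure(
    list(matrix = matrix, alphabet = paste(rownames(matrix), collapse = ""),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         lambda = lambda, K = K),
    class = "scoring_scheme"
  )
}

#' BLOSUM62 with unmatchable translation artefacts
#'
#' The published BLOSUM62 matrix, with `X` (unknown residue, produced by
#' ambiguous codons) forced to -1 against everything and the stop
#' character `*` forced to -4 against everything (including itself), so
#' that in-frame stops are effectively unmatchable rather than rewarded.
#'
#' @return An integer substitution matrix.
#' @export
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  mat <- env$BLOSUM62
  mat["X", ] <- -1L
  mat[, "X"] <- -1L
  mat["*", ] <- -4L
  mat[, "*"] <- -4L
  storage.mode(mat) <- "integer"
  mat
}

# nucleotide scheme used for isoform identity: match +1, mismatch -2,
# N unmatchable; affine gap open 5 / extend 2
nt_scheme <- function() {
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(-2L, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- 1L
  mat["N", "N"] <- -2L
  structure(
    list(matrix = mat, alphabet = paste(letters, collapse = ""),
         gap_open = 5L, gap_extend = 2L, lambda = NA_real_, K = NA_real_),
    class = "scoring_scheme"
  )
}

#' Translate a nucleotide sequence in all six frames
#'
#' Frames +1..+3 translate the sequence at offsets 0..2; frames -1..-3
#' translate the reverse complement at offsets 0..2.  Trailing partial
#' codons are dropped, stop codons are rendered `*`, and any codon
#' containing `N` translates to `X`.
#'
#' @param seq A nucleotide string over `A,C,G,T,N`.
#' @return A tibble with columns `frame` (+1,+2,+3,-1,-2,-3) and
#'   `peptide` (possibly empty strings for very short inputs).
#' @examples
#' six_frame_translate("ATGAAATAG")
#' @export
six_frame_translate <- function(seq) {
  stopifnot(length(seq) == 1)
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3
    if (n < 3) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, start = off + 1, width = n),
      if.fuzzy.codon = "X"
    ))
  }
  tibble::tibble(
    frame = c(1L, 2L, 3L, -1L, -2L, -3L),
    peptide = c(one(fwd, 0), one(fwd, 1), one(fwd, 2),
                one(rev, 0), one(rev, 1), one(rev, 2))
  )
}

# translate every transcript in all frames at once; returns a tibble
# query_id / frame / peptide, dropping empty peptides
six_frame_translate_all <- function(transcripts) {
  fwd <- Biostrings::DNAStringSet(transcripts$seq)
  rev <- Biostrings::reverseComplement(fwd)
  frame_of <- function(set, off) {
    w <- Biostrings::width(set) - off
    w <- w - w %% 3
    pep <- rep("", length(set))
    ok <- w >= 3
    if (any(ok)) {
      sub <- Biostrings::subseq(set[ok], start = off + 1, width = w[ok])
      pep[ok] <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
    }
    pep
  }
  out <- tidyr::expand_grid(query_id = transcripts$id,
                            frame = c(1L, 2L, 3L, -1L, -2L, -3L))
  peps <- cbind(frame_of(fwd, 0), frame_of(fwd, 1), frame_of(fwd, 2),
                frame_of(rev, 0), frame_of(rev, 1), frame_of(rev, 2))
  out$peptide <- as.vector(t(peps))
  out[nzchar(out$peptide), , drop = FALSE]
}

#' Smith-Waterman local alignment of two peptides
#'
#' Exhaustive affine-gap local alignment (Gotoh recursion), returning the
#' maximal-scoring local alignment.  Unknown residues `X` score -1 and
#' stops `*` score -4 under the default scheme, so both are effectively
#' unmatchable.  When several alignments tie, the one ending earliest in
#' `a` (then in `b`) is reported, with gaps placed by a fixed
#' diagonal-first traceback, so results are deterministic.
#'
#' @param a,b Non-empty peptide strings.
#' @param scheme A [scoring_scheme()].
#' @return A list with `score` (raw, substitution-matrix units),
#'   `a_start`/`a_end`/`b_start`/`b_end` (1-based inclusive; all 0 for an
#'   empty best alignment), the gapped alignment strings `a_aln`/`b_aln`,
#'   `columns`, `matches`, `mismatches`, `gap_opens`, `identity`
#'   (matches/columns) and the non-gap residue counts
#'   `a_nongap`/`b_nongap`.
#' @examples
#' smith_waterman("MKLV", "MKLV")$score # 5 + 5 + 4 + 4
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(nzchar(a), nzchar(b))
  res <- sw_align_cpp(a, b, scheme$matrix, scheme$alphabet,
                      scheme$gap_open, scheme$gap_extend)
  res$identity <- if (res$columns > 0) res$matches / res$columns else NA_real_
  res
}

#' Karlin-Altschul bit score and E-value
#'
#' `bit_score()` converts a raw local-alignment score into bits,
#' `bit = (lambda * raw - ln K) / ln 2`; `e_value()` converts a bit score
#' into the expected number of chance alignments for a query of `m`
#' residues against a database totalling `n` residues,
#' `E = m * n * 2^(-bit)`.
#'
#' @param raw_score Raw alignment score (matrix units), >= 0.
#' @param scheme A [scoring_scheme()] supplying `lambda` and `K`.
#' @param bit Bit score.
#' @param m Query length (amino acids).
#' @param n Total database length (amino acids).
#' @return A numeric vector (both functions vectorise).
#' @export
bit_score <- function(raw_score, scheme = scoring_scheme()) {
  stopifnot(all(raw_score >= 0))
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' @rdname bit_score
#' @export
e_value <- function(bit, m, n) {
  stopifnot(all(m >= 1), all(n >= 1))
  m * n * 2^(-bit)
}
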