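#' Translated search of transcripts against a reference proteome
#'
#' The blastx-like step of the pipeline: every transcript is translated
#' in all six frames and each frame is exhaustively locally aligned
#' (Smith-Waterman, affine gaps) against every reference protein; hits
#' with E-value at most `e_max` are returned.  A score-only sweep
#' shortlists (frame, protein) pairs before the costlier traceback, so
#' reported alignments always carry intervals, identity and gap
#' structure.  Unlike heuristic BLAST, no seeding is used, hits are not
#' split at in-frame stop codons (stops simply score -4), and no
#' composition-based score adjustment is applied, so E-values emulate
#' threshold behaviour rather than matching NCBI BLAST numerically.
#'
#' @param transcripts Nucleotide sequence tibble ([read_fasta()]).
#' @param proteome Protein sequence tibble.
#' @param scheme A [scoring_scheme()].
#' @param e_max E-value cutoff (default 1e-3, the conventional
#'   significance threshold for cross-species transcript annotation).
#' @return A hit tibble with one row per (transcript, frame, protein)
#'   alignment passing `e_max`: `query_id`, `subject_id`, `frame`,
#'   `q_aa_start`/`q_aa_end` (1-based inclusive on the translated frame),
#'   `s_start`/`s_end` (1-based inclusive on the protein), `aln_len`
#'   (alignment columns), `mismatches`, `gap_opens`, `identity`,
#'   `q_nongap` (non-gap query residues), `raw_score`, `bit_score`,
#'   `e_value`.
#' @seealso [top_hits()] to reduce to one best hit per transcript.
#' @export
translated_search <- function(transcripts, proteome,
                              scheme = scoring_scheme(), e_max = 1e-3) {
  stopifnot(nrow(proteome) > 0, e_max > 0)
  if (nrow(transcripts) == 0) return(empty_hits())
  frames <- six_frame_translate_all(transcripts)
  if (nrow(frames) == 0) return(empty_hits())
  db_len <- sum(nchar(proteome$seq))

  raw <- sw_score_all_cpp(frames$peptide, proteome$seq, scheme$matrix,
                          scheme$alphabet, scheme$gap_open, scheme$gap_extend)
  bits <- bit_score(raw, scheme)
  evals <- e_value(bits, m = nchar(frames$peptide), n = db_len)
  pass <- which(evals <= e_max, arr.ind = TRUE)
  if (nrow(pass) == 0) return(empty_hits())

  rows <- purrr::map(seq_len(nrow(pass)), function(k) {
    i <- pass[k, 1]; j <- pass[k, 2]
    aln <- sw_align_cpp(frames$peptide[i], proteome$seq[j], scheme$matrix,
                        scheme$alphabet, scheme$gap_open, scheme$gap_extend)
    tibble::tibble(
      query_id = frames$query_id[i], subject_id = proteome$id[j],
      frame = frames$frame[i],
      q_aa_start = aln$a_start, q_aa_end = aln$a_end,
      s_start = aln$b_start, s_end = aln$b_end,
      aln_len = aln$columns, mismatches = aln$mismatches,
      gap_opens = aln$gap_opens,
      identity = ifelse(aln$columns > 0, aln$matches / aln$columns, NA_real_),
      q_nongap = aln$a_nongap,
      raw_score = aln$score, bit_score = bits[i, j], e_value = evals[i, j]
    )
  })
  hits <- dplyr::bind_rows(rows)
  dplyr::arrange(hits, .data$query_id, .data$e_value, .data$subject_id)
}

#' Best hit per transcript
#'
#' Reduces a hit table to one top hit per query: the hit with the
#' highest bit score, ties broken by smaller E-value, then by
#' lexicographic subject id.  Queries with no passing hit are absent.
#'
#' @param hits Hit tibble from [translated_search()] or
#'   [read_hit_table()].
#' @return One-row-per-query hit tibble.
#' @export
top_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits |>
    dplyr::arrange(.data$query_id, dplyr::desc(.data$bit_score),
                   .data$e_value, .data$subject_id) |>
    dplyr::distinct(.data$query_id, .keep_all = TRUE)
}
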