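#' Read a FASTA file into a sequence tibble
#'
#' Sequences are uppercased and validated against the declared molecule
#' alphabet: `A,C,G,T,N` for nucleotide files, the 20 amino acids plus
#' `X` and `*` for protein files.  The record id is the header token
#' before the first whitespace; the remainder becomes the description.
#'
#' @param path Path to a FASTA file (line wrapping is allowed).
#' @param molecule `"nt"` for nucleotide or `"aa"` for protein sequences.
#' @return A tibble with columns `id`, `description`, `seq`, one row per
#'   record, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 first", "acgt", "ACGT"), fa)
#' read_fasta(fa, "nt")
#' @export
read_fasta <- function(path, molecule = c("nt", "aa")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("no FASTA records in ", path, call. = FALSE)
    return(tibble::tibble(id = character(), description = character(),
                          seq = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  check_alphabet(seqs, ids, molecule)
  tibble::tibble(id = ids, description = unname(desc), seq = unname(seqs))
}

# error with id and offending position, per record
check_alphabet <- function(seqs, ids, molecule) {
  pattern <- if (molecule == "nt") "[^ACGTN]" else "[^ACDEFGHIKLMNPQRSTVWYX*]"
  bad <- regexpr(pattern, seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal %s character '%s' at position %d in sequence '%s'",
                 if (molecule == "nt") "nucleotide" else "amino-acid",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a sequence tibble to FASTA
#'
#' @param x Tibble with columns `id`, `seq` and optionally `description`.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  desc <- if ("description" %in% names(x)) x$description else rep("", nrow(x))
  headers <- ifelse(nzchar(desc), paste(x$id, desc), x$id)
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into a read tibble
#'
#' Strictly validates the 4-line record structure: a truncated final
#' record or a quality string whose length differs from its sequence is
#' an error.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A tibble with columns `id`, `seq` and `qual`, where `qual` is
#'   a list column of integer Phred scores (one per base).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0)
    return(tibble::tibble(id = character(), seq = character(),
                          qual = list()))
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ record: file has ", length(lines),
         " lines, not a multiple of 4", call. = FALSE)
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  plus <- lines[seq(3, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  if (any(!startsWith(hdr, "@")))
    stop("malformed FASTQ header at record ",
         which(!startsWith(hdr, "@"))[1], call. = FALSE)
  if (any(!startsWith(plus, "+")))
    stop("malformed FASTQ separator at record ",
         which(!startsWith(plus, "+"))[1], call. = FALSE)
  bad <- nchar(seqs) != nchar(quals)
  if (any(bad))
    stop("sequence/quality length mismatch at record ", which(bad)[1],
         " (", sub("^@", "", sub("\\s.*$", "", hdr[which(bad)[1]])), ")",
         call. = FALSE)
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  check_alphabet(seqs, ids, "nt")
  tibble::tibble(
    id = ids, seq = seqs,
    qual = lapply(quals, function(q) utf8ToInt(q) - 33L)
  )
}

#' Filter raw reads by length, ambiguity and mean base quality
#'
#' A read is kept iff it is at least `min_len` bases long, contains no
#' ambiguous base (`N`, when `forbid_ambiguous` is on), and its mean
#' per-base error probability (the mean of `10^(-Q/10)` over bases) does
#' not exceed `max_mean_error`.  The defaults correspond to the common
#' RNA-seq preprocessing rule of discarding reads under 40 bases, any
#' read with an undetermined base, and reads below an average Phred
#' score of 20 (error probability 0.01).
#'
#' Each discarded read is attributed to the first failing rule in the
#' fixed order length, ambiguity, quality, so the discard tallies are
#' deterministic.
#'
#' @param reads Read tibble from [read_fastq()].
#' @param min_len Minimum read length in bases.
#' @param max_mean_error Maximum mean per-base error probability.
#' @param forbid_ambiguous Discard reads containing `N`?
#' @return A list with elements `reads` (the kept tibble, input order
#'   preserved) and `discards` (a tibble of per-rule discard counts).
#' @export
filter_reads <- function(reads, min_len = 40L, max_mean_error = 0.01,
                         forbid_ambiguous = TRUE) {
  stopifnot(min_len > 0, max_mean_error > 0)
  len_ok <- nchar(reads$seq) >= min_len
  amb_ok <- if (forbid_ambiguous) !grepl("N", reads$seq, fixed = TRUE)
            else rep(TRUE, nrow(reads))
  mean_err <- vapply(reads$qual, function(q) mean(10^(-q / 10)), numeric(1))
  qual_ok <- mean_err <= max_mean_error
  rule <- dplyr::case_when(
    !len_ok ~ "length",
    !amb_ok ~ "ambiguity",
    !qual_ok ~ "quality",
    TRUE ~ NA_character_
  )
  n_discard <- vapply(c("length", "ambiguity", "quality"),
                      function(r) sum(rule == r, na.rm = TRUE), integer(1))
  list(
    reads = reads[is.na(rule), , drop = FALSE],
    discards = tibble::tibble(rule = names(n_discard),
                              n = unname(n_discard))
  )
}

#' Filter assembly contigs by minimum length
#'
#' @param contigs Sequence tibble (nucleotide).
#' @param min_len Minimum contig length in bases (default 150, the usual
#'   short-contig cutoff applied after de novo assembly).
#' @return The kept contigs, input order preserved.
#' @export
filter_contigs <- function(contigs, min_len = 150L) {
  contigs[nchar(contigs$seq) >= min_len, , drop = FALSE]
}

# canonical 12-column tabular hit layout (BLAST outfmt 6), plus the
# optional 13th qframe column this package writes so that reimported hits
# retain the reading frame needed for ORF calling
hit_table_cols <- c("query_id", "subject_id", "pident", "aln_len",
                    "mismatches", "gap_opens", "q_start", "q_end",
                    "s_start", "s_end", "e_value", "bit_score")

#' Read a tabular alignment-hit file (BLAST outfmt-6 dialect)
#'
#' Accepts the conventional 12 tab-separated columns (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, E-value, bit score) plus an optional
#' 13th `qframe` column.  `#`-prefixed comment lines are skipped.  Query
#' coordinates are interpreted in amino-acid units on the translated
#' frame, 1-based inclusive, as written by [write_hit_table()].
#'
#' @param path Path to the tab-separated hit table.
#' @return A hit tibble as produced by [translated_search()]; `identity`
#'   is a fraction in `[0, 1]`, `q_nongap` is the span `q_aa_end -
#'   q_aa_start + 1`, and `frame`/`raw_score` are `NA` when the file does
#'   not carry them.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(!ncol %in% c(12L, 13L)))
    stop("expected 12 or 13 tab-separated columns but found ",
         ncol[which(!ncol %in% c(12L, 13L))[1]], " on line ",
         which(!ncol %in% c(12L, 13L))[1], call. = FALSE)
  if (length(unique(ncol)) > 1)
    stop("mixed column counts in hit table", call. = FALSE)
  m <- do.call(rbind, fields)
  num <- function(j, what) {
    x <- suppressWarnings(as.numeric(m[, j]))
    if (any(is.na(x)))
      stop("unparsable ", what, " '", m[which(is.na(x))[1], j],
           "' on line ", which(is.na(x))[1], call. = FALSE)
    x
  }
  frame <- if (ncol[1] == 13L) as.integer(num(13, "frame")) else
    rep(NA_integer_, nrow(m))
  q_start <- as.integer(num(7, "query start"))
  q_end <- as.integer(num(8, "query end"))
  tibble::tibble(
    query_id = m[, 1], subject_id = m[, 2],
    frame = frame,
    q_aa_start = q_start, q_aa_end = q_end,
    s_start = as.integer(num(9, "subject start")),
    s_end = as.integer(num(10, "subject end")),
    aln_len = as.integer(num(4, "alignment length")),
    mismatches = as.integer(num(5, "mismatch count")),
    gap_opens = as.integer(num(6, "gap open count")),
    identity = num(3, "percent identity") / 100,
    q_nongap = q_end - q_start + 1L,
    raw_score = rep(NA_integer_, nrow(m)),
    bit_score = num(12, "bit score"),
    e_value = num(11, "e-value")
  )
}

empty_hits <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(), frame = integer(),
    q_aa_start = integer(), q_aa_end = integer(), s_start = integer(),
    s_end = integer(), aln_len = integer(), mismatches = integer(),
    gap_opens = integer(), identity = numeric(), q_nongap = integer(),
    raw_score = integer(), bit_score = numeric(), e_value = numeric()
  )
}

#' Write alignment hits as a tabular (outfmt-6 dialect) file
#'
#' Writes the conventional 12 columns plus a 13th `qframe` column (as
#' `blastx -outfmt '6 std qframe'` would) so that a census run from a
#' reimported table can still call ORFs in the right frame.
#'
#' @param hits Hit tibble from [translated_search()] or
#'   [read_hit_table()].
#' @param path Output path.
#' @param frame_column Include the 13th frame column? Set `FALSE` for a
#'   strictly 12-column file.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, frame_column = TRUE) {
  df <- data.frame(
    hits$query_id, hits$subject_id,
    sprintf("%.3f", hits$identity * 100),
    hits$aln_len, hits$mismatches, hits$gap_opens,
    hits$q_aa_start, hits$q_aa_end, hits$s_start, hits$s_end,
    format(hits$e_value, digits = 6, scientific = TRUE),
    sprintf("%.2f", hits$bit_score)
  )
  if (frame_column) df <- cbind(df, hits$frame)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
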