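#' N50 of a set of contig lengths
#'
#' The shortest length among the longest contigs that together contain
#' at least half of the assembly's total bases: sort lengths in
#' decreasing order and return the length at which the running sum first
#' reaches half the total.
#'
#' @param lengths Positive integer vector (a multiset; order is
#'   irrelevant).
#' @return A single length.
#' @examples
#' n50(c(6, 5, 4, 3, 2)) # 5: 6 + 5 = 11 >= 10
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("n50 of an empty set is undefined",
                                 call. = FALSE)
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}

#' Histogram of contig lengths over half-open bins
#'
#' Bins are `[lo, hi)` at the supplied edges, with an implicit first bin
#' below the smallest edge and an open-ended last bin.
#'
#' @param lengths Positive integer vector.
#' @param edges Strictly increasing bin edges.
#' @return A tibble with columns `bin` (label), `lo`, `hi` (`Inf` for the
#'   last bin) and `n`; counts sum to `length(lengths)`.
#' @export
length_histogram <- function(lengths, edges) {
  stopifnot(length(edges) >= 1, !is.unsorted(edges, strictly = TRUE))
  lo <- c(-Inf, edges)
  hi <- c(edges, Inf)
  n <- vapply(seq_along(lo),
              function(i) sum(lengths >= lo[i] & lengths < hi[i]),
              numeric(1))
  label <- c(paste0("<", edges[1]),
             if (length(edges) > 1)
               paste0(utils::head(edges, -1), "-",
                      utils::tail(edges, -1) - 1),
             paste0(">=", edges[length(edges)]))
  tibble::tibble(bin = label, lo = lo, hi = hi, n = as.integer(n))
}

#' Ortholog hit ratio of one alignment hit
#'
#' The number of non-gap residues of the translated query in the
#' alignment divided by the length of the subject protein, both in
#' amino-acid units.  A value near one indicates a fully assembled
#' transcript; near zero, a small fragment.  Values above one can occur
#' when the subject carries many gaps and are reported uncapped (with a
#' warning above 1.2).
#'
#' @param hit One-row hit tibble (or list) with `q_nongap` and
#'   `subject_id`.
#' @param subject_length Length of the subject protein in amino acids.
#' @return A single ratio > 0.
#' @export
ohr <- function(hit, subject_length) {
  stopifnot(hit$q_nongap >= 1, subject_length >= 1)
  r <- hit$q_nongap / subject_length
  if (r > 1.2)
    warning("OHR ", round(r, 2), " above 1.2 for query ", hit$query_id,
            ": subject alignment is heavily gapped", call. = FALSE)
  r
}

#' Per-transcript ortholog hit ratios for a set of top hits
#'
#' @param hits Hit tibble, one row per query (use [top_hits()] first).
#' @param proteome Protein sequence tibble supplying subject lengths.
#' @return A tibble `query_id`, `subject_id`, `ohr`.
#' @export
ohr_table <- function(hits, proteome) {
  missing <- setdiff(hits$subject_id, proteome$id)
  if (length(missing) > 0)
    stop("subject(s) absent from proteome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(hits$query_id))
    stop("ohr_table expects one (top) hit per query", call. = FALSE)
  slen <- stats::setNames(nchar(proteome$seq), proteome$id)
  out <- tibble::tibble(
    query_id = hits$query_id, subject_id = hits$subject_id,
    ohr = unname(hits$q_nongap / slen[hits$subject_id])
  )
  high <- out$ohr > 1.2
  if (any(high))
    warning(sum(high), " OHR value(s) above 1.2: heavily gapped subjects",
            call. = FALSE)
  out
}

#' Fraction of matched transcripts above OHR thresholds
#'
#' @param records OHR tibble from [ohr_table()] (one record per query).
#' @param thresholds Strict lower thresholds (default `c(0.5, 0.7)`, the
#'   conventional reporting cutoffs for assembly completeness).
#' @return A tibble `threshold`, `fraction`; empty input yields `NA`
#'   fractions.
#' @export
ohr_summary <- function(records, thresholds = c(0.5, 0.7)) {
  tibble::tibble(
    threshold = thresholds,
    fraction = vapply(thresholds, function(t) {
      if (nrow(records) == 0) NA_real_ else mean(records$ohr > t)
    }, numeric(1))
  )
}

#' Partition queries by which reference sets they hit
#'
#' Given per-reference sets of queries with significant hits, assigns
#' every query with at least one hit to exactly one cell: the exact
#' subset of references it hits (the cells of a Venn diagram).
#'
#' @param hit_sets Named list; each element is a character vector of
#'   query ids with a significant hit in that reference (or a hit tibble
#'   with a `query_id` column).
#' @return A tibble `subset` (labels like `"refA&refB"`), `n`; cell
#'   counts sum to the number of distinct queries with any hit, stored in
#'   `attr(, "universe")`.
#' @export
hit_partition <- function(hit_sets) {
  stopifnot(length(hit_sets) >= 1, !is.null(names(hit_sets)),
            all(nzchar(names(hit_sets))))
  sets <- lapply(hit_sets, function(x) {
    if (is.data.frame(x)) unique(x$query_id) else unique(as.character(x))
  })
  refs <- names(sets)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  label <- apply(membership, 1, function(row)
    paste(refs[row], collapse = "&"))
  counts <- table(label)
  # order cells by subset size then label for a stable layout
  lab <- names(counts)
  ord <- order(lengths(strsplit(lab, "&", fixed = TRUE)), lab)
  out <- tibble::tibble(subset = lab[ord], n = as.integer(counts)[ord])
  attr(out, "universe") <- length(universe)
  out
}

#' Whole-assembly summary statistics
#'
#' @param contigs Nucleotide sequence tibble.
#' @param edges Bin edges for the length histogram.
#' @return A list with `stats` (a one-row tibble: contig count, total
#'   bases, mean/min/max length, N50) and `histogram`
#'   ([length_histogram()] output).
#' @export
assembly_summary <- function(contigs, edges = c(150, 250, 500, 1000, 2000)) {
  len <- nchar(contigs$seq)
  list(
    stats = tibble::tibble(
      n_contigs = length(len), total_bases = sum(len),
      mean_length = mean(len), min_length = min(len),
      max_length = max(len), n50 = n50(len)
    ),
    histogram = length_histogram(len, edges)
  )
}
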