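#' Select candidate transcripts for target superfamilies by keyword
#'
#' Transcripts are routed to a superfamily when the annotation of their
#' top-hit protein (description or family label) contains one of the
#' superfamily's keywords, case-insensitively.  The default keyword sets
#' are the conventional ones for detoxification/digestion censuses:
#' `"cytochrome P450"` and `"cathepsin"`/`"cysteine peptidase"`.  A
#' transcript belongs to at most one superfamily: the first matching
#' keyword set wins, and configurations whose keyword sets overlap (one
#' keyword a substring of a keyword in another set) are rejected.
#'
#' @param hits Top-hit tibble ([top_hits()]), one row per query.
#' @param annotations Annotation tibble with columns `protein_id`,
#'   `family`, `clan`, `description`.
#' @param keyword_sets Named list of character vectors.
#' @return A tibble `query_id`, `subject_id`, `superfamily` for selected
#'   transcripts.
#' @export
select_family_transcripts <- function(
    hits, annotations,
    keyword_sets = list(
      P450 = c("cytochrome p450"),
      cathepsin = c("cathepsin", "cysteine peptidase")
    )) {
  stopifnot(length(keyword_sets) >= 1, !is.null(names(keyword_sets)),
            all(lengths(keyword_sets) > 0))
  kw <- lapply(keyword_sets, tolower)
  if (length(kw) > 1) {
    for (i in seq_along(kw)) for (j in seq_along(kw)) {
      if (i == j) next
      clash <- outer(kw[[i]], kw[[j]],
                     Vectorize(function(a, b) grepl(a, b, fixed = TRUE)))
      if (any(clash))
        stop("overlapping keyword sets: '",
             kw[[i]][which(clash, arr.ind = TRUE)[1, 1]], "' in set '",
             names(kw)[i], "' also matches set '", names(kw)[j], "'",
             call. = FALSE)
    }
  }
  missing <- setdiff(hits$subject_id, annotations$protein_id)
  if (length(missing) > 0)
    stop("protein(s) in hits missing from annotation table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ann <- annotations[match(hits$subject_id, annotations$protein_id), ]
  text <- tolower(paste(ann$description, ann$family))
  superfamily <- rep(NA_character_, nrow(hits))
  for (name in names(kw)) {
    hit_any <- Reduce(`|`, lapply(kw[[name]],
                                  function(k) grepl(k, text, fixed = TRUE)))
    superfamily[is.na(superfamily) & hit_any] <- name
  }
  keep <- !is.na(superfamily)
  tibble::tibble(query_id = hits$query_id[keep],
                 subject_id = hits$subject_id[keep],
                 superfamily = superfamily[keep])
}

#' Minimum-length filter for census counting
#'
#' Transcripts shorter than `min_len` nucleotides (default 250) are
#' excluded from gene counting to avoid over-estimation from tiny
#' fragments.  This filter applies only to the census, not to
#' assembly-completeness metrics.
#'
#' @param transcripts Sequence tibble.
#' @param min_len Minimum nucleotide length.
#' @return The subset of `transcripts` with `nchar(seq) >= min_len`.
#' @export
apply_min_length <- function(transcripts, min_len = 250L) {
  transcripts[nchar(transcripts$seq) >= min_len, , drop = FALSE]
}

#' Collapse near-identical transcripts into isoform clusters
#'
#' Two transcripts are linked when the best nucleotide local alignment
#' between them (match +1, mismatch -2, gap open 5 / extend 2) has
#' identity at least `identity_min` over its columns and covers at least
#' `coverage_min` of the shorter transcript; clusters are the connected
#' components of this link graph (single linkage).  Each cluster's
#' representative is its longest member (ties: lexicographically
#' smallest id).
#'
#' A k-mer candidate screen (shared `screen_k`-mers >= `screen_min`)
#' avoids aligning the quadratically many unrelated pairs; at the 95
#' percent identity threshold a qualifying pair of >= 250-nt transcripts
#' shares far more 21-mers than the screen requires, so the screen does
#' not change which pairs link.
#'
#' @param transcripts Sequence tibble.
#' @param identity_min Minimum alignment identity (default 0.95, the
#'   conventional isoform threshold).
#' @param coverage_min Minimum aligned fraction of the shorter
#'   transcript.
#' @param screen_k,screen_min k-mer screen parameters; `screen_min = 0`
#'   disables the screen and aligns all pairs.
#' @return A tibble `id`, `cluster` (integer), `representative`
#'   (logical), in input order.
#' @export
cluster_isoforms <- function(transcripts, identity_min = 0.95,
                             coverage_min = 0.80, screen_k = 21L,
                             screen_min = 5L) {
  n <- nrow(transcripts)
  out <- tibble::tibble(id = transcripts$id, cluster = seq_len(n),
                        representative = FALSE)
  if (n == 0) return(out)
  pairs <- candidate_pairs(transcripts$seq, screen_k, screen_min)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  scheme <- nt_scheme()
  if (nrow(pairs) > 0) for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (find(i) == find(j)) next
    aln <- sw_align_cpp(transcripts$seq[i], transcripts$seq[j],
                        scheme$matrix, scheme$alphabet,
                        scheme$gap_open, scheme$gap_extend)
    if (aln$columns == 0) next
    identity <- aln$matches / aln$columns
    coverage <- aln$columns /
      min(nchar(transcripts$seq[i]), nchar(transcripts$seq[j]))
    if (identity >= identity_min && coverage >= coverage_min)
      parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out$cluster <- match(roots, unique(roots))
  len <- nchar(transcripts$seq)
  for (cl in unique(out$cluster)) {
    members <- which(out$cluster == cl)
    best <- members[order(-len[members], transcripts$id[members])][1]
    out$representative[best] <- TRUE
  }
  out
}

# pairs sharing at least `min_share` distinct k-mers (both orientations
# not considered: isoforms are assembled on a common strand)
candidate_pairs <- function(seqs, k, min_share) {
  n <- length(seqs)
  if (n < 2) return(tibble::tibble(i = integer(), j = integer()))
  if (min_share <= 0) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(tibble::tibble(i = idx[, "row"], j = idx[, "col"]))
  }
  kmers <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  })
  df <- tibble::tibble(
    kmer = unlist(kmers),
    seq_idx = rep(seq_len(n), lengths(kmers))
  )
  shared <- df |>
    dplyr::inner_join(df, by = "kmer", relationship = "many-to-many") |>
    dplyr::filter(.data$seq_idx.x < .data$seq_idx.y) |>
    dplyr::count(.data$seq_idx.x, .data$seq_idx.y) |>
    dplyr::filter(.data$n >= min_share)
  tibble::tibble(i = shared$seq_idx.x, j = shared$seq_idx.y)
}

#' Call ORF completeness for a transcript in its top-hit frame
#'
#' Within the reading frame fixed by the top hit, takes the maximal
#' stop-free segment of the translation containing the hit's query
#' interval.  The ORF is `complete` when an ATG (methionine) occurs at
#' or before the hit start within that segment *and* the segment is
#' terminated by a stop codon inside the transcript; otherwise
#' `truncated`.
#'
#' @param transcript One-row sequence tibble (or list with `id`, `seq`).
#' @param hit One-row hit tibble for this transcript (supplies `frame`,
#'   `q_aa_start`, `q_aa_end`).
#' @param proteome Optional proteome tibble; required to infer the frame
#'   when `hit$frame` is `NA` (e.g. hits from a 12-column table).
#' @return A one-row tibble: `transcript_id`, `frame`, `aa_start`,
#'   `aa_end` (segment bounds in the translated frame), `has_start`,
#'   `has_stop`, `status` (`"complete"` or `"truncated"`).
#' @export
call_orf <- function(transcript, hit, proteome = NULL) {
  frame <- hit$frame
  if (is.na(frame)) {
    if (is.null(proteome))
      stop("hit for ", transcript$id,
           " has no frame; supply the proteome to infer it", call. = FALSE)
    frame <- infer_frame(transcript$seq, hit, proteome)
  }
  frames <- six_frame_translate(transcript$seq)
  pep <- frames$peptide[frames$frame == frame]
  if (!nzchar(pep) || nchar(pep) < hit$q_aa_end)
    stop("hit frame ", frame, " inconsistent with transcript ",
         transcript$id, " of length ", nchar(transcript$seq), call. = FALSE)
  orf <- orf_from_peptide(pep, hit$q_aa_start, hit$q_aa_end)
  tibble::tibble(
    transcript_id = transcript$id, frame = as.integer(frame),
    aa_start = orf$aa_start, aa_end = orf$aa_end,
    has_start = orf$has_start, has_stop = orf$has_stop,
    status = orf$status
  )
}

# ORF completeness in a fixed translated frame: maximal stop-free segment
# containing the hit interval [qs, qe]
orf_from_peptide <- function(pep, qs, qe) {
  res <- strsplit(pep, "")[[1]]
  stops <- which(res == "*")
  before <- stops[stops < qs]
  after <- stops[stops > qe]
  aa_start <- if (length(before)) max(before) + 1L else 1L
  aa_end <- if (length(after)) min(after) - 1L else length(res)
  has_start <- any(res[aa_start:qs] == "M")
  has_stop <- length(after) > 0
  list(aa_start = as.integer(aa_start), aa_end = as.integer(aa_end),
       has_start = has_start, has_stop = has_stop,
       status = if (has_start && has_stop) "complete" else "truncated")
}

# choose the frame whose translation best matches the subject over the
# hit's intervals (used for frame-less, 12-column hit tables)
infer_frame <- function(seq, hit, proteome) {
  subj <- proteome$seq[match(hit$subject_id, proteome$id)]
  if (is.na(subj))
    stop("subject ", hit$subject_id, " absent from proteome", call. = FALSE)
  s_seg <- substr(subj, hit$s_start, hit$s_end)
  frames <- six_frame_translate(seq)
  score <- vapply(seq_len(6), function(i) {
    pep <- frames$peptide[i]
    if (nchar(pep) < hit$q_aa_end) return(-1)
    q_seg <- substr(pep, hit$q_aa_start, hit$q_aa_end)
    m <- min(nchar(q_seg), nchar(s_seg))
    sum(strsplit(substr(q_seg, 1, m), "")[[1]] ==
          strsplit(substr(s_seg, 1, m), "")[[1]])
  }, numeric(1))
  frames$frame[which.max(score)]
}

#' Resolve isoform clusters sharing one reference protein into gene
#' units
#'
#' Applies the fragment-merging rule: every cluster whose representative
#' ORF is complete is its own gene; among clusters with truncated ORFs,
#' those aligning to non-overlapping regions of the shared protein are
#' chained as fragments of one gene, while overlapping truncated
#' clusters are distinct genes.  Chaining is greedy first-fit in order
#' of subject start: a cluster joins the first existing chain none of
#' whose members it overlaps, else starts a new chain.  Two intervals
#' "overlap" when they share at least `min_overlap` residues or at
#' least 10 percent of the shorter interval (set `min_overlap = 1` for
#' the literal any-overlap rule).
#'
#' @param clusters Tibble with one row per isoform cluster on a single
#'   subject: `cluster_id`, `s_start`, `s_end`, `status` (`"complete"`
#'   or `"truncated"`).
#' @param min_overlap Overlap tolerance in amino acids.
#' @return A tibble `cluster_id`, `gene_unit` (integer within this
#'   subject), `basis` (`"complete"`, `"fragment_merge"` or
#'   `"singleton"`).
#' @export
resolve_gene_units <- function(clusters, min_overlap = 15L) {
  stopifnot(all(clusters$status %in% c("complete", "truncated")),
            all(clusters$s_start <= clusters$s_end))
  n <- nrow(clusters)
  unit <- integer(n)
  basis <- character(n)
  next_unit <- 0L
  complete <- which(clusters$status == "complete")
  for (i in complete) {
    next_unit <- next_unit + 1L
    unit[i] <- next_unit
    basis[i] <- "complete"
  }
  trunc <- which(clusters$status == "truncated")
  trunc <- trunc[order(clusters$s_start[trunc], clusters$s_end[trunc],
                       clusters$cluster_id[trunc])]
  chains <- list() # each: vector of row indices
  for (i in trunc) {
    placed <- FALSE
    for (k in seq_along(chains)) {
      members <- chains[[k]]
      if (!any(vapply(members, function(j)
        intervals_overlap(clusters$s_start[i], clusters$s_end[i],
                          clusters$s_start[j], clusters$s_end[j],
                          min_overlap), logical(1)))) {
        chains[[k]] <- c(members, i)
        placed <- TRUE
        break
      }
    }
    if (!placed) chains[[length(chains) + 1]] <- i
  }
  for (chain in chains) {
    next_unit <- next_unit + 1L
    unit[chain] <- next_unit
    basis[chain] <- if (length(chain) > 1) "fragment_merge" else "singleton"
  }
  tibble::tibble(cluster_id = clusters$cluster_id, gene_unit = unit,
                 basis = basis)
}

intervals_overlap <- function(s1, e1, s2, e2, min_overlap) {
  ov <- min(e1, e2) - max(s1, s2) + 1
  if (ov <= 0) return(FALSE)
  shorter <- min(e1 - s1 + 1, e2 - s2 + 1)
  ov >= min_overlap || ov >= 0.1 * shorter
}

#' Census of minimum gene counts per family
#'
#' The full census pipeline: keyword selection of candidate transcripts
#' by their top hit, the 250-nt minimum-length filter, isoform
#' clustering at >= 95 percent nucleotide identity, ORF-completeness
#' calling for each cluster representative, per-protein resolution of
#' clusters into gene units (complete ORFs are distinct genes; truncated
#' clusters aligning to non-overlapping regions of the same protein
#' merge as fragments of one gene), and roll-up by family and clan.
#' Clusters whose members top-hit different proteins are distinct genes
#' by definition.  The resulting per-family counts are minimum
#' estimates.
#'
#' @param transcripts Nucleotide sequence tibble.
#' @param proteome Protein sequence tibble.
#' @param annotations Annotation tibble (`protein_id`, `family`, `clan`,
#'   `description`).
#' @param hits Optional precomputed hit tibble (e.g. from
#'   [read_hit_table()]); when `NULL`, [translated_search()] is run.
#' @param keyword_sets Superfamily keyword sets, as in
#'   [select_family_transcripts()].
#' @param e_max E-value cutoff for the built-in search.
#' @param census_min_len Minimum transcript length for counting (nt).
#' @param isoform_identity,isoform_coverage Isoform clustering
#'   thresholds.
#' @param min_overlap Fragment-merge overlap tolerance (aa).
#' @param scheme Protein [scoring_scheme()] for the built-in search.
#' @return A `family_census` object: a list with `families` (tibble
#'   `family`, `clan`, `transcript_count`, `gene_count`, `display` with
#'   the conventional `">="` rendering), `ledger` (per-transcript
#'   provenance: superfamily, subject, isoform cluster, gene unit and
#'   the rule that placed it), `gene_units` (one row per counted gene),
#'   and `params`.
#' @export
family_census <- function(transcripts, proteome, annotations, hits = NULL,
                          keyword_sets = list(
                            P450 = c("cytochrome p450"),
                            cathepsin = c("cathepsin", "cysteine peptidase")
                          ),
                          e_max = 1e-3, census_min_len = 250L,
                          isoform_identity = 0.95, isoform_coverage = 0.80,
                          min_overlap = 15L, scheme = scoring_scheme()) {
  stopifnot(all(c("protein_id", "family", "clan", "description") %in%
                  names(annotations)))
  if (is.null(hits))
    hits <- translated_search(transcripts, proteome, scheme, e_max)
  missing <- setdiff(hits$subject_id, annotations$protein_id)
  if (length(missing) > 0)
    stop("protein(s) in hits missing from annotation table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  tops <- top_hits(hits)
  selected <- select_family_transcripts(tops, annotations, keyword_sets)

  # census length filter
  sel_tr <- transcripts[transcripts$id %in% selected$query_id, , drop = FALSE]
  sel_tr <- apply_min_length(sel_tr, census_min_len)
  selected <- selected[selected$query_id %in% sel_tr$id, , drop = FALSE]

  ledger <- tibble::tibble(
    transcript_id = character(), superfamily = character(),
    subject_id = character(), family = character(), clan = character(),
    cluster_id = character(), gene_unit = character(), rule = character()
  )
  units <- tibble::tibble(
    gene_unit = character(), superfamily = character(),
    subject_id = character(), family = character(), clan = character(),
    basis = character(), n_transcripts = integer()
  )

  for (sf in unique(selected$superfamily)) {
    q <- selected$query_id[selected$superfamily == sf]
    tr <- sel_tr[match(q, sel_tr$id), , drop = FALSE]
    cl <- cluster_isoforms(tr, isoform_identity, isoform_coverage)
    cl$subject_id <- tops$subject_id[match(cl$id, tops$query_id)]
    # cluster-level info from the representative; translations are batched
    # (one Biostrings call per frame) since per-sequence calls dominate cost
    reps <- cl[cl$representative, , drop = FALSE]
    rep_tr <- tr[match(reps$id, tr$id), , drop = FALSE]
    rep_frames <- six_frame_translate_all(rep_tr)
    rep_info <- purrr::map(seq_len(nrow(reps)), function(k) {
      rid <- reps$id[k]
      hit <- tops[tops$query_id == rid, , drop = FALSE]
      frame <- hit$frame
      if (is.na(frame))
        frame <- infer_frame(rep_tr$seq[k], hit, proteome)
      pep <- rep_frames$peptide[rep_frames$query_id == rid &
                                  rep_frames$frame == frame]
      if (length(pep) != 1 || nchar(pep) < hit$q_aa_end)
        stop("hit frame ", frame, " inconsistent with transcript ", rid,
             call. = FALSE)
      orf <- orf_from_peptide(pep, hit$q_aa_start, hit$q_aa_end)
      tibble::tibble(cluster = reps$cluster[k], rep_id = rid,
                     subject_id = hit$subject_id,
                     s_start = hit$s_start, s_end = hit$s_end,
                     status = orf$status)
    }) |> dplyr::bind_rows()

    # resolve gene units within each shared subject
    rep_info$cluster_id <- paste0(sf, "_c", rep_info$cluster)
    res <- rep_info |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::group_modify(function(df, key) {
        r <- resolve_gene_units(
          tibble::tibble(cluster_id = df$cluster_id, s_start = df$s_start,
                         s_end = df$s_end, status = df$status),
          min_overlap = min_overlap)
        dplyr::left_join(df, r, by = "cluster_id")
      }) |>
      dplyr::ungroup()
    res$gene_unit_id <- paste0(sf, "_", res$subject_id, "_g", res$gene_unit)

    ann <- annotations[match(res$subject_id, annotations$protein_id), ]
    res$family <- ann$family
    res$clan <- ann$clan

    cl <- dplyr::left_join(
      cl, res[, c("cluster", "cluster_id", "gene_unit_id", "basis",
                  "family", "clan")],
      by = "cluster")
    multi <- cl$cluster %in% cl$cluster[duplicated(cl$cluster)]
    cl$rule <- dplyr::case_when(
      cl$basis == "fragment_merge" ~ "fragment_merge",
      multi ~ "isoform",
      TRUE ~ cl$basis
    )
    ledger <- dplyr::bind_rows(ledger, tibble::tibble(
      transcript_id = cl$id, superfamily = sf, subject_id = cl$subject_id,
      family = cl$family, clan = cl$clan, cluster_id = cl$cluster_id,
      gene_unit = cl$gene_unit_id, rule = cl$rule
    ))
    unit_tbl <- res |>
      dplyr::group_by(.data$gene_unit_id, .data$subject_id, .data$family,
                      .data$clan) |>
      dplyr::summarise(
        basis = if (any(.data$basis == "fragment_merge")) "fragment_merge"
                else .data$basis[1],
        .groups = "drop")
    members <- ledger |>
      dplyr::filter(.data$superfamily == sf) |>
      dplyr::count(.data$gene_unit, name = "n_transcripts")
    unit_tbl <- dplyr::left_join(unit_tbl, members,
                                 by = c(gene_unit_id = "gene_unit"))
    units <- dplyr::bind_rows(units, tibble::tibble(
      gene_unit = unit_tbl$gene_unit_id, superfamily = sf,
      subject_id = unit_tbl$subject_id, family = unit_tbl$family,
      clan = unit_tbl$clan, basis = unit_tbl$basis,
      n_transcripts = unit_tbl$n_transcripts
    ))
  }

  families <- units |>
    dplyr::group_by(.data$superfamily, .data$family, .data$clan) |>
    dplyr::summarise(gene_count = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(
      ledger |> dplyr::count(.data$family, name = "transcript_count"),
      by = "family") |>
    dplyr::mutate(display = paste0(">=", .data$gene_count)) |>
    dplyr::select("superfamily", "family", "clan", "transcript_count",
                  "gene_count", "display") |>
    dplyr::arrange(.data$superfamily, .data$family)

  structure(
    list(families = families, ledger = ledger, gene_units = units,
         params = list(e_max = e_max, census_min_len = census_min_len,
                       isoform_identity = isoform_identity,
                       isoform_coverage = isoform_coverage,
                       min_overlap = min_overlap,
                       keyword_sets = keyword_sets)),
    class = "family_census"
  )
}

#' @export
print.family_census <- function(x, ...) {
  cat("Gene-family census:", nrow(x$families), "families,",
      nrow(x$gene_units), "gene units from", nrow(x$ledger),
      "transcripts\n")
  print(x$families, ...)
  invisible(x)
}

#' Tidy a family census into its per-family count table
#'
#' @param x A `family_census` object.
#' @param ... Unused.
#' @return The `families` tibble: one row per family with `clan`,
#'   `transcript_count`, `gene_count` (a minimum estimate) and the
#'   `">="`-formatted `display` column.
#' @export
tidy.family_census <- function(x, ...) x$families

#' One-row summary of a family census
#'
#' @param x A `family_census` object.
#' @param ... Unused.
#' @return A one-row tibble: numbers of superfamilies, families,
#'   transcripts counted, isoform clusters and gene units.
#' @export
glance.family_census <- function(x, ...) {
  tibble::tibble(
    n_superfamilies = length(unique(x$families$superfamily)),
    n_families = nrow(x$families),
    n_transcripts = nrow(x$ledger),
    n_clusters = length(unique(x$ledger$cluster_id)),
    n_gene_units = nrow(x$gene_units)
  )
}

#' Clan-by-family matrix of minimum gene counts
#'
#' @param x A `family_census` object.
#' @return A tibble with one row per clan and one column per family,
#'   cells holding minimum gene counts (0 where a family is absent).
#' @export
clan_family_matrix <- function(x) {
  stopifnot(inherits(x, "family_census"))
  x$families |>
    dplyr::select("clan", "family", "gene_count") |>
    tidyr::pivot_wider(names_from = "family", values_from = "gene_count",
                       values_fill = 0L)
}
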