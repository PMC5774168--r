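#' Configuration for the synthetic transcriptome generator
#'
#' Collects every knob of the simulator in one validated list.  The
#' defaults describe a benchmark of twenty paralogous gene families with
#' true per-family gene counts drawn uniformly from 1..10, founder
#' proteins of 200-400 amino acids, paralogs at 85 percent amino-acid
#' identity (low enough that top hits are unambiguous), a 50 percent
#' chance that one gene per family is fragmented into two
#' subject-disjoint pieces, a 20 percent chance of an extra isoform copy
#' at 97 percent nucleotide identity, fifty junk contigs shorter than
#' 250 nt, and no sequencing error.
#'
#' @param seed Integer seed; the generator is fully deterministic given
#'   `(seed, config)`.
#' @param n_families Number of gene families.
#' @param genes_per_family Integer vector of true gene counts (length
#'   `n_families`), or `NULL` to draw them uniformly from 1..10.
#' @param protein_length_range Founder protein length range (aa).
#' @param paralog_aa_identity Target amino-acid identity of paralogs to
#'   their family founder.
#' @param fragment_prob Probability that the fragmentation-eligible gene
#'   of a family is emitted as fragments instead of one full-length
#'   transcript.
#' @param n_fragments Number of subject-disjoint fragments (>= 2).
#' @param isoform_prob Per-gene probability of emitting one extra
#'   isoform copy.
#' @param isoform_nt_identity Nucleotide identity of isoform copies.
#' @param junk_contigs Number of random junk contigs.
#' @param junk_length_range Junk contig length range (nt).
#' @param base_error_rate Per-base substitution error rate applied to
#'   every emitted transcript.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_families = 20L,
                             genes_per_family = NULL,
                             protein_length_range = c(200L, 400L),
                             paralog_aa_identity = 0.85,
                             fragment_prob = 0.5, n_fragments = 2L,
                             isoform_prob = 0.2,
                             isoform_nt_identity = 0.97,
                             junk_contigs = 50L,
                             junk_length_range = c(150L, 249L),
                             base_error_rate = 0) {
  stopifnot(n_families >= 1, n_fragments >= 2,
            length(protein_length_range) == 2,
            protein_length_range[1] <= protein_length_range[2],
            length(junk_length_range) == 2,
            junk_length_range[1] <= junk_length_range[2],
            paralog_aa_identity >= 0, paralog_aa_identity <= 1,
            fragment_prob >= 0, fragment_prob <= 1,
            isoform_prob >= 0, isoform_prob <= 1,
            isoform_nt_identity >= 0, isoform_nt_identity <= 1,
            base_error_rate >= 0, base_error_rate <= 1)
  if (!is.null(genes_per_family))
    stopifnot(length(genes_per_family) == n_families,
              all(genes_per_family >= 1))
  structure(
    list(seed = as.integer(seed), n_families = as.integer(n_families),
         genes_per_family = genes_per_family,
         protein_length_range = as.integer(protein_length_range),
         paralog_aa_identity = paralog_aa_identity,
         fragment_prob = fragment_prob,
         n_fragments = as.integer(n_fragments),
         isoform_prob = isoform_prob,
         isoform_nt_identity = isoform_nt_identity,
         junk_contigs = as.integer(junk_contigs),
         junk_length_range = as.integer(junk_length_range),
         base_error_rate = base_error_rate),
    class = "generator_config"
  )
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# codons per amino acid, from the standard genetic code
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

reverse_translate <- function(pep, codons) {
  res <- strsplit(pep, "")[[1]]
  paste(vapply(res, function(a)
    sample(codons[[a]], 1), character(1), USE.NAMES = FALSE),
    collapse = "")
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# substitute bases at `rate` (per-base Bernoulli), always to a different base
mutate_nt <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# substitute an exact number of bases, round(divergence * length), so the
# emitted pairwise identity is the configured one up to rounding
mutate_nt_exact <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n_sub <- round(divergence * length(chars))
  if (n_sub == 0) return(seq)
  for (i in sample(length(chars), n_sub)) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a family-annotated reference proteome
#'
#' One founder protein per family (the census anchor), drawn uniformly
#' over amino acids at a length inside `protein_length_range`, always
#' beginning with methionine so that its coding sequence starts with
#' ATG.  Families are named `CYP301`, `CYP302`, ... with clans assigned
#' round-robin over the four P450 clans (CYP2, Mito, CYP3, CYP4); all
#' sequences are synthetic.
#'
#' @param config A [generator_config()].
#' @return A list with `proteome` (sequence tibble) and `annotations`
#'   (`protein_id`, `family`, `clan`, `description`).
#' @export
generate_proteome <- function(config) {
  set.seed(config$seed)
  clans <- c("CYP2", "Mito", "CYP3", "CYP4")
  fams <- sprintf("CYP%d", 300 + seq_len(config$n_families))
  lens <- sample(config$protein_length_range[1]:config$protein_length_range[2],
                 config$n_families, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste0("M", paste(sample(AA20, L - 1, replace = TRUE), collapse = "")),
    character(1))
  ids <- paste0("RP_", fams)
  list(
    proteome = tibble::tibble(
      id = ids,
      description = paste("cytochrome P450", fams, "(synthetic founder)"),
      seq = seqs),
    annotations = tibble::tibble(
      protein_id = ids, family = fams,
      clan = rep(clans, length.out = config$n_families),
      description = paste("cytochrome P450", fams, "(synthetic founder)"))
  )
}

#' Generate true gene coding sequences for each family
#'
#' Gene 1 of a family is an exact reverse translation of the founder
#' protein (codons drawn uniformly among synonyms); genes 2..k are
#' paralogs substituted at the amino-acid level down to
#' `paralog_aa_identity` (positions and replacement residues uniform,
#' the initial methionine kept) and then reverse-translated.  Every
#' coding sequence ends with a random stop codon.  Each paralog is
#' verified to score best against its own family founder in a
#' protein-level local-alignment sweep; violators are redrawn under a
#' fresh sub-seed (an error is raised after 100 attempts, advising lower
#' divergence).
#'
#' @param config A [generator_config()].
#' @param ref Output of [generate_proteome()].
#' @return A tibble with one row per true gene: `gene_id`, `family`,
#'   `protein_id`, `protein` (peptide), `cds` (nucleotides, stop codon
#'   included), `true_counts` attribute is not used; per-family counts
#'   come from the truth ledger.
#' @export
generate_genes <- function(config, ref) {
  set.seed(config$seed + 1L)
  codons <- codon_table()
  stops <- codons[["*"]]
  counts <- config$genes_per_family
  if (is.null(counts)) counts <- sample(1:10, config$n_families,
                                        replace = TRUE)
  founders <- ref$proteome

  make_paralog <- function(founder_pep) {
    res <- strsplit(founder_pep, "")[[1]]
    n_sub <- round((1 - config$paralog_aa_identity) * (length(res) - 1))
    pos <- sample(2:length(res), n_sub)
    for (i in pos) res[i] <- sample(setdiff(AA20, res[i]), 1)
    paste(res, collapse = "")
  }

  rows <- purrr::map(seq_len(config$n_families), function(f) {
    fam <- founders$id[f]
    pep <- founders$seq[f]
    prot <- vapply(seq_len(counts[f]), function(j) {
      if (j == 1) pep else make_paralog(pep)
    }, character(1))
    tibble::tibble(
      gene_id = sprintf("%s_g%02d", ref$annotations$family[f],
                        seq_len(counts[f])),
      family = ref$annotations$family[f], protein_id = fam,
      protein = prot
    )
  }) |> dplyr::bind_rows()

  # paralogs must still top-hit their own founder
  scheme <- scoring_scheme()
  for (attempt in seq_len(100L)) {
    scores <- sw_score_all_cpp(rows$protein, founders$seq, scheme$matrix,
                               scheme$alphabet, scheme$gap_open,
                               scheme$gap_extend)
    best <- founders$id[max.col(scores, ties.method = "first")]
    bad <- which(best != rows$protein_id)
    if (length(bad) == 0) break
    if (attempt == 100L)
      stop("paralogs failed to top-hit their own founder after 100 ",
           "attempts; lower the divergence (raise paralog_aa_identity)",
           call. = FALSE)
    set.seed(config$seed + 1000L + attempt)
    for (i in bad) {
      founder_pep <- founders$seq[founders$id == rows$protein_id[i]]
      rows$protein[i] <- make_paralog(founder_pep)
    }
  }

  set.seed(config$seed + 2L)
  rows$cds <- vapply(rows$protein, function(p)
    paste0(reverse_translate(p, codons), sample(stops, 1)),
    character(1), USE.NAMES = FALSE)
  rows
}

#' Emit a synthetic transcript assembly with a ground-truth ledger
#'
#' Each gene emits one full-length transcript (its coding sequence,
#' stop codon included, flanked by short random untranslated ends) or --
#' for the one fragmentation-eligible gene per family, with probability
#' `fragment_prob` -- `n_fragments` pieces whose translated spans are
#' disjoint on the founder protein with at least a 20-aa gap and which
#' never include the start or stop codon together, so each piece has a
#' truncated ORF.  Restricting fragmentation to one gene per family
#' makes the fragment-merge rule exactly invertible: fragments that
#' co-hit a founder always belong to the same gene.  With probability
#' `isoform_prob` a gene also emits an isoform copy of its first
#' transcript at `isoform_nt_identity`.  Junk contigs are uniform random
#' nucleotides.  Per-base substitution errors at `base_error_rate` are
#' applied to every transcript.  Fragmentation falls back to a
#' full-length transcript (with a warning) when the founder is too short
#' to host the requested fragments.
#'
#' @param config A [generator_config()].
#' @param genes Output of [generate_genes()].
#' @return A list with `transcripts` (sequence tibble) and `truth` (list
#'   of `transcripts`: `transcript_id`, `true_gene_id`, `true_family`,
#'   `role`; and `families`: `family`, `true_genes`).
#' @export
generate_transcripts <- function(config, genes) {
  set.seed(config$seed + 3L)
  min_frag_aa <- 85L # >= 255 nt, safely above the census length filter
  gap_aa <- 20L

  fams <- unique(genes$family)
  frag_candidate <- vapply(fams, function(f) {
    ids <- genes$gene_id[genes$family == f]
    sample(ids, 1)
  }, character(1))

  recs <- list()
  truth <- list()
  emit <- function(id, seq, gene, fam, role) {
    recs[[length(recs) + 1]] <<- tibble::tibble(
      id = id, description = "", seq = seq)
    truth[[length(truth) + 1]] <<- tibble::tibble(
      transcript_id = id, true_gene_id = gene, true_family = fam,
      role = role)
  }

  for (g in seq_len(nrow(genes))) {
    gene <- genes$gene_id[g]
    fam <- genes$family[g]
    cds <- genes$cds[g]
    aa_len <- (nchar(cds) - 3L) %/% 3L
    fragment <- gene %in% frag_candidate &&
      stats::runif(1) < config$fragment_prob
    if (fragment) {
      k <- config$n_fragments
      need <- k * min_frag_aa + (k - 1L) * gap_aa
      if (aa_len < need) {
        warning("founder of ", fam, " too short to host ", k,
                " fragments; emitting full-length for ", gene,
                call. = FALSE)
        fragment <- FALSE
      }
    }
    if (fragment) {
      k <- config$n_fragments
      slack <- aa_len - (k * min_frag_aa + (k - 1L) * gap_aa)
      alloc <- if (slack > 0)
        as.vector(stats::rmultinom(1, slack, rep(1, 2 * k + 1))) else
        rep(0L, 2 * k + 1)
      # slots: leading gap, then (fragment, gap) pairs, trailing gap
      pos <- 1L + alloc[1]
      first_tx <- NULL
      for (fi in seq_len(k)) {
        flen <- min_frag_aa + alloc[2 * fi]
        s_aa <- pos
        e_aa <- pos + flen - 1L
        pos <- e_aa + 1L + gap_aa + alloc[2 * fi + 1]
        frag_nt <- substr(cds, 3L * (s_aa - 1L) + 1L, 3L * e_aa)
        id <- sprintf("%s_frag%d", gene, fi)
        seq <- mutate_nt(frag_nt, config$base_error_rate)
        emit(id, seq, gene, fam, sprintf("fragment_%d_of_%d", fi, k))
        if (fi == 1) first_tx <- seq
      }
    } else {
      utr5 <- random_nt(sample(0:50, 1))
      utr3 <- random_nt(sample(0:50, 1))
      seq <- mutate_nt(paste0(utr5, cds, utr3), config$base_error_rate)
      emit(paste0(gene, "_full"), seq, gene, fam, "full")
      first_tx <- seq
    }
    if (stats::runif(1) < config$isoform_prob) {
      # derived from the emitted (post-error) transcript with an exact
      # substitution count, so the pair sits at isoform_nt_identity
      iso <- mutate_nt_exact(first_tx, 1 - config$isoform_nt_identity)
      emit(paste0(gene, "_iso"), iso, gene, fam, "isoform")
    }
  }

  for (j in seq_len(config$junk_contigs)) {
    len <- sample(config$junk_length_range[1]:config$junk_length_range[2], 1)
    emit(sprintf("junk%03d", j), random_nt(len), NA_character_,
         NA_character_, "junk")
  }

  truth_tbl <- dplyr::bind_rows(truth)
  list(
    transcripts = dplyr::bind_rows(recs),
    truth = list(
      transcripts = truth_tbl,
      families = truth_tbl |>
        dplyr::filter(.data$role != "junk") |>
        dplyr::distinct(.data$true_family, .data$true_gene_id) |>
        dplyr::count(.data$true_family, name = "true_genes") |>
        dplyr::rename(family = "true_family")
    )
  )
}

#' One-call synthetic benchmark: proteome, genes, transcripts, truth
#'
#' Runs [generate_proteome()], [generate_genes()] and
#' [generate_transcripts()] under one configuration.
#'
#' @param config A [generator_config()].
#' @return A list `proteome`, `annotations`, `genes`, `transcripts`,
#'   `truth`, `config`.
#' @export
simulate_transcriptome <- function(config = generator_config()) {
  ref <- generate_proteome(config)
  genes <- generate_genes(config, ref)
  tx <- generate_transcripts(config, genes)
  list(proteome = ref$proteome, annotations = ref$annotations,
       genes = genes, transcripts = tx$transcripts, truth = tx$truth,
       config = config)
}

#' Score a census against the generator's ground truth
#'
#' Compares estimated per-family minimum gene counts with the true
#' counts and reports transcript-level cluster purity: the fraction of
#' gene units all of whose member transcripts descend from one true
#' gene.
#'
#' @param census A `family_census` object.
#' @param truth The `truth` element of [simulate_transcriptome()].
#' @return A list with `per_family` (tibble `family`, `true_genes`,
#'   `estimated`, `exact`), `exact_fraction`, and `purity`.
#' @export
score_recovery <- function(census, truth) {
  stopifnot(inherits(census, "family_census"))
  est <- census$families[, c("family", "gene_count")]
  unknown <- setdiff(est$family, truth$families$family)
  if (length(unknown) > 0)
    stop("family present in census but not in truth: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  per_family <- truth$families |>
    dplyr::left_join(est, by = "family") |>
    dplyr::mutate(estimated = dplyr::coalesce(.data$gene_count, 0L),
                  exact = .data$estimated == .data$true_genes) |>
    dplyr::select("family", "true_genes", "estimated", "exact")
  membership <- census$ledger |>
    dplyr::left_join(truth$transcripts,
                     by = c(transcript_id = "transcript_id")) |>
    dplyr::group_by(.data$gene_unit) |>
    dplyr::summarise(pure = dplyr::n_distinct(.data$true_gene_id) == 1,
                     .groups = "drop")
  list(per_family = per_family,
       exact_fraction = mean(per_family$exact),
       purity = mean(membership$pure))
}
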