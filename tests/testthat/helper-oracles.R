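# Independent oracles and fixture builders used across the suite.
# Every oracle is written from the definition, separately from the package
# implementation it checks.

# Full-DP Gotoh local alignment, score only, in plain R.  Gap of length L
# costs go + L * ge, like the package convention.
sw_oracle_score <- function(a, b, mat, go, ge) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      E[i, j] <- max(H[i, j - 1] - go - ge, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go - ge, F[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Interval-overlap predicate mirroring the census rule, written from the
# rule statement (overlap >= tol residues OR >= 10% of the shorter).
overlap_oracle <- function(s1, e1, s2, e2, tol) {
  ov <- min(e1, e2) - max(s1, s2) + 1
  if (ov <= 0) return(FALSE)
  ov >= tol || ov >= 0.1 * min(e1 - s1 + 1, e2 - s2 + 1)
}

# Exhaustive minimal chaining: the minimum number of groups such that no
# group contains two overlapping intervals (exact search over colourings).
min_chains_oracle <- function(s, e, tol) {
  n <- length(s)
  if (n == 0) return(0L)
  adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    i != j && overlap_oracle(s[i], e[i], s[j], e[j], tol)))
  best <- n
  assign_next <- function(col) {
    i <- length(col) + 1
    if (i > n) {
      best <<- min(best, max(col))
      return(invisible())
    }
    used <- max(c(col, 0))
    for (k in seq_len(min(used + 1, best - 1))) {
      if (!any(adj[i, seq_len(i - 1)] & col == k)) assign_next(c(col, k))
    }
  }
  assign_next(integer(0))
  best
}

# N50 from the definition "the largest length l such that contigs of
# length >= l hold at least half the total bases".
n50_oracle <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (l in cand) if (sum(lengths[lengths >= l]) >= total / 2) return(l)
}

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(len) {
  paste(sample(AA_LETTERS, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# deterministic reverse translation (first codon of each amino acid)
codon1 <- local({
  gc <- Biostrings::GENETIC_CODE
  vapply(split(names(gc), unname(gc)), `[`, character(1), 1)
})
rev_translate1 <- function(pep) {
  paste(codon1[strsplit(pep, "")[[1]]], collapse = "")
}

# substitute exactly `k` bases at the given (or sampled) positions,
# cycling A->C->G->T->A so the change is deterministic
mutate_positions <- function(seq, positions) {
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  chars <- strsplit(seq, "")[[1]]
  chars[positions] <- nxt[chars[positions]]
  paste(chars, collapse = "")
}

# tiny annotated reference: two P450-like proteins built from fixed
# peptides, plus their reverse-translated coding sequences
tiny_reference <- function(pep_len = 120, n_prot = 2, seed = 7) {
  set.seed(seed)
  peps <- vapply(seq_len(n_prot), function(i)
    paste0("M", random_peptide(pep_len - 1)), character(1))
  ids <- sprintf("P%d", seq_len(n_prot))
  list(
    proteome = tibble::tibble(
      id = ids, description = sprintf("cytochrome P450 %s", ids),
      seq = peps),
    annotations = tibble::tibble(
      protein_id = ids, family = sprintf("CYPT%d", seq_len(n_prot)),
      clan = rep(c("CYP3", "CYP4"), length.out = n_prot),
      description = sprintf("cytochrome P450 %s", ids)),
    cds = vapply(peps, function(p) paste0(rev_translate1(p), "TAA"),
                 character(1), USE.NAMES = FALSE)
  )
}

write_tmp_fasta <- function(tbl, ext = ".fa") {
  path <- tempfile(fileext = ext)
  famexpand::write_fasta(tbl, path)
  path
}
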