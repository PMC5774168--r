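test_that("keyword selection routes transcripts by top-hit annotation", {
  hits <- tibble::tibble(query_id = c("t1", "t2", "t3"),
                         subject_id = c("P1", "P2", "P3"))
  ann <- tibble::tibble(
    protein_id = c("P1", "P2", "P3"),
    family = c("CYP6", "CTSL", "TRY"),
    clan = c("CYP3", "", ""),
    description = c("cytochrome P450 6BQ something",
                    "cysteine peptidase cathepsin-L",
                    "trypsin-like serine protease"))
  sel <- select_family_transcripts(hits, ann)
  expect_equal(sel$superfamily[sel$query_id == "t1"], "P450")
  # both cathepsin keywords match t2 but it is selected exactly once
  expect_equal(sum(sel$query_id == "t2"), 1)
  expect_equal(sel$superfamily[sel$query_id == "t2"], "cathepsin")
  expect_false("t3" %in% sel$query_id)

  expect_error(
    select_family_transcripts(hits, ann, keyword_sets = list(
      a = "cathepsin", b = "cathepsin-l")),
    "overlapping keyword sets")
  expect_error(
    select_family_transcripts(
      tibble::tibble(query_id = "t9", subject_id = "P9"), ann),
    "missing from annotation.*P9")
})

test_that("census length filter keeps exactly the >= 250 nt transcripts", {
  tx <- tibble::tibble(id = c("a", "b"), description = "",
                       seq = c(strrep("A", 249), strrep("A", 250)))
  kept <- apply_min_length(tx)
  expect_equal(kept$id, "b")
  expect_equal(apply_min_length(kept), kept)
  expect_equal(nrow(apply_min_length(tx[0, ])), 0)
})

test_that("isoform clustering links at >= 95% identity with coverage and
           chains by single linkage", {
  set.seed(31)
  base <- random_dna(400)
  spread <- function(k) round(seq(25, 375, length.out = k))
  tx96 <- tibble::tibble(
    id = c("a", "b"), description = "",
    seq = c(base, mutate_positions(base, spread(16)))) # 4% diverged
  cl96 <- cluster_isoforms(tx96)
  expect_equal(cl96$cluster[1], cl96$cluster[2])

  tx94 <- tibble::tibble(
    id = c("a", "b"), description = "",
    seq = c(base, mutate_positions(base, spread(24)))) # 6% diverged
  cl94 <- cluster_isoforms(tx94)
  expect_false(cl94$cluster[1] == cl94$cluster[2])

  # chain: a~b and b~c at 96%, a-c only ~92% -> one cluster of three
  pos <- spread(32)
  a <- mutate_positions(base, pos[seq(1, 32, 2)])
  c_ <- mutate_positions(base, pos[seq(2, 32, 2)])
  chain <- cluster_isoforms(tibble::tibble(
    id = c("a", "b", "c"), description = "", seq = c(a, base, c_)))
  expect_equal(length(unique(chain$cluster)), 1)
  # representative is the longest member, ties by id
  expect_equal(chain$id[chain$representative], "a")
})

test_that("the k-mer screen does not change clustering on qualifying
           pairs", {
  set.seed(32)
  base <- random_dna(300)
  tx <- tibble::tibble(
    id = c("a", "b"), description = "",
    seq = c(base, mutate_positions(base, round(seq(20, 280,
                                                   length.out = 9)))))
  with_screen <- cluster_isoforms(tx)
  without <- cluster_isoforms(tx, screen_min = 0)
  expect_equal(with_screen$cluster, without$cluster)
})

test_that("ORF calls distinguish complete from truncated", {
  ref <- tiny_reference(pep_len = 90)
  cds <- ref$cds[1] # ATG ... TAA
  utr5 <- "GGGTTT"
  utr3 <- "CCCGGG"
  full <- tibble::tibble(id = "full", description = "",
                         seq = paste0(utr5, cds, utr3))
  hit_full <- top_hits(translated_search(full, ref$proteome))
  orf <- call_orf(full, hit_full)
  expect_equal(orf$status, "complete")
  expect_true(orf$has_start && orf$has_stop)

  # interior fragment: no ATG at/before the hit start, no stop after
  frag <- tibble::tibble(id = "frag", description = "",
                         seq = substr(cds, 3 * 20 + 1, 3 * 80))
  hit_frag <- top_hits(translated_search(frag, ref$proteome))
  orf_frag <- call_orf(frag, hit_frag)
  expect_equal(orf_frag$status, "truncated")

  # ATG present but transcript ends before any stop codon
  headless <- tibble::tibble(id = "nostop", description = "",
                             seq = substr(cds, 1, nchar(cds) - 3))
  hit_h <- top_hits(translated_search(headless, ref$proteome))
  orf_h <- call_orf(headless, hit_h)
  expect_true(orf_h$has_start)
  expect_false(orf_h$has_stop)
  expect_equal(orf_h$status, "truncated")
})

test_that("gene-unit resolution merges non-overlapping truncated
           fragments and splits overlapping ones", {
  mk <- function(s, e, status = "truncated")
    tibble::tibble(cluster_id = sprintf("c%d", seq_along(s)),
                   s_start = s, s_end = e, status = status)
  # disjoint fragments -> one gene
  r1 <- resolve_gene_units(mk(c(1, 150), c(100, 250)))
  expect_equal(length(unique(r1$gene_unit)), 1)
  expect_true(all(r1$basis == "fragment_merge"))
  # 21-aa overlap -> two genes
  r2 <- resolve_gene_units(mk(c(1, 100), c(120, 220)))
  expect_equal(length(unique(r2$gene_unit)), 2)
  # three intervals: [1,80] chains with [90,160]; [140,230] overlaps the
  # second -> 2 genes
  r3 <- resolve_gene_units(mk(c(1, 90, 140), c(80, 160, 230)))
  expect_equal(length(unique(r3$gene_unit)), 2)
  expect_equal(r3$gene_unit[1], r3$gene_unit[2])
  # complete ORFs are always their own gene
  r4 <- resolve_gene_units(mk(c(1, 150), c(100, 250),
                              status = c("complete", "truncated")))
  expect_equal(length(unique(r4$gene_unit)), 2)
  expect_equal(r4$basis, c("complete", "singleton"))
})

test_that("greedy chaining matches the exhaustive minimal-chaining oracle
           on small random groups", {
  set.seed(33)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    s <- sample(1:300, n, replace = TRUE)
    e <- s + sample(20:150, n, replace = TRUE) - 1
    res <- resolve_gene_units(tibble::tibble(
      cluster_id = sprintf("c%d", 1:n), s_start = s, s_end = e,
      status = "truncated"))
    expect_equal(length(unique(res$gene_unit)), min_chains_oracle(s, e, 15))
  }
})

test_that("a small composed census counts genes by the published rules", {
  ref <- tiny_reference(pep_len = 150)
  base <- paste0("GGGT", ref$cds[1], "TGGG")
  iso <- mutate_positions(base, round(seq(20, nchar(base) - 20,
                                          length.out = round(0.03 * nchar(base)))))
  tx <- tibble::tibble(
    id = c("A", "B", "C"), description = "",
    seq = c(base, iso, paste0("CCTT", ref$cds[2], "ACGT")))
  cen <- family_census(tx, ref$proteome, ref$annotations)
  expect_equal(sum(cen$families$gene_count), 2)
  expect_equal(nrow(cen$ledger), 3)
  expect_equal(length(unique(cen$ledger$cluster_id[cen$ledger$transcript_id
                                                   %in% c("A", "B")])), 1)

  # two non-overlapping truncated fragments of a second gene on P1 plus
  # one complete transcript on P1 overlapping both -> 2 genes: the
  # fragments merge, the complete ORF stands alone
  ref2 <- tiny_reference(pep_len = 200)
  paralog_cds <- mutate_positions(ref2$cds[1],
                                  seq(5, nchar(ref2$cds[1]) - 5, by = 10))
  frag1 <- substr(paralog_cds, 1, 285)        # aa 1..95, no stop
  frag2 <- substr(paralog_cds, 316, 600)      # aa 106..200, no ATG@start
  tx2 <- tibble::tibble(
    id = c("full", "f1", "f2"), description = "",
    seq = c(paste0("GT", ref2$cds[1], "AC"), frag1, frag2))
  cen2 <- family_census(tx2, ref2$proteome, ref2$annotations)
  expect_equal(sum(cen2$families$gene_count), 2)
  units <- unique(cen2$ledger$gene_unit[cen2$ledger$transcript_id
                                        %in% c("f1", "f2")])
  expect_equal(length(units), 1)

  expect_error(
    family_census(tx, ref$proteome, ref$annotations[-1, ]),
    "missing from annotation")
})

test_that("census provenance is complete and counts are conservative", {
  sim <- simulate_transcriptome(generator_config(
    seed = 5, n_families = 5, junk_contigs = 10))
  cen <- family_census(sim$transcripts, sim$proteome, sim$annotations)
  # every selected transcript appears in exactly one cluster / gene unit
  expect_equal(anyDuplicated(cen$ledger$transcript_id), 0)
  per_subject <- cen$ledger |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(units = dplyr::n_distinct(gene_unit),
                     clusters = dplyr::n_distinct(cluster_id))
  expect_true(all(per_subject$units <= per_subject$clusters))
  # at least one gene per distinct top-hit subject
  expect_gte(sum(cen$families$gene_count), nrow(per_subject))
  expect_true(all(cen$families$gene_count <=
                    cen$families$transcript_count))
  expect_equal(tidy(cen), cen$families)
  g <- glance(cen)
  expect_equal(g$n_gene_units, sum(cen$families$gene_count))
})

test_that("census recovers the exact true counts on clean synthetic
           data", {
  sim <- simulate_transcriptome(generator_config(
    seed = 17, n_families = 6, junk_contigs = 15))
  cen <- family_census(sim$transcripts, sim$proteome, sim$annotations)
  rec <- score_recovery(cen, sim$truth)
  expect_equal(rec$exact_fraction, 1.0)
  expect_equal(rec$purity, 1.0)
  # junk contigs never enter the census
  junk <- sim$truth$transcripts$transcript_id[
    sim$truth$transcripts$role == "junk"]
  expect_false(any(junk %in% cen$ledger$transcript_id))
})
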