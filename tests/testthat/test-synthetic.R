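test_that("the generator is deterministic under (seed, config)", {
  cfg <- generator_config(seed = 3, n_families = 4, junk_contigs = 5)
  a <- simulate_transcriptome(cfg)
  b <- simulate_transcriptome(cfg)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$proteome, b$proteome)
  expect_identical(a$truth, b$truth)
  # a different seed changes sequences but not the configured structure
  cfg2 <- generator_config(seed = 4, n_families = 4,
                           genes_per_family = c(2, 3, 1, 4),
                           junk_contigs = 5)
  cfg3 <- generator_config(seed = 5, n_families = 4,
                           genes_per_family = c(2, 3, 1, 4),
                           junk_contigs = 5)
  s2 <- simulate_transcriptome(cfg2)
  s3 <- simulate_transcriptome(cfg3)
  expect_false(identical(s2$transcripts$seq, s3$transcripts$seq))
  expect_equal(s2$truth$families, s3$truth$families)
  expect_equal(s2$truth$families$true_genes, c(2, 3, 1, 4))
})

test_that("the proteome has one annotated founder per family with
           lengths in range", {
  cfg <- generator_config(seed = 8, n_families = 12,
                          protein_length_range = c(180, 260))
  ref <- generate_proteome(cfg)
  expect_equal(nrow(ref$proteome), 12)
  expect_equal(ref$proteome$id, ref$annotations$protein_id)
  lens <- nchar(ref$proteome$seq)
  expect_true(all(lens >= 180 & lens <= 260))
  expect_true(all(substr(ref$proteome$seq, 1, 1) == "M"))
  expect_equal(sort(unique(ref$annotations$clan)),
               sort(c("CYP2", "Mito", "CYP3", "CYP4")))
})

test_that("paralogs sit near the target amino-acid identity and fully
           identical paralogs are possible", {
  cfg <- generator_config(seed = 9, n_families = 3,
                          genes_per_family = c(4, 4, 4),
                          paralog_aa_identity = 0.85)
  ref <- generate_proteome(cfg)
  genes <- generate_genes(cfg, ref)
  founders <- stats::setNames(ref$proteome$seq, ref$proteome$id)
  for (i in seq_len(nrow(genes))) {
    # identity oracle: global alignment via Biostrings
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(genes$protein[i]),
      Biostrings::AAString(founders[genes$protein_id[i]]),
      type = "global")
    pid <- Biostrings::pid(pa) / 100
    target <- if (grepl("_g01$", genes$gene_id[i])) 1.0 else 0.85
    expect_lt(abs(pid - target), 0.02)
  }
  # CDS translates back to the protein (stop codon appended)
  tr <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(genes$cds)))
  expect_equal(tr, paste0(genes$protein, "*"))

  idf <- generator_config(seed = 9, n_families = 2,
                          genes_per_family = c(2, 2),
                          paralog_aa_identity = 1.0)
  refi <- generate_proteome(idf)
  gi <- generate_genes(idf, refi)
  expect_equal(gi$protein[1], gi$protein[2])
})

test_that("transcript roles account for every record and honour the
           configuration", {
  cfg <- generator_config(seed = 10, n_families = 8, junk_contigs = 12)
  sim <- simulate_transcriptome(cfg)
  roles <- sim$truth$transcripts$role
  expect_equal(nrow(sim$transcripts), length(roles))
  expect_equal(sum(roles == "junk"), 12)
  # fragments come in complete sets
  frags <- grep("^fragment", roles, value = TRUE)
  if (length(frags) > 0)
    expect_true(all(table(sub("_of_.*", "",
                              sim$truth$transcripts$true_gene_id[
                                grepl("^fragment", roles)])) ==
                      cfg$n_fragments))
  # per-family truth equals distinct true genes
  tally <- sim$truth$transcripts |>
    dplyr::filter(role != "junk") |>
    dplyr::distinct(true_family, true_gene_id) |>
    dplyr::count(true_family)
  expect_equal(sort(tally$n),
               sort(sim$truth$families$true_genes))
})

test_that("fragments of one gene align to disjoint subject regions", {
  cfg <- generator_config(seed = 11, n_families = 6, fragment_prob = 1,
                          isoform_prob = 0, junk_contigs = 0)
  sim <- simulate_transcriptome(cfg)
  frag_ids <- sim$truth$transcripts |>
    dplyr::filter(grepl("^fragment", role))
  expect_gt(nrow(frag_ids), 0)
  tx <- sim$transcripts[sim$transcripts$id %in% frag_ids$transcript_id, ]
  tops <- top_hits(translated_search(tx, sim$proteome))
  by_gene <- dplyr::left_join(tops, frag_ids,
                              by = c(query_id = "transcript_id"))
  for (g in unique(by_gene$true_gene_id)) {
    iv <- by_gene[by_gene$true_gene_id == g, ]
    if (nrow(iv) == 2)
      expect_true(iv$s_end[1] < iv$s_start[2] ||
                    iv$s_end[2] < iv$s_start[1])
  }
})

test_that("junk contigs fall below the census length filter", {
  cfg <- generator_config(seed = 12, n_families = 3, junk_contigs = 20)
  sim <- simulate_transcriptome(cfg)
  junk <- sim$truth$transcripts$transcript_id[
    sim$truth$transcripts$role == "junk"]
  lens <- nchar(sim$transcripts$seq[sim$transcripts$id %in% junk])
  expect_true(all(lens >= 150 & lens <= 249))
  expect_equal(nrow(apply_min_length(
    sim$transcripts[sim$transcripts$id %in% junk, ])), 0)
})

test_that("recovery scoring flags over-splits and rejects unknown
           families", {
  sim <- simulate_transcriptome(generator_config(
    seed = 13, n_families = 4, fragment_prob = 1, junk_contigs = 0))
  cen <- family_census(sim$transcripts, sim$proteome, sim$annotations)
  rec <- score_recovery(cen, sim$truth)
  expect_equal(rec$exact_fraction, 1.0)

  # corrupt the truth: pretend one family had one fewer gene
  truth2 <- sim$truth
  truth2$families$true_genes[1] <- truth2$families$true_genes[1] + 1L
  rec2 <- score_recovery(cen, truth2)
  expect_equal(rec2$exact_fraction, 0.75)

  truth3 <- sim$truth
  truth3$families <- truth3$families[-1, ]
  expect_error(score_recovery(cen, truth3), "not in truth")

  # scrambled transcript-to-gene labels destroy cluster purity
  truth4 <- sim$truth
  set.seed(99)
  truth4$transcripts$true_gene_id <-
    sample(truth4$transcripts$true_gene_id)
  rec4 <- score_recovery(cen, truth4)
  expect_lt(rec4$purity, 1.0)
})
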