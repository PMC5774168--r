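#' Run the full metrics + census pipeline and write a report bundle
#'
#' Executes the assembly summary, the translated search (or imports a
#' precomputed hit table), OHR metrics, the optional multi-reference hit
#' partition, and the gene-family census, writing tab-separated outputs
#' plus a JSON run manifest to `out_dir`.  Any stage failure aborts with
#' a stage-named error.
#'
#' Outputs: `assembly_summary.tsv`, `length_histogram.tsv`,
#' `ohr_table.tsv`, `ohr_summary.tsv`, `hit_table.tsv`,
#' `family_counts.tsv` (numeric `gene_count` plus a `display` column
#' with the conventional `>=` rendering), `cluster_ledger.tsv`,
#' `partition_table.tsv` (when several proteomes are given) and
#' `manifest.json`.
#'
#' @param transcripts_fasta Path to the assembly FASTA.
#' @param proteome_fasta Path to the reference proteome FASTA (may be a
#'   named character vector of several proteomes; the first is used for
#'   the census, all are used for the hit partition).
#' @param annotation_tsv Path to the annotation table (`protein_id`,
#'   `family`, `clan`, `description`; tab-separated with header).
#' @param out_dir Output directory (created if needed).
#' @param hit_table Optional path to a precomputed 12/13-column hit
#'   table; when given, the built-in aligner is skipped for the census
#'   proteome.
#' @param e_max,contig_min,census_min,isoform_identity,isoform_coverage,min_overlap
#'   Pipeline thresholds (defaults: 1e-3, 150, 250, 0.95, 0.80, 15).
#' @param keyword_sets Superfamily keyword sets for the census.
#' @param seed Seed echoed into the manifest (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with the in-memory results (`summary`,
#'   `hits`, `tops`, `ohr`, `ohr_summary`, `census`, `partition`).
#' @export
run_pipeline <- function(transcripts_fasta, proteome_fasta, annotation_tsv,
                         out_dir, hit_table = NULL, e_max = 1e-3,
                         contig_min = 150L, census_min = 250L,
                         isoform_identity = 0.95, isoform_coverage = 0.80,
                         min_overlap = 15L,
                         keyword_sets = list(
                           P450 = c("cytochrome p450"),
                           cathepsin = c("cathepsin", "cysteine peptidase")
                         ),
                         seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name)
    readr::write_tsv(x, file.path(out_dir, name))

  transcripts <- stage("read_transcripts",
                       read_fasta(transcripts_fasta, "nt"))
  transcripts <- stage("contig_filter",
                       filter_contigs(transcripts, contig_min))
  proteomes <- stage("read_proteome", {
    paths <- proteome_fasta
    if (is.null(names(paths)))
      names(paths) <- paste0("ref", seq_along(paths))
    lapply(paths, read_fasta, molecule = "aa")
  })
  annotations <- stage("read_annotations",
                       readr::read_tsv(annotation_tsv,
                                       show_col_types = FALSE))

  summary <- stage("assembly_summary", assembly_summary(transcripts))
  tsv(summary$stats, "assembly_summary.tsv")
  tsv(summary$histogram, "length_histogram.tsv")

  hits <- stage("translated_search", {
    if (is.null(hit_table))
      translated_search(transcripts, proteomes[[1]], e_max = e_max)
    else read_hit_table(hit_table)
  })
  stage("write_hits", write_hit_table(hits, file.path(out_dir,
                                                      "hit_table.tsv")))
  tops <- top_hits(hits)

  ohr_tbl <- stage("ohr", ohr_table(tops, proteomes[[1]]))
  tsv(ohr_tbl, "ohr_table.tsv")
  tsv(stage("ohr_summary", ohr_summary(ohr_tbl)), "ohr_summary.tsv")

  partition <- NULL
  if (length(proteomes) > 1) {
    partition <- stage("hit_partition", {
      sets <- lapply(proteomes, function(p)
        top_hits(translated_search(transcripts, p, e_max = e_max)))
      hit_partition(sets)
    })
    part_out <- partition
    part_out$universe <- attr(partition, "universe")
    tsv(part_out, "partition_table.tsv")
  }

  census <- stage("family_census", family_census(
    transcripts, proteomes[[1]], annotations, hits = hits,
    keyword_sets = keyword_sets, e_max = e_max,
    census_min_len = census_min, isoform_identity = isoform_identity,
    isoform_coverage = isoform_coverage, min_overlap = min_overlap))
  tsv(census$families, "family_counts.tsv")
  tsv(census$ledger, "cluster_ledger.tsv")

  manifest <- list(
    seed = seed,
    inputs = list(transcripts = transcripts_fasta,
                  proteomes = unname(proteome_fasta),
                  annotations = annotation_tsv,
                  hit_table = hit_table),
    thresholds = list(e_max = e_max, contig_min = contig_min,
                      census_min = census_min,
                      isoform_identity = isoform_identity,
                      isoform_coverage = isoform_coverage,
                      min_overlap = min_overlap),
    keyword_sets = keyword_sets,
    n_contigs = nrow(transcripts), n_hits = nrow(hits),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("famexpand"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summary = summary, hits = hits, tops = tops,
                 ohr = ohr_tbl, ohr_summary = ohr_summary(ohr_tbl),
                 census = census, partition = partition))
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `metrics`, `census` and `recover`
#' subcommands used by the installed `exec/famexpand` script.  `recover`
#' runs a census on simulated data and prints the exact-match fraction
#' as its final line.
#'
#' @param args Character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status (0 on success), invisibly.
#' @export
famexpand_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: famexpand <simulate|metrics|census|recover> [options]",
    "  common options:",
    "    --out DIR            output directory (default famexpand_out)",
    "    --seed INT           generator seed (default 1)",
    "  metrics/census options:",
    "    --transcripts FASTA  assembly contigs",
    "    --proteome FASTA     reference proteome",
    "    --annotations TSV    protein annotation table",
    "    --hits TSV           precomputed hit table (census only)",
    "    --min-overlap INT    fragment-merge overlap tolerance (aa)",
    sep = "\n")
  if (length(args) < 1) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_options(args[-1])
  out_dir <- opts$out %||% "famexpand_out"
  seed <- as.integer(opts$seed %||% "1")

  if (cmd == "simulate") {
    sim <- simulate_transcriptome(generator_config(seed = seed))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(sim$transcripts, file.path(out_dir, "transcripts.fa"))
    write_fasta(sim$proteome, file.path(out_dir, "proteome.fa"))
    readr::write_tsv(sim$annotations, file.path(out_dir, "annotations.tsv"))
    readr::write_tsv(sim$truth$transcripts, file.path(out_dir, "truth.tsv"))
    readr::write_tsv(sim$truth$families,
                     file.path(out_dir, "truth_families.tsv"))
    jsonlite::write_json(unclass(sim$config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    message("simulated ", nrow(sim$transcripts), " transcripts into ",
            out_dir)
    return(invisible(0L))
  }

  if (cmd %in% c("metrics", "census")) {
    for (req in c("transcripts", "proteome", "annotations"))
      if (is.null(opts[[req]]))
        stop("missing required option --", req, call. = FALSE)
    res <- run_pipeline(
      transcripts_fasta = opts$transcripts,
      proteome_fasta = opts$proteome,
      annotation_tsv = opts$annotations,
      out_dir = out_dir, hit_table = opts$hits,
      min_overlap = as.integer(opts[["min-overlap"]] %||% "15"),
      seed = seed)
    if (cmd == "census") print(res$census)
    return(invisible(0L))
  }

  if (cmd == "recover") {
    sim <- simulate_transcriptome(generator_config(seed = seed))
    cen <- family_census(sim$transcripts, sim$proteome, sim$annotations,
                         min_overlap =
                           as.integer(opts[["min-overlap"]] %||% "15"))
    rec <- score_recovery(cen, sim$truth)
    cat(sprintf("%.3f\n", rec$exact_fraction))
    return(invisible(0L))
  }

  stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "'", call. = FALSE)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("option --", key, " needs a value", call. = FALSE)
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  known <- c("out", "seed", "transcripts", "proteome", "annotations",
             "hits", "min-overlap")
  unknown <- setdiff(names(opts), known)
  if (length(unknown) > 0)
    stop("unknown option(s): ", paste0("--", unknown, collapse = ", "),
         call. = FALSE)
  opts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
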