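# Pipeline configuration and the end-to-end mining run.

#' Pipeline configuration
#'
#' Collects the tunable constants of the mining pipeline: the candidate
#' motif, the E-value significance threshold, the minimum aligned overlap
#' with the mature dyn A 1-17 interval, alignment and Karlin-Altschul
#' parameters, the query's dyn A interval, the radioligand conditions and
#' the BRET analysis window. Unknown keys are rejected.
#'
#' @param motif Candidate selection motif.
#' @param evalue_threshold Significance cutoff for hits.
#' @param min_dynA_overlap Minimum aligned query residues inside the dyn A
#'   interval.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @param lambda,K Karlin-Altschul parameters.
#' @param dynA_interval 1-based inclusive dyn A 1-17 interval of the query
#'   precursor (default: the human preprodynorphin annotation, residues
#'   207-223).
#' @param radioligand_conc,radioligand_Kd Binding-assay constants, nM.
#' @param bret_window BRET quantification window, seconds.
#' @param seed Integer seed recorded with each run.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(motif = "YGGF", evalue_threshold = 1e-6,
                            min_dynA_overlap = 8L, matrix = "BLOSUM62",
                            gap_open = 11, gap_extend = 1,
                            lambda = 0.267, K = 0.041,
                            dynA_interval = c(207L, 223L),
                            radioligand_conc = 1, radioligand_Kd = 0.87,
                            bret_window = c(311, 2411), seed = 1L) {
  stopifnot(evalue_threshold >= 0, min_dynA_overlap >= 1,
            gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0,
            length(dynA_interval) == 2L, length(bret_window) == 2L,
            radioligand_conc > 0, radioligand_Kd > 0)
  structure(list(
    motif = motif, evalue_threshold = evalue_threshold,
    min_dynA_overlap = as.integer(min_dynA_overlap), matrix = matrix,
    gap_open = gap_open, gap_extend = gap_extend, lambda = lambda, K = K,
    dynA_interval = as.integer(dynA_interval),
    radioligand_conc = radioligand_conc, radioligand_Kd = radioligand_Kd,
    bret_window = bret_window, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Run the mining pipeline end to end
#'
#' Reads contigs, metadata and the query precursor; selects motif-bearing
#' candidate frames; searches them against the query; deduplicates hits;
#' builds the taxonomic profile and the overall sequence-logo matrix; and
#' writes all result tables plus a machine-readable run summary. The run is
#' deterministic given its inputs.
#'
#' @param contigs_fasta Path to the contig FASTA.
#' @param metadata_tsv Path to the contig metadata TSV (contig_id, species,
#'   taxon).
#' @param query_fasta Path to the query precursor FASTA (first record
#'   used); the dyn A interval comes from `config$dynA_interval`.
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `hits`, `dedup`, `profile`, `logo`,
#'   `counts` and `paths`.
#' @export
run_pipeline <- function(contigs_fasta, metadata_tsv, query_fasta, out_dir,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  contigs <- read_fasta(contigs_fasta)
  md <- read_metadata(metadata_tsv)
  qrec <- read_fasta(query_fasta)
  if (nrow(qrec) == 0L) stop("query stage: empty query FASTA", call. = FALSE)
  query <- query_precursor(qrec$id[1], qrec$sequence[1],
                           config$dynA_interval)
  if (nrow(contigs) > 0L) {
    miss <- setdiff(contigs$id, md$contig_id)
    if (length(miss) > 0L)
      stop("metadata stage: contig without metadata: ", miss[1],
           call. = FALSE)
    idx <- match(contigs$id, md$contig_id)
    contigs$species <- md$species[idx]
    contigs$taxon <- md$taxon[idx]
  } else {
    contigs$species <- character(0)
    contigs$taxon <- character(0)
  }

  sel <- select_candidates(contigs, motif = config$motif)
  hits <- search_hits(query, sel,
                      evalue_threshold = config$evalue_threshold,
                      min_overlap = config$min_dynA_overlap,
                      matrix = config$matrix, gap_open = config$gap_open,
                      gap_extend = config$gap_extend,
                      lambda = config$lambda, K = config$K)
  dd <- dedup_hits(hits)
  taxonomy <- unique(md[, c("species", "taxon")])
  tr_counts <- if (nrow(taxonomy) > 0L) {
    as.data.frame(table(taxon = taxonomy$taxon),
                  responseName = "n_transcriptomes",
                  stringsAsFactors = FALSE)
  } else {
    data.frame(taxon = character(0), n_transcriptomes = integer(0))
  }
  profile <- taxonomic_profile(dd$pairs, taxonomy, tr_counts)
  logo <- if (dd$n_unique > 0L) logo_matrix(dd$pairs$mature_sequence) else
    NULL

  counts <- list(n_contigs = nrow(contigs),
                 n_motif_selected = sel$n_selected,
                 n_candidate_frames = nrow(sel$candidates),
                 n_hits = nrow(hits),
                 n_unique_hits = dd$n_unique)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(hits = file.path(out_dir, "hits.tsv"),
                unique_hits = file.path(out_dir, "unique_hits.tsv"),
                taxon_profile = file.path(out_dir, "taxon_profile.tsv"),
                logo = file.path(out_dir, "logo.tsv"),
                summary = file.path(out_dir, "run_summary.json"),
                log = file.path(out_dir, "run.log"))
  write_tsv(hits, paths$hits)
  write_tsv(dd$unique_hits, paths$unique_hits)
  write_tsv(profile$per_taxon, paths$taxon_profile)
  if (!is.null(logo)) {
    logo_df <- data.frame(column = seq_along(logo$information),
                          information = logo$information,
                          n_nongap = logo$n_nongap,
                          logo$frequencies, check.names = FALSE)
    write_tsv(logo_df, paths$logo)
  } else {
    paths$logo <- NULL
  }

  cfg_plain <- unclass(config)
  summary <- list(
    config = cfg_plain,
    config_hash = unname(tools::md5sum(
      tempfile_with(paste(deparse(cfg_plain), collapse = "\n")))),
    inputs = as.list(tools::md5sum(c(contigs_fasta, metadata_tsv,
                                     query_fasta))),
    counts = counts,
    totals = profile$totals)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_lines <- c(
    sprintf("query: %s (%d aa), dyn A interval %d-%d", query$id,
            nchar(query$sequence), query$dynA_interval[1],
            query$dynA_interval[2]),
    sprintf("contigs in: %d", counts$n_contigs),
    sprintf("motif-selected contigs: %d (%d candidate frames)",
            counts$n_motif_selected, counts$n_candidate_frames),
    sprintf("significant hits (E <= %g): %d", config$evalue_threshold,
            counts$n_hits),
    sprintf("unique hits: %d", counts$n_unique_hits))
  writeLines(log_lines, paths$log)

  invisible(list(query = query, hits = hits, dedup = dd, profile = profile,
                 logo = logo, counts = counts, paths = paths))
}

# write a string to a temp file and return the path (for hashing)
tempfile_with <- function(text) {
  p <- tempfile()
  writeLines(text, p)
  p
}
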