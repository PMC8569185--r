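# Homology search against a precursor query and downstream sequence
# analysis: significance filtering, mature-peptide extraction, unique-hit
# deduplication, taxonomic profiling and sequence-logo matrices.

#' Construct a query precursor object
#'
#' @param id Record id.
#' @param sequence Precursor amino-acid sequence.
#' @param dynA_interval 1-based inclusive interval of the mature dynorphin
#'   A 1-17 segment within the precursor; must be 17 residues long and
#'   begin with the YGGF motif.
#' @return List of class `"query_precursor"`.
#' @export
query_precursor <- function(id, sequence, dynA_interval) {
  stopifnot(length(dynA_interval) == 2L)
  dynA_interval <- as.integer(dynA_interval)
  if (diff(dynA_interval) + 1L != 17L)
    stop("dynA_interval must span exactly 17 residues", call. = FALSE)
  if (dynA_interval[1] < 1L || dynA_interval[2] > nchar(sequence))
    stop("dynA_interval outside the precursor", call. = FALSE)
  core <- substr(sequence, dynA_interval[1], dynA_interval[1] + 3L)
  if (core != "YGGF")
    stop("dynA_interval must begin with the YGGF motif, found: ", core,
         call. = FALSE)
  structure(list(id = id, sequence = sequence,
                 dynA_interval = dynA_interval),
            class = "query_precursor")
}

#' Search candidate frame translations against a precursor query
#'
#' Runs one optimal local alignment per candidate frame translation
#' ([align_local()]), scores significance with the Karlin-Altschul E-value
#' against the whole candidate database (n = total candidate residues), and
#' retains hits with E at or below the threshold whose aligned query span
#' overlaps the mature dyn A 1-17 interval by at least `min_overlap`
#' residues. Hits are sorted by ascending E-value.
#'
#' @param query A [query_precursor()].
#' @param candidates Candidate set from [select_candidates()] (the list or
#'   its `candidates` data.frame).
#' @param evalue_threshold Significance cutoff (default 1e-6).
#' @param min_overlap Minimum aligned query residues inside the dyn A
#'   interval (default 8).
#' @param matrix,gap_open,gap_extend Alignment parameters, see
#'   [align_local()].
#' @param lambda,K Karlin-Altschul parameters, see [evalue()].
#' @return data.frame with one row per retained hit: contig_id, species,
#'   taxon, strand, frame_offset, score, bitscore, evalue, query_start,
#'   query_end, subject_start, subject_end, mature_sequence.
#' @export
search_hits <- function(query, candidates, evalue_threshold = 1e-6,
                        min_overlap = 8L, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1,
                        lambda = 0.267, K = 0.041) {
  stopifnot(inherits(query, "query_precursor"))
  if (is.list(candidates) && !is.data.frame(candidates) &&
      !is.null(candidates$candidates)) {
    candidates <- candidates$candidates
  }
  empty <- data.frame(
    contig_id = character(0), species = character(0), taxon = character(0),
    strand = character(0), frame_offset = integer(0), score = numeric(0),
    bitscore = numeric(0), evalue = numeric(0), query_start = integer(0),
    query_end = integer(0), subject_start = integer(0),
    subject_end = integer(0), mature_sequence = character(0),
    stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) {
    warning("empty candidate set: no hits")
    return(empty)
  }
  m <- nchar(query$sequence)
  n_db <- sum(nchar(candidates$protein))
  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    aln <- align_local(query$sequence, candidates$protein[i],
                       matrix = matrix, gap_open = gap_open,
                       gap_extend = gap_extend)
    if (aln$score <= 0) next
    ev <- evalue(aln$score, m = m, n = n_db, lambda = lambda, K = K)
    if (ev$evalue > evalue_threshold) next
    ov <- .interval_overlap(aln$query_interval, query$dynA_interval)
    if (ov < min_overlap) next
    rows[[i]] <- data.frame(
      contig_id = candidates$contig_id[i], species = candidates$species[i],
      taxon = candidates$taxon[i], strand = candidates$strand[i],
      frame_offset = candidates$frame_offset[i], score = aln$score,
      bitscore = ev$bitscore, evalue = ev$evalue,
      query_start = aln$query_interval[1], query_end = aln$query_interval[2],
      subject_start = aln$subject_interval[1],
      subject_end = aln$subject_interval[2],
      mature_sequence = extract_mature(aln, query),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(hits)) return(empty)
  hits <- hits[order(hits$evalue, hits$contig_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

.interval_overlap <- function(a, b) {
  max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
}

#' Extract the mature dyn A 1-17-aligned peptide from an alignment
#'
#' Maps the gapped alignment columns onto the query's dyn A interval and
#' returns exactly one character per interval position: the subject residue
#' aligned to that query column, '-' where the subject has a gap or the
#' alignment does not reach the column. Subject insertions relative to the
#' query are dropped.
#'
#' @param alignment An `"sw_alignment"` from [align_local()].
#' @param query A [query_precursor()].
#' @return A 17-character mature peptide string (gap characters allowed).
#' @export
extract_mature <- function(alignment, query) {
  iv <- query$dynA_interval
  if (is.na(alignment$query_interval[1]) ||
      .interval_overlap(alignment$query_interval, iv) == 0L)
    stop("alignment does not overlap the dyn A interval", call. = FALSE)
  width <- iv[2] - iv[1] + 1L
  out <- rep("-", width)
  qchars <- strsplit(alignment$aligned_query, "")[[1]]
  schars <- strsplit(alignment$aligned_subject, "")[[1]]
  qpos <- alignment$query_interval[1]
  for (k in seq_along(qchars)) {
    if (qchars[k] == "-") next  # subject insertion: no query column
    if (qpos >= iv[1] && qpos <= iv[2]) out[qpos - iv[1] + 1L] <- schars[k]
    qpos <- qpos + 1L
  }
  paste(out, collapse = "")
}

#' Deduplicate hits into unique mature-peptide records
#'
#' A unique hit is a novel mature sequence, or an already-seen sequence
#' observed in a new species: the unique-hit count is the number of
#' distinct (mature_sequence, species) pairs. Records are grouped by mature
#' sequence, aggregating the species set and per-taxon species counts, in
#' deterministic order (sequence, then species).
#'
#' @param hits data.frame with columns `mature_sequence`, `species`,
#'   `taxon`, `contig_id` (as produced by [search_hits()]).
#' @return List with `unique_hits` (one row per mature sequence: columns
#'   mature_sequence, n_species, species, taxon_counts, first_seen),
#'   `pairs` (one row per (sequence, species) pair, same columns as the
#'   input) and `n_unique` (the unique-hit count).
#' @export
dedup_hits <- function(hits) {
  need <- c("mature_sequence", "species", "taxon", "contig_id")
  stopifnot(is.data.frame(hits), all(need %in% names(hits)))
  if (nrow(hits) > 0L && anyNA(hits$species)) {
    bad <- hits$contig_id[which(is.na(hits$species))[1]]
    stop("missing species metadata for contig: ", bad, call. = FALSE)
  }
  hits <- hits[order(hits$mature_sequence, hits$species), , drop = FALSE]
  pairs <- hits[!duplicated(hits[, c("mature_sequence", "species")]),
                need, drop = FALSE]
  rownames(pairs) <- NULL
  groups <- split(pairs, pairs$mature_sequence)
  uh <- do.call(rbind, lapply(groups, function(g) {
    tc <- table(g$taxon)
    data.frame(
      mature_sequence = g$mature_sequence[1],
      n_species = nrow(g),
      species = paste(sort(g$species), collapse = ";"),
      taxon_counts = paste(sprintf("%s:%d", names(tc), as.integer(tc)),
                           collapse = ";"),
      first_seen = g$contig_id[1],
      stringsAsFactors = FALSE)
  }))
  if (is.null(uh)) {
    uh <- data.frame(mature_sequence = character(0), n_species = integer(0),
                     species = character(0), taxon_counts = character(0),
                     first_seen = character(0), stringsAsFactors = FALSE)
  }
  rownames(uh) <- NULL
  list(unique_hits = uh, pairs = pairs, n_unique = nrow(pairs))
}

#' Taxonomic profile of unique hits
#'
#' Clusters unique hits by taxonomic group, reporting per taxon the number
#' of unique hits, the number of transcriptome datasets available, and the
#' number of species with at least one hit, plus overall fractions.
#'
#' @param pairs Unique-hit pairs (the `pairs` element of [dedup_hits()]):
#'   data.frame with columns `mature_sequence`, `species`.
#' @param taxonomy data.frame mapping `species` to `taxon` (one row per
#'   species).
#' @param transcriptome_counts data.frame with columns `taxon`,
#'   `n_transcriptomes`.
#' @return List with `per_taxon` (data.frame: taxon, n_unique_hits,
#'   n_transcriptomes, n_species_with_hits) and `totals` (list with the
#'   summed counts plus `species_with_hits_fraction`, over species in the
#'   taxonomy, and `taxa_with_hits_fraction`, over taxa with at least one
#'   transcriptome).
#' @export
taxonomic_profile <- function(pairs, taxonomy, transcriptome_counts) {
  stopifnot(is.data.frame(taxonomy),
            all(c("species", "taxon") %in% names(taxonomy)))
  if (anyDuplicated(taxonomy$species))
    stop("each species must map to exactly one taxon", call. = FALSE)
  unmapped <- setdiff(unique(pairs$species), taxonomy$species)
  if (length(unmapped) > 0L)
    stop("species not in taxonomy: ", unmapped[1], call. = FALSE)
  taxa <- sort(unique(c(taxonomy$taxon, transcriptome_counts$taxon)))
  ptax <- taxonomy$taxon[match(pairs$species, taxonomy$species)]
  nt <- transcriptome_counts$n_transcriptomes[
    match(taxa, transcriptome_counts$taxon)]
  nt[is.na(nt)] <- 0L
  per_taxon <- data.frame(
    taxon = taxa,
    n_unique_hits = vapply(taxa, function(t) sum(ptax == t), integer(1)),
    n_transcriptomes = as.integer(nt),
    n_species_with_hits = vapply(
      taxa, function(t) length(unique(pairs$species[ptax == t])), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  n_species_hits <- length(unique(pairs$species))
  with_tr <- per_taxon$n_transcriptomes > 0
  totals <- list(
    n_unique_hits = sum(per_taxon$n_unique_hits),
    n_species_with_hits = n_species_hits,
    n_species_total = nrow(taxonomy),
    species_with_hits_fraction = n_species_hits / max(1L, nrow(taxonomy)),
    taxa_with_hits_fraction =
      if (any(with_tr)) mean(per_taxon$n_unique_hits[with_tr] > 0) else 0)
  list(per_taxon = per_taxon, totals = totals)
}

#' Sequence-logo matrix: per-column frequencies and information content
#'
#' Column frequencies are computed over non-gap residues. Information
#' content per column is R = log2(20) - (H + e_n) bits, with H the Shannon
#' entropy of the column and, when `small_sample_correction` is set, the
#' correction e_n = 19 / (2 ln(2) n) for n non-gap residues; R is clamped
#' at 0.
#'
#' @param peptides Character vector of equal-length aligned peptide strings
#'   (typically 17-column mature peptides; '-' marks a gap).
#' @param small_sample_correction Apply the small-sample entropy
#'   correction? Default FALSE.
#' @return List of class `"logo_matrix"`: `frequencies` (columns x 20
#'   residues), `information` (bits per column), `n_sequences`, `n_nongap`.
#' @export
logo_matrix <- function(peptides, small_sample_correction = FALSE) {
  if (length(peptides) < 1L) stop("need at least one sequence", call. = FALSE)
  widths <- nchar(peptides)
  if (length(unique(widths)) != 1L)
    stop("ragged input: all sequences must have the same length",
         call. = FALSE)
  width <- widths[1]
  residues <- sort(names(.RESIDUE_MASS))
  chars <- do.call(rbind, strsplit(peptides, ""))
  freq <- matrix(0, nrow = width, ncol = 20L,
                 dimnames = list(NULL, residues))
  info <- numeric(width)
  n_nongap <- integer(width)
  for (j in seq_len(width)) {
    col <- chars[, j]
    col <- col[col %in% residues]
    n <- length(col)
    n_nongap[j] <- n
    if (n == 0L) next
    tab <- table(factor(col, levels = residues))
    p <- as.numeric(tab) / n
    freq[j, ] <- p
    h <- -sum(p[p > 0] * log2(p[p > 0]))
    en <- if (small_sample_correction) 19 / (2 * log(2) * n) else 0
    info[j] <- max(0, log2(20) - (h + en))
  }
  structure(list(frequencies = freq, information = info,
                 n_sequences = length(peptides), n_nongap = n_nongap),
            class = "logo_matrix")
}
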