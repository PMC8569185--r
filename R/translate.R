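# Six-frame conceptual translation and opioid-motif candidate selection.
#
# Frames are labeled (strand, offset) with the offset counted 0-based on the
# strand being read. Translation runs straight through stop codons ('*') —
# no ORF calling — and codons containing N translate to 'X'. Trailing 1-2
# nucleotides that do not fill a codon are dropped.

.check_contig_seq <- function(sequence, id = "<contig>") {
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    stop(sprintf("contig '%s' contains invalid nucleotide character '%s'",
                 id, substr(bad, 1, 1)), call. = FALSE)
  }
  invisible(TRUE)
}

# all six trimmed frame nucleotide strings for each input sequence;
# returns a 6 x n character matrix (rows: +0,+1,+2,-0,-1,-2)
.six_frame_nt <- function(sequences) {
  n <- length(sequences)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sequences)))
  out <- matrix("", nrow = 6L, ncol = n)
  for (o in 0:2) {
    for (s in 1:2) {
      src <- if (s == 1L) sequences else rc
      len <- nchar(src)
      width <- 3L * ((len - o) %/% 3L)
      width[width < 0L] <- 0L
      out[3L * (s - 1L) + o + 1L, ] <-
        ifelse(width > 0L, substring(src, o + 1L, o + width), "")
    }
  }
  out
}

# batch-translate frame nucleotide strings; strict translation for N-free
# frames (fast path), fuzzy-to-'X' for frames containing N
.translate_batch <- function(frames) {
  out <- character(length(frames))
  nonempty <- nchar(frames) > 0L
  hasN <- grepl("N", frames, fixed = TRUE)
  strict <- nonempty & !hasN
  if (any(strict)) {
    out[strict] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(frames[strict])))
  }
  if (any(nonempty & hasN)) {
    out[nonempty & hasN] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(frames[nonempty & hasN]),
      if.fuzzy.codon = "X"))
  }
  out
}

# six-frame proteins for a character vector of contig sequences:
# 6 x n character matrix (rows: strand +/-, offsets 0,1,2)
.six_frame_proteins <- function(sequences) {
  nt <- .six_frame_nt(sequences)
  matrix(.translate_batch(nt), nrow = 6L)
}

#' Translate a contig in all six reading frames
#'
#' Conceptual translation: all three offsets on the forward strand and on
#' the reverse complement, through stop codons, with no start-codon or ORF
#' requirement. Ambiguous (N-containing) codons yield 'X'; stops are '*'.
#'
#' @param sequence Nucleotide string over A,C,G,T,N (uppercase).
#' @param id Contig id used in error messages.
#' @return data.frame with 6 rows and columns `strand` ("+"/"-"),
#'   `frame_offset` (0,1,2) and `protein`.
#' @export
#' @examples
#' translate_six_frames("TATGGTGGTTTT")
translate_six_frames <- function(sequence, id = "<contig>") {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 3L)
    stop("contig sequence must be a single string of length >= 3", call. = FALSE)
  .check_contig_seq(sequence, id)
  data.frame(
    strand = rep(c("+", "-"), each = 3L),
    frame_offset = rep(0:2, 2L),
    protein = as.vector(.six_frame_proteins(sequence)),
    stringsAsFactors = FALSE
  )
}

#' Find all (possibly overlapping) motif occurrences in a protein
#'
#' Exact substring scan, left to right; 'X' never matches.
#'
#' @param protein Amino-acid string (may contain '*' and 'X').
#' @param motif Motif string over canonical residues (default the opioid
#'   N-terminal tetrapeptide "YGGF").
#' @return Integer vector of 0-based start positions (possibly empty).
#' @export
#' @examples
#' scan_motif("YGGFYGGF")
scan_motif <- function(protein, motif = "YGGF") {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L ||
      grepl("[^ACDEFGHIKLMNPQRSTVWY]", motif)) {
    stop("motif must be a non-empty string of canonical residues",
         call. = FALSE)
  }
  if (nchar(protein) < nchar(motif)) return(integer(0))
  # lookahead regex yields overlapping matches
  m <- gregexpr(paste0("(?=", motif, ")"), protein, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Select motif-bearing candidate frame translations from a contig set
#'
#' A contig is selected iff at least one of its six frame translations
#' contains at least one motif occurrence; the result lists every
#' motif-bearing frame (the pre-alignment filter of the mining pipeline).
#'
#' @param contigs data.frame with columns `id`, `sequence` and optionally
#'   `species`, `taxon`.
#' @param motif Motif to scan for; see [scan_motif()].
#' @return List with elements `candidates` (data.frame: contig_id, species,
#'   taxon, strand, frame_offset, protein, motif_positions as a
#'   comma-separated 0-based list), `n_selected` (selected contig count) and
#'   `n_total`.
#' @export
select_candidates <- function(contigs, motif = "YGGF") {
  stopifnot(is.data.frame(contigs), all(c("id", "sequence") %in% names(contigs)))
  if (anyDuplicated(contigs$id))
    stop("contig ids must be unique", call. = FALSE)
  if (nrow(contigs) == 0L) {
    warning("empty contig set: no candidates selected")
    return(list(candidates = data.frame(
      contig_id = character(0), species = character(0), taxon = character(0),
      strand = character(0), frame_offset = integer(0), protein = character(0),
      motif_positions = character(0), stringsAsFactors = FALSE),
      n_selected = 0L, n_total = 0L))
  }
  bad <- grepl("[^ACGTN]", contigs$sequence)
  if (any(bad)) .check_contig_seq(contigs$sequence[which(bad)[1]],
                                  contigs$id[which(bad)[1]])
  species <- if ("species" %in% names(contigs)) contigs$species else
    rep(NA_character_, nrow(contigs))
  taxon <- if ("taxon" %in% names(contigs)) contigs$taxon else
    rep(NA_character_, nrow(contigs))
  prot <- .six_frame_proteins(contigs$sequence)   # 6 x n matrix
  has_motif <- matrix(grepl(motif, prot, fixed = TRUE), nrow = 6L)
  strand_lab <- rep(c("+", "-"), each = 3L)
  offset_lab <- rep(0:2, 2L)
  rows <- vector("list", nrow(contigs))
  for (i in which(colSums(has_motif) > 0L)) {
    keep <- which(has_motif[, i])
    pos <- vapply(prot[keep, i],
                  function(p) paste(scan_motif(p, motif), collapse = ","),
                  character(1), USE.NAMES = FALSE)
    rows[[i]] <- data.frame(
      contig_id = contigs$id[i], species = species[i], taxon = taxon[i],
      strand = strand_lab[keep], frame_offset = offset_lab[keep],
      protein = prot[keep, i], motif_positions = pos,
      stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(cand)) {
    cand <- data.frame(contig_id = character(0), species = character(0),
                       taxon = character(0), strand = character(0),
                       frame_offset = integer(0), protein = character(0),
                       motif_positions = character(0), stringsAsFactors = FALSE)
  }
  rownames(cand) <- NULL
  list(candidates = cand,
       n_selected = length(unique(cand$contig_id)),
       n_total = nrow(contigs))
}
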