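# Local protein alignment and Karlin-Altschul significance.
#
# The alignment stage of the pipeline is an exact affine-gap Smith-Waterman
# (no heuristic seeding) with protein-BLAST default parameters: BLOSUM62,
# gap open 11, gap extend 1, E = K*m*n*exp(-lambda*S) with the published
# gapped-BLOSUM62 pair lambda = 0.267, K = 0.041. No composition-based
# statistics or edge-effect length correction are applied.

.ALN_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                   "P","S","T","W","Y","V","X","*")

.matrix_cache <- new.env(parent = emptyenv())

#' Substitution matrix over the alignment alphabet
#'
#' Loads a named protein scoring matrix and restricts it to the 20 canonical
#' residues plus 'X' (ambiguous) and '*' (stop), which score -4 against
#' everything (including themselves) so that ambiguous or stop-containing
#' frame positions are penalized without aborting the search.
#'
#' @param name Matrix name, e.g. "BLOSUM62" (default), "BLOSUM45",
#'   "BLOSUM80", "PAM250".
#' @return Numeric matrix with row/column names over the 22-letter alphabet.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  if (!is.character(name) || length(name) != 1L)
    stop("matrix name must be a single string", call. = FALSE)
  if (!is.null(.matrix_cache[[name]])) return(.matrix_cache[[name]])
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(err) FALSE)
  if (!ok || is.null(e[[name]]))
    stop("unknown substitution matrix: ", name, call. = FALSE)
  base <- e[[name]]
  canon <- .ALN_ALPHABET[1:20]
  if (!all(canon %in% rownames(base)))
    stop("matrix ", name, " lacks canonical residues", call. = FALSE)
  m <- matrix(-4, nrow = 22L, ncol = 22L,
              dimnames = list(.ALN_ALPHABET, .ALN_ALPHABET))
  m[canon, canon] <- base[canon, canon]
  .matrix_cache[[name]] <- m
  m
}

.aa_index <- function(sequence) {
  idx <- match(strsplit(sequence, "")[[1]], .ALN_ALPHABET)
  if (anyNA(idx)) {
    bad <- strsplit(sequence, "")[[1]][which(is.na(idx))[1]]
    stop(sprintf("residue '%s' not in alignment alphabet", bad), call. = FALSE)
  }
  idx
}

#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman with affine gaps: a gap of length k costs
#' `gap_open + k * gap_extend`. The empty alignment (score 0) is allowed.
#' Ties are broken deterministically (smallest subject end coordinate, then
#' smallest query end; traceback prefers diagonal over gap-in-subject over
#' gap-in-query).
#'
#' @param query,subject Amino-acid strings (canonical residues plus 'X','*').
#' @param matrix Substitution matrix name, see [substitution_matrix()].
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return List of class `"sw_alignment"`: `score`, `query_interval` and
#'   `subject_interval` (1-based inclusive, NA for the empty alignment),
#'   `aligned_query`, `aligned_subject` (equal-length gapped strings, '-'
#'   for gaps).
#' @export
#' @examples
#' align_local("YGGF", "AAYGGFAA")$score  # 25
align_local <- function(query, subject, matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(subject))
    stop("query and subject must be non-empty", call. = FALSE)
  mat <- substitution_matrix(matrix)
  res <- sw_align_cpp(.aa_index(query), .aa_index(subject), mat,
                      as.numeric(gap_open), as.numeric(gap_extend))
  to_str <- function(idx) {
    chars <- ifelse(idx == 0L, "-", .ALN_ALPHABET[pmax(idx, 1L)])
    paste(chars, collapse = "")
  }
  structure(list(
    score = res$score,
    query_interval = c(res$query_start, res$query_end),
    subject_interval = c(res$subject_start, res$subject_end),
    aligned_query = to_str(res$aligned_query),
    aligned_subject = to_str(res$aligned_subject)
  ), class = "sw_alignment")
}

#' Karlin-Altschul expectation value and bit score
#'
#' For a local alignment of raw score S between a query of m residues and a
#' database of n residues, E = K * m * n * exp(-lambda * S). The bit score
#' is S' = (lambda * S - ln K) / ln 2, under which E = m * n * 2^(-S').
#'
#' @param score Raw alignment score (matrix units).
#' @param m Query length in residues.
#' @param n Database length in residues (total across searched sequences).
#' @param lambda,K Karlin-Altschul parameters; defaults are the published
#'   gapped-BLOSUM62 (open 11 / extend 1) values.
#' @return List with `evalue` and `bitscore`.
#' @export
#' @examples
#' evalue(97, m = 80, n = 20000)
evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  if (!is.numeric(m) || !is.numeric(n) || m < 1 || n < 1)
    stop("sequence lengths must be >= 1", call. = FALSE)
  if (lambda <= 0 || K <= 0)
    stop("lambda and K must be positive", call. = FALSE)
  bits <- (lambda * score - log(K)) / log(2)
  list(evalue = K * m * n * exp(-lambda * score), bitscore = bits)
}
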