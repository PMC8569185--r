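# Independent oracles used across the suite.

# Brute-force local alignment score by enumeration over monotone matchings:
# an alignment is a sequence of matched residue pairs; a jump of (di, dj)
# between consecutive pairs pays one affine gap per sequence with a
# positive offset (cost open + ext * d each). This quartic recurrence is
# independent of the three-state affine dynamic program it checks.
brute_force_local_score <- function(query, subject, matrix = "BLOSUM62",
                                    gap_open = 11, gap_extend = 1) {
  mat <- substitution_matrix(matrix)
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  m <- length(qc); n <- length(sc)
  gapcost <- function(d) ifelse(d > 0, gap_open + gap_extend * d, 0)
  g <- matrix(-Inf, m, n)
  for (i in m:1) {
    for (j in n:1) {
      ext <- 0
      if (i < m && j < n) {
        for (i2 in (i + 1):m) {
          for (j2 in (j + 1):n) {
            cand <- g[i2, j2] - gapcost(i2 - i - 1) - gapcost(j2 - j - 1)
            if (cand > ext) ext <- cand
          }
        }
      }
      g[i, j] <- mat[qc[i], sc[j]] + ext
    }
  }
  max(0, max(g))
}

# random amino-acid string over the 20 canonical residues
random_protein <- function(n) {
  paste(sample(rownames(substitution_matrix())[1:20], n, replace = TRUE),
        collapse = "")
}

# reverse complement of a nucleotide string
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
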