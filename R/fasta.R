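# FASTA and tabular I/O, via Biostrings for the heavy lifting.

#' Read a FASTA file
#'
#' Accepts wrapped or unwrapped records; sequences are uppercased on read.
#' Record ids are the header text up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return data.frame with columns `id` and `sequence` (possibly 0 rows).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(lines[nonblank[1]], ">")) {
    stop(sprintf("malformed FASTA: sequence before first header at line %d",
                 nonblank[1]), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in ", path, call. = FALSE)
  }
  data.frame(id = ids, sequence = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write records to FASTA
#'
#' Sequences are wrapped at 60 columns. Writing then reading back
#' reproduces ids and sequences exactly.
#'
#' @param records data.frame with columns `id`, `sequence` (or a named
#'   character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read a contig metadata table
#'
#' Three-column tab-separated table mapping contig id to species and
#' taxonomic group.
#'
#' @param path Path to a TSV with columns `contig_id`, `species`, `taxon`.
#' @return data.frame with those columns.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "species", "taxon")
  if (!all(need %in% names(md))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  md[, need]
}

# write a data.frame as TSV with header, no quoting
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
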