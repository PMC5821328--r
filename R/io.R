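#' Read a FASTQ file into a read table
#'
#' Reads are represented throughout the package as a plain data frame with
#' columns \code{id}, \code{seq}, \code{qual} (Sanger Phred+33 string) and
#' \code{library}; this keeps filtering operations vectorised and
#' transparent. The library label is taken from the \code{library} argument
#' (one FASTQ per library).
#'
#' @param path FASTQ file (Sanger Phred+33).
#' @param library library label attached to every read.
#' @return data.frame with columns id, seq, qual, library.
#' @export
read_fastq <- function(path, library = NA_character_) {
  # Biostrings warns about dropped metadata columns on FASTQ input;
  # nothing we use is affected
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(
    id = sub("\\s.*$", "", names(x)),
    seq = as.character(x),
    qual = as.character(Biostrings::quality(x)),
    library = library,
    stringsAsFactors = FALSE
  )
}

#' Write a read table to FASTQ (Sanger Phred+33)
#'
#' @param reads read table (see [read_fastq()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences (full deflines as names).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, max(1L, nchar(s)), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Phred string <-> integer scores
qual_to_phred <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

phred_to_qual <- function(scores) {
  vapply(scores, function(s) rawToChar(as.raw(s + 33L)), character(1))
}

#' Write a GFF3 annotation file
#'
#' Internal coordinates are 0-based half-open; GFF3 output is 1-based
#' inclusive as the format requires.
#'
#' @param features data.frame with columns seqid, source, type, start, end
#'   (0-based half-open), strand, attributes (character).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    lines <- paste(features$seqid, features$source, features$type,
                   features$start + 1L, features$end, ".",
                   features$strand, ".", features$attributes, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
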