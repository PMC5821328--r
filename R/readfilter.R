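#' Median-quality and length filtering of reads
#'
#' A read is retained iff its median Phred score is >= \code{min_median}
#' and its length is >= \code{min_length}. The median of an even-length
#' quality vector is the arithmetic mean of the two central values.
#' Empty-sequence reads are rejected and counted separately.
#'
#' @param reads read table (id, seq, qual, library).
#' @param min_median minimum median Phred quality.
#' @param min_length minimum read length (bases).
#' @return list: retained (read table), rejected (read table), tally
#'   (named integer: input, retained, low_median, short, empty; a short
#'   low-quality read counts under both rules, so rule counts can exceed
#'   the number rejected).
#' @export
quality_filter <- function(reads, min_median = 20, min_length = 25) {
  len <- nchar(reads$seq)
  med <- vapply(qual_to_phred(reads$qual), function(q)
    if (length(q)) median(q) else -Inf, numeric(1))
  empty <- len == 0
  short <- !empty & len < min_length
  low <- !empty & med < min_median
  keep <- !empty & !short & !low
  list(
    retained = reads[keep, , drop = FALSE],
    rejected = reads[!keep, , drop = FALSE],
    tally = c(input = nrow(reads), retained = sum(keep),
              low_median = sum(low), short = sum(short),
              empty = sum(empty))
  )
}

#' Host subtraction by shared k-mers
#'
#' A read is host-matched iff it shares at least \code{min_kmers} exact
#' k-mers with the host reference, counting both strands (the host k-mer
#' set contains forward and reverse-complement k-mers, so
#' classification is strand-symmetric). The published workflow used a
#' short-read aligner for this step; shared-k-mer classification gives
#' the same downstream partition at desk scale with tunable sensitivity.
#' K-mers containing N never match. Reads shorter than k are unmatched by
#' definition and counted in the tally.
#'
#' @param reads read table.
#' @param host host reference sequence (single string or the first entry
#'   of a named vector from [read_fasta()]).
#' @param k k-mer size.
#' @param min_kmers minimum shared k-mer count (threshold T).
#' @return list: matched, unmatched (read tables), tally (named integer:
#'   input, matched, unmatched, too_short).
#' @export
subtract_host <- function(reads, host, k = 21, min_kmers = 5) {
  if (length(host) > 1 || !is.null(names(host))) host <- host[[1]]
  counts <- cpp_host_kmer_counts(reads$seq, host, as.integer(k))
  too_short <- nchar(reads$seq) < k
  matched <- counts >= min_kmers & !too_short
  list(
    matched = reads[matched, , drop = FALSE],
    unmatched = reads[!matched, , drop = FALSE],
    tally = c(input = nrow(reads), matched = sum(matched),
              unmatched = sum(!matched), too_short = sum(too_short))
  )
}
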