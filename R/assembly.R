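#' Find candidate suffix-prefix overlaps between reads
#'
#' Gap-free overlaps in either relative orientation, detected from shared
#' exact k-mer seeds: every distinct diagonal shared by a read pair is
#' evaluated over its full overlap region and the best-scoring overlap of
#' each (pair, orientation) meeting the length and identity thresholds is
#' reported. Overlaps are scored by length x identity (i.e. the match
#' count). The gap-free model matches the substitution-only error model
#' of the synthetic reads; an overlap shorter than the seed k-mer or with
#' every seed destroyed by errors is not recoverable (documented
#' sensitivity limit of the seeding).
#'
#' @param reads read table (id, seq, ...) or named character vector.
#' @param min_overlap minimum overlap length L_min (nt).
#' @param min_identity minimum percent identity I_min over the overlap.
#' @param k seed k-mer size.
#' @return data.frame: read_i, read_j (ids, i < j in input order), orient
#'   ("F" read j forward, "R" read j reverse-complemented), offset (start
#'   of read j in read i coordinates), length, matches, identity, score.
#' @export
find_overlaps <- function(reads, min_overlap = 40, min_identity = 90,
                          k = 12) {
  if (is.data.frame(reads)) {
    ids <- reads$id; seqs <- reads$seq
  } else {
    ids <- names(reads); seqs <- unname(reads)
  }
  ov <- cpp_find_overlaps(seqs, as.integer(k), as.integer(min_overlap),
                          min_identity)
  data.frame(read_i = ids[ov$i], read_j = ids[ov$j],
             i = ov$i, j = ov$j,
             orient = c("F", "R")[ov$orient + 1L],
             offset = ov$offset, length = ov$length, matches = ov$matches,
             identity = ov$identity, score = ov$score,
             stringsAsFactors = FALSE)
}

#' Greedy overlap-layout-consensus assembly
#'
#' Overlaps are processed in descending score order (ties: longer overlap,
#' then lexicographic read-id pair) and merged into growing contigs; an
#' overlap between reads already in the same contig is skipped (first
#' placement wins). The consensus is a per-column majority vote over the
#' placed reads, ties broken by the fixed base order A < C < G < T.
#' Per-library singleton membership is tallied from the read labels;
#' reads placed in no multi-read contig are returned as leftover
#' singletons.
#'
#' @param reads read table (id, seq, library).
#' @param overlaps output of [find_overlaps()] on the same reads (computed
#'   if NULL).
#' @param libraries library labels defining the count-vector columns
#'   (defaults to the labels present).
#' @param ... passed to [find_overlaps()] when overlaps is NULL.
#' @return list: contigs (data.frame id, seq, length, n_reads, one count
#'   column per library), members (data.frame contig_id, read_id, library,
#'   offset, flip), leftovers (read ids).
#' @export
greedy_assemble <- function(reads, overlaps = NULL, libraries = NULL,
                            ...) {
  if (is.null(overlaps)) overlaps <- find_overlaps(reads, ...)
  if (is.null(libraries)) libraries <- sort(unique(reads$library))
  n <- nrow(reads)
  lens <- nchar(reads$seq)
  if (nrow(overlaps)) {
    pair_lo <- pmin(overlaps$read_i, overlaps$read_j)
    pair_hi <- pmax(overlaps$read_i, overlaps$read_j)
    ord <- order(-overlaps$score, -overlaps$length, pair_lo, pair_hi)
    ov <- overlaps[ord, , drop = FALSE]
    lay <- cpp_greedy_layout(lens, ov$i, ov$j,
                             as.integer(ov$orient == "R"), ov$offset)
  } else {
    lay <- list(contig = seq_len(n), offset = rep(0L, n),
                flip = rep(0L, n))
  }
  groups <- split(seq_len(n), lay$contig)
  multi <- groups[lengths(groups) >= 2]
  leftovers <- reads$id[unlist(groups[lengths(groups) < 2],
                               use.names = FALSE)]
  # deterministic contig order: most members first, then smallest read idx
  if (length(multi)) {
    ordc <- order(-lengths(multi),
                  vapply(multi, min, integer(1)))
    multi <- multi[ordc]
  }
  contigs <- vector("list", length(multi))
  members <- vector("list", length(multi))
  for (ci in seq_along(multi)) {
    idx <- multi[[ci]]
    offs <- lay$offset[idx] - min(lay$offset[idx])
    flips <- lay$flip[idx]
    seqs <- reads$seq[idx]
    if (any(flips == 1)) seqs[flips == 1] <- revcomp(seqs[flips == 1])
    total <- max(offs + lens[idx])
    cons <- cpp_consensus(seqs, offs, total)
    id <- sprintf("Contig_%d", ci)
    libs <- reads$library[idx]
    counts <- setNames(integer(length(libraries)), libraries)
    tab <- table(libs)
    counts[names(tab)] <- as.integer(tab)
    contigs[[ci]] <- data.frame(id = id, seq = cons, length = nchar(cons),
                                n_reads = length(idx),
                                as.list(counts), check.names = FALSE,
                                stringsAsFactors = FALSE)
    members[[ci]] <- data.frame(contig_id = id, read_id = reads$id[idx],
                                library = libs, offset = offs,
                                flip = flips, stringsAsFactors = FALSE)
  }
  list(
    contigs = if (length(contigs)) do.call(rbind, contigs) else
      empty_contigs(libraries),
    members = if (length(members)) do.call(rbind, members) else
      data.frame(contig_id = character(0), read_id = character(0),
                 library = character(0), offset = integer(0),
                 flip = integer(0)),
    leftovers = leftovers
  )
}

empty_contigs <- function(libraries) {
  base <- data.frame(id = character(0), seq = character(0),
                     length = integer(0), n_reads = integer(0),
                     stringsAsFactors = FALSE)
  for (l in libraries) base[[l]] <- integer(0)
  base
}
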