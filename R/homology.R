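#' Six-frame translation
#'
#' Frames +1..+3 read the forward strand starting at offsets 0..2; frames
#' -1..-3 read the reverse complement the same way. Trailing partial
#' codons are dropped, stop codons are rendered "*", codons containing
#' ambiguous bases render "X".
#'
#' @param seq nucleotide string (A/C/G/T/N), length >= 3.
#' @return named character vector of 6 amino-acid strings
#'   ("+1","+2","+3","-1","-2","-3").
#' @export
six_frame_translate <- function(seq) {
  if (nchar(seq) < 3) stop("sequence must be at least 3 nt")
  if (grepl("[^ACGTNacgtn]", seq)) stop("non-ACGTN character in sequence")
  rc <- revcomp(seq)
  frames <- c(substring(seq, 1:3), substring(rc, 1:3))
  setNames(translate_f1(frames), c("+1", "+2", "+3", "-1", "-2", "-3"))
}

# Karlin-Altschul statistics: gapped BLASTX defaults for BLOSUM62 with
# gap open 11 / extend 1
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Bit score and E-value from a raw local-alignment score
#'
#' S' = (lambda * S - ln K) / ln 2; E = m * n * 2^(-S'), with search space
#' m = query length (aa) and n = total database residues, no length
#' correction.
#'
#' @param score raw alignment score.
#' @param m,n search-space dimensions.
#' @param lambda,K Karlin-Altschul constants.
#' @return list with bit_score and e_value (vectorised).
#' @export
blast_stats <- function(score, m, n, lambda = KA_LAMBDA, K = KA_K) {
  bit <- (lambda * score - log(K)) / log(2)
  list(bit_score = bit, e_value = m * n * 2^(-bit))
}

# BLOSUM62 as integer matrix plus which letters can seed words
# (the 20 standard residues)
scoring_blosum62 <- function() {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  mat <- data_env$BLOSUM62
  storage.mode(mat) <- "integer"
  letters <- rownames(mat)
  list(matrix = mat, letters = letters,
       seedable = letters %in% AA20)
}

# match +5 / mismatch -4, N scores 0 against anything; BLAST-like
# nucleotide gap costs
scoring_nucleotide <- function() {
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(-4L, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- 5L
  mat["N", ] <- 0L
  mat[, "N"] <- 0L
  list(matrix = mat, letters = letters, gap_open = 10L, gap_ext = 4L)
}

#' Translated homology search (seeded BLASTX-like)
#'
#' Translates each query in six frames and aligns frames against database
#' proteins by Smith-Waterman (BLOSUM62, gap open 11 / extend 1). A
#' subject is aligned only when it shares an exact amino-acid word of
#' length \code{word_size} (default 3, over the 20 standard residues) with
#' the frame; queries with no seed anywhere return no hit. The best hit
#' per query is the one with smallest E-value; ties break by higher
#' percent identity, then lexicographic subject id. Identity and coverage
#' are computed over the best local alignment; coverage is query-relative
#' (aligned query-frame span / frame length).
#'
#' @param queries named character vector of nucleotide sequences.
#' @param db protein database data.frame (see [read_protein_db()]).
#' @param word_size exact seed word length.
#' @param gap_open,gap_ext gap penalties (BLAST convention: a gap of
#'   length g costs gap_open + g * gap_ext).
#' @param lambda,K Karlin-Altschul constants.
#' @return data.frame, one row per query with a hit: query, subject,
#'   frame (+-1..3), score, bit_score, e_value, identity, coverage,
#'   taxon_bin, species, genome_type, family, flags. Queries without a
#'   seeded hit are absent.
#' @export
search_homology <- function(queries, db, word_size = 3, gap_open = 11,
                            gap_ext = 1, lambda = KA_LAMBDA, K = KA_K) {
  stopifnot(!is.null(names(queries)), nrow(db) > 0)
  bad <- grepl("[^ACGTNacgtn]", queries)
  if (any(bad)) stop("non-ACGTN character in query ", names(queries)[bad][1])
  sc <- scoring_blosum62()
  frames <- lapply(queries, six_frame_translate)
  n_db <- sum(nchar(db$seq))
  cand <- cpp_seeded_search(frames, db$seq, sc$matrix, sc$letters,
                            sc$seedable, as.integer(word_size),
                            as.integer(gap_open), as.integer(gap_ext), 0L)
  if (!nrow(cand)) return(empty_hits())
  frame_names <- c("+1", "+2", "+3", "-1", "-2", "-3")
  flen <- vapply(frames, nchar, integer(6))      # 6 x n_queries
  cand$m <- flen[cbind(cand$frame_idx, cand$query)]
  ka <- blast_stats(cand$score, cand$m, n_db, lambda, K)
  cand$bit_score <- ka$bit_score
  cand$e_value <- ka$e_value
  cand$subject_id <- db$id[cand$subject]

  # smallest E per query; identity (for reporting and the tie-break) is
  # computed only for the tied candidates
  emin <- tapply(cand$e_value, cand$query, min)
  tied <- cand[cand$e_value <= emin[as.character(cand$query)] *
                 (1 + 1e-12), , drop = FALSE]
  aln <- lapply(seq_len(nrow(tied)), function(i) {
    q <- frames[[tied$query[i]]][tied$frame_idx[i]]
    cpp_sw_align(q, db$seq[tied$subject[i]], sc$matrix, sc$letters,
                 as.integer(gap_open), as.integer(gap_ext))
  })
  tied$identity <- vapply(aln, function(a)
    if (a$length > 0) 100 * a$matches / a$length else 0, numeric(1))
  tied$coverage <- vapply(seq_len(nrow(tied)), function(i)
    100 * (aln[[i]]$aend - aln[[i]]$astart + 1) / tied$m[i], numeric(1))
  ord <- order(tied$query, -tied$identity, tied$subject_id)
  tied <- tied[ord, , drop = FALSE]
  best <- tied[!duplicated(tied$query), , drop = FALSE]
  qi <- best$query
  data.frame(
    query = names(queries)[qi],
    subject = best$subject_id,
    frame = frame_names[best$frame_idx],
    score = best$score,
    bit_score = best$bit_score,
    e_value = best$e_value,
    identity = best$identity,
    coverage = best$coverage,
    taxon_bin = db$taxon_bin[best$subject],
    species = db$species[best$subject],
    genome_type = db$genome_type[best$subject],
    family = db$family[best$subject],
    flags = db$flags[best$subject],
    stringsAsFactors = FALSE
  )
}

empty_hits <- function() {
  data.frame(query = character(0), subject = character(0),
             frame = character(0), score = integer(0),
             bit_score = numeric(0), e_value = numeric(0),
             identity = numeric(0), coverage = numeric(0),
             taxon_bin = character(0), species = character(0),
             genome_type = character(0), family = character(0),
             flags = character(0), stringsAsFactors = FALSE)
}

TAXON_BINS <- c("Animal", "Plant", "Fungi", "Bacteria", "Archaea",
                "Protist", "Phage", "NonPhageVirus")

#' Taxonomic binning of reads from best homology hits
#'
#' Reads whose best hit has E strictly below the threshold are assigned to
#' the best hit's taxon bin. Reads hitting a phiX-flagged subject are
#' removed (tallied separately, excluded from every bin). Reads with no
#' hit or E at/above threshold go to the unassigned pool. The partition is
#' exact: bin counts + phiX tally + unassigned = input reads.
#'
#' @param reads read table (id, library, ...).
#' @param hits best-hit table from [search_homology()].
#' @param threshold E-value cutoff (strict less-than).
#' @return list: assignments (data.frame read_id, library, bin; bin is a
#'   taxon bin, "phiX" or "unassigned"), bin_counts (named integer over
#'   the 8 bins), phix_tally, unassigned.
#' @export
bin_reads <- function(reads, hits, threshold = 1e-5) {
  idx <- match(reads$id, hits$query)
  has <- !is.na(idx)
  e <- ifelse(has, hits$e_value[idx], Inf)
  bin <- rep("unassigned", nrow(reads))
  sig <- has & e < threshold
  is_phix <- sig & grepl("\\bphiX\\b", ifelse(has, hits$flags[idx], ""))
  bin[sig] <- hits$taxon_bin[idx[sig]]
  bin[is_phix] <- "phiX"
  assignments <- data.frame(read_id = reads$id, library = reads$library,
                            bin = bin, stringsAsFactors = FALSE)
  bin_counts <- setNames(integer(length(TAXON_BINS)), TAXON_BINS)
  tab <- table(bin)
  common <- intersect(names(tab), TAXON_BINS)
  bin_counts[common] <- as.integer(tab[common])
  list(assignments = assignments,
       bin_counts = bin_counts,
       phix_tally = sum(bin == "phiX"),
       unassigned = sum(bin == "unassigned"))
}
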