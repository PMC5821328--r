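KNOWN_VIRUS_SPECIES <- c("SINV-1", "SINV-2", "SINV-3", "SINV-4", "SiDNV")

#' Match sequences against known-virus genomes
#'
#' A sequence is matched iff its best local nucleotide alignment to any
#' known genome (either strand; assembled contigs have arbitrary
#' orientation) reaches at least \code{min_identity} percent identity over
#' an aligned region of at least \code{min_aln_len} nt; the aligned-length
#' floor avoids trivially perfect micro-alignments, since the published
#' procedure states only the percentage. Matched sequences are binned by
#' virus species and excluded from downstream winnowing.
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param known named character vector of known-virus genomes (names are
#'   species labels).
#' @param min_identity percent-identity threshold (>=, strict at 95).
#' @param min_aln_len minimum aligned length (nt).
#' @return list: matched (data.frame id, species, identity, aln_length),
#'   unmatched (character ids), bins (named integer per species).
#' @export
match_known_viruses <- function(seqs, known, min_identity = 95,
                                min_aln_len = 50) {
  sc <- scoring_nucleotide()
  ids <- names(seqs)
  res <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    best <- NULL
    for (orient in c("+", "-")) {
      q <- if (orient == "+") s else revcomp(s)
      for (sp in names(known)) {
        score <- cpp_sw_score(q, known[[sp]], sc$matrix, sc$letters,
                              sc$gap_open, sc$gap_ext)
        if (is.null(best) || score > best$score)
          best <- list(score = score, species = sp, q = q)
      }
    }
    a <- cpp_sw_align(best$q, known[[best$species]], sc$matrix,
                      sc$letters, sc$gap_open, sc$gap_ext)
    ident <- if (a$length > 0) 100 * a$matches / a$length else 0
    data.frame(id = ids[i], species = best$species, identity = ident,
               aln_length = a$length, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  hit <- res$identity >= min_identity & res$aln_length >= min_aln_len
  matched <- res[hit, , drop = FALSE]
  bins <- setNames(integer(length(known)), names(known))
  if (nrow(matched)) {
    tab <- table(matched$species)
    bins[names(tab)] <- as.integer(tab)
  }
  list(matched = matched, unmatched = ids[!hit], bins = bins)
}

#' Apply the winnowing exclusion rules
#'
#' Sequences surviving known-virus matching are re-searched by translated
#' homology; a sequence is excluded if (in tally precedence order) it is
#' shorter than \code{min_length} nt, has no hit at E below
#' \code{threshold}, has a best hit in a non-virus taxon, or has a best
#' hit flagged as a plant virus. Each excluded item is tallied under the
#' first rule it violates; retained + excluded = input, exactly.
#'
#' @param items data.frame with columns id, length.
#' @param rehits best-hit table from [search_homology()] for the items.
#' @param threshold E-value cutoff (strict less-than).
#' @param min_length minimum sequence length (nt).
#' @return list: retained (data.frame id, length plus best-hit columns),
#'   excluded (data.frame id, rule), tally (named integer: input, short,
#'   no_match, non_virus, plant_virus, retained).
#' @export
apply_exclusions <- function(items, rehits, threshold = 1e-5,
                             min_length = 100) {
  idx <- match(items$id, rehits$query)
  has <- !is.na(idx)
  e <- ifelse(has, rehits$e_value[idx], Inf)
  bin <- ifelse(has, rehits$taxon_bin[idx], NA_character_)
  flags <- ifelse(has, rehits$flags[idx], "")
  rule <- rep(NA_character_, nrow(items))
  rule[items$length < min_length] <- "short"
  rule[is.na(rule) & !(e < threshold)] <- "no_match"
  rule[is.na(rule) & bin != "NonPhageVirus"] <- "non_virus"
  rule[is.na(rule) & grepl("\\bplant_virus\\b", flags)] <- "plant_virus"
  keep <- is.na(rule)
  retained <- cbind(items[keep, , drop = FALSE],
                    rehits[idx[keep], setdiff(names(rehits), "query"),
                           drop = FALSE])
  rownames(retained) <- NULL
  list(
    retained = retained,
    excluded = data.frame(id = items$id[!keep], rule = rule[!keep],
                          stringsAsFactors = FALSE),
    tally = c(input = nrow(items),
              short = sum(rule == "short", na.rm = TRUE),
              no_match = sum(rule == "no_match", na.rm = TRUE),
              non_virus = sum(rule == "non_virus", na.rm = TRUE),
              plant_virus = sum(rule == "plant_virus", na.rm = TRUE),
              retained = sum(keep))
  )
}

#' Classify library representation and rank viral prospects
#'
#' The representation class of a contig is the number of libraries with at
#' least one member singleton ("4-of-4" ... "1-of-4"). Records are ranked
#' in descending order of singleton total, then number of libraries
#' represented, then contig size; contigs represented in every library are
#' flagged high-likelihood viral prospects. A contig with an all-zero
#' count vector is invalid (contigs must contain reads).
#'
#' @param contig_table data.frame with columns id, size and one count
#'   column per library named in \code{lib_cols}; any other columns
#'   (best-hit species, E-value, genome type, family, ...) are carried
#'   through.
#' @param lib_cols names of the per-library count columns.
#' @return data.frame of prospect records sorted by rank, with columns
#'   total, n_libraries, representation_class, high_likelihood, rank
#'   appended.
#' @export
classify_and_rank <- function(contig_table, lib_cols) {
  counts <- as.matrix(contig_table[, lib_cols, drop = FALSE])
  storage.mode(counts) <- "integer"
  if (any(rowSums(counts) == 0))
    stop("contig with all-zero library counts: contigs must contain reads")
  n_lib <- length(lib_cols)
  total <- rowSums(counts)
  n_pos <- rowSums(counts > 0)
  out <- contig_table
  out$total <- as.integer(total)
  out$n_libraries <- as.integer(n_pos)
  out$representation_class <- sprintf("%d-of-%d", n_pos, n_lib)
  out$high_likelihood <- n_pos == n_lib
  ord <- order(-total, -n_pos, -out$size)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Fraction report over winnowing tallies
#'
#' Emits the headline fractions of the winnowing run with exact integer
#' numerators and denominators: per-taxon bin percentages of the non-host
#' total, the non-phage-virus share, the known-virus-matched share of the
#' non-phage pool and per-species counts. Percentages are rounded half-up
#' to one decimal; a zero denominator reports NA (undefined), not 0.
#'
#' @param bin_counts named integer vector over the 8 taxon bins (non-host
#'   reads assigned by homology).
#' @param known_by_species named integer vector of known-virus-matched
#'   sequence counts per species.
#' @param phix_tally count of phiX-removed sequences (reported, outside
#'   every bin).
#' @param unassigned count of unassigned sequences (part of the non-host
#'   total).
#' @return data.frame: label, numerator, denominator, percent.
#' @export
summarize_fractions <- function(bin_counts,
                                known_by_species = integer(0),
                                phix_tally = 0, unassigned = 0) {
  total <- sum(bin_counts) + unassigned
  rows <- list()
  add <- function(label, num, den) {
    rows[[length(rows) + 1]] <<- data.frame(
      label = label, numerator = num, denominator = den,
      percent = pct(num, den), stringsAsFactors = FALSE)
  }
  for (b in names(bin_counts)) {
    add(paste0("bin:", b), unname(bin_counts[b]), total)
  }
  if (unassigned > 0) add("bin:unassigned", unassigned, total)
  add("non_phage_virus_of_total", unname(bin_counts["NonPhageVirus"]),
      total)
  nonphage <- unname(bin_counts["NonPhageVirus"])
  if (length(known_by_species)) {
    add("known_virus_of_non_phage", sum(known_by_species), nonphage)
    for (sp in names(known_by_species)) {
      add(paste0("known:", sp), unname(known_by_species[sp]), nonphage)
    }
  }
  if (phix_tally > 0) add("phiX_removed", phix_tally, total + phix_tally)
  do.call(rbind, rows)
}

#' Write a prospect table in the published-table column layout
#'
#' Columns exactly: designation, singleton_total, size_nt, e_score,
#' coverage_identity (as "cov: id"), species, one column per library,
#' genome_type, family.
#'
#' @param prospects output of [classify_and_rank()] carrying best-hit
#'   columns (species, e_value, coverage, identity, genome_type, family).
#' @param path output TSV path.
#' @param lib_cols per-library count column names.
#' @return the path, invisibly.
#' @export
write_prospect_table <- function(prospects, path,
                                 lib_cols = paste0("SAL_", 1:4)) {
  df <- data.frame(
    designation = prospects$id,
    singleton_total = prospects$total,
    size_nt = prospects$size,
    e_score = format(prospects$e_value, digits = 3),
    coverage_identity = sprintf("%d: %d",
                                round(prospects$coverage),
                                round(prospects$identity)),
    species = prospects$species,
    prospects[, lib_cols, drop = FALSE],
    genome_type = prospects$genome_type,
    family = prospects$family,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  write_tsv(df, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Packaged printed-table fixtures
# ---------------------------------------------------------------------------

#' Load the packaged colony-count fixture (collection table)
#'
#' Transcription of the published collection summary: 25 Formosa sites
#' with colony counts and the library (SAL_1..SAL_4) each was pooled into.
#'
#' @return data.frame: site, colonies, library.
#' @export
load_table1_colonies <- function() {
  read_tsv(system.file("extdata", "table1_colonies.tsv",
                       package = "virowinnow"))
}

#' Load the packaged prospect-contig fixture (published contig table)
#'
#' Transcription of the published table of 38 contigs with significant
#' viral identity: singleton membership, size, best-hit E-score,
#' query coverage and identity, best-hit species, per-library singleton
#' counts, genome type and virus family.
#'
#' @return data.frame with columns designation, n_sequences, size,
#'   e_score, coverage, identity, species, SAL_1..SAL_4, genome_type,
#'   family.
#' @export
load_table2_contigs <- function() {
  read_tsv(system.file("extdata", "table2_contigs.tsv",
                       package = "virowinnow"))
}

#' Load the packaged headline sequence tallies
#'
#' The printed totals of the published run (non-host sequences, non-phage
#' virus sequences, known-virus matches per species, unmatched-singleton
#' and contig counts) used by the fraction arithmetic.
#'
#' @return named numeric vector.
#' @export
load_printed_counts <- function() {
  df <- read_tsv(system.file("extdata", "printed_counts.tsv",
                             package = "virowinnow"))
  setNames(df$value, df$key)
}
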