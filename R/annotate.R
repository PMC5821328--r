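#' Packaged motif library for dicistrovirus domain localisation
#'
#' Desk-scale stand-in for profile (pfam HMM) searches: each motif is a
#' short position-specific pattern of allowed residues with an integer
#' score (+1 per matched constrained position) and a per-motif threshold
#' equal to the number of constrained positions, i.e. every constrained
#' position must match. Wildcard positions (NULL) score 0. The pfam
#' accessions of the domains these patterns emulate are retained as
#' metadata labels only.
#'
#' Patterns: helicase = Walker-A-like G.PG.GK[ST]; peptidase =
#' 3C-protease-like G[DN]CG....H; RdRp = the conserved
#' SGxxxTxxxNS...GDD core; capsid = an invented CRPV-capsid-like anchor.
#'
#' @return named list of motifs; each has elements pattern, allowed,
#'   threshold, pfam.
#' @export
motif_library <- function() {
  mk <- function(pattern, allowed, pfam) {
    list(pattern = pattern, allowed = allowed,
         threshold = sum(!vapply(allowed, is.null, logical(1))),
         pfam = pfam)
  }
  list(
    helicase = mk("G.PG.GK[ST]",
                  list("G", NULL, "P", "G", NULL, "G", "K", c("S", "T")),
                  "pfam00910"),
    peptidase = mk("G[DN]CG....H",
                   list("G", c("D", "N"), "C", "G", NULL, NULL, NULL, NULL,
                        "H"),
                   "pfam12381"),
    RdRp = mk("SG...T...NS.GDD",
              list("S", "G", NULL, NULL, NULL, "T", NULL, NULL, NULL, "N",
                   "S", NULL, "G", "D", "D"),
              "pfam00680"),
    capsid = mk("P.G.AF.Q.W",
                list("P", NULL, "G", NULL, "A", "F", NULL, "Q", NULL, "W"),
                "pfam08762")
  )
}

#' Collapse nested ORF calls
#'
#' ORFs in the same frame sharing a stop (internal ATGs) are collapsed to
#' the 5'-most start.
#'
#' @param orfs data.frame from [find_orfs()] (sorted by start).
#' @return collapsed data.frame.
#' @export
collapse_orfs <- function(orfs) {
  if (!nrow(orfs)) return(orfs)
  orfs[!duplicated(paste(orfs$frame, orfs$end)), , drop = FALSE]
}

#' Call ATG-initiated open reading frames on the plus strand
#'
#' All ORFs beginning with ATG and ending at the next in-frame stop codon
#' (inclusive) or at the last complete codon of the sequence, in all three
#' plus-strand frames, with nucleotide length at least \code{min_length}.
#' Coordinates are 0-based half-open.
#'
#' @param genome nucleotide string.
#' @param min_length minimum ORF length in nt (ATG through stop).
#' @return data.frame: start, end, frame (1..3), length, translation
#'   (stop codon not translated), sorted by start.
#' @export
find_orfs <- function(genome, min_length = 60) {
  genome <- toupper(genome)
  L <- nchar(genome)
  out <- list()
  for (fr in 0:2) {
    starts3 <- seq.int(fr + 1L, L - 2L, by = 3L)
    if (!length(starts3)) next
    codons <- substring(genome, starts3, starts3 + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% STOP_CODONS)
    if (!length(atg)) next
    # index of first stop at or after each ATG
    nxt <- findInterval(atg - 1L, stp) + 1L
    end_codon <- ifelse(nxt <= length(stp), stp[nxt], length(codons))
    start_nt <- starts3[atg] - 1L            # 0-based
    end_nt <- starts3[end_codon] + 2L        # 0-based half-open
    keep <- (end_nt - start_nt) >= min_length
    if (!any(keep)) next
    out[[fr + 1]] <- data.frame(start = start_nt[keep], end = end_nt[keep],
                                frame = fr + 1L,
                                has_stop = (nxt <= length(stp))[keep])
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), length = integer(0),
                      translation = character(0)))
  }
  orfs <- do.call(rbind, out)
  orfs <- orfs[order(orfs$start, orfs$end), , drop = FALSE]
  orfs$length <- orfs$end - orfs$start
  tr_end <- ifelse(orfs$has_stop, orfs$end - 3L, orfs$end)
  orfs$translation <- translate_f1(substring(genome, orfs$start + 1L,
                                             tr_end))
  rownames(orfs) <- NULL
  orfs[c("start", "end", "frame", "length", "translation")]
}

#' Classify genome architecture against the dicistrovirus contract
#'
#' A genome is "dicistrovirus-like" iff it carries exactly two major
#' (>= \code{major_min} nt) plus-strand ORFs that do not overlap, are in
#' the same reading frame (start positions congruent mod 3), and are
#' separated and flanked by untranslated regions of at least
#' \code{utr_min} nt. Nested ORF calls sharing a stop (internal ATGs) are
#' collapsed to the 5'-most start before counting majors. The ORFx flag is
#' set when an ORF of at least \code{minor_min} nt overlaps the first
#' \code{orfx_window} nt of ORF2 in a different frame.
#'
#' @param genome nucleotide string.
#' @param orfs output of [find_orfs()]; recomputed if NULL.
#' @param major_min,minor_min major/minor ORF length cutoffs (nt).
#' @param utr_min minimum untranslated region length (nt).
#' @param orfx_window window at the 5' end of ORF2 searched for ORFx (nt).
#' @return list: class ("dicistrovirus-like" or "other"), orfx (flag),
#'   evidence (data.frame clause/satisfied/detail), majors (data.frame of
#'   the two major ORFs when present), utr lengths.
#' @export
classify_architecture <- function(genome, orfs = NULL, major_min = 600,
                                  minor_min = 60, utr_min = 10,
                                  orfx_window = 200) {
  if (is.null(orfs)) orfs <- find_orfs(genome, min_length = minor_min)
  L <- nchar(genome)
  orfs_c <- collapse_orfs(orfs)
  majors <- orfs_c[orfs_c$length >= major_min, , drop = FALSE]
  majors <- majors[order(majors$start), , drop = FALSE]

  ev <- list()
  note <- function(clause, ok, detail) {
    ev[[length(ev) + 1]] <<- data.frame(clause = clause, satisfied = ok,
                                        detail = detail)
  }
  note("two_major_orfs", nrow(majors) == 2,
       sprintf("%d major ORF(s) >= %d nt", nrow(majors), major_min))
  ok <- nrow(majors) == 2
  utr5 <- igr <- utr3 <- NA_integer_
  orfx <- FALSE
  if (ok) {
    o1 <- majors[1, ]; o2 <- majors[2, ]
    no_overlap <- o1$end <= o2$start
    note("non_overlapping", no_overlap,
         sprintf("ORF1 ends %d, ORF2 starts %d", o1$end, o2$start))
    inframe <- (o1$start %% 3) == (o2$start %% 3)
    note("in_frame", inframe,
         sprintf("starts %d and %d mod 3: %d vs %d", o1$start, o2$start,
                 o1$start %% 3, o2$start %% 3))
    utr5 <- o1$start; igr <- o2$start - o1$end; utr3 <- L - o2$end
    note("utr5", utr5 >= utr_min, sprintf("5' UTR %d nt", utr5))
    note("igr", no_overlap && igr >= utr_min,
         sprintf("intergenic region %d nt", igr))
    note("utr3", utr3 >= utr_min, sprintf("3' UTR %d nt", utr3))
    ok <- no_overlap && inframe && utr5 >= utr_min && igr >= utr_min &&
      utr3 >= utr_min
    win <- c(o2$start, min(o2$end, o2$start + orfx_window))
    cand <- orfs_c[orfs_c$length >= minor_min &
                     (orfs_c$start %% 3) != (o2$start %% 3) &
                     orfs_c$start < win[2] & orfs_c$end > win[1], ,
                   drop = FALSE]
    orfx <- nrow(cand) > 0
    note("orfx", orfx,
         sprintf("%d overlapping minor ORF(s) in the first %d nt of ORF2",
                 nrow(cand), orfx_window))
  }
  list(class = if (ok) "dicistrovirus-like" else "other",
       orfx = orfx,
       evidence = do.call(rbind, ev),
       majors = if (nrow(majors) == 2) majors else NULL,
       utr5 = utr5, igr = igr, utr3 = utr3)
}

#' Locate conserved domains in ORF translations by motif matching
#'
#' Scans every ORF translation with each motif of the library; the best
#' window with score >= threshold is reported. In a dicistrovirus,
#' helicase, peptidase and RdRp are expected in ORF1 (non-structural) and
#' capsid motifs in ORF2; violations of this order are reported in the
#' \code{expected} column, not treated as errors.
#'
#' @param orfs data.frame from [find_orfs()] (rows to scan).
#' @param motifs motif library (default [motif_library()]).
#' @return data.frame: motif, pfam, orf_row (row index into \code{orfs}),
#'   aa_start/aa_end (1-based in the translation), nt_start/nt_end
#'   (0-based half-open genome coordinates), score, threshold.
#' @export
locate_domains <- function(orfs, motifs = motif_library()) {
  out <- list()
  for (oi in seq_len(nrow(orfs))) {
    aa <- strsplit(orfs$translation[oi], "")[[1]]
    L <- length(aa)
    for (mn in names(motifs)) {
      m <- motifs[[mn]]
      k <- length(m$allowed)
      if (L < k) next
      npos <- L - k + 1L
      score <- integer(npos)
      for (j in seq_len(k)) {
        a <- m$allowed[[j]]
        if (is.null(a)) next
        score <- score + as.integer(aa[j:(j + npos - 1L)] %in% a)
      }
      best <- which.max(score)
      if (score[best] >= m$threshold) {
        nt0 <- orfs$start[oi] + (best - 1L) * 3L
        out[[length(out) + 1]] <- data.frame(
          motif = mn, pfam = m$pfam, orf_row = oi,
          aa_start = best, aa_end = best + k - 1L,
          nt_start = nt0, nt_end = nt0 + k * 3L,
          score = score[best], threshold = m$threshold
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(0), pfam = character(0),
                      orf_row = integer(0), aa_start = integer(0),
                      aa_end = integer(0), nt_start = integer(0),
                      nt_end = integer(0), score = integer(0),
                      threshold = integer(0)))
  }
  do.call(rbind, out)
}

#' Detect a 3'-terminal polyA tail
#' @param genome nucleotide string.
#' @param min_run minimum run of terminal A bases.
#' @return logical flag.
#' @export
detect_polyA <- function(genome, min_run = 10) {
  grepl(paste0("A{", min_run, ",}$"), toupper(genome))
}

#' Replicative-strand accounting
#'
#' In-silico analogue of strand-specific RT-PCR for the replicative
#' (minus) strand of a positive-sense RNA virus: given the strand tags of
#' the reads attributable to a genome, the replicative flag is set iff at
#' least \code{n_min} minus-strand reads are present.
#'
#' @param strands character vector of "+"/"-" tags.
#' @param n_min minimum minus-strand reads for the replicative call.
#' @return list: plus, minus (counts), replicative (flag).
#' @export
strand_accounting <- function(strands, n_min = 5) {
  plus <- sum(strands == "+")
  minus <- sum(strands == "-")
  list(plus = plus, minus = minus, replicative = minus >= n_min)
}

#' Annotate an assembled genome (orientation-aware)
#'
#' Assembled consensus sequences have arbitrary orientation; when
#' \code{both_strands} is TRUE the annotation is computed on both the
#' sequence and its reverse complement and the orientation with the better
#' architecture evidence is kept (dicistrovirus classification first, then
#' total major-ORF length, then polyA presence).
#'
#' @param seq nucleotide string.
#' @param id genome identifier used in reports/GFF3.
#' @param min_orf minimum ORF call length (nt).
#' @param both_strands consider the reverse complement too.
#' @param strands optional "+"/"-" read tags for [strand_accounting()]
#'   (tags refer to the original, pre-orientation sequence source).
#' @param n_min minus-strand threshold for the replicative flag.
#' @param ... passed to [classify_architecture()].
#' @return object of class \code{vw_annotation}: list with genome id,
#'   length, orientation, orfs, architecture, domains, polyA,
#'   strand counts and replicative flag.
#' @export
annotate_genome <- function(seq, id = "genome", min_orf = 60,
                            both_strands = TRUE, strands = NULL,
                            n_min = 5, ...) {
  candidates <- list(`+` = seq)
  if (both_strands) candidates$`-` <- revcomp(seq)
  evaluate <- function(s) {
    orfs <- find_orfs(s, min_length = min_orf)
    arch <- classify_architecture(s, orfs, ...)
    major_len <- if (!is.null(arch$majors)) sum(arch$majors$length) else
      if (nrow(orfs)) max(orfs$length) else 0
    list(seq = s, orfs = orfs, arch = arch, major_len = major_len,
         polyA = detect_polyA(s))
  }
  evals <- lapply(candidates, evaluate)
  pick <- order(
    -vapply(evals, function(e) e$arch$class == "dicistrovirus-like",
            logical(1)),
    -vapply(evals, function(e) e$major_len, numeric(1)),
    -vapply(evals, function(e) e$polyA, logical(1))
  )[1]
  ev <- evals[[pick]]
  sa <- if (!is.null(strands)) strand_accounting(strands, n_min) else
    list(plus = NA_integer_, minus = NA_integer_, replicative = NA)
  structure(list(
    id = id, length = nchar(seq), orientation = names(evals)[pick],
    orfs = ev$orfs, architecture = ev$arch,
    domains = locate_domains(collapse_orfs(ev$orfs)),
    polyA = ev$polyA,
    plus_strand_reads = sa$plus, minus_strand_reads = sa$minus,
    replicative = sa$replicative
  ), class = "vw_annotation")
}

#' Convert an annotation to GFF3 feature rows
#'
#' ORFs are emitted as CDS features, domains as misc_feature with their
#' pfam label, and the polyA tail (when present) as a polyA_site.
#'
#' @param ann a [annotate_genome()] object.
#' @return data.frame consumable by [write_gff3()].
#' @export
annotation_features <- function(ann) {
  feats <- list()
  orfs <- ann$orfs
  if (!is.null(ann$architecture$majors)) orfs <- ann$architecture$majors
  if (nrow(orfs)) {
    feats[[1]] <- data.frame(
      seqid = ann$id, source = "virowinnow", type = "CDS",
      start = orfs$start, end = orfs$end, strand = "+",
      attributes = sprintf("ID=orf%d;frame=%d", seq_len(nrow(orfs)),
                           orfs$frame)
    )
  }
  if (nrow(ann$domains)) {
    feats[[length(feats) + 1]] <- data.frame(
      seqid = ann$id, source = "virowinnow", type = "misc_feature",
      start = ann$domains$nt_start, end = ann$domains$nt_end, strand = "+",
      attributes = sprintf("Name=%s;pfam_label=%s", ann$domains$motif,
                           ann$domains$pfam)
    )
  }
  if (isTRUE(ann$polyA)) {
    feats[[length(feats) + 1]] <- data.frame(
      seqid = ann$id, source = "virowinnow", type = "polyA_site",
      start = ann$length - 1L, end = ann$length, strand = "+",
      attributes = "Note=3-prime polyA tail"
    )
  }
  if (!length(feats)) {
    return(data.frame(seqid = character(0), source = character(0),
                      type = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      attributes = character(0)))
  }
  do.call(rbind, feats)
}

#' @export
print.vw_annotation <- function(x, ...) {
  cat(sprintf("<%s> %d nt, orientation %s, %s\n", x$id, x$length,
              x$orientation, x$architecture$class))
  cat(sprintf("  ORFs called: %d; ORFx: %s; polyA: %s\n", nrow(x$orfs),
              x$architecture$orfx, x$polyA))
  if (nrow(x$domains)) {
    cat(sprintf("  domains: %s\n",
                paste(sprintf("%s@%d-%d", x$domains$motif,
                              x$domains$nt_start, x$domains$nt_end),
                      collapse = ", ")))
  }
  if (!is.na(x$replicative)) {
    cat(sprintf("  strand reads: +%d / -%d; replicative: %s\n",
                x$plus_strand_reads, x$minus_strand_reads, x$replicative))
  }
  invisible(x)
}
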