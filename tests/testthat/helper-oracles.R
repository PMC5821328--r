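# Independent oracles used across the suite. These deliberately avoid the
# package's own C++ kernels: alignments go through Biostrings'
# pairwiseAlignment, overlaps through an exhaustive all-offsets scan in
# plain R, and trees through exhaustive least squares / ape.

BASES4 <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(BASES4, n, replace = TRUE),
                              collapse = "")

rand_reads_df <- function(seqs, library = "SAL_1", qual_char = "I") {
  data.frame(id = sprintf("r%04d", seq_along(seqs)), seq = seqs,
             qual = strrep(qual_char, nchar(seqs)), library = library,
             stringsAsFactors = FALSE)
}

# reads tiling a genome region with fixed stagger (plus optional errors)
tiling_reads <- function(genome, from, to, read_len, step,
                         error_rate = 0) {
  starts <- seq(from, to - read_len, by = step)
  seqs <- substring(genome, starts + 1, starts + read_len)
  if (error_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      nm <- rbinom(1, nchar(s), error_rate)
      if (nm == 0) return(s)
      virowinnow:::mutate_dna(s, sample.int(nchar(s), nm))
    }, character(1), USE.NAMES = FALSE)
  }
  seqs
}

# Biostrings local protein alignment with BLAST-convention gap costs
oracle_protein_score <- function(a, b, gap_open = 11, gap_ext = 1) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
    gapExtension = gap_ext, scoreOnly = TRUE)
  as.integer(pa)
}

# exhaustive translated search: all 6 frames x all subjects, full SW via
# Biostrings; returns best subject/frame/score/E under the package's
# E-value formula and tie rules (identity ties resolved by alignment)
oracle_best_hit <- function(query, db) {
  frames <- six_frame_translate(query)
  n_db <- sum(nchar(db$seq))
  best <- NULL
  for (f in seq_along(frames)) {
    fr <- frames[f]
    if (nchar(fr) < 1) next
    for (s in seq_len(nrow(db))) {
      sc <- oracle_protein_score(fr, db$seq[s])
      if (sc <= 0) next
      e <- blast_stats(sc, nchar(fr), n_db)$e_value
      cand <- list(subject = db$id[s], frame = names(frames)[f],
                   score = sc, e_value = e)
      if (is.null(best) || e < best$e_value * (1 - 1e-12)) best <- cand
      else if (abs(e - best$e_value) <= best$e_value * 1e-12 &&
               cand$subject < best$subject) best <- cand
    }
  }
  best
}

# exhaustive gap-free overlap scan: all pairs, all offsets, both
# orientations; mirrors the documented overlap model
oracle_overlaps <- function(seqs, min_len, min_ident) {
  n <- length(seqs)
  rc <- virowinnow:::revcomp(seqs)
  out <- list()
  for (i in seq_len(n - 1)) {
    a <- strsplit(seqs[i], "")[[1]]
    La <- length(a)
    for (j in (i + 1):n) {
      for (orient in c("F", "R")) {
        b <- strsplit(if (orient == "F") seqs[j] else rc[j], "")[[1]]
        Lb <- length(b)
        best <- NULL
        for (d in (-Lb + min_len):(La - min_len)) {
          p0 <- max(0, d); p1 <- min(La, Lb + d)
          len <- p1 - p0
          if (len < min_len) next
          av <- a[(p0 + 1):p1]; bv <- b[(p0 - d + 1):(p1 - d)]
          matches <- sum(av == bv & av %in% BASES4)
          ident <- 100 * matches / len
          if (ident < min_ident) next
          score <- len * ident / 100
          if (is.null(best) || score > best$score ||
              (score == best$score && len > best$length))
            best <- list(offset = d, length = len, matches = matches,
                         identity = ident, score = score)
        }
        if (!is.null(best)) {
          out[[length(out) + 1]] <- data.frame(
            i = i, j = j, orient = orient, offset = best$offset,
            length = best$length, matches = best$matches,
            identity = best$identity, score = best$score)
        }
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# random additive tree: topology by sequential attachment, branch lengths
# positive; returns the ape tree and its exact leaf-to-leaf distances
rand_additive_tree <- function(n_taxa) {
  labels <- paste0("t", seq_len(n_taxa))
  tree <- ape::rtree(n_taxa, tip.label = labels)
  tree$edge.length <- runif(nrow(tree$edge), 0.05, 1)
  tree <- ape::unroot(tree)
  D <- cophenetic(tree)
  D <- D[labels, labels]
  list(tree = tree, D = D)
}

# exhaustive least-squares oracle for 4-taxon topology selection: fits
# branch lengths for each of the three unrooted topologies and returns
# the split of the best-fitting one
oracle_ls_quartet <- function(D) {
  taxa <- rownames(D)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))  # partner of taxon 1
  best <- NULL
  for (s in splits) {
    pair1 <- s; pair2 <- setdiff(1:4, s)
    # edges: 4 tip edges + internal; design matrix over the 6 distances
    combs <- t(combn(4, 2))
    X <- matrix(0, 6, 5)
    for (r in seq_len(6)) {
      i <- combs[r, 1]; j <- combs[r, 2]
      X[r, i] <- 1; X[r, j] <- 1
      same <- (all(c(i, j) %in% pair1)) || (all(c(i, j) %in% pair2))
      if (!same) X[r, 5] <- 1
    }
    y <- D[combs]
    fit <- lm.fit(X, y)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse,
                   split = paste(sort(taxa[pair2]), collapse = "|"))
  }
  best$split
}

# canonical splits of a tree, via the package helper (structure only)
splits_of <- function(tree) virowinnow:::tree_splits(tree)
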