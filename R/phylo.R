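#' Read a protein multiple alignment
#'
#' FASTA or relaxed (whitespace-separated) sequential PHYLIP. Rows must
#' have equal length; at least 3 taxa are required downstream.
#'
#' @param path alignment file.
#' @param format "fasta", "phylip" or "auto" (by first character).
#' @return object of class \code{vw_alignment}: list with taxa (labels),
#'   rows (named character vector) and mask (logical included-position
#'   vector, all TRUE initially).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1), 1, 1)
    format <- if (first == ">") "fasta" else "phylip"
  }
  rows <- if (format == "fasta") {
    x <- Biostrings::readAAStringSet(path)
    setNames(as.character(x), sub("\\s.*$", "", names(x)))
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    header <- strsplit(lines[1], "\\s+")[[1]]
    n <- as.integer(header[1])
    parts <- strsplit(lines[1 + seq_len(n)], "\\s+")
    setNames(vapply(parts, function(p) paste(p[-1], collapse = ""),
                    character(1)),
             vapply(parts, `[`, character(1), 1))
  }
  make_alignment(rows)
}

#' Construct an alignment object from named rows
#' @param rows named character vector of equal-length aligned sequences.
#' @param mask optional logical vector of included positions.
#' @return \code{vw_alignment} object.
#' @export
make_alignment <- function(rows, mask = NULL) {
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) stop("alignment rows differ in length")
  if (is.null(mask)) mask <- rep(TRUE, widths[1])
  if (length(mask) != widths[1]) stop("mask length must equal row length")
  structure(list(taxa = names(rows), rows = rows, mask = mask),
            class = "vw_alignment")
}

# alignment as a character matrix restricted to masked-in columns
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(toupper(aln$rows), ""))
  rownames(m) <- aln$taxa
  m[, aln$mask, drop = FALSE]
}

#' Pairwise distances from a protein alignment
#'
#' p-distance (mismatches over compared sites) or Poisson-corrected
#' distance d = -ln(1 - p). Gap columns ("-" or ".") are deleted pairwise:
#' a site is compared for a pair only when both rows have a residue.
#'
#' @param aln \code{vw_alignment}.
#' @param model "poisson" (default, the standard amino-acid choice) or
#'   "p-distance".
#' @return symmetric distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(aln, model = c("poisson", "p-distance")) {
  model <- match.arg(model)
  m <- alignment_matrix(aln)
  n <- nrow(m)
  res <- is_residue(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- res[i, ] & res[j, ]
      nc <- sum(both)
      if (nc == 0) stop("no comparable sites between ", rownames(m)[i],
                        " and ", rownames(m)[j])
      p <- sum(m[i, both] != m[j, both]) / nc
      d <- if (model == "poisson") {
        if (p >= 1) stop("saturated pair (p = 1) under the Poisson model")
        -log(1 - p)
      } else p
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

is_residue <- function(m) m != "-" & m != "."

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q criterion. Ties in Q break
#' deterministically by the lexicographically smallest label pair.
#' Negative branch lengths are clamped to zero; the original values are
#' kept in the \code{"clamped"} attribute of the returned tree.
#'
#' @param D symmetric distance matrix with labelled dimnames, n >= 3.
#' @return an \pkg{ape} \code{phylo} object (unrooted).
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  # node "subtrees" carried as Newick fragments; label carried for ties
  frag <- labels
  key <- labels
  d <- D
  clamped <- list()
  clamp <- function(x, a, b) {
    if (x < 0) clamped[[length(clamped) + 1]] <<- c(a, b, x)
    max(x, 0)
  }
  while (nrow(d) > 3) {
    nn <- nrow(d)
    r <- rowSums(d)
    q <- (nn - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    pk <- paste(pmin(key[best[, 1]], key[best[, 2]]),
                pmax(key[best[, 1]], key[best[, 2]]), sep = "\r")
    sel <- best[order(pk)[1], ]
    i <- sel[1]; j <- sel[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    lj <- d[i, j] - li
    li <- clamp(li, key[i], key[j]); lj <- clamp(lj, key[j], key[i])
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], li, frag[j], lj)
    newkey <- min(key[i], key[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    d <- d2
  }
  # resolve the final three nodes around a central vertex
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- clamp(la, key[1], "center")
  lb <- clamp(lb, key[2], "center")
  lc <- clamp(lc, key[3], "center")
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", frag[1], la, frag[2],
                 lb, frag[3], lc)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

# canonical split keys for all internal edges of an unrooted phylo tree:
# each split is the tip-label set on the child side of an internal edge,
# canonicalised to the side not containing the alphabetically first taxon
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  edge <- tree$edge
  below <- node_tipsets(tree)
  internal_children <- edge[, 2][edge[, 2] > ntip]
  keys <- character(0)
  for (nd in internal_children) {
    side <- below[[nd]]
    if (length(side) < 2 || length(side) > ntip - 2) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples included alignment columns with replacement, rebuilds the NJ
#' tree per replicate, and scores every internal bipartition of the
#' original tree by the percentage of replicates containing it. Supports
#' are attached as internal node labels; the resampled column indices of
#' every replicate are kept in the \code{"replicate_columns"} attribute
#' for audit.
#'
#' @param aln \code{vw_alignment}.
#' @param n_reps bootstrap replicates (0 returns the tree unannotated).
#' @param seed integer seed for the resampling.
#' @param model distance model, see [pairwise_distances()].
#' @return \pkg{ape} \code{phylo} with node labels giving bootstrap
#'   percentages (root label empty).
#' @export
nj_bootstrap <- function(aln, n_reps = 500, seed = 1,
                         model = c("poisson", "p-distance")) {
  model <- match.arg(model)
  tree <- neighbor_joining(pairwise_distances(aln, model))
  if (n_reps == 0) return(tree)
  set.seed(derive_seed(seed, 0))
  cols <- which(aln$mask)
  orig <- tree_splits(tree)
  tally <- setNames(integer(length(orig)), orig)
  rep_cols <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    pick <- sample(cols, length(cols), replace = TRUE)
    rep_cols[[b]] <- pick
    sub <- make_alignment(
      vapply(aln$rows, function(r)
        paste(strsplit(r, "")[[1]][pick], collapse = ""), character(1)))
    bt <- neighbor_joining(pairwise_distances(sub, model))
    hits <- intersect(tree_splits(bt), orig)
    tally[hits] <- tally[hits] + 1L
  }
  support <- 100 * tally / n_reps
  # map supports onto internal nodes of the original tree
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  labels <- rep("", nnode)
  ref <- sort(tree$tip.label)[1]
  edge <- tree$edge
  below <- node_tipsets(tree)
  for (nd in (ntip + 1):(ntip + nnode)) {
    side <- below[[nd]]
    if (length(side) < 2 || length(side) > ntip - 2) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    k <- paste(sort(side), collapse = "|")
    if (k %in% names(support))
      labels[nd - ntip] <- format(round(support[[k]], 1))
  }
  tree$node.label <- labels
  attr(tree, "replicate_columns") <- rep_cols
  attr(tree, "support") <- support
  tree
}

node_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  below <- vector("list", ntip + tree$Nnode)
  for (t in seq_len(ntip)) below[[t]] <- tree$tip.label[t]
  nodes <- sort(unique(edge[, 1]))
  repeat {
    done <- TRUE
    for (nd in nodes) {
      if (!is.null(below[[nd]])) next
      kids <- edge[edge[, 1] == nd, 2]
      if (all(!vapply(below[kids], is.null, logical(1)))) {
        below[[nd]] <- unlist(below[kids])
      } else done <- FALSE
    }
    if (done) break
  }
  below
}

#' Write a distance matrix as TSV
#' @param D distance matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(taxon = rownames(D), as.data.frame(D),
                   check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}
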