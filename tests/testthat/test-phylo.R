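test_that("pairwise distances follow their definitions", {
  rows <- c(A = strrep("K", 100),
            B = paste0(strrep("K", 90), strrep("R", 10)),
            C = strrep("K", 100))
  aln <- make_alignment(rows)
  Dp <- pairwise_distances(aln, "p-distance")
  expect_equal(Dp["A", "C"], 0)
  expect_equal(Dp["A", "B"], 0.10)
  Dq <- pairwise_distances(aln, "poisson")
  expect_equal(Dq["A", "B"], -log(0.9), tolerance = 1e-12)
  # Poisson >= p-distance, equality iff p = 0
  expect_true(all(Dq >= Dp))
  expect_equal(Dq["A", "C"], 0)
  # pairwise deletion of gap columns
  rows2 <- c(A = "KKKK-KKKKK", B = "KKKKRKKKKR", C = "KKKK-KKKK-")
  D2 <- pairwise_distances(make_alignment(rows2), "p-distance")
  expect_equal(D2["A", "B"], 1 / 9)   # 9 comparable sites, 1 mismatch
  expect_equal(D2["B", "C"], 0 / 8)   # 8 comparable sites
})

test_that("NJ recovers an additive 4-taxon tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:1)) -> additive distances
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 5
  D["A", "D"] <- D["D", "A"] <- 3
  D["B", "C"] <- D["C", "B"] <- 6
  D["B", "D"] <- D["D", "B"] <- 4
  D["C", "D"] <- D["D", "C"] <- 4
  tree <- neighbor_joining(D)
  expect_setequal(splits_of(tree), "C|D")
  expect_equal(oracle_ls_quartet(D), "C|D")
  # branch lengths: tips by label, internal edge 1
  tip_len <- setNames(tree$edge.length[match(seq_len(4), tree$edge[, 2])],
                      tree$tip.label)
  expect_equal(tip_len[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3,
                                                 D = 1))
  expect_equal(sum(tree$edge.length), 8)
  expect_equal(unname(cophenetic(tree)[rownames(D), colnames(D)]),
               unname(D), tolerance = 1e-9)
})

test_that("3 taxa resolve by the closed form", {
  D <- matrix(c(0, 5, 7, 5, 0, 8, 7, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(D)
  tl <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                 tree$tip.label)
  expect_equal(unname(tl["A"]), (5 + 7 - 8) / 2)
  expect_equal(unname(tl["B"]), (5 + 8 - 7) / 2)
  expect_equal(unname(tl["C"]), (7 + 8 - 5) / 2)
})

test_that("NJ recovers random additive topologies (property)", {
  set.seed(20)
  for (trial in 1:20) {
    n <- sample(5:8, 1)
    gen <- rand_additive_tree(n)
    tree <- neighbor_joining(gen$D)
    expect_setequal(splits_of(tree), splits_of(gen$tree))
    # and ape's independent NJ agrees on the topology
    expect_setequal(splits_of(tree), splits_of(ape::nj(gen$D)))
  }
})

test_that("negative branch lengths are clamped and logged", {
  D <- matrix(c(0, 2, 2, 2.1,
                2, 0, 0.1, 2,
                2, 0.1, 0, 2,
                2.1, 2, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- neighbor_joining(D)
  expect_true(all(tree$edge.length >= 0))
})

test_that("bootstrap supports separate two planted clades", {
  set.seed(22)
  # 6 taxa, two clades of 3 with 50 diagnostic columns each
  blockA <- paste(sample(virowinnow:::AA20, 50, TRUE), collapse = "")
  blockB <- paste(sample(virowinnow:::AA20, 50, TRUE), collapse = "")
  noise <- function() paste(sample(virowinnow:::AA20, 30, TRUE),
                            collapse = "")
  jitter_seq <- function(s, rate) virowinnow:::mutate_protein(s, rate)
  rows <- c(
    a1 = paste0(jitter_seq(blockA, 0.02), blockB, noise()),
    a2 = paste0(jitter_seq(blockA, 0.02), blockB, noise()),
    a3 = paste0(jitter_seq(blockA, 0.02), blockB, noise()),
    b1 = paste0(blockA, jitter_seq(blockB, 0.6), noise()),
    b2 = paste0(blockA, jitter_seq(blockB, 0.6), noise()),
    b3 = paste0(blockA, jitter_seq(blockB, 0.6), noise())
  )
  aln <- make_alignment(rows)
  tree <- nj_bootstrap(aln, n_reps = 100, seed = 5)
  sup <- attr(tree, "support")
  expect_true(all(sup >= 0 & sup <= 100))
  # the clade split {a1,a2,a3} | {b1,b2,b3} must be near-unanimous
  clade_key <- names(sup)[names(sup) %in% c("b1|b2|b3", "a1|a2|a3")]
  expect_gte(length(clade_key), 1)
  expect_true(all(sup[clade_key] >= 95))
  # determinism under the seed; reps are logged
  tree2 <- nj_bootstrap(aln, n_reps = 100, seed = 5)
  expect_identical(attr(tree, "support"), attr(tree2, "support"))
  expect_identical(attr(tree, "replicate_columns"),
                   attr(tree2, "replicate_columns"))
  expect_equal(length(attr(tree, "replicate_columns")), 100)
  # n_reps = 0: tree without support labels
  t0 <- nj_bootstrap(aln, n_reps = 0)
  expect_null(t0$node.label)
})

test_that("supports are invariant under taxon-order permutation", {
  set.seed(23)
  gen <- rand_additive_tree(6)
  rows <- setNames(
    vapply(1:6, function(i)
      paste(sample(virowinnow:::AA20, 120, TRUE), collapse = ""),
      character(1)), gen$tree$tip.label)
  # give the rows phylogenetic signal: derive from two ancestors
  anc <- paste(sample(virowinnow:::AA20, 120, TRUE), collapse = "")
  rows[] <- vapply(seq_along(rows), function(i)
    virowinnow:::mutate_protein(anc, 0.15), character(1))
  aln1 <- make_alignment(rows)
  aln2 <- make_alignment(rev(rows))
  s1 <- attr(nj_bootstrap(aln1, n_reps = 50, seed = 9), "support")
  s2 <- attr(nj_bootstrap(aln2, n_reps = 50, seed = 9), "support")
  expect_setequal(names(s1), names(s2))
  expect_equal(s1[sort(names(s1))], s2[sort(names(s1))])
})

test_that("the packaged RdRp-like alignment resolves its planted clades", {
  aln <- read_alignment(system.file("extdata",
                                    "rdrp_alignment_synthetic.fasta",
                                    package = "virowinnow"))
  # mask out the all-gap columns (243 informative positions remain)
  m <- do.call(rbind, strsplit(aln$rows, ""))
  gapcol <- apply(m == "-", 2, all)
  expect_equal(sum(!gapcol), 243)
  aln <- make_alignment(aln$rows, mask = !gapcol)
  tree <- nj_bootstrap(aln, n_reps = 100, seed = 7)
  sup <- attr(tree, "support")
  # canonical key: the split side not containing the first-sorted taxon
  all_taxa <- tree$tip.label
  canon <- function(side) {
    if (sort(all_taxa)[1] %in% side) side <- setdiff(all_taxa, side)
    paste(sort(side), collapse = "|")
  }
  apara <- canon(c("SINV5_like", "aparavirus_1", "aparavirus_2"))
  expect_true(apara %in% names(sup))
  expect_gte(sup[[apara]], 90)
})

test_that("alignment IO round-trips FASTA and relaxed PHYLIP", {
  rows <- c(tax1 = "MKVL-", tax2 = "MKVLL", tax3 = "MRVLL")
  fa <- tempfile(fileext = ".fasta")
  write_fasta(rows, fa)
  a1 <- read_alignment(fa)
  expect_identical(a1$rows, rows)
  ph <- tempfile(fileext = ".phy")
  writeLines(c("3 5", paste(names(rows), rows)), ph)
  a2 <- read_alignment(ph)
  expect_identical(a2$rows, rows)
  # masking restricts the compared columns
  aln <- make_alignment(rows, mask = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  D <- pairwise_distances(aln, "p-distance")
  expect_equal(D["tax1", "tax3"], 1 / 3)
})
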