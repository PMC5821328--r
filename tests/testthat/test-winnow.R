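# plant `n` evenly spread substitutions into a sequence
plant_mismatches <- function(seq, n) {
  L <- nchar(seq)
  pos <- round(seq(10, L - 10, length.out = n))
  virowinnow:::mutate_dna(seq, pos)
}

test_that("known-virus matching applies the strict 95% identity rule", {
  set.seed(14)
  known <- c("SINV-1" = rand_dna(2000), "SINV-2" = rand_dna(2000))
  frag <- substring(known[["SINV-1"]], 301, 800)   # 500 nt
  near <- plant_mismatches(frag, 10)               # ~98% identity
  far <- plant_mismatches(frag, 30)                # ~94% identity
  km <- match_known_viruses(c(a = near, b = far), known)
  expect_identical(km$matched$id, "a")
  expect_identical(km$matched$species, "SINV-1")
  expect_gte(km$matched$identity, 95)
  expect_identical(km$unmatched, "b")
  # reverse-complemented contig still matches (arbitrary orientation)
  km2 <- match_known_viruses(c(a = virowinnow:::revcomp(near)), known)
  expect_identical(km2$matched$id, "a")
  expect_identical(km2$matched$species, "SINV-1")
})

test_that("per-species bin totals equal a Biostrings alignment oracle", {
  set.seed(15)
  known <- c("SINV-1" = rand_dna(1500), "SINV-3" = rand_dna(1500),
             "SiDNV" = rand_dna(1200))
  frags <- list()
  truth <- character(0)
  for (i in 1:12) {
    sp <- sample(names(known), 1)
    from <- sample(200:900, 1)
    f <- substring(known[[sp]], from, from + 299)
    nm <- sample(c(2, 25), 1)          # clearly above / below threshold
    frags[[sprintf("f%02d", i)]] <- plant_mismatches(f, nm)
    truth[sprintf("f%02d", i)] <- if (nm == 2) sp else "none"
  }
  km <- match_known_viruses(unlist(frags), known)
  # oracle: best Biostrings local alignment per fragment
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5,
                                                  mismatch = -4)
  oracle_bins <- setNames(integer(length(known)), names(known))
  for (fn in names(frags)) {
    best <- NULL
    for (sp in names(known)) {
      for (q in c(frags[[fn]], virowinnow:::revcomp(frags[[fn]]))) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(q), Biostrings::DNAString(known[[sp]]),
          type = "local", substitutionMatrix = mat, gapOpening = 10,
          gapExtension = 4)
        sc <- Biostrings::score(pa)
        if (is.null(best) || sc > best$sc)
          best <- list(sc = sc, sp = sp,
                       len = Biostrings::nchar(pa),
                       ident = 100 * Biostrings::nmatch(pa) /
                         Biostrings::nchar(pa))
      }
    }
    if (best$ident >= 95 && best$len >= 50)
      oracle_bins[best$sp] <- oracle_bins[best$sp] + 1L
  }
  expect_identical(km$bins, oracle_bins)
  # and the truth labels agree where planted
  for (fn in names(frags)) {
    if (truth[[fn]] == "none") expect_true(fn %in% km$unmatched)
    else expect_identical(km$matched$species[km$matched$id == fn],
                          truth[[fn]])
  }
})

test_that("exclusion rules tally with the documented precedence", {
  items <- data.frame(id = c("c1", "c2", "c3", "c4"),
                      length = c(99, 500, 500, 500),
                      stringsAsFactors = FALSE)
  rehits <- data.frame(
    query = c("c1", "c2", "c4"),
    subject = "s", frame = "+1", score = 100, bit_score = 40,
    e_value = c(1e-20, 1e-20, 1e-8),
    identity = 80, coverage = 70,
    taxon_bin = c("NonPhageVirus", "NonPhageVirus", "NonPhageVirus"),
    species = c("v", "Tomato bushy stunt virus", "v"),
    genome_type = "ssRNA", family = "f",
    flags = c("", "plant_virus", ""), stringsAsFactors = FALSE)
  exc <- apply_exclusions(items, rehits)
  rules <- setNames(exc$excluded$rule, exc$excluded$id)
  expect_equal(unname(rules["c1"]), "short")       # despite a strong hit
  expect_equal(unname(rules["c2"]), "plant_virus")
  expect_equal(unname(rules["c3"]), "no_match")
  expect_identical(exc$retained$id, "c4")
  expect_equal(unname(exc$tally["retained"] +
                        sum(exc$tally[c("short", "no_match", "non_virus",
                                        "plant_virus")])),
               nrow(items))
})

test_that("the packaged contig table reproduces the printed class structure", {
  t2 <- load_table2_contigs()
  expect_equal(nrow(t2), 38)
  libs <- paste0("SAL_", 1:4)
  # row property: per-library vectors sum to the printed contig totals
  expect_equal(rowSums(t2[libs]), t2$n_sequences,
               ignore_attr = TRUE)
  ranked <- classify_and_rank(
    data.frame(id = t2$designation, size = t2$size, t2[libs],
               species = t2$species, check.names = FALSE), libs)
  cls_n <- table(ranked$representation_class)
  cls_sum <- tapply(ranked$total, ranked$representation_class, sum)
  expect_equal(unname(cls_n[c("4-of-4", "3-of-4", "2-of-4", "1-of-4")]),
               c(15L, 9L, 8L, 6L), ignore_attr = TRUE)
  expect_equal(unname(cls_sum[c("4-of-4", "3-of-4", "2-of-4", "1-of-4")]),
               c(46845, 1276, 927, 5180), ignore_attr = TRUE)
  expect_identical(ranked$id[ranked$high_likelihood],
                   t2$designation[rowSums(t2[libs] > 0) == 4])
  # the top-ranked record is the highest-expression 4-of-4 contig
  expect_equal(ranked$id[1], "Contig_29")
  expect_error(classify_and_rank(
    data.frame(id = "z", size = 10, SAL_1 = 0, SAL_2 = 0, SAL_3 = 0,
               SAL_4 = 0), libs), "all-zero")
})

test_that("fraction arithmetic matches the printed percentages", {
  expect_equal(virowinnow:::pct(292499, 876528), 33.4)
  expect_equal(virowinnow:::pct(230555, 292499), 78.8)
  expect_true(is.na(virowinnow:::pct(5, 0)))
  bins <- c(Animal = 100, Plant = 0, Fungi = 0, Bacteria = 0,
            Archaea = 0, Protist = 0, Phage = 50, NonPhageVirus = 50)
  fr <- summarize_fractions(bins, c("SINV-1" = 30), phix_tally = 10,
                            unassigned = 0)
  expect_equal(fr$percent[fr$label == "bin:NonPhageVirus"], 25)
  expect_equal(fr$percent[fr$label == "known_virus_of_non_phage"], 60)
  expect_equal(fr$numerator[fr$label == "known:SINV-1"], 30)
  # zero denominator propagates as NA, not 0
  fr0 <- summarize_fractions(setNames(rep(0, 8), names(bins)))
  expect_true(all(is.na(fr0$percent)))
})

test_that("colony counts in the packaged collection table sum as printed", {
  t1 <- load_table1_colonies()
  sums <- tapply(t1$colonies, t1$library, sum)
  expect_equal(unname(sums[paste0("SAL_", 1:4)]), c(46, 53, 44, 39),
               ignore_attr = TRUE)
  expect_equal(sum(t1$colonies), 182)
})
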