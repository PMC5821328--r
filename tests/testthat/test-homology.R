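test_that("six-frame translation follows the standard code and symmetry", {
  expect_identical(unname(six_frame_translate("ATGGCC")["+1"]), "MA")
  expect_identical(unname(six_frame_translate("TAA")["+1"]), "*")
  # frame -1 of s equals frame +1 of the reverse complement
  set.seed(1)
  for (i in 1:20) {
    s <- rand_dna(sample(10:60, 1))
    fr <- six_frame_translate(s)
    frc <- six_frame_translate(virowinnow:::revcomp(s))
    expect_identical(unname(fr["-1"]), unname(frc["+1"]))
    expect_identical(unname(fr["+2"]), unname(frc["-2"]))
  }
  expect_error(six_frame_translate("AT"), "at least 3")
  expect_error(six_frame_translate("ATGXGG"), "non-ACGTN")
})

test_that("Karlin-Altschul statistics reproduce the closed form", {
  # S = 100, lambda = 0.267, K = 0.041: S' = (26.7 + 3.1942) / ln 2
  st <- blast_stats(100, m = 1, n = 1)
  expect_equal(st$bit_score, (0.267 * 100 - log(0.041)) / log(2),
               tolerance = 1e-12)
  # recomputed at full precision: (26.7 + 3.194183) / 0.6931472 = 43.128
  expect_equal(st$bit_score, 43.1282, tolerance = 1e-5)
  e <- blast_stats(100, m = 1000, n = 1000)$e_value
  expect_equal(e, 1e6 * 2^(-st$bit_score), tolerance = 1e-12)
  expect_equal(e, 1.032e-7, tolerance = 1e-3)
  # E strictly decreasing in raw score for fixed (lambda, K, m, n)
  es <- blast_stats(seq(10, 200, by = 5), m = 50, n = 1e4)$e_value
  expect_true(all(diff(es) < 0))
})

test_that("an exact translation of a database protein is a perfect self-hit", {
  set.seed(2)
  aa <- paste(sample(virowinnow:::AA20, 50, replace = TRUE),
              collapse = "")
  nt <- virowinnow:::aa_to_codons(aa)
  db <- data.frame(id = c("T1", "D1"), seq = c(aa,
    paste(sample(virowinnow:::AA20, 80, replace = TRUE), collapse = "")),
    taxon_bin = "NonPhageVirus", species = "x", genome_type = "ssRNA",
    family = "f", flags = "", stringsAsFactors = FALSE)
  hit <- search_homology(c(q = nt), db)
  expect_equal(hit$subject, "T1")
  expect_equal(hit$frame, "+1")
  expect_equal(hit$identity, 100)
  expect_equal(hit$coverage, 100)
})

test_that("seeded search equals the exhaustive Smith-Waterman oracle", {
  # instances <= 300 nt vs a 20-protein database; queries are diverged
  # fragments of database proteins (plus their reverse complements)
  set.seed(33)
  db <- data.frame(
    id = sprintf("P%02d", 1:20),
    seq = vapply(1:20, function(i)
      paste(sample(virowinnow:::AA20, sample(60:120, 1), replace = TRUE),
            collapse = ""), character(1)),
    taxon_bin = "NonPhageVirus", species = "x", genome_type = "ssRNA",
    family = "f", flags = "", stringsAsFactors = FALSE)
  queries <- character(0)
  for (i in 1:12) {
    src <- sample(20, 1)
    aa <- db$seq[src]
    from <- sample(seq_len(nchar(aa) - 30), 1)
    frag <- substr(aa, from, from + sample(20:min(60, nchar(aa) - from),
                                           1))
    frag <- virowinnow:::mutate_protein(frag, 0.15)
    nt <- virowinnow:::aa_to_codons(frag)
    if (i %% 3 == 0) nt <- virowinnow:::revcomp(nt)
    if (nchar(nt) > 300) nt <- substr(nt, 1, 300)
    queries[sprintf("q%02d", i)] <- nt
  }
  hits <- search_homology(queries, db)
  for (qn in names(queries)) {
    o <- oracle_best_hit(queries[[qn]], db)
    row <- hits[hits$query == qn, ]
    expect_equal(nrow(row), 1, label = qn)
    expect_equal(row$score, o$score, label = qn)
    expect_equal(row$subject, o$subject, label = qn)
    expect_equal(row$frame, o$frame, label = qn)
  }
})

test_that("binning applies the strict E threshold and removes phiX", {
  reads <- rand_reads_df(c("ACGT", "ACGT", "ACGT", "ACGT"))
  hits <- data.frame(
    query = c("r0001", "r0002", "r0003"),
    subject = c("A", "B", "C"),
    frame = "+1", score = 50, bit_score = 20,
    e_value = c(1e-5, 0.9e-5, 1e-9),
    identity = 90, coverage = 80,
    taxon_bin = c("NonPhageVirus", "Plant", "Phage"),
    species = c("v", "p", "Enterobacteria phage phiX174"),
    genome_type = "", family = "", flags = c("", "", "phiX"),
    stringsAsFactors = FALSE)
  b <- bin_reads(reads, hits, threshold = 1e-5)
  asg <- setNames(b$assignments$bin, b$assignments$read_id)
  # E exactly at the threshold is NOT tabulated (strict less-than)
  expect_equal(unname(asg["r0001"]), "unassigned")
  expect_equal(unname(asg["r0002"]), "Plant")
  # phiX removed: absent from the Phage bin, counted in the tally
  expect_equal(unname(asg["r0003"]), "phiX")
  expect_equal(b$bin_counts[["Phage"]], 0)
  expect_equal(b$phix_tally, 1)
  # no hit at all -> unassigned
  expect_equal(unname(asg["r0004"]), "unassigned")
  # exact partition
  expect_equal(sum(b$bin_counts) + b$phix_tally + b$unassigned,
               nrow(reads))
})

test_that("novel-virus reads bin as non-phage virus on simulated data", {
  cfg <- sim_config(reads_per_library = 500, host_genome_length = 20000,
                    seed = 21)
  refs <- build_references(cfg)
  sim <- simulate_reads(cfg, refs)
  hs <- subtract_host(sim$reads, refs$host)
  unm <- hs$unmatched
  hits <- search_homology(setNames(unm$seq, unm$id), refs$protein_db)
  b <- bin_reads(unm, hits)
  novel_ids <- sim$manifest$read_id[sim$manifest$taxon == "novel"]
  asg <- b$assignments
  got <- asg$bin[asg$read_id %in% novel_ids]
  expect_gte(mean(got == "NonPhageVirus"), 0.95)
  expect_equal(sum(b$bin_counts) + b$phix_tally + b$unassigned,
               nrow(unm))
})
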