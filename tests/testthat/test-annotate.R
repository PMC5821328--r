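test_that("ORF calling handles minimal and degenerate inputs", {
  orfs <- find_orfs("ATGAAATAA", min_length = 9)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$translation, "MK")
  expect_equal(orfs$start, 0)
  expect_equal(orfs$end, 9)
  expect_equal(nrow(find_orfs("CCCCCCCCCCCC", min_length = 6)), 0)
  # ORF without a stop runs to the last complete codon
  orfs2 <- find_orfs("CCATGAAAGGG", min_length = 9)
  expect_equal(orfs2$end - orfs2$start, 9)
  expect_equal(orfs2$translation, "MKG")
})

test_that("architecture classification distinguishes genome layouts", {
  set.seed(16)
  # single-ORF genome -> other, citing the ORF-count clause
  g1 <- paste0(virowinnow:::random_utr(20), virowinnow:::random_cds(900),
               virowinnow:::random_utr(20))
  a1 <- classify_architecture(g1)
  expect_equal(a1$class, "other")
  expect_false(a1$evidence$satisfied[a1$evidence$clause ==
                                       "two_major_orfs"])
  # a T-free interior is stop-free in every frame: > 2 major ORFs and
  # mutually overlapping -> other
  g2 <- paste0("ATG",
               paste(sample(virowinnow:::TFREE_CODONS, 400, TRUE),
                     collapse = ""), "TAA")
  a2 <- classify_architecture(g2)
  expect_equal(a2$class, "other")
  # the planted genome classifies dicistrovirus-like with ORFx
  refs <- build_references(sim_config(reads_per_library = 10,
                                      host_genome_length = 5000,
                                      seed = 16))
  a3 <- classify_architecture(refs$novel$seq)
  expect_equal(a3$class, "dicistrovirus-like")
  expect_true(a3$orfx)
  # invariant to 3' UTR padding beyond the minimum
  a4 <- classify_architecture(paste0(refs$novel$seq,
                                     virowinnow:::random_utr(500)))
  expect_equal(a4$class, "dicistrovirus-like")
  expect_equal(a4$orfx, a3$orfx)
})

test_that("domains are localised at their planted offsets", {
  refs <- build_references(sim_config(reads_per_library = 10,
                                      host_genome_length = 5000,
                                      seed = 17))
  truth <- refs$novel$truth
  orfs <- collapse_orfs(find_orfs(refs$novel$seq))
  dom <- locate_domains(orfs)
  expect_setequal(unique(dom$motif),
                  c("helicase", "peptidase", "RdRp", "capsid"))
  o1 <- which(orfs$start == truth$orf1_span[1] &
                orfs$end == truth$orf1_span[2])
  o2 <- which(orfs$start == truth$orf2_span[1] &
                orfs$end == truth$orf2_span[2])
  for (mn in c("helicase", "peptidase", "RdRp")) {
    row <- dom[dom$motif == mn & dom$orf_row == o1, ]
    expect_equal(nrow(row), 1, label = mn)
    expect_equal(row$aa_start,
                 truth$motif_aa_spans$orf1[[mn]][1], label = mn)
  }
  cap <- dom[dom$motif == "capsid" & dom$orf_row == o2, ]
  expect_equal(nrow(cap), 1)
  expect_equal(cap$aa_start, truth$motif_aa_spans$orf2$capsid[1])
  # every domain span lies inside its host ORF, every ORF inside the genome
  for (r in seq_len(nrow(dom))) {
    expect_gte(dom$nt_start[r], orfs$start[dom$orf_row[r]])
    expect_lte(dom$nt_end[r], orfs$end[dom$orf_row[r]])
  }
  expect_true(all(orfs$end <= nchar(refs$novel$seq)))
  # motif-free translation yields no domains
  none <- locate_domains(data.frame(start = 0, end = 90, frame = 1,
                                    length = 90,
                                    translation = strrep("K", 30)))
  expect_equal(nrow(none), 0)
})

test_that("polyA detection respects the terminal-run boundary", {
  set.seed(18)
  core <- paste0(rand_dna(50), "C")   # guarantee a non-A boundary
  expect_true(detect_polyA(paste0(core, strrep("A", 12))))
  expect_true(detect_polyA(paste0(core, strrep("A", 10))))
  expect_false(detect_polyA(paste0(core, strrep("A", 9))))
  expect_false(detect_polyA(paste0(core, "AC")))
})

test_that("strand accounting flags replication at the threshold", {
  expect_true(strand_accounting(c(rep("+", 900), rep("-", 100)))$replicative)
  expect_false(strand_accounting(rep("+", 1000))$replicative)
  expect_false(strand_accounting(c(rep("+", 10), rep("-", 4)))$replicative)
  expect_true(strand_accounting(c(rep("+", 10), rep("-", 5)))$replicative)
})

test_that("annotation is orientation-aware and exports GFF3", {
  refs <- build_references(sim_config(reads_per_library = 10,
                                      host_genome_length = 5000,
                                      seed = 19))
  g <- refs$novel$seq
  fwd <- annotate_genome(g, id = "fwd")
  rev <- annotate_genome(virowinnow:::revcomp(g), id = "rev")
  expect_equal(fwd$architecture$class, "dicistrovirus-like")
  expect_equal(rev$architecture$class, "dicistrovirus-like")
  expect_equal(rev$orientation, "-")
  expect_true(fwd$polyA && rev$polyA)
  # GFF3: 1-based inclusive coordinates, CDS + misc_feature + polyA_site
  feats <- annotation_features(fwd)
  path <- tempfile(fileext = ".gff3")
  write_gff3(feats, path)
  lines <- readLines(path)
  expect_equal(lines[1], "##gff-version 3")
  cds <- strsplit(grep("\tCDS\t", lines, value = TRUE)[1], "\t")[[1]]
  expect_equal(as.integer(cds[4]),
               fwd$architecture$majors$start[1] + 1L)
  expect_equal(as.integer(cds[5]), fwd$architecture$majors$end[1])
  expect_true(any(grepl("pfam_label=pfam00680", lines)))
  expect_true(any(grepl("polyA_site", lines)))
})
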