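#' Simulation configuration for a synthetic four-library metavirome
#'
#' Builds and validates the configuration for the synthetic read generator.
#' The defaults emulate the structure of the four pooled fire-ant RNA
#' libraries the winnowing pipeline was designed for: a dominant host
#' fraction, five known fire-ant viruses whose abundance varies by library,
#' one planted novel dicistrovirus present in every library, phiX and a
#' second phage as sequencing controls/bystanders, and plant / fungal /
#' bacterial / plant-virus dietary decoys. Abundances are fractions of
#' reads per library and every row must sum to 1.
#'
#' ORF lengths are given in nucleotides and include both the initiator ATG
#' and the stop codon; they must be multiples of 3. The intergenic region
#' must be a multiple of 3 so that the two major ORFs are in frame
#' (start positions congruent mod 3), and all untranslated regions must be
#' at least 10 nt.
#'
#' @param n_libraries number of libraries (default 4, labelled SAL_1..n).
#' @param reads_per_library reads simulated per library.
#' @param read_length read length in bases (single-end).
#' @param host_genome_length host reference length in bases.
#' @param known_virus_set data.frame with columns label, length,
#'   genome_type, family, replicating describing the known-virus genomes.
#' @param novel_virus list with elements orf1, orf2, orfx, utr5, igr, utr3,
#'   polya (lengths in nt).
#' @param abundance_matrix numeric matrix, one row per library, one column
#'   per source taxon; rows must sum to 1 (tolerance 1e-9).
#' @param minus_strand_fraction fraction of reads from replicating viruses
#'   drawn from the minus (replicative) strand, in [0, 1].
#' @param substitution_error_rate per-base substitution probability.
#' @param quality_median centre of the per-base Phred quality distribution.
#' @param seed integer seed; all generator draws derive from it.
#' @return object of class \code{vw_sim_config}.
#' @export
sim_config <- function(n_libraries = 4,
                       reads_per_library = 10000,
                       read_length = 150,
                       host_genome_length = 100000,
                       known_virus_set = default_known_viruses(),
                       novel_virus = list(orf1 = 1800, orf2 = 1200,
                                          orfx = 90, utr5 = 30, igr = 30,
                                          utr3 = 30, polya = 60),
                       abundance_matrix = default_abundance(n_libraries),
                       minus_strand_fraction = 0.1,
                       substitution_error_rate = 0.005,
                       quality_median = 30,
                       seed = 1) {
  cfg <- list(n_libraries = as.integer(n_libraries),
              reads_per_library = as.integer(reads_per_library),
              read_length = as.integer(read_length),
              host_genome_length = as.integer(host_genome_length),
              known_virus_set = known_virus_set,
              novel_virus = novel_virus,
              abundance_matrix = abundance_matrix,
              minus_strand_fraction = minus_strand_fraction,
              substitution_error_rate = substitution_error_rate,
              quality_median = quality_median,
              seed = as.integer(seed))
  cfg$libraries <- paste0("SAL_", seq_len(cfg$n_libraries))
  class(cfg) <- "vw_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default known-virus set (five fire-ant viruses, desk-scale lengths)
#' @return data.frame with one row per known virus.
#' @export
default_known_viruses <- function() {
  data.frame(
    label = c("SINV-1", "SINV-2", "SINV-3", "SINV-4", "SiDNV"),
    length = c(2400L, 2700L, 2100L, 2400L, 1800L),
    genome_type = c("ssRNA", "ssRNA", "ssRNA", "ssRNA", "ssDNA"),
    family = c("Dicistroviridae", "Unclassified", "Unclassified",
               "Unclassified", "Parvoviridae"),
    replicating = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default per-library abundance matrix
#'
#' Host-dominated libraries with library-varying known-virus load (the
#' survey found known-virus prevalence varying across regions), a planted
#' novel virus at 5 percent everywhere, and small decoy fractions. The
#' known-virus load is kept far below the real libraries' share so that
#' desk-scale assembly stays tractable; the published fractions are
#' exercised through the packaged printed-table fixtures instead.
#'
#' @param n_libraries number of libraries (rows); beyond 4 the first four
#'   rows are recycled.
#' @return matrix with rows summing to 1.
#' @export
default_abundance <- function(n_libraries = 4) {
  taxa <- c("host", "SINV-1", "SINV-2", "SINV-3", "SINV-4", "SiDNV",
            "novel", "phiX", "phage", "plant", "fungi", "bacteria",
            "plant_virus")
  base <- rbind(
    c(0.740, 0.040, 0.015, 0.007, 0.050, 0.003, 0.05, 0.015, 0.015,
      0.02, 0.02, 0.02, 0.005),
    c(0.740, 0.045, 0.020, 0.007, 0.040, 0.003, 0.05, 0.015, 0.015,
      0.02, 0.02, 0.02, 0.005),
    c(0.740, 0.030, 0.030, 0.007, 0.045, 0.003, 0.05, 0.015, 0.015,
      0.02, 0.02, 0.02, 0.005),
    c(0.740, 0.050, 0.020, 0.007, 0.035, 0.003, 0.05, 0.015, 0.015,
      0.02, 0.02, 0.02, 0.005)
  )
  m <- base[rep_len(seq_len(4), n_libraries), , drop = FALSE]
  dimnames(m) <- list(paste0("SAL_", seq_len(n_libraries)), taxa)
  m
}

validate_sim_config <- function(cfg) {
  nv <- cfg$novel_virus
  lens <- c(cfg$read_length, cfg$host_genome_length,
            cfg$known_virus_set$length, unlist(nv))
  if (any(lens <= 0)) stop("all lengths must be positive")
  if (nv$orf1 %% 3 != 0 || nv$orf2 %% 3 != 0 || nv$orfx %% 3 != 0)
    stop("ORF lengths must be multiples of 3")
  if (any(c(nv$utr5, nv$igr, nv$utr3) < 10))
    stop("UTR and intergenic lengths must be at least 10 nt")
  if (nv$igr %% 3 != 0)
    stop("intergenic length must be a multiple of 3 (in-frame ORFs)")
  if (nv$orf1 < 300 || nv$orf2 < 300)
    stop("major ORFs must be at least 300 nt to carry the domain motifs")
  if (nv$orfx < 60 || nv$orfx > 180 || nv$orfx + 4 > nv$orf2 - 6)
    stop("orfx length must be in [60, 180] and fit inside ORF2")
  if (nv$polya < 10) stop("polyA tail must be at least 10 nt")
  am <- cfg$abundance_matrix
  if (nrow(am) != cfg$n_libraries)
    stop("abundance_matrix must have one row per library")
  if (any(abs(rowSums(am) - 1) > 1e-9))
    stop("each abundance row must sum to 1 (tolerance 1e-9)")
  if (any(am < 0)) stop("abundances must be non-negative")
  msf <- cfg$minus_strand_fraction
  if (msf < 0 || msf > 1) stop("minus_strand_fraction must be in [0, 1]")
  invisible(cfg)
}

# ---------------------------------------------------------------------------
# Sequence construction helpers
# ---------------------------------------------------------------------------

BASES <- c("A", "C", "G", "T")
# codons without T can never spell a stop (all stops contain T) in any frame
TFREE_CODONS <- apply(expand.grid(c("A", "C", "G"), c("A", "C", "G"),
                                  c("A", "C", "G")), 1, paste, collapse = "")
ALL_CODONS <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# random DNA containing no ATG (used for UTRs so that no spurious upstream
# start codon extends a major ORF into an untranslated region)
random_utr <- function(n) {
  repeat {
    s <- random_dna(n)
    if (!grepl("ATG", s, fixed = TRUE)) return(s)
  }
}

# ATG + interior sense codons + TAA; length nt includes start and stop
random_cds <- function(len_nt) {
  stopifnot(len_nt %% 3 == 0, len_nt >= 9)
  n_int <- len_nt / 3 - 2
  paste0("ATG", paste(sample(SENSE_CODONS, n_int, replace = TRUE),
                      collapse = ""), "TAA")
}

# encode an amino-acid string as codons (first listed codon per residue,
# deterministic)
aa_to_codons <- local({
  tab <- NULL
  function(aa) {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- vapply(unique(gc), function(a) names(gc)[gc == a][1],
                     character(1))
    }
    paste(tab[strsplit(aa, "")[[1]]], collapse = "")
  }
})

# substitute bases at given 1-based positions with a different base
mutate_dna <- function(seq, positions) {
  if (!length(positions)) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# mutate an amino-acid string at `rate`, sparing `spare` (list of c(start,
# end) 1-based aa spans, e.g. planted motifs)
mutate_protein <- function(aa, rate, spare = list()) {
  chars <- strsplit(aa, "")[[1]]
  keep <- rep(FALSE, length(chars))
  for (sp in spare) keep[sp[1]:sp[2]] <- TRUE
  hit <- which(runif(length(chars)) < rate & !keep)
  for (p in hit) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  paste(chars, collapse = "")
}

# ---------------------------------------------------------------------------
# Reference construction
# ---------------------------------------------------------------------------

#' Build the synthetic reference set
#'
#' Deterministically (from \code{config$seed}) generates the host genome,
#' the known-virus genomes, the planted novel dicistrovirus genome, phage
#' and decoy sequences, and the taxon-labelled protein database used by the
#' translated homology search. Draw order is fixed: host genome, known
#' viruses (in table order), novel genome, phiX, phage, decoy transcript
#' pools (plant, fungi, bacteria), plant virus, novel-virus relatives,
#' remaining decoy proteins.
#'
#' The novel genome satisfies the dicistrovirus architecture contract of
#' the annotation module by construction: two in-frame non-overlapping
#' major ORFs separated and flanked by untranslated regions, a short
#' overlapping ORF (ORFx) in a different frame at the 5' end of ORF2, and
#' a 3' polyA tail. Helicase, peptidase and RdRp motifs are planted into
#' ORF1 and a capsid motif into ORF2 at recorded offsets. The protein
#' database contains diverged (70 percent identity, motifs spared)
#' relatives of the novel ORFs labelled with dicistrovirus species names,
#' so that reads from the planted virus bin as non-phage virus without the
#' novel genome itself being present in the database.
#'
#' @param config a [sim_config()].
#' @return object of class \code{vw_references}: list with elements
#'   \code{host}, \code{known} (named character), \code{known_meta},
#'   \code{novel} (list: seq, truth), \code{sources} (named character,
#'   one sequence per simulated taxon), \code{protein_db} (data.frame),
#'   and \code{config}.
#' @export
build_references <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  nv <- config$novel_virus

  host <- random_dna(config$host_genome_length)
  # embed three stop-free coding windows so residual (unsubtracted) host
  # reads can still find an "Animal" protein
  host_prot <- character(0)
  host_cds_at <- floor(config$host_genome_length * c(0.2, 0.5, 0.8))
  for (i in seq_along(host_cds_at)) {
    cds <- random_cds(450)
    p <- host_cds_at[i]
    host <- paste0(substr(host, 1, p), cds,
                   substr(host, p + 451, nchar(host)))
    host <- substr(host, 1, config$host_genome_length)
    host_prot[paste0("HOSTP", i)] <- sub("\\*$", "", translate_f1(cds))
  }

  kv <- config$known_virus_set
  known <- character(0)
  known_prot <- list()
  for (i in seq_len(nrow(kv))) {
    glen <- kv$length[i]
    orf_len <- (glen - 45) %/% 3 * 3
    u5 <- random_utr(20)
    cds <- random_cds(orf_len)
    u3 <- random_utr(glen - 20 - orf_len)
    known[kv$label[i]] <- paste0(u5, cds, u3)
    known_prot[[kv$label[i]]] <- sub("\\*$", "", translate_f1(cds))
  }

  novel <- build_novel_genome(nv)

  phix_cds <- random_cds(1200)
  phix <- paste0(random_utr(150), phix_cds, random_utr(150))
  phage_cds <- random_cds(1200)
  phage <- paste0(random_utr(150), phage_cds, random_utr(150))

  pools <- list()
  pool_prot <- list()
  for (taxon in c("plant", "fungi", "bacteria")) {
    tr <- replicate(3, random_cds(600))
    pools[[taxon]] <- paste(tr, collapse = "")
    pool_prot[[taxon]] <- vapply(tr, function(x)
      sub("\\*$", "", translate_f1(x)), character(1), USE.NAMES = FALSE)
  }

  pv_cds <- random_cds(900)
  plant_virus <- paste0(random_utr(20), pv_cds, random_utr(20))

  # diverged relatives of the novel ORFs (db homologs for the novel virus)
  orf1_aa <- novel$truth$orf1_aa
  orf2_aa <- novel$truth$orf2_aa
  rel1 <- mutate_protein(orf1_aa, 0.30, spare = novel$truth$motif_aa_spans$orf1)
  rel2 <- mutate_protein(orf2_aa, 0.30, spare = novel$truth$motif_aa_spans$orf2)

  random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                      collapse = "")
  arch_prot <- replicate(2, random_protein(80))
  prot_prot <- replicate(2, random_protein(80))

  db <- rbind(
    data.frame(id = names(host_prot), seq = unname(host_prot),
               taxon_bin = "Animal", species = "Solenopsis invicta",
               genome_type = "", family = "", flags = ""),
    data.frame(id = paste0("KV", seq_len(nrow(kv))),
               seq = unlist(known_prot, use.names = FALSE),
               taxon_bin = "NonPhageVirus", species = kv$label,
               genome_type = kv$genome_type, family = kv$family, flags = ""),
    data.frame(id = c("REL1", "REL2"), seq = c(rel1, rel2),
               taxon_bin = "NonPhageVirus",
               species = c("Israeli acute paralysis virus",
                           "Acute bee paralysis virus"),
               genome_type = "ssRNA", family = "Dicistroviridae",
               flags = ""),
    data.frame(id = "PHIX1", seq = sub("\\*$", "", translate_f1(phix_cds)),
               taxon_bin = "Phage",
               species = "Enterobacteria phage phiX174",
               genome_type = "ssDNA", family = "Microviridae",
               flags = "phiX"),
    data.frame(id = "PHG1", seq = sub("\\*$", "", translate_f1(phage_cds)),
               taxon_bin = "Phage", species = "Microvirus sp.",
               genome_type = "ssDNA", family = "Microviridae", flags = ""),
    data.frame(id = paste0("PLANT", 1:3), seq = pool_prot$plant,
               taxon_bin = "Plant", species = "Glycine max",
               genome_type = "", family = "", flags = ""),
    data.frame(id = paste0("FUNGI", 1:3), seq = pool_prot$fungi,
               taxon_bin = "Fungi", species = "Beauveria bassiana",
               genome_type = "", family = "", flags = ""),
    data.frame(id = paste0("BACT", 1:3), seq = pool_prot$bacteria,
               taxon_bin = "Bacteria", species = "Escherichia coli",
               genome_type = "", family = "", flags = ""),
    data.frame(id = "PV1", seq = sub("\\*$", "", translate_f1(pv_cds)),
               taxon_bin = "NonPhageVirus",
               species = "Tomato bushy stunt virus",
               genome_type = "ssRNA", family = "Tombusviridae",
               flags = "plant_virus"),
    data.frame(id = paste0("ARCH", 1:2), seq = arch_prot,
               taxon_bin = "Archaea", species = "Methanococcus sp.",
               genome_type = "", family = "", flags = ""),
    data.frame(id = paste0("PROT", 1:2), seq = prot_prot,
               taxon_bin = "Protist", species = "Leishmania sp.",
               genome_type = "", family = "", flags = "")
  )
  rownames(db) <- NULL

  sources <- c(host = host, known,
               novel = novel$seq, phiX = phix, phage = phage,
               plant = pools$plant, fungi = pools$fungi,
               bacteria = pools$bacteria, plant_virus = plant_virus)

  refs <- list(host = host, known = known, known_meta = kv, novel = novel,
               sources = sources, protein_db = db, config = config)
  class(refs) <- "vw_references"
  refs
}

# Construct the planted dicistrovirus genome. Layout (0-based, half-open):
#   [0, utr5)                          5' UTR (no ATG)
#   [utr5, utr5+orf1)                  ORF1  ATG ... TAA, motifs planted
#   [.., +igr)                         intergenic (no ATG), igr %% 3 == 0
#   [S2, S2+orf2)                      ORF2  in frame with ORF1
#   [S2+4, S2+4+orfx)                  ORFx  overlapping ORF2, frame +1
#   [.., +utr3)                        3' UTR (no ATG)
#   [.., +polya)                       polyA tail
build_novel_genome <- function(nv) {
  motifs <- motif_library()
  plant_into <- function(interior, motif_aa, at) {
    # `at` is a codon index into the interior (1-based); returns new
    # interior and the aa span within the full ORF translation (incl. ATG)
    n_aa <- nchar(motif_aa)
    codons <- substring(interior, seq(1, nchar(interior) - 2, 3),
                        seq(3, nchar(interior), 3))
    codons[at:(at + n_aa - 1)] <-
      substring(aa_to_codons(motif_aa), seq(1, n_aa * 3 - 2, 3),
                seq(3, n_aa * 3, 3))
    list(interior = paste(codons, collapse = ""),
         aa_span = c(at + 1, at + n_aa))  # +1 for the initiator M
  }
  exemplar <- function(name) {
    m <- motifs[[name]]
    paste(vapply(m$allowed, function(a)
      if (is.null(a)) "A" else a[1], character(1)), collapse = "")
  }

  # ORF1 with helicase, peptidase, RdRp (5' to 3' order)
  n1 <- nv$orf1 / 3 - 2
  int1 <- paste(sample(SENSE_CODONS, n1, replace = TRUE), collapse = "")
  at_hel <- max(2, round(0.10 * n1))
  at_pep <- round(0.45 * n1)
  at_rdrp <- round(0.75 * n1)
  p <- plant_into(int1, exemplar("helicase"), at_hel)
  hel_span <- p$aa_span
  p <- plant_into(p$interior, exemplar("peptidase"), at_pep)
  pep_span <- p$aa_span
  p <- plant_into(p$interior, exemplar("RdRp"), at_rdrp)
  rdrp_span <- p$aa_span
  orf1 <- paste0("ATG", p$interior, "TAA")

  # ORF2 with the overlapping ORFx and a capsid motif
  n2 <- nv$orf2 / 3 - 2
  s_stop <- nv$orfx + 1          # 0-based nt offset of the ORFx stop in ORF2
  k1 <- (s_stop - 1) / 3         # ORF2 codon index (0-based) carrying "CTA"
  codons2 <- sample(SENSE_CODONS, n2, replace = TRUE)
  codons2[1] <- "AAT"            # ...A ATG... puts an ATG at offset 4
  codons2[2] <- "GGC"
  if (k1 > 3) codons2[3:(k1 - 1)] <-
      sample(TFREE_CODONS, k1 - 3, replace = TRUE)
  codons2[k1] <- "CTA"           # plants T,A,A at nt s_stop..s_stop+2
  codons2[k1 + 1] <- "AAC"
  int2 <- paste(codons2, collapse = "")
  at_cap <- min(n2 - 12, k1 + 12)
  p2 <- plant_into(int2, exemplar("capsid"), at_cap)
  cap_span <- p2$aa_span
  orf2 <- paste0("ATG", p2$interior, "TAA")

  utr5 <- random_utr(nv$utr5)
  igr <- random_utr(nv$igr)
  utr3 <- random_utr(nv$utr3)
  seq <- paste0(utr5, orf1, igr, orf2, utr3,
                strrep("A", nv$polya))

  s1 <- nv$utr5
  s2 <- nv$utr5 + nv$orf1 + nv$igr
  truth <- list(
    orf1_span = c(s1, s1 + nv$orf1),
    orf2_span = c(s2, s2 + nv$orf2),
    orfx_span = c(s2 + 4, s2 + 4 + nv$orfx),
    orf1_aa = sub("\\*$", "", translate_f1(orf1)),
    orf2_aa = sub("\\*$", "", translate_f1(orf2)),
    motif_aa_spans = list(
      orf1 = list(helicase = hel_span, peptidase = pep_span,
                  RdRp = rdrp_span),
      orf2 = list(capsid = cap_span)
    )
  )
  list(seq = seq, truth = truth)
}

#' Write reference FASTA files
#'
#' Protein deflines use the pipe-delimited syntax
#' \code{id|taxon_bin|species|genome_type|family|flags} with flags
#' semicolon-separated (e.g. \code{phiX}, \code{plant_virus}).
#'
#' @param refs a [build_references()] object.
#' @param dir output directory (created if needed).
#' @return named list of file paths.
#' @export
write_references <- function(refs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    host = file.path(dir, "host.fasta"),
    known = file.path(dir, "known_viruses.fasta"),
    proteins = file.path(dir, "proteins.fasta"),
    novel = file.path(dir, "novel_genome_truth.fasta")
  )
  write_fasta(c(host = refs$host), paths$host)
  write_fasta(refs$known, paths$known)
  db <- refs$protein_db
  deflines <- paste(db$id, db$taxon_bin, db$species, db$genome_type,
                    db$family, db$flags, sep = "|")
  write_fasta(setNames(db$seq, deflines), paths$proteins)
  write_fasta(c(novel_truth = refs$novel$seq), paths$novel)
  paths
}

#' Parse a taxon-labelled protein database FASTA
#'
#' @param path FASTA written with the defline syntax of
#'   [write_references()].
#' @return data.frame with columns id, seq, taxon_bin, species,
#'   genome_type, family, flags.
#' @export
read_protein_db <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  # strsplit drops the trailing empty field (empty flags); pad back to 6
  parts <- lapply(parts, function(p) if (length(p) == 5) c(p, "") else p)
  bad <- lengths(parts) != 6
  if (any(bad)) stop("malformed protein defline: ", names(seqs)[bad][1])
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- c("id", "taxon_bin", "species", "genome_type", "family",
                 "flags")
  df$seq <- unname(seqs)
  df[c("id", "seq", "taxon_bin", "species", "genome_type", "family",
       "flags")]
}

# ---------------------------------------------------------------------------
# Read simulation
# ---------------------------------------------------------------------------

#' Simulate per-library reads with a ground-truth manifest
#'
#' Per-library taxon read counts are a multinomial draw from the library's
#' abundance row. For replicating (ssRNA virus) taxa a
#' \code{minus_strand_fraction} of reads is reverse-complemented and
#' flagged minus-strand in the manifest. Per-base qualities are a
#' discretised normal centred on \code{quality_median} (sd 4, clipped to
#' [2, 40]); substitution errors are applied at the configured rate.
#' Draws use seed \code{config$seed + 1} so that reference building and
#' read simulation are independently reproducible; within the run the
#' order is: per library, per taxon (abundance column order): counts,
#' starts, strand flags, error counts/positions/bases, qualities.
#'
#' @param config a [sim_config()].
#' @param refs matching [build_references()] output.
#' @return list with elements \code{reads} (data.frame id, seq, qual,
#'   library) and \code{manifest} (data.frame read_id, library, taxon,
#'   genome, strand, start).
#' @export
simulate_reads <- function(config, refs) {
  validate_sim_config(config)
  if (!identical(refs$config$seed, config$seed))
    stop("references were built with a different seed")
  set.seed(derive_seed(config$seed, 1))

  am <- config$abundance_matrix
  taxa <- colnames(am)
  replicating <- replicating_taxa(config)
  rl <- config$read_length

  all_reads <- vector("list", config$n_libraries)
  all_manifest <- vector("list", config$n_libraries)
  for (li in seq_len(config$n_libraries)) {
    lib <- config$libraries[li]
    counts <- as.integer(rmultinom(1, config$reads_per_library, am[li, ]))
    recs <- vector("list", length(taxa))
    for (ti in seq_along(taxa)) {
      n <- counts[ti]
      if (n == 0) next
      taxon <- taxa[ti]
      src <- refs$sources[[taxon]]
      L <- nchar(src)
      len <- min(rl, L)
      starts <- sample.int(L - len + 1L, n, replace = TRUE) - 1L
      minus <- if (taxon %in% replicating)
        runif(n) < config$minus_strand_fraction else rep(FALSE, n)
      seqs <- substring(src, starts + 1L, starts + len)
      nmut <- rbinom(n, len, config$substitution_error_rate)
      for (r in which(nmut > 0)) {
        seqs[r] <- mutate_dna(seqs[r], sample.int(len, nmut[r]))
      }
      if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
      q <- matrix(pmin(40L, pmax(2L, as.integer(round(
        rnorm(n * len, config$quality_median, 4))))), nrow = n)
      quals <- phred_to_qual(split(q, row(q)))
      recs[[ti]] <- data.frame(
        taxon = taxon, genome = taxon,
        strand = ifelse(minus, "-", "+"), start = starts,
        seq = seqs, qual = quals, stringsAsFactors = FALSE
      )
    }
    recs <- do.call(rbind, recs)
    recs$library <- lib
    recs$read_id <- sprintf("%s_%06d", lib, seq_len(nrow(recs)))
    all_reads[[li]] <- data.frame(id = recs$read_id, seq = recs$seq,
                                  qual = recs$qual, library = lib,
                                  stringsAsFactors = FALSE)
    all_manifest[[li]] <- recs[c("read_id", "library", "taxon", "genome",
                                 "strand", "start")]
  }
  list(reads = do.call(rbind, all_reads),
       manifest = do.call(rbind, all_manifest))
}

# taxa treated as actively replicating (ssRNA viruses): these can emit
# minus-strand (replicative-intermediate) reads
replicating_taxa <- function(config) {
  kv <- config$known_virus_set
  c(kv$label[kv$replicating], "novel", "plant_virus")
}

#' Write simulated reads and manifest to a directory
#' @param sim [simulate_reads()] output.
#' @param dir output directory.
#' @return named list of file paths.
#' @export
write_simulated <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  libs <- unique(sim$reads$library)
  fastqs <- setNames(file.path(dir, paste0(libs, ".fastq")), libs)
  for (lib in libs) {
    write_fastq(sim$reads[sim$reads$library == lib, ], fastqs[[lib]])
  }
  manifest <- file.path(dir, "manifest.tsv")
  write_tsv(sim$manifest, manifest)
  list(fastq = fastqs, manifest = manifest)
}
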