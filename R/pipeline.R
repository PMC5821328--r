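#' Pipeline configuration
#'
#' Bundles the stage parameters of the full winnowing pipeline with the
#' simulation configuration. Unknown parameter names are rejected;
#' thresholds are validated against their documented ranges.
#'
#' @param sim a [sim_config()] describing the synthetic input.
#' @param ... stage parameter overrides; see Details.
#'
#' @details Stage parameters and defaults: \code{min_median} (20) and
#' \code{min_read_len} (25) for quality filtering; \code{host_k} (21) and
#' \code{host_T} (5) for k-mer host subtraction; \code{evalue} (1e-5)
#' homology threshold; \code{min_overlap} (40), \code{overlap_identity}
#' (90) and \code{overlap_k} (12) for assembly; \code{known_identity}
#' (95) and \code{known_aln_len} (50) for known-virus matching;
#' \code{exclusion_min_len} (100); \code{orf_min} (60), \code{major_min}
#' (600), \code{utr_min} (10), \code{orfx_window} (200),
#' \code{polya_min_run} (10) and \code{n_min_minus} (5) for annotation;
#' \code{annotate_top} (3) prospects annotated; \code{verbose} (FALSE).
#'
#' @return object of class \code{vw_pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(), ...) {
  cfg <- list(
    min_median = 20, min_read_len = 25,
    host_k = 21, host_T = 5,
    evalue = 1e-5,
    min_overlap = 40, overlap_identity = 90, overlap_k = 12,
    known_identity = 95, known_aln_len = 50,
    exclusion_min_len = 100,
    orf_min = 60, major_min = 600, utr_min = 10, orfx_window = 200,
    polya_min_run = 10, n_min_minus = 5,
    annotate_top = 3,
    verbose = FALSE
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(cfg))
  if (length(unknown)) stop("unknown pipeline parameter(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, extra)
  stopifnot(cfg$min_median >= 0, cfg$min_read_len >= 1,
            cfg$host_k >= 4, cfg$host_T >= 1,
            cfg$evalue > 0,
            cfg$min_overlap >= cfg$overlap_k,
            cfg$overlap_identity > 50, cfg$overlap_identity <= 100,
            cfg$known_identity > 50, cfg$known_identity <= 100,
            cfg$exclusion_min_len >= 1, cfg$n_min_minus >= 1)
  cfg$sim <- sim
  class(cfg) <- "vw_pipeline_config"
  cfg
}

#' Run the full winnowing pipeline on synthetic data
#'
#' Executes the stages in the published order: read simulation, quality
#' filter, host subtraction, translated homology binning (with phiX
#' removal), assembly of the non-phage-virus bin, known-virus matching,
#' exclusion rules, library-representation classification and ranking,
#' and annotation of the top prospects (with replicative-strand
#' accounting from the ground-truth manifest). Every conservation tally
#' is recorded in the run summary; a stage failure aborts with the stage
#' name.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory; created. NULL skips all file output.
#' @return list (invisibly written as \code{summary.json}): per-stage
#'   tallies, prospect table, annotations, and conservation checks.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  logf <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    logf <- file.path(out_dir, "log.txt")
  }
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(fmt, ...))
    if (!is.null(logf)) cat(line, "\n", file = logf, append = TRUE)
    if (isTRUE(config$verbose)) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  scfg <- config$sim
  refs <- stage("simulate", build_references(scfg))
  sim <- stage("simulate", simulate_reads(scfg, refs))
  say("simulate", "%d reads in %d libraries", nrow(sim$reads),
      scfg$n_libraries)

  qf <- stage("quality_filter",
              quality_filter(sim$reads, config$min_median,
                             config$min_read_len))
  say("quality_filter", "%d retained / %d input", qf$tally["retained"],
      qf$tally["input"])

  hs <- stage("subtract_host",
              subtract_host(qf$retained, refs$host, config$host_k,
                            config$host_T))
  say("subtract_host", "%d host-matched, %d unmatched",
      hs$tally["matched"], hs$tally["unmatched"])

  unm <- hs$unmatched
  hits <- stage("homology", search_homology(
    setNames(unm$seq, unm$id), refs$protein_db))
  bins <- stage("homology", bin_reads(unm, hits, config$evalue))
  say("homology", "bins: %s; phiX removed %d; unassigned %d",
      paste(names(bins$bin_counts), bins$bin_counts, collapse = " ",
            sep = "="),
      bins$phix_tally, bins$unassigned)

  npv_ids <- bins$assignments$read_id[bins$assignments$bin ==
                                        "NonPhageVirus"]
  npv <- unm[unm$id %in% npv_ids, , drop = FALSE]
  asm <- stage("assembly", greedy_assemble(
    npv, libraries = scfg$libraries, min_overlap = config$min_overlap,
    min_identity = config$overlap_identity, k = config$overlap_k))
  say("assembly", "%d contigs from %d reads; %d leftover singletons",
      nrow(asm$contigs), nrow(npv), length(asm$leftovers))

  left <- npv[npv$id %in% asm$leftovers, , drop = FALSE]
  all_seqs <- c(setNames(asm$contigs$seq, asm$contigs$id),
                setNames(left$seq, left$id))
  km <- stage("known_matching", match_known_viruses(
    all_seqs, refs$known, config$known_identity, config$known_aln_len))
  # per-species totals in read (singleton) units
  known_reads <- setNames(integer(length(refs$known)), names(refs$known))
  if (nrow(km$matched)) {
    w <- ifelse(km$matched$id %in% asm$contigs$id,
                asm$contigs$n_reads[match(km$matched$id, asm$contigs$id)],
                1L)
    agg <- tapply(w, km$matched$species, sum)
    known_reads[names(agg)] <- as.integer(agg)
  }
  say("known_matching", "%d sequences matched known viruses (%d reads)",
      nrow(km$matched), sum(known_reads))

  unmatched_seqs <- all_seqs[km$unmatched]
  items <- data.frame(id = names(unmatched_seqs),
                      length = nchar(unmatched_seqs),
                      stringsAsFactors = FALSE)
  rehits <- stage("exclusions", if (length(unmatched_seqs))
    search_homology(unmatched_seqs, refs$protein_db) else empty_hits())
  exc <- stage("exclusions", apply_exclusions(
    items, rehits, config$evalue, config$exclusion_min_len))
  say("exclusions", "retained %d of %d", exc$tally["retained"],
      exc$tally["input"])

  ret_contigs <- exc$retained[exc$retained$id %in% asm$contigs$id, ,
                              drop = FALSE]
  prospects <- NULL
  if (nrow(ret_contigs)) {
    ct <- asm$contigs[match(ret_contigs$id, asm$contigs$id), ,
                      drop = FALSE]
    tab <- data.frame(id = ct$id, size = ct$length,
                      ct[, scfg$libraries, drop = FALSE],
                      species = ret_contigs$species,
                      e_value = ret_contigs$e_value,
                      coverage = ret_contigs$coverage,
                      identity = ret_contigs$identity,
                      genome_type = ret_contigs$genome_type,
                      family = ret_contigs$family,
                      check.names = FALSE, stringsAsFactors = FALSE)
    prospects <- stage("classify_and_rank",
                       classify_and_rank(tab, scfg$libraries))
  }
  say("classify_and_rank", "%d prospect contigs, %d high-likelihood",
      NROW(prospects), sum(prospects$high_likelihood %||% FALSE))

  annotations <- list()
  if (!is.null(prospects) && nrow(prospects)) {
    top <- head(prospects$id, config$annotate_top)
    for (cid in top) {
      memb <- asm$members$read_id[asm$members$contig_id == cid]
      strands <- sim$manifest$strand[match(memb, sim$manifest$read_id)]
      annotations[[cid]] <- stage("annotate", annotate_genome(
        asm$contigs$seq[asm$contigs$id == cid], id = cid,
        min_orf = config$orf_min, strands = strands,
        n_min = config$n_min_minus,
        major_min = config$major_min, utr_min = config$utr_min,
        orfx_window = config$orfx_window))
    }
  }

  fractions <- summarize_fractions(bins$bin_counts, known_reads,
                                   bins$phix_tally, bins$unassigned)

  conservation <- list(
    quality = unname(qf$tally["retained"] + nrow(qf$rejected)) ==
      nrow(sim$reads),
    host = unname(hs$tally["matched"] + hs$tally["unmatched"]) ==
      nrow(qf$retained),
    bins = unname(sum(bins$bin_counts) + bins$phix_tally +
                    bins$unassigned) == nrow(unm),
    assembly = sum(asm$contigs$n_reads) + length(asm$leftovers) ==
      nrow(npv),
    exclusions = unname(exc$tally["retained"] + sum(exc$tally[
      c("short", "no_match", "non_virus", "plant_virus")])) ==
      length(km$unmatched)
  )
  if (!all(unlist(conservation)))
    stop("conservation invariant violated: ",
         paste(names(conservation)[!unlist(conservation)],
               collapse = ", "))

  summary <- list(
    seed = scfg$seed,
    tallies = list(quality = as.list(qf$tally), host = as.list(hs$tally),
                   bins = as.list(bins$bin_counts),
                   phix = bins$phix_tally, unassigned = bins$unassigned,
                   known_reads = as.list(known_reads),
                   exclusions = as.list(exc$tally)),
    conservation = conservation,
    n_contigs = nrow(asm$contigs),
    runtime_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  result <- list(config = config, refs = refs, sim = sim, quality = qf,
                 host = hs, hits = hits, bins = bins, assembly = asm,
                 known = km, exclusions = exc, prospects = prospects,
                 annotations = annotations, fractions = fractions,
                 summary = summary)
  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  say("done", "%.1f s", summary$runtime_sec)
  invisible(result)
}

write_run_outputs <- function(res, out_dir) {
  write_references(res$refs, file.path(out_dir, "references"))
  write_simulated(res$sim, file.path(out_dir, "reads"))
  unm <- res$host$unmatched
  write_fasta(setNames(unm$seq, unm$id),
              file.path(out_dir, "host_unmatched.fasta"))
  write_tsv(res$hits, file.path(out_dir, "homology_hits.tsv"))
  write_tsv(res$bins$assignments, file.path(out_dir, "bins.tsv"))
  if (nrow(res$assembly$contigs)) {
    write_fasta(setNames(res$assembly$contigs$seq, res$assembly$contigs$id),
                file.path(out_dir, "contigs.fasta"))
    write_tsv(res$assembly$members, file.path(out_dir, "membership.tsv"))
  }
  if (!is.null(res$prospects)) {
    write_tsv(res$prospects, file.path(out_dir, "prospects.tsv"))
    write_prospect_table(res$prospects,
                         file.path(out_dir, "table2_style.tsv"),
                         res$config$sim$libraries)
  }
  write_tsv(res$fractions, file.path(out_dir, "fractions.tsv"))
  for (cid in names(res$annotations)) {
    ann <- res$annotations[[cid]]
    write_gff3(annotation_features(ann),
               file.path(out_dir, paste0(cid, ".gff3")))
    jsonlite::write_json(
      list(id = ann$id, class = ann$architecture$class,
           orientation = ann$orientation, orfx = ann$architecture$orfx,
           polyA = ann$polyA, replicative = ann$replicative,
           plus_strand_reads = ann$plus_strand_reads,
           minus_strand_reads = ann$minus_strand_reads,
           evidence = ann$architecture$evidence,
           domains = ann$domains),
      file.path(out_dir, paste0(cid, "_evidence.json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Render a human-readable report for a pipeline run directory
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param file connection or path for the report ("" prints to stdout).
#' @return the report lines, invisibly.
#' @export
report_run <- function(run_dir, file = "") {
  if (!dir.exists(run_dir)) stop("run directory not found: ", run_dir)
  out <- character(0)
  emit <- function(...) out <<- c(out, sprintf(...))
  s <- jsonlite::read_json(file.path(run_dir, "summary.json"),
                           simplifyVector = TRUE)
  emit("Winnowing run summary (seed %s)", s$seed)
  emit("  reads in: %s; quality-retained: %s; host-unmatched: %s",
       s$tallies$quality$input, s$tallies$quality$retained,
       s$tallies$host$unmatched)
  fr <- read_tsv(file.path(run_dir, "fractions.tsv"))
  emit("Taxonomic fractions (numerator/denominator = percent):")
  for (i in seq_len(nrow(fr))) {
    emit("  %-28s %8s / %-8s = %s%%", fr$label[i], fr$numerator[i],
         fr$denominator[i], fr$percent[i])
  }
  pf <- file.path(run_dir, "prospects.tsv")
  if (file.exists(pf)) {
    pr <- read_tsv(pf)
    emit("Viral prospects (%d):", nrow(pr))
    for (i in seq_len(nrow(pr))) {
      emit("  #%d %s  %d singletons  %s  %d nt  %s%s", pr$rank[i],
           pr$id[i], pr$total[i], pr$representation_class[i], pr$size[i],
           pr$species[i],
           if (isTRUE(pr$high_likelihood[i]))
             "  [high likelihood viral prospect]" else "")
    }
  } else {
    emit("Viral prospects: none")
  }
  ev <- list.files(run_dir, pattern = "_evidence\\.json$",
                   full.names = TRUE)
  for (f in ev) {
    e <- jsonlite::read_json(f, simplifyVector = TRUE)
    emit("Annotation %s: %s; ORFx=%s polyA=%s replicative=%s (+%s/-%s)",
         e$id, e$class, e$orfx, e$polyA, e$replicative,
         e$plus_strand_reads, e$minus_strand_reads)
  }
  writeLines(out, file)
  invisible(out)
}
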