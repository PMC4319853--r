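# Pipeline orchestration: simulate -> clean -> annotate -> discover ->
# isomir -> targets -> de -> report, every stage writing deterministic
# TSV/FASTA outputs into a run directory.

#' Default pipeline configuration
#'
#' Thresholds default to the study's stated values where given (length
#' bounds 15/30, <= 2 mismatches for conserved identification, MFE <=
#' -18, mature read support > 5, <= 3 nt terminal divergence, G-U = 0.5
#' mismatch, energy ratio >= 0.75, adjusted p < 0.01, |log2fc| > 1);
#' remaining keys are repo defaults for the simulator and cleaning rules.
#'
#' @return named list of configuration values
#' @export
defaultConfig <- function() {
  list(
    seed = 42L, out_dir = "pomir_run",
    depth_ck = 1e5, depth_tr = 1e5,
    n_transcripts = 24L, n_planted = 30L, n_families = 12L, n_ncrna = 8L,
    n_target_sites = 8L, isomir_rate = 1,
    adaptor3 = .SIM_ADAPTOR3, adaptor5 = .SIM_ADAPTOR5,
    min_len = 15L, max_len = 30L, polya_frac = 0.8, min_mean_q = 20,
    mismatches = 2L,
    flank = 150L, mfe_max = -18, max_bulge = 3L, min_reads = 6L,
    max_terminal = 3L, tail_max = 3L,
    max_mismatch_target = 4, max_score_1_12 = 2.5, mfe_ratio_min = 0.75,
    pseudo_tpm = 0.01, p_thresh = 0.01, lfc_thresh = 1)
}

#' Validate a pipeline configuration
#'
#' Fills missing keys from \code{defaultConfig()}; unknown keys are
#' rejected.
#'
#' @param config named list of overrides
#' @return complete validated configuration list
#' @export
validateConfig <- function(config = list()) {
  def <- defaultConfig()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  def[names(config)] <- config
  def
}

#' Write / read a configuration as YAML
#'
#' @param config configuration list
#' @param path YAML file path
#' @return path (write) or validated configuration (read)
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) validateConfig(yaml::read_yaml(path))

# derive conserved-representative precursors by excising and evaluating
# hairpin windows around the representatives' perfect hits
.conservedPrecursors <- function(tempDb, transcriptome, flank, mfeMax,
                                 maxBulge) {
  empty <- data.frame(id = character(), precursor = character(),
                      mature = character(), family = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(tempDb)) return(empty)
  repLib <- TagLibrary(tempDb$sequence, rep(1L, nrow(tempDb)), "reps")
  hits <- mapPerfect(repLib, transcriptome)
  wins <- exciseCandidates(hits, transcriptome, flank = flank)
  if (!nrow(wins)) return(empty)
  ev <- do.call(rbind, lapply(seq_len(nrow(wins)), function(i)
    evaluateCandidate(wins$window[i], wins$tag[i], mfeMax = mfeMax,
                      maxBulge = maxBulge)))
  cand <- cbind(wins[, c("tag", "transcript", "start", "end", "strand")], ev)
  cand <- cand[cand$verdict, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(cand$tag, cand$mfe, cand$transcript, cand$start), ,
               drop = FALSE]
  cand <- cand[!duplicated(cand$tag), , drop = FALSE]
  fam <- tempDb$family[match(cand$tag, tempDb$sequence)]
  data.frame(id = paste0("pre-", fam), precursor = cand$window,
             mature = cand$tag, family = fam, stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Simulates the two libraries from the seeded generator, then runs
#' cleaning, annotation, conserved quantification, novel-miRNA
#' discovery, isomiR cataloguing, target prediction, differential
#' expression and reporting. Every stage writes its tables under
#' \code{config$out_dir}; rerunning with the same configuration
#' reproduces every output byte for byte.
#'
#' @param config configuration list (see \code{defaultConfig}); partial
#'   lists are completed and validated
#' @return invisibly, a list with the run directory, stage outputs and
#'   in-memory results
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  # simulate
  refs <- makeReferences(cfg$seed, nTranscripts = cfg$n_transcripts,
                         nPlantedPrecursors = cfg$n_planted,
                         nConservedFamilies = cfg$n_families,
                         nNcrna = cfg$n_ncrna,
                         nTargetSites = cfg$n_target_sites)
  writeReferenceFasta(refs$transcriptome, file.path(out, "transcriptome.fa"))
  writeReferenceFasta(refs$catalog, file.path(out, "mirna_catalog.fa"))
  writeReferenceFasta(refs$ncrna, file.path(out, "ncrna.fa"))
  writeTruth(refs$truth, file.path(out, "truth.json"))
  fq <- simulateLibraries(refs, depthCk = cfg$depth_ck,
                          depthTr = cfg$depth_tr, seed = cfg$seed,
                          outDir = out, isomirRate = cfg$isomir_rate)

  # clean
  libs <- list(); reports <- list()
  for (lib in c("CK", "TR")) {
    reads <- readFastqReads(fq[[tolower(lib)]])
    cl <- cleanReads(reads, cfg$adaptor3, cfg$adaptor5,
                     minLen = cfg$min_len, maxLen = cfg$max_len,
                     polyAFrac = cfg$polya_frac, minMeanQ = cfg$min_mean_q,
                     label = lib)
    libs[[lib]] <- cl$library
    reports[[lib]] <- cleaningCounts(cl$report)
    writeTagFasta(cl$library, file.path(out, paste0(tolower(lib), "_tags.fa")))
  }
  cleanTab <- data.frame(library = rep(c("CK", "TR"),
                                       each = length(.CLEAN_REASONS)),
                         reason = rep(.CLEAN_REASONS, 2L),
                         count = c(reports$CK, reports$TR))
  .writeTsv(cleanTab, file.path(out, "clean_report.tsv"))

  # annotate (temporary db from the pooled clean data of both libraries)
  pooled <- TagLibrary(c(tagSequences(libs$CK), tagSequences(libs$TR)),
                       c(unname(tagCounts(libs$CK)), unname(tagCounts(libs$TR))),
                       "pooled")
  tempDb <- buildTempMirnaDb(pooled, refs$catalog,
                             maxMismatch = cfg$mismatches)
  prof <- lapply(libs, quantifyConserved, tempDb = tempDb,
                 maxMismatch = cfg$mismatches)
  conserved <- data.frame(family = tempDb$family, sequence = tempDb$sequence,
                          stringsAsFactors = FALSE)
  for (lib in c("CK", "TR")) {
    m <- match(conserved$family, prof[[lib]]$family)
    conserved[[paste0("count_", lib)]] <-
      ifelse(is.na(m), 0L, prof[[lib]]$count[m])
  }
  .writeTsv(conserved, file.path(out, "conserved_mirna.tsv"))
  ann <- lapply(libs, annotateTags, transcriptome = refs$transcriptome,
                ncrnaRefs = refs$ncrna, tempDb = tempDb)
  annTab <- rbind(cbind(library = "CK", ann$CK), cbind(library = "TR", ann$TR))
  .writeTsv(annTab, file.path(out, "annotation.tsv"))

  # discover novel miRNAs from the unannotated mapped tags (both libraries)
  unannot <- sort(unique(c(ann$CK$sequence[ann$CK$category == "unannotated_mapped"],
                           ann$TR$sequence[ann$TR$category == "unannotated_mapped"])))
  disc <- discoverNovel(unannot, libs, refs$transcriptome, flank = cfg$flank,
                        mfeMax = cfg$mfe_max, maxBulge = cfg$max_bulge,
                        minReads = cfg$min_reads)
  novel <- disc$novel
  .writeTsv(novel[, setdiff(names(novel), c("precursor", "structure"))],
            file.path(out, "novel_mirna.tsv"))
  .writeTsv(disc$candidates[, setdiff(names(disc$candidates),
                                      c("window", "structure"))],
            file.path(out, "candidates.tsv"))
  if (nrow(novel)) {
    preFa <- Biostrings::RNAStringSet(novel$precursor)
    names(preFa) <- novel$id
    Biostrings::writeXStringSet(preFa, file.path(out, "precursors.fa"),
                                width = 200L)
    writeLines(unlist(lapply(seq_len(nrow(novel)), function(i)
      c(paste0(">", novel$id[i]), novel$precursor[i], novel$structure[i]))),
      file.path(out, "precursors.dot"))
  } else {
    writeLines(character(0), file.path(out, "precursors.fa"))
    writeLines(character(0), file.path(out, "precursors.dot"))
  }

  # isomiR catalog over conserved + novel precursors
  conPre <- .conservedPrecursors(tempDb, refs$transcriptome, cfg$flank,
                                 cfg$mfe_max, cfg$max_bulge)
  preSeqs <- c(stats::setNames(conPre$precursor, conPre$id),
               stats::setNames(novel$precursor, novel$id))
  canonical <- data.frame(
    precursor = c(conPre$id, novel$id),
    start = c(vapply(seq_len(nrow(conPre)), function(i)
      as.integer(regexpr(conPre$mature[i], conPre$precursor[i],
                         fixed = TRUE)) - 1L, integer(1)),
      vapply(seq_len(nrow(novel)), function(i)
        as.integer(regexpr(novel$mature[i], novel$precursor[i],
                           fixed = TRUE)) - 1L, integer(1))),
    stringsAsFactors = FALSE)
  canonical$end <- canonical$start +
    nchar(c(conPre$mature, novel$mature))
  isoTabs <- lapply(c("CK", "TR"), function(lib) {
    cat <- isomirCatalog(libs[[lib]], preSeqs, canonical,
                         tailMax = cfg$tail_max)
    if (nrow(cat)) cbind(library = lib, cat) else cat
  })
  isoTab <- do.call(rbind, isoTabs[vapply(isoTabs, nrow, integer(1)) > 0])
  if (is.null(isoTab)) isoTab <- data.frame()
  .writeTsv(isoTab, file.path(out, "isomir_catalog.tsv"))
  isoSum <- if (nrow(isoTab))
    summarizeIsomirs(isoTab[isoTab$library == "CK", -1L]) else
    summarizeIsomirs(data.frame(tag = character(), count = integer(),
                                precursor = character(), offset5 = integer(),
                                offset3 = integer(), tail = character(),
                                class = character()))
  .writeTsv(isoSum, file.path(out, "isomir_summary.tsv"))

  # target prediction for conserved representatives + novel matures
  mirnas <- c(stats::setNames(tempDb$sequence, tempDb$family),
              stats::setNames(novel$mature, novel$id))
  targets <- predictTargets(mirnas, refs$transcriptome,
                            maxMismatch = cfg$max_mismatch_target,
                            maxScore112 = cfg$max_score_1_12,
                            minMfeRatio = cfg$mfe_ratio_min)
  .writeTsv(targets, file.path(out, "targets.tsv"))

  # differential expression (conserved families + novel miRNAs)
  counts <- data.frame(
    id = c(conserved$family, novel$id),
    x = c(conserved$count_CK, novel$count_CK),
    y = c(conserved$count_TR, novel$count_TR), stringsAsFactors = FALSE)
  de <- diffExpression(counts, totalCleanReads(libs$CK),
                       totalCleanReads(libs$TR), pseudo = cfg$pseudo_tpm,
                       pThresh = cfg$p_thresh, lfcThresh = cfg$lfc_thresh)
  .writeTsv(de, file.path(out, "de_results.tsv"))

  # report
  rep <- pipelineReport(out, libs = libs)

  invisible(list(dir = out, refs = refs, libs = libs, tempDb = tempDb,
                 conserved = conserved, novel = novel, candidates =
                   disc$candidates, isomirs = isoTab, targets = targets,
                 de = de, report = rep))
}

#' Summaries over a completed run
#'
#' Emits the reporting tables: per-library length distribution and
#' first-nucleotide bias, common-vs-specific tag counts between the two
#' libraries (total reads and unique tags), and the stage summary
#' (library sizes, composition, conserved/novel counts, significant DE
#' counts up/down).
#'
#' @param runDir a completed run directory
#' @param libs optional named list of the cleaned \code{TagLibrary}s; if
#'   missing they are re-read from the run directory
#' @return list of summary data.frames (also written as TSV)
#' @export
pipelineReport <- function(runDir, libs = NULL) {
  need <- c("ck_tags.fa", "tr_tags.fa", "annotation.tsv",
            "conserved_mirna.tsv", "novel_mirna.tsv", "de_results.tsv")
  missing <- need[!file.exists(file.path(runDir, need))]
  if (length(missing))
    stop("incomplete run: missing ", paste(missing, collapse = ", "))
  if (is.null(libs))
    libs <- list(CK = readTagFasta(file.path(runDir, "ck_tags.fa"), "CK"),
                 TR = readTagFasta(file.path(runDir, "tr_tags.fa"), "TR"))
  lenTab <- do.call(rbind, lapply(c("CK", "TR"), function(l)
    cbind(library = l, lengthDistribution(libs[[l]], by = "reads"))))
  fnTab <- do.call(rbind, lapply(c("CK", "TR"), function(l)
    cbind(library = l, firstNucleotideBias(libs[[l]]))))
  ckC <- tagCounts(libs$CK); trC <- tagCounts(libs$TR)
  common <- intersect(names(ckC), names(trC))
  commonReads <- sum(ckC[common]) + sum(trC[common])
  totalReads <- sum(ckC) + sum(trC)
  cs <- data.frame(
    set = c("common", "ck_specific", "tr_specific"),
    unique_tags = c(length(common), length(ckC) - length(common),
                    length(trC) - length(common)),
    reads = c(commonReads, sum(ckC) - sum(ckC[common]),
              sum(trC) - sum(trC[common])))
  cs$read_fraction <- if (totalReads > 0) cs$reads / totalReads else 0
  de <- .readTsv(file.path(runDir, "de_results.tsv"))
  conserved <- .readTsv(file.path(runDir, "conserved_mirna.tsv"))
  novel <- .readTsv(file.path(runDir, "novel_mirna.tsv"))
  ann <- .readTsv(file.path(runDir, "annotation.tsv"))
  comp <- stats::aggregate(count ~ library + category, data = ann, FUN = sum)
  summary <- data.frame(
    metric = c("clean_reads_ck", "clean_reads_tr", "unique_tags_ck",
               "unique_tags_tr", "conserved_families", "novel_mirnas",
               "de_significant", "de_up", "de_down",
               "common_read_fraction"),
    value = c(totalCleanReads(libs$CK), totalCleanReads(libs$TR),
              length(ckC), length(trC), nrow(conserved), nrow(novel),
              sum(de$significant), sum(de$significant & de$direction == "up"),
              sum(de$significant & de$direction == "down"),
              round(cs$read_fraction[1L], 6)))
  .writeTsv(lenTab, file.path(runDir, "length_distribution.tsv"))
  .writeTsv(fnTab, file.path(runDir, "first_nucleotide.tsv"))
  .writeTsv(cs, file.path(runDir, "common_specific.tsv"))
  .writeTsv(comp, file.path(runDir, "composition.tsv"))
  .writeTsv(summary, file.path(runDir, "summary.tsv"))
  list(summary = summary, lengths = lenTab, first_base = fnTab,
       common_specific = cs, composition = comp)
}
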