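#' Run the simulate-process-cluster-enrich pipeline
#'
#' Executes a full in-silico selection analysis from a configuration
#' list: simulate the scenario, build per-cycle frequency tables for the
#' sequenced cycles, retain and cluster sequences into families, fill
#' family trajectories and rank candidates.  All stage outputs are
#' written as TSV under `outDir` and hashed into a JSON manifest, so an
#' identical config reproduces byte-identical outputs.
#'
#' Config keys (unknown keys are rejected before any work):
#' \describe{
#'   \item{scenario}{a [SelexScenario-class] (required).}
#'   \item{outDir}{output directory (required).}
#'   \item{sequencedCycles}{cycle labels to analyze; default "C0" plus
#'     every cycle from C5+ on.}
#'   \item{maxMismatch, minLen, maxLen}{trimming parameters (2, 25, 32).}
#'   \item{threshold}{retention threshold (1e-4).}
#'   \item{radius, linkage}{clustering parameters (6, "seed").}
#'   \item{topK, minRatio}{candidate ranking parameters (10, 2).}
#' }
#'
#' @param config named list, see Details.
#' @param quiet suppress per-stage log messages.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`): parameters, seed, per-file md5 hashes, and the
#'   candidate table.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  known <- c("scenario", "outDir", "sequencedCycles", "maxMismatch",
             "minLen", "maxLen", "threshold", "radius", "linkage",
             "topK", "minRatio")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$scenario) || !is(config$scenario, "SelexScenario"))
    stop("config$scenario must be a SelexScenario")
  if (is.null(config$outDir)) stop("config$outDir is required")
  scenario <- config$scenario
  validObject(scenario)
  p <- list(
    maxMismatch = config$maxMismatch %||% 2,
    minLen = config$minLen %||% 25,
    maxLen = config$maxLen %||% 32,
    threshold = config$threshold %||% 1e-4,
    radius = config$radius %||% 6,
    linkage = config$linkage %||% "seed",
    topK = config$topK %||% 10,
    minRatio = config$minRatio %||% 2
  )
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- function(stage, ...) {
    if (!quiet) message("[", stage, "] seed=", scenario@seed, " ", ...)
  }

  log("simulate", "reads/cycle=", scenario@readsPerCycle,
      " cycles=", nrow(scenario@schedule))
  pools <- simulateSelex(scenario)

  sequenced <- config$sequencedCycles %||% {
    sch <- scenario@schedule$label
    c("C0", sch[seq(which(sch == "C5+") %||% 1, length(sch))])
  }
  sequenced <- intersect(sequenced, names(pools))
  log("process", "cycles=", paste(sequenced, collapse = ","),
      " window=", p$minLen, "-", p$maxLen)
  tables <- lapply(pools[sequenced], buildFrequencyTable,
                   design = scenario@design, maxMismatch = p$maxMismatch,
                   minLen = p$minLen, maxLen = p$maxLen)
  files <- character()
  for (tb in tables) {
    f <- file.path(outDir, paste0("freq_", gsub("[^A-Za-z0-9]", "_",
                                                cycleLabel(tb)), ".tsv"))
    writeFrequencyTable(tb, f)
    files <- c(files, f)
  }

  log("cluster", "threshold=", p$threshold, " radius=", p$radius,
      " linkage=", p$linkage)
  fams <- clusterFamilies(tables, radius = p$radius, threshold = p$threshold,
                          linkage = p$linkage)
  fams <- familyFrequencies(fams, tables)
  ff <- file.path(outDir, "families.tsv")
  mf <- file.path(outDir, "members.tsv")
  writeFamilies(fams, ff, mf)
  files <- c(files, ff, mf)

  log("enrich", "topK=", p$topK, " minRatio=", p$minRatio)
  sched_full <- rbind(
    data.frame(label = "C0", source = NA, dna_nmol = NA, protein_pmol = NA,
               branch = "positive", stringsAsFactors = FALSE),
    scenario@schedule
  )
  traj <- trajectory(fams, sched_full)
  tf <- file.path(outDir, "trajectories.tsv")
  utils::write.table(traj, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  cand <- rankCandidates(fams, scenario@schedule, k = p$topK,
                         minRatio = p$minRatio)
  cf <- file.path(outDir, "candidates.tsv")
  utils::write.table(cand, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, tf, cf)

  manifest <- list(
    package_version = as.character(utils::packageVersion("aptacycle")),
    seed = scenario@seed,
    reads_per_cycle = scenario@readsPerCycle,
    parameters = p,
    sequenced_cycles = sequenced,
    n_families = nrow(families(fams)),
    n_flagged = sum(cand$flagged),
    candidates = cand,
    files = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log("done", "families=", manifest$n_families,
      " flagged=", manifest$n_flagged)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a
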