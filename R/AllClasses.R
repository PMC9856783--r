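#' @importFrom methods new validObject is slot show setValidity
NULL

.valid_dna <- function(x, allowN = FALSE) {
  pat <- if (allowN) "^[ACGTN]+$" else "^[ACGT]+$"
  all(grepl(pat, x))
}

#' Oligonucleotide library design
#'
#' Describes a SELEX library: two fixed primer-binding flanks around a
#' randomized region synthesized with a given base composition.  The
#' default corresponds to a 70-nt library with 20-nt flanks, a 30-nt
#' random region and an A:C:G:T phosphoramidite ratio of 29:29:20:22%.
#'
#' @slot fixed5 5' fixed flank (character, ACGT only).
#' @slot fixed3 3' fixed flank (character, ACGT only).
#' @slot randomLength length of the randomized region in nucleotides.
#' @slot baseProbs named numeric of sampling probabilities for A, C, G, T;
#'   must sum to one.
#' @export
setClass("LibraryDesign",
  representation(
    fixed5 = "character",
    fixed3 = "character",
    randomLength = "integer",
    baseProbs = "numeric"
  )
)

setValidity("LibraryDesign", function(object) {
  msg <- character()
  if (length(object@fixed5) != 1L || !.valid_dna(object@fixed5))
    msg <- c(msg, "fixed5 must be a single ACGT string")
  if (length(object@fixed3) != 1L || !.valid_dna(object@fixed3))
    msg <- c(msg, "fixed3 must be a single ACGT string")
  if (length(object@randomLength) != 1L || object@randomLength <= 0L)
    msg <- c(msg, "randomLength must be a positive integer")
  p <- object@baseProbs
  if (!identical(sort(names(p)), c("A", "C", "G", "T")))
    msg <- c(msg, "baseProbs must be named A, C, G, T")
  else if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "baseProbs must be nonnegative and sum to 1 (tol 1e-9)")
  if (length(msg)) msg else TRUE
})

#' @param fixed5,fixed3 fixed flank sequences.
#' @param randomLength randomized-region length (nt).
#' @param baseProbs named base probabilities (A, C, G, T).
#' @rdname LibraryDesign-class
#' @export
libraryDesign <- function(fixed5 = "TCGCACATTCCGCTTCTACC",
                          fixed3 = "CGTAAGTCCGTGTGTGCGAA",
                          randomLength = 30,
                          baseProbs = c(A = 0.29, C = 0.29, G = 0.20, T = 0.22)) {
  new("LibraryDesign",
    fixed5 = toupper(fixed5), fixed3 = toupper(fixed3),
    randomLength = as.integer(randomLength),
    baseProbs = baseProbs[c("A", "C", "G", "T")]
  )
}

#' Reads observed in one selection cycle
#'
#' Holds the (possibly aggregated) reads of one SELEX cycle: unique
#' sequences with positive counts.
#'
#' @slot cycleLabel cycle label, e.g. "C5+" or "C9-".
#' @slot sequences character vector of reads (ACGT, N allowed).
#' @slot counts integer read counts aligned with `sequences`.
#' @export
setClass("CycleReads",
  representation(
    cycleLabel = "character",
    sequences = "character",
    counts = "integer"
  )
)

setValidity("CycleReads", function(object) {
  msg <- character()
  if (length(object@cycleLabel) != 1L || !nzchar(object@cycleLabel))
    msg <- c(msg, "cycleLabel must be a non-empty string")
  if (length(object@sequences) != length(object@counts))
    msg <- c(msg, "sequences and counts must be aligned")
  if (length(object@counts) && any(object@counts <= 0L))
    msg <- c(msg, "counts must be positive")
  if (length(object@sequences) && !.valid_dna(object@sequences, allowN = TRUE))
    msg <- c(msg, "sequences must be uppercase ACGT(N)")
  if (length(msg)) msg else TRUE
})

#' @param cycleLabel cycle label.
#' @param sequences read sequences.
#' @param counts read counts (default 1 per sequence).
#' @rdname CycleReads-class
#' @export
cycleReads <- function(cycleLabel, sequences, counts = rep(1L, length(sequences))) {
  new("CycleReads",
    cycleLabel = as.character(cycleLabel),
    sequences = as.character(sequences),
    counts = as.integer(counts)
  )
}

#' Per-cycle variable-region frequency table
#'
#' Frequencies of trimmed variable regions within one cycle, together with
#' the number of retained reads and a tally of trimming rejections by
#' reason.
#'
#' @slot cycleLabel cycle label.
#' @slot sequences unique variable-region sequences.
#' @slot counts retained read counts per sequence.
#' @slot frequencies counts / totalReads; sum to one.
#' @slot totalReads number of retained reads.
#' @slot rejections named integer tally of rejected reads by reason code.
#' @export
setClass("FrequencyTable",
  representation(
    cycleLabel = "character",
    sequences = "character",
    counts = "integer",
    frequencies = "numeric",
    totalReads = "integer",
    rejections = "integer"
  )
)

setValidity("FrequencyTable", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (length(object@counts) != n || length(object@frequencies) != n)
    msg <- c(msg, "sequences, counts and frequencies must be aligned")
  if (n && abs(sum(object@frequencies) - 1) > 1e-9)
    msg <- c(msg, "frequencies must sum to 1 (tol 1e-9)")
  if (length(object@totalReads) != 1L || object@totalReads < 0L)
    msg <- c(msg, "totalReads must be a single nonnegative integer")
  if (length(msg)) msg else TRUE
})

#' Sequence families from sequential edit-distance clustering
#'
#' The result of single-pass seed-linkage clustering of retained
#' sequences: a family table (id, seed, size), the member assignment, and
#' (after [familyFrequencies()]) a family-by-cycle frequency matrix.
#'
#' @slot families data.frame with columns family_id, seed, n_members.
#' @slot members data.frame with columns sequence, family_id.
#' @slot cycleFrequencies numeric matrix, families x cycles.
#' @slot cycleTotals named integer, retained reads per cycle.
#' @export
setClass("FamilySet",
  representation(
    families = "data.frame",
    members = "data.frame",
    cycleFrequencies = "matrix",
    cycleTotals = "integer"
  )
)

setValidity("FamilySet", function(object) {
  msg <- character()
  if (!all(c("family_id", "seed", "n_members") %in% names(object@families)))
    msg <- c(msg, "families must have family_id, seed, n_members")
  if (!all(c("sequence", "family_id") %in% names(object@members)))
    msg <- c(msg, "members must have sequence, family_id")
  if (anyDuplicated(object@members$sequence))
    msg <- c(msg, "each sequence must belong to exactly one family")
  if (!all(object@families$seed %in% object@members$sequence))
    msg <- c(msg, "every family seed must be a member")
  if (nrow(object@cycleFrequencies) &&
      nrow(object@cycleFrequencies) != nrow(object@families))
    msg <- c(msg, "cycleFrequencies rows must match families")
  if (length(msg)) msg else TRUE
})

#' Droplet digital PCR well
#'
#' Raw droplet fluorescence amplitudes for one well, plus the
#' classification threshold and positive/negative counts once
#' [classifyDroplets()] has been applied.
#'
#' @slot wellId well identifier.
#' @slot amplitudes droplet end-point fluorescence amplitudes (RFU).
#' @slot threshold classification threshold (length 0 until set).
#' @slot nPositive,nNegative classified droplet counts (length 0 until
#'   classified).
#' @export
setClass("DropletSet",
  representation(
    wellId = "character",
    amplitudes = "numeric",
    threshold = "numeric",
    nPositive = "integer",
    nNegative = "integer"
  )
)

setValidity("DropletSet", function(object) {
  msg <- character()
  if (length(object@wellId) != 1L) msg <- c(msg, "wellId must be length 1")
  if (length(object@nPositive) == 1L && length(object@nNegative) == 1L) {
    if (object@nPositive + object@nNegative != length(object@amplitudes))
      msg <- c(msg, "nPositive + nNegative must equal droplet count")
  }
  if (length(msg)) msg else TRUE
})

#' @param wellId well identifier.
#' @param amplitudes droplet amplitudes (RFU).
#' @rdname DropletSet-class
#' @export
dropletSet <- function(wellId, amplitudes) {
  new("DropletSet",
    wellId = as.character(wellId), amplitudes = as.numeric(amplitudes),
    threshold = numeric(), nPositive = integer(), nNegative = integer()
  )
}

#' Poisson quantification result for a ddPCR well
#'
#' @slot lambda mean copies per droplet.
#' @slot copiesPerUl template concentration (copies/uL).
#' @slot ci 95% confidence interval on copiesPerUl.
#' @slot qcPass TRUE if the total droplet count exceeded the QC minimum.
#' @slot saturated TRUE if essentially all droplets were positive.
#' @slot nTotal,nPositive,nNegative droplet counts.
#' @export
setClass("QuantResult",
  representation(
    lambda = "numeric",
    copiesPerUl = "numeric",
    ci = "numeric",
    qcPass = "logical",
    saturated = "logical",
    nTotal = "integer",
    nPositive = "integer",
    nNegative = "integer"
  )
)

#' Melt curve of a dye-stained aptamer
#'
#' Fluorescence versus temperature for one well: a fixed aptamer
#' concentration incubated with one protein concentration.
#'
#' @slot aptamerId aptamer identifier.
#' @slot proteinConcnM total protein concentration (nM).
#' @slot replicateId replicate identifier.
#' @slot temperature temperature grid (degrees C, strictly increasing).
#' @slot rfu fluorescence readings aligned with the grid.
#' @export
setClass("MeltCurve",
  representation(
    aptamerId = "character",
    proteinConcnM = "numeric",
    replicateId = "character",
    temperature = "numeric",
    rfu = "numeric"
  )
)

setValidity("MeltCurve", function(object) {
  msg <- character()
  if (length(object@temperature) != length(object@rfu))
    msg <- c(msg, "temperature and rfu must be aligned")
  if (length(object@temperature) > 1L && any(diff(object@temperature) <= 0))
    msg <- c(msg, "temperature grid must be strictly increasing")
  if (length(object@proteinConcnM) != 1L || object@proteinConcnM < 0)
    msg <- c(msg, "proteinConcnM must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

#' @param aptamerId,proteinConcnM,replicateId curve metadata.
#' @param temperature,rfu the curve.
#' @rdname MeltCurve-class
#' @export
meltCurve <- function(aptamerId, proteinConcnM, temperature, rfu,
                      replicateId = "r1") {
  new("MeltCurve",
    aptamerId = as.character(aptamerId),
    proteinConcnM = as.numeric(proteinConcnM),
    replicateId = as.character(replicateId),
    temperature = as.numeric(temperature), rfu = as.numeric(rfu)
  )
}

#' Negative first derivative of a melt curve
#'
#' @slot temperature temperature grid (degrees C).
#' @slot negDeriv -d(RFU)/dT aligned with the grid.
#' @slot provenance "raw" or "blank_subtracted".
#' @export
setClass("DerivativeCurve",
  representation(
    temperature = "numeric",
    negDeriv = "numeric",
    provenance = "character"
  )
)

setValidity("DerivativeCurve", function(object) {
  msg <- character()
  if (length(object@temperature) != length(object@negDeriv))
    msg <- c(msg, "temperature and negDeriv must be aligned")
  if (length(object@temperature) > 1L && any(diff(object@temperature) <= 0))
    msg <- c(msg, "temperature grid must be strictly increasing")
  if (!object@provenance %in% c("raw", "blank_subtracted"))
    msg <- c(msg, "provenance must be 'raw' or 'blank_subtracted'")
  if (length(msg)) msg else TRUE
})

#' Concentration-response binding curve
#'
#' Blank-subtracted -d(RFU)/dT evaluated at the melting temperature of the
#' bound state, per protein concentration, averaged over replicates.
#'
#' @slot aptamerId aptamer identifier.
#' @slot tmBoundC melting temperature of the bound state used for
#'   evaluation (degrees C).
#' @slot points data.frame with columns protein_conc_nM, signal, sd, n.
#' @export
setClass("BindingCurve",
  representation(
    aptamerId = "character",
    tmBoundC = "numeric",
    points = "data.frame"
  )
)

setValidity("BindingCurve", function(object) {
  msg <- character()
  need <- c("protein_conc_nM", "signal", "sd", "n")
  if (!all(need %in% names(object@points)))
    msg <- c(msg, "points must have protein_conc_nM, signal, sd, n")
  else {
    if (any(object@points$protein_conc_nM < 0))
      msg <- c(msg, "concentrations must be nonnegative")
    if (anyDuplicated(object@points$protein_conc_nM))
      msg <- c(msg, "concentrations must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Dissociation-constant fit
#'
#' @slot kdnM fitted (apparent) dissociation constant (nM).
#' @slot kdSEnM standard error of the fit (nM).
#' @slot params named fitted parameters (floor, span, kd, optionally hill).
#' @slot model "hill", "hyperbolic" or "depletion".
#' @slot converged FALSE when the optimizer failed or input was degenerate.
#' @slot rss residual sum of squares.
#' @slot bootCI optional bootstrap percentile CI (length 0 or 2).
#' @slot data the fitted points (protein_conc_nM, signal).
#' @export
setClass("KdFit",
  representation(
    kdnM = "numeric",
    kdSEnM = "numeric",
    params = "numeric",
    model = "character",
    converged = "logical",
    rss = "numeric",
    bootCI = "numeric",
    data = "data.frame"
  )
)

#' Variant family planted in a simulated selection
#'
#' A binder is a variable-region seed with multiplicative fitness in
#' positive (target) and counter (matrix) rounds.  Family variants are
#' emitted around the seed with a per-base mutation rate, capped within
#' edit distance 6 of the seed.
#'
#' @slot seedSequence variable-region seed (ACGT).
#' @slot targetAffinity fitness multiplier per positive round (>= 0).
#' @slot matrixAffinity fitness multiplier per counter round (>= 0).
#' @slot variantRate per-base substitution/indel probability between 0 and 0.2.
#' @slot initialCopies copies of the seed present in the starting pool.
#' @export
setClass("BinderSpec",
  representation(
    seedSequence = "character",
    targetAffinity = "numeric",
    matrixAffinity = "numeric",
    variantRate = "numeric",
    initialCopies = "integer"
  )
)

setValidity("BinderSpec", function(object) {
  msg <- character()
  if (!.valid_dna(object@seedSequence))
    msg <- c(msg, "seedSequence must be ACGT")
  if (object@targetAffinity < 0 || object@matrixAffinity < 0)
    msg <- c(msg, "affinity multipliers must be >= 0")
  if (object@variantRate < 0 || object@variantRate > 0.2)
    msg <- c(msg, "variantRate must be in [0, 0.2]")
  if (object@initialCopies <= 0L)
    msg <- c(msg, "initialCopies must be positive")
  if (length(msg)) msg else TRUE
})

#' @param seedSequence variable-region seed.
#' @param targetAffinity,matrixAffinity per-round fitness multipliers.
#' @param variantRate per-base mutation probability when emitting variants.
#' @param initialCopies seed copies in the starting pool.
#' @rdname BinderSpec-class
#' @export
binderSpec <- function(seedSequence, targetAffinity = 2,
                       matrixAffinity = 1, variantRate = 0.005,
                       initialCopies = 5) {
  new("BinderSpec",
    seedSequence = toupper(seedSequence),
    targetAffinity = as.numeric(targetAffinity),
    matrixAffinity = as.numeric(matrixAffinity),
    variantRate = as.numeric(variantRate),
    initialCopies = as.integer(initialCopies)
  )
}

#' Full synthetic selection scenario
#'
#' @slot design the [LibraryDesign-class].
#' @slot binders list of [BinderSpec-class] (may be empty).
#' @slot schedule data.frame with columns label, source, dna_nmol,
#'   protein_pmol, branch ("positive"/"counter"); sources must refer to
#'   "C0" (the starting library) or an earlier label.
#' @slot readsPerCycle reads drawn per cycle.
#' @slot seed integer random seed for the whole scenario.
#' @export
setClass("SelexScenario",
  representation(
    design = "LibraryDesign",
    binders = "list",
    schedule = "data.frame",
    readsPerCycle = "integer",
    seed = "integer"
  )
)

setValidity("SelexScenario", function(object) {
  msg <- character()
  sch <- object@schedule
  need <- c("label", "source", "dna_nmol", "protein_pmol", "branch")
  if (!all(need %in% names(sch)))
    msg <- c(msg, "schedule needs label, source, dna_nmol, protein_pmol, branch")
  else {
    if (anyDuplicated(sch$label)) msg <- c(msg, "schedule labels must be unique")
    if (!all(sch$branch %in% c("positive", "counter")))
      msg <- c(msg, "branch must be 'positive' or 'counter'")
    ok_src <- sch$source %in% c("C0", sch$label)
    if (!all(ok_src)) msg <- c(msg, "every source must be 'C0' or another label")
  }
  if (object@readsPerCycle <= 0L) msg <- c(msg, "readsPerCycle must be positive")
  if (!all(vapply(object@binders, is, logical(1), class2 = "BinderSpec")))
    msg <- c(msg, "binders must be a list of BinderSpec")
  if (length(msg)) msg else TRUE
})

#' @param design,binders,schedule,readsPerCycle,seed see slots.
#' @rdname SelexScenario-class
#' @export
selexScenario <- function(design = libraryDesign(), binders = list(),
                          schedule = selexSchedule(),
                          readsPerCycle = 200000, seed = 1) {
  new("SelexScenario",
    design = design, binders = binders, schedule = schedule,
    readsPerCycle = as.integer(readsPerCycle), seed = as.integer(seed)
  )
}
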