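#' DNA-to-protein molar ratio of a selection cycle
#'
#' The selection stringency of a cycle, `dna_nmol / (protein_pmol /
#' 1000)`, i.e. a plain nmol:nmol ratio.  1.25 nmol DNA against 200 pmol
#' protein gives 6.25.
#'
#' @param dnaNmol DNA input (nmol, > 0).
#' @param proteinPmol protein input (pmol, > 0).
#' @return dimensionless ratio; vectorized.
#' @export
dnaProteinRatio <- function(dnaNmol, proteinPmol) {
  if (any(proteinPmol <= 0)) stop("proteinPmol must be > 0")
  if (any(dnaNmol <= 0)) stop("dnaNmol must be > 0")
  dnaNmol / (proteinPmol / 1000)
}

#' Family frequency trajectories in schedule order
#'
#' Long-format trajectory of every family across the schedule's cycles,
#' with zeros for cycles where a family (or the whole cycle) is absent
#' from the frequency matrix.  Cycle order comes from the schedule, never
#' from label parsing.
#'
#' @param familySet a [FamilySet-class] with frequencies filled.
#' @param schedule data.frame with at least `label` (and optionally
#'   `branch`) columns; must cover every cycle present in the family set.
#' @return data.frame with columns family_id, cycle, frequency, ordered
#'   by family then schedule position.
#' @export
trajectory <- function(familySet, schedule) {
  stopifnot(is(familySet, "FamilySet"))
  freq <- familySet@cycleFrequencies
  if (!ncol(freq)) stop("familySet has no cycle frequencies; run familyFrequencies()")
  unknown <- setdiff(colnames(freq), schedule$label)
  if (length(unknown)) {
    stop("cycle label(s) not in schedule: ", paste(unknown, collapse = ", "))
  }
  cycles <- schedule$label
  full <- matrix(0, nrow = nrow(freq), ncol = length(cycles),
                 dimnames = list(NULL, cycles))
  full[, colnames(freq)[colnames(freq) %in% cycles]] <-
    freq[, colnames(freq)[colnames(freq) %in% cycles], drop = FALSE]
  data.frame(
    family_id = rep(familySet@families$family_id, times = length(cycles)),
    cycle = rep(cycles, each = nrow(freq)),
    frequency = as.vector(full),
    stringsAsFactors = FALSE
  )
}

#' Positive versus counter-selection enrichment ratio
#'
#' `(freqPos + pseudo) / (freqNeg + pseudo)`: the additive
#' pseudo-frequency keeps the ratio finite when a family is absent from
#' the counter branch.  The default pseudo equals the standard retention
#' threshold (0.01%): frequencies at or below the detection limit are
#' not distinguishable from it, so their ratios are shrunk toward 1,
#' which keeps the false-flagging rate of neutral (non-binding) families
#' low.  Pass `1 / total retained reads` for the raw one-read
#' convention.
#'
#' @param freqPos,freqNeg frequencies between 0 and 1; vectorized.
#' @param pseudo additive pseudo-frequency (> 0).
#' @return ratio >= 0.
#' @export
posNegRatio <- function(freqPos, freqNeg, pseudo = 1e-4) {
  stopifnot(all(freqPos >= 0 & freqPos <= 1), all(freqNeg >= 0 & freqNeg <= 1),
            pseudo > 0)
  (freqPos + pseudo) / (freqNeg + pseudo)
}

#' Rank candidate aptamer families
#'
#' Families are ranked by their frequency in the last positive cycle
#' (descending, ties broken by family id), annotated with their
#' positive/counter enrichment ratio in the paired last cycles, and
#' flagged as candidates when the ratio reaches `minRatio` — the
#' operational form of "enriched with the target, depleted without it".
#'
#' @param familySet a [FamilySet-class] with frequencies filled.
#' @param schedule data.frame with `label` and `branch` columns giving
#'   cycle order; the last positive and last counter cycles present in
#'   the frequency matrix are compared.
#' @param k number of candidates to return (default 10).
#' @param minRatio flagging threshold on the pos/counter ratio (default 2).
#' @param pseudo additive pseudo-frequency (see [posNegRatio()]).
#' @return data.frame with columns rank, family_id, seed, freq_pos,
#'   freq_neg, ratio, flagged (first `k` rows of the full ranking).
#' @export
rankCandidates <- function(familySet, schedule, k = 10, minRatio = 2,
                           pseudo = 1e-4) {
  stopifnot(is(familySet, "FamilySet"))
  freq <- familySet@cycleFrequencies
  if (!ncol(freq)) stop("familySet has no cycle frequencies; run familyFrequencies()")
  present <- schedule$label[schedule$label %in% colnames(freq)]
  bra <- schedule$branch[match(present, schedule$label)]
  posCycle <- utils::tail(present[bra == "positive"], 1L)
  negCycle <- utils::tail(present[bra == "counter"], 1L)
  if (!length(posCycle)) stop("no positive cycle present in the frequency matrix")
  fpos <- freq[, posCycle]
  fneg <- if (length(negCycle)) freq[, negCycle] else rep(0, nrow(freq))
  ratio <- posNegRatio(fpos, fneg, pseudo)
  o <- order(-fpos, familySet@families$family_id)
  out <- data.frame(
    rank = seq_along(o),
    family_id = familySet@families$family_id[o],
    seed = familySet@families$seed[o],
    freq_pos = fpos[o],
    freq_neg = fneg[o],
    ratio = ratio[o],
    flagged = ratio[o] >= minRatio,
    stringsAsFactors = FALSE
  )
  attr(out, "cycles") <- c(positive = posCycle,
                           counter = if (length(negCycle)) negCycle else NA_character_)
  utils::head(out, k)
}
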