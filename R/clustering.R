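#' Levenshtein edit distance
#'
#' Unit-cost edit distance (substitutions, insertions, deletions) between
#' pairs of strings, computed by banded dynamic programming.  With a
#' `cutoff`, computation stops as soon as the distance provably exceeds
#' it and `cutoff + 1` is returned; clustering only needs to know whether
#' a distance is within its radius.
#'
#' `a` and `b` are recycled against each other (either may be length 1).
#'
#' @param a,b character vectors.
#' @param cutoff optional early-exit bound; NULL computes exactly.
#' @return integer vector of distances (values capped at `cutoff + 1`
#'   when a cutoff is given).
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b, cutoff = NULL) {
  .levenshtein_cpp(as.character(a), as.character(b),
                   if (is.null(cutoff)) -1L else as.integer(cutoff))
}

#' Sequentially cluster retained sequences into families
#'
#' Sequences are visited in order of decreasing maximum per-cycle
#' frequency (ties broken lexicographically).  Each sequence joins the
#' earliest-founded family whose seed lies within `radius` edit
#' operations (`linkage = "seed"`, the default single-pass rule that
#' bounds every family's radius), or within `radius` of any member
#' (`linkage = "any"`); otherwise it founds a new family with itself as
#' seed.  The result is a partition of the retained set.
#'
#' @param tables list of [FrequencyTable-class] used for the retention
#'   filter and the processing order.
#' @param radius clustering radius (default 6 edits).
#' @param threshold retention threshold passed to
#'   [retainAboveThreshold()]; ignored when `sequences` is given.
#' @param linkage "seed" or "any".
#' @param sequences optional explicit retained set.
#' @return a [FamilySet-class] (cycle frequencies empty until
#'   [familyFrequencies()] is applied).
#' @export
clusterFamilies <- function(tables, radius = 6, threshold = 1e-4,
                            linkage = c("seed", "any"), sequences = NULL) {
  linkage <- match.arg(linkage)
  if (is.null(sequences)) sequences <- retainAboveThreshold(tables, threshold)
  if (!length(sequences)) stop("no sequences to cluster")
  maxfreq <- rep(0, length(sequences))
  for (tb in tables) {
    m <- match(sequences, tb@sequences)
    f <- ifelse(is.na(m), 0, tb@frequencies[m])
    maxfreq <- pmax(maxfreq, f)
  }
  o <- order(-maxfreq, sequences)
  seqs <- sequences[o]
  fam <- .assign_families_cpp(seqs, as.integer(radius), linkage == "any")
  seeds <- seqs[!duplicated(fam)][order(unique(fam))]
  famdf <- data.frame(
    family_id = sort(unique(fam)),
    seed = seeds,
    n_members = as.integer(table(fam)),
    stringsAsFactors = FALSE
  )
  new("FamilySet",
    families = famdf,
    members = data.frame(sequence = seqs, family_id = fam,
                         stringsAsFactors = FALSE),
    cycleFrequencies = matrix(numeric(), nrow = nrow(famdf), ncol = 0),
    cycleTotals = integer()
  )
}

#' Fill per-cycle family frequencies
#'
#' A family's frequency in a cycle is the sum of its members' frequencies
#' there (0 for absent members).  Totals over all families stay <= 1:
#' unretained background reads are excluded.  Also records the number of
#' retained reads per cycle (used downstream as the pseudo-frequency
#' denominator).
#'
#' @param familySet a [FamilySet-class].
#' @param tables list of [FrequencyTable-class].
#' @return the [FamilySet-class] with `cycleFrequencies` and
#'   `cycleTotals` filled.
#' @export
familyFrequencies <- function(familySet, tables) {
  stopifnot(is(familySet, "FamilySet"))
  mem <- familySet@members
  labs <- vapply(tables, cycleLabel, character(1))
  if (anyDuplicated(labs)) stop("duplicate cycle labels in tables")
  freq <- matrix(0, nrow = nrow(familySet@families), ncol = length(tables),
                 dimnames = list(NULL, labs))
  totals <- integer(length(tables)); names(totals) <- labs
  seen <- rep(FALSE, nrow(mem))
  for (j in seq_along(tables)) {
    tb <- tables[[j]]
    m <- match(mem$sequence, tb@sequences)
    seen <- seen | !is.na(m)
    f <- ifelse(is.na(m), 0, tb@frequencies[m])
    agg <- rowsum(f, mem$family_id)
    freq[as.integer(rownames(agg)), j] <- agg[, 1L]
    cnt <- ifelse(is.na(m), 0L, tb@counts[m])
    totals[j] <- as.integer(sum(cnt))
  }
  if (!all(seen)) {
    stop(sum(!seen), " family member(s) absent from every frequency table")
  }
  familySet@cycleFrequencies <- freq
  familySet@cycleTotals <- totals
  familySet
}
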