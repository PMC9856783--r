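#' Trim fixed flanks off reads, keeping the variable region
#'
#' Locates the design's 5' flank as an anchored prefix and the 3' flank
#' as an anchored suffix, each allowing up to `maxMismatch` substitutions
#' (no indels), and returns the interior.  Reads that fail are not
#' errors: each carries a reason code so rejections can be tallied.
#'
#' Reason codes: `ok`, `missing_flank` (either flank absent at its
#' tolerance, or the read shorter than the two flanks),
#' `length_out_of_bounds` (interior outside `[minLen, maxLen]`),
#' `ambiguous_base` (interior contains N).
#'
#' With `design = NULL` the reads are taken as already-trimmed variable
#' regions and only the length/ambiguity checks apply.
#'
#' @param reads character vector of reads (or a [CycleReads-class]).
#' @param design a [LibraryDesign-class], or NULL for flankless mode.
#' @param maxMismatch substitutions tolerated per flank (default 2).
#' @param minLen,maxLen inclusive interior length bounds (default 25-32).
#' @return data.frame with columns `read`, `region`, `status`; `region`
#'   is NA unless `status == "ok"`.
#' @examples
#' fx <- selexFixtures()
#' trimFixedRegions(fx$aptamers[["AHE1"]], fx$design)$region
#' @export
trimFixedRegions <- function(reads, design, maxMismatch = 2,
                             minLen = 25, maxLen = 32) {
  if (is(reads, "CycleReads")) reads <- rep(sequences(reads), counts(reads))
  if (!length(reads)) stop("no reads given")
  n <- length(reads)
  status <- rep("ok", n)
  if (is.null(design)) {
    region <- reads
  } else {
    stopifnot(is(design, "LibraryDesign"))
    f5 <- design@fixed5; f3 <- design@fixed3
    len <- nchar(reads)
    flanks <- nchar(f5) + nchar(f3)
    mm5 <- .flank_mismatch_cpp(reads, f5, FALSE)
    mm3 <- .flank_mismatch_cpp(reads, f3, TRUE)
    # flanks must fit without overlapping; mismatch tolerance per flank
    bad_flank <- len < flanks | is.na(mm5) | mm5 > maxMismatch |
      is.na(mm3) | mm3 > maxMismatch
    status[bad_flank] <- "missing_flank"
    # both flanks present but empty interior: a length failure (0 < minLen)
    empty <- !bad_flank & len == flanks
    status[empty] <- "length_out_of_bounds"
    region <- rep(NA_character_, n)
    ok <- status == "ok"
    region[ok] <- substr(reads[ok], nchar(f5) + 1L, len[ok] - nchar(f3))
  }
  ok <- status == "ok"
  bad_len <- ok & !lengthFilter(region, minLen, maxLen)
  status[bad_len] <- "length_out_of_bounds"
  hasN <- status == "ok" & grepl("N", region, fixed = TRUE)
  status[hasN] <- "ambiguous_base"
  region[status != "ok"] <- NA_character_
  data.frame(read = reads, region = region, status = status,
             stringsAsFactors = FALSE)
}

#' Variable-region length filter
#'
#' TRUE iff `minLen <= nchar(region) <= maxLen` (inclusive bounds).
#'
#' @param region character vector of variable regions.
#' @param minLen,maxLen inclusive bounds (default 25 and 32).
#' @export
lengthFilter <- function(region, minLen = 25, maxLen = 32) {
  n <- nchar(region)
  !is.na(region) & n >= minLen & n <= maxLen
}

#' Build a per-cycle variable-region frequency table
#'
#' Trims each read ([trimFixedRegions()]), tallies rejections by reason,
#' and computes the frequency of every retained variable region as its
#' count over the total retained reads.
#'
#' @param reads a [CycleReads-class].
#' @param design a [LibraryDesign-class], or NULL for already-trimmed input.
#' @param maxMismatch,minLen,maxLen passed to [trimFixedRegions()].
#' @return a [FrequencyTable-class].
#' @export
buildFrequencyTable <- function(reads, design, maxMismatch = 2,
                                minLen = 25, maxLen = 32) {
  stopifnot(is(reads, "CycleReads"))
  tr <- trimFixedRegions(sequences(reads), design, maxMismatch, minLen, maxLen)
  cnt <- counts(reads)
  rej <- c(missing_flank = 0L, length_out_of_bounds = 0L, ambiguous_base = 0L)
  bad <- tr$status != "ok"
  if (any(bad)) {
    tal <- tapply(cnt[bad], tr$status[bad], sum)
    rej[names(tal)] <- as.integer(tal)
  }
  ok <- !bad
  if (!any(ok)) {
    stop("no reads of cycle '", cycleLabel(reads), "' survived trimming")
  }
  agg <- rowsum(cnt[ok], tr$region[ok], reorder = FALSE)
  seqs <- rownames(agg)
  kcnt <- as.integer(agg[, 1L])
  o <- order(-kcnt, seqs)
  seqs <- seqs[o]; kcnt <- kcnt[o]
  total <- sum(kcnt)
  new("FrequencyTable",
    cycleLabel = cycleLabel(reads), sequences = seqs, counts = kcnt,
    frequencies = kcnt / total, totalReads = total, rejections = rej
  )
}

#' Retain sequences above a frequency threshold in at least one cycle
#'
#' A sequence is retained iff its frequency is `>= threshold` in at least
#' one of the given tables (the default 1e-4 is the 0.01% cut; boundary
#' values are kept).
#'
#' @param tables list of [FrequencyTable-class].
#' @param threshold retention threshold on the fraction scale.
#' @return sorted character vector of retained sequences.
#' @export
retainAboveThreshold <- function(tables, threshold = 1e-4) {
  stopifnot(length(tables) >= 1)
  keep <- lapply(tables, function(tb) {
    stopifnot(is(tb, "FrequencyTable"))
    tb@sequences[tb@frequencies >= threshold]
  })
  sort(unique(unlist(keep)))
}
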