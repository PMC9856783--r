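#' @importFrom stats binom.test sd
NULL

#' Choose a droplet classification threshold
#'
#' Automatic mode finds the optimal two-group split of the 1-D amplitude
#' distribution (the split minimizing total within-group variance, an
#' exact scan over the sorted amplitudes) and places the threshold midway
#' between the two group means.  If the two groups are not separated
#' (centre distance below `minSeparation` pooled within-group SDs) the
#' well is treated as unimodal — e.g. a no-template control — and, with a
#' warning, the threshold is set at mean + 5 SD of the single cluster so
#' that classification yields no positives.
#'
#' @param x a [DropletSet-class] or numeric amplitudes.
#' @param mode "auto" or "manual".
#' @param manualValue threshold to pass through in manual mode.
#' @param minSeparation separation (in pooled within-group SDs) below
#'   which the distribution is declared unimodal (default 3).
#' @return threshold (numeric scalar).
#' @export
setThreshold <- function(x, mode = c("auto", "manual"), manualValue = NULL,
                         minSeparation = 3) {
  mode <- match.arg(mode)
  amp <- if (is(x, "DropletSet")) amplitudes(x) else as.numeric(x)
  if (mode == "manual") {
    if (is.null(manualValue)) stop("manual mode needs manualValue")
    return(as.numeric(manualValue))
  }
  if (length(amp) < 100) stop("auto threshold needs >= 100 droplets")
  a <- sort(amp)
  n <- length(a)
  cs <- cumsum(a); cs2 <- cumsum(a^2)
  i <- seq_len(n - 1L)
  # within-group sum of squares for split after position i
  m1 <- cs[i] / i
  m2 <- (cs[n] - cs[i]) / (n - i)
  ss1 <- cs2[i] - i * m1^2
  ss2 <- (cs2[n] - cs2[i]) - (n - i) * m2^2
  best <- which.min(ss1 + ss2)
  lo <- a[seq_len(best)]; hi <- a[(best + 1L):n]
  pooled <- sqrt((ss1[best] + ss2[best]) / (n - 2L))
  if (pooled == 0 || (mean(hi) - mean(lo)) < minSeparation * pooled) {
    warning("amplitude distribution looks unimodal; threshold set at mean + 5 SD")
    return(mean(amp) + 5 * sd(amp))
  }
  (mean(lo) + mean(hi)) / 2
}

#' Classify droplets against a threshold
#'
#' Amplitudes strictly above the threshold are positive, the rest
#' negative.
#'
#' @param x a [DropletSet-class].
#' @param threshold classification threshold (RFU).
#' @return the [DropletSet-class] with threshold and counts filled.
#' @export
classifyDroplets <- function(x, threshold) {
  stopifnot(is(x, "DropletSet"))
  if (!length(amplitudes(x))) stop("no droplets to classify")
  npos <- sum(amplitudes(x) > threshold)
  x@threshold <- as.numeric(threshold)
  x@nPositive <- as.integer(npos)
  x@nNegative <- as.integer(length(amplitudes(x)) - npos)
  validObject(x)
  x
}

#' Total-droplet quality control
#'
#' Accurate absolute quantification requires the total droplet count to
#' exceed `minTotal` (strictly: 10,000 droplets fail, 10,001 pass).
#'
#' @param nTotal total droplets (>= 0).
#' @param minTotal QC minimum (default 10000).
#' @return logical; vectorized.
#' @export
qcTotalDroplets <- function(nTotal, minTotal = 10000) {
  stopifnot(all(nTotal >= 0))
  nTotal > minTotal
}

#' Poisson quantification of a classified ddPCR well
#'
#' The mean occupancy is `lambda = -ln(n_negative / n_total)` copies per
#' droplet; the template concentration is `lambda / dropletVolumeUl`.
#' The 95% CI is the exact (Clopper-Pearson) binomial CI on the negative
#' fraction propagated through `-ln`.  A well with no negative droplets
#' is saturated: `copiesPerUl` is `Inf` and no finite estimate exists.
#'
#' @param x a classified [DropletSet-class].
#' @param dropletVolumeUl droplet volume in uL (default 0.85 nL).
#' @param minTotal QC minimum for [qcTotalDroplets()].
#' @param satFraction positive fraction at or above which the well is
#'   flagged saturated (default 0.999).
#' @return a [QuantResult-class].
#' @export
quantifyDroplets <- function(x, dropletVolumeUl = 0.00085,
                             minTotal = 10000, satFraction = 0.999) {
  stopifnot(is(x, "DropletSet"), dropletVolumeUl > 0)
  if (!length(x@nPositive)) stop("droplets are not classified; run classifyDroplets()")
  ntot <- length(amplitudes(x))
  nneg <- x@nNegative
  npos <- x@nPositive
  qc <- qcTotalDroplets(ntot, minTotal)
  if (nneg == 0L) {
    return(new("QuantResult",
      lambda = Inf, copiesPerUl = Inf, ci = c(NA_real_, NA_real_),
      qcPass = qc, saturated = TRUE,
      nTotal = ntot, nPositive = npos, nNegative = nneg
    ))
  }
  lambda <- -log(nneg / ntot)
  ci_neg <- binom.test(nneg, ntot)$conf.int
  lambda_ci <- sort(-log(ci_neg))
  new("QuantResult",
    lambda = lambda,
    copiesPerUl = lambda / dropletVolumeUl,
    ci = lambda_ci / dropletVolumeUl,
    qcPass = qc,
    saturated = npos / ntot >= satFraction,
    nTotal = ntot, nPositive = npos, nNegative = nneg
  )
}

#' Copies per microliter of a reaction
#'
#' Worked bookkeeping for rare templates: 3 bound sequences in a 20 uL
#' reaction are 0.15 copies/uL and will seed 3 positive droplets.
#'
#' @param copies template copies (>= 0).
#' @param reactionVolumeUl reaction volume (uL, > 0).
#' @return copies/uL; vectorized.
#' @export
reactionConcentration <- function(copies, reactionVolumeUl) {
  if (any(reactionVolumeUl <= 0)) stop("reactionVolumeUl must be > 0")
  copies / reactionVolumeUl
}
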