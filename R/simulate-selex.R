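#' @importFrom stats rbinom rmultinom rnorm rpois runif plogis setNames
NULL

# Deterministic child seeds so each stage of a scenario has its own stream.
.childSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

# n random-region strings drawn i.i.d. from the design's base composition.
.randomRegions <- function(design, n) {
  bases <- names(design@baseProbs)
  L <- design@randomLength
  m <- matrix(sample(bases, n * L, replace = TRUE, prob = design@baseProbs),
              nrow = n, ncol = L)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate reads from a naive oligonucleotide library
#'
#' Each read is the 5' fixed flank, a random region drawn i.i.d. from the
#' design's base composition, and the 3' fixed flank.
#'
#' @param design a [LibraryDesign-class].
#' @param nReads number of reads to draw.
#' @param seed optional random seed.
#' @param cycleLabel label for the returned [CycleReads-class].
#' @return a [CycleReads-class] with one count per read (identical draws
#'   are not aggregated).
#' @examples
#' lib <- simulateLibrary(libraryDesign(), 5, seed = 1)
#' sequences(lib)
#' @export
simulateLibrary <- function(design, nReads, seed = NULL, cycleLabel = "C0") {
  stopifnot(is(design, "LibraryDesign"), nReads > 0)
  validObject(design)
  .withSeed(seed, {
    regions <- .randomRegions(design, nReads)
    cycleReads(cycleLabel, paste0(design@fixed5, regions, design@fixed3))
  })
}

# Mutate n copies of a variable-region seed: per-base substitutions at rate
# `rate` (capped at 5 per read) plus at most one single-base indel (prob
# `rate`), so every variant stays within edit distance 6 of the seed.
.mutateSeed <- function(seedSeq, n, rate) {
  if (n == 0L) return(character())
  chars <- strsplit(seedSeq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  for (i in seq_len(n)) {
    v <- chars
    nsub <- min(rbinom(1L, L, rate), 5L)
    if (nsub > 0L) {
      pos <- sample.int(L, nsub)
      for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1L)
    }
    if (runif(1L) < rate) {
      if (runif(1L) < 0.5 && length(v) > 1L) {
        v <- v[-sample.int(length(v), 1L)]
      } else {
        at <- sample.int(length(v) + 1L, 1L)
        v <- append(v, sample(bases, 1L), after = at - 1L)
      }
    }
    out[i] <- paste(v, collapse = "")
  }
  out
}

#' Simulate a multi-cycle SELEX experiment
#'
#' The pool starts as `readsPerCycle` library draws plus each binder's
#' seed at its `initialCopies`.  Every scheduled cycle resamples
#' `readsPerCycle` reads from its source pool by a multinomial whose
#' weights multiply each binder family's counts by `targetAffinity`
#' (positive rounds) or `matrixAffinity` (counter rounds); background
#' sequences keep weight 1.  Binder reads are emitted as seed variants
#' (per-base rate `variantRate`, edit distance <= 6 from the seed).
#' Branch splits (e.g. C9+/C9- both sourced from C8+) fall out of the
#' schedule's `source` column.
#'
#' @param scenario a [SelexScenario-class].
#' @return named list of [CycleReads-class]: the starting pool under
#'   "C0", then one entry per schedule row, in order.
#' @export
simulateSelex <- function(scenario) {
  stopifnot(is(scenario, "SelexScenario"))
  validObject(scenario)
  design <- scenario@design
  sch <- scenario@schedule
  nR <- scenario@readsPerCycle
  seeds <- .childSeeds(scenario@seed, nrow(sch) + 1L)

  set.seed(seeds[1L])
  pool <- list(
    seqs = paste0(design@fixed5, .randomRegions(design, nR), design@fixed3),
    cnt = rep(1L, nR),
    fam = rep(0L, nR)
  )
  for (k in seq_along(scenario@binders)) {
    b <- scenario@binders[[k]]
    pool$seqs <- c(pool$seqs, paste0(design@fixed5, b@seedSequence, design@fixed3))
    pool$cnt <- c(pool$cnt, b@initialCopies)
    pool$fam <- c(pool$fam, k)
  }
  pools <- list(C0 = pool)

  tmult <- vapply(scenario@binders, slot, numeric(1), name = "targetAffinity")
  mmult <- vapply(scenario@binders, slot, numeric(1), name = "matrixAffinity")
  vrate <- vapply(scenario@binders, slot, numeric(1), name = "variantRate")

  for (r in seq_len(nrow(sch))) {
    set.seed(seeds[r + 1L])
    src <- pools[[sch$source[r]]]
    if (is.null(src)) stop("schedule source '", sch$source[r], "' not yet simulated")
    mult <- if (sch$branch[r] == "positive") tmult else mmult
    w <- src$cnt * c(1, mult)[src$fam + 1L]
    if (all(w == 0)) stop("all pool weights are zero in cycle ", sch$label[r])
    newc <- as.integer(rmultinom(1L, nR, w))
    keep <- newc > 0L
    np <- list(seqs = src$seqs[keep], cnt = newc[keep], fam = src$fam[keep])
    # variant emission for binder reads
    if (length(scenario@binders)) {
      addS <- character(); addF <- integer()
      for (k in seq_along(scenario@binders)) {
        if (vrate[k] <= 0) next
        idx <- which(np$fam == k)
        if (!length(idx)) next
        b <- scenario@binders[[k]]
        pmut <- 1 - (1 - vrate[k])^nchar(b@seedSequence) * (1 - vrate[k])
        for (i in idx) {
          nmut <- rbinom(1L, np$cnt[i], pmut)
          if (nmut == 0L) next
          nmut <- min(nmut, np$cnt[i])
          np$cnt[i] <- np$cnt[i] - nmut
          vars <- .mutateSeed(b@seedSequence, nmut, vrate[k])
          addS <- c(addS, paste0(design@fixed5, vars, design@fixed3))
          addF <- c(addF, rep(k, nmut))
        }
      }
      keep2 <- np$cnt > 0L
      np <- list(seqs = c(np$seqs[keep2], addS),
                 cnt = c(np$cnt[keep2], rep(1L, length(addS))),
                 fam = c(np$fam[keep2], addF))
      # aggregate duplicates introduced by mutation
      key <- paste(np$fam, np$seqs, sep = "\r")
      agg <- rowsum(np$cnt, key, reorder = FALSE)
      first <- !duplicated(key)
      np <- list(seqs = np$seqs[first], cnt = as.integer(agg[, 1L]),
                 fam = np$fam[first])
    }
    pools[[sch$label[r]]] <- np
  }

  lapply(setNames(names(pools), names(pools)), function(lbl) {
    p <- pools[[lbl]]
    cycleReads(lbl, p$seqs, p$cnt)
  })
}

#' Simulate droplet amplitudes for one ddPCR well
#'
#' Droplet occupancy is Poisson with mean `copiesPerUl * dropletVolumeUl`;
#' empty droplets draw their end-point amplitude from the negative
#' Gaussian, occupied droplets from the positive one.  Amplitudes are
#' returned unclassified.
#'
#' @param copiesPerUl template concentration (copies/uL, >= 0).
#' @param nDroplets number of droplets (> 0).
#' @param dropletVolumeUl droplet volume in uL (default 0.85 nL).
#' @param ampNegMean,ampPosMean Gaussian amplitude means for empty and
#'   occupied droplets (RFU); defaults mirror the ~5,500 vs ~11,000 RFU
#'   bands of saturated versus well-resolved wells.
#' @param ampSd Gaussian amplitude standard deviation (RFU).
#' @param seed optional random seed.
#' @param wellId well identifier.
#' @return an unclassified [DropletSet-class].
#' @export
simulateDroplets <- function(copiesPerUl, nDroplets,
                             dropletVolumeUl = 0.00085,
                             ampNegMean = 5500, ampPosMean = 11000,
                             ampSd = 500, seed = NULL, wellId = "A01") {
  if (copiesPerUl < 0) stop("copiesPerUl must be >= 0")
  stopifnot(nDroplets > 0, ampPosMean > ampNegMean, dropletVolumeUl > 0)
  .withSeed(seed, {
    lambda <- copiesPerUl * dropletVolumeUl
    occ <- rpois(nDroplets, lambda)
    amp <- rnorm(nDroplets,
                 mean = ifelse(occ > 0, ampPosMean, ampNegMean),
                 sd = ampSd)
    dropletSet(wellId, amp)
  })
}

#' Equilibrium bound fraction under single-site ligand depletion
#'
#' Fraction of total aptamer bound at equilibrium for total aptamer `A`,
#' total protein `P` and dissociation constant `Kd` (all in the same
#' concentration unit):
#' `fb = ((A + P + Kd) - sqrt((A + P + Kd)^2 - 4 A P)) / (2 A)`.
#' The stoichiometric limit `Kd = 0` gives `fb = min(P / A, 1)`.
#'
#' @param aptTotal,protTotal total concentrations (>= 0); vectorized.
#' @param kd dissociation constant (>= 0).
#' @return bound fraction between 0 and 1.
#' @examples
#' boundFraction(100, 100, 100)  # 0.382
#' @export
boundFraction <- function(aptTotal, protTotal, kd) {
  if (any(aptTotal < 0) || any(protTotal < 0) || any(kd < 0))
    stop("concentrations and kd must be >= 0")
  n <- max(length(aptTotal), length(protTotal), length(kd))
  A <- rep_len(aptTotal, n); P <- rep_len(protTotal, n); K <- rep_len(kd, n)
  fb <- numeric(n)
  zero_kd <- K == 0
  fb[zero_kd & A > 0] <- pmin(P[zero_kd & A > 0] / A[zero_kd & A > 0], 1)
  fb[zero_kd & A == 0] <- as.numeric(P[zero_kd & A == 0] > 0)
  i <- !zero_kd
  az <- i & A == 0
  fb[az] <- P[az] / (P[az] + K[az])
  i <- i & A > 0
  s <- A[i] + P[i] + K[i]
  fb[i] <- (s - sqrt(pmax(s^2 - 4 * A[i] * P[i], 0))) / (2 * A[i])
  pmin(pmax(fb, 0), 1)
}

#' Simulate a two-state aptamer melt curve
#'
#' The bound fraction `fb` follows the single-site ligand-depletion
#' solution ([boundFraction()]).  Fluorescence is a mixture of two
#' logistic melting transitions:
#' `RFU(T) = baseline + amplitude * ((1 - fb) * s((tmFree - T)/width) +
#' fb * s((tmBound - T)/width)) + noise`, with `s` the standard logistic.
#'
#' @param aptTotalnM,protTotalnM total aptamer and protein (nM).
#' @param kdnM dissociation constant (nM).
#' @param tmFreeC,tmBoundC melting temperatures of the free and bound
#'   states (degrees C, bound > free).
#' @param widthC transition width (degrees C).
#' @param amplitude,baseline fluorescence scale and offset (RFU).
#' @param noiseSd Gaussian noise SD (RFU); 0 gives a deterministic curve.
#' @param tempGrid temperature grid (default 4-90 C in 0.5 C steps).
#' @param seed optional random seed.
#' @param aptamerId,replicateId curve metadata.
#' @return a [MeltCurve-class].
#' @export
simulateMeltCurve <- function(aptTotalnM, protTotalnM, kdnM,
                              tmFreeC, tmBoundC, widthC = 2.5,
                              amplitude = 1000, baseline = 100,
                              noiseSd = 0, tempGrid = seq(4, 90, by = 0.5),
                              seed = NULL, aptamerId = "apt",
                              replicateId = "r1") {
  stopifnot(aptTotalnM >= 0, protTotalnM >= 0, kdnM >= 0,
            tmBoundC > tmFreeC, widthC > 0)
  fb <- boundFraction(aptTotalnM, protTotalnM, kdnM)
  .withSeed(seed, {
    rfu <- baseline + amplitude *
      ((1 - fb) * plogis((tmFreeC - tempGrid) / widthC) +
         fb * plogis((tmBoundC - tempGrid) / widthC))
    if (noiseSd > 0) rfu <- rfu + rnorm(length(tempGrid), sd = noiseSd)
    meltCurve(aptamerId, protTotalnM, tempGrid, rfu, replicateId)
  })
}
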