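#' @importFrom stats approx coef quantile residuals vcov
NULL

#' Negative first derivative of a melt curve
#'
#' Smooths the fluorescence with a Savitzky-Golay local-polynomial
#' filter (default window 11 points, degree 2) and differentiates it,
#' returning `-d(RFU)/dT` on the same grid.  The filter fits one-sided
#' polynomials at the ends, so endpoints are handled without padding.
#' Requires a uniform, strictly increasing temperature grid with at
#' least `smoothWindow` points.
#'
#' @param curve a [MeltCurve-class].
#' @param smoothWindow odd window length in points (default 11).
#' @param degree polynomial degree (default 2).
#' @return a [DerivativeCurve-class] with provenance "raw".
#' @export
negativeDerivative <- function(curve, smoothWindow = 11, degree = 2) {
  stopifnot(is(curve, "MeltCurve"))
  tt <- curve@temperature
  if (length(tt) < max(11, smoothWindow)) stop("need at least 11 grid points")
  dts <- diff(tt)
  if (any(dts <= 0)) stop("temperature grid must be strictly increasing")
  if (diff(range(dts)) > 1e-6 * mean(dts)) {
    stop("temperature grid must be uniform")
  }
  if (smoothWindow %% 2 == 0) stop("smoothWindow must be odd")
  d1 <- signal::sgolayfilt(curve@rfu, p = degree, n = smoothWindow,
                           m = 1, ts = mean(dts))
  new("DerivativeCurve", temperature = tt, negDeriv = -d1, provenance = "raw")
}

#' Subtract a blank derivative curve
#'
#' Pointwise difference of two derivative curves on the same grid.  The
#' blank is the free-aptamer-only well; subtracting it isolates the
#' bound-complex transition.  Mismatched grids are an error unless
#' `interpolate = TRUE`, which linearly interpolates the blank onto the
#' sample grid.
#'
#' @param sample,blank [DerivativeCurve-class] objects.
#' @param interpolate allow linear interpolation of the blank.
#' @return a [DerivativeCurve-class] with provenance "blank_subtracted".
#' @export
subtractBlank <- function(sample, blank, interpolate = FALSE) {
  stopifnot(is(sample, "DerivativeCurve"), is(blank, "DerivativeCurve"))
  if (!isTRUE(all.equal(sample@temperature, blank@temperature))) {
    if (!interpolate) stop("temperature grids differ; set interpolate = TRUE")
    b <- approx(blank@temperature, blank@negDeriv,
                xout = sample@temperature, rule = 2)$y
  } else {
    b <- blank@negDeriv
  }
  new("DerivativeCurve", temperature = sample@temperature,
      negDeriv = sample@negDeriv - b, provenance = "blank_subtracted")
}

#' Locate a melting temperature peak
#'
#' Tm is the grid location of the maximum of `-d(RFU)/dT` within the
#' search range, refined below grid resolution by a quadratic fit
#' through the three points around the maximum.  A flat curve (range of
#' the derivative within `noiseFloor`) yields a no-peak result rather
#' than an error.
#'
#' @param deriv a [DerivativeCurve-class].
#' @param searchRange numeric length-2 temperature window (default the
#'   whole grid).
#' @param noiseFloor minimum derivative range for a peak call (default 0:
#'   only an exactly flat curve is peakless).
#' @return list with `tm` (degrees C), `height` and `peak` (logical).
#' @export
findTm <- function(deriv, searchRange = NULL, noiseFloor = 0) {
  stopifnot(is(deriv, "DerivativeCurve"))
  tt <- deriv@temperature; y <- deriv@negDeriv
  if (!is.null(searchRange)) {
    if (searchRange[1] < min(tt) || searchRange[2] > max(tt))
      stop("searchRange outside the temperature grid")
    keep <- tt >= searchRange[1] & tt <= searchRange[2]
    tt <- tt[keep]; y <- y[keep]
  }
  if (diff(range(y)) <= noiseFloor) {
    return(list(tm = NA_real_, height = NA_real_, peak = FALSE))
  }
  i <- which.max(y)
  if (i == 1L || i == length(y)) {
    return(list(tm = tt[i], height = y[i], peak = TRUE))
  }
  # quadratic through (t[i-1], t[i], t[i+1]); vertex of the parabola
  h <- tt[i + 1L] - tt[i]
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  off <- if (denom == 0) 0 else 0.5 * (y[i - 1L] - y[i + 1L]) / denom * h
  off <- max(min(off, h), -h)
  ypk <- y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * (off / h)
  list(tm = tt[i] + off, height = ypk, peak = TRUE)
}

#' Melting-temperature shift on binding
#'
#' `tmBound - tmFree` (degrees C); negative values mean destabilization.
#'
#' @param tmBound,tmFree melting temperatures (degrees C).
#' @return shift in degrees C; vectorized.
#' @export
deltaTm <- function(tmBound, tmFree) {
  stopifnot(all(is.finite(tmBound)), all(is.finite(tmFree)))
  tmBound - tmFree
}

#' Build a concentration-response binding curve from melt curves
#'
#' For every replicate, the 0 nM (blank) well's `-d(RFU)/dT` is
#' subtracted from each protein-containing well's, and the residual
#' signal is read off at the bound-state melting temperature.
#' Replicates are then averaged per concentration (mean, sample SD, n).
#'
#' The default differentiation window here (41 points, i.e. 20.5 C at
#' the 0.5 C cadence) is much wider than the peak-location default of
#' [negativeDerivative()]: the readout is an amplitude estimate, where
#' smoothing attenuation is uniform across concentrations and cancels
#' into the fitted span, while the derivative's noise variance falls
#' roughly as the cube of the window length.  Narrow it for instruments
#' with drifting baselines.
#'
#' @param curves list of [MeltCurve-class] covering concentrations and
#'   replicates of one aptamer.
#' @param tmBoundC bound-state Tm at which to evaluate (degrees C); must
#'   lie on the grid span.  NULL (the default) locates it as the
#'   blank-subtracted derivative peak of the highest-concentration well
#'   within `searchRange`.
#' @param blankConcnM concentration regarded as blank (default 0).
#' @param searchRange temperature window for the automatic bound-state
#'   Tm search (default 10-85 C, avoiding endpoint artifacts).
#' @param smoothWindow,degree passed to [negativeDerivative()].
#' @return a [BindingCurve-class] with concentrations sorted ascending;
#'   the Tm used is recorded in the `tmBoundC` slot.
#' @export
buildBindingCurve <- function(curves, tmBoundC = NULL, blankConcnM = 0,
                              searchRange = c(10, 85),
                              smoothWindow = 41, degree = 2) {
  stopifnot(length(curves) > 0,
            all(vapply(curves, is, logical(1), class2 = "MeltCurve")))
  apt <- unique(vapply(curves, function(x) x@aptamerId, character(1)))
  if (length(apt) != 1L) stop("curves must belong to a single aptamer")
  reps <- vapply(curves, function(x) x@replicateId, character(1))
  concs <- vapply(curves, function(x) x@proteinConcnM, numeric(1))
  if (is.null(tmBoundC)) {
    # bound-state Tm from the highest-concentration well of the first
    # replicate, blank-subtracted, with the peak-location window
    hi <- which(concs == max(concs))[1L]
    bl <- which(reps == reps[hi] & concs == blankConcnM)
    if (!length(bl)) stop("replicate '", reps[hi], "' has no blank (",
                          blankConcnM, " nM) well")
    dv <- subtractBlank(negativeDerivative(curves[[hi]]),
                        negativeDerivative(curves[[bl[1L]]]))
    pk <- findTm(dv, searchRange = searchRange)
    if (!pk$peak) stop("no bound-state peak found to place tmBoundC")
    tmBoundC <- pk$tm
  }
  rows <- list()
  for (r in unique(reps)) {
    idx <- which(reps == r)
    bi <- idx[concs[idx] == blankConcnM]
    if (!length(bi)) stop("replicate '", r, "' has no blank (", blankConcnM, " nM) well")
    blank <- negativeDerivative(curves[[bi[1L]]], smoothWindow, degree)
    for (i in idx) {
      dv <- subtractBlank(negativeDerivative(curves[[i]], smoothWindow, degree),
                          blank)
      if (tmBoundC < min(dv@temperature) || tmBoundC > max(dv@temperature))
        stop("tmBoundC outside the temperature grid")
      sig <- approx(dv@temperature, dv@negDeriv, xout = tmBoundC)$y
      rows[[length(rows) + 1L]] <- data.frame(
        protein_conc_nM = concs[i], replicate = r, signal = sig,
        stringsAsFactors = FALSE
      )
    }
  }
  long <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(long, long$protein_conc_nM), function(d) {
    data.frame(protein_conc_nM = d$protein_conc_nM[1L],
               signal = mean(d$signal),
               sd = if (nrow(d) > 1L) sd(d$signal) else NA_real_,
               n = nrow(d))
  }))
  agg <- agg[order(agg$protein_conc_nM), , drop = FALSE]
  rownames(agg) <- NULL
  new("BindingCurve", aptamerId = apt, tmBoundC = as.numeric(tmBoundC),
      points = agg)
}

.kd_models <- list(
  hill = function(conc, p) {
    p[["floor"]] + p[["span"]] * conc^p[["hill"]] /
      (p[["kd"]]^p[["hill"]] + conc^p[["hill"]])
  },
  hyperbolic = function(conc, p) {
    p[["floor"]] + p[["span"]] * conc / (p[["kd"]] + conc)
  },
  depletion = function(conc, p, aptTotal) {
    p[["floor"]] + p[["span"]] * boundFraction(aptTotal, conc, p[["kd"]])
  }
)

#' Fit a dissociation constant to a binding curve
#'
#' Least-squares fit of the concentration response.  Models:
#' * `"hill"` — 4-parameter sigmoid
#'   `S(c) = floor + span c^h / (Kd^h + c^h)` with the exponent free;
#' * `"hyperbolic"` — the same with `h = 1`;
#' * `"depletion"` — `S(c) = floor + span * fb(A, c, Kd)` with `fb` the
#'   single-site ligand-depletion solution ([boundFraction()]) at known
#'   total aptamer `A` (`aptTotalnM`); this recovers the underlying Kd
#'   even when the aptamer concentration is comparable to Kd, where the
#'   sigmoid's midpoint is only an apparent constant (about Kd + A/2).
#'
#' Initialization is multi-start over a log-spaced Kd grid spanning the
#' data range; the lowest residual sum of squares wins.  The SE comes
#' from the fit covariance; an optional bootstrap (residual resampling)
#' adds a percentile CI.  Degenerate input (fewer than 5 distinct
#' concentrations, or constant signal) and optimizer failure yield a
#' non-converged result, not an error.
#'
#' @param binding a [BindingCurve-class].
#' @param model "hill", "hyperbolic" or "depletion".
#' @param aptTotalnM total aptamer concentration (nM); required for the
#'   depletion model.
#' @param bootstrapN bootstrap replicates (default 0 = none).
#' @param seed optional seed for the bootstrap.
#' @return a [KdFit-class].
#' @export
fitKd <- function(binding, model = c("hill", "hyperbolic", "depletion"),
                  aptTotalnM = NULL, bootstrapN = 0, seed = NULL) {
  model <- match.arg(model)
  stopifnot(is(binding, "BindingCurve"))
  d <- binding@points[, c("protein_conc_nM", "signal")]
  failed <- function() new("KdFit",
    kdnM = NA_real_, kdSEnM = NA_real_, params = numeric(), model = model,
    converged = FALSE, rss = NA_real_, bootCI = numeric(), data = d)
  if (length(unique(d$protein_conc_nM)) < 5 ||
      diff(range(d$signal)) == 0) return(failed())
  if (model == "depletion" && is.null(aptTotalnM))
    stop("the depletion model needs aptTotalnM")

  conc <- d$protein_conc_nM; sig <- d$signal
  pos <- conc[conc > 0]
  grid <- exp(seq(log(max(min(pos), 1e-3)), log(max(pos)), length.out = 8))
  span0 <- max(sig) - min(sig)
  floor0 <- min(sig)

  fit_one <- function(kd0) {
    start <- switch(model,
      hill = list(floor = floor0, span = span0, kd = kd0, hill = 1),
      hyperbolic = list(floor = floor0, span = span0, kd = kd0),
      depletion = list(floor = floor0, span = span0, kd = kd0))
    fml <- switch(model,
      hill = sig ~ floor + span * conc^hill / (kd^hill + conc^hill),
      hyperbolic = sig ~ floor + span * conc / (kd + conc),
      depletion = sig ~ floor + span * boundFraction(aptTotalnM, conc, kd))
    lower <- switch(model,
      hill = c(-Inf, 0, 1e-6, 0.2),
      c(-Inf, 0, 1e-6))
    upper <- switch(model,
      hill = c(Inf, Inf, Inf, 8),
      c(Inf, Inf, Inf))
    tryCatch(
      minpack.lm::nlsLM(fml,
        data = data.frame(conc = conc, sig = sig),
        start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }

  fits <- Filter(Negate(is.null), lapply(grid, fit_one))
  if (!length(fits)) return(failed())
  rss <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- coef(best)
  se <- tryCatch(sqrt(diag(vcov(best)))[["kd"]], error = function(e) NA_real_)

  bootCI <- numeric()
  if (bootstrapN > 0) {
    .withSeed(seed, {
      fitted_vals <- sig - residuals(best)
      res <- residuals(best)
      kds <- rep(NA_real_, bootstrapN)
      for (b in seq_len(bootstrapN)) {
        sig_b <- fitted_vals + sample(res, replace = TRUE)
        db <- d; db$signal <- sig_b
        bb <- binding; bb@points$signal <- sig_b
        fb <- fitKd(bb, model, aptTotalnM, bootstrapN = 0)
        if (fb@converged) kds[b] <- fb@kdnM
      }
      if (sum(!is.na(kds)) >= bootstrapN / 2) {
        bootCI <- unname(quantile(kds, c(0.025, 0.975), na.rm = TRUE))
      }
    })
  }

  new("KdFit",
    kdnM = unname(cf[["kd"]]), kdSEnM = unname(se), params = cf,
    model = model, converged = TRUE, rss = min(rss),
    bootCI = bootCI, data = d)
}
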