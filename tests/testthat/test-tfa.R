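grid <- seq(4, 90, by = 0.5)

test_that("negative derivative handles constant and linear curves exactly", {
  const <- meltCurve("a", 0, grid, rep(500, length(grid)))
  expect_true(all(abs(negativeDerivative(const)@negDeriv) < 1e-9))
  lin <- meltCurve("a", 0, grid, -2 * grid + 1000)
  expect_equal(negativeDerivative(lin)@negDeriv, rep(2, length(grid)),
               tolerance = 1e-9)
  bad <- new("MeltCurve", aptamerId = "a", proteinConcnM = 0, replicateId = "r",
             temperature = c(grid[1:20], grid[20] + cumsum(runif(20, 0.1, 1))),
             rfu = rnorm(40))
  expect_error(negativeDerivative(bad), "uniform")
})

test_that("the derivative of a noiseless melt peaks at the midpoint", {
  mc <- simulateMeltCurve(100, 0, 87, tmFreeC = 60, tmBoundC = 75)
  dv <- negativeDerivative(mc)
  expect_equal(dv@temperature[which.max(dv@negDeriv)], 60, tolerance = 0.5)
})

test_that("blank subtraction is exact pointwise algebra", {
  mc <- simulateMeltCurve(100, 100, 100, tmFreeC = 47.4, tmBoundC = 60)
  dv <- negativeDerivative(mc)
  expect_true(all(abs(subtractBlank(dv, dv)@negDeriv) < 1e-12))
  zero <- new("DerivativeCurve", temperature = dv@temperature,
              negDeriv = rep(0, length(grid)), provenance = "raw")
  expect_equal(subtractBlank(dv, zero)@negDeriv, dv@negDeriv)
  expect_equal(subtractBlank(dv, zero)@provenance, "blank_subtracted")
  short <- new("DerivativeCurve", temperature = grid[1:100],
               negDeriv = rep(0, 100), provenance = "raw")
  expect_error(subtractBlank(dv, short), "interpolate")
})

test_that("a 50% bound mixture minus the free blank shows the two lobes", {
  # fb = 0.5 when P = Kd + A/2
  mix <- simulateMeltCurve(100, 150, 100, tmFreeC = 47.4, tmBoundC = 60)
  blank <- simulateMeltCurve(100, 0, 100, tmFreeC = 47.4, tmBoundC = 60)
  dsub <- subtractBlank(negativeDerivative(mix), negativeDerivative(blank))
  at <- function(tC) dsub@negDeriv[which.min(abs(dsub@temperature - tC))]
  expect_gt(at(60), 0)    # bound transition appears
  expect_lt(at(47.4), 0)  # free transition is depleted
})

test_that("Tm location matches the simulated free state and is affine-invariant", {
  mc <- simulateMeltCurve(100, 0, 87, tmFreeC = 47.4, tmBoundC = 60,
                          noiseSd = 5, seed = 80)
  tm <- findTm(negativeDerivative(mc), searchRange = c(10, 85))
  expect_lt(abs(tm$tm - 47.4), 0.5)
  # affine rescaling of the fluorescence does not move the peak
  mc2 <- meltCurve("a", 0, mc@temperature, 3.7 * mc@rfu + 250)
  tm2 <- findTm(negativeDerivative(mc2), searchRange = c(10, 85))
  expect_equal(tm2$tm, tm$tm, tolerance = 1e-9)
  expect_equal(tm2$height, 3.7 * tm$height, tolerance = 1e-9)
})

test_that("two peaks separated by a valley are found in split ranges", {
  mix <- simulateMeltCurve(100, 150, 100, tmFreeC = 40, tmBoundC = 70)
  dv <- negativeDerivative(mix)
  lo <- findTm(dv, searchRange = c(10, 55))
  hi <- findTm(dv, searchRange = c(55, 85))
  expect_lt(abs(lo$tm - 40), 0.5)
  expect_lt(abs(hi$tm - 70), 0.5)
})

test_that("a flat derivative yields a no-peak result", {
  flat <- new("DerivativeCurve", temperature = grid,
              negDeriv = rep(0, length(grid)), provenance = "raw")
  res <- findTm(flat)
  expect_false(res$peak)
  expect_true(is.na(res$tm))
})

test_that("Tm shifts subtract as stated", {
  expect_equal(deltaTm(55, 47.4), 7.6)
  expect_lt(abs(deltaTm(55, 47.4) - 7.5), 0.15)  # the reported AHE1 shift
  expect_equal(deltaTm(50, 50), 0)
  expect_lt(deltaTm(45, 50), 0)
})

make_curves <- function(kd, concs = c(0, 25, 50, 100, 200, 300, 400, 800),
                        reps = 1, noise = 0, seed0 = 0) {
  out <- list(); i <- 0
  for (r in seq_len(reps)) for (p in concs) {
    i <- i + 1
    out[[i]] <- simulateMeltCurve(100, p, kd, tmFreeC = 47.4, tmBoundC = 60,
                                  noiseSd = noise,
                                  seed = if (noise > 0) seed0 + i else NULL,
                                  aptamerId = "AHE1",
                                  replicateId = paste0("r", r))
  }
  out
}

test_that("noiseless binding curves are proportional to the bound fraction", {
  concs <- c(0, 25, 50, 100, 200, 300, 400, 800)
  bc <- buildBindingCurve(make_curves(100), tmBoundC = 60)
  expect_equal(bc@points$protein_conc_nM, concs)
  expect_equal(bc@points$signal[1], 0)  # self-subtraction at 0 nM
  fb <- boundFraction(100, concs[-1], 100)
  ratio <- bc@points$signal[-1] / fb
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
})

test_that("the bound-state Tm is located automatically when not given", {
  bc <- buildBindingCurve(make_curves(100), tmBoundC = NULL)
  expect_lt(abs(bc@tmBoundC - 60), 1.5)  # wide smoothing shifts it slightly
  sig_auto <- bc@points$signal
  sig_man <- buildBindingCurve(make_curves(100), tmBoundC = 60)@points$signal
  expect_gt(cor(sig_auto, sig_man), 0.999)
})

test_that("replicate aggregation reports mean, SD and n", {
  bc <- buildBindingCurve(make_curves(100, reps = 3, noise = 10, seed0 = 90),
                          tmBoundC = 60)
  expect_true(all(bc@points$n == 3))
  expect_true(all(is.finite(bc@points$sd)))
  # a replicate without a blank is an error
  curves <- make_curves(100)[-1]
  expect_error(buildBindingCurve(curves, tmBoundC = 60), "blank")
})

test_that("fitKd recovers the generating constant from exact model data", {
  conc <- c(0, 10, 25, 50, 100, 200, 400, 800)
  # hill data with h = 1.3
  sig <- 5 + 80 * conc^1.3 / (87^1.3 + conc^1.3)
  bc <- new("BindingCurve", aptamerId = "x", tmBoundC = 60,
            points = data.frame(protein_conc_nM = conc, signal = sig,
                                sd = NA_real_, n = 1L))
  f <- fitKd(bc, model = "hill")
  expect_true(f@converged)
  expect_lt(abs(kd(f) - 87) / 87, 1e-3)
  expect_equal(unname(fitParams(f)[["hill"]]), 1.3, tolerance = 1e-3)
})

test_that("hyperbolic fits are exact across the Kd range", {
  conc <- c(0, 5, 15, 40, 100, 250, 600, 1500)
  for (kd0 in c(1, 10, 100, 1000)) {
    sig <- 2 + 50 * conc / (kd0 + conc)
    bc <- new("BindingCurve", aptamerId = "x", tmBoundC = 60,
              points = data.frame(protein_conc_nM = conc, signal = sig,
                                  sd = NA_real_, n = 1L))
    f <- fitKd(bc, model = "hyperbolic")
    expect_lt(abs(kd(f) - kd0) / kd0, 1e-5)
  }
})

test_that("degenerate binding data is flagged, not an error", {
  bc <- new("BindingCurve", aptamerId = "x", tmBoundC = 60,
            points = data.frame(protein_conc_nM = c(0, 25, 50, 100, 200),
                                signal = rep(3, 5), sd = NA_real_, n = 1L))
  f <- fitKd(bc, model = "hill")
  expect_false(f@converged)
  few <- new("BindingCurve", aptamerId = "x", tmBoundC = 60,
             points = data.frame(protein_conc_nM = c(0, 100, 300),
                                 signal = c(0, 10, 20), sd = NA_real_, n = 1L))
  expect_false(fitKd(few, model = "hill")@converged)
})

test_that("the ligand-depletion model recovers Kd from the noiseless pipeline", {
  bc <- buildBindingCurve(make_curves(87), tmBoundC = 60)
  f <- fitKd(bc, model = "depletion", aptTotalnM = 100)
  expect_lt(abs(kd(f) - 87) / 87, 0.02)
  # the free-exponent sigmoid instead reports the apparent midpoint Kd + A/2
  fh <- fitKd(bc, model = "hill")
  expect_lt(abs(kd(fh) - (87 + 50)) / 137, 0.25)
  expect_gt(kd(fh), kd(f))
})

test_that("bootstrap CIs bracket the point estimate", {
  bc <- buildBindingCurve(make_curves(87, reps = 3, noise = 30, seed0 = 91),
                          tmBoundC = 60)
  f <- fitKd(bc, model = "depletion", aptTotalnM = 100, bootstrapN = 60,
             seed = 92)
  expect_length(f@bootCI, 2)
  expect_true(f@bootCI[1] <= kd(f) && kd(f) <= f@bootCI[2])
})
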