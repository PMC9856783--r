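test_that("simulateLibrary reads have the designed structure and composition", {
  design <- libraryDesign()
  lib <- simulateLibrary(design, 100000, seed = 101)
  expect_equal(sum(counts(lib)), 100000)
  # structural identity on a single read
  one <- sequences(simulateLibrary(design, 1, seed = 5))
  expect_equal(nchar(one), 70)
  expect_equal(substr(one, 1, 20), design@fixed5)
  expect_equal(substr(one, 51, 70), design@fixed3)
  # empirical base composition of the random regions converges
  regions <- substr(sequences(lib), 21, 50)
  tab <- table(strsplit(paste(regions, collapse = ""), "")[[1]])
  fr <- as.numeric(tab[c("A", "C", "G", "T")]) / sum(tab)
  expect_lt(max(abs(fr - c(0.29, 0.29, 0.20, 0.22))), 0.01)
  # reproducible given seed
  expect_identical(sequences(lib), sequences(simulateLibrary(design, 100000, seed = 101)))
})

test_that("degenerate base composition gives homogeneous random regions", {
  design <- libraryDesign(baseProbs = c(A = 1, C = 0, G = 0, T = 0))
  lib <- simulateLibrary(design, 10, seed = 1)
  expect_true(all(substr(sequences(lib), 21, 50) == strrep("A", 30)))
})

test_that("library design rejects invalid flanks and compositions", {
  expect_error(libraryDesign(fixed5 = "ACGTX"), "ACGT")
  expect_error(libraryDesign(baseProbs = c(A = 0.5, C = 0.5, G = 0.1, T = 0)),
               "sum to 1")
})

# family frequency in a cycle = all reads whose variable region is within
# radius of the binder seed (independent of the generator's bookkeeping)
family_freq <- function(reads, design, seed_seq, radius = 6) {
  tb <- buildFrequencyTable(reads, design)
  d <- levenshtein(sequences(tb), seed_seq, cutoff = radius)
  sum(frequencies(tb)[d <= radius])
}

test_that("a binder with positive selective advantage enriches monotonically", {
  design <- libraryDesign()
  b <- binderSpec(rand_seqs(1), targetAffinity = 3, matrixAffinity = 1,
                  initialCopies = 10)
  sc <- selexScenario(design = design, binders = list(b),
                      readsPerCycle = 20000, seed = 301)
  pools <- simulateSelex(sc)
  expect_named(pools, c("C0", selexSchedule()$label))
  # reads per scheduled cycle are conserved
  expect_true(all(vapply(pools[-1], function(p) sum(counts(p)), numeric(1)) == 20000))
  pos <- c("C5+", "C6+", "C7+", "C8+", "C9+", "C10+")
  freqs <- vapply(pos, function(lbl) {
    family_freq(pools[[lbl]], design, b@seedSequence)
  }, numeric(1))
  expect_true(all(diff(freqs) > 0))
})

test_that("neutral binders stay near background frequency", {
  b <- binderSpec(rand_seqs(1), targetAffinity = 1, matrixAffinity = 1,
                  initialCopies = 5)
  sc <- selexScenario(binders = list(b), readsPerCycle = 20000, seed = 302)
  pools <- simulateSelex(sc)
  f <- family_freq(pools[["C10+"]], sc@design, b@seedSequence)
  # 5 initial copies in 20k; critical drift keeps the family rare
  expect_lt(f, 0.005)
})

test_that("counter-selection depletes a matrix-averse binder", {
  set.seed(303)
  b <- binderSpec(rand_seqs(1), targetAffinity = 5, matrixAffinity = 0.5,
                  initialCopies = 10)
  # short schedule: four shared positive rounds, then a branch split
  sch <- data.frame(
    label = c("C1+", "C2+", "C3+", "C4+", "C5+", "C5-"),
    source = c("C0", "C1+", "C2+", "C3+", "C4+", "C4+"),
    dna_nmol = 0.1, protein_pmol = 100,
    branch = c(rep("positive", 5), "counter"),
    stringsAsFactors = FALSE
  )
  sc <- selexScenario(binders = list(b), schedule = sch,
                      readsPerCycle = 20000, seed = 303)
  pools <- simulateSelex(sc)
  fp <- family_freq(pools[["C5+"]], sc@design, b@seedSequence)
  fn <- family_freq(pools[["C5-"]], sc@design, b@seedSequence)
  expect_gt(fp / fn, 2)
})

test_that("pure-background scenarios are allowed and reproducible", {
  sc <- selexScenario(binders = list(), readsPerCycle = 5000, seed = 304)
  p1 <- simulateSelex(sc)
  p2 <- simulateSelex(sc)
  expect_identical(sequences(p1[["C10+"]]), sequences(p2[["C10+"]]))
})

test_that("droplet occupancy follows the Poisson partition model", {
  # no template: all droplets from the negative cluster
  d0 <- simulateDroplets(0, 1000, seed = 401)
  expect_lt(max(amplitudes(d0)), 8250)
  # lambda = ln 2: positive fraction 1/2 up to binomial noise
  lam <- log(2)
  d <- simulateDroplets(lam / 0.00085, 20000, seed = 402)
  posfrac <- mean(amplitudes(d) > 8250)
  expect_lt(abs(posfrac - 0.5), 3 * sqrt(0.25 / 20000) + 1e-3)
  # heavy template: saturation; Poisson tail 1 - exp(-10) > 0.9999
  ds <- simulateDroplets(10 / 0.00085, 20000, seed = 403)
  expect_gte(mean(amplitudes(ds) > 8250), 0.999)
  expect_error(simulateDroplets(-1, 100), ">= 0")
})

test_that("positive fraction converges to 1 - exp(-lambda)", {
  for (lam in c(0.1, 0.7, 1.5)) {
    d <- simulateDroplets(lam / 0.00085, 50000, seed = 404 + round(10 * lam))
    posfrac <- mean(amplitudes(d) > 8250)
    expect_lt(abs(posfrac - (1 - exp(-lam))), 0.01)
  }
})

test_that("bound fraction follows the ligand-depletion closed form", {
  # quadratic solution at A = P = Kd = 100
  expect_equal(boundFraction(100, 100, 100), 0.3819660, tolerance = 1e-6)
  # no ligand / saturating ligand
  expect_equal(boundFraction(100, 0, 87), 0)
  expect_gt(boundFraction(100, 1e9, 87), 0.999)
  # stoichiometric limit Kd = 0
  expect_equal(boundFraction(100, 40, 0), 0.4)
  expect_equal(boundFraction(100, 250, 0), 1)
})

test_that("melt curves are deterministic, two-state and monotone decreasing", {
  mc <- simulateMeltCurve(100, 0, 87, tmFreeC = 47.4, tmBoundC = 60)
  mc2 <- simulateMeltCurve(100, 0, 87, tmFreeC = 47.4, tmBoundC = 60)
  expect_identical(mc@rfu, mc2@rfu)
  expect_true(all(diff(mc@rfu) < 0))
  # free-only: single transition at tmFree
  tm <- findTm(negativeDerivative(mc))
  expect_lt(abs(tm$tm - 47.4), 0.5)
  # saturating protein: transition moves to tmBound
  mcb <- simulateMeltCurve(100, 1e9, 87, tmFreeC = 47.4, tmBoundC = 60)
  tmb <- findTm(negativeDerivative(mcb))
  expect_lt(abs(tmb$tm - 60), 0.5)
  expect_error(simulateMeltCurve(100, 100, 100, tmFreeC = 60, tmBoundC = 50))
})
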