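test_that("levenshtein matches known distances", {
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  s <- rand_seqs(1)
  expect_equal(levenshtein(s, s), 0L)
  expect_equal(levenshtein(s, substr(s, 1, 29)), 1L)  # single deletion
})

test_that("levenshtein agrees with an independent full-DP oracle", {
  set.seed(30)
  n <- 300
  a <- rand_seqs(n, len = sample(25:32, n, replace = TRUE))
  b <- rand_seqs(n, len = sample(25:32, n, replace = TRUE))
  ours <- levenshtein(a, b)
  oracle <- mapply(function(x, y) as.integer(adist(x, y)), a, b, USE.NAMES = FALSE)
  expect_identical(ours, oracle)
})

test_that("cutoff-accelerated distance equals full DP whenever within cutoff", {
  set.seed(31)
  a <- rand_seqs(200, 30)
  b <- vapply(a, function(s) substitute_k(s, sample(0:10, 1)), character(1),
              USE.NAMES = FALSE)
  full <- levenshtein(a, b)
  cut <- levenshtein(a, b, cutoff = 6)
  expect_identical(cut[full <= 6], full[full <= 6])
  expect_true(all(cut[full > 6] == 7L))
})

test_that("levenshtein is a metric on random triples", {
  set.seed(32)
  for (i in 1:100) {
    x <- rand_seqs(3, len = sample(25:32, 3, replace = TRUE))
    dab <- levenshtein(x[1], x[2])
    dba <- levenshtein(x[2], x[1])
    dbc <- levenshtein(x[2], x[3])
    dac <- levenshtein(x[1], x[3])
    expect_identical(dab, dba)
    expect_equal(levenshtein(x[1], x[1]), 0L)
    expect_lte(dac, dab + dbc)
  }
})

test_that("sequences beyond the radius found separate families", {
  set.seed(33)
  s1 <- rand_seqs(1)
  s2 <- substitute_k(s1, 7)
  stopifnot(levenshtein(s1, s2) == 7)
  tb <- mk_table("C9+", c(s1, s2), c(60L, 40L))
  fams <- clusterFamilies(list(tb), radius = 6, threshold = 1e-4)
  expect_equal(nrow(families(fams)), 2L)
})

test_that("a seed and its variants within distance 6 form one family", {
  set.seed(34)
  seed <- rand_seqs(1)
  members <- c(seed, vapply(1:29, function(i) substitute_k(seed, sample(1:6, 1)),
                            character(1)))
  members <- unique(members)
  cnts <- c(1000L, rep(10L, length(members) - 1L))
  tb <- mk_table("C9+", members, cnts)
  fams <- clusterFamilies(list(tb), radius = 6)
  expect_equal(nrow(families(fams)), 1L)
  expect_equal(families(fams)$n_members, length(members))
  expect_equal(families(fams)$seed, seed)  # most frequent founds the family
})

# independent R oracle: the same ordered seed-linkage rule, but with a
# naive full adist() matrix
oracle_cluster <- function(seqs, freqs, radius = 6) {
  o <- order(-freqs, seqs)
  seqs <- seqs[o]
  D <- adist(seqs)
  seeds <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- which(D[i, seeds] <= radius)
    if (length(hit)) {
      assign[i] <- hit[1L]
    } else {
      seeds <- c(seeds, i)
      assign[i] <- length(seeds)
    }
  }
  split(seqs, assign)
}

test_that("clustering agrees with a brute-force full-matrix oracle", {
  for (rep in 1:3) {
    set.seed(40 + rep)
    n <- if (rep == 1) 12 else 60
    seeds <- planted_seeds(max(3, n %/% 8))
    seqs <- unique(c(seeds, vapply(seq_len(n - length(seeds)), function(i) {
      substitute_k(sample(seeds, 1), sample(0:8, 1))
    }, character(1))))
    cnts <- sample(10:1000, length(seqs), replace = TRUE)
    tb <- mk_table("C9+", seqs, cnts)
    fams <- familyFrequencies(clusterFamilies(list(tb), radius = 6), list(tb))
    got <- split(familyMembers(fams)$sequence, familyMembers(fams)$family_id)
    want <- oracle_cluster(seqs, cnts / sum(cnts))
    # same partition (family ids may differ in labeling)
    norm <- function(p) unname(lapply(p, sort)[order(vapply(p, min, character(1)))])
    expect_equal(norm(got), norm(want))
  }
})

test_that("clustering recovers well-separated planted families exactly", {
  set.seed(41)
  seeds <- planted_seeds(25, minDist = 12)
  truth <- list()
  seqs <- character(0); cnts <- integer(0)
  for (k in seq_along(seeds)) {
    mem <- unique(c(seeds[k],
      vapply(1:7, function(i) substitute_k(seeds[k], sample(1:6, 1)), character(1))))
    truth[[k]] <- sort(mem)
    seqs <- c(seqs, mem)
    cnts <- c(cnts, c(500L, rep(20L, length(mem) - 1L)))
  }
  sh <- sample(length(seqs))
  tb <- mk_table("C9+", seqs[sh], cnts[sh])
  fams <- clusterFamilies(list(tb), radius = 6)
  got <- lapply(split(familyMembers(fams)$sequence, familyMembers(fams)$family_id), sort)
  norm <- function(p) unname(p[order(vapply(p, `[`, character(1), 1L))])
  expect_equal(norm(got), norm(truth))
  # partition property: every retained sequence in exactly one family
  expect_setequal(familyMembers(fams)$sequence, seqs)
  expect_false(anyDuplicated(familyMembers(fams)$sequence) > 0)
})

test_that("family frequencies add member frequencies per cycle", {
  set.seed(42)
  seed <- rand_seqs(1)
  mem2 <- substitute_k(seed, 2)
  filler <- substitute_k(seed, 15)
  # member frequencies 0.02 and 0.007 -> family frequency 0.027
  t9 <- mk_table("C9+", c(seed, mem2, filler), c(20L, 7L, 973L))
  t10 <- mk_table("C10+", c(seed, filler), c(15L, 985L))
  fams <- clusterFamilies(list(t9, t10), radius = 6, threshold = 1e-4)
  fams <- familyFrequencies(fams, list(t9, t10))
  fid <- familyMembers(fams)$family_id[familyMembers(fams)$sequence == seed]
  expect_equal(unname(cycleFrequencies(fams)[fid, "C9+"]), 0.027)
  # conservation: one family holding every retained sequence
  fams1 <- clusterFamilies(list(t9), radius = 30)
  fams1 <- familyFrequencies(fams1, list(t9))
  expect_equal(nrow(families(fams1)), 1L)
  expect_equal(unname(cycleFrequencies(fams1)[1, "C9+"]), 1)
  # family absent from a cycle has frequency zero
  tb_only <- mk_table("C5+", c(filler, rand_seqs(1)), c(10L, 90L))
  fams2 <- familyFrequencies(clusterFamilies(list(t9), radius = 6),
                             list(t9, tb_only))
  fid2 <- familyMembers(fams2)$family_id[familyMembers(fams2)$sequence == mem2]
  expect_equal(unname(cycleFrequencies(fams2)[fid2, "C5+"]), 0)
  # integrity: members absent from every table are an error
  ghost <- mk_table("C9+", c(seed, rand_seqs(1)), c(1L, 9L))
  fams3 <- clusterFamilies(list(t9), radius = 6)
  expect_error(familyFrequencies(fams3, list(ghost)), "absent")
})
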