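#' Twelve-round selection schedule
#'
#' The stringency schedule of the reference selection: ten positive
#' rounds against the immobilized target plus two counter rounds against
#' the bare bead/tag matrix, with the DNA and protein inputs of each
#' round.  The pool is split after C8+ into the positive (C9+, C10+) and
#' counter (C9-, C10-) branches.  "C0" denotes the naive library.
#'
#' @return data.frame with columns label, source, dna_nmol, protein_pmol,
#'   branch (12 rows, C1+ .. C10-).
#' @examples
#' sch <- selexSchedule()
#' dnaProteinRatio(sch$dna_nmol, sch$protein_pmol)
#' @export
selexSchedule <- function() {
  data.frame(
    label = c("C1+", "C2+", "C3+", "C4+", "C5+", "C6+", "C7+", "C8+",
              "C9+", "C9-", "C10+", "C10-"),
    source = c("C0", "C1+", "C2+", "C3+", "C4+", "C5+", "C6+", "C7+",
               "C8+", "C8+", "C9+", "C9-"),
    dna_nmol = c(1.25, 0.47, 0.08, 0.13, 0.15, 0.04, 0.03, 0.08,
                 0.10, 0.10, 0.10, 0.10),
    protein_pmol = c(200, 200, 100, 100, 100, 200, 200, 200,
                     200, 200, 100, 100),
    branch = c(rep("positive", 9), "counter", "positive", "counter"),
    stringsAsFactors = FALSE
  )
}

#' Bundled reference sequences and tables
#'
#' In-memory fixtures for examples and tests: the three candidate
#' anti-HE4 aptamers (70-mers), the scrambled negative-control 70-mer,
#' the amplification primers, the library design, the selection schedule
#' and the artificial-urine recipe.
#'
#' @return list with elements `aptamers` (named character: AHE1, AHE2,
#'   AHE3), `scramble`, `primers` (forward, reverse), `design`
#'   ([LibraryDesign-class]), `schedule` (see [selexSchedule()]) and
#'   `urine` (see [urineRecipe()]).
#' @export
selexFixtures <- function() {
  list(
    aptamers = c(
      AHE1 = "TCGCACATTCCGCTTCTACCCCCAACCAACGTCTATACTTCCCCAACCTCCGTAAGTCCGTGTGTGCGAA",
      AHE2 = "TCGCACATTCCGCTTCTACCGCCAACATCGTACTCCATCTGCCACCCCCACGTAAGTCCGTGTGTGCGAA",
      AHE3 = "TCGCACATTCCGCTTCTACCCATCAATCAGCATACCCACCATGTACGTCCCGTAAGTCCGTGTGTGCGAA"
    ),
    scramble = "ATCGCGTCCGTCAATTACCTACGCTGCACCACTTATGAGCCGGTATCGCCATCCGTCAACTCACGCCTCC",
    primers = c(
      forward = "TCGCACATTCCGCTTCTACC",
      reverse = "TTCGCACACACGGACTTACG"
    ),
    design = libraryDesign(),
    schedule = selexSchedule(),
    urine = urineRecipe()
  )
}
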