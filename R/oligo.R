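#' GC content of a DNA sequence
#'
#' `100 * (#G + #C) / length`, computed on whichever sequence is given.
#' Candidate aptamers are conventionally compared on their variable
#' regions (trim the fixed flanks first), where the three candidates of
#' the bundled fixtures score 53.3, 60 and 50%.
#'
#' @param sequence character vector of ACGT sequences.
#' @param rounded round to the nearest integer percent (default FALSE).
#' @return percent between 0 and 100; vectorized.
#' @examples
#' gcContent("ACGT")  # 50
#' @export
gcContent <- function(sequence, rounded = FALSE) {
  if (any(!nzchar(sequence))) stop("empty sequence")
  if (!.valid_dna(sequence)) stop("sequence must contain only A, C, G, T")
  gc <- nchar(gsub("[AT]", "", sequence))
  pct <- 100 * gc / nchar(sequence)
  if (rounded) round(pct) else pct
}

#' Molar concentration from absorbance (Beer-Lambert)
#'
#' `c = A260 / (epsilon * l)` in mol/L.
#'
#' @param a260 absorbance at 260 nm.
#' @param epsilon molar extinction coefficient (L mol^-1 cm^-1, > 0).
#' @param pathCm optical path length (cm, default 1).
#' @return mol/L; vectorized.
#' @export
molarConcentration <- function(a260, epsilon, pathCm = 1) {
  if (any(epsilon <= 0)) stop("epsilon must be > 0")
  if (any(pathCm <= 0)) stop("pathCm must be > 0")
  a260 / (epsilon * pathCm)
}

#' Mass concentration from molar concentration
#'
#' `c(ng/uL) = c(mol/L) * MW * 1000`.
#'
#' @param cMolar concentration (mol/L, >= 0).
#' @param mw molecular weight (g/mol, >= 0).
#' @return ng/uL; vectorized.
#' @export
massConcentration <- function(cMolar, mw) {
  stopifnot(all(cMolar >= 0), all(mw >= 0))
  cMolar * mw * 1000
}

#' Expected molecular weight of a library design
#'
#' Sum over positions of the expected monomer mass: fixed flanks exactly,
#' random positions weighted by the base composition, plus an end
#' adjustment.  Defaults use the anhydrous nucleoside-monophosphate
#' convention for ssDNA with a 5'-OH end correction of -61.96 g/mol
#' (loss of one phosphate group plus gain of the terminal hydroxyls).
#' MW conventions differ between vendors at the per-mille level, so
#' comparisons against quoted constants should allow a few tenths of a
#' percent.
#'
#' @param design a [LibraryDesign-class].
#' @param monomerMasses named masses for A, C, G, T (g/mol).
#' @param endAdjustment additive end-group correction (g/mol).
#' @return expected MW (g/mol).
#' @export
meanMolecularWeight <- function(design,
                                monomerMasses = c(A = 313.21, C = 289.18,
                                                  G = 329.21, T = 304.2),
                                endAdjustment = -61.96) {
  stopifnot(is(design, "LibraryDesign"))
  stopifnot(all(c("A", "C", "G", "T") %in% names(monomerMasses)))
  fixed <- paste0(design@fixed5, design@fixed3)
  tab <- table(factor(strsplit(fixed, "")[[1]], levels = c("A", "C", "G", "T")))
  fixed_mass <- sum(as.numeric(tab) * monomerMasses[c("A", "C", "G", "T")])
  per_random <- sum(design@baseProbs[c("A", "C", "G", "T")] *
                      monomerMasses[c("A", "C", "G", "T")])
  fixed_mass + design@randomLength * per_random + endAdjustment
}

# Ion stoichiometry of the artificial-urine recipe compounds.
# Nonionic organics (urea, creatinine, uric acid) contribute no ions.
.ION_STOICHIOMETRY <- list(
  "Na2SO4"         = c(Na = 2, SO4 = 1),
  "C5H4N4O3"       = c(),                     # uric acid
  "Na3C6H5O7.2H2O" = c(Na = 3, citrate = 1),
  "C4H7N3O"        = c(),                     # creatinine
  "CH4N2O"         = c(),                     # urea
  "KCl"            = c(K = 1, Cl = 1),
  "NaCl"           = c(Na = 1, Cl = 1),
  "CaCl2"          = c(Ca = 1, Cl = 2),
  "NH4Cl"          = c(NH4 = 1, Cl = 1),
  "K2C2O4.H2O"     = c(K = 2, oxalate = 1),
  "MgSO4.7H2O"     = c(Mg = 1, SO4 = 1),
  "NaH2PO4.2H2O"   = c(Na = 1, PO4 = 1),
  "Na2HPO4.2H2O"   = c(Na = 2, PO4 = 1)
)

#' Artificial urine recipe
#'
#' The 13-compound artificial-urine formulation used as the selection and
#' binding matrix, as compound molarities (mM).
#'
#' @return data.frame with columns `compound`, `mM`.
#' @export
urineRecipe <- function() {
  data.frame(
    compound = c("Na2SO4", "C5H4N4O3", "Na3C6H5O7.2H2O", "C4H7N3O",
                 "CH4N2O", "KCl", "NaCl", "CaCl2", "NH4Cl", "K2C2O4.H2O",
                 "MgSO4.7H2O", "NaH2PO4.2H2O", "Na2HPO4.2H2O"),
    mM = c(11.965, 1.487, 2.450, 7.791, 249.750, 30.953, 30.053, 1.663,
           23.667, 0.19, 4.389, 18.667, 4.667),
    stringsAsFactors = FALSE
  )
}

#' Total ion concentrations of a recipe
#'
#' Sums `molarity x stoichiometric count` over every compound, using the
#' built-in stoichiometry table (complete dissociation of the salts;
#' urea, creatinine and uric acid contribute nothing).  Note that the
#' full-recipe sodium total of the default artificial urine is 89.3 mM by
#' direct summation.
#'
#' @param recipe data.frame with columns `compound`, `mM` (default the
#'   built-in [urineRecipe()]).
#' @param digits decimals for reporting (default 1); NULL for raw values.
#' @return named numeric of ion totals (mM).
#' @examples
#' ionTotals()[["Mg"]]  # 4.4
#' @export
ionTotals <- function(recipe = urineRecipe(), digits = 1) {
  stopifnot(all(c("compound", "mM") %in% names(recipe)),
            all(recipe$mM >= 0))
  unknown <- setdiff(recipe$compound, names(.ION_STOICHIOMETRY))
  if (length(unknown)) {
    stop("unknown compound(s): ", paste(unknown, collapse = ", "))
  }
  ions <- c("Na", "K", "NH4", "Ca", "Mg", "Cl", "SO4", "PO4",
            "citrate", "oxalate")
  tot <- stats::setNames(numeric(length(ions)), ions)
  for (i in seq_len(nrow(recipe))) {
    st <- .ION_STOICHIOMETRY[[recipe$compound[i]]]
    for (ion in names(st)) tot[ion] <- tot[ion] + recipe$mM[i] * st[[ion]]
  }
  if (!is.null(digits)) tot <- round(tot, digits)
  tot
}
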