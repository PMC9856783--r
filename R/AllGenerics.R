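#' @importFrom methods setGeneric setMethod
NULL

#' Accessors for aptacycle classes
#'
#' Standard accessors: `cycleLabel()`, `sequences()`, `counts()`,
#' `frequencies()`, `totalReads()`, `amplitudes()`, `threshold()`,
#' `families()`, `familyMembers()`, `cycleFrequencies()`, `kd()`,
#' `fitParams()`.
#'
#' @param object an aptacycle S4 object.
#' @param ... additional arguments, ignored.
#' @return the slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cycleLabel", function(object) standardGeneric("cycleLabel"))
#' @rdname accessors
#' @export
setGeneric("sequences", function(object) standardGeneric("sequences"))

# counts() is the BiocGenerics generic, re-exported with methods here
#' @rdname accessors
#' @importFrom BiocGenerics counts
#' @export
counts <- BiocGenerics::counts
#' @rdname accessors
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("totalReads", function(object) standardGeneric("totalReads"))
#' @rdname accessors
#' @export
setGeneric("rejections", function(object) standardGeneric("rejections"))
#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("threshold", function(object) standardGeneric("threshold"))
#' @rdname accessors
#' @export
setGeneric("nPositive", function(object) standardGeneric("nPositive"))
#' @rdname accessors
#' @export
setGeneric("nNegative", function(object) standardGeneric("nNegative"))
#' @rdname accessors
#' @export
setGeneric("families", function(object) standardGeneric("families"))
#' @rdname accessors
#' @export
setGeneric("familyMembers", function(object) standardGeneric("familyMembers"))
#' @rdname accessors
#' @export
setGeneric("cycleFrequencies", function(object) standardGeneric("cycleFrequencies"))
#' @rdname accessors
#' @export
setGeneric("kd", function(object) standardGeneric("kd"))
#' @rdname accessors
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))

#' @rdname accessors
#' @export
setMethod("cycleLabel", "CycleReads", function(object) object@cycleLabel)
#' @rdname accessors
#' @export
setMethod("cycleLabel", "FrequencyTable", function(object) object@cycleLabel)
#' @rdname accessors
#' @export
setMethod("sequences", "CycleReads", function(object) object@sequences)
#' @rdname accessors
#' @export
setMethod("sequences", "FrequencyTable", function(object) object@sequences)
#' @rdname accessors
#' @export
setMethod("counts", "CycleReads", function(object, ...) object@counts)
#' @rdname accessors
#' @export
setMethod("counts", "FrequencyTable", function(object, ...) object@counts)
#' @rdname accessors
#' @export
setMethod("frequencies", "FrequencyTable", function(object) {
  stats::setNames(object@frequencies, object@sequences)
})
#' @rdname accessors
#' @export
setMethod("totalReads", "FrequencyTable", function(object) object@totalReads)
#' @rdname accessors
#' @export
setMethod("rejections", "FrequencyTable", function(object) object@rejections)
#' @rdname accessors
#' @export
setMethod("amplitudes", "DropletSet", function(object) object@amplitudes)
#' @rdname accessors
#' @export
setMethod("threshold", "DropletSet", function(object) {
  if (length(object@threshold)) object@threshold else NA_real_
})
#' @rdname accessors
#' @export
setMethod("nPositive", "DropletSet", function(object) {
  if (length(object@nPositive)) object@nPositive else NA_integer_
})
#' @rdname accessors
#' @export
setMethod("nNegative", "DropletSet", function(object) {
  if (length(object@nNegative)) object@nNegative else NA_integer_
})
#' @rdname accessors
#' @export
setMethod("families", "FamilySet", function(object) object@families)
#' @rdname accessors
#' @export
setMethod("familyMembers", "FamilySet", function(object) object@members)
#' @rdname accessors
#' @export
setMethod("cycleFrequencies", "FamilySet", function(object) object@cycleFrequencies)
#' @rdname accessors
#' @export
setMethod("kd", "KdFit", function(object) object@kdnM)
#' @rdname accessors
#' @export
setMethod("fitParams", "KdFit", function(object) object@params)

setMethod("show", "LibraryDesign", function(object) {
  cat("LibraryDesign:", object@fixed5, "-N", object@randomLength, "-",
      object@fixed3, "\n", sep = "")
  cat("  base probabilities:",
      paste(names(object@baseProbs), object@baseProbs, sep = "=", collapse = " "),
      "\n")
})

setMethod("show", "CycleReads", function(object) {
  cat("CycleReads '", object@cycleLabel, "': ", sum(object@counts),
      " reads, ", length(object@sequences), " unique sequences\n", sep = "")
})

setMethod("show", "FrequencyTable", function(object) {
  cat("FrequencyTable '", object@cycleLabel, "': ", length(object@sequences),
      " sequences over ", object@totalReads, " retained reads\n", sep = "")
  if (length(object@rejections) && sum(object@rejections) > 0) {
    cat("  rejections:",
        paste(names(object@rejections), object@rejections,
              sep = "=", collapse = " "), "\n")
  }
})

setMethod("show", "FamilySet", function(object) {
  cat("FamilySet:", nrow(object@families), "families,",
      nrow(object@members), "member sequences\n")
  if (ncol(object@cycleFrequencies))
    cat("  cycles:", paste(colnames(object@cycleFrequencies), collapse = " "), "\n")
})

setMethod("show", "DropletSet", function(object) {
  cat("DropletSet well '", object@wellId, "': ", length(object@amplitudes),
      " droplets", sep = "")
  if (length(object@threshold)) {
    cat(", threshold ", format(object@threshold, digits = 5),
        " (", object@nPositive, " pos / ", object@nNegative, " neg)", sep = "")
  }
  cat("\n")
})

setMethod("show", "QuantResult", function(object) {
  cat("QuantResult: lambda =", format(object@lambda, digits = 4),
      "copies/droplet;", format(object@copiesPerUl, digits = 4), "copies/uL\n")
  cat("  95% CI [", format(object@ci[1], digits = 4), ", ",
      format(object@ci[2], digits = 4), "]; QC ",
      ifelse(object@qcPass, "pass", "FAIL"),
      ifelse(object@saturated, "; SATURATED", ""), "\n", sep = "")
})

setMethod("show", "MeltCurve", function(object) {
  cat("MeltCurve '", object@aptamerId, "' (", object@replicateId, "): ",
      object@proteinConcnM, " nM protein, ", length(object@temperature),
      " points over ", min(object@temperature), "-", max(object@temperature),
      " C\n", sep = "")
})

setMethod("show", "BindingCurve", function(object) {
  cat("BindingCurve '", object@aptamerId, "' at Tm(bound) = ",
      object@tmBoundC, " C: ", nrow(object@points),
      " concentrations\n", sep = "")
})

setMethod("show", "KdFit", function(object) {
  cat("KdFit (", object@model, "): Kd = ", format(object@kdnM, digits = 4),
      " +/- ", format(object@kdSEnM, digits = 3), " nM",
      ifelse(object@converged, "", " [NOT CONVERGED]"), "\n", sep = "")
})
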