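#' @import methods
NULL

.FRACTION_TOL <- 1e-9

#' MIDVector: mass isotopologue distribution for one amino acid in one sample
#'
#' Ordered non-negative intensities (or unitless fractions) over the
#' isotopologues M+0..M+xmax of a single compound, where the mass shift x
#' counts incorporated heavy nitrogen atoms. Raw detector intensities and
#' normalized fractions share the container; `isFractional` records which
#' of the two the values are.
#'
#' @slot aminoAcid compound name, e.g. `"proline"`.
#' @slot values numeric vector of length xmax + 1; element x + 1 is the
#'   M+x signal. All values must be non-negative; fractional vectors must
#'   sum to 1 within 1e-9.
#' @slot isFractional logical flag: `TRUE` once the vector has been
#'   normalized to fractions of the compound total.
#' @slot sampleId optional sample identifier carried through for error
#'   messages and reporting.
#'
#' @exportClass MIDVector
setClass("MIDVector",
  slots = c(
    aminoAcid = "character",
    values = "numeric",
    isFractional = "logical",
    sampleId = "character"
  ),
  prototype = prototype(isFractional = FALSE, sampleId = NA_character_)
)

setValidity("MIDVector", function(object) {
  msg <- character()
  if (length(object@aminoAcid) != 1L || is.na(object@aminoAcid))
    msg <- c(msg, "aminoAcid must be a single non-missing name")
  if (length(object@values) < 1L)
    msg <- c(msg, "values must contain at least M+0")
  if (anyNA(object@values))
    msg <- c(msg, "values must not contain NA")
  else if (any(object@values < 0))
    msg <- c(msg, "isotopologue values must be non-negative")
  if (isTRUE(object@isFractional) && !anyNA(object@values) &&
      abs(sum(object@values) - 1) > .FRACTION_TOL)
    msg <- c(msg, sprintf(
      "fractional values must sum to 1 (got %.12g)", sum(object@values)))
  if (length(msg)) msg else TRUE
})

#' Construct a MIDVector
#'
#' @param aminoAcid compound name.
#' @param values numeric M+0..M+xmax signals.
#' @param isFractional whether `values` are fractions summing to 1.
#' @param sampleId optional sample identifier.
#' @return A [MIDVector-class] object.
#' @examples
#' MIDVector("proline", c(80, 20))
#' @export
MIDVector <- function(aminoAcid, values, isFractional = FALSE,
                      sampleId = NA_character_) {
  new("MIDVector", aminoAcid = as.character(aminoAcid),
      values = as.numeric(values),
      isFractional = isTRUE(isFractional),
      sampleId = as.character(sampleId))
}

#' AminoAcidSpec: identity and nitrogen stoichiometry of an amino acid
#'
#' @slot name amino-acid name.
#' @slot nAtoms number of nitrogen atoms per molecule (proline and
#'   glutamate 1, glutamine 2).
#' @slot internalStandard whether this compound is the spiked internal
#'   standard rather than an analyte.
#'
#' @exportClass AminoAcidSpec
setClass("AminoAcidSpec",
  slots = c(name = "character", nAtoms = "integer",
            internalStandard = "logical"),
  prototype = prototype(internalStandard = FALSE)
)

setValidity("AminoAcidSpec", function(object) {
  if (length(object@nAtoms) != 1L || is.na(object@nAtoms) ||
      object@nAtoms < 1L)
    return("nAtoms must be a single integer >= 1")
  TRUE
})

#' Construct an AminoAcidSpec
#'
#' @param name amino-acid name.
#' @param nAtoms nitrogen atoms per molecule.
#' @param internalStandard internal-standard flag.
#' @return An [AminoAcidSpec-class] object.
#' @examples
#' aminoAcidSpec("glutamine", 2)
#' @export
aminoAcidSpec <- function(name, nAtoms, internalStandard = FALSE) {
  new("AminoAcidSpec", name = as.character(name),
      nAtoms = as.integer(nAtoms),
      internalStandard = isTRUE(internalStandard))
}

#' LabellingResult: fractional and net 15N labelling for one compound
#'
#' Holds the per-isotopologue fractional labelling (the share of each
#' M+x in the compound total), the net labelling relative to the T0
#' natural-abundance baseline (signed, sums to zero), and the mean
#' number of labelled nitrogen atoms per molecule derived from the net
#' distribution.
#'
#' @slot aminoAcid compound name.
#' @slot fractional per-isotopologue fractions in [0, 1], summing to 1.
#' @slot net signed per-isotopologue net fractions (sample minus T0),
#'   summing to 0; length 0 until [netLabelling()] has been applied.
#' @slot meanLabelledAtoms mean labelled N atoms per molecule,
#'   `sum(x * net(x))`; `NA` until net labelling is available.
#' @slot sampleId optional sample identifier.
#'
#' @exportClass LabellingResult
setClass("LabellingResult",
  slots = c(
    aminoAcid = "character",
    fractional = "numeric",
    net = "numeric",
    meanLabelledAtoms = "numeric",
    sampleId = "character"
  ),
  prototype = prototype(net = numeric(0), meanLabelledAtoms = NA_real_,
                        sampleId = NA_character_)
)

setValidity("LabellingResult", function(object) {
  msg <- character()
  if (length(object@fractional) &&
      abs(sum(object@fractional) - 1) > .FRACTION_TOL)
    msg <- c(msg, "fractional labelling must sum to 1")
  if (length(object@fractional) && any(object@fractional < -.FRACTION_TOL))
    msg <- c(msg, "fractional labelling must be non-negative")
  if (length(object@net)) {
    if (length(object@net) != length(object@fractional))
      msg <- c(msg, "net and fractional must have equal length")
    if (abs(sum(object@net)) > .FRACTION_TOL)
      msg <- c(msg, "net labelling must sum to 0")
  }
  if (length(msg)) msg else TRUE
})

#' ArtifactModel: derivatization M+1 shift artifact
#'
#' AccQTag derivatization shifts a fraction r of each isotopologue's
#' signal up by one mass unit, adding an artificial M+1 enrichment
#' (around 20 percent in the source experiments). The model is
#' estimated from 15N-free external standards and inverted per sample.
#'
#' @slot r fraction of signal shifted up one mass unit, in [0, 1).
#' @slot mode correction mode: `"shift_deconvolution"` (invert the
#'   shift convolution recursively) or `"subtract_standard"` (subtract
#'   the standard's M+1 fraction from M+1 and return it to M+0).
#'
#' @exportClass ArtifactModel
setClass("ArtifactModel",
  slots = c(r = "numeric", mode = "character"),
  prototype = prototype(mode = "shift_deconvolution")
)

setValidity("ArtifactModel", function(object) {
  if (length(object@r) != 1L || is.na(object@r) ||
      object@r < 0 || object@r >= 1)
    return("artifact fraction r must lie in [0, 1)")
  if (!object@mode %in% c("shift_deconvolution", "subtract_standard"))
    return("mode must be 'shift_deconvolution' or 'subtract_standard'")
  TRUE
})

#' Construct an ArtifactModel
#'
#' @param r artifact fraction in [0, 1).
#' @param mode correction mode (see [ArtifactModel-class]).
#' @return An [ArtifactModel-class] object.
#' @examples
#' artifactModel(0.2)
#' @export
artifactModel <- function(r, mode = c("shift_deconvolution",
                                      "subtract_standard")) {
  mode <- match.arg(mode)
  new("ArtifactModel", r = as.numeric(r), mode = mode)
}

#' CalibrationCurve: linear external calibration of peak area
#'
#' Ordinary least-squares line of detector area against standard
#' concentration for one amino acid, with the fitted area range kept so
#' that inversions outside it can raise an extrapolation warning.
#'
#' @slot aminoAcid compound name.
#' @slot slope area per micromolar; must be positive.
#' @slot intercept area at zero concentration.
#' @slot rSquared coefficient of determination of the fit.
#' @slot areaRange range of areas covered by the standards.
#'
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  slots = c(aminoAcid = "character", slope = "numeric",
            intercept = "numeric", rSquared = "numeric",
            areaRange = "numeric")
)

setValidity("CalibrationCurve", function(object) {
  if (length(object@slope) != 1L || is.na(object@slope) ||
      object@slope <= 0)
    return("calibration slope must be a single positive number")
  if (length(object@areaRange) != 2L)
    return("areaRange must have length 2")
  TRUE
})

#' PrimerSpec: qPCR primer pair amplification efficiency
#'
#' @slot gene gene (primer pair) name.
#' @slot efficiency amplification factor E per cycle, in (1, 2.2];
#'   E = 2 is perfect doubling.
#'
#' @exportClass PrimerSpec
setClass("PrimerSpec", slots = c(gene = "character", efficiency = "numeric"))

setValidity("PrimerSpec", function(object) {
  if (length(object@efficiency) != 1L || is.na(object@efficiency) ||
      object@efficiency <= 1 || object@efficiency > 2.2)
    return("primer efficiency must lie in (1, 2.2]")
  TRUE
})

#' Construct a PrimerSpec
#'
#' @param gene gene name.
#' @param efficiency per-cycle amplification factor in (1, 2.2].
#' @return A [PrimerSpec-class] object.
#' @examples
#' primerSpec("BnaC.UBQ11", 2.0)
#' @export
primerSpec <- function(gene, efficiency) {
  new("PrimerSpec", gene = as.character(gene),
      efficiency = as.numeric(efficiency))
}
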