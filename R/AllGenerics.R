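#' Accessors for TraceN15 classes
#'
#' Small accessor generics for the S4 containers: `aminoAcid()` the
#' compound name, `midValues()` the isotopologue vector,
#' `isFractional()` the normalization flag, `fractions()` the
#' fractional labelling, `netFractions()` the net labelling,
#' `artifactFraction()` the M+1 shift fraction r, and `efficiency()`
#' the qPCR amplification factor.
#'
#' @param x an object of the documented class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("aminoAcid", function(x) standardGeneric("aminoAcid"))

#' @rdname accessors
#' @export
setGeneric("midValues", function(x) standardGeneric("midValues"))

#' @rdname accessors
#' @export
setGeneric("isFractional", function(x) standardGeneric("isFractional"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setGeneric("netFractions", function(x) standardGeneric("netFractions"))

#' @rdname accessors
#' @export
setGeneric("artifactFraction", function(x) standardGeneric("artifactFraction"))

#' @rdname accessors
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))

#' Mean labelled nitrogen atoms per molecule
#'
#' The first moment of the net labelling distribution,
#' `sum(x * net(x))` over isotopologues M+x: the mean number of
#' nitrogen atoms per molecule that became 15N over the labelling
#' period, net of natural abundance. Because the net distribution sums
#' to zero, the value is signed and bounded by the compound's nitrogen
#' count in magnitude.
#'
#' @param x a numeric vector of net fractions (summing to 0) or a
#'   [LabellingResult-class] whose net slot is filled.
#' @return A single number, atoms per molecule.
#' @examples
#' meanLabelledAtoms(c(-0.10, 0.10))          # 1-N amino acid, 0.1
#' meanLabelledAtoms(c(-0.15, 0.05, 0.10))    # 2-N amino acid, 0.25
#' @export
setGeneric("meanLabelledAtoms", function(x) standardGeneric("meanLabelledAtoms"))

#' @rdname accessors
#' @export
setMethod("aminoAcid", "MIDVector", function(x) x@aminoAcid)

#' @rdname accessors
#' @export
setMethod("aminoAcid", "LabellingResult", function(x) x@aminoAcid)

#' @rdname accessors
#' @export
setMethod("aminoAcid", "AminoAcidSpec", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("aminoAcid", "CalibrationCurve", function(x) x@aminoAcid)

#' @rdname accessors
#' @export
setMethod("midValues", "MIDVector", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("isFractional", "MIDVector", function(x) x@isFractional)

#' @rdname accessors
#' @export
setMethod("fractions", "LabellingResult", function(x) x@fractional)

#' @rdname accessors
#' @export
setMethod("netFractions", "LabellingResult", function(x) x@net)

#' @rdname accessors
#' @export
setMethod("artifactFraction", "ArtifactModel", function(x) x@r)

#' @rdname accessors
#' @export
setMethod("efficiency", "PrimerSpec", function(x) x@efficiency)

setMethod("show", "MIDVector", function(object) {
  cat(sprintf("MIDVector: %s (%s)\n", object@aminoAcid,
              if (object@isFractional) "fractional" else "intensities"))
  v <- object@values
  names(v) <- paste0("M+", seq_along(v) - 1L)
  print(signif(v, 6))
  invisible(object)
})

setMethod("show", "LabellingResult", function(object) {
  cat(sprintf("LabellingResult: %s\n", object@aminoAcid))
  tab <- data.frame(isotopologue = paste0("M+", seq_along(object@fractional) - 1L),
                    fractional = signif(object@fractional, 6))
  if (length(object@net)) tab$net <- signif(object@net, 6)
  print(tab, row.names = FALSE)
  if (!is.na(object@meanLabelledAtoms))
    cat(sprintf("mean labelled N atoms/molecule: %.6g\n",
                object@meanLabelledAtoms))
  invisible(object)
})

setMethod("show", "ArtifactModel", function(object) {
  cat(sprintf("ArtifactModel: r = %.4g (%s)\n", object@r, object@mode))
  invisible(object)
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve: %s  area = %.4g * conc + %.4g  (R2 = %.4f)\n",
    object@aminoAcid, object@slope, object@intercept, object@rSquared))
  invisible(object)
})

setMethod("show", "PrimerSpec", function(object) {
  cat(sprintf("PrimerSpec: %s  E = %.4f\n", object@gene, object@efficiency))
  invisible(object)
})
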