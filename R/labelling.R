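#' Fractional 15N labelling from an isotopologue vector
#'
#' Normalizes the M+0..M+xmax signal vector of one compound to fractions
#' of the compound total: `fraction(x) = [M+x] / sum_y [M+y]`. This is
#' the "true 15N labelling" of each isotopologue (reported as percent at
#' output boundaries; stored as fractions internally).
#'
#' @param mid a [MIDVector-class] of raw intensities or fractions.
#' @return A [LabellingResult-class] with the fractional slot filled and
#'   the net slot empty (see [netLabelling()]).
#' @examples
#' fractionalLabelling(MIDVector("proline", c(80, 20)))
#' @seealso [correctM1Artifact()] to remove the derivatization M+1
#'   artifact before normalization.
#' @export
fractionalLabelling <- function(mid) {
  stopifnot(is(mid, "MIDVector"))
  v <- midValues(mid)
  tot <- sum(v)
  if (tot <= 0)
    stop(sprintf(
      "all-zero isotopologue vector for %s (sample %s): fractional labelling undefined",
      aminoAcid(mid), mid@sampleId), call. = FALSE)
  new("LabellingResult", aminoAcid = aminoAcid(mid), fractional = v / tot,
      sampleId = mid@sampleId)
}

#' Estimate the derivatization M+1 artifact from unlabelled standards
#'
#' AccQTag derivatization shifts part of each isotopologue's signal up
#' one mass unit; the shift fraction r is estimated as the mean excess
#' M+1 fraction observed in 15N-free external standards, above a
#' configurable natural-abundance baseline. The default baseline is
#' zero: the T0 subtraction performed by [netLabelling()] absorbs the
#' natural 15N abundance, so the standard's whole M+1 share is treated
#' as artifact. A theoretical baseline (binomial M+1 share at natural
#' 15N abundance 0.003663 per N atom) is available instead.
#'
#' @param standards a list of [MIDVector-class] objects measured on
#'   unlabelled standards (raw intensities or fractions).
#' @param baseline `"zero"` (default) or `"theoretical"`.
#' @param nAtoms nitrogen atoms per molecule; only used for the
#'   theoretical baseline.
#' @param mode correction mode recorded in the returned model.
#' @return An [ArtifactModel-class].
#' @examples
#' stds <- list(MIDVector("proline", c(0.80, 0.20), isFractional = TRUE))
#' estimateM1Artifact(stds)   # r = 0.2
#' @export
estimateM1Artifact <- function(standards,
                               baseline = c("zero", "theoretical"),
                               nAtoms = 1L,
                               mode = c("shift_deconvolution",
                                        "subtract_standard")) {
  baseline <- match.arg(baseline)
  mode <- match.arg(mode)
  if (is(standards, "MIDVector")) standards <- list(standards)
  if (length(standards) == 0L)
    stop("no unlabelled standards supplied: cannot estimate the M+1 artifact",
         call. = FALSE)
  base <- if (baseline == "zero") 0 else
    naturalM1Fraction(nAtoms)
  m1 <- vapply(standards, function(s) {
    f <- fractions(fractionalLabelling(s))
    if (length(f) < 2L) 0 else f[2L]
  }, numeric(1))
  excess <- m1 - base
  if (any(excess < 0)) {
    warning(sprintf(
      "M+1 fraction below the %s baseline in %d standard(s); clamped to 0",
      baseline, sum(excess < 0)), call. = FALSE)
    excess[excess < 0] <- 0
  }
  artifactModel(mean(excess), mode = mode)
}

#' Theoretical natural-abundance M+1 fraction
#'
#' Binomial M+1 share for a molecule with `nAtoms` nitrogen atoms at
#' the natural 15N abundance p0.
#'
#' @param nAtoms nitrogen atoms per molecule.
#' @param p0 natural 15N abundance per atom.
#' @return The expected M+1 fraction.
#' @export
naturalM1Fraction <- function(nAtoms, p0 = 0.003663) {
  stats::dbinom(1L, as.integer(nAtoms), p0)
}

#' Forward derivatization shift model
#'
#' Applies the one-mass-unit shift convolution that models the AccQTag
#' artifact: `observed(x) = (1 - r) * true(x) + r * true(x - 1)`. Used
#' by the synthetic-data generator; [correctM1Artifact()] inverts it.
#' Signal shifted past the last tracked isotopologue is dropped, so a
#' vector whose final element is nonzero loses mass `r * true(xmax)`.
#'
#' @param values numeric M+0..M+xmax vector.
#' @param r shift fraction in [0, 1).
#' @return The convolved vector, same length.
#' @examples
#' applyM1Artifact(c(1, 0), 0.2)   # c(0.8, 0.2)
#' @export
applyM1Artifact <- function(values, r) {
  stopifnot(r >= 0, r < 1)
  (1 - r) * values + r * c(0, values[-length(values)])
}

#' Correct the derivatization M+1 artifact
#'
#' Removes the artificial M+1 enrichment introduced by derivatization.
#' In the default `shift_deconvolution` mode the shift convolution
#' `observed(x) = (1 - r) * true(x) + r * true(x - 1)` is inverted by
#' the recursion `true(0) = observed(0) / (1 - r)`,
#' `true(x) = (observed(x) - r * true(x - 1)) / (1 - r)`, which reduces
#' to a plain M+1 subtraction when only M+0/M+1 carry signal. The
#' simpler `subtract_standard` mode moves the standard's M+1 fraction
#' from M+1 back to M+0 and is provided for sensitivity checks.
#' Negative corrected values are clipped to 0 with a warning reporting
#' the clipped magnitude, and fractional vectors are renormalized.
#'
#' @param mid a [MIDVector-class], raw or fractional.
#' @param artifact an [ArtifactModel-class].
#' @return A corrected [MIDVector-class] of the same representation.
#' @examples
#' mid <- MIDVector("proline", c(0.8, 0.2), isFractional = TRUE)
#' midValues(correctM1Artifact(mid, artifactModel(0.2)))  # c(1, 0)
#' @export
correctM1Artifact <- function(mid, artifact) {
  stopifnot(is(mid, "MIDVector"), is(artifact, "ArtifactModel"))
  r <- artifactFraction(artifact)
  if (r >= 1) stop("invalid artifact model: r must be < 1", call. = FALSE)
  v <- midValues(mid)
  if (artifact@mode == "shift_deconvolution") {
    true <- numeric(length(v))
    true[1L] <- v[1L] / (1 - r)
    if (length(v) > 1L)
      for (x in 2:length(v))
        true[x] <- (v[x] - r * true[x - 1L]) / (1 - r)
  } else {
    tot <- sum(v)
    f <- if (tot > 0) v / tot else v
    if (length(f) > 1L) {
      shift <- min(r, f[2L])
      f[2L] <- f[2L] - shift
      f[1L] <- f[1L] + shift
    }
    true <- f * tot
    if (mid@isFractional) true <- f
  }
  if (any(true < 0)) {
    clipped <- -sum(true[true < 0])
    # stay silent on pure floating-point dust
    if (clipped > 1e-12 * max(sum(abs(true)), .Machine$double.xmin))
      warning(sprintf(
        "artifact correction produced negative values for %s (total magnitude %.3g); clipped to 0",
        aminoAcid(mid), clipped), call. = FALSE)
    true[true < 0] <- 0
  }
  if (mid@isFractional && sum(true) > 0) true <- true / sum(true)
  MIDVector(aminoAcid(mid), true, isFractional = mid@isFractional,
            sampleId = mid@sampleId)
}

#' Net 15N labelling relative to the T0 baseline
#'
#' Subtracts the fractional labelling measured at T0 of the experiment
#' (the natural-abundance baseline) from the sample's fractional
#' labelling, isotopologue by isotopologue. The resulting net
#' distribution is signed (M+0 is typically depleted), sums to zero,
#' and is never clipped. The mean labelled atom count
#' `sum(x * net(x))` is computed and stored alongside.
#'
#' @param sample a [LabellingResult-class] for the labelled sample.
#' @param t0 a [LabellingResult-class] for the matched T0 baseline;
#'   must be the same amino acid with the same number of isotopologues.
#' @return A [LabellingResult-class] with net and meanLabelledAtoms
#'   filled.
#' @examples
#' s  <- fractionalLabelling(MIDVector("proline", c(90, 10)))
#' t0 <- fractionalLabelling(MIDVector("proline", c(99, 1)))
#' netFractions(netLabelling(s, t0))  # c(-0.09, 0.09)
#' @export
netLabelling <- function(sample, t0) {
  stopifnot(is(sample, "LabellingResult"), is(t0, "LabellingResult"))
  if (!identical(aminoAcid(sample), aminoAcid(t0)))
    stop(sprintf("amino-acid mismatch: sample is %s, T0 is %s",
                 aminoAcid(sample), aminoAcid(t0)), call. = FALSE)
  if (length(fractions(sample)) != length(fractions(t0)))
    stop("sample and T0 track different numbers of isotopologues",
         call. = FALSE)
  net <- fractions(sample) - fractions(t0)
  new("LabellingResult", aminoAcid = aminoAcid(sample),
      fractional = fractions(sample), net = net,
      meanLabelledAtoms = .meanLabelledAtoms(net),
      sampleId = sample@sampleId)
}

.meanLabelledAtoms <- function(net) {
  sum((seq_along(net) - 1) * net)
}

#' @rdname meanLabelledAtoms
#' @export
setMethod("meanLabelledAtoms", "numeric", function(x) {
  if (abs(sum(x)) > 1e-6)
    warning("net labelling does not sum to 0; result may be biased",
            call. = FALSE)
  .meanLabelledAtoms(x)
})

#' @rdname meanLabelledAtoms
#' @export
setMethod("meanLabelledAtoms", "LabellingResult", function(x) {
  if (!length(x@net))
    stop("net labelling not available; call netLabelling() first",
         call. = FALSE)
  x@meanLabelledAtoms
})

#' Labelling analysis of a long-format isotopologue table
#'
#' Runs the full single-table chain on a long intensity table: estimate
#' the M+1 artifact per amino acid from the unlabelled standard rows,
#' correct every sample, normalize to fractional labelling, subtract
#' the per-group mean T0 baseline, and derive the mean labelled atom
#' count per molecule.
#'
#' @param intensities data.frame with columns `sample_id`, `timepoint`
#'   (`"T0"`, a labelled timepoint such as `"T4h"`, or `"standard"`),
#'   `amino_acid`, `isotopologue` (integer x of M+x), `intensity`, and
#'   optionally `group` (e.g. leaf rank) used to match samples to their
#'   T0 baseline; without it a single global T0 baseline is used.
#' @param artifact optional [ArtifactModel-class] or named list of
#'   models per amino acid; estimated from the `"standard"` rows when
#'   `NULL`.
#' @param baseline baseline passed to [estimateM1Artifact()].
#' @param mode correction mode passed to [estimateM1Artifact()].
#' @return A list with `results`: long data.frame (sample_id, group,
#'   timepoint, amino_acid, isotopologue, fractional, net), `summary`:
#'   one row per labelled sample and amino acid with
#'   `mean_labelled_atoms`, and `artifacts`: the per-amino-acid models.
#' @export
analyseLabellingTable <- function(intensities, artifact = NULL,
                                  baseline = "zero",
                                  mode = "shift_deconvolution") {
  req <- c("sample_id", "timepoint", "amino_acid", "isotopologue",
           "intensity")
  if (!all(req %in% names(intensities)))
    stop("intensity table must have columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  if (!"group" %in% names(intensities)) intensities$group <- "all"

  aas <- unique(intensities$amino_acid)
  asMid <- function(df, fractional = FALSE) {
    df <- df[order(df$isotopologue), , drop = FALSE]
    MIDVector(df$amino_acid[1L], df$intensity, isFractional = fractional,
              sampleId = df$sample_id[1L])
  }

  ## per-amino-acid artifact models
  artifacts <- list()
  for (aa in aas) {
    if (is(artifact, "ArtifactModel")) {
      artifacts[[aa]] <- artifact
    } else if (is.list(artifact) && !is.null(artifact[[aa]])) {
      artifacts[[aa]] <- artifact[[aa]]
    } else {
      std <- intensities[intensities$timepoint == "standard" &
                           intensities$amino_acid == aa, , drop = FALSE]
      if (!nrow(std))
        stop(sprintf("no unlabelled standard rows for %s and no artifact model supplied", aa),
             call. = FALSE)
      mids <- lapply(split(std, std$sample_id), asMid)
      artifacts[[aa]] <- estimateM1Artifact(mids, baseline = baseline,
                                            mode = mode)
    }
  }

  samples <- intensities[intensities$timepoint != "standard", , drop = FALSE]
  keys <- unique(samples[c("sample_id", "group", "timepoint", "amino_acid")])
  frac <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    rows <- samples[samples$sample_id == k$sample_id &
                      samples$amino_acid == k$amino_acid, , drop = FALSE]
    corrected <- correctM1Artifact(asMid(rows), artifacts[[k$amino_acid]])
    frac[[i]] <- fractions(fractionalLabelling(corrected))
  }
  keys$.frac <- frac

  ## mean T0 fractional baseline per (group, amino acid)
  t0keys <- keys[keys$timepoint == "T0", , drop = FALSE]
  if (!nrow(t0keys)) stop("no T0 rows found", call. = FALSE)
  baselineOf <- function(group, aa) {
    sel <- t0keys[t0keys$group == group & t0keys$amino_acid == aa, , drop = FALSE]
    if (!nrow(sel))
      sel <- t0keys[t0keys$amino_acid == aa, , drop = FALSE]
    if (!nrow(sel))
      stop(sprintf("no T0 baseline for %s", aa), call. = FALSE)
    Reduce(`+`, sel$.frac) / nrow(sel)
  }

  out <- list(); summ <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    f <- k$.frac[[1L]]
    b <- baselineOf(k$group, k$amino_acid)
    net <- f - b
    xs <- seq_along(f) - 1L
    out[[i]] <- data.frame(
      sample_id = k$sample_id, group = k$group, timepoint = k$timepoint,
      amino_acid = k$amino_acid, isotopologue = xs,
      fractional = f, net = net)
    if (k$timepoint != "T0")
      summ[[length(summ) + 1L]] <- data.frame(
        sample_id = k$sample_id, group = k$group, timepoint = k$timepoint,
        amino_acid = k$amino_acid,
        mean_labelled_atoms = .meanLabelledAtoms(net))
  }
  list(results = do.call(rbind, out),
       summary = do.call(rbind, summ),
       artifacts = artifacts)
}
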