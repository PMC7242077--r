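#' Primer efficiency from a serial dilution
#'
#' Estimates the per-cycle amplification factor E of a primer pair from
#' a serial dilution of mixed cDNA: Cq is regressed on log10 relative
#' input by ordinary least squares and `E = 10^(-1/slope)`. A perfect
#' doubling assay gives slope -3.3219 and E = 2.
#'
#' @param log10Input log10 relative template input of each dilution
#'   point (e.g. 0, -1, -2, -3).
#' @param cq matching quantification cycles.
#' @param gene gene name recorded on the result.
#' @return A [PrimerSpec-class].
#' @examples
#' primerEfficiency(c(0, -1, -2, -3), 20 + 3.3219 * c(0, 1, 2, 3), "UBQ11")
#' @export
primerEfficiency <- function(log10Input, cq, gene = "") {
  stopifnot(length(log10Input) == length(cq))
  if (length(unique(log10Input)) < 3L)
    stop("primer efficiency requires >= 3 dilution points", call. = FALSE)
  span <- diff(range(log10Input))
  if (span < 2)
    warning(sprintf(
      "dilution series spans only %.2g log10 units (< 2); E may be unstable",
      span), call. = FALSE)
  slope <- unname(stats::coef(stats::lm(cq ~ log10Input))[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("dilution series has non-negative slope; series inverted or degenerate",
         call. = FALSE)
  primerSpec(gene, 10^(-1 / slope))
}

#' Efficiency-corrected relative expression
#'
#' Expression of a target gene normalized to the geometric mean
#' expression of the reference genes, with per-gene measured primer
#' efficiencies:
#' `RE = E_t^(-Cq_t) / geomean_j( E_j^(-Cq_j) )`.
#' Computed in log space for numerical stability. With equal
#' efficiencies everywhere, RE is invariant under a uniform additive
#' shift of all Cq values.
#'
#' @param targetCq target-gene Cq (technical replicates already
#'   averaged).
#' @param targetE target primer efficiency ([PrimerSpec-class] or
#'   number).
#' @param refCq numeric vector of reference-gene Cq values for the same
#'   sample.
#' @param refE matching reference efficiencies ([PrimerSpec-class]
#'   list or numeric vector).
#' @return Relative expression, a positive unitless number.
#' @examples
#' relativeExpression(21, 2, c(20, 20), c(2, 2))   # 0.5
#' @export
relativeExpression <- function(targetCq, targetE, refCq, refE) {
  eNum <- function(e) {
    if (is(e, "PrimerSpec")) efficiency(e)
    else if (is.list(e)) vapply(e, efficiency, numeric(1))
    else as.numeric(e)
  }
  tE <- eNum(targetE); rE <- eNum(refE)
  if (length(refCq) < 1L)
    stop("at least one reference gene is required", call. = FALSE)
  if (length(rE) != length(refCq))
    stop("one efficiency per reference Cq is required", call. = FALSE)
  if (!all(is.finite(c(targetCq, refCq))))
    stop("all Cq values must be finite", call. = FALSE)
  log2re <- -targetCq * log2(tE) - mean(-refCq * log2(rE))
  2^log2re
}

#' Average technical replicates of a Cq plate
#'
#' Collapses technical replicates to one mean Cq per sample and gene,
#' the standard practice before relative-expression computation.
#' Missing (undetected) wells propagate as `NA` rather than Cq = 40.
#'
#' @param cq data.frame with columns `sample_id`, `gene`, `Cq` and
#'   optionally `replicate`.
#' @return data.frame with one row per sample and gene, column `Cq`.
#' @export
averageTechnicalReplicates <- function(cq) {
  agg <- stats::aggregate(Cq ~ sample_id + gene, data = cq, FUN = mean,
                          na.action = stats::na.pass)
  agg
}

#' Relative expression for every sample on a plate
#'
#' Applies [relativeExpression()] across a tidy Cq table. Samples
#' missing a reference-gene Cq are excluded with a warning; targets
#' undetected in a sample yield `NA` relative expression for that
#' sample (reported as not-detected, never as zero).
#'
#' @param cq data.frame with columns `sample_id`, `gene`, `Cq`
#'   (technical replicates may be present and are averaged first).
#' @param efficiencies named numeric vector or list of
#'   [PrimerSpec-class] giving E per gene.
#' @param referenceGenes character vector of reference gene names
#'   (default the study's pair).
#' @return data.frame (sample_id, gene, relative_expression) for all
#'   non-reference genes.
#' @export
relativeExpressionTable <- function(cq, efficiencies,
                                    referenceGenes = c("BnaC.UBQ11",
                                                       "BnaC.RibS3")) {
  eNum <- function(e) if (is(e, "PrimerSpec")) efficiency(e) else as.numeric(e)
  effs <- vapply(efficiencies, eNum, numeric(1))
  if (is.null(names(effs)) && !is.null(names(efficiencies)))
    names(effs) <- names(efficiencies)
  cqm <- averageTechnicalReplicates(cq)
  missingE <- setdiff(unique(cqm$gene), names(effs))
  if (length(missingE))
    stop("no efficiency for gene(s): ", paste(missingE, collapse = ", "),
         call. = FALSE)
  targets <- setdiff(unique(cqm$gene), referenceGenes)
  out <- list()
  for (s in unique(cqm$sample_id)) {
    sub <- cqm[cqm$sample_id == s, , drop = FALSE]
    refCq <- sub$Cq[match(referenceGenes, sub$gene)]
    if (anyNA(refCq)) {
      warning(sprintf("sample %s missing reference-gene Cq; excluded", s),
              call. = FALSE)
      next
    }
    for (g in targets) {
      tCq <- sub$Cq[match(g, sub$gene)]
      re <- if (is.na(tCq)) NA_real_ else
        relativeExpression(tCq, effs[[g]], refCq, effs[referenceGenes])
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, gene = g, relative_expression = re)
    }
  }
  do.call(rbind, out)
}

#' GeNorm reference-gene stability
#'
#' For each candidate reference gene j, the GeNorm stability measure
#' M_j is the mean over all other candidates k of the standard
#' deviation across samples of `log2(a_j / a_k)`: a gene whose
#' expression ratio to every other candidate is constant across samples
#' has M = 0 and is maximally stable. At least three candidates are
#' required for M to be defined.
#'
#' @param expr numeric matrix of positive expression values, samples in
#'   rows, candidate genes in columns (column names = gene names).
#' @return A data.frame (gene, M) sorted from most to least stable.
#' @examples
#' m <- cbind(a = c(1, 2, 4), b = c(2, 4, 8), c = c(1, 8, 2))
#' geNormStability(m)   # gene c least stable
#' @export
geNormStability <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L)
    stop("GeNorm M is defined for >= 3 candidate genes", call. = FALSE)
  if (nrow(expr) < 2L)
    stop("GeNorm requires >= 2 samples", call. = FALSE)
  if (any(!is.finite(expr)) || any(expr <= 0))
    stop("expression values must be positive and finite", call. = FALSE)
  genes <- colnames(expr)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(expr)))
  lg <- log2(expr)
  M <- vapply(seq_len(ncol(expr)), function(j) {
    others <- setdiff(seq_len(ncol(expr)), j)
    mean(vapply(others, function(k) stats::sd(lg[, j] - lg[, k]),
                numeric(1)))
  }, numeric(1))
  out <- data.frame(gene = genes, M = M)
  out[order(out$M), , drop = FALSE]
}

#' GeNorm iterative exclusion ranking
#'
#' Repeatedly removes the least stable candidate (largest M) and
#' recomputes M on the remainder until two genes are left, the
#' canonical GeNorm selection procedure. The last two genes are the
#' most stable pair.
#'
#' @param expr as in [geNormStability()].
#' @return A data.frame (gene, M_at_exclusion, rank) where rank 1 marks
#'   the least stable gene (excluded first); the final two rows share
#'   the top rank and carry the M of the final pair round.
#' @export
geNormRank <- function(expr) {
  expr <- as.matrix(expr)
  if (is.null(colnames(expr)))
    colnames(expr) <- paste0("gene", seq_len(ncol(expr)))
  excluded <- list(); step <- 1L
  while (ncol(expr) > 2L) {
    M <- geNormStability(expr)
    worst <- M$gene[nrow(M)]
    excluded[[step]] <- data.frame(gene = worst,
                                   M_at_exclusion = M$M[nrow(M)],
                                   rank = step)
    expr <- expr[, colnames(expr) != worst, drop = FALSE]
    step <- step + 1L
  }
  ## final pair: M is the SD of their log ratio, shared
  finalM <- stats::sd(log2(expr[, 1L]) - log2(expr[, 2L]))
  fin <- data.frame(gene = colnames(expr), M_at_exclusion = finalM,
                    rank = step)
  rbind(do.call(rbind, excluded), fin)
}

#' Fold change and log2 fold-change ratio
#'
#' Fold change is the ratio of relative expression between two
#' consecutive time points, computed separately for the treated and
#' control arms; the treatment effect is summarized as
#' `log2(FC_treatment / FC_control)`.
#'
#' @param reTreatT1,reTreatT0 relative expression of the treated arm at
#'   the later and earlier time point.
#' @param reCtrlT1,reCtrlT0 same for the control arm.
#' @return A list with `fcTreatment`, `fcControl`, `log2FcRatio`.
#' @examples
#' foldChangeRatio(8, 1, 1, 1)$log2FcRatio   # 3
#' @export
foldChangeRatio <- function(reTreatT1, reTreatT0, reCtrlT1, reCtrlT0) {
  vals <- c(reTreatT1, reTreatT0, reCtrlT1, reCtrlT0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("relative expression values must be positive and finite",
         call. = FALSE)
  fcT <- reTreatT1 / reTreatT0
  fcC <- reCtrlT1 / reCtrlT0
  list(fcTreatment = fcT, fcControl = fcC,
       log2FcRatio = log2(fcT / fcC))
}
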