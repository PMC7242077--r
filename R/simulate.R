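#' Simulation configuration
#'
#' Builds the configuration driving the synthetic-data generators. The
#' defaults reproduce the conditions of the leaf-disc tracer study the
#' package targets: four leaf ranks spanning the sink-to-source
#' gradient, proline per-atom 15N incorporation probabilities of
#' 0.10 / 0.07 / 0.02 / 0.005 from L15 to L3, rank-independent
#' glutamate (0.54) and glutamine (0.68 per atom) incorporation, a 20
#' percent derivatization M+1 artifact, natural 15N abundance 0.003663,
#' 2 percent multiplicative intensity noise, and three biological
#' replicates. Proline contents are set so that content times net
#' labelling reproduces allocation magnitudes of roughly 200 nmol 15N
#' per g DW in L15 falling to near zero in L7/L3.
#'
#' @param leafRanks leaf-rank labels, youngest (sink) first.
#' @param enrichment named list per amino acid of per-atom 15N
#'   incorporation probabilities by rank (values in [0, 1]).
#' @param nAtoms named integer vector of nitrogen atoms per amino acid.
#' @param contents named list per amino acid of contents (umol per g
#'   DW) by rank.
#' @param artifactR derivatization M+1 shift fraction in [0, 1).
#' @param naturalAbundance per-atom natural 15N abundance p0.
#' @param noiseCV multiplicative (lognormal) CV on intensities.
#' @param nReplicates biological replicates per rank and timepoint.
#' @param nStandards number of unlabelled external standard injections.
#' @param totalIntensity detector counts for one unit of content.
#' @param xMax highest tracked isotopologue (M+0..M+xMax).
#' @param quant list of quantification-table settings: `slopes` (named,
#'   area per uM), `intercept`, `isNominalArea`, `isCV`,
#'   `dryWeightG`, `extractVolumeMl`, `calibrationConcentrations`,
#'   `areaCV`.
#' @param qpcr list of qPCR settings: `referenceGenes` (named E),
#'   `decoyGene`, `decoySdLog2`, `targets` (data.frame gene,
#'   efficiency, baseExpression, log2FcRatio), `cqNoiseSD`,
#'   `techReplicates`, `cqIntercept`, `dilutionLog10`,
#'   `dilutionNoiseSD`, `refBaseExpression`, `refSdLog2`.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(
    leafRanks = c("L15", "L11", "L7", "L3"),
    enrichment = list(
      proline   = c(L15 = 0.10, L11 = 0.07, L7 = 0.02, L3 = 0.005),
      glutamate = c(L15 = 0.54, L11 = 0.54, L7 = 0.54, L3 = 0.54),
      glutamine = c(L15 = 0.68, L11 = 0.68, L7 = 0.68, L3 = 0.68)),
    nAtoms = c(proline = 1L, glutamate = 1L, glutamine = 2L),
    contents = list(
      proline   = c(L15 = 2.0, L11 = 1.07, L7 = 0.6, L3 = 0.3),
      glutamate = c(L15 = 10,  L11 = 10,   L7 = 10,  L3 = 10),
      glutamine = c(L15 = 15,  L11 = 15,   L7 = 15,  L3 = 15)),
    artifactR = 0.20,
    naturalAbundance = 0.003663,
    noiseCV = 0.02,
    nReplicates = 3L,
    nStandards = 3L,
    totalIntensity = 1e6,
    xMax = 4L,
    quant = list(
      slopes = c(proline = 2000, glutamate = 1800, glutamine = 1500),
      intercept = 0,
      isNominalArea = 5e4,
      isCV = 0.02,
      dryWeightG = 0.01,
      extractVolumeMl = 0.9,
      calibrationConcentrations = c(1, 2, 5, 10, 20, 50, 100, 200),
      areaCV = 0.02),
    qpcr = list(
      referenceGenes = c(BnaC.UBQ11 = 2.0, BnaC.RibS3 = 2.0),
      refBaseExpression = c(BnaC.UBQ11 = 1.0, BnaC.RibS3 = 0.5),
      refSdLog2 = 0.05,
      decoyGene = "BnaDecoy",
      decoyEfficiency = 2.0,
      decoySdLog2 = 1.0,
      targets = data.frame(
        gene = c("BnaC.ProDH1b", "BnaA.P5CS1"),
        efficiency = c(1.95, 1.90),
        baseExpression = c(0.01, 0.2),
        log2FcRatio = c(7, -2)),
      cqNoiseSD = 0.2,
      techReplicates = 2L,
      cqIntercept = 24,
      dilutionLog10 = c(0, -1, -2, -3),
      dilutionNoiseSD = 0.05)) {
  cfg <- list(leafRanks = leafRanks, enrichment = enrichment,
              nAtoms = nAtoms, contents = contents,
              artifactR = artifactR, naturalAbundance = naturalAbundance,
              noiseCV = noiseCV, nReplicates = as.integer(nReplicates),
              nStandards = as.integer(nStandards),
              totalIntensity = totalIntensity, xMax = as.integer(xMax),
              quant = quant, qpcr = qpcr)
  class(cfg) <- "SimulationConfig"
  validateSimulationConfig(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `SimulationConfig` list.
#' @return `cfg` invisibly; errors with a field-level message on the
#'   first violated constraint.
#' @export
validateSimulationConfig <- function(cfg) {
  fail <- function(field, why)
    stop(sprintf("invalid config field '%s': %s", field, why),
         call. = FALSE)
  if (!length(cfg$leafRanks)) fail("leafRanks", "at least one rank")
  for (aa in names(cfg$enrichment)) {
    p <- cfg$enrichment[[aa]]
    if (any(p < 0) || any(p > 1))
      fail(paste0("enrichment$", aa), "probabilities must lie in [0, 1]")
    if (!all(cfg$leafRanks %in% names(p)))
      fail(paste0("enrichment$", aa), "one probability per leaf rank")
    if (is.null(cfg$nAtoms[[aa]]))
      fail("nAtoms", paste("missing nitrogen count for", aa))
    if (cfg$nAtoms[[aa]] > cfg$xMax)
      fail("xMax", paste("must be >= nAtoms of", aa))
  }
  if (cfg$artifactR < 0 || cfg$artifactR >= 1)
    fail("artifactR", "must lie in [0, 1)")
  if (cfg$naturalAbundance < 0 || cfg$naturalAbundance > 1)
    fail("naturalAbundance", "must lie in [0, 1]")
  if (cfg$nReplicates < 1L) fail("nReplicates", "must be >= 1")
  if (cfg$noiseCV < 0) fail("noiseCV", "must be >= 0")
  q <- cfg$qpcr
  if (any(c(q$referenceGenes, q$decoyEfficiency,
            q$targets$efficiency) <= 1))
    fail("qpcr", "all efficiencies must exceed 1")
  invisible(cfg)
}

## lognormal multiplicative noise with given CV, mean 1
.mnoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## binomial MID over M+0..M+xMax for per-atom labelling probability p
.binomMID <- function(p, nAtoms, xMax) {
  c(stats::dbinom(0:nAtoms, nAtoms, p), rep(0, xMax - nAtoms))
}

#' Simulate a 15N leaf-disc labelling experiment
#'
#' Generates the long-format isotopologue intensity table of a tracer
#' experiment: for every leaf rank, biological replicate and amino
#' acid, each of the molecule's nitrogen positions is 15N with the
#' configured per-atom incorporation probability at the labelled
#' timepoint (T4h) and with natural abundance p0 at T0, giving a
#' binomial isotopologue distribution. The distribution is
#' forward-convolved with the derivatization M+1 shift artifact,
#' scaled to detector intensities proportional to the compound content,
#' and perturbed with lognormal multiplicative noise. Unlabelled
#' external standards (natural abundance plus artifact, no biological
#' noise structure beyond the same CV) are appended for artifact
#' estimation.
#'
#' @param config a `SimulationConfig` from [simulationConfig()].
#' @param seed integer random seed; identical seeds give identical
#'   tables.
#' @return A list with `intensities` (sample_id, group, timepoint,
#'   amino_acid, isotopologue, intensity) and `truth` (group,
#'   amino_acid, per-atom enrichment, expected net labelling per
#'   isotopologue and expected mean labelled atoms).
#' @export
simulateLabellingExperiment <- function(config = simulationConfig(),
                                        seed = 1L) {
  validateSimulationConfig(config)
  set.seed(as.integer(seed))
  p0 <- config$naturalAbundance
  xs <- 0:config$xMax
  rows <- list(); truth <- list()
  for (aa in names(config$enrichment)) {
    n <- config$nAtoms[[aa]]
    midT0 <- applyM1Artifact(.binomMID(p0, n, config$xMax),
                             config$artifactR)
    for (rank in config$leafRanks) {
      p <- config$enrichment[[aa]][[rank]]
      pEff <- p + (1 - p) * p0   # tracer on top of natural abundance
      midT4 <- applyM1Artifact(.binomMID(pEff, n, config$xMax),
                               config$artifactR)
      scale <- config$totalIntensity * config$contents[[aa]][[rank]]
      for (rep_ in seq_len(config$nReplicates)) {
        for (tp in c("T0", "T4h")) {
          mid <- if (tp == "T0") midT0 else midT4
          noisy <- mid * scale * .mnoise(length(mid), config$noiseCV)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sprintf("%s_%s_rep%d", rank, tp, rep_),
            group = rank, timepoint = tp, amino_acid = aa,
            isotopologue = xs, intensity = noisy)
        }
      }
      netTrue <- .binomMID(pEff, n, config$xMax) - .binomMID(p0, n, config$xMax)
      truth[[length(truth) + 1L]] <- data.frame(
        group = rank, amino_acid = aa, per_atom_enrichment = p,
        isotopologue = xs, expected_net = netTrue,
        expected_mean_labelled_atoms = sum(xs * netTrue))
    }
    ## unlabelled standards: natural abundance + artifact
    midStd <- applyM1Artifact(.binomMID(p0, n, config$xMax),
                              config$artifactR)
    for (s in seq_len(config$nStandards)) {
      noisy <- midStd * config$totalIntensity *
        .mnoise(length(midStd), config$noiseCV)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("STD_%s_%d", aa, s),
        group = "standard", timepoint = "standard", amino_acid = aa,
        isotopologue = xs, intensity = noisy)
    }
  }
  list(intensities = do.call(rbind, rows),
       truth = do.call(rbind, truth))
}

#' Simulate calibration and sample-area quantification tables
#'
#' Generates the external calibration series (linear detector response
#' with multiplicative noise) and the per-sample peak-area table with
#' internal-standard recovery jitter, from the configured amino-acid
#' contents. The ground truth (configured contents) is returned
#' alongside.
#'
#' @param config a `SimulationConfig`.
#' @param seed integer random seed.
#' @return A list with `calibration` (amino_acid, concentration_uM,
#'   area), `samples` (sample_id, group, amino_acid, area, is_area,
#'   dry_weight_g, extract_volume_ml) and `truth` (group, amino_acid,
#'   content_umol_per_gDW).
#' @export
simulateQuantTables <- function(config = simulationConfig(), seed = 1L) {
  validateSimulationConfig(config)
  set.seed(as.integer(seed) + 1L)
  q <- config$quant
  cal <- list(); smp <- list(); truth <- list()
  for (aa in names(config$contents)) {
    slope <- q$slopes[[aa]]
    conc <- q$calibrationConcentrations
    cal[[aa]] <- data.frame(
      amino_acid = aa, concentration_uM = conc,
      area = (q$intercept + slope * conc) * .mnoise(length(conc), q$areaCV))
    for (rank in config$leafRanks) {
      content <- config$contents[[aa]][[rank]]
      concSample <- content * q$dryWeightG / (q$extractVolumeMl / 1000)
      for (rep_ in seq_len(config$nReplicates)) {
        isJitter <- .mnoise(1L, q$isCV)
        smp[[length(smp) + 1L]] <- data.frame(
          sample_id = sprintf("%s_rep%d", rank, rep_), group = rank,
          amino_acid = aa,
          ## recovery loss scales analyte and IS together
          area = q$intercept + slope * concSample * isJitter *
            .mnoise(1L, q$areaCV),
          is_area = q$isNominalArea * isJitter,
          dry_weight_g = q$dryWeightG,
          extract_volume_ml = q$extractVolumeMl)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        group = rank, amino_acid = aa, content_umol_per_gDW = content)
    }
  }
  list(calibration = do.call(rbind, cal),
       samples = do.call(rbind, smp),
       truth = do.call(rbind, truth))
}

#' Simulate a qPCR plate with dilution series
#'
#' Generates Cq values for two stable reference genes, one deliberately
#' unstable decoy gene (for GeNorm testing), and condition-responsive
#' target genes across a two-arm (treatment/control), two-timepoint
#' design: `Cq = intercept - log_E(expression) + Normal(0, sd)`. Target
#' genes change expression between T0 and T1 in the treatment arm by
#' the configured log2 fold-change ratio (control arm dynamics flat),
#' emulating strong stress inductions (log2 FC ratio above 7) as well
#' as repressions. A per-gene serial dilution series is generated for
#' primer-efficiency estimation.
#'
#' @param config a `SimulationConfig`.
#' @param seed integer random seed.
#' @return A list with `cq` (sample_id, arm, timepoint, replicate,
#'   gene, technical_replicate, Cq), `dilution` (gene, log10_input,
#'   Cq) and `truth` (gene, efficiency, log2FcRatio configured; NA for
#'   reference/decoy genes).
#' @export
simulateQPCRPlate <- function(config = simulationConfig(), seed = 1L) {
  validateSimulationConfig(config)
  set.seed(as.integer(seed) + 2L)
  q <- config$qpcr
  genes <- data.frame(
    gene = c(names(q$referenceGenes), q$decoyGene, q$targets$gene),
    efficiency = c(unname(q$referenceGenes), q$decoyEfficiency,
                   q$targets$efficiency),
    stringsAsFactors = FALSE)
  base <- c(unname(q$refBaseExpression), 1.0, q$targets$baseExpression)
  names(base) <- genes$gene
  l2fc <- c(rep(NA_real_, length(q$referenceGenes) + 1L),
            q$targets$log2FcRatio)
  names(l2fc) <- genes$gene

  cq <- list()
  for (arm in c("control", "treatment")) for (tp in c("T0", "T1")) {
    for (rep_ in seq_len(config$nReplicates)) {
      sid <- sprintf("%s_%s_rep%d", arm, tp, rep_)
      for (gi in seq_len(nrow(genes))) {
        g <- genes$gene[gi]; E <- genes$efficiency[gi]
        expr <- base[[g]]
        if (!is.na(l2fc[[g]]) && arm == "treatment" && tp == "T1")
          expr <- expr * 2^l2fc[[g]]
        if (g == q$decoyGene)
          expr <- expr * 2^stats::rnorm(1L, 0, q$decoySdLog2)
        else if (g %in% names(q$referenceGenes))
          expr <- expr * 2^stats::rnorm(1L, 0, q$refSdLog2)
        trueCq <- q$cqIntercept - log(expr) / log(E)
        for (tr in seq_len(q$techReplicates)) {
          cq[[length(cq) + 1L]] <- data.frame(
            sample_id = sid, arm = arm, timepoint = tp,
            replicate = rep_, gene = g, technical_replicate = tr,
            Cq = trueCq + stats::rnorm(1L, 0, q$cqNoiseSD))
        }
      }
    }
  }

  dil <- list()
  for (gi in seq_len(nrow(genes))) {
    E <- genes$efficiency[gi]
    dil[[gi]] <- data.frame(
      gene = genes$gene[gi], log10_input = q$dilutionLog10,
      Cq = q$cqIntercept - q$dilutionLog10 / log10(E) +
        stats::rnorm(length(q$dilutionLog10), 0, q$dilutionNoiseSD))
  }

  list(cq = do.call(rbind, cq),
       dilution = do.call(rbind, dil),
       truth = data.frame(genes, log2FcRatio = unname(l2fc)))
}
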