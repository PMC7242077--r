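#' One-way ANOVA with Tukey HSD compact letters
#'
#' The leaf-rank comparison scheme: a one-way ANOVA across groups
#' followed by Tukey's HSD studentized-range pairwise comparisons, with
#' the pairwise outcome summarized as a compact letter display — groups
#' sharing a letter are not significantly different at `alpha`. Letters
#' are assigned by the insert-and-absorb algorithm on the pairwise
#' significance matrix, with groups ordered by decreasing mean so the
#' largest group takes letter "a".
#'
#' @param value numeric observations.
#' @param group group labels (factor or character), e.g. leaf ranks.
#' @param alpha significance level, default 0.05.
#' @param transform `"identity"` or `"log"` (natural log applied before
#'   testing, as done for relative expression values).
#' @return A list with `letters` (named character vector per group),
#'   `pMatrix` (symmetric Tukey pairwise p-values), `anovaP` (the
#'   F-test p-value) and `means` (group means on the analysis scale).
#' @examples
#' set.seed(1)
#' anovaTukeyLetters(c(rnorm(5), rnorm(5, 100)),
#'                   rep(c("low", "high"), each = 5))$letters
#' @export
anovaTukeyLetters <- function(value, group, alpha = 0.05,
                              transform = c("identity", "log")) {
  transform <- match.arg(transform)
  group <- as.character(group)
  stopifnot(length(value) == length(group))
  if (transform == "log") value <- logTransformExpression(value)
  counts <- table(group)
  if (length(counts) < 2L)
    stop("at least 2 groups are required", call. = FALSE)
  if (any(counts < 2L))
    stop(sprintf("group(s) with < 2 replicates: %s",
                 paste(names(counts)[counts < 2L], collapse = ", ")),
         call. = FALSE)
  dat <- data.frame(value = value, group = factor(group))
  fit <- stats::aov(value ~ group, data = dat)
  anovaP <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  lev <- levels(dat$group)
  pmat <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1L]; b <- pairs[[i]][2L]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  means <- tapply(dat$value, dat$group, mean)
  letters <- .compactLetters(pmat < alpha, order(-means))
  list(letters = letters[lev], pMatrix = pmat, anovaP = anovaP,
       means = means)
}

## Insert-and-absorb compact letter display.
## sig: logical matrix, TRUE where the pair differs significantly.
## ord: index order in which groups receive letters (largest mean first).
.compactLetters <- function(sig, ord = seq_len(nrow(sig))) {
  n <- nrow(sig)
  groups <- rownames(sig)
  ## columns = letter sets, start with one set containing everything
  cols <- list(rep(TRUE, n))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        ## duplicate the set, drop i from one copy and j from the other
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1L]] <- c2
      }
    }
    ## absorb sets that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] &&
          all(cols[[a]] | !cols[[b]]) && !identical(cols[[a]], cols[[b]]))
        keep[b] <- FALSE
      if (a != b && keep[a] && keep[b] &&
          identical(cols[[a]], cols[[b]]) && b > a)
        keep[b] <- FALSE
    }
    cols <- cols[keep]
  }
  ## order letter sets by the first (largest-mean) group they contain
  firstIn <- vapply(cols, function(col) min(match(which(col), ord)),
                    numeric(1))
  cols <- cols[order(firstIn)]
  out <- vapply(seq_len(n), function(g)
    paste(letters[which(vapply(cols, `[`, logical(1), g))], collapse = ""),
    character(1))
  names(out) <- groups
  out
}

#' Two-sided equal-variance t-test
#'
#' Student's t-test with pooled variance and a bilateral alternative,
#' the scheme used for two-treatment comparisons (light vs dark,
#' control vs stress) per leaf rank. Degenerate inputs with zero pooled
#' variance return p = 1 when the means are equal and p = 0, flagged,
#' when they differ.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param alpha significance level for the returned flag.
#' @param transform `"identity"` or `"log"` (natural log before
#'   testing).
#' @return A list with `statistic`, `p.value`, `significant`,
#'   `degenerate`.
#' @examples
#' twoSampleT(c(1, 2, 3), c(1, 2, 3))$p.value   # 1
#' @export
twoSampleT <- function(a, b, alpha = 0.05,
                       transform = c("identity", "log")) {
  transform <- match.arg(transform)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs >= 2 observations", call. = FALSE)
  if (transform == "log") {
    a <- logTransformExpression(a)
    b <- logTransformExpression(b)
  }
  pooled <- ((length(a) - 1) * stats::var(a) +
               (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, p.value = 1, significant = FALSE,
                  degenerate = TRUE))
    return(list(statistic = Inf * sign(mean(a) - mean(b)), p.value = 0,
                significant = TRUE, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       significant = tt$p.value < alpha, degenerate = FALSE)
}

#' Natural-log transform of expression values
#'
#' Relative expression values are log-transformed before parametric
#' tests to obtain approximately normally distributed values; the base
#' (natural log here) does not affect test decisions.
#'
#' @param values positive numeric vector.
#' @return `log(values)`.
#' @examples
#' logTransformExpression(c(1, exp(1), exp(2)))
#' @export
logTransformExpression <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("log transform requires strictly positive finite values",
         call. = FALSE)
  log(values)
}
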