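test_that("homogeneous groups share one letter", {
  value <- rep(c(1, 2, 3), 4)
  group <- rep(c("L15", "L11", "L7", "L3"), each = 3)
  res <- anovaTukeyLetters(value, group)
  expect_true(all(res$letters == "a"))
  expect_true(all(res$pMatrix >= 0.05))
})

test_that("well-separated groups receive distinct letters", {
  set.seed(41)
  value <- c(rnorm(5, 100, 1), rnorm(5, 0, 1))
  group <- rep(c("high", "low"), each = 5)
  res <- anovaTukeyLetters(value, group)
  expect_equal(unname(res$letters[c("high", "low")]), c("a", "b"))
  expect_lt(res$pMatrix["high", "low"], 1e-6)
})

test_that("letters are invariant to group input order", {
  set.seed(42)
  value <- c(rnorm(4, 0), rnorm(4, 5), rnorm(4, 50))
  group <- rep(c("g1", "g2", "g3"), each = 4)
  res1 <- anovaTukeyLetters(value, group)
  ord <- sample(length(value))
  res2 <- anovaTukeyLetters(value[ord], group[ord])
  expect_equal(res1$letters, res2$letters)
})

test_that("groups with fewer than two replicates are rejected", {
  expect_error(anovaTukeyLetters(c(1, 2, 3), c("a", "a", "b")),
               "< 2 replicates")
})

test_that("compact letters agree with the pairwise significance matrix", {
  set.seed(43)
  for (i in 1:40) {
    k <- sample(3:5, 1)
    n <- sample(3:5, 1)
    means <- runif(k, 0, 6)
    value <- unlist(lapply(means, function(m) rnorm(n, m, 1)))
    group <- rep(paste0("g", seq_len(k)), each = n)
    res <- anovaTukeyLetters(value, group)
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      ga <- paste0("g", a); gb <- paste0("g", b)
      shared <- length(intersect(strsplit(res$letters[[ga]], "")[[1]],
                                 strsplit(res$letters[[gb]], "")[[1]])) > 0
      expect_equal(shared, res$pMatrix[ga, gb] >= 0.05,
                   info = sprintf("iter %d pair %s-%s p=%.4f", i, ga, gb,
                                  res$pMatrix[ga, gb]))
    }
  }
})

test_that("compact letters match multcomp's display on a reference case", {
  skip_if_not_installed("multcomp")
  set.seed(44)
  value <- c(rnorm(5, 0), rnorm(5, 1), rnorm(5, 4), rnorm(5, 4.5))
  group <- factor(rep(c("a1", "a2", "a3", "a4"), each = 5))
  ours <- anovaTukeyLetters(value, as.character(group))
  fit <- stats::aov(value ~ group)
  cld <- multcomp::cld(multcomp::glht(fit, multcomp::mcp(group = "Tukey")))
  # same partition: pairs share a letter in ours iff they do in multcomp
  lets <- cld$mcletters$Letters
  for (a in levels(group)) for (b in levels(group)) {
    if (a >= b) next
    sharedOurs <- length(intersect(
      strsplit(ours$letters[[a]], "")[[1]],
      strsplit(ours$letters[[b]], "")[[1]])) > 0
    sharedRef <- length(intersect(strsplit(lets[[a]], "")[[1]],
                                  strsplit(lets[[b]], "")[[1]])) > 0
    expect_equal(sharedOurs, sharedRef)
  }
})

test_that("equal-variance t-test handles standard and degenerate inputs", {
  expect_equal(twoSampleT(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  set.seed(45)
  a <- rnorm(3, 0, 1e-3); b <- 10 + rnorm(3, 0, 1e-3)
  expect_lt(twoSampleT(a, b)$p.value, 1e-6)
  # symmetry
  expect_equal(twoSampleT(a, b)$p.value, twoSampleT(b, a)$p.value)
  # zero pooled variance conventions
  same <- twoSampleT(c(2, 2, 2), c(2, 2))
  expect_equal(same$p.value, 1); expect_true(same$degenerate)
  diffr <- twoSampleT(c(2, 2, 2), c(3, 3))
  expect_equal(diffr$p.value, 0); expect_true(diffr$degenerate)
  expect_error(twoSampleT(1, c(1, 2)), ">= 2")
})

test_that("t-squared equals the ANOVA F statistic for two groups", {
  set.seed(46)
  for (i in 1:20) {
    a <- rnorm(sample(3:6, 1), 0, 1)
    b <- rnorm(sample(3:6, 1), runif(1, 0, 2), 1)
    tt <- twoSampleT(a, b)
    fit <- stats::aov(v ~ g, data = data.frame(
      v = c(a, b), g = rep(c("a", "b"), c(length(a), length(b)))))
    Fp <- summary(fit)[[1]][["Pr(>F)"]][1]
    Fv <- summary(fit)[[1]][["F value"]][1]
    expect_equal(tt$statistic^2, Fv, tolerance = 1e-9)
    expect_equal(tt$p.value, Fp, tolerance = 1e-9)
  }
})

test_that("log transform behaves as the natural log and stabilizes variance", {
  expect_equal(logTransformExpression(c(1, exp(1), exp(2))), c(0, 1, 2))
  x <- c(0.5, 1, 7)
  expect_equal(exp(logTransformExpression(x)), x)
  expect_error(logTransformExpression(c(1, 0)), "positive")
  expect_error(logTransformExpression(c(1, -2)), "positive")
  # proportional groups with equal CV have exactly equal log-scale variance
  g1 <- c(1, 1.2, 0.9); g2 <- 50 * g1
  expect_equal(var(logTransformExpression(g1)),
               var(logTransformExpression(g2)))
  # log option inside the tests matches manual pre-transformation
  v <- c(g1, g2); g <- rep(c("a", "b"), each = 3)
  direct <- anovaTukeyLetters(log(v), g)
  viaFlag <- anovaTukeyLetters(v, g, transform = "log")
  expect_equal(viaFlag$pMatrix, direct$pMatrix)
})
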