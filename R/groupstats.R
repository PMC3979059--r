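## Group-comparison statistics.
##
## One-way fixed-effects ANOVA with Tukey's HSD post hoc test (studentized
## range distribution) for the morphometric parameters, and the two-sided
## Mann-Whitney U test for ordinal clinical-score-like data. All tests are
## two-sided; summaries report mean, SD (n - 1 denominator) and SEM.

.checkGroupTable <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  if (anyNA(values)) stop("missing measurement values")
  tab <- table(groups)
  if (length(tab) < 2) stop("ANOVA requires at least 2 groups")
  if (any(tab < 2)) stop("ANOVA requires at least 2 observations per group")
  invisible(tab)
}

#' One-way ANOVA with Tukey's post hoc test
#'
#' Fixed-effects one-way ANOVA with pairwise Tukey honest significant
#' difference comparisons over all group pairs, adjusted via the
#' studentized range distribution.
#'
#' @param values numeric measurements.
#' @param groups group labels (coerced to factor, order of appearance).
#' @param alpha significance level for the pairwise flags (default 0.05).
#' @return A \linkS4class{StatsResult} with the F statistic, omnibus
#'   p-value and one Tukey-adjusted p per group pair.
#' @examples
#' r <- anovaTukey(c(1, 2, 3, 2, 3, 4, 7, 8, 9),
#'                 rep(c("a", "b", "c"), each = 3))
#' r@statistic  # F
#' @export
anovaTukey <- function(values, groups, alpha = 0.05) {
  if (is.data.frame(values)) {
    groups <- values$group
    values <- values$value
  }
  .checkGroupTable(values, groups)
  f <- factor(groups, levels = unique(groups))
  if (var(values) == 0) {
    # no variance at all: no between-group signal by definition
    pairs <- combn(levels(f), 2)
    pw <- data.frame(groupA = pairs[2, ], groupB = pairs[1, ], diff = 0,
                     pAdj = 1, significant = FALSE)
    return(new("StatsResult", test = "one-way ANOVA + Tukey HSD",
               statistic = 0, pValue = 1, pairwise = pw, alpha = alpha))
  }
  fit <- aov(values ~ f)
  an <- summary(fit)[[1]]
  Fval <- an[["F value"]][1]
  pval <- an[["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$f
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  pw <- data.frame(
    groupA = vapply(pairs, `[`, "", 1),
    groupB = vapply(pairs, `[`, "", 2),
    diff = tk[, "diff"], pAdj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha, row.names = NULL)
  new("StatsResult", test = "one-way ANOVA + Tukey HSD",
      statistic = Fval, pValue = pval, pairwise = pw, alpha = alpha)
}

#' Two-sided Mann-Whitney U test
#'
#' U is the number of (A, B) pairs with A > B, counting ties as 1/2.
#' The p-value is exact for tie-free samples with \code{nA * nB <= 400}
#' (Wilcoxon distribution), exact by complete enumeration of group
#' assignments for tied samples when that enumeration is feasible, and
#' otherwise a tie-corrected normal approximation with continuity
#' correction.
#'
#' @param a,b numeric samples (both non-empty).
#' @param alpha significance level recorded in the result.
#' @param exact force (TRUE) or forbid (FALSE) the exact branch;
#'   default NULL chooses automatically.
#' @return A \linkS4class{StatsResult} with the U statistic and two-sided
#'   p-value.
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))@pValue  # 2/6
#' @export
mannWhitney <- function(a, b, alpha = 0.05, exact = NULL) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  m <- length(a); n <- length(b)
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  ties <- anyDuplicated(c(a, b)) > 0
  doExact <- if (!is.null(exact)) exact
             else if (!ties) m * n <= 400
             else choose(m + n, m) <= 2e5
  if (doExact && !ties) {
    # exact two-sided p from the null Wilcoxon distribution
    pLow <- pwilcox(U, m, n)
    pHigh <- 1 - pwilcox(U - 1, m, n)
    p <- min(1, 2 * min(pLow, pHigh))
  } else if (doExact) {
    if (choose(m + n, m) > 2e5)
      stop("exact enumeration infeasible for these sample sizes")
    pool <- c(a, b)
    idx <- combn(m + n, m)
    dev <- abs(apply(idx, 2, function(ii) {
      aa <- pool[ii]; bb <- pool[-ii]
      sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
    }) - m * n / 2)
    p <- mean(dev >= abs(U - m * n / 2) - 1e-9)
  } else {
    # tie-corrected normal approximation with continuity correction and an
    # Edgeworth kurtosis term (the U null is symmetric but platykurtic)
    N <- m + n
    tiecnt <- table(c(a, b))
    tiesum <- sum(tiecnt^3 - tiecnt)
    sigma2 <- m * n / 12 * ((N + 1) - tiesum / (N * (N - 1)))
    g2 <- -6 / 5 * (m^2 + n^2 + m * n + m + n) / (m * n * (N + 1))
    cdf <- function(x) {
      z <- (x - m * n / 2) / sqrt(sigma2)
      pnorm(z) - g2 / 24 * (z^3 - 3 * z) * dnorm(z)
    }
    p <- min(1, max(0, 2 * min(cdf(U + 0.5), 1 - cdf(U - 0.5))))
  }
  new("StatsResult", test = "Mann-Whitney U", statistic = U,
      pValue = p, pairwise = data.frame(), alpha = alpha)
}

#' Per-group summary statistics
#'
#' Per measurement and group: n, mean, sample SD (n - 1 denominator) and
#' SEM. SD and SEM are NA for single observations.
#'
#' @param table data.frame with columns \code{group}, \code{value} and
#'   optionally \code{measurement} (one summary row per measurement and
#'   group).
#' @return data.frame with columns \code{measurement}, \code{group},
#'   \code{n}, \code{mean}, \code{sd}, \code{sem}.
#' @examples
#' summariseGroups(data.frame(group = "a", value = c(2, 4, 6)))
#' @export
summariseGroups <- function(table) {
  stopifnot(all(c("group", "value") %in% names(table)))
  if (is.null(table$measurement)) table$measurement <- "value"
  out <- do.call(rbind, lapply(
    split(table, list(table$measurement, table$group), drop = TRUE),
    function(d) {
      n <- nrow(d)
      s <- if (n > 1) sd(d$value) else NA_real_
      data.frame(measurement = d$measurement[1], group = d$group[1],
                 n = n, mean = mean(d$value), sd = s, sem = s / sqrt(n))
    }))
  rownames(out) <- NULL
  out[order(out$measurement, out$group), ]
}
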