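# direct-formula ANOVA/Tukey oracle for a balanced one-way layout
anovaOracle <- function(groups) {
  k <- length(groups); n <- lengths(groups); N <- sum(n)
  gm <- mean(unlist(groups))
  ssb <- sum(n * (vapply(groups, mean, 1) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- pf(F, k - 1, N - k, lower.tail = FALSE)
  mse <- ssw / (N - k)
  pairs <- combn(k, 2)
  pAdj <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    q <- abs(mean(groups[[i]]) - mean(groups[[j]])) /
      sqrt(mse / 2 * (1 / n[i] + 1 / n[j]))
    ptukey(q, k, N - k, lower.tail = FALSE)
  })
  list(F = F, p = p, pAdj = pAdj)
}

test_that("ANOVA and Tukey match the direct formulas on toy triples", {
  g <- list(c(1, 2, 3), c(2, 3, 4), c(7, 8, 9))
  want <- anovaOracle(g)
  got <- anovaTukey(unlist(g), rep(c("a", "b", "c"), each = 3))
  expect_equal(got@statistic, want$F, tolerance = 1e-12)
  expect_equal(got@pValue, want$p, tolerance = 1e-12)
  expect_equal(sort(got@pairwise$pAdj), sort(want$pAdj), tolerance = 1e-9)
  expect_identical(nrow(got@pairwise), 3L)  # all pairs covered
})

test_that("ANOVA degenerate and invariance properties", {
  vals <- rep(5, 9); grp <- rep(c("a", "b", "c"), each = 3)
  expect_equal(anovaTukey(vals, grp)@statistic, 0)
  expect_error(anovaTukey(1:6, rep("a", 6)), "at least 2 groups")
  expect_error(anovaTukey(1:3, c("a", "a", "b")), "2 observations")

  set.seed(10)
  v <- rnorm(30); g <- rep(letters[1:3], each = 10)
  base <- anovaTukey(v, g)
  shifted <- anovaTukey(v + 100, g)
  scaled <- anovaTukey(v * 7, g)
  expect_equal(base@statistic, shifted@statistic, tolerance = 1e-9)
  expect_equal(base@statistic, scaled@statistic, tolerance = 1e-9)
  expect_equal(base@pairwise$pAdj, shifted@pairwise$pAdj, tolerance = 1e-9)

  # Tukey-adjusted p is never below the unadjusted pairwise t-test p
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    pt <- t.test(v[g == pair[1]], v[g == pair[2]], var.equal = TRUE)$p.value
    pw <- base@pairwise
    row <- (pw$groupA %in% pair) & (pw$groupB %in% pair)
    expect_gte(pw$pAdj[row] + 1e-12, pt)
  }
})

test_that("Mann-Whitney matches exact enumeration and handles ties", {
  # A = {1,2}, B = {3,4}: U = 0, exact two-sided p = 2/6
  r <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(r@statistic, 0)
  expect_equal(r@pValue, 2 / 6, tolerance = 1e-12)

  # identical samples: maximal p
  expect_equal(mannWhitney(c(1, 2, 3), c(1, 2, 3))@pValue, 1)

  # full-enumeration oracle on 4 + 4 with ties
  a <- c(0, 1, 1, 2); b <- c(1, 2, 2, 3)
  got <- mannWhitney(a, b)@pValue
  pool <- c(a, b)
  U <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  dev <- abs(apply(combn(8, 4), 2, function(ii)
    U(pool[ii], pool[-ii])) - 8)
  want <- mean(dev >= abs(U(a, b) - 8) - 1e-9)
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(mannWhitney(numeric(0), 1), "non-empty")
})

test_that("exact and asymptotic Mann-Whitney branches agree on 8 vs 8", {
  set.seed(20)
  for (rep in 1:5) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    pe <- mannWhitney(a, b, exact = TRUE)@pValue
    pa <- mannWhitney(a, b, exact = FALSE)@pValue
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("tie-heavy scores match a brute-force permutation oracle", {
  a <- c(0, 0, 1, 2, 2); b <- c(1, 2, 2, 3, 3)
  got <- mannWhitney(a, b)@pValue
  pool <- c(a, b)
  U <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  dev <- abs(apply(combn(10, 5), 2, function(ii)
    U(pool[ii], pool[-ii])) - 12.5)
  want <- mean(dev >= abs(U(a, b) - 12.5) - 1e-9)
  expect_lt(abs(got - want), 0.01)
})

test_that("group summaries report n, mean, SD and SEM", {
  s <- summariseGroups(data.frame(group = "a", value = c(2, 4, 6)))
  expect_equal(s$mean, 4)
  expect_equal(s$sd, 2)
  expect_equal(s$sem, 2 / sqrt(3))
  s1 <- summariseGroups(data.frame(group = "a", value = 5))
  expect_true(is.na(s1$sd) && is.na(s1$sem))

  set.seed(30)
  big <- data.frame(group = "g", value = rnorm(400, 10, 2))
  sb <- summariseGroups(big)
  expect_lt(abs(sb$mean - 10), 3 * sb$sem)
})
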