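test_that("Kruskal-Wallis H matches the rank formula and conventions", {
  kw <- kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)
  # degenerate all-ties convention
  kw0 <- kruskal_wallis(list(a = rep(2, 4), b = rep(2, 4)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)
  # rank-based: invariant under strictly monotone transforms
  set.seed(2)
  x <- rnorm(30); g <- rep(letters[1:3], 10)
  expect_equal(kruskal_wallis(x, g)$statistic,
               kruskal_wallis(exp(x), g)$statistic)
  expect_error(kruskal_wallis(list(a = 1:3)), "2 groups")
})

test_that("Conover p-values equal an independent direct-formula oracle", {
  set.seed(7)
  for (rep in 1:5) {
    groups <- list(a = rnorm(5), b = rnorm(5, 1), c = rnorm(5, 2))
    ph <- conover_posthoc(groups)
    expect_equal(max(abs(ph$p_matrix - conover_oracle(groups))), 0,
                 tolerance = 1e-10)
  }
  # with ties
  groups <- list(a = c(1, 1, 2, 3), b = c(2, 2, 3, 4), c = c(4, 4, 5, 5))
  ph <- conover_posthoc(groups)
  expect_equal(max(abs(ph$p_matrix - conover_oracle(groups))), 0,
               tolerance = 1e-10)
})

test_that("Conover separates distant groups and not identical ones", {
  ph <- conover_posthoc(list(a = 1:10, b = 1:10 + 0.5))
  expect_gt(ph$p_matrix["a", "b"], 0.3)
  wide <- conover_posthoc(list(a = 1:10, b = 101:110, c = 201:210))
  up <- wide$p_matrix[upper.tri(wide$p_matrix)]
  expect_true(all(up < 0.01))
  expect_equal(unname(wide$letters), c("c", "b", "a"))
  # p-values monotone in the rank-mean gap, all else equal
  base <- c(1, 2, 3, 4, 5)
  ps <- vapply(c(0.5, 1.5, 2.5, 3.5), function(d)
    conover_posthoc(list(a = base, b = base + d))$p_matrix[1, 2], numeric(1))
  expect_true(all(diff(ps) < 0))
  # Holm adjustment never decreases p-values
  set.seed(9)
  x <- rnorm(30); g <- rep(letters[1:3], each = 10)
  expect_true(all(conover_posthoc(x, g, p_adjust = "holm")$p_matrix >=
                  conover_posthoc(x, g)$p_matrix - 1e-15))
})

test_that("letter displays mirror the pairwise significance structure", {
  mk <- function(p, meds) {
    k <- length(meds)
    m <- matrix(1, k, k, dimnames = list(names(meds), names(meds)))
    m[upper.tri(m)] <- p
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  # no significant pairs -> single clique
  expect_equal(unname(letter_display(mk(c(.5, .6, .7), c(A = 3, B = 2, C = 1)),
                                     c(A = 3, B = 2, C = 1))),
               c("a", "a", "a"))
  # all pairs significant -> singletons ordered by descending median
  expect_equal(letter_display(mk(c(.01, .01, .01), c(A = 1, B = 2, C = 3)),
                              c(A = 1, B = 2, C = 3)),
               c(A = "c", B = "b", C = "a"))
  # only the extremes differ -> a / ab / b
  expect_equal(letter_display(mk(c(.3, .01, .3), c(A = 3, B = 2, C = 1)),
                              c(A = 3, B = 2, C = 1)),
               c(A = "a", B = "ab", C = "b"))
})

test_that("letters are consistent for every significance pattern up to 5 groups", {
  # exhaustively: sharing a letter <=> pair not significant
  for (k in 2:5) {
    pairs <- utils::combn(k, 2)
    n_pat <- 2^ncol(pairs)
    meds <- stats::setNames(seq(k, 1), LETTERS[1:k])
    for (pat in 0:(n_pat - 1)) {
      sig <- as.logical(bitwAnd(pat, 2^(seq_len(ncol(pairs)) - 1)))
      m <- matrix(1, k, k, dimnames = list(names(meds), names(meds)))
      for (e in which(sig)) {
        i <- pairs[1, e]; j <- pairs[2, e]
        m[i, j] <- m[j, i] <- 0.001
      }
      lt <- letter_display(m, meds, alpha = 0.05)
      for (e in seq_len(ncol(pairs))) {
        i <- pairs[1, e]; j <- pairs[2, e]
        share <- length(intersect(strsplit(lt[i], "")[[1]],
                                  strsplit(lt[j], "")[[1]])) > 0
        expect_equal(share, m[i, j] >= 0.05,
          info = sprintf("k=%d pattern=%d pair=%s%s", k, pat,
                         names(meds)[i], names(meds)[j]))
      }
    }
  }
})

test_that("the null rejection rate of the KW test is calibrated", {
  set.seed(123)
  rej <- mean(replicate(2000, {
    kruskal_wallis(rnorm(30), rep(1:3, each = 10))$p_value < 0.05
  }))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("the KW test has power against a 1.5 SD location shift", {
  set.seed(31)
  rej <- mean(replicate(500, {
    x <- c(rnorm(20), rnorm(20), rnorm(20, 1.5))
    kruskal_wallis(x, rep(1:3, each = 20))$p_value < 0.05
  }))
  expect_gt(rej, 0.8)
})

test_that("Pearson validation gives r = 1 for proportional data and matches
           the covariance formula", {
  a <- c(10, 20, 30, 40, 50)
  expect_equal(pearson_validation(a, 0.3 * a)$r, 1)
  set.seed(17)
  x <- rnorm(10); y <- 0.5 * x + rnorm(10)
  pv <- pearson_validation(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pv$r, r_oracle, tolerance = 1e-12)
  expect_error(pearson_validation(a, rep(2, 5)), "variance")
  # proportional mean + 10% noise at n = 144 gives strong correlation
  set.seed(19)
  area <- exp(rnorm(144, 8, 0.6))
  fw <- 0.004 * area * (1 + rnorm(144, 0, 0.1))
  expect_gt(pearson_validation(area, fw)$r, 0.9)
})
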