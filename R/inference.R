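# Group comparison: Kruskal-Wallis, Conover-Iman post-hoc, compact letter
# display, and the Pearson validation correlation against fresh weight.

as_groups <- function(x, g = NULL) {
  if (is.list(x)) {
    if (is.null(names(x))) names(x) <- paste0("group", seq_along(x))
    g <- rep(names(x), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  stopifnot(length(x) == length(g))
  g <- factor(g, levels = unique(g))
  if (nlevels(g) < 2) stop("at least 2 groups required")
  if (any(tabulate(g) == 0) || anyNA(x)) stop("every group must be non-empty")
  list(x = as.numeric(x), g = g)
}

#' Kruskal-Wallis rank test across groups
#'
#' Ties-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom (delegating to [stats::kruskal.test()]). The degenerate case of
#' all observations equal returns H = 0, p = 1 instead of failing on the
#' vanishing tie correction.
#'
#' @param x Either a list of numeric vectors (one per group) or a numeric
#'   vector accompanied by `g`.
#' @param g Group labels, when `x` is a vector.
#' @return An object of class `kw_test`: `statistic` (H), `df`, `p_value`,
#'   `n`.
#' @examples
#' kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))  # H = 7.2
#' @export
kruskal_wallis <- function(x, g = NULL) {
  d <- as_groups(x, g)
  if (length(unique(d$x)) == 1) {
    res <- list(statistic = 0, df = nlevels(d$g) - 1L, p_value = 1)
  } else {
    kt <- stats::kruskal.test(d$x, d$g)
    res <- list(statistic = unname(kt$statistic),
                df = unname(kt$parameter), p_value = kt$p.value)
  }
  structure(c(res, list(n = length(d$x), k = nlevels(d$g))),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (n = %d)\n",
    x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}

#' Conover-Iman pairwise post-hoc test after Kruskal-Wallis
#'
#' Pairwise comparisons of mean ranks using the pooled rank variance and
#' the t distribution on N - k degrees of freedom:
#' \deqn{t_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{S^2 \frac{N-1-H}{N-k}\left(\frac1{n_i}+\frac1{n_j}\right)}}}
#' with \eqn{S^2 = (\sum r^2 - N(N+1)^2/4)/(N-1)} over the pooled
#' (mid-)ranks, which handles ties. P-values are unadjusted by default;
#' `p_adjust = "holm"` (or any [stats::p.adjust()] method) is available.
#'
#' @inheritParams kruskal_wallis
#' @param alpha Significance level used for the letter display.
#' @param p_adjust Multiplicity adjustment method (default `"none"`).
#' @return An object of class `conover_posthoc`: symmetric `p_matrix` with
#'   unit diagonal, `t_matrix`, `letters` (compact letter display),
#'   `medians`, `alpha`, and the originating `kw` test.
#' @examples
#' ph <- conover_posthoc(list(a = 1:5, b = 3:7, c = 11:15))
#' ph$letters
#' @export
conover_posthoc <- function(x, g = NULL, alpha = 0.05, p_adjust = "none") {
  d <- as_groups(x, g)
  kw <- kruskal_wallis(d$x, d$g)
  k <- nlevels(d$g); N <- length(d$x)
  if (N <= k) stop("need more observations than groups")
  r <- rank(d$x)
  n_i <- tabulate(d$g)
  rbar <- tapply(r, d$g, mean)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  H <- kw$statistic
  pmat <- matrix(1, k, k, dimnames = list(levels(d$g), levels(d$g)))
  tmat <- matrix(0, k, k, dimnames = dimnames(pmat))
  scale2 <- S2 * (N - 1 - H) / (N - k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(scale2 * (1 / n_i[i] + 1 / n_i[j]))
    tij <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    tmat[i, j] <- tmat[j, i] <- tij
    pmat[i, j] <- pmat[j, i] <- 2 * stats::pt(-abs(tij), df = N - k)
  }
  if (p_adjust != "none") {
    up <- upper.tri(pmat)
    pmat[up] <- stats::p.adjust(pmat[up], method = p_adjust)
    pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  }
  medians <- tapply(d$x, d$g, stats::median)
  structure(list(p_matrix = pmat, t_matrix = tmat, alpha = alpha,
    letters = letter_display(pmat, medians, alpha),
    medians = medians, kw = kw, p_adjust = p_adjust),
    class = "conover_posthoc")
}

#' @export
print.conover_posthoc <- function(x, ...) {
  print(x$kw)
  cat(sprintf("Conover-Iman pairwise comparisons (alpha = %g, adjust = %s)\n",
    x$alpha, x$p_adjust))
  df <- data.frame(median = as.numeric(x$medians),
                   letters = x$letters[names(x$medians)])
  print(df)
  invisible(x)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: start with all groups in one letter class,
#' split every class containing a significantly different pair, then drop
#' classes contained in another. Letters are assigned in descending order
#' of group medians, so the best-performing group carries "a". Two groups
#' share a letter if and only if they are not significantly different at
#' `alpha`.
#'
#' @param p_matrix Symmetric pairwise p-value matrix with group names.
#' @param medians Named group medians used to order the letters.
#' @param alpha Significance level.
#' @return Named character vector of letter strings, one per group.
#' @export
letter_display <- function(p_matrix, medians, alpha = 0.05) {
  groups <- rownames(p_matrix)
  ord <- groups[order(-as.numeric(medians[groups]))]
  cols <- list(ord)
  if (length(ord) > 1) {
    for (i in 1:(length(ord) - 1)) for (j in (i + 1):length(ord)) {
      gi <- ord[i]; gj <- ord[j]
      if (p_matrix[gi, gj] >= alpha) next
      newcols <- list()
      for (cl in cols) {
        if (all(c(gi, gj) %in% cl))
          newcols <- c(newcols, list(setdiff(cl, gi)), list(setdiff(cl, gj)))
        else newcols <- c(newcols, list(cl))
      }
      newcols <- unique(lapply(newcols[lengths(newcols) > 0], sort))
      # absorb classes contained in a larger one
      is_sub <- vapply(seq_along(newcols), function(u)
        any(vapply(seq_along(newcols), function(v)
          u != v && length(newcols[[u]]) < length(newcols[[v]]) &&
            all(newcols[[u]] %in% newcols[[v]]), logical(1))),
        logical(1))
      cols <- newcols[!is_sub]
    }
  }
  # order classes by their best-ranked member, letter them a, b, c, ...
  first <- vapply(cols, function(cl) min(match(cl, ord)), numeric(1))
  cols <- cols[order(first)]
  lett <- stats::setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols))
    for (gr in cols[[ci]])
      lett[gr] <- paste0(lett[gr], letters[ci])
  vapply(groups, function(gr)
    paste(sort(strsplit(lett[gr], "")[[1]]), collapse = ""), character(1))
}

#' Pearson validation correlation (green area vs fresh weight)
#'
#' Pearson's r between paired measurements, with significance from the
#' regression F-test of the linear model (the ANOVA on the fitted line).
#'
#' @param areas,fresh_weights Paired numeric vectors, n >= 3.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_validation <- function(areas, fresh_weights) {
  stopifnot(length(areas) == length(fresh_weights))
  if (length(areas) < 3) stop("need at least 3 pairs")
  if (stats::var(areas) == 0 || stats::var(fresh_weights) == 0)
    stop("zero variance in areas or fresh weights")
  fit <- stats::lm(fresh_weights ~ areas)
  fs <- suppressWarnings(summary(fit))$fstatistic
  list(r = stats::cor(areas, fresh_weights),
       p_value = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       n = length(areas))
}

#' Per-day group-comparison report
#'
#' For each time point with at least two groups: the Kruskal-Wallis test
#' across treatments and the Conover letter display — the machine twin of
#' the per-day letter columns of the assay's result tables.
#'
#' @param long Long data frame with `treatment`, `time`, `area`.
#' @param alpha Significance level for letters.
#' @param p_adjust Adjustment method for the Conover p-values.
#' @return Data frame with `time`, `treatment`, `median`, `H`, `p_value`,
#'   `letters`.
#' @export
stats_report <- function(long, alpha = 0.05, p_adjust = "none") {
  out <- lapply(split(long, long$time), function(d) {
    if (length(unique(d$treatment)) < 2) return(NULL)
    ph <- conover_posthoc(d$area, d$treatment, alpha = alpha,
                          p_adjust = p_adjust)
    data.frame(time = d$time[1], treatment = names(ph$letters),
      median = as.numeric(ph$medians[names(ph$letters)]),
      H = ph$kw$statistic, p_value = ph$kw$p_value,
      letters = unname(ph$letters), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
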