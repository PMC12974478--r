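#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' k - 1 degrees of freedom. Degenerate input (all values identical) gives
#' H = 0, p = 1 rather than an error.
#'
#' @param groups list of numeric vectors (>= 2 groups, each nonempty).
#' @return List `H`, `p`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) == 0)) stop("all groups must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  H <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_corr <= 0) {
    H <- 0
  } else {
    H <- H / tie_corr
  }
  df <- length(groups) - 1L
  list(H = H, p = if (H == 0) 1 else pchisq(H, df, lower.tail = FALSE),
       df = df, n = n)
}

#' Dunn's post hoc test with Bonferroni correction
#'
#' Pairwise z statistics from mean-rank differences with tie-corrected
#' variance; two-sided p values multiplied by the number of pairwise
#' comparisons k(k-1)/2 and capped at 1. Significance is flagged at adjusted
#' p < `alpha`.
#'
#' @param groups list of numeric vectors (optionally named).
#' @param alpha significance level on the adjusted p.
#' @return A `group_comparison` list: omnibus `H`/`p`, pairwise table
#'   (group1, group2, z, p_raw, p_adj, significant), group medians.
#' @export
dunn_bonferroni <- function(groups, alpha = 0.05) {
  kw <- kruskal_wallis(groups)
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), vapply(groups, length, 1L))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tabulate(g)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  m <- k * (k - 1) / 2
  pairs <- utils::combn(k, 2)
  tab <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se2 <- (n * (n + 1) / 12 - tie_term) * (1 / ni[i1] + 1 / ni[i2])
    z <- if (se2 > 0) (rbar[i1] - rbar[i2]) / sqrt(se2) else 0
    p_raw <- 2 * pnorm(-abs(z))
    data.frame(group1 = nm[i1], group2 = nm[i2], z = unname(z),
               p_raw = unname(p_raw),
               p_adj = min(1, unname(p_raw) * m),
               stringsAsFactors = FALSE)
  }))
  tab$significant <- tab$p_adj < alpha
  structure(list(H = kw$H, p = kw$p, df = kw$df,
                 pairwise = tab,
                 medians = setNames(vapply(groups, median, 1, na.rm = TRUE), nm),
                 n_comparisons = m, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> Kruskal-Wallis H =", signif(x$H, 4),
      ", df =", x$df, ", p =", signif(x$p, 3), "\n")
  cat("medians:", paste(names(x$medians), signif(x$medians, 4),
                        sep = "=", collapse = ", "), "\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
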