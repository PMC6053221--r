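#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the "sum of small p-values" convention:
#' the sum, over all tables with the observed margins, of the conditional
#' hypergeometric probabilities not exceeding that of the observed table
#' (with a relative slack of 1e-7 for floating-point ties). Probabilities
#' are computed from log-factorials, so counts in the tens of thousands
#' remain exact to double precision.
#'
#' @param table 2x2 numeric matrix of non-negative counts: rows are
#'   groups, columns the two outcomes.
#' @return object of class `fisher_result`: `p_two_sided`, `odds_ratio`
#'   (the sample odds ratio `a*d / (b*c)`), and `degenerate` (`TRUE` when a
#'   zero margin makes the table untestable, in which case `p = 1`).
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tb < 0) || any(tb != round(tb))) stop("counts must be non-negative integers")
  a <- tb[1L, 1L]; b <- tb[1L, 2L]; cc <- tb[2L, 1L]; d <- tb[2L, 2L]
  or <- (a * d) / (b * cc)
  if (is.nan(or)) or <- NA_real_
  m <- a + b; n <- cc + d; k <- a + cc
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    return(structure(list(p_two_sided = 1, odds_ratio = or,
                          degenerate = TRUE), class = "fisher_result"))
  }
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  log_obs <- logp[support == a]
  p <- sum(exp(logp[logp <= log_obs + log1p(1e-7)]))
  structure(list(p_two_sided = min(1, p), odds_ratio = or,
                 degenerate = FALSE), class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("<fisher_result: p = %.4g (two-sided), OR = %.3f%s>\n",
              x$p_two_sided, x$odds_ratio,
              if (x$degenerate) ", degenerate table" else ""))
  invisible(x)
}

#' Build a 2x2 condition contingency table of near-membrane counts
#'
#' Rows are the two conditions; columns are (within threshold, beyond
#' threshold), i.e. `n_within` and `n_total - n_within`.
#'
#' @param counts list of [near_membrane_fraction()] results whose
#'   `condition` fields cover `pair`; entries for other compartments are
#'   ignored when `compartment` is given.
#' @param pair character vector of the two conditions (row order).
#' @param compartment optional compartment filter.
#' @return 2x2 integer matrix with condition row names.
#' @export
build_condition_contingency <- function(counts, pair, compartment = NULL) {
  if (length(pair) != 2L) stop("pair must name exactly two conditions")
  if (!is.null(compartment))
    counts <- Filter(function(x) identical(x$compartment, compartment), counts)
  pick <- function(cond) {
    hit <- Filter(function(x) identical(x$condition, cond), counts)
    if (length(hit) == 0L) stop("missing condition: ", cond)
    hit[[1L]]
  }
  rows <- lapply(pair, pick)
  for (r in rows) {
    if (r$n_total == 0) stop("condition with zero total count: ", r$condition)
    if (r$n_within > r$n_total)
      stop("within-count exceeds total for condition: ", r$condition)
  }
  out <- t(vapply(rows, function(r) c(r$n_within, r$n_total - r$n_within),
                  numeric(2L)))
  dimnames(out) <- list(pair, c("within", "beyond"))
  out
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' The omnibus H statistic (tie-corrected, via [stats::kruskal.test()])
#' plus Dunn's pairwise z statistics computed from mean midranks with the
#' tie-corrected variance, and Bonferroni-adjusted two-sided p-values
#' (`p_adj = min(1, p * n_comparisons)`).
#'
#' @param groups named list of numeric samples (>= 2 groups, each n >= 2).
#' @param n_comparisons multiplier for the adjustment; defaults to the
#'   number of pairs actually compared.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @param metric optional metric name carried into the result.
#' @return object of class `group_comparison`: `metric`, `H`, `df`,
#'   `p_omnibus`, and `pairwise` (data frame: group1, group2, z, p, p_adj).
#' @export
kruskal_wallis_dunn <- function(groups, n_comparisons = NULL,
                                adjust = c("bonferroni", "none"),
                                metric = NA_character_) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("each group needs at least 2 observations")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  N <- length(x)
  pairs <- utils::combn(names(groups), 2L)
  if (is.null(n_comparisons)) n_comparisons <- ncol(pairs)

  if (length(unique(x)) == 1L) {
    pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                     z = 0, p = 1, p_adj = 1)
    return(structure(list(metric = metric, H = 0, df = length(groups) - 1L,
                          p_omnibus = 1, pairwise = pw),
                     class = "group_comparison"))
  }

  kw <- stats::kruskal.test(x, g)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  base_var <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   z = NA_real_, p = NA_real_, p_adj = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    se <- sqrt(base_var * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    pw$z[i] <- z
    pw$p[i] <- p
    pw$p_adj[i] <- if (adjust == "bonferroni") min(1, p * n_comparisons) else p
  }
  structure(list(metric = metric,
                 H = unname(kw$statistic), df = unname(kw$parameter),
                 p_omnibus = kw$p.value, pairwise = pw),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison%s: H = %.3f (df %d), omnibus p = %.4g>\n",
              if (is.na(x$metric)) "" else paste0(" [", x$metric, "]"),
              x$H, x$df, x$p_omnibus))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
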