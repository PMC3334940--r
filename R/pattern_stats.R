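#' Support of a pattern in a sample group
#'
#' The support (frequency) of a pattern is the fraction of samples in a
#' group in which every item of the pattern is present.  Support is
#' anti-monotone: adding items can only lower it.
#'
#' @param P pattern (item index vector from [pattern()]).
#' @param B a `binary_item_matrix`.
#' @param group logical or integer subset of samples.
#' @return Fraction in \[0, 1\].
#' @export
support <- function(P, B, group) {
  pres <- pattern_presence(B, P)[group]
  if (!length(pres)) stop_data("empty sample group")
  mean(pres)
}

#' SupMaxPair objective of a pattern
#'
#' For the case-enriched direction, SupMaxPair is the support of the
#' pattern in the cases minus the maximal support among all its size-2
#' subsets in the controls; for a size-2 pattern the only size-2 subset
#' is the pattern itself.  The control-enriched direction swaps the two
#' groups.  SupMaxPair is anti-monotone, which is what makes Apriori
#' pruning in [mine()] exact.
#'
#' @inheritParams support
#' @param labels case/control factor aligned to the samples of `B`.
#' @param direction `"case-enriched"` or `"control-enriched"`.
#' @return Signed fraction.
#' @export
supmaxpair <- function(P, B, labels, direction = "case-enriched") {
  direction <- match.arg(direction, c("case-enriched", "control-enriched"))
  if (length(P) < 2L) stop_data("SupMaxPair is defined for patterns of size >= 2")
  validate_phenotypes(labels)
  enr <- if (direction == "case-enriched") labels == "case" else labels == "control"
  pairs <- utils::combn(as.integer(P), 2L)
  max_pair <- max(apply(pairs, 2L, function(q) support(q, B, !enr)))
  support(P, B, enr) - max_pair
}

#' 2x2 contingency table of a pattern against the phenotype
#'
#' @inheritParams supmaxpair
#' @return Named integer vector `(a, b, c, d)`: pattern-present cases,
#'   pattern-present controls, pattern-absent cases, pattern-absent
#'   controls.
#' @export
contingency <- function(P, B, labels) {
  validate_phenotypes(labels)
  pres <- pattern_presence(B, P)
  cs <- labels == "case"
  c(a = sum(pres & cs), b = sum(pres & !cs),
    c = sum(!pres & cs), d = sum(!pres & !cs))
}

#' Pearson chi-square on a 2x2 table, 1 degree of freedom
#'
#' No continuity correction.  Because every pattern, whatever its size,
#' reduces to a present/absent binary variable, the test always has one
#' degree of freedom and statistics of patterns of different sizes are
#' directly comparable.  A table with a zero row or column margin
#' returns statistic 0 and p-value 1 (such patterns are never
#' discriminative).
#'
#' @param tab numeric vector `(a, b, c, d)` as from [contingency()].
#' @return List with `statistic` and `p_value`.
#' @export
chi2_df1 <- function(tab) {
  s <- chi2_stat_vec(tab[1L], tab[2L], tab[3L], tab[4L])
  list(statistic = s, p_value = stats::pchisq(s, df = 1L, lower.tail = FALSE))
}

# Vectorised closed form n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)); degenerate
# margins give 0 by convention.
chi2_stat_vec <- function(a, b, c, d) {
  # double arithmetic: (ad-bc)^2 overflows 32-bit integers at large n
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  out <- numeric(length(den))
  ok <- den > 0
  out[ok] <- (n[ok] * (a[ok] * d[ok] - b[ok] * c[ok])^2) / den[ok]
  out
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product ratio `ad / bc`.  If any cell is zero, the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and the
#' result is flagged.
#'
#' @inheritParams chi2_df1
#' @return List with `odds_ratio` and `corrected` (logical).
#' @export
odds_ratio_2x2 <- function(tab) {
  v <- odds_ratio_vec(tab[1L], tab[2L], tab[3L], tab[4L])
  list(odds_ratio = v$or, corrected = v$corrected)
}

odds_ratio_vec <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  a[corrected] <- a[corrected] + 0.5
  b[corrected] <- b[corrected] + 0.5
  c[corrected] <- c[corrected] + 0.5
  d[corrected] <- d[corrected] + 0.5
  list(or = (a * d) / (b * c), corrected = corrected)
}

#' Two-sided Fisher exact p-value on a 2x2 table
#'
#' Sums, over the hypergeometric distribution with the table's margins,
#' the probabilities of all tables no more likely than the observed one
#' (the same two-sided convention as [stats::fisher.test()]).
#'
#' @inheritParams chi2_df1
#' @return p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  fisher_p_vec(tab[1L], tab[2L], tab[3L], tab[4L])
}

fisher_p_vec <- function(a, b, c, d) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    m <- a[i] + c[i]            # cases
    k <- a[i] + b[i]            # pattern-present samples
    lo <- max(0L, k - (b[i] + d[i]))
    hi <- min(k, m)
    dens <- stats::dhyper(lo:hi, m, b[i] + d[i], k)
    out[i] <- sum(dens[dens <= dens[a[i] - lo + 1L] * (1 + 1e-7)])
  }
  pmin(out, 1)
}

#' Jump of a pattern: gain over its best subset
#'
#' The jump of a pattern is its chi-square statistic minus the best
#' chi-square among all of its proper non-empty subsets (sizes
#' 1 to size-1, enumerated exhaustively).  A positive jump means the
#' combination is informative beyond all of its parts; a negative jump
#' marks a trivial extension of a stronger subset.  Jump is not
#' anti-monotone, so it is applied as a post-mining filter
#' ([jump_filter()]), never as a search objective.
#'
#' @inheritParams supmaxpair
#' @return Signed real, `jump <= chi2(P)`.
#' @export
jump_stat <- function(P, B, labels) {
  if (length(P) < 2L)
    stop_data("jump is defined for patterns of size >= 2 (no proper subsets otherwise)")
  own <- chi2_of_items(P, B, labels)
  best <- -Inf
  for (k in seq_len(length(P) - 1L)) {
    subs <- utils::combn(as.integer(P), k)
    for (j in seq_len(ncol(subs)))
      best <- max(best, chi2_of_items(subs[, j], B, labels))
  }
  own - best
}

chi2_of_items <- function(idx, B, labels) {
  tab <- contingency(idx, B, labels)
  chi2_stat_vec(tab[1L], tab[2L], tab[3L], tab[4L])
}

# Full per-pattern statistics table from contingency counts.  `a`..`d`
# are parallel vectors; returns a data.frame block shared by mine() and
# pattern_stats().
stats_block <- function(a, b, c, d) {
  n_case <- a + c
  n_ctrl <- b + d
  chi2 <- chi2_stat_vec(a, b, c, d)
  orv <- odds_ratio_vec(a, b, c, d)
  data.frame(
    supp_case = a / n_case,
    supp_ctrl = b / n_ctrl,
    chi2 = chi2,
    p_chi2 = stats::pchisq(chi2, 1L, lower.tail = FALSE),
    odds_ratio = orv$or,
    or_corrected = orv$corrected,
    fisher_p = fisher_p_vec(a, b, c, d))
}

#' All statistics for one pattern
#'
#' Convenience wrapper computing support in both classes, SupMaxPair,
#' chi-square (df = 1), odds ratio, Fisher exact p and jump for a
#' single pattern.
#'
#' @inheritParams supmaxpair
#' @return One-row data frame.
#' @export
pattern_stats <- function(P, B, labels, direction = "case-enriched") {
  tab <- contingency(P, B, labels)
  out <- stats_block(tab[1L], tab[2L], tab[3L], tab[4L])
  out$supmaxpair <- if (length(P) >= 2L) supmaxpair(P, B, labels, direction) else NA_real_
  out$jump <- if (length(P) >= 2L) jump_stat(P, B, labels) else NA_real_
  out$direction <- direction
  out$pattern <- pattern_string(B, P)
  out$size <- length(P)
  out[, c("pattern", "size", "supp_case", "supp_ctrl", "supmaxpair",
          "chi2", "p_chi2", "odds_ratio", "or_corrected", "fisher_p",
          "jump", "direction")]
}
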