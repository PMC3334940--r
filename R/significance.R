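# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Randomly permute case/control labels
#'
#' Uniformly shuffles the assignment of labels to samples while
#' preserving the case/control ratio exactly (it is a permutation of
#' the observed labels).  Deterministic given `seed`.
#'
#' @param labels case/control factor.
#' @param seed integer seed.
#' @return Permuted factor with the original `names`.
#' @export
permute_labels <- function(labels, seed) {
  validate_phenotypes(labels)
  perm <- with_seed(seed, sample.int(length(labels)))
  out <- labels[perm]
  names(out) <- names(labels)
  out
}

#' Size-specific permutation FDR for mined patterns
#'
#' Reruns the complete mining pass (same threshold, directions,
#' gene-set constraints and jump filter -- asserted via config digest)
#' on `n_perm` label permutations and pools the chi-square statistics
#' of the resulting random patterns by pattern size.  For a real
#' size-k pattern with chi-square `c`, with `m` real size-k patterns at
#' chi-square >= `c` (at least 1: the pattern counts itself) and `n`
#' pooled random size-k patterns at chi-square >= `c`, the estimate is
#' `fdr = n / (n_perm * m)`.  When `n = 0` the estimate is 0 and
#' `fdr_upper` carries the resolution bound `1 / (n_perm * m)` (e.g.
#' < 0.002 at 500 permutations); otherwise `fdr_upper` equals `fdr`.
#' No second-stage correction across sizes is applied; each pattern is
#' judged within its own size stratum.
#'
#' @param real a `mining_result` from [mine()], optionally passed
#'   through [jump_filter()]; its recorded configuration must match
#'   `cfg`.
#' @param B,labels the data the real result was mined from.
#' @param cfg the [mining_config()] of the real run (including
#'   `jump_min` if filtering was applied).
#' @param n_perm number of permutations (default 100).
#' @param seed master seed; permutation i uses a seed derived from it.
#' @return `real` with `fdr` and `fdr_upper` columns appended (class
#'   `fdr_result`); the pooled null statistics are attached as
#'   attribute `null_chi2` (data frame: `size`, `perm`, `chi2`).
#' @export
estimate_fdr <- function(real, B, labels, cfg, n_perm = 100L, seed = 1L) {
  stopifnot(inherits(real, "mining_result"))
  if (n_perm < 1L) stop_data("n_perm must be at least 1")
  validate_phenotypes(labels)
  if (!identical(attr(real, "config_digest"), mining_config_digest(cfg)))
    stop_data("configuration of the real run and the permutation runs differ; the correction would be biased")

  null_tabs <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    labs_i <- permute_labels(labels, derive_seed(seed, i))
    tab <- mine_light(B, labs_i, cfg)
    if (nrow(tab)) tab$perm <- i
    null_tabs[[i]] <- tab
  }
  null_chi2 <- do.call(rbind, null_tabs[vapply(null_tabs, nrow, 0L) > 0L])
  if (is.null(null_chi2))
    null_chi2 <- data.frame(size = integer(), chi2 = numeric(), perm = integer())

  fdr <- fdr_upper <- rep(NA_real_, nrow(real))
  tol <- 1e-9
  for (k in unique(real$size)) {
    rk <- which(real$size == k)
    null_k <- null_chi2$chi2[null_chi2$size == k]
    for (r in rk) {
      cstat <- real$chi2[r]
      m <- sum(real$chi2[rk] >= cstat - tol)
      n <- sum(null_k >= cstat - tol)
      fdr[r] <- n / (n_perm * m)
      fdr_upper[r] <- max(n, 1L) / (n_perm * m)
    }
  }
  out <- as.data.frame(real)
  out$fdr <- fdr
  out$fdr_upper <- fdr_upper
  structure(out, items = attr(real, "items"), config = cfg,
            config_digest = attr(real, "config_digest"),
            level_counts = attr(real, "level_counts"),
            n_perm = n_perm, null_chi2 = null_chi2,
            class = c("fdr_result", "mining_result", "data.frame"))
}
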