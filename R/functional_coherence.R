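#' Split mined patterns into jump groups
#'
#' Partitions patterns into `G_neg` (jump <= `low`), `G_mid`
#' (`low` < jump < `high`) and `G_pos` (jump >= `high`).  The default
#' bounds of -5 and +5 follow the usual visualization thresholds for
#' separating trivial extensions from combinations that are informative
#' beyond their subsets.
#'
#' @param patterns a `mining_result` (or any data frame with `jump`).
#' @param low,high group boundaries, `low < high`.
#' @return Named list of three data frames `G_neg`, `G_mid`, `G_pos`
#'   partitioning the input.
#' @export
group_by_jump <- function(patterns, low = -5, high = 5) {
  stopifnot(low < high, "jump" %in% names(patterns))
  df <- as.data.frame(patterns)
  list(G_neg = df[df$jump <= low, , drop = FALSE],
       G_mid = df[df$jump > low & df$jump < high, , drop = FALSE],
       G_pos = df[df$jump >= high, , drop = FALSE])
}

#' Unique within-pattern gene pairs of a pattern group
#'
#' Maps every SNP of every pattern to its gene, forms all unordered
#' gene pairs within each pattern, drops pairs where both SNPs map to
#' the same gene, and deduplicates pairs across the group.  SNPs
#' without a gene mapping are skipped with a warning.
#'
#' @param group data frame with a `pattern` column
#'   (`"snp:gt;snp:gt"` strings, as produced by [mine()]).
#' @param gene_map named vector `snp_id -> gene`.
#' @return Data frame with columns `geneA`, `geneB` (sorted within
#'   pair), zero rows if no pairs arise.
#' @export
within_pattern_pairs <- function(group, gene_map) {
  pairs <- list()
  unmapped <- character()
  for (p in group$pattern) {
    snps <- vapply(strsplit(strsplit(p, ";", fixed = TRUE)[[1L]],
                            ":", fixed = TRUE), `[[`, "", 1L)
    genes <- gene_map[snps]
    unmapped <- c(unmapped, snps[is.na(genes)])
    genes <- unique(unname(genes[!is.na(genes)]))
    if (length(genes) >= 2L) {
      cmb <- utils::combn(sort(genes), 2L)
      pairs[[length(pairs) + 1L]] <- data.frame(geneA = cmb[1L, ],
                                                geneB = cmb[2L, ])
    }
  }
  if (length(unmapped))
    warning(sprintf("%d SNP(s) without gene mapping skipped",
                    length(unique(unmapped))))
  if (!length(pairs)) return(data.frame(geneA = character(), geneB = character()))
  out <- do.call(rbind, pairs)
  out[!duplicated(pair_key(out$geneA, out$geneB)), , drop = FALSE]
}

#' Degree-preserving null samples of a gene-pair set
#'
#' Each replicate rewires the observed pair set by shuffling the gene
#' slots of the pair multiset: it has exactly the same number of pairs
#' and preserves the number of times each gene occurs (the degree
#' sequence).  Replicates containing a self-pair or a duplicate pair
#' are rejected and redrawn, up to `max_tries` attempts.
#'
#' @param pairs data frame with `geneA`, `geneB` columns.
#' @param n_rep number of replicates (default 100).
#' @param seed integer seed.
#' @param max_tries rejection-sampling bound per replicate.
#' @return List of `n_rep` data frames shaped like `pairs`.
#' @export
coherence_null <- function(pairs, n_rep = 100L, seed = 1L, max_tries = 1000L) {
  stopifnot(n_rep >= 1)
  slots <- c(rbind(pairs$geneA, pairs$geneB))
  n_pairs <- nrow(pairs)
  with_seed(seed, lapply(seq_len(n_rep), function(i) {
    for (t in seq_len(max_tries)) {
      s <- sample(slots)
      a <- s[seq(1L, by = 2L, length.out = n_pairs)]
      b <- s[seq(2L, by = 2L, length.out = n_pairs)]
      key <- pair_key(a, b)
      if (!any(a == b) && !anyDuplicated(key))
        return(data.frame(geneA = pmin(a, b), geneB = pmax(a, b)))
    }
    stop_data("degree sequence could not be rewired without self- or duplicate pairs after %d tries",
              max_tries)
  }))
}

#' Functional coherence of jump groups against a network
#'
#' For each jump group of mined patterns, looks up the functional
#' similarity of its unique within-pattern gene pairs in a weighted
#' gene network (absent pairs score 0), reports the fraction of pairs
#' with similarity above `cutoff`, and compares the similarity
#' distributions between groups and against a pooled degree-preserving
#' null (built from the `G_pos` pairs) with two-sided rank-sum tests
#' (normal approximation with tie correction).  Groups with fewer than
#' 2 mapped pairs are skipped with a notice.
#'
#' @param patterns a `mining_result` / `fdr_result` with a `jump`
#'   column.
#' @param gene_map named vector `snp_id -> gene`.
#' @param network a `functional_network` ([read_network()]).
#' @param cutoff similarity binarization cutoff (default 0.5).
#' @param jump_bounds length-2 numeric, the [group_by_jump()] bounds.
#' @param n_null number of degree-preserving null replicates
#'   (default 100).
#' @param seed integer seed for the null.
#' @return Object of class `coherence_report`: list with `groups`
#'   (data frame: group, n_pairs, frac_above), `tests` (data frame:
#'   comparison, statistic, p_value, side), `cutoff` and the per-group
#'   similarity vectors in `similarities`.
#' @export
coherence_report <- function(patterns, gene_map, network, cutoff = 0.5,
                             jump_bounds = c(-5, 5), n_null = 100L,
                             seed = 1L) {
  stopifnot(inherits(network, "functional_network"))
  grp <- group_by_jump(patterns, jump_bounds[1L], jump_bounds[2L])
  pair_sets <- lapply(grp, within_pattern_pairs, gene_map = gene_map)
  sims <- lapply(pair_sets, function(p)
    if (nrow(p)) network_similarity(network, p$geneA, p$geneB) else numeric())

  # pooled null anchored on the G_pos pair set (degree-preserving)
  null_sims <- numeric()
  if (nrow(pair_sets$G_pos) >= 2L) {
    reps <- coherence_null(pair_sets$G_pos, n_rep = n_null, seed = seed)
    null_sims <- unlist(lapply(reps, function(p)
      network_similarity(network, p$geneA, p$geneB)))
  }
  sims$null <- null_sims

  groups <- data.frame(
    group = names(sims),
    n_pairs = vapply(sims, length, 0L),
    frac_above = vapply(sims, function(s)
      if (length(s)) mean(s > cutoff) else NA_real_, 0))

  comparisons <- list(c("G_pos", "G_mid"), c("G_pos", "G_neg"),
                      c("G_mid", "G_neg"), c("G_pos", "null"),
                      c("G_mid", "null"), c("G_neg", "null"))
  tests <- do.call(rbind, lapply(comparisons, function(cp) {
    x <- sims[[cp[1L]]]; y <- sims[[cp[2L]]]
    if (length(x) < 2L || length(y) < 2L) {
      message(sprintf("comparison %s vs %s skipped (fewer than 2 pairs)",
                      cp[1L], cp[2L]))
      return(data.frame(comparison = paste(cp, collapse = " vs "),
                        statistic = NA_real_, p_value = NA_real_,
                        side = "two-sided"))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))
    data.frame(comparison = paste(cp, collapse = " vs "),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               side = "two-sided")
  }))
  structure(list(groups = groups, tests = tests, cutoff = cutoff,
                 similarities = sims),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat(sprintf("coherence_report (cutoff %.2f)\n", x$cutoff))
  print(x$groups, row.names = FALSE)
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Simulate a weighted gene functional network
#'
#' Random background network: each gene pair gets an edge with
#' probability `density`, with weight Uniform(0, `background_max`).
#' Pairs listed in `planted` additionally receive weights
#' Uniform(`planted_min`, 1), emulating a functionally coherent core.
#' Used by the tests and the worked examples; real analyses load a
#' network with [read_network()].
#'
#' @param genes character vector of gene symbols.
#' @param density background edge probability (default 0.05).
#' @param planted optional data frame with `geneA`, `geneB` of pairs to
#'   plant with high similarity.
#' @param planted_min lower bound of planted weights (default 0.6).
#' @param background_max upper bound of background weights
#'   (default 1).
#' @param seed integer seed.
#' @return A `functional_network`.
#' @export
simulate_functional_network <- function(genes, density = 0.05,
                                        planted = NULL, planted_min = 0.6,
                                        background_max = 1, seed = 1L) {
  stopifnot(length(genes) >= 2L)
  with_seed(seed, {
    cmb <- utils::combn(sort(unique(genes)), 2L)
    on <- stats::runif(ncol(cmb)) < density
    a <- cmb[1L, on]; b <- cmb[2L, on]
    w <- stats::runif(sum(on), 0, background_max)
    if (!is.null(planted) && nrow(planted)) {
      a <- c(a, pmin(planted$geneA, planted$geneB))
      b <- c(b, pmax(planted$geneA, planted$geneB))
      w <- c(w, stats::runif(nrow(planted), planted_min, 1))
    }
    if (!length(a)) stop_data("empty network; raise density")
    functional_network(a, b, w)
  })
}
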