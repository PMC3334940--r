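#' Mining configuration
#'
#' Bundles every parameter of the Apriori/SupMaxPair search so that the
#' real run and each permutation run in [estimate_fdr()] provably use
#' the same setup (compared by config digest).
#'
#' @param threshold SupMaxPair cutoff in (0, 1].  The paper-scale
#'   analyses use 0.1-0.2; every reported pattern then has support at
#'   least `threshold` in its enriched class.
#' @param max_size largest pattern size searched (default 10).
#' @param directions which enrichment directions to mine; both by
#'   default.  The two passes are symmetric and their results are
#'   concatenated (they cannot overlap for `threshold > 0`).
#' @param min_size_report smallest size reported (default 2; SupMaxPair
#'   is undefined below 2).
#' @param gene_map optional named vector `snp_id -> gene`
#'   ([read_gene_map()]); required when `gene_sets` is given.
#' @param gene_sets optional gene set collection ([read_gene_sets()]).
#'   When set, a candidate is kept only if the genes of all its SNPs
#'   are jointly contained in at least one set -- an anti-monotone
#'   constraint applied at every level.
#' @param jump_min optional jump threshold.  [mine()] itself never
#'   filters on jump (jump is not anti-monotone); the value is carried
#'   so that [jump_filter()] and the permutation runs of
#'   [estimate_fdr()] apply the identical post-filter.
#' @param candidate_budget guard on the live pattern frontier per level
#'   (default 5e6); joined candidate batches are additionally capped at
#'   20x this value.  Exceeding either aborts with advice to raise the
#'   threshold.
#' @return Object of class `mining_config`.
#' @export
mining_config <- function(threshold, max_size = 10L,
                          directions = c("case-enriched", "control-enriched"),
                          min_size_report = 2L,
                          gene_map = NULL, gene_sets = NULL,
                          jump_min = NULL, candidate_budget = 5e6) {
  stopifnot(threshold > 0, threshold <= 1, max_size >= 2, min_size_report >= 2)
  directions <- match.arg(directions, c("case-enriched", "control-enriched"),
                          several.ok = TRUE)
  if (!is.null(gene_sets) && is.null(gene_map))
    stop_data("gene_sets require a gene_map")
  structure(list(threshold = threshold, max_size = as.integer(max_size),
                 directions = directions,
                 min_size_report = as.integer(min_size_report),
                 gene_map = gene_map, gene_sets = gene_sets,
                 jump_min = jump_min, candidate_budget = candidate_budget),
            class = "mining_config")
}

# Digest over the parameters that define the hypothesis space; gene
# structures enter via their content hash.
mining_config_digest <- function(cfg) {
  config_digest(list(
    threshold = cfg$threshold, max_size = cfg$max_size,
    directions = paste(cfg$directions, collapse = "+"),
    min_size_report = cfg$min_size_report,
    jump_min = cfg$jump_min %||% "none",
    gene_map = if (is.null(cfg$gene_map)) "none" else
      fnv1a(paste(names(cfg$gene_map), cfg$gene_map, collapse = ";")),
    gene_sets = if (is.null(cfg$gene_sets)) "none" else
      fnv1a(paste(names(cfg$gene_sets),
                  vapply(cfg$gene_sets, paste, "", collapse = ","),
                  collapse = ";"))))
}

# ---- gene-set constraint machinery -----------------------------------

# Per-item vector of retained-set indices containing the item's gene.
# An item whose SNP is unmapped, or whose gene is in no set, can never
# satisfy the constraint.
build_constraint <- function(B, cfg) {
  if (is.null(cfg$gene_sets)) return(NULL)
  gene_of_item <- unname(cfg$gene_map[B$items$snp_id])
  genes <- unique(stats::na.omit(gene_of_item))
  sets_of_gene <- lapply(stats::setNames(genes, genes), function(g)
    which(vapply(cfg$gene_sets, function(s) g %in% s, NA)))
  item_sets <- lapply(gene_of_item, function(g)
    if (is.na(g)) integer() else sets_of_gene[[g]])
  list(item_sets = item_sets)
}

# m x m logical matrix: do items i and j share at least one set?
pair_allowed_matrix <- function(constraint, items) {
  nset <- max(c(1L, unlist(constraint$item_sets[items])))
  M <- matrix(0, length(items), nset)
  for (r in seq_along(items)) M[r, constraint$item_sets[[items[r]]]] <- 1
  tcrossprod(M) > 0
}

#' Filter pattern candidates by gene-set containment
#'
#' Keeps a candidate iff the genes of all its SNPs are jointly
#' contained in at least one retained gene set.  SNPs without a gene
#' mapping fail every constraint.  The predicate is anti-monotone, so
#' [mine()] applies it as an additional prune at every level; this
#' function is the standalone surface for pre-filtering candidate
#' lists.
#'
#' @param candidates list of patterns (item index vectors, see
#'   [pattern()]).
#' @param B the `binary_item_matrix` the patterns refer to.
#' @param gene_map named vector `snp_id -> gene`.
#' @param gene_sets gene set collection ([read_gene_sets()]).
#' @return The subset of `candidates` satisfying the constraint.
#' @export
apply_geneset_constraint <- function(candidates, B, gene_map, gene_sets) {
  constraint <- build_constraint(B, list(gene_map = gene_map, gene_sets = gene_sets))
  keep <- vapply(candidates, function(idx) {
    sets <- Reduce(intersect, constraint$item_sets[idx])
    length(sets) > 0L
  }, NA)
  candidates[keep]
}

# ---- the SMP search ---------------------------------------------------

# Chain lookup of item tuples into the per-level survivor stores.
# `tuples` is an N x j integer matrix of sorted item indices; returns
# the row of each tuple in levels[[j]] (NA if not a survivor).  Level
# keys are prow * base + last, with prow the row of the first j-1 items
# in the previous level; base exceeds the largest item index so the
# arithmetic is exact in doubles.
chain_match <- function(tuples, levels, base) {
  j <- ncol(tuples)
  r <- match(tuples[, 1L] * base + tuples[, 2L], levels[[2L]]$key)
  jj <- 3L
  while (jj <= j) {
    r <- match(r * base + tuples[, jj], levels[[jj]]$key)
    jj <- jj + 1L
  }
  r
}

# One directional Apriori pass.  Returns per-level survivor stores with
# counts, SupMaxPair components, chi-square and best-subset chi-square
# (so jump is available without re-scanning), plus per-level
# candidate/survivor counts.
smp_core <- function(B, labels, cfg, direction) {
  bits <- B$bits
  n <- nrow(bits)
  cs <- labels == "case"
  enr <- if (direction == "case-enriched") cs else !cs
  ne <- sum(enr); no <- n - ne
  n_case <- sum(cs); n_ctrl <- n - n_case
  thr <- cfg$threshold
  eps <- 1e-9
  snp_of <- B$items$snp_index
  budget <- cfg$candidate_budget
  base <- as.numeric(ncol(bits) + 1L)
  constraint <- build_constraint(B, cfg)

  # chi2 of a survivor from its counts in the two classes
  lev_chi2 <- function(ce, co) {
    a <- if (direction == "case-enriched") ce else co
    b <- if (direction == "case-enriched") co else ce
    chi2_stat_vec(a, b, n_case - a, n_ctrl - b)
  }

  # level 1: an item can appear in a qualifying pattern only if its own
  # support in the enriched class reaches the threshold (SupMaxPair of
  # any superset is bounded by that support)
  cnt_case1 <- colSums(bits[cs, , drop = FALSE])
  cnt_ctrl1 <- colSums(bits[!cs, , drop = FALSE])
  chi2_1 <- chi2_stat_vec(cnt_case1, cnt_ctrl1,
                          n_case - cnt_case1, n_ctrl - cnt_ctrl1)
  cnt_e1 <- if (direction == "case-enriched") cnt_case1 else cnt_ctrl1
  surv1 <- which(cnt_e1 / ne >= thr - eps)
  if (!is.null(constraint))
    surv1 <- surv1[lengths(constraint$item_sets[surv1]) > 0L]
  level_counts <- data.frame(size = 1L, candidates = ncol(bits),
                             survivors = length(surv1))
  levels <- list()

  if (length(surv1) >= 2L) {
    # level 2: bulk pair evaluation; SupMaxPair of a pair is its own
    # enriched support minus its own support in the other class
    X <- bits[, surv1, drop = FALSE]
    storage.mode(X) <- "double"
    CE <- crossprod(X[enr, , drop = FALSE])
    CO <- crossprod(X[!enr, , drop = FALSE])
    ok <- upper.tri(CE) & outer(snp_of[surv1], snp_of[surv1], "!=")
    if (!is.null(constraint))
      ok <- ok & pair_allowed_matrix(constraint, surv1)
    n_cand2 <- sum(ok)
    pass <- ok & (CE * no - CO * ne >= thr * ne * no - 1e-6)
    sel <- which(pass, arr.ind = TRUE)
    level_counts <- rbind(level_counts,
                          data.frame(size = 2L, candidates = n_cand2,
                                     survivors = nrow(sel)))
    if (nrow(sel) > budget)
      stop_budget("level-2 frontier (%d patterns) exceeds the candidate budget; raise the SupMaxPair threshold",
                  nrow(sel))
    if (nrow(sel) > 0L) {
      ii <- surv1[sel[, 1L]]; jj <- surv1[sel[, 2L]]
      o <- order(ii, jj)
      ii <- ii[o]; jj <- jj[o]
      ce <- CE[sel][o]; co <- CO[sel][o]
      lev <- list(items = cbind(ii, jj, deparse.level = 0),
                  prow = ii, last = jj, key = ii * base + jj,
                  ce = ce, co = co, mp = co / no,
                  chi2 = lev_chi2(ce, co),
                  best = pmax(chi2_1[ii], chi2_1[jj]),
                  P = bits[, ii, drop = FALSE] & bits[, jj, drop = FALSE])
      if (!is.null(constraint))
        lev$sets <- mapply(intersect, constraint$item_sets[ii],
                           constraint$item_sets[jj], SIMPLIFY = FALSE)
      levels[[2L]] <- lev
    }
  } else {
    level_counts <- rbind(level_counts,
                          data.frame(size = 2L, candidates = 0L, survivors = 0L))
  }

  # levels >= 3: prefix join of (k-1)-survivors sharing their first k-2
  # items (equivalently, the same previous-level parent row), bulk
  # support counting per prefix group, then vectorised
  # all-subsets-survive checks via chain lookup.  The best-subset
  # chi-square is carried along, so jump never needs a rescan.
  k <- 3L
  while (k <= cfg$max_size && length(levels) >= k - 1L &&
         !is.null(levels[[k - 1L]]) && nrow(levels[[k - 1L]]$items) >= 2L) {
    prev <- levels[[k - 1L]]
    np <- nrow(prev$items)
    groups <- split(seq_len(np), prev$prow)
    groups <- groups[lengths(groups) >= 2L]

    gA <- list(); gB <- list(); gsc <- list(); gco <- list()
    n_cand <- 0
    for (g in groups) {
      lasts <- prev$last[g]
      sg <- snp_of[lasts]
      psel <- which(upper.tri(diag(length(g))) & outer(sg, sg, "!="),
                    arr.ind = TRUE)
      if (!nrow(psel)) next
      n_cand <- n_cand + nrow(psel)
      if (n_cand > 20 * budget)
        stop_budget("more than %g candidates joined at size %d; raise the SupMaxPair threshold",
                    20 * budget, k)
      A <- g[psel[, 1L]]; Bb <- g[psel[, 2L]]
      # cheap necessary condition first: SupMaxPair <= sc - parents' mp
      Pe <- prev$P[enr, g, drop = FALSE] * 1
      Le <- bits[enr, prev$last[g], drop = FALSE] * 1
      Ceg <- crossprod(Pe, Le)
      sc <- Ceg[cbind(psel[, 1L], psel[, 2L])]
      pre <- sc / ne - pmax(prev$mp[A], prev$mp[Bb]) >= thr - eps
      if (!any(pre)) next
      Po <- prev$P[!enr, g, drop = FALSE] * 1
      Lo <- bits[!enr, prev$last[g], drop = FALSE] * 1
      Cog <- crossprod(Po, Lo)
      w <- which(pre)
      gA[[length(gA) + 1L]] <- A[w]
      gB[[length(gB) + 1L]] <- Bb[w]
      gsc[[length(gsc) + 1L]] <- sc[w]
      gco[[length(gco) + 1L]] <- Cog[cbind(psel[, 1L], psel[, 2L])][w]
    }
    level_counts <- rbind(level_counts,
                          data.frame(size = k, candidates = n_cand,
                                     survivors = 0L))
    if (!length(gA)) break
    A <- unlist(gA); Bb <- unlist(gB)
    ce <- unlist(gsc); co <- unlist(gco)

    # candidate tuples: shared prefix of the two parents + both lasts
    items <- cbind(prev$items[A, seq_len(k - 2L), drop = FALSE],
                   prev$last[A], prev$last[Bb], deparse.level = 0)
    mp <- pmax(prev$mp[A], prev$mp[Bb])
    bestM <- pmax(pmax(prev$chi2[A], prev$best[A]),
                  pmax(prev$chi2[Bb], prev$best[Bb]))
    keep <- rep(TRUE, length(A))
    for (d in seq_len(k - 2L)) {
      r <- chain_match(items[, -d, drop = FALSE], levels, base)
      keep <- keep & !is.na(r)
      mp <- pmax(mp, ifelse(is.na(r), -Inf, prev$mp[r]))
      bestM <- pmax(bestM, ifelse(is.na(r), -Inf,
                                  pmax(prev$chi2[r], prev$best[r])))
    }
    if (!is.null(constraint)) {
      csets <- mapply(intersect, prev$sets[A], prev$sets[Bb], SIMPLIFY = FALSE)
      keep <- keep & lengths(csets) > 0L
    }
    keep <- keep & (ce / ne - mp >= thr - eps)
    w <- which(keep)
    if (!length(w)) break
    if (length(w) > budget)
      stop_budget("size-%d frontier (%d patterns) exceeds the candidate budget; raise the SupMaxPair threshold",
                  k, length(w))
    o <- w[do.call(order, as.data.frame(items[w, , drop = FALSE]))]
    lev <- list(items = items[o, , drop = FALSE],
                prow = A[o], last = prev$last[Bb][o],
                key = A[o] * base + prev$last[Bb][o],
                ce = ce[o], co = co[o], mp = mp[o],
                chi2 = lev_chi2(ce[o], co[o]),
                best = bestM[o],
                P = prev$P[, A[o], drop = FALSE] &
                  bits[, prev$last[Bb][o], drop = FALSE])
    if (!is.null(constraint)) lev$sets <- csets[o]
    levels[[k]] <- lev
    level_counts$survivors[level_counts$size == k] <- length(w)
    levels[[k - 1L]]$P <- NULL  # presence only needed for the next join
    k <- k + 1L
  }
  if (length(levels) >= 2L && !is.null(levels[[length(levels)]]))
    levels[[length(levels)]]$P <- NULL

  list(levels = levels, level_counts = level_counts,
       direction = direction, ne = ne, no = no,
       n_case = n_case, n_ctrl = n_ctrl)
}

# Turn per-level survivor stores into the result table for one
# direction.
assemble_direction <- function(B, core, cfg, compute = c("full", "chi2")) {
  compute <- match.arg(compute)
  out <- list(); items_out <- list()
  item_label <- colnames(B$bits)
  for (k in seq_along(core$levels)) {
    lev <- core$levels[[k]]
    if (is.null(lev) || k < cfg$min_size_report) next
    a <- if (core$direction == "case-enriched") lev$ce else lev$co
    b <- if (core$direction == "case-enriched") lev$co else lev$ce
    tab <- if (compute == "full") {
      stats_block(a, b, core$n_case - a, core$n_ctrl - b)
    } else {
      data.frame(chi2 = lev$chi2)
    }
    tab$supmaxpair <- lev$ce / core$ne - lev$mp
    tab$jump <- lev$chi2 - lev$best
    tab$size <- k
    tab$direction <- core$direction
    lab <- item_label[lev$items]
    dim(lab) <- dim(lev$items)
    tab$pattern <- do.call(paste, c(as.data.frame(lab), sep = ";"))
    out[[length(out) + 1L]] <- tab
    items_out <- c(items_out, asplit(lev$items, 1L))
  }
  list(table = if (length(out)) do.call(rbind, out),
       items = items_out, level_counts = core$level_counts)
}

mining_result <- function(table, items, cfg, level_counts, digest) {
  cols <- c("pattern", "size", "supp_case", "supp_ctrl", "supmaxpair",
            "chi2", "p_chi2", "odds_ratio", "or_corrected", "fisher_p",
            "jump", "direction")
  if (is.null(table)) {
    table <- data.frame(pattern = character(), size = integer(),
                        supp_case = numeric(), supp_ctrl = numeric(),
                        supmaxpair = numeric(), chi2 = numeric(),
                        p_chi2 = numeric(), odds_ratio = numeric(),
                        or_corrected = logical(), fisher_p = numeric(),
                        jump = numeric(), direction = character())
  }
  table <- table[, intersect(cols, names(table)), drop = FALSE]
  rownames(table) <- NULL
  structure(table, items = items, config = cfg,
            config_digest = digest, level_counts = level_counts,
            class = c("mining_result", "data.frame"))
}

#' @export
print.mining_result <- function(x, ...) {
  cat(sprintf("mining_result: %d patterns (sizes %s), SupMaxPair threshold %g\n",
              nrow(x),
              if (nrow(x)) paste(range(x$size), collapse = "-") else "-",
              attr(x, "config")$threshold))
  NextMethod()
}

#' Mine discriminative SNP-genotype combinations
#'
#' Level-wise Apriori search returning exactly the set of patterns of
#' size `min_size_report..max_size` whose SupMaxPair reaches
#' `cfg$threshold` in each requested direction, with full per-pattern
#' statistics.  Candidates at level k are generated only from surviving
#' level k-1 patterns (prefix join under the global item order followed
#' by the all-subsets-survive check); two items of the same SNP are
#' never joined; gene-set constraints, when configured, prune at every
#' level.  Pattern supports are counted by incremental bit-column
#' intersection, never by re-scanning the matrix per candidate.  Output
#' order is deterministic: direction, then size, then item order.
#'
#' @param B a `binary_item_matrix` from [encode_binary()].
#' @param labels case/control factor aligned to the samples of `B`.
#' @param cfg a [mining_config()].
#' @return A `mining_result`: a data frame of patterns and statistics
#'   with the item indices, configuration, config digest and per-level
#'   candidate/survivor counts as attributes.
#' @export
mine <- function(B, labels, cfg) {
  stopifnot(inherits(B, "binary_item_matrix"), inherits(cfg, "mining_config"))
  validate_phenotypes(labels)
  if (nrow(B$bits) != length(labels))
    stop_data("labels and binary matrix disagree on sample count")
  parts <- lapply(cfg$directions, function(d)
    assemble_direction(B, smp_core(B, labels, cfg, d), cfg, "full"))
  tabs <- do.call(rbind, lapply(parts, `[[`, "table"))
  items <- do.call(c, lapply(parts, `[[`, "items"))
  counts <- do.call(rbind, Map(function(p, d)
    cbind(p$level_counts, direction = d), parts, cfg$directions))
  mining_result(tabs, items %||% list(), cfg, counts, mining_config_digest(cfg))
}

# Light-weight mining pass used inside permutation tests: chi2/jump
# only, with the configured jump filter applied, identical search setup.
mine_light <- function(B, labels, cfg) {
  parts <- lapply(cfg$directions, function(d)
    assemble_direction(B, smp_core(B, labels, cfg, d), cfg, "chi2"))
  tab <- do.call(rbind, lapply(parts, `[[`, "table"))
  if (is.null(tab))
    return(data.frame(size = integer(), chi2 = numeric()))
  if (!is.null(cfg$jump_min))
    tab <- tab[tab$jump >= cfg$jump_min, , drop = FALSE]
  tab[, c("size", "chi2")]
}

#' Exhaustive reference miner
#'
#' Enumerates every genotype pattern up to `cfg$max_size` over all SNP
#' subsets (no Apriori pruning beyond the exact zero-support cut) and
#' returns those meeting the SupMaxPair threshold.  Exists as an
#' independent oracle for [mine()]; guarded to at most 20 SNPs.
#'
#' @inheritParams mine
#' @return A `mining_result` (statistics computed per pattern from
#'   first principles via [pattern_stats()]).
#' @export
brute_force_mine <- function(B, labels, cfg) {
  if (length(B$snp_ids) > 20L)
    stop_data("brute_force_mine is a testing oracle; at most 20 SNPs allowed")
  validate_phenotypes(labels)
  bits <- B$bits
  cs <- labels == "case"
  thr <- cfg$threshold; eps <- 1e-9
  snp_of <- B$items$snp_index
  constraint <- build_constraint(B, cfg)
  n_items <- ncol(bits)
  found_items <- list(); found_dir <- character()

  for (direction in cfg$directions) {
    enr <- if (direction == "case-enriched") cs else !cs
    ne <- sum(enr); no <- sum(!enr)
    Xo <- bits[!enr, , drop = FALSE]
    storage.mode(Xo) <- "double"
    PO <- crossprod(Xo) / no   # pair supports in the other class

    rec <- function(idx, pres, mp) {
      last_snp <- snp_of[idx[length(idx)]]
      for (j in seq_len(n_items)) {
        if (snp_of[j] <= last_snp) next
        pres2 <- pres & bits[, j]
        sc <- sum(pres2[enr]) / ne
        if (sc == 0) next  # supersets all have zero enriched support
        mp2 <- max(mp, max(PO[idx, j]))
        idx2 <- c(idx, j)
        if (sc - mp2 >= thr - eps) {
          ok <- is.null(constraint) ||
            length(Reduce(intersect, constraint$item_sets[idx2])) > 0L
          if (ok && length(idx2) >= cfg$min_size_report) {
            found_items[[length(found_items) + 1L]] <<- idx2
            found_dir[[length(found_dir) + 1L]] <<- direction
          }
        }
        if (length(idx2) < cfg$max_size) rec(idx2, pres2, mp2)
      }
    }
    for (i in seq_len(n_items)) rec(i, bits[, i], -Inf)
  }

  if (!length(found_items))
    return(mining_result(NULL, list(), cfg, NULL, mining_config_digest(cfg)))
  tab <- do.call(rbind, Map(function(idx, d)
    pattern_stats(structure(idx, class = "snp_pattern"), B, labels, d),
    found_items, found_dir))
  o <- order(match(tab$direction, cfg$directions), tab$size, tab$pattern)
  mining_result(tab[o, ], found_items[o], cfg, NULL, mining_config_digest(cfg))
}

#' Filter mined patterns by jump
#'
#' Keeps patterns whose jump (chi-square gain over their best proper
#' subset, already computed by [mine()]) reaches `jump_min`.  The
#' filter is recorded in the result's configuration so that
#' [estimate_fdr()] applies the same filter inside every permutation.
#'
#' @param result a `mining_result`.
#' @param jump_min minimum jump retained; `-Inf` is the identity.
#' @param B,labels accepted for recomputation symmetry with the other
#'   operations; unused because `result` already carries jump.
#' @return Filtered `mining_result`.
#' @export
jump_filter <- function(result, jump_min, B = NULL, labels = NULL) {
  stopifnot(inherits(result, "mining_result"))
  keep <- result$jump >= jump_min
  cfg <- attr(result, "config")
  cfg["jump_min"] <- list(if (is.finite(jump_min)) jump_min else NULL)
  out <- as.data.frame(result)[keep, , drop = FALSE]
  mining_result(out, attr(result, "items")[keep], cfg,
                attr(result, "level_counts"), mining_config_digest(cfg))
}
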