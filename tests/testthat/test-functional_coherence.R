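make_patterns <- function(jumps, snp_sets) {
  data.frame(pattern = vapply(snp_sets, function(s)
    paste0(s, ":MM", collapse = ";"), ""), size = lengths(snp_sets),
    jump = jumps)
}

test_that("jump groups partition patterns at the configured bounds", {
  pats <- data.frame(pattern = letters[1:6], jump = c(-10, -5, -1, 0, 5, 14.4))
  g <- group_by_jump(pats, -5, 5)
  expect_equal(g$G_neg$jump, c(-10, -5))       # boundary -5 inclusive below
  expect_equal(g$G_mid$jump, c(-1, 0))
  expect_equal(g$G_pos$jump, c(5, 14.4))       # boundary +5 inclusive above
  expect_equal(nrow(g$G_neg) + nrow(g$G_mid) + nrow(g$G_pos), nrow(pats))
  expect_error(group_by_jump(pats, 5, -5))
})

test_that("within-pattern gene pairs are deduplicated and never self-paired", {
  gm <- c(rs1 = "A", rs2 = "B", rs3 = "C", rs4 = "A", rs5 = "B")
  grp <- make_patterns(c(10, 10, 10),
                       list(c("rs1", "rs2", "rs3"),   # A,B,C -> AB AC BC
                            c("rs1", "rs2"),          # AB again -> dedup
                            c("rs1", "rs4")))         # A,A -> no self pair
  pairs <- within_pattern_pairs(grp, gm)
  expect_equal(nrow(pairs), 3)
  expect_setequal(paste(pairs$geneA, pairs$geneB), c("A B", "A C", "B C"))
  expect_warning(
    within_pattern_pairs(make_patterns(1, list(c("rs1", "rsX"))), gm),
    "without gene mapping")
})

test_that("degree-preserving rewiring keeps pair counts and gene occurrence counts", {
  pairs <- data.frame(geneA = c("A", "C", "A"), geneB = c("B", "D", "C"))
  reps <- coherence_null(pairs, n_rep = 50, seed = 3)
  deg0 <- sort(table(c(pairs$geneA, pairs$geneB)))
  for (r in reps) {
    expect_equal(nrow(r), 3)
    expect_false(any(r$geneA == r$geneB))
    expect_equal(sort(table(c(r$geneA, r$geneB))), deg0)
  }
  # two-pair case: replicates live in the three perfect matchings of
  # the degree sequence, and sampling visits more than one of them
  p2 <- data.frame(geneA = c("A", "C"), geneB = c("B", "D"))
  keys <- vapply(coherence_null(p2, n_rep = 60, seed = 4), function(r)
    paste(sort(paste(r$geneA, r$geneB)), collapse = "/"), "")
  expect_true(all(keys %in% c("A B/C D", "A C/B D", "A D/B C")))
  expect_gt(length(unique(keys)), 1)
  # degree sequence {A:2, B:2} over two pairs admits only a duplicate
  # or self-pair matching -> unrealizable
  expect_error(coherence_null(data.frame(geneA = c("A", "A"),
                                         geneB = c("B", "B")),
                              n_rep = 1, seed = 1, max_tries = 5),
               "rewired")
})

test_that("coherence report recovers planted high-similarity G_pos pairs", {
  genes <- sprintf("g%02d", 1:30)
  gm <- stats::setNames(rep(genes, each = 1), sprintf("rs%02d", 1:30))
  # G_pos patterns over genes g1..g10 (planted coherent); G_mid over
  # g11..g20; G_neg over g21..g30
  snp_of <- stats::setNames(names(gm), gm)
  sets_pos <- lapply(seq(1, 9, 2), function(i) snp_of[genes[c(i, i + 1, (i + 2 - 1) %% 10 + 1)]])
  sets_mid <- lapply(seq(11, 19, 2), function(i) snp_of[genes[c(i, i + 1)]])
  sets_neg <- lapply(seq(21, 29, 2), function(i) snp_of[genes[c(i, i + 1)]])
  pats <- rbind(make_patterns(rep(10, 5), sets_pos),
                make_patterns(rep(0, 5), sets_mid),
                make_patterns(rep(-10, 5), sets_neg))
  planted <- within_pattern_pairs(pats[pats$jump >= 5, ], gm)
  net <- simulate_functional_network(genes, density = 0.05,
                                     planted = planted,
                                     planted_min = 0.8, seed = 6)
  rep <- coherence_report(pats, gm, net, cutoff = 0.5, n_null = 100, seed = 7)
  frac <- stats::setNames(rep$groups$frac_above, rep$groups$group)
  expect_gt(frac[["G_pos"]], frac[["G_mid"]])
  expect_gt(frac[["G_pos"]], frac[["null"]])
  p_pos_null <- rep$tests$p_value[rep$tests$comparison == "G_pos vs null"]
  expect_lt(p_pos_null, 0.01)
})

test_that("rank-sum comparisons: identical groups give p near 1; separated groups are significant", {
  genes <- sprintf("h%02d", 1:42)
  gm <- stats::setNames(genes, sprintf("rx%02d", 1:42))
  snp_of <- stats::setNames(names(gm), gm)
  # 20 all-similar pairs (G_pos) vs 20 never-connected pairs (G_neg)
  sets_pos <- lapply(seq(1, 39, 2), function(i) snp_of[genes[c(i, i + 1)]])
  pats <- rbind(make_patterns(rep(10, 20), sets_pos[1:10]),
                make_patterns(rep(-10, 20), sets_pos[11:20]))
  planted <- within_pattern_pairs(pats[pats$jump >= 5, ], gm)
  net <- simulate_functional_network(genes, density = 0,
                                     planted = planted,
                                     planted_min = 0.9, seed = 8)
  rep <- coherence_report(pats, gm, net, n_null = 50, seed = 9)
  p <- stats::setNames(rep$tests$p_value, rep$tests$comparison)
  expect_lt(p[["G_pos vs G_neg"]], 0.01)
  # identical distributions -> p = 1 up to the normal approximation
  x <- c(0.9, 0.8, 0.7, 0.6, 0.55)
  w <- suppressWarnings(stats::wilcox.test(x, x, exact = FALSE,
                                           correct = FALSE))$p.value
  expect_equal(w, 1)
})

test_that("raising the binarization cutoff never increases any group fraction", {
  genes <- sprintf("k%02d", 1:12)
  gm <- stats::setNames(genes, sprintf("rz%02d", 1:12))
  snp_of <- stats::setNames(names(gm), gm)
  pats <- make_patterns(c(10, 0, -10),
                        list(snp_of[genes[1:3]], snp_of[genes[4:6]],
                             snp_of[genes[7:9]]))
  net <- simulate_functional_network(genes, density = 0.8, seed = 10)
  fr <- sapply(c(0.3, 0.5, 0.7, 0.9), function(cut)
    coherence_report(pats, gm, net, cutoff = cut, n_null = 20,
                     seed = 11)$groups$frac_above)
  for (r in seq_len(nrow(fr)))
    expect_true(all(diff(fr[r, ]) <= 1e-12))
})
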