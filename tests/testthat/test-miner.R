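test_that("mine equals the exhaustive oracle on random instances", {
  for (seed in 1:8) {
    d <- rand_dataset(25, 25, 10, seed = seed)
    B <- encode_binary(d$genotypes)
    cfg <- mining_config(threshold = c(0.1, 0.2, 0.3)[seed %% 3 + 1],
                         max_size = 4)
    r1 <- mine(B, d$labels, cfg)
    r2 <- brute_force_mine(B, d$labels, cfg)
    expect_same_patterns(r1, r2)
    # statistics agree on the shared set
    m <- match(paste(r2$pattern, r2$direction), paste(r1$pattern, r1$direction))
    expect_equal(r1$chi2[m], r2$chi2, tolerance = 1e-9)
    expect_equal(r1$supmaxpair[m], r2$supmaxpair, tolerance = 1e-9)
    expect_equal(r1$jump[m], r2$jump, tolerance = 1e-9)
    expect_equal(r1$fisher_p[m], r2$fisher_p, tolerance = 1e-9)
    expect_equal(r1$odds_ratio[m], r2$odds_ratio, tolerance = 1e-9)
  }
})

test_that("an embedded pattern with strong frequency differential is reported", {
  ep <- embedded_pattern_spec(1:4, f_case = 0.45, f_ctrl = 0.05)
  d <- rand_dataset(40, 40, 12, seed = 3, embedded = list(ep))
  B <- encode_binary(d$genotypes)
  r <- mine(B, d$labels, mining_config(0.15, max_size = 4))
  expect_true(d$truth$pattern %in% r$pattern)
  r2 <- brute_force_mine(B, d$labels, mining_config(0.15, max_size = 4))
  expect_same_patterns(r, r2)
})

test_that("unattainable thresholds give empty results and raising the threshold never adds patterns", {
  d <- rand_dataset(20, 20, 8, seed = 4)
  B <- encode_binary(d$genotypes)
  expect_equal(nrow(mine(B, d$labels, mining_config(1.0, max_size = 3))), 0)
  r_lo <- mine(B, d$labels, mining_config(0.15, max_size = 3))
  r_hi <- mine(B, d$labels, mining_config(0.3, max_size = 3))
  expect_true(all(paste(r_hi$pattern, r_hi$direction) %in%
                    paste(r_lo$pattern, r_lo$direction)))
})

test_that("every reported pattern has support >= threshold in its enriched class", {
  d <- rand_dataset(30, 30, 15, seed = 6)
  B <- encode_binary(d$genotypes)
  r <- mine(B, d$labels, mining_config(0.2, max_size = 4))
  enriched_supp <- ifelse(r$direction == "case-enriched", r$supp_case, r$supp_ctrl)
  expect_true(all(enriched_supp >= 0.2 - 1e-9))
  # no pattern joins two genotypes of the same SNP
  snps <- lapply(strsplit(r$pattern, ";"), function(x) sub(":.*", "", x))
  expect_true(all(vapply(snps, anyDuplicated, 0L) == 0))
})

test_that("mining output is deterministic and ordered by direction, size, item order", {
  d <- rand_dataset(25, 25, 10, seed = 9)
  B <- encode_binary(d$genotypes)
  cfg <- mining_config(0.2, max_size = 4)
  r1 <- mine(B, d$labels, cfg)
  r2 <- mine(B, d$labels, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  dir_rank <- match(r1$direction, c("case-enriched", "control-enriched"))
  expect_true(!is.unsorted(dir_rank))
  for (s in split(r1$size, dir_rank)) expect_true(!is.unsorted(s))
})

test_that("gene-set constraints prune exactly the non-contained candidates", {
  d <- rand_dataset(30, 30, 8, seed = 12)
  B <- encode_binary(d$genotypes)
  gm <- stats::setNames(c("A", "B", "C", "D", "A", "B", "C", "D"), B$snp_ids)
  gs <- list(s1 = c("A", "B", "C"), s2 = c("C", "D"))
  # standalone predicate
  keep <- apply_geneset_constraint(
    list(pattern(B, B$snp_ids[c(1, 2)], c("MM", "MM")),   # A,B in s1
         pattern(B, B$snp_ids[c(2, 4)], c("MM", "MM"))),  # B,D in no set
    B, gm, gs)
  expect_length(keep, 1)
  # constrained mining is a subset of unconstrained, and equals the
  # oracle under the same constraint
  cfg_u <- mining_config(0.15, max_size = 3)
  cfg_c <- mining_config(0.15, max_size = 3, gene_map = gm, gene_sets = gs)
  r_u <- mine(B, d$labels, cfg_u)
  r_c <- mine(B, d$labels, cfg_c)
  expect_true(all(paste(r_c$pattern, r_c$direction) %in%
                    paste(r_u$pattern, r_u$direction)))
  expect_same_patterns(r_c, brute_force_mine(B, d$labels, cfg_c))
  genes_of <- function(p) unname(gm[vapply(strsplit(p, ";")[[1]],
                                           function(x) sub(":.*", "", x), "")])
  ok <- vapply(r_c$pattern, function(p)
    any(vapply(gs, function(s) all(genes_of(p) %in% s), NA)), NA)
  expect_true(all(ok))
})

test_that("jump_filter thresholds, is idempotent, and records itself in the config", {
  d <- rand_dataset(30, 30, 10, seed = 13)
  B <- encode_binary(d$genotypes)
  r <- mine(B, d$labels, mining_config(0.15, max_size = 3))
  f5 <- jump_filter(r, 5)
  expect_true(all(f5$jump >= 5))
  expect_gte(nrow(r), nrow(f5))
  expect_identical(as.data.frame(jump_filter(f5, 5)), as.data.frame(f5))
  expect_identical(as.data.frame(jump_filter(r, -Inf)), as.data.frame(r))
  expect_equal(attr(f5, "config")$jump_min, 5)
  expect_false(identical(attr(f5, "config_digest"), attr(r, "config_digest")))
})

test_that("the candidate budget guard aborts with an actionable error", {
  d <- rand_dataset(30, 30, 30, seed = 14)
  B <- encode_binary(d$genotypes)
  expect_error(mine(B, d$labels, mining_config(0.05, candidate_budget = 50)),
               class = "snpcombine_budget_error")
})

test_that("the oracle itself enumerates the full genotype-pair space on 2 SNPs", {
  # cases cover all nine genotype pairs; controls carry no genotype at
  # all (missing), so every present pair qualifies at a low threshold
  V <- as.matrix(expand.grid(0:2, 0:2))
  V <- V[rep(1:9, 2), ]
  V2 <- rbind(V, matrix(NA_integer_, 6, 2))
  dimnames(V2) <- list(sprintf("s%02d", 1:24), c("rs1", "rs2"))
  labels <- factor(rep(c("case", "control"), c(18, 6)),
                   levels = c("case", "control"))
  names(labels) <- rownames(V2)
  B <- encode_binary(genotype_matrix(V2))
  r <- brute_force_mine(B, labels, mining_config(0.05, max_size = 2,
                                                 directions = "case-enriched"))
  expect_equal(nrow(r), 9)
  expect_equal(sort(r$pattern),
               sort(apply(expand.grid(c("mm", "Mm", "MM"),
                                      c("mm", "Mm", "MM")), 1,
                          function(g) paste0("rs1:", g[1], ";rs2:", g[2]))))
})
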