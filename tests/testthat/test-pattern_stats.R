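test_that("support counts pattern presence per group", {
  h <- handmade_dataset()
  B <- encode_binary(h$G)
  P <- pattern(B, c("rs1", "rs2", "rs3"), c("mm", "mm", "mm"))
  expect_equal(support(P, B, h$labels == "case"), 0.4)
  expect_equal(support(P, B, h$labels == "control"), 0)
  p1 <- pattern(B, "rs1", "mm")
  expect_equal(support(p1, B, seq_len(40)), mean(B$bits[, p1]))
  expect_error(support(P, B, integer()), "empty")
  # conjunction anti-monotonicity on the same data
  expect_lte(support(P, B, h$labels == "case"),
             support(pattern(B, c("rs1", "rs2"), c("mm", "mm")), B,
                     h$labels == "case"))
})

test_that("SupMaxPair matches its definition on a hand-computed dataset", {
  h <- handmade_dataset()
  B <- encode_binary(h$G)
  P3 <- pattern(B, c("rs1", "rs2", "rs3"), c("mm", "mm", "mm"))
  # supp_case 0.4; pair control supports {0.10, 0.25, 0.20} -> 0.4 - 0.25
  expect_equal(supmaxpair(P3, B, h$labels), 0.15)
  P2 <- pattern(B, c("rs1", "rs2"), c("mm", "mm"))
  expect_equal(supmaxpair(P2, B, h$labels),
               support(P2, B, h$labels == "case") -
                 support(P2, B, h$labels == "control"))
  # control-enriched direction mirrors exactly under label swap
  swapped <- factor(ifelse(h$labels == "case", "control", "case"),
                    levels = c("case", "control"))
  expect_equal(supmaxpair(P3, B, swapped, "control-enriched"),
               supmaxpair(P3, B, h$labels, "case-enriched"))
  expect_error(supmaxpair(pattern(B, "rs1", "mm"), B, h$labels), "size >= 2")
})

test_that("contingency tables conserve margins", {
  h <- handmade_dataset()
  B <- encode_binary(h$G)
  P <- pattern(B, c("rs1", "rs2", "rs3"), c("mm", "mm", "mm"))
  tab <- contingency(P, B, h$labels)
  expect_equal(unname(tab), c(8, 0, 12, 20))
  expect_equal(sum(tab), 40)
  P4 <- pattern(B, "rs4", "mm")   # absent everywhere
  expect_equal(unname(contingency(P4, B, h$labels)), c(0, 0, 20, 20))
})

test_that("chi-square df=1 closed form matches stats::chisq.test and handles degeneracy", {
  expect_equal(chi2_df1(c(35, 5, 5, 35))$statistic, 45)
  expect_equal(chi2_df1(c(20, 20, 20, 20))$statistic, 0)
  expect_equal(chi2_df1(c(20, 20, 20, 20))$p_value, 1)
  expect_equal(chi2_df1(c(0, 0, 30, 40))$statistic, 0)  # zero row margin
  # invariance under simultaneous row and column swap
  expect_equal(chi2_df1(c(35, 5, 5, 35))$statistic,
               chi2_df1(c(35, 5, 5, 35)[c(4, 3, 2, 1)])$statistic)
  set.seed(7)
  for (i in 1:1000) {
    tab <- rpois(4, 12) + c(1, 0, 1, 0)
    m <- matrix(tab, 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    got <- chi2_df1(c(m[1, 1], m[1, 2], m[2, 1], m[2, 2]))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(unname(ref$parameter), 1)
  }
})

test_that("odds ratio applies the Haldane-Anscombe correction on zero cells", {
  expect_equal(odds_ratio_2x2(c(35, 5, 5, 35))$odds_ratio, 49)
  expect_false(odds_ratio_2x2(c(35, 5, 5, 35))$corrected)
  expect_equal(odds_ratio_2x2(c(20, 20, 20, 20))$odds_ratio, 1)
  res <- odds_ratio_2x2(c(10, 0, 60, 70))
  expect_true(res$corrected)
  expect_equal(res$odds_ratio, (10.5 * 70.5) / (0.5 * 60.5))
})

test_that("Fisher exact p matches stats::fisher.test and behaves monotonically", {
  expect_equal(fisher_exact_2x2(c(20, 20, 20, 20)), 1)
  set.seed(11)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    a <- rmultinom(1, n, rep(0.25, 4))
    ref <- stats::fisher.test(matrix(a, 2, byrow = TRUE))$p.value
    expect_equal(fisher_exact_2x2(a), ref, tolerance = 1e-9)
  }
  # p decreases as (35,5,5,35) is made more extreme towards (40,0,0,40)
  ps <- vapply(0:5, function(k) fisher_exact_2x2(c(35 + k, 5 - k, 5 - k, 35 + k)), 0)
  expect_true(all(diff(ps) < 0))
})

test_that("jump equals an independent exhaustive subset re-enumeration", {
  d <- rand_dataset(30, 30, 8, seed = 5)
  B <- encode_binary(d$genotypes)
  set.seed(5)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    snps <- sample(B$snp_ids, k)
    gts <- sample(c("mm", "Mm", "MM"), k, replace = TRUE)
    P <- pattern(B, snps, gts)
    j <- jump_stat(P, B, d$labels)
    expect_equal(j, oracle_jump(as.integer(P), B, d$labels), tolerance = 1e-9)
    expect_lte(j, snpcombine:::chi2_of_items(P, B, d$labels) + 1e-12)
  }
  expect_error(jump_stat(pattern(B, B$snp_ids[1], "mm"), B, d$labels),
               "size >= 2")
})

test_that("anti-monotonicity of support and SupMaxPair on random pattern/superset draws", {
  d <- rand_dataset(30, 30, 12, seed = 8)
  B <- encode_binary(d$genotypes)
  cases <- d$labels == "case"
  set.seed(8)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    snps <- sample(B$snp_ids, k + 1)
    gts <- sample(c("mm", "Mm", "MM"), k + 1, replace = TRUE)
    P <- pattern(B, snps[1:k], gts[1:k])
    Psup <- pattern(B, snps, gts)
    expect_lte(support(Psup, B, cases), support(P, B, cases))
    expect_lte(supmaxpair(Psup, B, d$labels), supmaxpair(P, B, d$labels) + 1e-12)
  }
})
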