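# Shared fixture builders; everything is generated in code.

# Tiny hand-written genotype matrix with one missing cell.
tiny_geno <- function() {
  genotype_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2,
                         dimnames = list(c("s1", "s2"), c("rs1", "rs2"))),
                  chrom = c("1", "2"))
}

# Random HWE dataset (optionally with embedded patterns) plus labels.
rand_dataset <- function(n_case = 25, n_ctrl = 25, n_snps = 10, seed = 1,
                         embedded = list()) {
  simulate_dataset(synthetic_spec(n_case, n_ctrl, n_snps,
                                  embedded = embedded, seed = seed))
}

# Deterministic dataset where the pattern rs1:mm;rs2:mm;rs3:mm has
# case support 8/20 = 0.4 and its three pairs have control supports
# 2/20, 5/20 and 4/20 (max 0.25), so SupMaxPair = 0.15 exactly.
handmade_dataset <- function() {
  V <- matrix(0L, 40, 4, dimnames = list(sprintf("s%02d", 1:40),
                                         c("rs1", "rs2", "rs3", "rs4")))
  V[1:8, 1:3] <- 2L                # cases 1-8 carry the full triple
  V[21:22, c(1, 2)] <- 2L          # controls: rs1+rs2 pair only
  V[23:27, c(1, 3)] <- 2L          # controls: rs1+rs3 pair only
  V[28:31, c(2, 3)] <- 2L          # controls: rs2+rs3 pair only
  labels <- factor(rep(c("case", "control"), each = 20),
                   levels = c("case", "control"))
  names(labels) <- rownames(V)
  list(G = genotype_matrix(V), labels = labels)
}

# Independent chi-square for a pattern, written from scratch on top of
# stats::chisq.test (oracle for jump re-enumeration).
oracle_chi2 <- function(pres, labels) {
  tab <- table(factor(pres, levels = c(TRUE, FALSE)), labels)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(0)
  unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
}

# Oracle jump: exhaustive subset re-enumeration independent of the
# package internals (works on raw bit columns).
oracle_jump <- function(idx, B, labels) {
  pres_of <- function(ix) Reduce(`&`, lapply(ix, function(j) B$bits[, j]))
  own <- oracle_chi2(pres_of(idx), labels)
  best <- -Inf
  for (k in seq_len(length(idx) - 1)) {
    cmb <- utils::combn(idx, k)
    for (cc in seq_len(ncol(cmb)))
      best <- max(best, oracle_chi2(pres_of(cmb[, cc]), labels))
  }
  own - best
}

expect_same_patterns <- function(r1, r2) {
  expect_setequal(paste(r1$pattern, r1$direction),
                  paste(r2$pattern, r2$direction))
}
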