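#' Specification of a synthetic case-control SNP dataset
#'
#' Describes a background of independent SNPs in Hardy-Weinberg
#' equilibrium (identically distributed in cases and controls, so the
#' background carries no disease-associated loci) plus a list of
#' embedded high-order patterns with target presence fractions in each
#' class.
#'
#' @param n_case,n_ctrl group sizes.
#' @param n_snps number of SNPs.
#' @param maf_range minor-allele-frequency interval for background
#'   SNPs, sampled uniformly per SNP.
#' @param embedded list of embedded pattern specifications from
#'   [embedded_pattern_spec()]; may be empty for pure-noise data.
#' @param embedded_maf fixed MAF given to the SNPs that carry an
#'   embedded item, so the embedded genotypes stay rare in the
#'   background (default 0.2; with the default `mm` items the
#'   background genotype frequency is 0.04).
#' @param seed integer seed; the whole dataset is deterministic in it.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_case, n_ctrl, n_snps,
                           maf_range = c(0.05, 0.5),
                           embedded = list(), embedded_maf = 0.2,
                           seed = 1L) {
  stopifnot(n_case >= 1, n_ctrl >= 1, n_snps >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  for (ep in embedded) {
    if (max(ep$snp_index) > n_snps)
      stop_data("embedded pattern uses SNP index %d beyond n_snps = %d",
                max(ep$snp_index), n_snps)
  }
  structure(list(n_case = as.integer(n_case), n_ctrl = as.integer(n_ctrl),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 embedded = embedded, embedded_maf = embedded_maf,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' One embedded ground-truth pattern
#'
#' @param snp_index integer vector of distinct SNP indices (size 2-8).
#' @param genotype genotype codes of the items (recycled; default
#'   `"mm"`, the minor homozygote, keeping the pattern rare in the
#'   background).
#' @param f_case,f_ctrl target presence fractions; one must strictly
#'   exceed the other.
#' @return Object of class `embedded_pattern_spec`.
#' @export
embedded_pattern_spec <- function(snp_index, genotype = "mm",
                                  f_case, f_ctrl) {
  snp_index <- as.integer(snp_index)
  stopifnot(length(snp_index) >= 2, length(snp_index) <= 8,
            !anyDuplicated(snp_index),
            f_case >= 0, f_case <= 1, f_ctrl >= 0, f_ctrl <= 1,
            f_case != f_ctrl)
  genotype <- rep_len(genotype, length(snp_index))
  stopifnot(all(genotype %in% GENOTYPE_CODES))
  structure(list(snp_index = snp_index, genotype = genotype,
                 f_case = f_case, f_ctrl = f_ctrl),
            class = "embedded_pattern_spec")
}

# genotype code -> dosage
dosage_of <- function(code) c(mm = 2L, Mm = 1L, MM = 0L)[code]

#' Simulate the Hardy-Weinberg background
#'
#' Each SNP gets a MAF drawn uniformly from `maf_range` (embedded SNPs
#' get the fixed `embedded_maf`), and genotypes are drawn i.i.d. per
#' sample with P(mm) = p^2, P(Mm) = 2p(1-p), P(MM) = (1-p)^2 --
#' identically in cases and controls, so the background alone contains
#' no association.
#'
#' @param spec a [synthetic_spec()].
#' @return A [genotype_matrix()] with `n_case + n_ctrl` rows (cases
#'   first); the per-SNP MAFs are attached as attribute `maf`.
#' @export
simulate_background <- function(spec) {
  n <- spec$n_case + spec$n_ctrl
  S <- spec$n_snps
  with_seed(spec$seed, {
    maf <- stats::runif(S, spec$maf_range[1], spec$maf_range[2])
    emb_snps <- unique(unlist(lapply(spec$embedded, `[[`, "snp_index")))
    maf[emb_snps] <- spec$embedded_maf
    u <- matrix(stats::runif(n * S), n, S)
    p2 <- matrix(maf^2, n, S, byrow = TRUE)
    het <- matrix(2 * maf * (1 - maf), n, S, byrow = TRUE)
    V <- (u < p2) * 2L + (u >= p2 & u < p2 + het) * 1L
    G <- genotype_matrix(V,
                         sample_ids = sprintf("S%05d", seq_len(n)),
                         snp_ids = sprintf("snp%05d", seq_len(S)),
                         chrom = rep("1", S))
    attr(G, "maf") <- maf
    G
  })
}

#' Embed a ground-truth pattern into a genotype matrix
#'
#' Overwrites the pattern genotypes in `round(f_case * n_case)` random
#' cases and `round(f_ctrl * n_ctrl)` random controls (nearest integer,
#' ties upward), then perturbs one uniformly chosen pattern SNP to a
#' different genotype in every remaining sample that matches the full
#' pattern by chance -- so the realized presence count is exact.  The
#' number of perturbed samples is attached as attribute
#' `n_perturbed`.  Uses the current RNG stream.
#'
#' @param G a [genotype_matrix()].
#' @param labels case/control factor aligned to the rows of `G`.
#' @param ep an [embedded_pattern_spec()].
#' @param seed optional seed for a standalone reproducible call.
#' @return Modified [genotype_matrix()].
#' @export
embed_pattern <- function(G, labels, ep, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, embed_pattern(G, labels, ep)))
  validate_phenotypes(labels)
  V <- unclass(G)
  snps <- ep$snp_index
  dos <- dosage_of(ep$genotype)
  case_idx <- which(labels == "case"); ctrl_idx <- which(labels == "control")
  t_case <- round_half_up(ep$f_case * length(case_idx))
  t_ctrl <- round_half_up(ep$f_ctrl * length(ctrl_idx))
  if (t_case > length(case_idx) || t_ctrl > length(ctrl_idx))
    stop_data("target presence count exceeds group size")
  sel <- c(if (t_case > 0) sample(case_idx, t_case),
           if (t_ctrl > 0) sample(ctrl_idx, t_ctrl))
  V[sel, snps] <- matrix(dos, length(sel), length(snps), byrow = TRUE)
  # exact-presence cleanup: break accidental background matches
  rest <- setdiff(seq_len(nrow(V)), sel)
  match_full <- rest[rowSums(
    V[rest, snps, drop = FALSE] ==
      matrix(dos, length(rest), length(snps), byrow = TRUE),
    na.rm = TRUE) == length(snps) &
      !apply(is.na(V[rest, snps, drop = FALSE]), 1L, any)]
  for (r in match_full) {
    j <- if (length(snps) == 1L) snps else sample(snps, 1L)
    V[r, j] <- sample(setdiff(0:2, V[r, j]), 1L)
  }
  out <- genotype_matrix(V, chrom = snp_chrom(G))
  attr(out, "maf") <- attr(G, "maf")
  attr(out, "n_perturbed") <- length(match_full)
  out
}

#' Simulate a full case-control dataset with embedded patterns
#'
#' Background plus all embeddings plus a ground-truth table recording,
#' per embedded pattern, the realized class frequencies and the
#' realized SupMaxPair (case-enriched).
#'
#' @param spec a [synthetic_spec()], e.g. from [synthetic_preset()].
#' @return List with `genotypes` ([genotype_matrix()]), `labels`
#'   (factor, cases first) and `truth` (data frame: `pattern`, `size`,
#'   `f_case_target`, `f_ctrl_target`, `f_case`, `f_ctrl`,
#'   `supmaxpair`, `chi2`, `n_perturbed`).
#' @export
simulate_dataset <- function(spec) {
  G <- simulate_background(spec)
  labels <- factor(rep(c("case", "control"), c(spec$n_case, spec$n_ctrl)),
                   levels = c("case", "control"))
  names(labels) <- rownames(G)
  n_pert <- integer(length(spec$embedded))
  with_seed(spec$seed + 1L, {
    for (i in seq_along(spec$embedded)) {
      G <- embed_pattern(G, labels, spec$embedded[[i]])
      n_pert[i] <- attr(G, "n_perturbed")
    }
  })
  B <- encode_binary(G)
  truth <- do.call(rbind, lapply(seq_along(spec$embedded), function(i) {
    ep <- spec$embedded[[i]]
    P <- pattern(B, B$snp_ids[ep$snp_index], ep$genotype)
    data.frame(
      pattern = pattern_string(B, P),
      size = length(P),
      f_case_target = ep$f_case, f_ctrl_target = ep$f_ctrl,
      f_case = support(P, B, labels == "case"),
      f_ctrl = support(P, B, labels == "control"),
      supmaxpair = supmaxpair(P, B, labels, "case-enriched"),
      chi2 = chi2_of_items(P, B, labels),
      n_perturbed = n_pert[i])
  }))
  if (is.null(truth))
    truth <- data.frame(pattern = character(), size = integer(),
                        f_case_target = numeric(), f_ctrl_target = numeric(),
                        f_case = numeric(), f_ctrl = numeric(),
                        supmaxpair = numeric(), chi2 = numeric(),
                        n_perturbed = integer())
  list(genotypes = G, labels = labels, truth = truth)
}

# The four stock embedded patterns of sizes 3-6 on disjoint SNP blocks.
# Class frequencies decrease with size; every overall frequency stays
# below 0.25 and the construction keeps SupMaxPair >= 0.15 with margin.
default_embedded <- function() {
  f_case <- c(0.40, 0.35, 0.30, 0.25)
  sizes <- 3:6
  start <- cumsum(c(1L, sizes[-4L]))
  Map(function(sz, st, fc)
    embedded_pattern_spec(snp_index = st:(st + sz - 1L),
                          genotype = "mm", f_case = fc, f_ctrl = 0.05),
    sizes, start, f_case)
}

#' Standard synthetic presets
#'
#' `"paper"` is the 70-case / 70-control, 2172-SNP dataset with four
#' embedded patterns of sizes 3-6; the `"nXXX"` presets scale the total
#' sample size (cases and controls combined, split equally) through
#' 140-5600 while keeping the per-class pattern frequencies fixed.
#'
#' @param preset one of `"paper"` (140 samples), `"n140"`, `"n280"`,
#'   `"n420"`, `"n560"`, `"n1400"`, `"n2800"`, `"n5600"`.
#' @param n_snps number of SNPs (default 2172).
#' @param seed integer seed.
#' @return A [synthetic_spec()].
#' @export
synthetic_preset <- function(preset = "paper", n_snps = 2172L, seed = 1L) {
  sizes <- c(paper = 140L, n140 = 140L, n280 = 280L, n420 = 420L,
             n560 = 560L, n1400 = 1400L, n2800 = 2800L, n5600 = 5600L)
  preset <- match.arg(preset, names(sizes))
  n <- sizes[[preset]]
  synthetic_spec(n_case = n %/% 2L, n_ctrl = n %/% 2L, n_snps = n_snps,
                 embedded = default_embedded(), seed = seed)
}
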