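#' Lossless three-column binary encoding of genotypes
#'
#' Each SNP expands into three boolean item columns, one per genotype
#' (`mm`, `Mm`, `MM` in that fixed order), and a sample sets the column
#' matching its genotype: dosage 2 -> (1,0,0), 1 -> (0,1,0),
#' 0 -> (0,0,1).  A missing genotype leaves all three columns 0, so any
#' pattern touching that SNP is counted absent in that sample.  With no
#' missing values exactly one third of all bits are 1.  The item order
#' (SNP file order, then `mm < Mm < MM`) is the global total order used
#' for deterministic candidate generation throughout the package.
#'
#' @param G a [genotype_matrix()].
#' @return An object of class `binary_item_matrix`: a list with
#'   `bits` (samples x 3*SNPs logical matrix) and `items` (data frame
#'   with `snp_id`, `genotype`, `snp_index`).
#' @export
encode_binary <- function(G) {
  V <- unclass(G)
  n <- nrow(V); S <- ncol(V)
  bits <- matrix(FALSE, n, 3L * S)
  # dosage 2 = mm is column 1 of each SNP triple, 1 = Mm column 2, 0 = MM column 3
  off <- 3L * (seq_len(S) - 1L)
  for (g in 0:2) {
    col <- off + (3L - g)  # g=2 -> +1 (mm), g=1 -> +2 (Mm), g=0 -> +3 (MM)
    hit <- !is.na(V) & V == g
    bits[, col][hit] <- TRUE
  }
  items <- data.frame(
    snp_id = rep(colnames(V), each = 3L),
    genotype = rep(GENOTYPE_CODES, S),
    snp_index = rep(seq_len(S), each = 3L),
    stringsAsFactors = FALSE)
  rownames(bits) <- rownames(V)
  colnames(bits) <- paste(items$snp_id, items$genotype, sep = ":")
  structure(list(bits = bits, items = items, snp_ids = colnames(V),
                 sample_ids = rownames(V)),
            class = "binary_item_matrix")
}

#' @export
print.binary_item_matrix <- function(x, ...) {
  cat(sprintf("binary_item_matrix: %d samples x %d items (%d SNPs), density %.3f\n",
              nrow(x$bits), ncol(x$bits), length(x$snp_ids), mean(x$bits)))
  invisible(x)
}

#' Decode a binary item matrix back to genotypes
#'
#' Inverse of [encode_binary()]; an all-zero triple decodes to `NA`.
#'
#' @param B a `binary_item_matrix`.
#' @return A [genotype_matrix()].
#' @export
decode_binary <- function(B) {
  n <- nrow(B$bits); S <- length(B$snp_ids)
  V <- matrix(NA_integer_, n, S, dimnames = list(B$sample_ids, B$snp_ids))
  off <- 3L * (seq_len(S) - 1L)
  for (g in 0:2) {
    col <- off + (3L - g)
    V[B$bits[, col, drop = FALSE]] <- g
  }
  genotype_matrix(V)
}

# Map (snp_id, genotype) pairs to item column indices; errors on unknown.
item_index <- function(B, snp_ids, genotypes) {
  si <- match(snp_ids, B$snp_ids)
  if (anyNA(si)) stop_data("unknown SNP '%s'", snp_ids[which(is.na(si))[1L]])
  gi <- match(genotypes, GENOTYPE_CODES)
  if (anyNA(gi)) stop_data("unknown genotype code '%s' (use mm, Mm, MM)",
                           genotypes[which(is.na(gi))[1L]])
  3L * (si - 1L) + gi
}

item_snp_index <- function(B, idx) B$items$snp_index[idx]

# Canonical pattern string "snp:gt;snp:gt" for a sorted item index vector.
pattern_string <- function(B, idx) {
  paste(B$items$snp_id[idx], B$items$genotype[idx], sep = ":", collapse = ";")
}

#' Build a pattern from SNP/genotype pairs
#'
#' A pattern is a conjunction of genotype items at distinct SNPs; it is
#' present in a sample iff all its items are set in the binary
#' encoding.  Items are stored sorted by the global item order.
#'
#' @param B a `binary_item_matrix`.
#' @param snp_ids character vector of SNP IDs.
#' @param genotypes parallel vector of genotype codes (`mm`/`Mm`/`MM`).
#' @return Integer vector of item column indices (class `snp_pattern`).
#' @export
pattern <- function(B, snp_ids, genotypes) {
  idx <- sort(item_index(B, snp_ids, genotypes))
  if (anyDuplicated(item_snp_index(B, idx)))
    stop_data("pattern items must come from distinct SNPs")
  if (!length(idx)) stop_data("empty pattern")
  structure(idx, class = "snp_pattern")
}

#' Parse a pattern string
#'
#' Inverse of the `pattern` column in result tables:
#' `"rs1:mm;rs7:MM"` -> item indices.
#'
#' @inheritParams pattern
#' @param x pattern string, items separated by `;`, SNP and genotype by
#'   `:`.
#' @export
parse_pattern <- function(B, x) {
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  pattern(B, vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L))
}

# Presence vector of an item set (logical over all samples).
pattern_presence <- function(B, idx) {
  if (length(idx) == 1L) return(B$bits[, idx])
  out <- B$bits[, idx[1L]]
  for (j in idx[-1L]) out <- out & B$bits[, j]
  out
}
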