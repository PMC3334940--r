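#' Construct a genotype matrix
#'
#' A `genotype_matrix` is an integer matrix of minor-allele dosages with
#' samples as rows and SNPs as columns.  Coding: 0 = homozygous major
#' (MM), 1 = heterozygous (Mm), 2 = homozygous minor (mm); `NA` marks a
#' missing genotype.  An optional per-SNP chromosome label supports
#' autosome filtering in [qc_filter()].
#'
#' @param values integer matrix (samples x SNPs) with entries in
#'   \{0, 1, 2, NA\}.
#' @param sample_ids,snp_ids unique row/column identifiers; defaults
#'   taken from `dimnames(values)`.
#' @param chrom optional character vector of chromosome labels, one per
#'   SNP (e.g. `"1"`, `"X"`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, sample_ids = rownames(values),
                            snp_ids = colnames(values), chrom = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids) || is.null(snp_ids))
    stop_data("genotype_matrix needs sample and SNP identifiers")
  if (nrow(values) == 0L) stop_data("no samples")
  if (ncol(values) == 0L) stop_data("no SNPs")
  if (anyDuplicated(sample_ids)) stop_data("duplicate sample IDs")
  if (anyDuplicated(snp_ids)) stop_data("duplicate SNP IDs")
  storage.mode(values) <- "integer"
  bad <- !is.na(values) & !(values %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_data("invalid genotype value at sample '%s', SNP '%s' (must be 0, 1, 2 or NA)",
              sample_ids[idx[1L]], snp_ids[idx[2L]])
  }
  if (!is.null(chrom) && length(chrom) != ncol(values))
    stop_data("chrom must have one label per SNP")
  dimnames(values) <- list(sample_ids, snp_ids)
  attr(values, "chrom") <- if (is.null(chrom)) NULL else as.character(chrom)
  class(values) <- c("genotype_matrix", "matrix", "array")
  values
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d missing, %.1f%%)\n",
              nrow(x), ncol(x), sum(is.na(x)),
              100 * mean(is.na(x))))
  invisible(x)
}

snp_chrom <- function(G) attr(G, "chrom")

#' Read a genotype dosage table
#'
#' Expects a TSV with a header row of SNP IDs, the first column holding
#' sample IDs, and cells in \{0, 1, 2, NA\} (minor-allele dosage).  An
#' optional special row with sample ID `#chrom` supplies per-SNP
#' chromosome labels (the row written by [write_genotypes()] when the
#' matrix carries them).
#'
#' @param path file path.
#' @param dialect currently only `"tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = "tsv") {
  dialect <- match.arg(dialect, "tsv")
  if (!file.exists(path)) stop_data("genotype file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", comment.char = "")
  if (ncol(raw) < 2L) stop_data("no SNP columns in %s", path)
  ids <- raw[[1L]]
  chrom <- NULL
  chrow <- which(ids == "#chrom")
  if (length(chrow)) {
    chrom <- as.character(raw[chrow[1L], -1L])
    raw <- raw[-chrow, , drop = FALSE]
    ids <- raw[[1L]]
  }
  if (nrow(raw) == 0L) stop_data("no samples in %s", path)
  snp_ids <- colnames(raw)[-1L]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  ok <- is.na(vals) | vals %in% c("0", "1", "2", "NA", "")
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1L, ]
    stop_data("malformed genotype '%s' at sample '%s', SNP '%s' in %s",
              vals[idx[1L], idx[2L]], ids[idx[1L]], snp_ids[idx[2L]], path)
  }
  vals[vals %in% c("NA", "")] <- NA
  storage.mode(vals) <- "integer"
  genotype_matrix(vals, sample_ids = ids, snp_ids = snp_ids, chrom = chrom)
}

#' Write a genotype dosage table
#'
#' Inverse of [read_genotypes()]; `read_genotypes(write_genotypes(G))`
#' reproduces `G` exactly, including chromosome labels.
#'
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  df <- as.data.frame(unclass(G), check.names = FALSE)
  df <- cbind(sample_id = rownames(G), df)
  if (!is.null(snp_chrom(G)))
    df <- rbind(c("#chrom", snp_chrom(G)), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write case/control phenotype labels
#'
#' Two-column TSV (`sample_id`, `label`) with labels in
#' \{`case`, `control`\}.  The returned factor is aligned to
#' `sample_ids` when given.
#'
#' @param path file path.
#' @param sample_ids optional sample ordering to align to.
#' @return Named factor with levels `case`, `control`.
#' @export
read_phenotypes <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop_data("phenotype file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 2L) stop_data("phenotype file needs sample_id and label columns")
  labs <- df[[2L]]
  bad <- !labs %in% c("case", "control")
  if (any(bad))
    stop_data("invalid phenotype label '%s' for sample '%s'",
              labs[which(bad)[1L]], df[[1L]][which(bad)[1L]])
  ph <- factor(labs, levels = c("case", "control"))
  names(ph) <- df[[1L]]
  if (!is.null(sample_ids)) {
    if (!all(sample_ids %in% names(ph)))
      stop_data("phenotype file is missing %d sample(s)",
                sum(!sample_ids %in% names(ph)))
    ph <- ph[sample_ids]
  }
  validate_phenotypes(ph)
  ph
}

#' @rdname read_phenotypes
#' @param labels named factor as returned by `read_phenotypes()`.
#' @export
write_phenotypes <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_phenotypes <- function(labels) {
  if (!all(levels(labels) == c("case", "control")))
    stop_data("phenotype labels must be a factor with levels case, control")
  if (any(is.na(labels))) stop_data("missing phenotype labels")
  n <- table(labels)
  if (n[["case"]] == 0L || n[["control"]] == 0L)
    stop_data("need at least one case and one control")
  invisible(labels)
}

#' QC filter on SNPs
#'
#' Drops every SNP whose missing fraction strictly exceeds
#' `max_missing_frac` (a SNP with exactly the threshold fraction is
#' kept), and optionally all non-autosomal SNPs (chromosome labels
#' `X`, `Y`, `MT`/`M`, case-insensitive, with or without a `chr`
#' prefix).  Survivor order is preserved; the filter is idempotent.
#'
#' @param G a [genotype_matrix()].
#' @param max_missing_frac maximum tolerated missing fraction per SNP
#'   (default 0.05).
#' @param autosomes_only if `TRUE`, drop sex and mitochondrial SNPs
#'   (requires chromosome labels on `G`).
#' @return Filtered [genotype_matrix()].
#' @export
qc_filter <- function(G, max_missing_frac = 0.05, autosomes_only = FALSE) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  keep <- colMeans(is.na(unclass(G))) <= max_missing_frac
  if (autosomes_only) {
    ch <- snp_chrom(G)
    if (is.null(ch))
      stop_data("autosomes_only requires chromosome labels")
    sex <- toupper(sub("^chr", "", ch, ignore.case = TRUE)) %in% c("X", "Y", "MT", "M")
    keep <- keep & !sex
  }
  if (!any(keep)) stop_data("qc_filter removed every SNP")
  genotype_matrix(unclass(G)[, keep, drop = FALSE],
                  chrom = if (is.null(snp_chrom(G))) NULL else snp_chrom(G)[keep])
}

#' Read a SNP-to-gene map
#'
#' Two-column TSV (`snp_id`, `gene`); each SNP maps to at most one gene
#' (closest-gene semantics are the caller's responsibility).
#'
#' @param path file path.
#' @return Named character vector, `snp_id -> gene`.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop_data("gene map not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 2L) stop_data("gene map needs snp_id and gene columns")
  if (anyDuplicated(df[[1L]])) stop_data("duplicate SNP in gene map")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.  Sets with more than
#' `max_set_size` genes are excluded (a set with exactly
#' `max_set_size` genes is retained).
#'
#' @param path GMT file path.
#' @param max_set_size largest retained set size (default `Inf`).
#' @return Named list of character vectors with attribute
#'   `max_set_size`.
#' @export
read_gene_sets <- function(path, max_set_size = Inf) {
  if (!file.exists(path)) stop_data("gene set file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop_data("unreadable GMT line %d in %s (need name, description, genes)",
                i, path)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) <= max_set_size) sets[[f[[1L]]]] <- genes
  }
  if (!length(sets))
    warning("no gene sets retained after size filtering")
  attr(sets, "max_set_size") <- max_set_size
  sets
}

#' Read a weighted gene-pair functional network
#'
#' Three-column TSV (`geneA`, `geneB`, `weight` in \[0, 1\]).  The
#' network is undirected; self-pairs are rejected, duplicate pairs keep
#' the last weight seen.  Gene pairs absent from the file have implicit
#' similarity 0.
#'
#' @param path file path.
#' @return Object of class `functional_network` (an environment-free
#'   list with a named weight vector keyed by sorted gene pairs).
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop_data("network file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"))
  if (ncol(df) < 3L) stop_data("network needs geneA, geneB, weight columns")
  functional_network(df[[1L]], df[[2L]], df[[3L]])
}

#' @rdname read_network
#' @param geneA,geneB,weight parallel vectors of edges.
#' @export
functional_network <- function(geneA, geneB, weight) {
  if (any(geneA == geneB)) stop_data("self-pairs are not allowed in the network")
  if (any(weight < 0 | weight > 1)) stop_data("weights must be in [0, 1]")
  key <- pair_key(geneA, geneB)
  w <- stats::setNames(weight, key)
  w <- w[!duplicated(names(w), fromLast = TRUE)]
  structure(list(weights = w, genes = sort(unique(c(geneA, geneB)))),
            class = "functional_network")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

network_similarity <- function(net, pairs_a, pairs_b) {
  w <- net$weights[pair_key(pairs_a, pairs_b)]
  w[is.na(w)] <- 0
  unname(w)
}
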