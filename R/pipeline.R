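# Valid configuration schema for run_pipeline(); NULL marks "any value".
pipeline_schema <- list(
  seed = NULL, out_dir = NULL,
  simulate = list(preset = NULL, n_snps = NULL),
  input = list(genotypes = NULL, phenotypes = NULL, gene_map = NULL,
               gene_sets = NULL, max_set_size = NULL, network = NULL),
  qc = list(max_missing_frac = NULL, autosomes_only = NULL),
  mine = list(threshold = NULL, max_size = NULL, directions = NULL,
              min_size_report = NULL, jump_min = NULL,
              candidate_budget = NULL),
  fdr = list(n_perm = NULL),
  coherence = list(cutoff = NULL, jump_low = NULL, jump_high = NULL,
                   n_null = NULL))

check_config_keys <- function(cfg, schema = pipeline_schema, prefix = "") {
  for (k in names(cfg)) {
    if (!k %in% names(schema))
      stop_data("unknown config key '%s%s'; valid keys: %s", prefix, k,
                paste0(prefix, names(schema), collapse = ", "))
    if (is.list(schema[[k]]) && length(schema[[k]]) && is.list(cfg[[k]]))
      check_config_keys(cfg[[k]], schema[[k]], paste0(prefix, k, "."))
  }
  invisible(cfg)
}

# Write a result table as TSV with '# key: value' provenance header
# lines.  No timestamp, so identical config + seed gives byte-identical
# files.
write_result_tsv <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(provenance))
    writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
  utils::write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a result table written by the pipeline
#'
#' @param path TSV path with `#`-prefixed provenance header.
#' @return Data frame; the provenance lines are attached as attribute
#'   `provenance`.
#' @export
read_result_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines)
  df <- utils::read.delim(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                       collapse = "\n"),
                          sep = "\t", header = TRUE)
  attr(df, "provenance") <- sub("^# ", "", lines[hdr])
  df
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages in order: simulate (or load) the
#' dataset, QC-filter, mine, jump-filter, permutation FDR, functional
#' coherence.  Identical configuration and seed give byte-identical
#' output tables.  Every output carries the config digest, the master
#' seed, a dataset digest and the package version in its provenance
#' header.
#'
#' @param cfg nested configuration list; unknown keys abort with the
#'   list of valid keys.  Top level: `seed`, `out_dir`, and the stage
#'   blocks `simulate` (`preset`, `n_snps`), `input` (`genotypes`,
#'   `phenotypes`, `gene_map`, `gene_sets`, `max_set_size`, `network`),
#'   `qc` (`max_missing_frac`, `autosomes_only`), `mine` (`threshold`,
#'   `max_size`, `directions`, `min_size_report`, `jump_min`,
#'   `candidate_budget`), `fdr` (`n_perm`), `coherence` (`cutoff`,
#'   `jump_low`, `jump_high`, `n_null`).  A stage runs iff its block is
#'   present (`mine` requires `simulate` or `input`).
#' @return Invisibly, a list of written file paths plus the in-memory
#'   results.
#' @export
run_pipeline <- function(cfg) {
  check_config_keys(cfg)
  seed <- cfg$seed %||% 1L
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- "setup"
  withCallingHandlers({
    prov_base <- list(tool = paste0("snpcombine ",
                                    as.character(utils::packageVersion("snpcombine"))),
                      seed = seed,
                      config_digest = config_digest(
                        cfg[setdiff(names(cfg), "out_dir")]))

    # ---- data ----
    stage <- "simulate/input"
    truth <- NULL
    if (!is.null(cfg$simulate)) {
      spec <- synthetic_preset(cfg$simulate$preset %||% "paper",
                               n_snps = cfg$simulate$n_snps %||% 2172L,
                               seed = seed)
      sim <- simulate_dataset(spec)
      G <- sim$genotypes; labels <- sim$labels; truth <- sim$truth
      paths$genotypes <- file.path(out_dir, "genotypes.tsv")
      write_genotypes(G, paths$genotypes)
      paths$phenotypes <- file.path(out_dir, "phenotypes.tsv")
      write_phenotypes(labels, paths$phenotypes)
      paths$truth <- file.path(out_dir, "truth.tsv")
      write_result_tsv(truth, paths$truth, prov_base)
    } else if (!is.null(cfg$input)) {
      G <- read_genotypes(cfg$input$genotypes)
      labels <- read_phenotypes(cfg$input$phenotypes, rownames(G))
    } else {
      return(invisible(paths))
    }
    gene_map <- if (!is.null(cfg$input$gene_map)) read_gene_map(cfg$input$gene_map)
    gene_sets <- if (!is.null(cfg$input$gene_sets))
      read_gene_sets(cfg$input$gene_sets, cfg$input$max_set_size %||% Inf)

    if (!is.null(cfg$qc)) {
      stage <- "qc"
      G <- qc_filter(G, cfg$qc$max_missing_frac %||% 0.05,
                     cfg$qc$autosomes_only %||% FALSE)
    }
    prov_base$dataset_digest <- fnv1a(paste(c(dim(G), unclass(G)), collapse = ","))

    if (is.null(cfg$mine)) return(invisible(paths))

    # ---- mine ----
    stage <- "mine"
    B <- encode_binary(G)
    mcfg <- mining_config(
      threshold = cfg$mine$threshold %||% 0.15,
      max_size = cfg$mine$max_size %||% 10L,
      directions = cfg$mine$directions %||% c("case-enriched", "control-enriched"),
      min_size_report = cfg$mine$min_size_report %||% 2L,
      gene_map = gene_map, gene_sets = gene_sets,
      candidate_budget = cfg$mine$candidate_budget %||% 5e6)
    res <- mine(B, labels, mcfg)
    if (!is.null(cfg$mine$jump_min)) {
      stage <- "jump_filter"
      res <- jump_filter(res, cfg$mine$jump_min)
      mcfg <- attr(res, "config")
    }
    paths$patterns <- file.path(out_dir, "patterns.tsv")
    write_result_tsv(res, paths$patterns,
                     c(prov_base, threshold = mcfg$threshold))

    # ---- fdr ----
    if (!is.null(cfg$fdr)) {
      stage <- "fdr"
      res <- estimate_fdr(res, B, labels, mcfg,
                          n_perm = cfg$fdr$n_perm %||% 100L,
                          seed = seed)
      paths$patterns_fdr <- file.path(out_dir, "patterns_fdr.tsv")
      write_result_tsv(res, paths$patterns_fdr,
                       c(prov_base, n_perm = cfg$fdr$n_perm %||% 100L))
    }

    # ---- coherence ----
    if (!is.null(cfg$coherence)) {
      stage <- "coherence"
      if (is.null(gene_map) || is.null(cfg$input$network))
        stop_data("coherence stage needs input$gene_map and input$network")
      net <- read_network(cfg$input$network)
      rep <- coherence_report(res, gene_map, net,
                              cutoff = cfg$coherence$cutoff %||% 0.5,
                              jump_bounds = c(cfg$coherence$jump_low %||% -5,
                                              cfg$coherence$jump_high %||% 5),
                              n_null = cfg$coherence$n_null %||% 100L,
                              seed = seed)
      paths$coherence_groups <- file.path(out_dir, "coherence_groups.tsv")
      write_result_tsv(rep$groups, paths$coherence_groups, prov_base)
      paths$coherence_tests <- file.path(out_dir, "coherence_tests.tsv")
      write_result_tsv(rep$tests, paths$coherence_tests, prov_base)
      paths$coherence_report <- rep
    }
    paths$result <- res
    paths$truth_table <- truth
    invisible(paths)
  }, error = function(e) {
    if (!inherits(e, "snpcombine_stage_error")) {
      e2 <- errorCondition(sprintf("pipeline stage '%s' failed: %s",
                                   stage, conditionMessage(e)),
                           class = c("snpcombine_stage_error",
                                     class(e)[1L], "error"))
      stop(e2)
    }
  })
}
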