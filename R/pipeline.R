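# End-to-end run: read the six input tables, compute darkness profiles and
# the residue partition, annotation enrichment (with treemap export),
# autonomy, dark gene clusters and tissue darkness, and write one TSV per
# stage plus a run manifest. Outputs are written atomically (tempfile +
# rename); a failed stage leaves a .failed marker naming the error.

#' Pipeline run configuration
#'
#' Validates paths and parameters before any stage runs.
#'
#' @param proteins,annotations,coverage,links,genes,expression,sequences
#'   input paths (the last four optional, `NULL` to skip the stages needing
#'   them).
#' @param out_dir output directory.
#' @param alpha enrichment false-discovery level in (0,1).
#' @param treemap_cutoff readability cutoff on -log10(adjusted p).
#' @param autonomy_cutoff interaction-count confidence cutoff.
#' @param n_permutations permutations per chromosome.
#' @param weighting tissue weighting, `"presence"` or `"intensity"`.
#' @param dark_definition see [dark_labels()].
#' @param seed integer seed for the permutation tests.
#' @return a validated list of class `dp_config`.
#' @export
dp_config <- function(proteins, annotations = NULL, coverage = NULL,
                      links = NULL, genes = NULL, expression = NULL,
                      sequences = NULL, out_dir = tempfile("dp_run"),
                      alpha = 0.01, treemap_cutoff = 0,
                      autonomy_cutoff = 700L, n_permutations = 1000L,
                      weighting = c("presence", "intensity"),
                      dark_definition = c("strict_D1", "threshold"),
                      seed = 1L) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    dp_stop("alpha must be in (0, 1)")
  if (n_permutations < 1L) dp_stop("n_permutations must be >= 1")
  paths <- list(proteins = proteins, annotations = annotations,
                coverage = coverage, links = links, genes = genes,
                expression = expression, sequences = sequences)
  for (nm in names(paths))
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]))
      dp_stop("input '%s' does not exist: %s", nm, paths[[nm]])
  structure(list(paths = paths, out_dir = out_dir, alpha = alpha,
                 treemap_cutoff = treemap_cutoff,
                 autonomy_cutoff = as.integer(autonomy_cutoff),
                 n_permutations = as.integer(n_permutations),
                 weighting = match.arg(weighting),
                 dark_definition = match.arg(dark_definition),
                 seed = as.integer(seed)),
            class = "dp_config")
}

write_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  file.rename(tmp, path)
  invisible(path)
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(conditionMessage(e), file.path(out_dir, paste0(name, ".failed")))
    dp_stop("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full dark-proteome pipeline
#'
#' Executes every stage the configured inputs allow and writes
#' `darkness.tsv`, `partition.tsv`, `enrichment.tsv` + `treemap.json`,
#' `autonomy.tsv`, `clusters.tsv` and `tissues.tsv` to the output directory,
#' plus `run_manifest.json` echoing the parameters and seed.
#'
#' @param config a [dp_config()].
#' @return invisibly, a list with the in-memory stage results and the output
#'   paths.
#' @export
dp_run <- function(config) {
  stopifnot(inherits(config, "dp_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$paths
  results <- list()

  proteins <- run_stage("read", config$out_dir, {
    read_proteins(p$proteins)
  })
  coverage <- if (!is.null(p$coverage)) {
    run_stage("read", config$out_dir, read_coverage(p$coverage, proteins))
  } else {
    data.frame(accession = character(), start = integer(), end = integer(),
               criterion = character(), source_id = character())
  }

  results$darkness <- run_stage("darkness", config$out_dir, {
    prof <- darkness_profiles(proteins, coverage)
    write_atomic(as.data.frame(prof), file.path(config$out_dir, "darkness.tsv"))
    prof
  })
  dark <- dark_labels(results$darkness, config$dark_definition)

  results$partition <- run_stage("partition", config$out_dir, {
    part <- proteome_partition(results$darkness)
    write_atomic(as.data.frame(part), file.path(config$out_dir, "partition.tsv"))
    part
  })

  if (!is.null(p$annotations)) {
    results$enrichment <- run_stage("enrichment", config$out_dir, {
      ann <- read_annotations(p$annotations, proteins)
      cfg <- enrichment_config(alpha = config$alpha,
                               treemap_cutoff = config$treemap_cutoff)
      res <- enrich(proteins, ann, dark, cfg)
      write_atomic(as.data.frame(res),
                   file.path(config$out_dir, "enrichment.tsv"))
      write_treemap_json(res, file.path(config$out_dir, "treemap.json"),
                         cutoff = config$treemap_cutoff)
      res
    })
  }

  links <- if (!is.null(p$links))
    run_stage("read", config$out_dir, read_links(p$links, proteins))
  if (!is.null(links)) {
    results$autonomy <- run_stage("autonomy", config$out_dir, {
      aut <- autonomy_table(proteins, dark, links, config$autonomy_cutoff)
      write_atomic(as.data.frame(aut), file.path(config$out_dir, "autonomy.tsv"))
      aut
    })
  }

  if (!is.null(p$genes)) {
    results$clusters <- run_stage("clusters", config$out_dir, {
      genes <- read_gene_positions(p$genes, proteins)
      seqs <- if (!is.null(p$sequences)) read_sequences(p$sequences)
      cl <- find_dark_clusters(proteins, genes, dark, links = links,
                               sequences = seqs,
                               n_permutations = config$n_permutations,
                               seed = config$seed)
      write_atomic(as.data.frame(cl), file.path(config$out_dir, "clusters.tsv"))
      cl
    })
  }

  if (!is.null(p$expression)) {
    results$tissues <- run_stage("tissues", config$out_dir, {
      expr <- zero_fill(read_expression(p$expression, proteins))
      td <- tissue_darkness(expr, results$darkness, config$weighting)
      write_atomic(as.data.frame(td), file.path(config$out_dir, "tissues.tsv"))
      td
    })
  }

  manifest <- list(package_version = as.character(utils::packageVersion("darkproteome")),
                   parameters = config[setdiff(names(config), "paths")],
                   inputs = p[!vapply(p, is.null, TRUE)],
                   stages_run = names(results))
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, out_dir = config$out_dir))
}
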