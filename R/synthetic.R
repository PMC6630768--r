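# Synthetic proteome bundles with planted, recoverable structure. The
# generator emulates every input the pipeline consumes -- protein universe,
# annotations, structural coverage, interaction links, gene positions and
# tissue expression -- with planted parameters (class fractions, annotation
# odds ratios, degree means, cluster runs, tissue darkness targets) recorded
# in a ground-truth manifest, so every downstream statistic has a known
# expected value.

#' Specification of a synthetic protein universe
#'
#' @param n_proteins number of proteins.
#' @param length_meanlog,length_sdlog log-normal residue-length parameters
#'   (defaults give a median around 220 residues, a typical eukaryotic
#'   protein length).
#' @param class_fractions named fractions `c(dark=, grey=, white=)` summing
#'   to 1; defaults (0.25/0.55/0.20) give a eukaryote-like total darkness
#'   near 50\%.
#' @param grey_dark_range interval within (0,1) from which each grey
#'   protein's dark fraction is drawn uniformly.
#' @param taxon_group one of `"archaea"`, `"bacteria"`, `"eukaryota"`,
#'   `"viruses"`.
#' @param organism organism label.
#' @param seed master integer seed; all component substreams derive from it.
#' @return a list of class `dp_universe_spec`.
#' @export
universe_spec <- function(n_proteins = 1000L,
                          length_meanlog = 5.4, length_sdlog = 0.5,
                          class_fractions = c(dark = 0.25, grey = 0.55,
                                              white = 0.20),
                          grey_dark_range = c(0.1, 0.9),
                          taxon_group = "eukaryota",
                          organism = "synthetic", seed = 1L) {
  stopifnot(n_proteins >= 1, taxon_group %in% TAXON_GROUPS)
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9)
    dp_stop("class_fractions must be non-negative and sum to 1")
  if (!all(names(class_fractions) == c("dark", "grey", "white")))
    dp_stop("class_fractions must be named dark, grey, white in that order")
  if (grey_dark_range[1] <= 0 || grey_dark_range[2] >= 1 ||
      grey_dark_range[1] > grey_dark_range[2])
    dp_stop("grey_dark_range must lie within (0,1)")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 class_fractions = class_fractions,
                 grey_dark_range = grey_dark_range,
                 taxon_group = taxon_group, organism = organism,
                 seed = as.integer(seed)),
            class = "dp_universe_spec")
}

#' Planted signals for a synthetic bundle
#'
#' @param enriched_annotations data frame with columns `field`,
#'   `subcategory`, `text`, `odds_ratio`, `prevalence_nondark`: annotations
#'   planted so that the population odds ratio between dark and non-dark
#'   proteins equals `odds_ratio` exactly (per-class probabilities solve the
#'   2x2 odds identity).
#' @param n_null_annotations number of additional annotations with no
#'   dark/non-dark association (population odds ratio 1).
#' @param null_prevalence presence probability of the null annotations.
#' @param degree_means named `c(dark=, nondark=)` expected interaction
#'   degrees; partners are drawn Chung-Lu style so expected degree tracks
#'   the class mean.
#' @param score_range integer range from which combined scores are drawn
#'   uniformly.
#' @param n_chromosomes chromosomes over which genes are scattered.
#' @param clusters data frame with columns `chromosome`, `start_index`,
#'   `run_length`: dark proteins are placed in a consecutive run at the given
#'   position of the chromosome's gene order.
#' @param tissue_targets data frame with columns `tissue`,
#'   `target_dark_ratio` in \[0,1\]: expressed protein sets are assembled so
#'   the realized dark-residue ratio tracks the target.
#' @param n_expressed_per_tissue proteins expressed per tissue.
#' @param missing_rate probability that an expressed measurement is dropped
#'   (missing, later zero-filled).
#' @param dark_seq_bias composition bias of dark-protein sequences: the
#'   probability mass put on one preferred residue.
#' @return a list of class `dp_planted_signals`.
#' @export
planted_signals <- function(enriched_annotations = NULL,
                            n_null_annotations = 0L,
                            null_prevalence = 0.1,
                            degree_means = c(dark = 1, nondark = 10),
                            score_range = c(0L, 999L),
                            n_chromosomes = 4L,
                            clusters = NULL,
                            tissue_targets = NULL,
                            n_expressed_per_tissue = 100L,
                            missing_rate = 0.1,
                            dark_seq_bias = 0.3) {
  if (!is.null(enriched_annotations)) {
    ea <- enriched_annotations
    stopifnot(all(c("field", "subcategory", "text", "odds_ratio",
                    "prevalence_nondark") %in% names(ea)))
    if (any(ea$odds_ratio <= 0)) dp_stop("planted odds ratios must be > 0")
    if (any(ea$prevalence_nondark <= 0 | ea$prevalence_nondark >= 1))
      dp_stop("prevalence_nondark must lie in (0,1)")
  }
  if (!is.null(clusters)) {
    stopifnot(all(c("chromosome", "start_index", "run_length") %in%
                    names(clusters)))
    if (any(clusters$run_length < 1)) dp_stop("planted run lengths must be >= 1")
  }
  if (!is.null(tissue_targets)) {
    stopifnot(all(c("tissue", "target_dark_ratio") %in% names(tissue_targets)))
    if (any(tissue_targets$target_dark_ratio < 0 |
              tissue_targets$target_dark_ratio > 1))
      dp_stop("tissue targets must lie in [0,1]")
  }
  stopifnot(missing_rate >= 0, missing_rate < 1,
            score_range[1] >= 0, score_range[2] <= 999,
            score_range[1] <= score_range[2])
  structure(list(enriched_annotations = enriched_annotations,
                 n_null_annotations = as.integer(n_null_annotations),
                 null_prevalence = null_prevalence,
                 degree_means = degree_means,
                 score_range = as.integer(score_range),
                 n_chromosomes = as.integer(n_chromosomes),
                 clusters = clusters,
                 tissue_targets = tissue_targets,
                 n_expressed_per_tissue = as.integer(n_expressed_per_tissue),
                 missing_rate = missing_rate,
                 dark_seq_bias = dark_seq_bias),
            class = "dp_planted_signals")
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Simulate a complete synthetic input bundle
#'
#' Generates, under a single master seed with per-component substreams,
#' every input table the pipeline consumes. Coverage intervals are
#' constructed so the realized darkness score matches the planted class
#' exactly (dark proteins get no intervals, white proteins a full-length
#' interval, grey proteins partial coverage hitting a drawn dark fraction);
#' annotation presence probabilities solve the planted odds-ratio identity;
#' link degrees follow the planted class means; chromosome orders carry the
#' planted dark runs; expressed protein sets track the planted tissue
#' darkness targets. Identical spec and seed yield identical bundles.
#'
#' @param spec a [universe_spec()].
#' @param signals a [planted_signals()] (default: no planted signals).
#' @return a list of class `dp_bundle` with elements `proteins`,
#'   `annotations`, `coverage`, `links`, `genes`, `expression`, `sequences`
#'   and `manifest` (ground truth: the spec, the signals, the substream
#'   seeds and realized summaries).
#' @export
simulate_universe <- function(spec, signals = planted_signals()) {
  stopifnot(inherits(spec, "dp_universe_spec"),
            inherits(signals, "dp_planted_signals"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 6L)

  # -- universe, classes, coverage -------------------------------------------
  set.seed(sub[1])
  n <- spec$n_proteins
  acc <- sprintf("SYN%05d", seq_len(n))
  len <- pmax(30L, as.integer(round(rlnorm(n, spec$length_meanlog,
                                           spec$length_sdlog))))
  klass <- sample(c("dark", "grey", "white"), n, replace = TRUE,
                  prob = spec$class_fractions)
  proteins <- data.frame(accession = acc, organism = spec$organism,
                         taxon_group = spec$taxon_group, length = len,
                         stringsAsFactors = FALSE)
  cov_rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (klass[i] == "white") {
      cov_rows[[i]] <- data.frame(accession = acc[i], start = 1L,
                                  end = len[i], criterion = "A",
                                  source_id = sprintf("str%05d", i),
                                  stringsAsFactors = FALSE)
    } else if (klass[i] == "grey") {
      f <- runif(1, spec$grey_dark_range[1], spec$grey_dark_range[2])
      ncov <- min(max(1L, as.integer(round(len[i] * (1 - f)))), len[i] - 1L)
      s <- sample.int(len[i] - ncov + 1L, 1L)
      if (ncov >= 10L && runif(1) < 0.5) {
        # split the covered block over criteria A and B to exercise the union
        cut <- sample.int(ncov - 1L, 1L)
        cov_rows[[i]] <- data.frame(
          accession = acc[i], start = c(s, s + cut),
          end = c(s + cut - 1L, s + ncov - 1L), criterion = c("A", "B"),
          source_id = sprintf("str%05d%s", i, c("a", "b")),
          stringsAsFactors = FALSE)
      } else {
        cov_rows[[i]] <- data.frame(accession = acc[i], start = s,
                                    end = s + ncov - 1L,
                                    criterion = sample(c("A", "B"), 1L),
                                    source_id = sprintf("str%05d", i),
                                    stringsAsFactors = FALSE)
      }
    }
  }
  coverage <- do.call(rbind, cov_rows[!vapply(cov_rows, is.null, TRUE)])
  if (is.null(coverage))
    coverage <- data.frame(accession = character(), start = integer(),
                           end = integer(), criterion = character(),
                           source_id = character(), stringsAsFactors = FALSE)
  rownames(coverage) <- NULL
  is_dark <- klass == "dark"

  # -- annotations ------------------------------------------------------------
  set.seed(sub[2])
  ann_rows <- list()
  ea <- signals$enriched_annotations
  if (!is.null(ea)) {
    for (j in seq_len(nrow(ea))) {
      p_nd <- ea$prevalence_nondark[j]
      o_d <- ea$odds_ratio[j] * p_nd / (1 - p_nd)
      p_d <- o_d / (1 + o_d)                 # solves the 2x2 odds identity
      has <- ifelse(is_dark, rbinom(n, 1, p_d), rbinom(n, 1, p_nd)) == 1
      if (any(has))
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          accession = acc[has], field = ea$field[j],
          subcategory = ea$subcategory[j], text = ea$text[j],
          stringsAsFactors = FALSE)
    }
  }
  if (signals$n_null_annotations > 0L) {
    for (j in seq_len(signals$n_null_annotations)) {
      has <- rbinom(n, 1, signals$null_prevalence) == 1
      if (any(has))
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          accession = acc[has], field = "DE", subcategory = "NULLCAT",
          text = sprintf("null annotation %03d", j), stringsAsFactors = FALSE)
    }
  }
  annotations <- do.call(rbind, ann_rows)
  if (is.null(annotations))
    annotations <- data.frame(accession = character(), field = character(),
                              subcategory = character(), text = character(),
                              stringsAsFactors = FALSE)
  rownames(annotations) <- NULL

  # -- interaction links (Chung-Lu: expected degree tracks the class mean) ---
  set.seed(sub[3])
  target <- ifelse(is_dark, signals$degree_means[["dark"]],
                   signals$degree_means[["nondark"]])
  n_edges <- as.integer(round(sum(target) / 2))
  links <- data.frame(accession_a = character(), accession_b = character(),
                      combined_score = integer(), stringsAsFactors = FALSE)
  if (n_edges > 0L && any(target > 0)) {
    a <- sample.int(n, n_edges, replace = TRUE, prob = target)
    b <- sample.int(n, n_edges, replace = TRUE, prob = target)
    keep <- a != b
    scores <- sample(seq(signals$score_range[1], signals$score_range[2]),
                     n_edges, replace = TRUE)
    links <- normalize_links(data.frame(accession_a = acc[a[keep]],
                                        accession_b = acc[b[keep]],
                                        combined_score = scores[keep],
                                        stringsAsFactors = FALSE))
  }

  # -- gene positions with planted dark runs ---------------------------------
  set.seed(sub[4])
  chrom <- sprintf("chr%d", sample.int(signals$n_chromosomes, n,
                                       replace = TRUE))
  resample <- function(x) x[sample.int(length(x))]   # safe for length 1
  order_on <- lapply(split(seq_len(n), chrom), resample)
  if (!is.null(signals$clusters)) {
    for (j in seq_len(nrow(signals$clusters))) {
      cl <- signals$clusters[j, ]
      idx <- order_on[[cl$chromosome]]
      if (is.null(idx)) dp_stop("planted cluster chromosome '%s' is empty",
                                cl$chromosome)
      lastpos <- cl$start_index + cl$run_length - 1L
      if (lastpos > length(idx))
        dp_stop("planted run [%d,%d] exceeds chromosome '%s' size %d",
                cl$start_index, lastpos, cl$chromosome, length(idx))
      dark_here <- idx[is_dark[idx]]
      if (length(dark_here) < cl$run_length)
        dp_stop("chromosome '%s' has only %d dark proteins; planted run needs %d",
                cl$chromosome, length(dark_here), cl$run_length)
      chosen <- dark_here[seq_len(cl$run_length)]
      rest <- setdiff(idx, chosen)
      slots <- seq.int(cl$start_index, lastpos)
      newidx <- integer(length(idx))
      newidx[slots] <- chosen
      newidx[-slots] <- rest
      order_on[[cl$chromosome]] <- newidx
    }
  }
  gene_rows <- lapply(names(order_on), function(ch) {
    idx <- order_on[[ch]]
    pos <- sort(sample.int(100000000L, length(idx)))
    data.frame(accession = acc[idx], chromosome = ch, central_position = pos,
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL

  # -- tissue expression tracking planted darkness targets -------------------
  set.seed(sub[5])
  dark_res <- ifelse(klass == "dark", len,
                     ifelse(klass == "white", 0L, NA_integer_))
  # realized dark residues of grey proteins, from the generated coverage
  if (any(klass == "grey")) {
    covlen <- tapply(coverage$end - coverage$start + 1L, coverage$accession, sum)
    g <- which(klass == "grey")
    dark_res[g] <- len[g] - as.integer(covlen[acc[g]])
  }
  expression <- matrix(numeric(), nrow = 0, ncol = n,
                       dimnames = list(NULL, acc))
  tt <- signals$tissue_targets
  if (!is.null(tt) && nrow(tt)) {
    expression <- matrix(NA_real_, nrow = nrow(tt), ncol = n,
                         dimnames = list(tt$tissue, acc))
    for (j in seq_len(nrow(tt))) {
      target_r <- tt$target_dark_ratio[j]
      # greedy tracking: raise the ratio with fully dark proteins, lower it
      # with fully white ones; grey proteins only when a pool runs out
      pool_dark <- resample(which(klass == "dark"))
      pool_white <- resample(which(klass == "white"))
      pool_grey <- resample(which(klass == "grey"))
      if (target_r > 0 && !length(pool_dark))
        dp_stop("tissue target %g infeasible: no dark proteins", target_r)
      if (target_r < 1 && !length(pool_white) && !length(pool_grey))
        dp_stop("tissue target %g infeasible: no non-dark proteins", target_r)
      take <- function(pool) { i <<- pool[1]; pool[-1] }
      sel <- integer(); sd_ <- 0; sl <- 0
      nexp <- min(signals$n_expressed_per_tissue, n)
      for (k in seq_len(nexp)) {
        want_dark <- (sl == 0 && target_r > 0) || (sl > 0 && sd_ / sl < target_r)
        i <- NA_integer_
        if (want_dark) {
          if (length(pool_dark)) pool_dark <- take(pool_dark)
          else if (length(pool_grey)) pool_grey <- take(pool_grey)
          else if (length(pool_white)) pool_white <- take(pool_white)
        } else {
          if (length(pool_white)) pool_white <- take(pool_white)
          else if (length(pool_grey)) pool_grey <- take(pool_grey)
          else if (length(pool_dark)) pool_dark <- take(pool_dark)
        }
        if (is.na(i)) break
        sel <- c(sel, i); sd_ <- sd_ + dark_res[i]; sl <- sl + len[i]
      }
      intensity <- round(abs(rnorm(length(sel), mean = 5, sd = 1)) + 0.01, 4)
      expression[j, sel] <- intensity
      if (signals$missing_rate > 0) {
        drop <- runif(length(sel)) < signals$missing_rate
        expression[j, sel[drop]] <- NA_real_
      }
    }
  }

  # -- toy sequences (dark proteins carry a composition bias) ----------------
  set.seed(sub[6])
  sequences <- character(n)
  for (i in seq_len(n)) {
    if (is_dark[i] && signals$dark_seq_bias > 0) {
      pref <- sample(AA20, 1L)
      w <- rep((1 - signals$dark_seq_bias) / 19, 20)
      w[match(pref, AA20)] <- signals$dark_seq_bias
      sequences[i] <- paste(sample(AA20, len[i], replace = TRUE, prob = w),
                            collapse = "")
    } else {
      sequences[i] <- paste(sample(AA20, len[i], replace = TRUE),
                            collapse = "")
    }
  }
  names(sequences) <- acc

  manifest <- list(
    spec = unclass(spec), signals = unclass(signals),
    substream_seeds = sub,
    realized = list(
      n_proteins = n,
      class_counts = as.list(table(factor(klass,
                                          c("dark", "grey", "white")))),
      total_residues = sum(len),
      total_dark_residues = sum(dark_res),
      planted_dark_accessions = acc[is_dark]))
  structure(list(proteins = proteins, annotations = annotations,
                 coverage = coverage, links = links, genes = genes,
                 expression = expression, sequences = sequences,
                 manifest = manifest),
            class = "dp_bundle")
}

#' @export
print.dp_bundle <- function(x, ...) {
  cc <- x$manifest$realized$class_counts
  cat(sprintf(
    "Synthetic bundle: %d proteins (%d dark / %d grey / %d white), %d coverage rows,\n  %d annotation rows, %d links, %d genes, %d tissue(s)\n",
    nrow(x$proteins), cc$dark, cc$grey, cc$white, nrow(x$coverage),
    nrow(x$annotations), nrow(x$links), nrow(x$genes), nrow(x$expression)))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Serialises every table of a [simulate_universe()] bundle in the package's
#' TSV dialects, plus the ground-truth manifest as JSON. Identical bundles
#' produce byte-identical files.
#'
#' @param bundle a `dp_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "dp_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(proteins = file.path(dir, "proteins.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             coverage = file.path(dir, "coverage.tsv"),
             links = file.path(dir, "links.tsv"),
             genes = file.path(dir, "genes.tsv"),
             expression = file.path(dir, "expression.tsv"),
             sequences = file.path(dir, "sequences.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_proteins(bundle$proteins, paths["proteins"])
  write_annotations(bundle$annotations, paths["annotations"])
  write_coverage(bundle$coverage, paths["coverage"])
  write_links(bundle$links, paths["links"])
  write_gene_positions(bundle$genes, paths["genes"])
  write_expression(bundle$expression, paths["expression"])
  write_sequences(bundle$sequences, paths["sequences"])
  jsonlite::write_json(bundle$manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
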