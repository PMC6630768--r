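# Annotation enrichment in dark vs non-dark proteins: per distinct
# (field, subcategory, text) annotation a 2x2 presence/absence table, a
# two-sided Fisher exact p, and Benjamini-Hochberg control within each
# annotation field (DE and FT corrected separately) at alpha = 1%.

#' Enrichment configuration
#'
#' @param alpha accepted false-discovery rate for the BH step-up (default
#'   0.01: annotations with adjusted p <= 1\% are reported).
#' @param dark_definition how the dark protein set is formed: `"strict_D1"`
#'   (D = 1 proteins versus all others, default) or `"threshold"`.
#' @param dark_threshold darkness threshold for `"threshold"`.
#' @param excluded_subcategories subcategories removed before testing;
#'   `"SIMILARITY"` by default because similarity annotations describe groups
#'   of near-identical proteins rather than general properties.
#' @param treemap_cutoff readability cutoff on -log10(adjusted p) used when
#'   exporting treemaps.
#' @return a list of class `dp_enrichment_config`.
#' @export
enrichment_config <- function(alpha = 0.01,
                              dark_definition = c("strict_D1", "threshold"),
                              dark_threshold = 0.5,
                              excluded_subcategories = "SIMILARITY",
                              treemap_cutoff = 0) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    dp_stop("alpha must be in (0, 1)")
  structure(list(alpha = alpha,
                 dark_definition = match.arg(dark_definition),
                 dark_threshold = dark_threshold,
                 excluded_subcategories = excluded_subcategories,
                 treemap_cutoff = treemap_cutoff),
            class = "dp_enrichment_config")
}

#' Contingency tables per distinct annotation
#'
#' Builds one 2x2 table per distinct (field, subcategory, text) annotation:
#' dark proteins with/without the annotation versus non-dark proteins
#' with/without it. A protein counts at most once per distinct annotation
#' (presence/absence), regardless of how many times the annotation row is
#' repeated for it. Annotations held by nobody do not appear.
#'
#' @param annotations annotation data frame (`accession`, `field`,
#'   `subcategory`, `text`).
#' @param dark named logical vector over the whole universe (`TRUE` = dark),
#'   keyed by accession.
#' @return data frame with one row per annotation: `field`, `subcategory`,
#'   `annotation`, `dark_with`, `dark_without`, `nondark_with`,
#'   `nondark_without`.
#' @export
build_tables <- function(annotations, dark) {
  if (is.null(names(dark))) dp_stop("dark labels must be named by accession")
  unknown <- setdiff(unique(annotations$accession), names(dark))
  if (length(unknown))
    dp_stop("annotations reference accession(s) without a dark label: %s",
            paste(head(unknown, 3L), collapse = ", "))
  n_dark <- sum(dark)
  n_nondark <- sum(!dark)
  if (nrow(annotations) == 0L)
    return(data.frame(field = character(), subcategory = character(),
                      annotation = character(), dark_with = integer(),
                      dark_without = integer(), nondark_with = integer(),
                      nondark_without = integer(), stringsAsFactors = FALSE))
  key <- paste(annotations$field, annotations$subcategory, annotations$text,
               sep = "\r")
  pair <- !duplicated(paste(key, annotations$accession, sep = "\r"))
  key <- key[pair]
  is_d <- unname(dark[annotations$accession[pair]])
  a <- tapply(is_d, key, sum)                 # dark proteins holding it
  tot <- tapply(is_d, key, length)
  parts <- strsplit(names(a), "\r", fixed = TRUE)
  out <- data.frame(field = vapply(parts, `[`, "", 1L),
                    subcategory = vapply(parts, `[`, "", 2L),
                    annotation = vapply(parts, `[`, "", 3L),
                    dark_with = as.integer(a),
                    dark_without = n_dark - as.integer(a),
                    nondark_with = as.integer(tot) - as.integer(a),
                    stringsAsFactors = FALSE)
  out$nondark_without <- n_nondark - out$nondark_with
  out <- out[order(out$field, out$subcategory, out$annotation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact test for 2x2 tables
#'
#' Computes the exact two-sided p by enumerating, for the fixed margins, all
#' tables whose hypergeometric probability does not exceed that of the
#' observed table (the same rule, with the same relative tie tolerance, as
#' `stats::fisher.test`), and the sample odds ratio
#' (`dark_with * nondark_without / (dark_without * nondark_with)`); the odds
#' ratio is `Inf` when only the denominator vanishes and 1 when both products
#' vanish. Vectorised over tables.
#'
#' @param dark_with,dark_without,nondark_with,nondark_without non-negative
#'   integer cell counts (vectors of equal length).
#' @return data frame with columns `p` and `odds_ratio`.
#' @examples
#' fisher_exact(5, 5, 5, 5)   # p = 1, OR = 1
#' @export
fisher_exact <- function(dark_with, dark_without, nondark_with, nondark_without) {
  a <- as.numeric(dark_with); b <- as.numeric(dark_without)
  c_ <- as.numeric(nondark_with); d <- as.numeric(nondark_without)
  if (any(c(a, b, c_, d) < 0)) dp_stop("negative cell count")
  if (any(a + b + c_ + d == 0)) dp_stop("all four cells are zero")
  n <- length(a)
  p <- vapply(seq_len(n), function(i)
    fisher_p_one(a[i], b[i], c_[i], d[i]), numeric(1))
  num <- a * d; den <- b * c_
  or <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 1))
  data.frame(p = p, odds_ratio = or)
}

# exact two-sided p for one table: sum of hypergeometric probabilities
# <= observed, with the customary 1 + 1e-7 relative tolerance on ties
fisher_p_one <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  pr <- stats::dhyper(lo:hi, m, n, k)
  min(1, sum(pr[pr <= pr[a - lo + 1] * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values `min(1, min_{j >= i} p_(j) * n / j)` over the ascending
#' order statistics, returned in input order, together with the rank k of
#' each p (ties share the rank of their first position after a stable sort).
#'
#' @param p numeric vector of raw p-values in \[0,1\].
#' @return data frame with columns `p`, `rank_k`, `p_adjusted` in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))$p_adjusted  # all 0.03
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(data.frame(p = numeric(), rank_k = integer(),
                                    p_adjusted = numeric()))
  if (any(is.na(p) | p < 0 | p > 1)) dp_stop("p-values must lie in [0,1]")
  data.frame(p = p,
             rank_k = as.integer(rank(p, ties.method = "min")),
             p_adjusted = p.adjust(p, method = "BH"))
}

#' Annotation enrichment in dark versus non-dark proteins
#'
#' Runs the full enrichment analysis: drops excluded subcategories, builds a
#' 2x2 presence/absence table per distinct annotation, applies the two-sided
#' Fisher exact test, adjusts p-values by Benjamini-Hochberg separately
#' within the DE and FT families, and keeps annotations with adjusted
#' p <= alpha. `direction` is `"over"` when the sample odds ratio exceeds 1
#' (annotation over-represented in dark proteins), `"under"` otherwise.
#'
#' @param proteins protein universe data frame.
#' @param annotations annotation data frame.
#' @param dark named logical vector keyed by accession (e.g. from
#'   [dark_labels()]); must cover the universe.
#' @param config an [enrichment_config()].
#' @return a `dp_enrichment` data frame sorted by adjusted p ascending, with
#'   columns `field`, `subcategory`, `annotation`, `nondark_with`,
#'   `dark_with`, `odds_ratio`, `total`, `fisher_p`, `adjusted_p`, `rank_k`,
#'   `direction` (mirroring the Non-dark / Dark / Ratio / Total table layout).
#' @export
enrich <- function(proteins, annotations, dark, config = enrichment_config()) {
  if (nrow(proteins) == 0L) dp_stop("empty protein universe")
  if (!all(proteins$accession %in% names(dark)))
    dp_stop("dark labels must cover the universe")
  dark <- dark[proteins$accession]
  annotations <- annotations[!(annotations$subcategory %in%
                                 config$excluded_subcategories), , drop = FALSE]
  tab <- build_tables(annotations, dark)
  if (nrow(tab) == 0L) {
    out <- data.frame(field = character(), subcategory = character(),
                      annotation = character(), nondark_with = integer(),
                      dark_with = integer(), odds_ratio = numeric(),
                      total = integer(), fisher_p = numeric(),
                      adjusted_p = numeric(), rank_k = integer(),
                      direction = character(), stringsAsFactors = FALSE)
    class(out) <- c("dp_enrichment", "data.frame")
    return(out)
  }
  ft <- fisher_exact(tab$dark_with, tab$dark_without,
                     tab$nondark_with, tab$nondark_without)
  tab$fisher_p <- ft$p
  tab$odds_ratio <- ft$odds_ratio
  tab$adjusted_p <- NA_real_
  tab$rank_k <- NA_integer_
  for (f in unique(tab$field)) {           # DE and FT corrected separately
    sel <- tab$field == f
    adj <- bh_adjust(tab$fisher_p[sel])
    tab$adjusted_p[sel] <- adj$p_adjusted
    tab$rank_k[sel] <- adj$rank_k
  }
  tab <- tab[tab$adjusted_p <= config$alpha, , drop = FALSE]
  tab$direction <- ifelse(tab$odds_ratio > 1, "over", "under")
  tab$total <- tab$dark_with + tab$nondark_with
  tab <- tab[order(tab$adjusted_p, tab$fisher_p, tab$field,
                   tab$subcategory, tab$annotation), , drop = FALSE]
  out <- tab[, c("field", "subcategory", "annotation", "nondark_with",
                 "dark_with", "odds_ratio", "total", "fisher_p",
                 "adjusted_p", "rank_k", "direction")]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("dp_enrichment", "data.frame")
  out
}

#' @export
print.dp_enrichment <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Annotation enrichment: %d annotation(s) at adjusted p <= %g\n",
              nrow(x), if (is.null(cfg)) NA else cfg$alpha))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
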