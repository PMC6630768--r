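# Chromosomal clusters of dark genes: per chromosome, proteins are sorted by
# the central nucleotide of their gene, duplicated proteins keep only their
# first occurrence, the longest run of consecutive dark proteins is scanned,
# and its p-value is the fraction of random re-orderings of the chromosome's
# labels that attain an equally long or longer run (1,000 by default, so the
# per-chromosome false-positive floor is 1/1000).

#' Per-chromosome protein order
#'
#' Sorts each chromosome's proteins by central gene position, keeps only the
#' first occurrence of a protein duplicated along one chromosome, and breaks
#' exact position ties by accession (lexicographic), so the order is a
#' deterministic function of the input.
#'
#' @param genes gene-position data frame (`accession`, `chromosome`,
#'   `central_position`).
#' @param dark named logical dark labels keyed by accession.
#' @return named list of data frames (one per chromosome, sorted by
#'   chromosome name), each with columns `accession`, `central_position`,
#'   `is_dark`.
#' @export
build_order <- function(genes, dark) {
  unknown <- setdiff(unique(genes$accession), names(dark))
  if (length(unknown))
    dp_stop("gene positions reference accession(s) without a dark label: %s",
            paste(head(unknown, 3L), collapse = ", "))
  out <- list()
  for (chr in sort(unique(genes$chromosome))) {
    g <- genes[genes$chromosome == chr, , drop = FALSE]
    g <- g[order(g$central_position, g$accession), , drop = FALSE]
    g <- g[!duplicated(g$accession), , drop = FALSE]   # first occurrence only
    out[[chr]] <- data.frame(accession = g$accession,
                             central_position = g$central_position,
                             is_dark = unname(dark[g$accession]),
                             stringsAsFactors = FALSE)
  }
  out
}

#' Longest run of dark proteins
#'
#' Maximal number of consecutive `TRUE` labels; on ties the leftmost run is
#' reported.
#'
#' @param is_dark logical vector (chromosome order).
#' @return list with `length` and `members` (indices of the run; empty when
#'   no label is dark).
#' @examples
#' longest_run(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))$length  # 3
#' @export
longest_run <- function(is_dark) {
  if (!length(is_dark) || !any(is_dark))
    return(list(length = 0L, members = integer()))
  r <- rle(as.logical(is_dark))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dark_runs <- which(r$values)
  best <- dark_runs[which.max(r$lengths[dark_runs])]   # which.max -> leftmost
  list(length = r$lengths[best], members = starts[best]:ends[best])
}

#' Permutation p-value for the longest dark run
#'
#' Shuffles the chromosome's dark/non-dark labels uniformly (preserving
#' their counts) `n_permutations` times and reports the fraction of
#' re-orderings whose longest dark run is at least as long as the observed
#' one. With the default plain count/n estimate the smallest attainable
#' nonzero false-positive rate is `1/n_permutations`; `plus_one = TRUE`
#' applies the (count+1)/(n+1) correction instead.
#'
#' @param is_dark logical label vector in chromosome order.
#' @param n_permutations number of random re-orderings (default 1000).
#' @param seed integer seed for reproducibility.
#' @param plus_one use the add-one permutation p estimate.
#' @return p-value on the grid `{0, 1/n, ..., 1}` (or the shifted grid under
#'   `plus_one`).
#' @export
permutation_pvalue <- function(is_dark, n_permutations = 1000L, seed = 1L,
                               plus_one = FALSE) {
  if (n_permutations < 1L) dp_stop("n_permutations must be >= 1")
  if (!length(is_dark)) dp_stop("empty chromosome order")
  obs <- longest_run(is_dark)$length
  if (obs == 0L) return(1)      # every permutation has run >= 0
  n <- length(is_dark)
  hits <- 0L
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (i in seq_len(n_permutations)) {
    perm <- is_dark[sample.int(n)]
    if (longest_run(perm)$length >= obs) hits <- hits + 1L
  }
  if (plus_one) (hits + 1) / (n_permutations + 1) else hits / n_permutations
}

#' Largest single-amino-acid composition of a sequence
#'
#' @param sequence amino-acid string (`NA` allowed).
#' @return percentage (0-100) of the most frequent residue, or `NA`.
#' @examples
#' composition_bias("CCCCS")  # 80
#' @export
composition_bias <- function(sequence) {
  if (is.na(sequence) || !nzchar(sequence)) return(NA_real_)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  100 * max(table(aa)) / length(aa)
}

#' Find chromosomal clusters of dark genes
#'
#' Runs the longest-run scan and permutation test on every chromosome and
#' summarises the members of each longest run: protein length, number of
#' interaction partners within the same cluster ("Binds") and the largest
#' single-amino-acid composition ("Bias", a percentage; absent when no
#' sequence is available).
#'
#' @param proteins protein universe data frame (for lengths).
#' @param genes gene-position data frame.
#' @param dark named logical dark labels keyed by accession.
#' @param links optional link table for within-cluster partner counts.
#' @param sequences optional named character vector of protein sequences.
#' @param n_permutations permutations per chromosome (default 1000).
#' @param seed integer seed; each chromosome uses an offset substream.
#' @param plus_one see [permutation_pvalue()].
#' @return a `dp_clusters` data frame (one row per chromosome: `chromosome`,
#'   `n_genes`, `n_dark`, `run_length`, `p_perm`, `n_permutations`, `seed`,
#'   `members` as a comma-joined string) with attribute `member_tables`, a
#'   named list of per-member data frames (`accession`, `length`, `binds`,
#'   `bias`).
#' @export
find_dark_clusters <- function(proteins, genes, dark, links = NULL,
                               sequences = NULL, n_permutations = 1000L,
                               seed = 1L, plus_one = FALSE) {
  orders <- build_order(genes, dark)
  len <- setNames(proteins$length, proteins$accession)
  if (!is.null(links)) links <- normalize_links(links)
  rows <- list(); member_tables <- list()
  for (i in seq_along(orders)) {
    chr <- names(orders)[i]
    ord <- orders[[i]]
    run <- longest_run(ord$is_dark)
    p <- if (nrow(ord)) {
      permutation_pvalue(ord$is_dark, n_permutations,
                         seed = seed + i - 1L, plus_one = plus_one)
    } else NA_real_
    members <- ord$accession[run$members]
    binds <- rep(NA_integer_, length(members))
    if (!is.null(links) && length(members)) {
      within <- links[links$accession_a %in% members &
                        links$accession_b %in% members, , drop = FALSE]
      binds <- vapply(members, function(a)
        sum(within$accession_a == a) + sum(within$accession_b == a), integer(1))
    }
    bias <- rep(NA_real_, length(members))
    if (!is.null(sequences) && length(members)) {
      has <- members %in% names(sequences)
      bias[has] <- vapply(sequences[members[has]], composition_bias, numeric(1))
    }
    member_tables[[chr]] <- data.frame(accession = members,
                                       length = as.integer(len[members]),
                                       binds = binds, bias = bias,
                                       stringsAsFactors = FALSE)
    rows[[i]] <- data.frame(chromosome = chr, n_genes = nrow(ord),
                            n_dark = sum(ord$is_dark),
                            run_length = run$length, p_perm = p,
                            n_permutations = as.integer(n_permutations),
                            seed = as.integer(seed + i - 1L),
                            members = paste(members, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chromosome = character(), n_genes = integer(),
                      n_dark = integer(), run_length = integer(),
                      p_perm = numeric(), n_permutations = integer(),
                      seed = integer(), members = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "member_tables") <- member_tables
  class(out) <- c("dp_clusters", "data.frame")
  out
}

#' @export
print.dp_clusters <- function(x, ...) {
  cat(sprintf("Dark gene clusters over %d chromosome(s):\n", nrow(x)))
  print.data.frame(as.data.frame(x)[, c("chromosome", "n_genes", "n_dark",
                                        "run_length", "p_perm")], digits = 4)
  invisible(x)
}
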