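# Protein autonomy from an interaction link table. m(N) is the number of
# distinct partners with combined score strictly greater than N, N on the
# integer grid [0, 900]. A protein with m(0) = 0 is fully autonomous
# (score 1); one retaining partners above 900 is fully non-autonomous
# (score 0); in between the score is 1 - N*/1000 where N* is the smallest
# grid N with m(N) = 0, i.e. the protein's maximum incident combined score.

# incident links of each accession as (partner, score) long form
incident_links <- function(links, accessions) {
  long <- data.frame(
    accession = c(links$accession_a, links$accession_b),
    partner = c(links$accession_b, links$accession_a),
    score = c(links$combined_score, links$combined_score),
    stringsAsFactors = FALSE)
  long[long$accession %in% accessions, , drop = FALSE]
}

#' Interaction counts above a confidence cutoff
#'
#' Number of distinct interaction partners of each protein with combined
#' score strictly greater than `cutoff`. Duplicate pair rows in the input
#' collapse to one partner (the table is normalised first).
#'
#' @param links link table (see [read_links()]).
#' @param accessions accessions to report (defaults to all endpoints in
#'   `links`).
#' @param cutoff integer confidence cutoff in \[0, 999\]; the conventional
#'   high-quality tier is `> 700`.
#' @return named integer vector of partner counts.
#' @export
interaction_counts <- function(links, accessions = NULL, cutoff = 700L) {
  stopifnot(cutoff >= 0, cutoff <= 999)
  links <- normalize_links(links)
  if (is.null(accessions))
    accessions <- sort(unique(c(links$accession_a, links$accession_b)))
  long <- incident_links(links[links$combined_score > cutoff, , drop = FALSE],
                         accessions)
  counts <- table(factor(long$accession, levels = accessions))
  setNames(as.integer(counts), accessions)
}

#' Partner-count function m(N)
#'
#' `m(N)` = number of distinct partners of the protein with combined score
#' strictly greater than N, evaluated on the integer grid 0..900.
#'
#' @param links link table.
#' @param accession one accession.
#' @return integer vector of length 901 (`m(0)` ... `m(900)`), non-increasing.
#' @export
m_at <- function(links, accession) {
  links <- normalize_links(links)
  long <- incident_links(links, accession)
  grid <- 0:900
  vapply(grid, function(N) sum(long$score > N), integer(1))
}

#' Autonomy score
#'
#' Scores each protein's independence from the interaction network: 1 when
#' it has no partners at any confidence (`m(0) = 0`), 0 when partners persist
#' above combined score 900 (`m(900) != 0`), and otherwise
#' `1 - N*/1000`, where `N*` is the smallest N in 0..900 with `m(N) = 0` —
#' equal to the protein's maximum incident combined score under the
#' strictly-greater-than convention. Consequently the score lies in
#' `{0}` or `[0.1, 1]`.
#'
#' @param links link table.
#' @param accessions accessions to score (defaults to all endpoints).
#' @return named numeric vector of autonomy scores in \[0,1\].
#' @examples
#' links <- data.frame(accession_a = "P1", accession_b = "P2",
#'                     combined_score = 400L)
#' autonomy_score(links, c("P1", "P3"))  # P1 = 0.6, P3 = 1
#' @export
autonomy_score <- function(links, accessions = NULL) {
  links <- normalize_links(links)
  if (is.null(accessions))
    accessions <- sort(unique(c(links$accession_a, links$accession_b)))
  long <- incident_links(links, accessions)
  smax <- tapply(long$score, factor(long$accession, levels = accessions), max)
  smax <- ifelse(is.na(smax), 0L, smax)     # no links: m(0) = 0
  score <- ifelse(smax > 900, 0, 1 - smax / 1000)
  setNames(as.numeric(score), accessions)
}

#' Per-protein autonomy table
#'
#' @param proteins protein universe data frame.
#' @param dark named logical dark labels keyed by accession.
#' @param links link table.
#' @param cutoff confidence cutoff for the reported interaction count
#'   (default 700, the high-quality tier).
#' @return a `dp_autonomy` data frame: `accession`, `is_dark`,
#'   `max_incident_score`, `autonomy`, `n_interactions`.
#' @export
autonomy_table <- function(proteins, dark, links, cutoff = 700L) {
  accs <- proteins$accession
  links <- normalize_links(links)
  long <- incident_links(links, accs)
  smax <- tapply(long$score, factor(long$accession, levels = accs), max)
  out <- data.frame(accession = accs,
                    is_dark = unname(dark[accs]),
                    max_incident_score = as.integer(ifelse(is.na(smax), NA, smax)),
                    autonomy = unname(autonomy_score(links, accs)),
                    n_interactions = unname(interaction_counts(links, accs, cutoff)),
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("dp_autonomy", "data.frame")
  out
}

#' @export
print.dp_autonomy <- function(x, ...) {
  cat(sprintf("Autonomy for %d proteins (cutoff %d): median autonomy %.2f\n",
              nrow(x), attr(x, "cutoff"), median(x$autonomy)))
  print.data.frame(head(as.data.frame(x), 10L), digits = 3)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Dark versus non-dark interaction-count distributions
#'
#' Histograms of per-protein interaction counts above a confidence cutoff,
#' split by dark label, with class medians — the comparison behind the
#' observation that dark proteins interact far less than non-dark ones.
#'
#' @param proteins protein universe data frame.
#' @param dark named logical dark labels keyed by accession.
#' @param links link table.
#' @param cutoff confidence cutoff (default 700).
#' @return list with `dark` and `nondark` count tables, `median_dark`,
#'   `median_nondark`, and `cutoff`. An empty class yields an empty histogram
#'   with a warning.
#' @export
autonomy_distribution <- function(proteins, dark, links, cutoff = 700L) {
  counts <- interaction_counts(links, proteins$accession, cutoff)
  is_d <- unname(dark[proteins$accession])
  if (!any(is_d)) warning("no dark proteins in universe", call. = FALSE)
  if (all(is_d)) warning("no non-dark proteins in universe", call. = FALSE)
  dk <- counts[is_d]; nd <- counts[!is_d]
  list(dark = table(dk), nondark = table(nd),
       median_dark = if (length(dk)) median(dk) else NA_real_,
       median_nondark = if (length(nd)) median(nd) else NA_real_,
       cutoff = cutoff)
}
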