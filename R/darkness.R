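# Residue-level darkness: a residue is "non-dark" iff it is covered by at
# least one structural coverage interval (criterion A or B, union); all other
# residues are dark. D = dark residues / length; D = 0 -> white (PDB),
# D = 1 -> dark, otherwise grey.

#' Per-residue dark mask
#'
#' Marks every residue of a protein dark unless it is covered by at least one
#' coverage interval (criterion A or criterion B; their union).
#'
#' @param length protein length in residues (positive integer).
#' @param coverage coverage data frame (columns `start`, `end`, 1-based
#'   inclusive; rows for this protein only). May have zero rows.
#' @return logical vector of length `length`; `TRUE` = dark.
#' @examples
#' residue_mask(10, data.frame(start = 3, end = 7))
#' @export
residue_mask <- function(length, coverage) {
  stopifnot(length >= 1)
  mask <- rep(TRUE, length)
  if (!is.null(coverage) && nrow(coverage)) {
    if (any(coverage$start < 1L | coverage$end > length |
            coverage$end < coverage$start))
      dp_stop("coverage interval outside [1,%d]", length)
    for (i in seq_len(nrow(coverage)))
      mask[coverage$start[i]:coverage$end[i]] <- FALSE
  }
  mask
}

#' Darkness score D
#'
#' The fraction of a protein's residues that are dark.
#'
#' @param mask logical dark mask from [residue_mask()].
#' @return D in \[0,1\].
#' @export
darkness_score <- function(mask) {
  if (length(mask) == 0L) dp_stop("empty residue mask")
  sum(mask) / length(mask)
}

#' Classify a protein by its darkness score
#'
#' Exact thresholds: `white` iff D = 0 (fully structurally covered, "PDB"),
#' `dark` iff D = 1, `grey` otherwise. No tolerance is applied.
#'
#' @param score darkness score in \[0,1\].
#' @return `"white"`, `"grey"` or `"dark"`.
#' @export
classify_darkness <- function(score) {
  stopifnot(all(score >= 0 & score <= 1))
  ifelse(score == 0, "white", ifelse(score == 1, "dark", "grey"))
}

#' Maximal runs of consecutive dark residues
#'
#' @param mask logical dark mask.
#' @param min_length minimum run length to report (default 1: a single dark
#'   residue is a run).
#' @return data frame `start`, `end` (1-based inclusive), disjoint, maximal,
#'   sorted.
#' @export
dark_runs <- function(mask, min_length = 1L) {
  r <- rle(mask)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  data.frame(start = start[keep], end = end[keep])
}

#' Darkness profiles for a protein universe
#'
#' Computes, for every protein, the dark mask summary: dark residue count,
#' darkness score D, white/grey/dark class and the number of maximal dark
#' runs.
#'
#' @param proteins protein universe data frame (see [read_proteins()]).
#' @param coverage coverage data frame (see [read_coverage()]); intervals are
#'   validated against protein lengths.
#' @return a `dp_darkness` data frame with columns `accession`, `length`,
#'   `dark_residues`, `score_D`, `class`, `n_dark_runs`.
#' @export
darkness_profiles <- function(proteins, coverage) {
  if (nrow(proteins) == 0L) dp_stop("empty protein universe")
  unknown <- setdiff(unique(coverage$accession), proteins$accession)
  if (length(unknown))
    dp_stop("coverage references unknown accession(s): %s",
            paste(unknown, collapse = ", "))
  cov_by <- split(seq_len(nrow(coverage)), coverage$accession)
  n <- nrow(proteins)
  dark <- integer(n); runs <- integer(n)
  for (i in seq_len(n)) {
    idx <- cov_by[[proteins$accession[i]]]
    m <- residue_mask(proteins$length[i],
                      if (is.null(idx)) NULL else coverage[idx, , drop = FALSE])
    dark[i] <- sum(m)
    runs[i] <- nrow(dark_runs(m))
  }
  out <- data.frame(accession = proteins$accession,
                    length = proteins$length,
                    dark_residues = dark,
                    score_D = dark / proteins$length,
                    class = classify_darkness(dark / proteins$length),
                    n_dark_runs = runs,
                    stringsAsFactors = FALSE)
  class(out) <- c("dp_darkness", "data.frame")
  out
}

#' @export
print.dp_darkness <- function(x, ...) {
  cat(sprintf("Darkness profiles for %d proteins (%d dark, %d grey, %d white)\n",
              nrow(x), sum(x$class == "dark"), sum(x$class == "grey"),
              sum(x$class == "white")))
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Dark-protein labels from profiles
#'
#' The default "dark" set is the strict D = 1 class versus all others; the
#' alternative labels a protein dark when D is at or above a threshold
#' (dark-or-grey reading).
#'
#' @param profiles a `dp_darkness` data frame.
#' @param definition `"strict_D1"` (default) or `"threshold"`.
#' @param threshold darkness threshold used when `definition = "threshold"`.
#' @return named logical vector keyed by accession.
#' @export
dark_labels <- function(profiles, definition = c("strict_D1", "threshold"),
                        threshold = 0.5) {
  definition <- match.arg(definition)
  lab <- if (definition == "strict_D1") profiles$score_D == 1
         else profiles$score_D >= threshold
  setNames(lab, profiles$accession)
}

#' Four-way residue partition of a proteome
#'
#' Splits the summed residues of a universe into four categories: residues of
#' fully dark proteins (`pct_dark_proteins`), dark residues of grey proteins
#' (`pct_dark_regions`), covered residues of grey proteins
#' (`pct_grey_regions`) and residues of white proteins (`pct_pdb_regions`).
#' All four are percentages of the total residue count and sum to 100; total
#' darkness is the sum of the first two.
#'
#' @param profiles a `dp_darkness` data frame (at least one row).
#' @return a `dp_partition` list with the four percentages, `total_darkness`
#'   and `total_residues`.
#' @examples
#' p <- data.frame(accession = c("A","B","C","D"), length = 100,
#'                 dark_residues = c(100, 0, 30, 30),
#'                 score_D = c(1, 0, .3, .3),
#'                 class = c("dark","white","grey","grey"),
#'                 n_dark_runs = c(1, 0, 1, 1))
#' class(p) <- c("dp_darkness", "data.frame")
#' proteome_partition(p)
#' @export
proteome_partition <- function(profiles) {
  if (nrow(profiles) == 0L) dp_stop("empty profile set")
  total <- sum(as.numeric(profiles$length))
  dark_p <- sum(as.numeric(profiles$length[profiles$class == "dark"]))
  white_p <- sum(as.numeric(profiles$length[profiles$class == "white"]))
  grey <- profiles$class == "grey"
  dark_r <- sum(as.numeric(profiles$dark_residues[grey]))
  grey_r <- sum(as.numeric(profiles$length[grey])) - dark_r
  out <- list(pct_dark_proteins = 100 * dark_p / total,
              pct_dark_regions = 100 * dark_r / total,
              pct_grey_regions = 100 * grey_r / total,
              pct_pdb_regions = 100 * white_p / total,
              total_residues = total)
  out$total_darkness <- out$pct_dark_proteins + out$pct_dark_regions
  class(out) <- "dp_partition"
  out
}

#' @export
print.dp_partition <- function(x, ...) {
  cat("Proteome residue partition (%):\n")
  cat(sprintf("  dark proteins: %5.1f\n  dark regions:  %5.1f\n  grey regions:  %5.1f\n  PDB regions:   %5.1f\n",
              x$pct_dark_proteins, x$pct_dark_regions,
              x$pct_grey_regions, x$pct_pdb_regions))
  cat(sprintf("  total darkness: %.1f (over %.0f residues)\n",
              x$total_darkness, x$total_residues))
  invisible(x)
}

#' @export
as.data.frame.dp_partition <- function(x, ...) {
  data.frame(pct_dark_proteins = x$pct_dark_proteins,
             pct_dark_regions = x$pct_dark_regions,
             pct_grey_regions = x$pct_grey_regions,
             pct_pdb_regions = x$pct_pdb_regions,
             total_darkness = x$total_darkness)
}
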