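# Tissue darkness: for every tissue, the fraction of dark residues among the
# residues of the proteins expressed there (nonzero normalised intensity
# after zero-filling missing measurements).

#' Replace missing expression entries by zero
#'
#' Proteins without any mass-spectrometry measurement in a tissue carry no
#' intensity; those empty entries are treated as 0. Every other value is
#' left bit-identical.
#'
#' @param expression tissue-by-accession matrix with `NA` = missing.
#' @return the same matrix with all `NA` replaced by 0.
#' @export
zero_fill <- function(expression) {
  expression[is.na(expression)] <- 0
  expression
}

#' Tissue darkness ratios
#'
#' For each tissue, the ratio of dark residues among expressed proteins:
#' with `weighting = "presence"` (default), the sum of dark residues of
#' proteins with intensity above `min_intensity` divided by the sum of their
#' lengths; with `weighting = "intensity"`, both sums are weighted by the
#' normalised intensity. Tissues are returned ranked by ratio descending,
#' ties broken by tissue name.
#'
#' @param expression zero-filled tissue-by-accession matrix (see
#'   [zero_fill()]); an error is raised if `NA` entries remain.
#' @param profiles a `dp_darkness` data frame covering every expressed
#'   accession.
#' @param weighting `"presence"` (default) or `"intensity"`.
#' @param min_intensity expression threshold; a protein counts as expressed
#'   when its intensity is strictly greater (default 0).
#' @return a `dp_tissues` data frame: `rank`, `tissue`,
#'   `ratio_dark_residues`, `n_expressed`, `weighting`. A tissue with no
#'   expressed protein gets ratio `NA` with a warning and is ranked last.
#' @export
tissue_darkness <- function(expression, profiles,
                            weighting = c("presence", "intensity"),
                            min_intensity = 0) {
  weighting <- match.arg(weighting)
  if (any(is.na(expression)))
    dp_stop("expression matrix has missing entries; apply zero_fill() first")
  accs <- colnames(expression)
  missing_prof <- setdiff(accs[colSums(expression > min_intensity) > 0],
                          profiles$accession)
  if (length(missing_prof))
    dp_stop("expressed accession(s) without darkness profile: %s",
            paste(head(missing_prof, 3L), collapse = ", "))
  dk <- setNames(as.numeric(profiles$dark_residues), profiles$accession)
  ln <- setNames(as.numeric(profiles$length), profiles$accession)
  tissues <- rownames(expression)
  ratio <- numeric(length(tissues)); nexp <- integer(length(tissues))
  for (i in seq_along(tissues)) {
    v <- expression[i, ]
    expressed <- v > min_intensity
    nexp[i] <- sum(expressed)
    if (!nexp[i]) {
      warning(sprintf("tissue '%s' has no expressed protein", tissues[i]),
              call. = FALSE)
      ratio[i] <- NA_real_
      next
    }
    a <- accs[expressed]
    w <- if (weighting == "intensity") v[expressed] else rep(1, nexp[i])
    ratio[i] <- sum(w * dk[a]) / sum(w * ln[a])
  }
  ord <- order(-ratio, tissues, na.last = TRUE)
  out <- data.frame(rank = seq_along(tissues),
                    tissue = tissues[ord],
                    ratio_dark_residues = ratio[ord],
                    n_expressed = nexp[ord],
                    weighting = weighting,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dp_tissues", "data.frame")
  out
}

#' @export
print.dp_tissues <- function(x, ...) {
  cat(sprintf("Tissue darkness ranking (%s weighting):\n", x$weighting[1]))
  print.data.frame(head(as.data.frame(x)[, 1:4], 15L), digits = 3)
  if (nrow(x) > 15L) cat(sprintf("... %d more tissues\n", nrow(x) - 15L))
  invisible(x)
}
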