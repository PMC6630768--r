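#' @importFrom stats median p.adjust rbinom rlnorm rnorm runif setNames
#' @importFrom utils read.delim write.table head packageVersion
NULL

# ---- internal helpers -------------------------------------------------------

TAXON_GROUPS <- c("archaea", "bacteria", "eukaryota", "viruses")

dp_stop <- function(...) stop(sprintf(...), call. = FALSE)

# read a mandatory-header TSV and check its columns
read_dialect <- function(path, columns) {
  if (!file.exists(path)) dp_stop("file not found: %s", path)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE,
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!identical(names(df), columns))
    dp_stop("%s: expected header '%s', got '%s'", path,
            paste(columns, collapse = "\t"), paste(names(df), collapse = "\t"))
  df
}

as_int_col <- function(x, what, path) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) | out != suppressWarnings(as.numeric(x)))
  if (length(bad))
    dp_stop("%s: non-integer %s at line %d", path, what, bad[1] + 1L)
  out
}

check_no_tabs <- function(df) {
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.character(x) && any(grepl("[\t\n]", x)))
      dp_stop("field '%s' contains tab or newline; dialect is tab-separated", nm)
  }
  invisible(df)
}

write_dialect <- function(df, path) {
  check_no_tabs(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# shared handling of accessions referenced by auxiliary tables but absent
# from the protein universe; strict failure is the default because silent
# drops would bias darkness denominators
resolve_unknown <- function(df, accessions, universe, what,
                            on_unknown = c("error", "drop")) {
  on_unknown <- match.arg(on_unknown)
  unknown <- !(accessions %in% universe)
  if (!any(unknown)) return(df)
  if (on_unknown == "error")
    dp_stop("%s references unknown accession(s): %s", what,
            paste(unique(accessions[unknown]), collapse = ", "))
  warning(sprintf("%s: dropped %d row(s) with unknown accession",
                  what, sum(unknown)), call. = FALSE)
  df[!unknown, , drop = FALSE]
}

# ---- protein universe -------------------------------------------------------

#' Read a protein universe table
#'
#' Reads the `proteins.tsv` dialect (columns `accession`, `organism`,
#' `taxon_group`, `length`; tab-separated, UTF-8, mandatory header) into a
#' validated data frame. Each row is one Swiss-Prot-style protein entry.
#'
#' @param path path to a tab-separated file.
#' @return a `data.frame` with columns `accession` (character), `organism`
#'   (character), `taxon_group` (one of `"archaea"`, `"bacteria"`,
#'   `"eukaryota"`, `"viruses"`) and `length` (positive integer, residues).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("accession\torganism\ttaxon_group\tlength",
#'              "P1\thuman\teukaryota\t100"), tf)
#' read_proteins(tf)
#' @export
read_proteins <- function(path) {
  df <- read_dialect(path, c("accession", "organism", "taxon_group", "length"))
  if (nrow(df) == 0L)
    return(data.frame(accession = character(), organism = character(),
                      taxon_group = character(), length = integer(),
                      stringsAsFactors = FALSE))
  df$length <- as_int_col(df$length, "length", path)
  bad <- which(df$length < 1L)
  if (length(bad)) dp_stop("%s: length < 1 at line %d", path, bad[1] + 1L)
  bad <- which(!df$taxon_group %in% TAXON_GROUPS)
  if (length(bad)) dp_stop("%s: unknown taxon_group '%s' at line %d",
                           path, df$taxon_group[bad[1]], bad[1] + 1L)
  dup <- duplicated(df$accession)
  if (any(dup)) dp_stop("%s: duplicate accession '%s' at line %d",
                        path, df$accession[which(dup)[1]], which(dup)[1] + 1L)
  df
}

#' @rdname read_proteins
#' @param proteins a protein data frame to serialise.
#' @export
write_proteins <- function(proteins, path) write_dialect(proteins, path)

#' Read an annotation table
#'
#' Reads the `annotations.tsv` dialect (columns `accession`, `field`,
#' `subcategory`, `text`). `field` is `DE` (description) or `FT` (sequence
#' feature); the triple (field, subcategory, text) is the enrichment unit.
#'
#' @param path path to a tab-separated file.
#' @param proteins optional protein universe; when given, annotation rows are
#'   checked against its accessions.
#' @param on_unknown `"error"` (default) or `"drop"` for rows whose accession
#'   is not in `proteins`.
#' @return data frame with columns `accession`, `field`, `subcategory`, `text`.
#' @export
read_annotations <- function(path, proteins = NULL,
                             on_unknown = c("error", "drop")) {
  df <- read_dialect(path, c("accession", "field", "subcategory", "text"))
  bad <- which(!df$field %in% c("DE", "FT"))
  if (length(bad)) dp_stop("%s: field must be DE or FT at line %d", path, bad[1] + 1L)
  bad <- which(!nzchar(df$subcategory))
  if (length(bad)) dp_stop("%s: empty subcategory at line %d", path, bad[1] + 1L)
  if (!is.null(proteins))
    df <- resolve_unknown(df, df$accession, proteins$accession,
                          "annotations", on_unknown)
  df
}

#' @rdname read_annotations
#' @param annotations an annotation data frame to serialise.
#' @export
write_annotations <- function(annotations, path) write_dialect(annotations, path)

#' Read structural coverage intervals
#'
#' Reads the `coverage.tsv` dialect (columns `accession`, `start`, `end`,
#' `criterion`, `source_id`). An interval declares residues `start..end`
#' (1-based, inclusive) of a protein structurally covered ("non-dark") under
#' criterion A (alignment onto an ATOM record of a matched structure) or
#' criterion B (alignment onto a PDB entry cross-referenced in the protein's
#' UniProt record). Intervals that overrun the protein length are an error,
#' never silently truncated.
#'
#' @param path path to a tab-separated file.
#' @param proteins the protein universe (used to validate interval bounds).
#' @param on_unknown `"error"` (default) or `"drop"` for unknown accessions.
#' @return data frame with columns `accession`, `start`, `end` (integers),
#'   `criterion` (`"A"` or `"B"`), `source_id`.
#' @export
read_coverage <- function(path, proteins = NULL,
                          on_unknown = c("error", "drop")) {
  df <- read_dialect(path, c("accession", "start", "end", "criterion", "source_id"))
  if (nrow(df) == 0L)
    return(data.frame(accession = character(), start = integer(),
                      end = integer(), criterion = character(),
                      source_id = character(), stringsAsFactors = FALSE))
  df$start <- as_int_col(df$start, "start", path)
  df$end <- as_int_col(df$end, "end", path)
  bad <- which(!df$criterion %in% c("A", "B"))
  if (length(bad)) dp_stop("%s: criterion must be A or B at line %d", path, bad[1] + 1L)
  bad <- which(df$start < 1L | df$end < df$start)
  if (length(bad)) dp_stop("%s: invalid interval [%d,%d] at line %d",
                           path, df$start[bad[1]], df$end[bad[1]], bad[1] + 1L)
  if (!is.null(proteins)) {
    df <- resolve_unknown(df, df$accession, proteins$accession,
                          "coverage", on_unknown)
    len <- setNames(proteins$length, proteins$accession)
    over <- which(df$end > len[df$accession])
    if (length(over))
      dp_stop("coverage: interval [%d,%d] exceeds length %d of %s",
              df$start[over[1]], df$end[over[1]],
              len[df$accession[over[1]]], df$accession[over[1]])
  }
  df
}

#' @rdname read_coverage
#' @param coverage a coverage data frame to serialise.
#' @export
write_coverage <- function(coverage, path) write_dialect(coverage, path)

#' Read an interaction link table
#'
#' Reads the `links.tsv` dialect (columns `accession_a`, `accession_b`,
#' `combined_score`). Scores are STRING-style combined confidence scores on
#' the integer scale 0-999 (tiers: low < 400, medium 400-700, high > 700).
#' The table is normalised to one row per undirected pair: endpoints are
#' ordered lexicographically, duplicates collapse keeping the maximum score,
#' and self-links are rejected.
#'
#' @param path path to a tab-separated file.
#' @param proteins optional protein universe for accession validation.
#' @param on_unknown `"error"` (default) or `"drop"` for unknown accessions.
#' @return data frame with columns `accession_a`, `accession_b`,
#'   `combined_score`, one row per undirected pair.
#' @export
read_links <- function(path, proteins = NULL, on_unknown = c("error", "drop")) {
  df <- read_dialect(path, c("accession_a", "accession_b", "combined_score"))
  if (nrow(df) == 0L)
    return(data.frame(accession_a = character(), accession_b = character(),
                      combined_score = integer(), stringsAsFactors = FALSE))
  df$combined_score <- as_int_col(df$combined_score, "combined_score", path)
  bad <- which(df$combined_score < 0L | df$combined_score > 999L)
  if (length(bad)) dp_stop("%s: combined_score outside [0,999] at line %d",
                           path, bad[1] + 1L)
  bad <- which(df$accession_a == df$accession_b)
  if (length(bad)) dp_stop("%s: self-link at line %d", path, bad[1] + 1L)
  if (!is.null(proteins)) {
    df <- resolve_unknown(df, df$accession_a, proteins$accession,
                          "links", on_unknown)
    df <- resolve_unknown(df, df$accession_b, proteins$accession,
                          "links", on_unknown)
  }
  normalize_links(df)
}

#' Normalise a link table to undirected form
#'
#' Orders each pair lexicographically and collapses duplicate pairs to a
#' single row keeping the maximum combined score.
#'
#' @param links data frame with columns `accession_a`, `accession_b`,
#'   `combined_score`.
#' @return normalised link data frame, sorted by endpoints.
#' @export
normalize_links <- function(links) {
  if (nrow(links) == 0L) return(links)
  a <- pmin(links$accession_a, links$accession_b)
  b <- pmax(links$accession_a, links$accession_b)
  key <- paste(a, b, sep = "\r")
  score <- tapply(links$combined_score, key, max)
  parts <- strsplit(names(score), "\r", fixed = TRUE)
  out <- data.frame(accession_a = vapply(parts, `[`, "", 1L),
                    accession_b = vapply(parts, `[`, "", 2L),
                    combined_score = as.integer(score),
                    stringsAsFactors = FALSE)
  out <- out[order(out$accession_a, out$accession_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname read_links
#' @param links a link data frame to serialise.
#' @export
write_links <- function(links, path) write_dialect(links, path)

#' Read gene positions
#'
#' Reads the `genes.tsv` dialect (columns `accession`, `chromosome`,
#' `central_position`): the chromosome and the position (bp) of the central
#' nucleotide of the gene encoding each protein.
#'
#' @param path path to a tab-separated file.
#' @param proteins optional protein universe for accession validation.
#' @param on_unknown `"error"` (default) or `"drop"`.
#' @return data frame with columns `accession`, `chromosome`,
#'   `central_position` (non-negative integer).
#' @export
read_gene_positions <- function(path, proteins = NULL,
                                on_unknown = c("error", "drop")) {
  df <- read_dialect(path, c("accession", "chromosome", "central_position"))
  if (nrow(df) == 0L)
    return(data.frame(accession = character(), chromosome = character(),
                      central_position = integer(), stringsAsFactors = FALSE))
  df$central_position <- as_int_col(df$central_position, "central_position", path)
  bad <- which(df$central_position < 0L)
  if (length(bad)) dp_stop("%s: negative central_position at line %d",
                           path, bad[1] + 1L)
  if (!is.null(proteins))
    df <- resolve_unknown(df, df$accession, proteins$accession,
                          "genes", on_unknown)
  df
}

#' @rdname read_gene_positions
#' @param genes a gene-position data frame to serialise.
#' @export
write_gene_positions <- function(genes, path) write_dialect(genes, path)

#' Read a tissue expression matrix
#'
#' Reads the `expression.tsv` dialect (long form: columns `tissue`,
#' `accession`, `normalized_intensity`) into a tissue-by-protein matrix of
#' log-scale normalised intensities. A (tissue, accession) pair absent from
#' the file is MISSING and is represented as `NA`, distinguishable from a
#' literal 0 until [zero_fill()] is applied.
#'
#' @param path path to a tab-separated file.
#' @param proteins optional protein universe; when given, the matrix gets one
#'   column per universe accession (absent pairs `NA`) and unknown accessions
#'   are handled per `on_unknown`.
#' @param on_unknown `"error"` (default) or `"drop"`.
#' @return numeric matrix, rows = tissues, columns = accessions, `NA` =
#'   missing measurement.
#' @export
read_expression <- function(path, proteins = NULL,
                            on_unknown = c("error", "drop")) {
  df <- read_dialect(path, c("tissue", "accession", "normalized_intensity"))
  df$normalized_intensity <- suppressWarnings(as.numeric(df$normalized_intensity))
  bad <- which(is.na(df$normalized_intensity))
  if (length(bad)) dp_stop("%s: non-numeric normalized_intensity at line %d",
                           path, bad[1] + 1L)
  if (!is.null(proteins))
    df <- resolve_unknown(df, df$accession, proteins$accession,
                          "expression", on_unknown)
  dup <- duplicated(df[c("tissue", "accession")])
  if (any(dup)) dp_stop("%s: duplicate (tissue, accession) pair at line %d",
                        path, which(dup)[1] + 1L)
  tissues <- sort(unique(df$tissue))
  accs <- if (is.null(proteins)) sort(unique(df$accession)) else proteins$accession
  mat <- matrix(NA_real_, nrow = length(tissues), ncol = length(accs),
                dimnames = list(tissues, accs))
  if (nrow(df)) mat[cbind(df$tissue, df$accession)] <- df$normalized_intensity
  mat
}

#' @rdname read_expression
#' @param expression a tissue-by-accession matrix (`NA` = missing) to
#'   serialise; `NA` entries are omitted from the file.
#' @export
write_expression <- function(expression, path) {
  idx <- which(!is.na(expression), arr.ind = TRUE)
  df <- data.frame(tissue = rownames(expression)[idx[, 1]],
                   accession = colnames(expression)[idx[, 2]],
                   normalized_intensity = expression[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(df$tissue, df$accession), , drop = FALSE]
  write_dialect(df, path)
}

#' Read protein sequences
#'
#' Reads the optional `sequences.tsv` dialect (columns `accession`,
#' `sequence`), used for amino-acid composition bias in cluster reports.
#'
#' @param path path to a tab-separated file.
#' @return named character vector of sequences keyed by accession.
#' @export
read_sequences <- function(path) {
  df <- read_dialect(path, c("accession", "sequence"))
  dup <- duplicated(df$accession)
  if (any(dup)) dp_stop("%s: duplicate accession at line %d", path, which(dup)[1] + 1L)
  setNames(df$sequence, df$accession)
}

#' @rdname read_sequences
#' @param sequences named character vector of sequences to serialise.
#' @export
write_sequences <- function(sequences, path) {
  write_dialect(data.frame(accession = names(sequences),
                           sequence = unname(sequences),
                           stringsAsFactors = FALSE), path)
}

# ---- UniProt flat-file (DAT) fragment adapter -------------------------------

#' Parse one UniProt flat-file (DAT) record
#'
#' Adapter for single-record ingestion of Swiss-Prot flat-file text
#' (`ID` ... `//`). Extracts the primary accession (AC line), the sequence
#' length (ID line), DE lines as description annotations, FT table rows as
#' feature annotations keyed by the feature key, and `DR PDB` lines as
#' structure cross-references with parsed chain ranges (e.g. `A=1-120`,
#' `A/B=5-60`). A `DR PDB` line whose range cannot be parsed (e.g. `-`) is
#' skipped with a warning rather than failing the record.
#'
#' @param text a character scalar (the whole record) or character vector of
#'   lines.
#' @return an object of class `protein_record`: a list with elements
#'   `accession`, `length`, `annotations` (data frame `field`, `subcategory`,
#'   `text`) and `pdb_crossrefs` (data frame `structure_id`, `chain`, `start`,
#'   `end`; 1-based inclusive residue intervals).
#' @examples
#' rec <- parse_uniprot_dat(c(
#'   "ID   TEST_HUMAN              Reviewed;         100 AA.",
#'   "AC   P00001;",
#'   "DE   RecName: Full=Test protein;",
#'   "DR   PDB; 1ABC; X-ray; 2.00 A; A=5-60.",
#'   "//"))
#' rec$pdb_crossrefs
#' @export
parse_uniprot_dat <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  id_line <- grep("^ID   ", lines, value = TRUE)
  if (!length(id_line)) dp_stop("DAT record has no ID line")
  m <- regmatches(id_line[1], regexec("(\\d+)\\s+AA\\.?\\s*$", id_line[1]))[[1]]
  if (length(m) < 2L) dp_stop("cannot parse sequence length from ID line")
  len <- as.integer(m[2])
  ac_line <- grep("^AC   ", lines, value = TRUE)
  if (!length(ac_line)) dp_stop("DAT record has no AC line")
  acc <- sub(";.*$", "", sub("^AC   ", "", ac_line[1]))
  acc <- trimws(acc)

  ann <- list()
  for (l in grep("^DE   ", lines, value = TRUE)) {
    body <- sub("^DE   ", "", l)
    subcat <- trimws(sub(":.*$", "", body))
    txt <- if (grepl(":", body)) trimws(sub("^[^:]*:", "", body)) else ""
    txt <- sub(";\\s*$", "", txt)
    ann[[length(ann) + 1L]] <- c("DE", subcat, txt)
  }
  # FT table: key rows start at column 6; continuation rows are further indented
  for (l in grep("^FT   \\S", lines, value = TRUE)) {
    body <- sub("^FT   ", "", l)
    key <- sub("\\s.*$", "", body)
    txt <- trimws(sub("^\\S+\\s*", "", body))
    ann[[length(ann) + 1L]] <- c("FT", key, txt)
  }
  annotations <- if (length(ann)) {
    data.frame(field = vapply(ann, `[`, "", 1L),
               subcategory = vapply(ann, `[`, "", 2L),
               text = vapply(ann, `[`, "", 3L), stringsAsFactors = FALSE)
  } else {
    data.frame(field = character(), subcategory = character(),
               text = character(), stringsAsFactors = FALSE)
  }

  xref <- list()
  for (l in grep("^DR   PDB;", lines, value = TRUE)) {
    parts <- trimws(strsplit(sub("^DR   ", "", l), ";", fixed = TRUE)[[1]])
    sid <- parts[2]
    range_field <- sub("\\.$", "", parts[length(parts)])
    pieces <- trimws(strsplit(range_field, ",", fixed = TRUE)[[1]])
    ok <- FALSE
    for (p in pieces) {
      m <- regmatches(p, regexec("^([A-Za-z0-9/]+)=(\\d+)-(\\d+)$", p))[[1]]
      if (length(m) == 4L) {
        chains <- strsplit(m[2], "/", fixed = TRUE)[[1]]
        s <- as.integer(m[3]); e <- as.integer(m[4])
        if (s >= 1L && s <= e && e <= len) {
          for (ch in chains)
            xref[[length(xref) + 1L]] <- list(sid, ch, s, e)
          ok <- TRUE
        }
      }
    }
    if (!ok)
      warning(sprintf("skipping DR PDB line with unparseable range: %s", l),
              call. = FALSE)
  }
  pdb_crossrefs <- if (length(xref)) {
    data.frame(structure_id = vapply(xref, function(x) x[[1]], ""),
               chain = vapply(xref, function(x) x[[2]], ""),
               start = vapply(xref, function(x) x[[3]], 1L),
               end = vapply(xref, function(x) x[[4]], 1L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(structure_id = character(), chain = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  }

  structure(list(accession = acc, length = len, annotations = annotations,
                 pdb_crossrefs = pdb_crossrefs),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa), %d annotation(s), %d PDB cross-ref(s)\n",
              x$accession, x$length, nrow(x$annotations), nrow(x$pdb_crossrefs)))
  invisible(x)
}

#' Criterion-B coverage intervals from a parsed UniProt record
#'
#' Converts the `DR PDB` chain ranges of a parsed record into coverage
#' intervals under criterion B (residues aligned onto a PDB entry
#' cross-referenced in the UniProt record).
#'
#' @param record a `protein_record` from [parse_uniprot_dat()].
#' @return a coverage data frame (`accession`, `start`, `end`, `criterion`,
#'   `source_id`).
#' @export
crossref_coverage <- function(record) {
  x <- record$pdb_crossrefs
  data.frame(accession = rep(record$accession, nrow(x)),
             start = x$start, end = x$end,
             criterion = rep("B", nrow(x)),
             source_id = x$structure_id, stringsAsFactors = FALSE)
}

# ---- treemap export ---------------------------------------------------------

#' Write an enrichment treemap as JSON
#'
#' Serialises enrichment results as the nested structure used for
#' significance treemaps: category (annotation field) -> subcategory ->
#' annotation leaf. Each leaf carries `label`, `area` = -log10(adjusted p)
#' and `direction` (`"over"` or `"under"`, by the odds ratio). Leaves whose
#' area falls below the readability cutoff are excluded. An adjusted p of
#' exactly 0 (underflow) maps to a finite area cap so that areas stay
#' finite. Keys are emitted in deterministic (sorted) order.
#'
#' @param results an enrichment result data frame (see [enrich()]), needing
#'   columns `field`, `subcategory`, `annotation`, `adjusted_p`, `direction`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @param cutoff readability cutoff on -log10(adjusted p); leaves strictly
#'   below it are dropped (default 0 keeps everything with positive area).
#' @param area_cap area assigned when `adjusted_p == 0` (default 320,
#'   roughly -log10 of the smallest positive double).
#' @return invisibly, the JSON string.
#' @export
write_treemap_json <- function(results, path = NULL, cutoff = 0, area_cap = 320) {
  stopifnot(cutoff >= 0, area_cap > 0)
  if (nrow(results)) {
    area <- ifelse(results$adjusted_p == 0, area_cap,
                   pmin(-log10(results$adjusted_p), area_cap))
    keep <- area >= cutoff & area > 0
    results <- results[keep, , drop = FALSE]
    area <- area[keep]
  } else {
    area <- numeric()
  }
  cats <- list()
  for (f in sort(unique(results$field))) {
    sel <- results$field == f
    subs <- list()
    for (s in sort(unique(results$subcategory[sel]))) {
      sel2 <- sel & results$subcategory == s
      ord <- order(results$annotation[sel2])
      leaves <- lapply(which(sel2)[ord], function(i)
        list(label = results$annotation[i], area = area[i],
             direction = results$direction[i]))
      subs[[length(subs) + 1L]] <- list(subcategory = s, leaves = leaves)
    }
    cats[[length(cats) + 1L]] <- list(category = f, subcategories = subs)
  }
  doc <- list(n_leaves = if (nrow(results)) nrow(results) else 0L,
              cutoff = cutoff, categories = cats)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(json, path)
  invisible(as.character(json))
}
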