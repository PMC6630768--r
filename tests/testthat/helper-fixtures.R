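# in-code fixtures shared across test files

make_proteins <- function(n = 4L, lengths = rep(100L, n),
                          taxon = "eukaryota") {
  data.frame(accession = sprintf("P%02d", seq_len(n)),
             organism = "test", taxon_group = taxon,
             length = as.integer(lengths), stringsAsFactors = FALSE)
}

cov_row <- function(acc, start, end, criterion = "A", source = "s1") {
  data.frame(accession = acc, start = as.integer(start),
             end = as.integer(end), criterion = criterion,
             source_id = source, stringsAsFactors = FALSE)
}

link_row <- function(a, b, score) {
  data.frame(accession_a = a, accession_b = b,
             combined_score = as.integer(score), stringsAsFactors = FALSE)
}

write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# a minimal Swiss-Prot style flat-file record used by the DAT adapter tests
DAT_FIXTURE <- c(
  "ID   TEST1_HUMAN             Reviewed;         100 AA.",
  "AC   P99901; Q00001;",
  "DE   RecName: Full=Synthetic test protein 1;",
  "DE   AltName: Full=Fixture protein;",
  "DR   PDB; 1ABC; X-ray; 2.00 A; A=5-60.",
  "FT   TRANSMEM        10..30",
  "FT   TRANSMEM        40..62",
  "//")

# exhaustive-window longest-run oracle (cumulative sums over every window;
# independent of the rle-based implementation)
window_longest_run <- function(x) {
  n <- length(x)
  if (!n) return(0L)
  cs <- c(0L, cumsum(as.integer(x)))
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  ok <- j >= i & (cs[j + 1L] - cs[i]) == (j - i + 1L)
  if (any(ok)) max((j - i + 1L)[ok]) else 0L
}

# brute-force per-residue membership darkness mask
membership_mask <- function(len, cov) {
  vapply(seq_len(len), function(r)
    !any(cov$start <= r & r <= cov$end), logical(1))
}
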