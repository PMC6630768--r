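test_that("protein reader handles empty files, round-trips rows, rejects bad input", {
  hdr <- "accession\torganism\ttaxon_group\tlength"
  expect_equal(nrow(read_proteins(write_tsv_lines(hdr))), 0L)

  tf <- write_tsv_lines(c(hdr, "P1\thuman\teukaryota\t100",
                          "P2\thuman\teukaryota\t55",
                          "P3\thuman\teukaryota\t7"))
  p <- read_proteins(tf)
  expect_equal(p$accession, c("P1", "P2", "P3"))
  expect_equal(p$length, c(100L, 55L, 7L))

  expect_error(read_proteins(write_tsv_lines(c(hdr, "P1\th\teukaryota\t0"))),
               "line 2")
  expect_error(read_proteins(write_tsv_lines(c(hdr, "P1\th\teukaryota\t10",
                                               "P1\th\teukaryota\t20"))),
               "duplicate accession")
  expect_error(read_proteins(write_tsv_lines(c(hdr, "P1\th\tplantae\t10"))),
               "taxon_group")
  expect_error(read_proteins(write_tsv_lines("wrong\theader")), "header")
})

test_that("coverage reader validates intervals against protein lengths", {
  prot <- make_proteins(1, lengths = 10L)
  prot$accession <- "P1"
  hdr <- "accession\tstart\tend\tcriterion\tsource_id"
  ok <- read_coverage(write_tsv_lines(c(hdr, "P1\t3\t7\tA\ts1")), prot)
  expect_equal(ok$start, 3L)
  expect_error(read_coverage(write_tsv_lines(c(hdr, "P1\t3\t12\tA\ts1")), prot),
               "exceeds length")
  expect_error(read_coverage(write_tsv_lines(c(hdr, "P1\t0\t5\tA\ts1")), prot),
               "invalid interval")
  expect_error(read_coverage(write_tsv_lines(c(hdr, "P1\t3\t7\tC\ts1")), prot),
               "criterion")
  # unknown accessions fail fast by default, drop with warning on request
  expect_error(read_coverage(write_tsv_lines(c(hdr, "PX\t3\t7\tA\ts1")), prot),
               "unknown accession")
  expect_warning(
    dropped <- read_coverage(write_tsv_lines(c(hdr, "PX\t3\t7\tA\ts1")),
                             prot, on_unknown = "drop"),
    "dropped")
  expect_equal(nrow(dropped), 0L)
})

test_that("link reader enforces the score range and normalises undirected pairs", {
  hdr <- "accession_a\taccession_b\tcombined_score"
  expect_error(read_links(write_tsv_lines(c(hdr, "P1\tP2\t1000"))), "0,999")
  expect_error(read_links(write_tsv_lines(c(hdr, "P1\tP1\t500"))), "self-link")
  l <- read_links(write_tsv_lines(c(hdr, "P2\tP1\t500", "P1\tP2\t700",
                                    "P1\tP3\t200")))
  expect_equal(nrow(l), 2L)            # duplicate pair collapsed
  expect_equal(l$combined_score[l$accession_b == "P2"], 700L)  # max kept
  expect_true(all(l$accession_a < l$accession_b))
})

test_that("expression reader distinguishes missing from zero until zero_fill", {
  prot <- make_proteins(3)
  hdr <- "tissue\taccession\tnormalized_intensity"
  m <- read_expression(write_tsv_lines(c(hdr, "heart\tP01\t5.5",
                                         "heart\tP02\t0",
                                         "brain\tP01\t2.0")), prot)
  expect_true(is.na(m["heart", "P03"]))
  expect_identical(m["heart", "P02"], 0)      # literal zero preserved
  filled <- zero_fill(m)
  expect_false(anyNA(filled))
  expect_identical(filled["heart", "P01"], 5.5)
})

test_that("every dialect round-trips a simulated bundle exactly", {
  b <- simulate_universe(
    universe_spec(n_proteins = 60, seed = 11),
    planted_signals(
      enriched_annotations = data.frame(
        field = "DE", subcategory = "SUBCELLULAR LOCATION",
        text = "Cell membrane", odds_ratio = 4, prevalence_nondark = 0.2),
      tissue_targets = data.frame(tissue = "heart", target_dark_ratio = 0.5)))
  dir <- tempfile()
  paths <- write_bundle(b, dir)
  expect_identical(read_proteins(paths["proteins"]), b$proteins)
  expect_identical(read_annotations(paths["annotations"], b$proteins),
                   b$annotations)
  expect_identical(read_coverage(paths["coverage"], b$proteins), b$coverage)
  expect_identical(read_links(paths["links"], b$proteins), b$links)
  expect_identical(read_gene_positions(paths["genes"], b$proteins)[
    order(b$genes$chromosome, b$genes$central_position), ]$accession,
    b$genes$accession)
  expect_identical(read_sequences(paths["sequences"]), b$sequences)
  m <- read_expression(paths["expression"], b$proteins)
  expect_identical(m[rownames(b$expression), colnames(b$expression),
                     drop = FALSE],
                   b$expression)
})

test_that("DAT fragment parsing extracts accession, length, DE/FT annotations and PDB ranges", {
  rec <- parse_uniprot_dat(DAT_FIXTURE)
  expect_equal(rec$accession, "P99901")
  expect_equal(rec$length, 100L)
  # hand-parse of the fixture: one cross-ref with chain A residues 5-60
  expect_equal(nrow(rec$pdb_crossrefs), 1L)
  expect_equal(rec$pdb_crossrefs$structure_id, "1ABC")
  expect_equal(rec$pdb_crossrefs$start, 5L)
  expect_equal(rec$pdb_crossrefs$end, 60L)
  ft <- rec$annotations[rec$annotations$field == "FT", ]
  expect_equal(ft$subcategory, c("TRANSMEM", "TRANSMEM"))
  de <- rec$annotations[rec$annotations$field == "DE", ]
  expect_equal(de$subcategory, c("RecName", "AltName"))
  expect_match(de$text[1], "Synthetic test protein 1")

  cov <- crossref_coverage(rec)
  expect_equal(cov$criterion, "B")
  expect_equal(cov[, c("start", "end")], data.frame(start = 5L, end = 60L))

  no_dr <- parse_uniprot_dat(DAT_FIXTURE[-5])
  expect_equal(nrow(no_dr$pdb_crossrefs), 0L)

  bad <- DAT_FIXTURE
  bad[5] <- "DR   PDB; 2XYZ; NMR; -; -."
  expect_warning(rec2 <- parse_uniprot_dat(bad), "unparseable")
  expect_equal(nrow(rec2$pdb_crossrefs), 0L)

  expect_error(parse_uniprot_dat(c("AC   P1;", "//")), "ID line")
})

test_that("DAT fixture file in extdata parses identically to the inline record", {
  path <- system.file("extdata", "synthetic_record.dat",
                      package = "darkproteome")
  expect_true(nzchar(path))
  rec <- parse_uniprot_dat(readLines(path))
  expect_equal(rec$accession, "P99901")
  expect_equal(rec$pdb_crossrefs$end, 60L)
})

test_that("treemap export applies areas, caps and cutoffs deterministically", {
  empty <- data.frame(field = character(), subcategory = character(),
                      annotation = character(), adjusted_p = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
  doc <- jsonlite::fromJSON(write_treemap_json(empty), simplifyVector = FALSE)
  expect_equal(doc$n_leaves, 0L)

  res <- data.frame(field = c("DE", "DE", "FT"),
                    subcategory = c("s1", "s1", "s2"),
                    annotation = c("leaf a", "leaf b", "leaf c"),
                    adjusted_p = c(1e-10, 1e-60, 0),
                    direction = c("over", "under", "over"),
                    stringsAsFactors = FALSE)
  doc <- jsonlite::fromJSON(write_treemap_json(res), simplifyVector = FALSE)
  leaves <- doc$categories[[1]]$subcategories[[1]]$leaves
  expect_equal(leaves[[1]]$area, 10)              # -log10(1e-10)
  expect_equal(leaves[[2]]$area, 60)
  expect_equal(doc$categories[[2]]$subcategories[[1]]$leaves[[1]]$area, 320)

  # readability cutoff 50 drops the area-10 leaf
  doc50 <- jsonlite::fromJSON(write_treemap_json(res, cutoff = 50),
                              simplifyVector = FALSE)
  expect_equal(doc50$n_leaves, 2L)
  labels <- unlist(lapply(doc50$categories, function(cat)
    lapply(cat$subcategories, function(s)
      lapply(s$leaves, `[[`, "label"))))
  expect_false("leaf a" %in% labels)

  # all areas finite and non-negative even at p = 0
  areas <- unlist(lapply(doc$categories, function(cat)
    lapply(cat$subcategories, function(s) lapply(s$leaves, `[[`, "area"))))
  expect_true(all(is.finite(areas) & areas >= 0))
})
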