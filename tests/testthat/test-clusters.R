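test_that("chromosome orders sort by position, deduplicate and break ties deterministically", {
  genes <- data.frame(
    accession = c("P03", "P01", "P01", "P02", "P04"),
    chromosome = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    central_position = c(500L, 100L, 900L, 500L, 10L),
    stringsAsFactors = FALSE)
  dark <- setNames(rep(TRUE, 4), sprintf("P%02d", 1:4))
  ord <- build_order(genes, dark)
  # P01 duplicated at 100 and 900: first occurrence kept
  expect_equal(ord$chr1$accession, c("P01", "P02", "P03"))
  expect_equal(ord$chr1$central_position[1], 100L)
  # equal positions 500: lexicographic accession order
  expect_equal(ord$chr1$accession[2:3], c("P02", "P03"))
  expect_equal(ord$chr2$accession, "P04")
  expect_length(build_order(genes[0, ], dark), 0L)
})

test_that("longest run scans match direct expectations and the leftmost-tie rule", {
  expect_equal(longest_run(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))$length, 3L)
  expect_equal(longest_run(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))$members, 4:6)
  expect_equal(longest_run(rep(FALSE, 6))$length, 0L)
  expect_equal(longest_run(logical(0))$length, 0L)
  # tie between runs 1:2 and 4:5 -> leftmost
  expect_equal(longest_run(c(TRUE, TRUE, FALSE, TRUE, TRUE))$members, 1:2)
})

test_that("longest run equals the exhaustive window oracle on random vectors", {
  set.seed(17)
  for (i in 1:200) {
    x <- runif(sample(1:15, 1)) < 0.4
    expect_identical(longest_run(x)$length, window_longest_run(x))
  }
})

test_that("permutation p-values are reproducible, grid-valued and correct at the edges", {
  expect_equal(permutation_pvalue(rep(TRUE, 10), 100, seed = 1), 1)
  expect_equal(permutation_pvalue(rep(FALSE, 10), 100, seed = 1), 1)
  set.seed(123)
  lab <- runif(60) < 0.3
  p1 <- permutation_pvalue(lab, 500, seed = 42)
  p2 <- permutation_pvalue(lab, 500, seed = 42)
  expect_identical(p1, p2)
  expect_true(p1 %in% seq(0, 1, by = 1 / 500))
  # add-one variant lives on the shifted grid and never reaches zero
  pp <- permutation_pvalue(lab, 500, seed = 42, plus_one = TRUE)
  expect_gte(pp, 1 / 501)
  expect_error(permutation_pvalue(lab, 0), "n_permutations")
  expect_error(permutation_pvalue(logical(0)), "empty")
})

test_that("removing later copies of duplicated dark proteins never lengthens the run", {
  set.seed(31)
  for (i in 1:30) {
    dark <- setNames(runif(12) < 0.5, sprintf("P%02d", 1:12))
    base <- sprintf("P%02d", sample(1:12))
    dup_pool <- names(dark)[dark]          # gene duplication of dark proteins
    accs <- c(base, sample(dup_pool, sample(1:3, 1)))
    genes <- data.frame(accession = accs, chromosome = "chr1",
                        central_position = sample(1e6, length(accs)),
                        stringsAsFactors = FALSE)
    with_dup <- genes[order(genes$central_position, genes$accession), ]
    run_dup <- longest_run(unname(dark[with_dup$accession]))$length
    run_dedup <- longest_run(build_order(genes, dark)$chr1$is_dark)$length
    expect_lte(run_dedup, run_dup)
  }
})

test_that("composition bias reports the largest single-amino-acid share", {
  expect_equal(composition_bias("CCCCS"), 80)
  expect_equal(composition_bias("KKKKKKK"), 100)
  expect_true(is.na(composition_bias(NA_character_)))
})

test_that("find_dark_clusters summarises runs with lengths, within-cluster partners and bias", {
  prot <- make_proteins(6, lengths = c(100L, 80L, 60L, 90L, 70L, 50L))
  genes <- data.frame(accession = prot$accession, chromosome = "chr1",
                      central_position = seq(100L, 600L, by = 100L),
                      stringsAsFactors = FALSE)
  dark <- setNames(c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE), prot$accession)
  links <- rbind(link_row("P02", "P03", 800),   # within cluster
                 link_row("P02", "P05", 900))   # outside cluster
  seqs <- setNames(c("AAAA", "CCCCS", "DEDED", "KKKKKKK", "AA", "AA"),
                   prot$accession)
  cl <- find_dark_clusters(prot, genes, dark, links = links,
                           sequences = seqs, n_permutations = 200, seed = 5)
  expect_equal(cl$run_length, 3L)
  expect_equal(cl$members, "P02,P03,P04")
  mt <- attr(cl, "member_tables")$chr1
  expect_equal(mt$length, c(80L, 60L, 90L))
  expect_equal(mt$binds, c(1L, 1L, 0L))        # P02-P05 link is outside
  expect_equal(mt$bias, c(80, 60, 100))
  # isolated cluster members have zero binds; missing sequence gives NA bias
  cl2 <- find_dark_clusters(prot, genes, dark, links = NULL,
                            sequences = seqs["P02"], n_permutations = 50,
                            seed = 5)
  mt2 <- attr(cl2, "member_tables")$chr1
  expect_equal(mt2$bias, c(80, NA, NA))
})

test_that("a planted dark run in a sparse chromosome is detected as improbable", {
  b <- simulate_universe(
    universe_spec(n_proteins = 500,
                  class_fractions = c(dark = 0.05, grey = 0.15, white = 0.8),
                  seed = 29),
    planted_signals(n_chromosomes = 1L,
                    clusters = data.frame(chromosome = "chr1",
                                          start_index = 100L,
                                          run_length = 10L)))
  prof <- darkness_profiles(b$proteins, b$coverage)
  cl <- find_dark_clusters(b$proteins, b$genes, dark_labels(prof),
                           n_permutations = 1000, seed = 2)
  expect_gte(cl$run_length, 10L)
  expect_lte(cl$p_perm, 0.005)
})
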