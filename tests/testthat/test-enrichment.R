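test_that("contingency tables count protein-level presence against class margins", {
  dark <- setNames(c(rep(TRUE, 4), rep(FALSE, 6)), sprintf("P%02d", 1:10))
  ann <- data.frame(accession = c("P01", "P02", "P03", "P05", "P01"),
                    field = "DE", subcategory = "LOC",
                    text = "membrane", stringsAsFactors = FALSE)
  tab <- build_tables(ann, dark)      # held by 3 dark, 1 non-dark; P01 repeated
  expect_equal(tab$dark_with, 3L)
  expect_equal(tab$dark_without, 1L)
  expect_equal(tab$nondark_with, 1L)
  expect_equal(tab$nondark_without, 5L)

  held_by_all <- data.frame(accession = names(dark), field = "FT",
                            subcategory = "chain", text = "x",
                            stringsAsFactors = FALSE)
  tab2 <- build_tables(held_by_all, dark)
  expect_equal(unlist(tab2[, c("dark_with", "dark_without", "nondark_with",
                               "nondark_without")], use.names = FALSE),
               c(4L, 0L, 6L, 0L))

  expect_equal(nrow(build_tables(ann[0, ], dark)), 0L)   # held by nobody
  expect_error(build_tables(data.frame(accession = "PX", field = "DE",
                                       subcategory = "s", text = "t"), dark),
               "without a dark label")
})

test_that("Fisher exact matches frozen enumeration values and fisher.test", {
  r <- fisher_exact(5, 5, 5, 5)
  expect_equal(r$p, 1)
  expect_equal(r$odds_ratio, 1)

  # frozen from exhaustive hypergeometric enumeration of the 11 tables
  # sharing the margins of (8,2,2,8)
  expect_equal(fisher_exact(8, 2, 2, 8)$p, 0.023014137565221134,
               tolerance = 1e-14)

  deg <- fisher_exact(4, 0, 6, 0)     # degenerate margin, no overflow
  expect_equal(deg$p, 1)
  expect_equal(deg$odds_ratio, 1)     # both cross-products vanish
  expect_equal(fisher_exact(4, 0, 6, 1)$odds_ratio, Inf)  # only denominator 0

  set.seed(5)
  for (i in 1:25) {
    cells <- as.numeric(sample(0:40, 4, replace = TRUE))
    if (sum(cells) == 0) next
    ours <- fisher_exact(cells[1], cells[2], cells[3], cells[4])$p
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-10)
  }
  expect_error(fisher_exact(0, 0, 0, 0), "zero")
  expect_error(fisher_exact(-1, 1, 1, 1), "negative")
})

test_that("BH adjustment reproduces hand-computed step-up values and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03))$p_adjusted, c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(1.0)$p_adjusted, 1.0)
  r <- bh_adjust(c(0.5, 0.5))          # ties: n/k factors 2 then 1
  expect_equal(r$p_adjusted, c(0.5, 0.5))
  expect_equal(r$rank_k, c(1L, 1L))    # ties share the first rank
  # hand-computed: sorted (.01,.04,.9) -> candidates .03,.06,.9; monotone min
  expect_equal(bh_adjust(c(0.9, 0.01, 0.04))$p_adjusted, c(0.9, 0.03, 0.06))

  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)$p_adjusted
    expect_true(all(adj >= p))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-15))   # monotone in raw p
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0,1")
})

test_that("enrich recovers a planted over-represented annotation and honours exclusions", {
  b <- simulate_universe(
    universe_spec(n_proteins = 2000, seed = 21),
    planted_signals(
      enriched_annotations = data.frame(
        field = "DE", subcategory = "SUBCELLULAR LOCATION",
        text = "Cell membrane", odds_ratio = 8, prevalence_nondark = 0.05),
      n_null_annotations = 5))
  prof <- darkness_profiles(b$proteins, b$coverage)
  dark <- dark_labels(prof)
  res <- enrich(b$proteins, b$annotations, dark)
  hit <- res[res$annotation == "Cell membrane", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$direction, "over")
  expect_gt(hit$odds_ratio, 1)
  expect_true(all(diff(res$adjusted_p) >= 0))    # Tables-style ordering

  # excluded subcategories never reach the output
  ann2 <- rbind(b$annotations,
                data.frame(accession = b$proteins$accession[1:50],
                           field = "DE", subcategory = "SIMILARITY",
                           text = "Belongs to fixture family",
                           stringsAsFactors = FALSE))
  res2 <- enrich(b$proteins, ann2, dark)
  expect_false(any(res2$subcategory == "SIMILARITY"))
})

test_that("DE and FT families are corrected separately", {
  # one DE and one FT annotation with identical counts must get identical
  # adjusted p even when the other family carries many more tests
  dark <- setNames(rep(c(TRUE, FALSE), each = 30), sprintf("P%02d", 1:60))
  accs_with <- sprintf("P%02d", c(1:12, 31:33))
  base <- rbind(
    data.frame(accession = accs_with, field = "DE", subcategory = "LOC",
               text = "planted", stringsAsFactors = FALSE),
    data.frame(accession = accs_with, field = "FT", subcategory = "transmem",
               text = "planted", stringsAsFactors = FALSE))
  extra_de <- do.call(rbind, lapply(1:6, function(j)
    data.frame(accession = sprintf("P%02d", seq(j, 60, by = 7)),
               field = "DE", subcategory = "LOC",
               text = sprintf("filler %d", j), stringsAsFactors = FALSE)))
  cfg <- enrichment_config(alpha = 0.999)
  res <- enrich(make_proteins(60), rbind(base, extra_de), dark, cfg)
  de_p <- res$adjusted_p[res$field == "DE" & res$annotation == "planted"]
  ft_p <- res$adjusted_p[res$field == "FT" & res$annotation == "planted"]
  expect_equal(res$fisher_p[res$field == "DE" & res$annotation == "planted"],
               res$fisher_p[res$field == "FT" & res$annotation == "planted"])
  # same raw p, but the DE family has 7 tests and FT only 1
  expect_gte(de_p, ft_p)
  expect_equal(ft_p, res$fisher_p[res$field == "FT" &
                                    res$annotation == "planted"])
})

test_that("configuration validation rejects alpha outside (0,1)", {
  expect_error(enrichment_config(alpha = 1.5), "alpha")
  expect_error(enrichment_config(alpha = 0), "alpha")
  expect_silent(enrichment_config(alpha = 0.05))
})
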