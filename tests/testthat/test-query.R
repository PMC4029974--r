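d6 <- toy6()

test_that("prefilters reproduce the hand-derived TOY6 counts", {
  fs0 <- apply_prefilters(d6, list())
  expect_equal(fs0$total, 5)
  expect_equal(nrow(fs0$result$interactions), 5)

  fs1 <- apply_prefilters(d6, list("protein.organism equals B"))
  expect_equal(fs1$steps$count, 2)
  expect_setequal(paste(fs1$result$interactions$a, fs1$result$interactions$b),
                  c("P3 P4", "P4 P5"))

  fs2 <- apply_prefilters(d6, list("protein.organism equals B",
                                   "interaction.score ge 0.6"))
  expect_equal(fs2$steps$count, c(2, 1))
  expect_equal(paste(fs2$result$interactions$a, fs2$result$interactions$b), "P3 P4")

  # either-endpoint semantics on a text contains filter
  fs3 <- apply_prefilters(d6, list("protein.description contains sensor"))
  expect_equal(fs3$steps$count, 4)

  # both-endpoints switch
  fs4 <- apply_prefilters(d6, list("protein.description contains sensor"),
                          protein_match = "both")
  expect_equal(fs4$steps$count, 1)

  fs5 <- apply_prefilters(d6, list("interaction.string present"))
  expect_equal(fs5$steps$count, 1)
})

test_that("unknown filter fields raise an error listing available fields", {
  expect_error(apply_prefilters(d6, list("protein.nope equals x")), "organism")
  expect_error(apply_prefilters(d6, list("interaction.nope gt 1")), "score")
})

test_that("cumulative prefilter counts are non-increasing and match the oracle", {
  for (seed in 1:6) {
    g <- rand_ppi(20, seed = seed, expression = TRUE)
    conds <- list(
      filter_condition("protein", "organism", "equals", "ORG1"),
      filter_condition("interaction", "score", "ge", 0.3),
      filter_condition("interaction", "evidence1", "present"),
      filter_condition("protein", "description", "contains", "kin"))
    fs <- apply_prefilters(g, conds)
    expect_true(all(diff(c(fs$total, fs$steps$count)) <= 0))
    expect_equal(fs$steps$count, oracle_filter_count(g, conds))
  }
})

test_that("search modes match their definitions on TOY6", {
  s1 <- search_network(d6, "P1", "normal")
  expect_setequal(s1$proteins, c("P1", "P2", "P3"))
  expect_setequal(paste(s1$interactions$a, s1$interactions$b),
                  c("P1 P2", "P1 P3"))

  s2 <- search_network(d6, c("P1", "P4"), "explicit")
  expect_setequal(s2$proteins, c("P1", "P4"))
  expect_equal(nrow(s2$interactions), 0)

  s3 <- search_network(d6, "P3", "recursive")
  expect_setequal(s3$proteins, c("P1", "P2", "P3", "P4"))
  expect_setequal(paste(s3$interactions$a, s3$interactions$b),
                  c("P1 P2", "P1 P3", "P2 P3", "P3 P4"))
})

test_that("explicit mode links queried proteins to already displayed ones", {
  disp <- search_network(d6, "P1", "normal")   # P1,P2,P3 displayed
  s <- search_network(d6, "P4", "explicit", displayed = disp)
  expect_true("P3|P4" %in% paste(s$interactions$a, s$interactions$b, sep = "|"))
  # additive: everything previously displayed is still there
  expect_true(all(disp$proteins %in% s$proteins))
})

test_that("unknown and empty queries warn instead of failing", {
  s <- search_network(d6, c("P1", "ZZZ"), "normal")
  expect_match(attr(s, "warnings"), "ZZZ")
  expect_true("P1" %in% s$proteins)

  disp <- search_network(d6, "P1", "normal")
  s2 <- search_network(d6, character(0), "normal", displayed = disp)
  expect_setequal(s2$proteins, disp$proteins)
  expect_match(attr(s2, "warnings"), "empty query")
})

test_that("search results are closed and idempotent", {
  for (seed in 1:5) {
    g <- rand_ppi(30, seed = seed)
    q <- g$proteins$accession[c(1, 5, 9)]
    for (mode in c("normal", "explicit", "recursive")) {
      s <- search_network(g, q, mode)
      expect_true(all(c(s$interactions$a, s$interactions$b) %in% s$proteins))
      s2 <- search_network(g, q, mode, displayed = s)
      expect_setequal(s2$proteins, s$proteins)
      expect_setequal(edge_key(s2$interactions$a, s2$interactions$b),
                      edge_key(s$interactions$a, s$interactions$b))
    }
  }
})

test_that("autocomplete matches prefixes case-insensitively, sorted and truncated", {
  expect_equal(autocomplete(d6, "P", 10)$accession, paste0("P", 1:6))
  expect_equal(autocomplete(d6, "P1", 10)$accession, "P1")
  expect_equal(autocomplete(d6, "p3", 10)$organism, "A")
  expect_equal(autocomplete(d6, "", 3)$accession, c("P1", "P2", "P3"))
  expect_equal(nrow(autocomplete(d6, "ZZZ", 5)), 0)
})

test_that("protein cards list organism, features and expression in order", {
  expect_equal(get_protein_card(d6, "P1"),
               list(organism = "A", description = "kinase alpha"))
  expect_error(get_protein_card(d6, "ZZ"), "unknown accession")

  # stub proteins expose only the placeholder organism
  d <- build_dataset(parse_interactions("P1\tP2\t0.9\n"),
                     parse_features("P1\torgA\tdesc\n", feature_names = "description"))
  expect_equal(get_protein_card(d, "P2"), list(organism = "unspecified"))

  g <- rand_ppi(6, seed = 2, expression = TRUE)
  card <- get_protein_card(g, g$proteins$accession[1])
  expect_true(all(c("cond1", "cond2") %in% names(card)))
  expect_equal(names(card)[1], "organism")
})
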