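d6 <- toy6()

# a short scripted session used by several tests
scripted_session <- function() {
  s <- new_session(d6, "toy6")
  s <- record(s, "load", list(), d6)
  s <- record(s, "search", list(ids = list("P1"), mode = "normal"), d6)
  s <- record(s, "add_rule", list(rule = list(
    target = "protein",
    condition = list(scope = "protein", field = "degree", op = "gt", value = 2),
    action = list(kind = "show_label", params = list(feature = "description")))), d6)
  s <- record(s, "set_layout", list(engine = "circle",
                                    params = list(seed = 7, width = 500)), d6)
  s
}

test_that("recording appends history and applies the operation", {
  s <- new_session(d6, "toy6")
  s <- record(s, "load", list(), d6)
  s <- record(s, "search", list(ids = list("P1"), mode = "normal"), d6)
  expect_length(s$history, 2)
  expect_equal(vapply(s$history, `[[`, 0L, "index"), c(0L, 1L))
  expect_setequal(s$displayed$proteins, c("P1", "P2", "P3"))

  expect_error(record(s, "teleport", list(), d6), "invalid operation")
  expect_error(record(s, "remove_rule", list(index = 5), d6), "no rule at index")
  # failed record leaves the original untouched
  expect_length(s$history, 2)
  expect_setequal(s$displayed$proteins, c("P1", "P2", "P3"))
})

test_that("replay reconstructs the recorded state; prefixes give intermediate states", {
  s <- scripted_session()
  r <- replay(d6, s$history, "toy6")
  expect_setequal(r$displayed$proteins, s$displayed$proteins)
  expect_equal(length(r$rules), length(s$rules))
  expect_equal(r$layout_engine, s$layout_engine)
  expect_equal(r$layout_params, s$layout_params)

  r2 <- replay(d6, s$history[1:2], "toy6")
  expect_setequal(r2$displayed$proteins, c("P1", "P2", "P3"))
  expect_length(r2$rules, 0)

  r0 <- replay(d6, list(), "toy6")
  expect_length(r0$displayed$proteins, 0)
  expect_length(r0$rules, 0)

  bad <- s$history
  bad[[2]]$params$ids <- list("P1")
  bad[[3]]$params$rule$condition$field <- "no_such_field"
  expect_error(replay(d6, bad, "toy6"), "history entry 2")
})

test_that("serialization round-trips losslessly and is byte-stable", {
  s <- scripted_session()
  j1 <- serialize_session(s)
  expect_match(j1, "pinv-state-v1")
  s2 <- deserialize_session(j1, d6)
  expect_equal(serialize_session(s2), j1)
  expect_setequal(s2$displayed$proteins, s$displayed$proteins)
  expect_setequal(paste(s2$displayed$interactions$a, s2$displayed$interactions$b),
                  paste(s$displayed$interactions$a, s$displayed$interactions$b))
  expect_equal(s2$layout_params, s$layout_params)
  expect_equal(length(s2$rules), length(s$rules))
  expect_equal(s2$rules[[1]]$action$kind, "show_label")

  expect_identical(serialize_session(s), serialize_session(s))
})

test_that("schema violations and dataset mismatches are rejected", {
  s <- scripted_session()
  j <- serialize_session(s)
  no_version <- sub('"version":"pinv-state-v1",', "", j, fixed = TRUE)
  expect_error(deserialize_session(no_version, d6), "version")

  other <- rand_ppi(12, seed = 5)  # accessions P01..P12: no key overlap
  expect_error(deserialize_session(j, other), "mismatch")
  # explicit opt-out skips the fingerprint check but still needs valid keys
  expect_error(deserialize_session(j, other, check_hash = FALSE), "interaction")
})

test_that("replay is the identity on randomized recorded sessions", {
  ops_pool <- c("search", "add_rule", "set_layout", "export", "prefilter")
  set.seed(2024)
  for (trial in 1:12) {
    g <- rand_ppi(15, seed = trial, p_in = 0.3)
    s <- new_session(g, "rand")
    s <- record(s, "load", list(), g)
    for (k in 1:8) {
      op <- sample(ops_pool, 1)
      s <- switch(op,
        search = record(s, "search", list(
          ids = as.list(sample(g$proteins$accession, 2)),
          mode = sample(c("normal", "explicit", "recursive"), 1)), g),
        add_rule = record(s, "add_rule", list(rule = list(
          target = "protein", condition = NULL,
          action = list(kind = "set_size", params = list(size = k + 1)))), g),
        set_layout = record(s, "set_layout", list(
          engine = sample(c("force", "circle"), 1),
          params = list(seed = k)), g),
        export = record(s, "export", list(svg = "out.svg"), g),
        prefilter = record(s, "prefilter", list(
          conditions = list("interaction.score ge 0.2")), g))
    }
    r <- replay(g, s$history, "rand")
    expect_setequal(r$displayed$proteins, s$displayed$proteins)
    expect_setequal(edge_key(r$displayed$interactions$a, r$displayed$interactions$b),
                    edge_key(s$displayed$interactions$a, s$displayed$interactions$b))
    expect_equal(r$rules, s$rules)
    expect_equal(r$layout_params, s$layout_params)
    expect_equal(serialize_session(r), serialize_session(s))
  }
})

test_that("embed snippets are single escaped iframes", {
  h <- embed_snippet("https://x/y", 600, 400)
  expect_match(h, '^<iframe src="https://x/y" width="600" height="400"')
  h2 <- embed_snippet('https://x/?a="b"&c=1', 300, 200)
  expect_match(h2, "&amp;c=1", fixed = TRUE)
  expect_match(h2, "&quot;b&quot;", fixed = TRUE)
  expect_error(embed_snippet("", 10, 10), "non-empty")
})

test_that("the dataset fingerprint tracks content", {
  expect_equal(dataset_hash(toy6()), dataset_hash(toy6()))
  expect_false(dataset_hash(toy6()) == dataset_hash(rand_ppi(6, seed = 1)))
})
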