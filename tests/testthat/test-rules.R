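d6 <- toy6()
full6 <- full_subnetwork(d6)
mt6 <- metric_table(full6)

test_that("conditions evaluate against proteins, metrics and interactions", {
  deg_gt2 <- filter_condition("protein", "degree", "gt", 2)
  expect_true(evaluate_condition(deg_gt2, "P3", full6, d6, mt6))
  expect_false(evaluate_condition(deg_gt2, "P1", full6, d6, mt6))

  with_p1 <- filter_condition("interaction", "protein", "equals", "P1")
  edge_p1p2 <- which(full6$interactions$a == "P1" & full6$interactions$b == "P2")
  expect_true(evaluate_condition(with_p1, edge_p1p2, full6, d6, mt6))
  edge_p4p5 <- which(full6$interactions$a == "P4")
  expect_false(evaluate_condition(with_p1, edge_p4p5, full6, d6, mt6))

  org_b <- filter_condition("protein", "organism", "equals", "B")
  expect_false(evaluate_condition(org_b, "P1", full6, d6, mt6))
  expect_true(evaluate_condition(org_b, "P4", full6, d6, mt6))
})

test_that("type mismatches fail at rule compile time, not per element", {
  bad <- style_rule("protein", filter_condition("protein", "description", "gt", 1),
                    style_action("set_color", color = "#ff0000"))
  expect_error(apply_rules(full6, list(bad), d6), "numeric operator on text field")
  bad2 <- style_rule("protein", filter_condition("protein", "degree", "contains", "x"),
                     style_action("hide"))
  expect_error(apply_rules(full6, list(bad2), d6), "contains")
})

test_that("no rules yields complete default styling and an empty legend", {
  st <- apply_rules(full6, list(), d6)
  expect_equal(nrow(st$node_style), length(full6$proteins))
  expect_equal(nrow(st$edge_style), nrow(full6$interactions))
  expect_true(all(st$node_style$color == "#888888"))
  expect_true(all(st$node_style$size == 5))
  expect_true(all(is.na(st$node_style$label)))
  expect_true(all(st$node_style$visible))
  expect_true(all(st$edge_style$color == "#999999"))
  expect_equal(nrow(st$legend), 0)
})

test_that("the degree > 2 labelling rule selects exactly the hub of TOY6", {
  rule <- style_rule("protein", "protein.degree gt 2",
                     style_action("show_label", feature = "description"))
  st <- apply_rules(full6, list(rule), d6)
  labelled <- st$node_style$accession[!is.na(st$node_style$label)]
  expect_equal(labelled, "P3")
  expect_equal(st$node_style$label[st$node_style$accession == "P3"],
               "Sensor histidine kinase")
})

test_that("later rules override earlier ones and categorical coloring fills the legend", {
  rules <- list(
    style_rule("protein", NULL, style_action("color_by_category", feature = "organism")),
    style_rule("protein", "protein.accession equals P1",
               style_action("set_color", color = "#ff0000")))
  st <- apply_rules(full6, rules, d6)
  ns <- st$node_style
  expect_equal(ns$color[ns$accession == "P1"], "#ff0000")
  # others carry the palette colors in first-seen category order: A then B
  expect_equal(st$legend$value, c("A", "B"))
  expect_equal(ns$color[ns$accession == "P2"], st$legend$color[1])
  expect_equal(ns$color[ns$accession == "P4"], st$legend$color[2])

  # reversed order: the category coloring wins
  st2 <- apply_rules(full6, rev(rules), d6)
  expect_equal(st2$node_style$color[st2$node_style$accession == "P1"],
               st2$legend$color[1])
})

test_that("override order holds for random rule pairs on the same attribute", {
  accs <- full6$proteins
  set.seed(99)
  for (trial in 1:20) {
    target <- sample(accs, 1)
    c1 <- sprintf("#%06x", sample(0:16777215, 1))
    c2 <- sprintf("#%06x", sample(0:16777215, 1))
    rules <- list(
      style_rule("protein", sprintf("protein.accession equals %s", target),
                 style_action("set_color", color = c1)),
      style_rule("protein", sprintf("protein.accession equals %s", target),
                 style_action("set_color", color = c2)))
    st <- apply_rules(full6, rules, d6)
    expect_equal(st$node_style$color[st$node_style$accession == target], c2)
  }
})

test_that("missing category values get the reserved unannotated gray, listed last", {
  d <- build_dataset(parse_interactions("P1\tP2\t0.5\n"),
                     parse_features("P1\tA\tkinase\nP2\tA\t\n",
                                    feature_names = "class"))
  sub <- full_subnetwork(d)
  st <- apply_rules(sub, list(style_rule("protein", NULL,
                    style_action("color_by_category", feature = "class"))), d)
  expect_equal(st$legend$value, c("kinase", "unannotated"))
  expect_equal(st$node_style$color[st$node_style$accession == "P2"], "#bdbdbd")
})

test_that("quantitative gradients interpolate, clamp and round half-down", {
  expect_equal(quantitative_color(0, 0, 1, "#102030", "#ffffff"), "#102030")
  expect_equal(quantitative_color(1, 0, 1, "#102030", "#ffffff"), "#ffffff")
  expect_equal(quantitative_color(0.5, 0, 1, "#000000", "#ffffff"), "#7f7f7f")
  # clamping outside [vmin, vmax]
  expect_equal(quantitative_color(-5, 0, 1, "#000000", "#ffffff"), "#000000")
  expect_equal(quantitative_color(99, 0, 1, "#000000", "#ffffff"), "#ffffff")
  expect_error(quantitative_color(0.5, 1, 1, "#000000", "#ffffff"), "vmin")
})

test_that("expression values drive value-based coloring", {
  g <- rand_ppi(8, seed = 3, expression = TRUE)
  sub <- full_subnetwork(g)
  st <- apply_rules(sub, list(style_rule("protein", NULL,
    style_action("color_by_value", field = "cond1", vmin = 0, vmax = 10,
                 color_low = "#000000", color_high = "#ffffff"))), g)
  v <- g$expression[st$node_style$accession, "cond1"]
  expect_equal(st$node_style$color,
               quantitative_color(v, 0, 10, "#000000", "#ffffff"))
})

test_that("contextual rules target only the selected protein and are idempotent", {
  r <- contextual_rule_for("P1", style_action("set_color", color = "#00ff00"), full6)
  st1 <- apply_rules(full6, list(r), d6)
  expect_equal(st1$node_style$color[st1$node_style$accession == "P1"], "#00ff00")
  expect_true(all(st1$node_style$color[st1$node_style$accession != "P1"] == "#888888"))
  st2 <- apply_rules(full6, list(r, r), d6)
  expect_equal(st1$node_style, st2$node_style)
  expect_error(contextual_rule_for("P9", style_action("hide"), full6), "not displayed")
})

test_that("styling is deterministic and complete for every element", {
  rules <- list(
    style_rule("protein", NULL, style_action("color_by_category", feature = "description")),
    style_rule("interaction", "interaction.score ge 0.7",
               style_action("set_color", color = "#ff00ff")),
    style_rule("protein", "protein.degree gt 2", style_action("set_size", size = 9)))
  st1 <- apply_rules(full6, rules, d6)
  st2 <- apply_rules(full6, rules, d6)
  expect_identical(st1, st2)
  expect_equal(nrow(st1$node_style), length(full6$proteins))
  expect_equal(nrow(st1$edge_style), nrow(full6$interactions))
})
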