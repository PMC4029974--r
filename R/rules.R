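#' @title Rule-based styling of nodes and edges
#' @description
#' Visual manipulation is declarative: a rule names a target (protein or
#' interaction), an optional condition, and an action ("paint green", "show
#' label", ...). Rules are plain serialisable records, applied in list order
#' over a default style; later rules override earlier ones on the same
#' attribute of the same element. Categorical coloring fills the legend.
#' @name rules_engine
NULL

ACTION_KINDS <- c("set_color", "color_by_category", "color_by_value",
                  "show_label", "hide_label", "set_size", "size_by_value",
                  "hide", "show")

# fixed qualitative palette, cycled with a warning past 12 categories
PALETTE12 <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
               "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf",
               "#aec7e8", "#ffbb78")
UNANNOTATED_COLOR <- "#bdbdbd"

NODE_DEFAULTS <- list(color = "#888888", size = 5.0, label = NA_character_, visible = TRUE)
EDGE_DEFAULTS <- list(color = "#999999", width = 1.0, visible = TRUE)

#' Build a style action
#'
#' @param kind one of `set_color`, `color_by_category`, `color_by_value`,
#'   `show_label`, `hide_label`, `set_size`, `size_by_value`, `hide`, `show`.
#' @param ... parameters required by the kind: `color` (set_color);
#'   `feature` (color_by_category, show_label); `field`, `vmin`, `vmax`,
#'   `color_low`, `color_high` (color_by_value); `size` (set_size); `field`,
#'   `vmin`, `vmax`, `size_min`, `size_max` (size_by_value).
#' @return an object of class `pinv_action`.
#' @examples
#' style_action("set_color", color = "#00ff00")
#' style_action("color_by_category", feature = "organism")
#' @export
style_action <- function(kind, ...) {
  kind <- match.arg(kind, ACTION_KINDS)
  params <- list(...)
  need <- switch(kind,
    set_color = "color",
    color_by_category = "feature",
    color_by_value = c("field", "vmin", "vmax", "color_low", "color_high"),
    show_label = "feature",
    set_size = "size",
    size_by_value = c("field", "vmin", "vmax", "size_min", "size_max"),
    character(0))
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop(sprintf("action '%s' requires parameter(s): %s", kind,
                 paste(missing, collapse = ", ")))
  }
  for (p in c("color", "color_low", "color_high")) {
    if (p %in% names(params) && !grepl("^#[0-9a-fA-F]{6}$", params[[p]])) {
      stop(sprintf("action '%s': '%s' must be a #rrggbb hex color", kind, p))
    }
  }
  if (kind %in% c("color_by_value", "size_by_value") && params$vmin >= params$vmax) {
    stop("vmin must be < vmax")
  }
  structure(list(kind = kind, params = params), class = "pinv_action")
}

as_action <- function(x) {
  if (inherits(x, "pinv_action")) return(x)
  do.call(style_action, c(list(kind = x$kind), x$params))
}

#' Build a styling rule
#'
#' @param target `"protein"` or `"interaction"`.
#' @param condition a `pinv_condition` (scope must match the target), a
#'   condition string, or `NULL` to match every element.
#' @param action a `pinv_action`.
#' @return an object of class `pinv_rule`.
#' @examples
#' style_rule("protein", "protein.degree gt 2",
#'            style_action("show_label", feature = "gene"))
#' @export
style_rule <- function(target, condition, action) {
  target <- match.arg(target, c("protein", "interaction"))
  if (is.character(condition)) condition <- parse_condition(condition)
  if (!is.null(condition)) {
    condition <- as_condition(condition)
    if (condition$scope != target) {
      stop(sprintf("condition scope '%s' does not match rule target '%s'",
                   condition$scope, target))
    }
  }
  structure(list(target = target, condition = condition, action = as_action(action)),
            class = "pinv_rule")
}

as_rule <- function(x) {
  if (inherits(x, "pinv_rule")) return(x)
  cond <- if (is.null(x$condition) || length(x$condition) == 0) NULL else x$condition
  style_rule(x$target, cond, x$action)
}

#' Rule that applies to a single selected protein
#'
#' The programmatic equivalent of the contextual right-click menu: wraps an
#' action in a rule whose condition matches only the given accession.
#' @param accession a displayed protein.
#' @param action a `pinv_action`.
#' @param sub the displayed `pinv_subnetwork` (the accession must be in it).
#' @export
contextual_rule_for <- function(accession, action, sub) {
  if (!accession %in% sub$proteins) {
    stop(sprintf("accession '%s' is not displayed", accession))
  }
  style_rule("protein",
             filter_condition("protein", "accession", "equals", accession),
             action)
}

#' @export
print.pinv_rule <- function(x, ...) {
  cat(sprintf("<rule> %s [%s] -> %s\n", x$target,
              if (is.null(x$condition)) "all" else format_condition(x$condition),
              x$action$kind))
  invisible(x)
}

# rule-compile-time type checking: numeric operators only on numeric fields
compile_rules <- function(rules, dataset) {
  rules <- lapply(rules, as_rule)
  num_protein <- c("degree", "betweenness",
                   if (!is.null(dataset$expression)) colnames(dataset$expression))
  txt_protein <- c("accession", "organism", dataset$feature_columns)
  num_inter <- c("score", dataset$evidence_columns)
  txt_inter <- c("protein", "accession")
  for (r in rules) {
    cond <- r$condition
    if (is.null(cond)) next
    known <- if (r$target == "protein") c(num_protein, txt_protein)
             else c(num_inter, txt_inter)
    if (!cond$field %in% known) {
      stop(sprintf("rule condition references unknown %s field '%s'; available: %s",
                   r$target, cond$field, paste(known, collapse = ", ")))
    }
    numeric_field <- cond$field %in% (if (r$target == "protein") num_protein else num_inter)
    check_numeric_op(cond, numeric_field)
    if (numeric_field && cond$op == "contains") {
      stop(sprintf("rule condition '%s': 'contains' applies to text fields",
                   format_condition(cond)))
    }
  }
  rules
}

#' Evaluate one rule condition against one element
#'
#' Pure predicate used by [apply_rules()]; exposed for testing and for
#' interactive inspection. Protein conditions may reference the organism,
#' any feature, `degree`, `betweenness` or expression conditions;
#' interaction conditions may reference `score`, evidence sources or an
#' endpoint accession (field `protein`).
#' @param condition a `pinv_condition` (or `NULL` = always true).
#' @param element an accession (protein scope) or a row index into
#'   `sub$interactions` (interaction scope).
#' @param sub the displayed `pinv_subnetwork`.
#' @param dataset the `pinv_dataset`.
#' @param metrics result of [metric_table()] for `sub`.
#' @export
evaluate_condition <- function(condition, element, sub, dataset, metrics = NULL) {
  if (is.null(condition)) return(TRUE)
  if (condition$scope == "protein") {
    i <- match(element, dataset$proteins$accession)
    if (is.na(i)) stop(sprintf("unknown accession '%s'", element))
    if (condition$field %in% c("degree", "betweenness")) {
      if (is.null(metrics)) metrics <- metric_table(sub)
      v <- metrics[[condition$field]][match(element, metrics$accession)]
      return(unname(op_compare(v, condition$op, condition$value)))
    }
    unname(eval_protein_condition(dataset, condition, metrics)[i])
  } else {
    unname(eval_interaction_condition(dataset, condition,
                                      sub$interactions[element, , drop = FALSE]))
  }
}

#' Resolve rules into a style table
#'
#' Applies defaults (gray nodes of size 5, labels hidden, everything
#' visible) and then each rule in order. `color_by_category` assigns palette
#' colors to distinct category values in first-seen order (the order of
#' `sub$proteins`) and replaces the legend; elements with an empty value get
#' a reserved "unannotated" gray listed last. `color_by_value` and
#' `size_by_value` map a numeric field linearly between the stated bounds,
#' clamped.
#'
#' @param sub the displayed `pinv_subnetwork`.
#' @param rules list of `pinv_rule`.
#' @param dataset the `pinv_dataset`.
#' @param metrics optional precomputed [metric_table()].
#' @return an object of class `pinv_style`: list with `node_style`
#'   (data.frame `accession`, `color`, `size`, `label`, `visible`),
#'   `edge_style` (data.frame `a`, `b`, `color`, `width`, `visible`) and
#'   `legend` (data.frame `value`, `color`).
#' @examples
#' d <- toy6()
#' sub <- search_network(d, c("P1", "P4"), mode = "recursive")
#' st <- apply_rules(sub, list(
#'   style_rule("protein", NULL, style_action("color_by_category", feature = "organism"))
#' ), d)
#' st$legend
#' @export
apply_rules <- function(sub, rules, dataset, metrics = NULL) {
  rules <- compile_rules(rules, dataset)
  needs_metrics <- any(vapply(rules, function(r) {
    !is.null(r$condition) && r$condition$field %in% c("degree", "betweenness")
  }, TRUE)) || any(vapply(rules, function(r) {
    r$action$kind %in% c("color_by_value", "size_by_value") &&
      r$action$params$field %in% c("degree", "betweenness")
  }, TRUE))
  if (is.null(metrics) && needs_metrics) metrics <- metric_table(sub)

  nN <- length(sub$proteins)
  ns <- data.frame(accession = sub$proteins,
                   color = rep(NODE_DEFAULTS$color, nN),
                   size = rep(NODE_DEFAULTS$size, nN),
                   label = rep(NODE_DEFAULTS$label, nN),
                   visible = rep(NODE_DEFAULTS$visible, nN),
                   stringsAsFactors = FALSE)
  nE <- nrow(sub$interactions)
  es <- data.frame(a = sub$interactions$a, b = sub$interactions$b,
                   color = rep(EDGE_DEFAULTS$color, nE),
                   width = rep(EDGE_DEFAULTS$width, nE),
                   visible = rep(EDGE_DEFAULTS$visible, nE),
                   stringsAsFactors = FALSE)
  legend <- data.frame(value = character(0), color = character(0),
                       stringsAsFactors = FALSE)

  protein_value <- function(field, accs) {
    if (field %in% c("degree", "betweenness")) {
      return(metrics[[field]][match(accs, metrics$accession)])
    }
    if (!is.null(dataset$expression) && field %in% colnames(dataset$expression)) {
      return(dataset$expression[match(accs, rownames(dataset$expression)), field])
    }
    i <- match(accs, dataset$proteins$accession)
    if (field == "accession") return(accs)
    if (field == "organism") return(dataset$proteins$organism[i])
    if (field %in% dataset$feature_columns) return(dataset$proteins[[field]][i])
    stop(sprintf("unknown protein field '%s'", field))
  }

  for (r in rules) {
    act <- r$action
    if (r$target == "protein") {
      hit <- vapply(ns$accession, function(a)
        isTRUE(evaluate_condition(r$condition, a, sub, dataset, metrics)), TRUE)
      idx <- which(hit)
      if (act$kind == "set_color") ns$color[idx] <- act$params$color
      else if (act$kind == "set_size") ns$size[idx] <- act$params$size
      else if (act$kind == "hide") ns$visible[idx] <- FALSE
      else if (act$kind == "show") ns$visible[idx] <- TRUE
      else if (act$kind == "hide_label") ns$label[idx] <- NA_character_
      else if (act$kind == "show_label") {
        lab <- as.character(protein_value(act$params$feature, ns$accession[idx]))
        ns$label[idx] <- lab
      } else if (act$kind == "color_by_category") {
        vals <- as.character(protein_value(act$params$feature, ns$accession[idx]))
        vals[is.na(vals) | !nzchar(vals)] <- NA
        cats <- unique(vals[!is.na(vals)])  # first-seen order over sub$proteins
        if (length(cats) > length(PALETTE12)) {
          warning(sprintf("%d categories exceed the 12-color palette; colors cycle",
                          length(cats)))
        }
        colors <- PALETTE12[((seq_along(cats) - 1L) %% length(PALETTE12)) + 1L]
        map <- stats::setNames(colors, cats)
        ns$color[idx] <- ifelse(is.na(vals), UNANNOTATED_COLOR, map[vals])
        legend <- data.frame(value = cats, color = unname(map[cats]),
                             stringsAsFactors = FALSE)
        if (any(is.na(vals))) {
          legend <- rbind(legend, data.frame(value = "unannotated",
                                             color = UNANNOTATED_COLOR))
        }
      } else if (act$kind == "color_by_value") {
        v <- as.numeric(protein_value(act$params$field, ns$accession[idx]))
        ok <- !is.na(v)
        ns$color[idx[ok]] <- quantitative_color(v[ok], act$params$vmin, act$params$vmax,
                                                act$params$color_low, act$params$color_high)
      } else if (act$kind == "size_by_value") {
        v <- as.numeric(protein_value(act$params$field, ns$accession[idx]))
        ok <- !is.na(v)
        t <- pmin(1, pmax(0, (v[ok] - act$params$vmin) /
                               (act$params$vmax - act$params$vmin)))
        ns$size[idx[ok]] <- act$params$size_min +
          t * (act$params$size_max - act$params$size_min)
      }
    } else {  # interaction target
      nE <- nrow(es)
      hit <- if (is.null(r$condition)) rep(TRUE, nE) else
        eval_interaction_condition(dataset, r$condition, sub$interactions)
      idx <- which(hit)
      if (act$kind == "set_color") es$color[idx] <- act$params$color
      else if (act$kind == "set_size") es$width[idx] <- act$params$size
      else if (act$kind == "hide") es$visible[idx] <- FALSE
      else if (act$kind == "show") es$visible[idx] <- TRUE
      else if (act$kind == "color_by_value") {
        fld <- act$params$field
        v <- if (fld == "score") sub$interactions$score[idx] else
          sub$interactions[[fld]][idx]
        ok <- !is.na(v)
        es$color[idx[ok]] <- quantitative_color(v[ok], act$params$vmin, act$params$vmax,
                                                act$params$color_low, act$params$color_high)
      } else {
        stop(sprintf("action '%s' does not apply to interactions", act$kind))
      }
    }
  }
  structure(list(node_style = ns, edge_style = es, legend = legend),
            class = "pinv_style")
}

#' Map a numeric value onto a two-color gradient
#'
#' Componentwise linear interpolation in RGB between `color_low` (at `vmin`)
#' and `color_high` (at `vmax`); values outside the range are clamped.
#' Channels are rounded half-down to integers so the midpoint of black and
#' white is `#7f7f7f` bit-stably.
#' @param value numeric vector.
#' @param vmin,vmax gradient bounds, `vmin < vmax`.
#' @param color_low,color_high `#rrggbb` hex colors.
#' @return character vector of hex colors.
#' @examples
#' quantitative_color(0.5, 0, 1, "#000000", "#ffffff")
#' @export
quantitative_color <- function(value, vmin, vmax, color_low, color_high) {
  if (vmin >= vmax) stop("vmin must be < vmax")
  lo <- grDevices::col2rgb(color_low)[, 1]
  hi <- grDevices::col2rgb(color_high)[, 1]
  t <- pmin(1, pmax(0, (value - vmin) / (vmax - vmin)))
  vapply(t, function(tt) {
    ch <- as.integer(ceiling(lo + tt * (hi - lo) - 0.5))  # round half down
    sprintf("#%02x%02x%02x", ch[1], ch[2], ch[3])
  }, "")
}

#' @export
print.pinv_style <- function(x, ...) {
  cat(sprintf("Style: %d node entries, %d edge entries, %d legend categories\n",
              nrow(x$node_style), nrow(x$edge_style), nrow(x$legend)))
  invisible(x)
}
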