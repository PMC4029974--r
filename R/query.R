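#' @title Prefilters, search modes and autocomplete
#' @description
#' The query engine reduces the full dataset to the displayed subnetwork.
#' Prefilters are an ordered conjunction of conditions on interactions or on
#' their endpoint proteins, reported with cumulative interaction counts; the
#' three search modes (normal, explicit, recursive) grow the displayed
#' subnetwork additively.
#' @name query_engine
NULL

FILTER_OPS <- c("contains", "equals", "gt", "ge", "lt", "le", "present")

#' Build a filter condition
#'
#' @param scope `"protein"` or `"interaction"`.
#' @param field for protein scope: `"accession"`, `"organism"`, a feature
#'   column or an expression condition name; for interaction scope:
#'   `"score"`, an evidence source name, or `"protein"`/`"accession"`
#'   (endpoint membership, the "interactions with protein Y" condition).
#'   Rule conditions may additionally use `"degree"` and `"betweenness"`.
#' @param op one of `contains`, `equals`, `gt`, `ge`, `lt`, `le`, `present`.
#'   `contains` is a case-insensitive substring match; numeric comparison
#'   operators apply only to numeric fields; `present` tests that the value
#'   was non-empty in the file.
#' @param value comparison value (omitted for `present`).
#' @return an object of class `pinv_condition`.
#' @examples
#' filter_condition("protein", "organism", "contains", "tuberculosis")
#' @export
filter_condition <- function(scope, field, op, value = NULL) {
  scope <- match.arg(scope, c("protein", "interaction"))
  op <- match.arg(op, FILTER_OPS)
  if (op == "present") {
    value <- NULL
  } else if (is.null(value)) {
    stop(sprintf("operator '%s' requires a value", op))
  }
  structure(list(scope = scope, field = field, op = op, value = value),
            class = "pinv_condition")
}

as_condition <- function(x) {
  if (inherits(x, "pinv_condition")) return(x)
  filter_condition(x$scope, x$field, x$op, x$value)
}

#' Parse a condition string
#'
#' Grammar: `<scope>.<field> <op> <value>` where scope is `protein` or
#' `interaction`, op is one of the filter operators and the value is the
#' rest of the string (may contain spaces). `present` takes no value.
#' @param text e.g. `"protein.organism contains tuberculosis"`.
#' @export
parse_condition <- function(text) {
  m <- regmatches(text, regexec("^\\s*([a-z]+)\\.(\\S+)\\s+(\\S+)(\\s+(.*))?$", text))[[1]]
  if (length(m) == 0 || !nzchar(m[2])) {
    stop(sprintf("cannot parse condition '%s'; expected '<scope>.<field> <op> [value]'", text))
  }
  op <- m[4]
  value <- if (nzchar(m[6]) || op != "present") m[6] else NULL
  if (!is.null(value) && op %in% c("gt", "ge", "lt", "le")) {
    num <- suppressWarnings(as.numeric(value))
    if (!is.na(num)) value <- num
  }
  filter_condition(m[2], m[3], op, value)
}

format_condition <- function(cond) {
  paste(c(paste0(cond$scope, ".", cond$field), cond$op,
          if (!is.null(cond$value)) as.character(cond$value)), collapse = " ")
}

#' @export
print.pinv_condition <- function(x, ...) {
  cat("<condition>", format_condition(x), "\n")
  invisible(x)
}

# -- condition evaluation -----------------------------------------------------

protein_fields <- function(dataset) {
  c("accession", "organism", dataset$feature_columns,
    if (!is.null(dataset$expression)) colnames(dataset$expression))
}

interaction_fields <- function(dataset) {
  c("score", dataset$evidence_columns, "protein", "accession")
}

op_compare <- function(x, op, value) {
  out <- switch(op,
    contains = grepl(tolower(as.character(value)), tolower(as.character(x)), fixed = TRUE),
    equals   = if (is.numeric(x)) x == as.numeric(value) else as.character(x) == as.character(value),
    gt = as.numeric(x) >  as.numeric(value),
    ge = as.numeric(x) >= as.numeric(value),
    lt = as.numeric(x) <  as.numeric(value),
    le = as.numeric(x) <= as.numeric(value),
    present = if (is.numeric(x)) !is.na(x) else !is.na(x) & nzchar(as.character(x))
  )
  out & !is.na(out)
}

check_numeric_op <- function(cond, numeric_field) {
  if (cond$op %in% c("gt", "ge", "lt", "le") && !numeric_field) {
    stop(sprintf("condition '%s': numeric operator on text field '%s'",
                 format_condition(cond), cond$field))
  }
}

# logical vector over dataset$proteins rows
eval_protein_condition <- function(dataset, cond, metrics = NULL) {
  prot <- dataset$proteins
  f <- cond$field
  if (f %in% c("accession", "organism")) {
    check_numeric_op(cond, FALSE)
    return(op_compare(prot[[f]], cond$op, cond$value))
  }
  if (f %in% dataset$feature_columns) {
    check_numeric_op(cond, FALSE)
    return(op_compare(prot[[f]], cond$op, cond$value))
  }
  if (!is.null(dataset$expression) && f %in% colnames(dataset$expression)) {
    v <- dataset$expression[match(prot$accession, rownames(dataset$expression)), f]
    return(op_compare(v, cond$op, cond$value))
  }
  if (!is.null(metrics) && f %in% c("degree", "betweenness")) {
    v <- metrics[[f]][match(prot$accession, metrics$accession)]
    return(op_compare(v, cond$op, cond$value))
  }
  stop(sprintf("unknown protein field '%s'; available fields: %s", f,
               paste(c(protein_fields(dataset),
                       if (!is.null(metrics)) c("degree", "betweenness")),
                     collapse = ", ")))
}

# logical vector over interaction rows `ints`
eval_interaction_condition <- function(dataset, cond, ints) {
  f <- cond$field
  if (f == "score") return(op_compare(ints$score, cond$op, cond$value))
  if (f %in% dataset$evidence_columns) {
    return(op_compare(ints[[f]], cond$op, cond$value))
  }
  if (f %in% c("protein", "accession")) {
    check_numeric_op(cond, FALSE)
    return(op_compare(ints$a, cond$op, cond$value) |
           op_compare(ints$b, cond$op, cond$value))
  }
  stop(sprintf("unknown interaction field '%s'; available fields: %s", f,
               paste(interaction_fields(dataset), collapse = ", ")))
}

# -- subnetworks --------------------------------------------------------------

#' Construct a subnetwork
#'
#' A subnetwork is the displayed selection: a set of protein accessions plus
#' the interactions among them (closure: every interaction endpoint is a
#' member protein; endpoints are added if missing).
#' @param proteins character vector of accessions.
#' @param interactions data.frame with at least columns `a`, `b`, `score`.
#' @export
subnetwork <- function(proteins, interactions) {
  proteins <- unique(c(as.character(proteins), interactions$a, interactions$b))
  rownames(interactions) <- NULL
  structure(list(proteins = proteins, interactions = interactions),
            class = "pinv_subnetwork")
}

#' @rdname subnetwork
#' @param dataset used only for the interaction column layout.
#' @export
empty_subnetwork <- function(dataset) {
  subnetwork(character(0), dataset$interactions[0, , drop = FALSE])
}

#' @export
print.pinv_subnetwork <- function(x, ...) {
  cat(sprintf("Subnetwork: %d proteins, %d interactions\n",
              length(x$proteins), nrow(x$interactions)))
  w <- attr(x, "warnings")
  if (length(w)) cat("  warnings:", paste(w, collapse = "; "), "\n")
  invisible(x)
}

edge_keys <- function(ints) paste(ints$a, ints$b, sep = "|")

# union of two interaction data.frames, first one's order preserved
union_interactions <- function(x, y) {
  out <- rbind(x, y)
  out <- out[!duplicated(paste(out$a, out$b, sep = "\t")), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# -- prefilters ---------------------------------------------------------------

#' Apply prefilters to the whole dataset
#'
#' Conditions are combined with AND in the order given. An interaction
#' passes a protein-scope condition if at least one endpoint satisfies it
#' (`protein_match = "either"`, the default, which keeps host-pathogen edges
#' visible when filtering on one organism) or only if both endpoints do
#' (`"both"`). After each condition the running interaction count is
#' recorded, mirroring the dynamically updated filter panel.
#'
#' @param dataset a `pinv_dataset`.
#' @param conditions list of `pinv_condition` (or condition strings, parsed
#'   with [parse_condition()]).
#' @param protein_match `"either"` or `"both"`.
#' @return an object of class `pinv_filter_summary`: list with `total`
#'   (interaction count before filtering), `steps` (data.frame `condition`,
#'   `count`), and `result` (the passing `pinv_subnetwork`).
#' @examples
#' d <- toy6()
#' apply_prefilters(d, list("protein.description contains sensor"))
#' @export
apply_prefilters <- function(dataset, conditions = list(),
                             protein_match = c("either", "both")) {
  protein_match <- match.arg(protein_match)
  if (inherits(conditions, "pinv_condition")) conditions <- list(conditions)
  conditions <- lapply(conditions, function(cc) {
    if (is.character(cc)) parse_condition(cc) else as_condition(cc)
  })
  ints <- dataset$interactions
  keep <- rep(TRUE, nrow(ints))
  steps <- data.frame(condition = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  for (cond in conditions) {
    if (cond$scope == "protein") {
      pv <- eval_protein_condition(dataset, cond)
      pass_acc <- dataset$proteins$accession[pv]
      pa <- ints$a %in% pass_acc
      pb <- ints$b %in% pass_acc
      pass <- if (protein_match == "either") pa | pb else pa & pb
    } else {
      pass <- eval_interaction_condition(dataset, cond, ints)
    }
    keep <- keep & pass
    steps <- rbind(steps, data.frame(condition = format_condition(cond),
                                     count = sum(keep), stringsAsFactors = FALSE))
  }
  structure(list(total = nrow(ints), steps = steps,
                 result = subnetwork(character(0), ints[keep, , drop = FALSE])),
            class = "pinv_filter_summary")
}

#' @export
print.pinv_filter_summary <- function(x, ...) {
  cat(sprintf("Prefilter: %d interactions in dataset\n", x$total))
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  AND %-45s -> %d\n", x$steps$condition[i], x$steps$count[i]))
  }
  print(x$result)
  invisible(x)
}

# -- search -------------------------------------------------------------------

#' Search the dataset with one of the three query modes
#'
#' * `normal` adds the queried proteins and every interaction with at least
#'   one endpoint in the query;
#' * `explicit` adds only interactions between queried proteins, plus
#'   interactions linking a queried protein to an already displayed one;
#' * `recursive` adds the induced subgraph on the query and its neighbours
#'   (equivalently: a normal query followed by an explicit query for each
#'   recovered protein), so every interaction between displayed proteins is
#'   shown.
#'
#' Search is additive: it never removes previously displayed content.
#' Unknown accessions are reported in the `"warnings"` attribute of the
#' result, not fatal; an empty (or fully unknown) query returns `displayed`
#' unchanged with a warning.
#'
#' @param dataset a `pinv_dataset`.
#' @param query character vector of accessions.
#' @param mode `"normal"`, `"explicit"` or `"recursive"`.
#' @param displayed the current `pinv_subnetwork` (default: empty).
#' @return the new displayed `pinv_subnetwork`.
#' @examples
#' d <- toy6()
#' search_network(d, "P3", mode = "recursive")
#' @export
search_network <- function(dataset, query, mode = c("normal", "explicit", "recursive"),
                           displayed = NULL) {
  mode <- match.arg(mode)
  if (is.null(displayed)) displayed <- empty_subnetwork(dataset)
  query <- unique(as.character(query))
  warnings <- character(0)
  unknown <- setdiff(query, dataset$proteins$accession)
  if (length(unknown)) {
    warnings <- c(warnings, sprintf("unknown accession '%s' ignored", unknown))
    query <- setdiff(query, unknown)
  }
  if (length(query) == 0) {
    warnings <- c(warnings, "empty query; displayed subnetwork unchanged")
    attr(displayed, "warnings") <- warnings
    return(displayed)
  }
  ints <- dataset$interactions
  ina <- ints$a %in% query
  inb <- ints$b %in% query
  sel <- switch(mode,
    normal = ina | inb,
    explicit = (ina & inb) |
      (ina & ints$b %in% displayed$proteins) |
      (inb & ints$a %in% displayed$proteins),
    recursive = {
      closure <- unique(c(query, ints$a[inb], ints$b[ina]))
      ints$a %in% closure & ints$b %in% closure
    })
  out <- subnetwork(unique(c(displayed$proteins, query)),
                    union_interactions(displayed$interactions,
                                       ints[sel, , drop = FALSE]))
  attr(out, "warnings") <- warnings
  out
}

#' Autocomplete accessions by prefix
#'
#' Case-insensitive prefix match on accessions, sorted lexicographically
#' (C locale) and truncated to `limit`.
#' @param dataset a `pinv_dataset`.
#' @param prefix query prefix; the empty string matches everything.
#' @param limit maximum number of suggestions (>= 1).
#' @return data.frame with columns `accession`, `organism`.
#' @export
autocomplete <- function(dataset, prefix, limit = 10L) {
  stopifnot(limit >= 1)
  prot <- dataset$proteins
  hit <- startsWith(tolower(prot$accession), tolower(prefix))
  res <- prot[hit, c("accession", "organism"), drop = FALSE]
  res <- res[order(res$accession, method = "radix"), , drop = FALSE]
  res <- utils::head(res, limit)
  rownames(res) <- NULL
  res
}

#' Feature card for one protein
#'
#' The lookup behind the node pop-up: organism first, then the annotation
#' features in file column order (empty cells omitted), then expression
#' values.
#' @param dataset a `pinv_dataset`.
#' @param accession protein accession (must exist).
#' @return named list of values.
#' @export
get_protein_card <- function(dataset, accession) {
  prot <- dataset$proteins
  i <- match(accession, prot$accession)
  if (is.na(i)) stop(sprintf("unknown accession '%s'", accession))
  card <- list(organism = prot$organism[i])
  for (f in dataset$feature_columns) {
    v <- prot[[f]][i]
    if (!is.na(v) && nzchar(v)) card[[f]] <- v
  }
  ex <- dataset$expression
  if (!is.null(ex) && accession %in% rownames(ex)) {
    for (cn in colnames(ex)) card[[cn]] <- unname(ex[accession, cn])
  }
  card
}
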