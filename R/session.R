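#' @title Provenance history, replay and shareable state
#' @description
#' Every user-level operation (load, prefilter, search, add/remove rule,
#' set layout, export) is recorded as a history entry storing the
#' operation's parameters, not its results; replaying the history from a
#' fresh load deterministically regenerates the displayed subnetwork, the
#' rule list and the layout parameters. The serialized JSON state (schema
#' `pinv-state-v1`) is the shareable payload: it references the dataset by
#' id plus a content hash so collaborators detect a dataset mismatch.
#' @name session_state
NULL

SESSION_OPS <- c("load", "prefilter", "search", "add_rule", "remove_rule",
                 "set_layout", "export")
STATE_SCHEMA <- "pinv-state-v1"

#' Fingerprint of the dataset content
#'
#' FNV-1a 32-bit hash over the canonical TSV serialization of the dataset;
#' embedded in shared session payloads.
#' @param dataset a `pinv_dataset`.
#' @export
dataset_hash <- function(dataset) {
  fnv1a32(paste0(write_interactions_tsv(dataset), write_features_tsv(dataset),
                 write_expression_tsv(dataset)))
}

#' Start a session
#' @param dataset a `pinv_dataset`.
#' @param dataset_id label identifying the dataset (e.g. its file paths).
#' @return an object of class `pinv_session`.
#' @export
new_session <- function(dataset, dataset_id = "dataset") {
  structure(list(dataset_id = dataset_id,
                 dataset_hash = dataset_hash(dataset),
                 displayed = empty_subnetwork(dataset),
                 rules = list(),
                 layout_engine = "force",
                 layout_params = layout_params(),
                 history = list()),
            class = "pinv_session")
}

# apply one operation to the state (no history bookkeeping)
apply_session_op <- function(state, op, params, dataset) {
  if (!op %in% SESSION_OPS) {
    stop(sprintf("invalid operation '%s'; valid: %s", op,
                 paste(SESSION_OPS, collapse = ", ")))
  }
  switch(op,
    load = {
      state$displayed <- empty_subnetwork(dataset)
      state$rules <- list()
    },
    prefilter = {
      conds <- lapply(params$conditions, function(cc) {
        if (is.character(cc)) parse_condition(cc) else as_condition(cc)
      })
      pm <- if (is.null(params$protein_match)) "either" else params$protein_match
      state$displayed <- apply_prefilters(dataset, conds, protein_match = pm)$result
    },
    search = {
      state$displayed <- search_network(dataset, unlist(params$ids),
                                        mode = params$mode,
                                        displayed = state$displayed)
      attr(state$displayed, "warnings") <- NULL
    },
    add_rule = {
      # compile against the dataset so a rule naming an unknown field fails
      # at record/replay time, not at styling time
      state$rules <- c(state$rules, compile_rules(list(params$rule), dataset))
    },
    remove_rule = {
      i <- params$index
      if (is.null(i) || i < 1 || i > length(state$rules)) {
        stop(sprintf("remove_rule: no rule at index %s", i))
      }
      state$rules[[i]] <- NULL
    },
    set_layout = {
      if (!is.null(params$engine)) {
        state$layout_engine <- match.arg(params$engine, c("force", "circle"))
      }
      if (!is.null(params$params)) {
        merged <- unclass(state$layout_params)
        upd <- params$params
        merged[names(upd)] <- upd
        state$layout_params <- as_layout_params(merged)
      }
    },
    export = {
      # pure provenance: recorded, changes nothing
    })
  state
}

#' Record an operation in the session
#'
#' Applies the operation and appends a history entry (index, op, params).
#' Pure: returns the new state; on error the input state is unchanged.
#' @param state a `pinv_session`.
#' @param op one of `load`, `prefilter`, `search`, `add_rule`,
#'   `remove_rule`, `set_layout`, `export`.
#' @param params named list of serializable parameters for the operation.
#' @param dataset the `pinv_dataset` the session runs against.
#' @export
record <- function(state, op, params = list(), dataset) {
  new <- apply_session_op(state, op, params, dataset)
  entry <- list(index = length(state$history), op = op, params = params)
  new$history <- c(state$history, list(entry))
  new
}

#' Replay a history against a dataset
#'
#' Deterministically reconstructs the session state a history produced. An
#' entry that fails (for example an unknown field after the dataset
#' changed) aborts with an error naming the entry index. `replay` with the
#' first `k` entries gives the state after step `k` ("jump to a state").
#' @param dataset a `pinv_dataset`.
#' @param history list of history entries (from a `pinv_session`).
#' @param dataset_id passed to [new_session()].
#' @export
replay <- function(dataset, history, dataset_id = "dataset") {
  state <- new_session(dataset, dataset_id)
  for (i in seq_along(history)) {
    e <- history[[i]]
    state <- tryCatch(
      apply_session_op(state, e$op, e$params, dataset),
      error = function(err) {
        stop(sprintf("history entry %d (%s): %s", i - 1, e$op, conditionMessage(err)))
      })
  }
  state$history <- lapply(seq_along(history), function(i) {
    e <- history[[i]]; e$index <- i - 1L; e
  })
  state
}

# strip classes/attributes so jsonlite serializes plainly and stably
plainify <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    attr(x, "warnings") <- NULL
    lapply(x, plainify)
  } else x
}

#' Serialize a session to JSON
#'
#' Schema `pinv-state-v1`, fixed key order, no timestamps: equal states
#' serialize to identical bytes. The displayed subnetwork is stored as
#' protein accessions plus canonical interaction keys (`"a|b"`); the
#' interactions themselves are re-resolved from the (hash-checked) dataset
#' on deserialization, keeping payloads small and replay authoritative.
#' @param state a `pinv_session`.
#' @return a JSON string.
#' @export
serialize_session <- function(state) {
  payload <- list(
    version = STATE_SCHEMA,
    dataset_id = state$dataset_id,
    dataset_hash = state$dataset_hash,
    displayed = list(
      proteins = as.list(sort(state$displayed$proteins, method = "radix")),
      interaction_keys = as.list(sort(edge_keys(state$displayed$interactions),
                                      method = "radix"))),
    rules = plainify(state$rules),
    layout_engine = state$layout_engine,
    layout_params = plainify(state$layout_params),
    history = plainify(state$history))
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Deserialize a session JSON against a dataset
#'
#' Validates the schema version and (by default) the dataset content hash,
#' then rebuilds the full session state, resolving interaction keys back to
#' dataset rows.
#' @param json JSON string from [serialize_session()].
#' @param dataset the `pinv_dataset` the state refers to.
#' @param check_hash set `FALSE` to skip the dataset fingerprint check.
#' @export
deserialize_session <- function(json, dataset, check_hash = TRUE) {
  s <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (is.null(s$version)) stop("schema error at $.version: missing")
  if (!identical(s$version, STATE_SCHEMA)) {
    stop(sprintf("schema error at $.version: expected '%s', got '%s'",
                 STATE_SCHEMA, s$version))
  }
  for (f in c("dataset_id", "dataset_hash", "displayed", "rules",
              "layout_engine", "layout_params", "history")) {
    if (is.null(s[[f]])) stop(sprintf("schema error at $.%s: missing", f))
  }
  if (check_hash && !identical(s$dataset_hash, dataset_hash(dataset))) {
    stop(sprintf("dataset mismatch: state was saved against content hash %s, loaded dataset hashes to %s",
                 s$dataset_hash, dataset_hash(dataset)))
  }
  keys <- unlist(s$displayed$interaction_keys)
  all_keys <- edge_keys(dataset$interactions)
  idx <- match(keys, all_keys)
  if (anyNA(idx)) {
    stop(sprintf("schema error at $.displayed.interaction_keys: unknown interaction '%s'",
                 keys[which(is.na(idx))[1]]))
  }
  displayed <- subnetwork(unlist(s$displayed$proteins),
                          dataset$interactions[idx, , drop = FALSE])
  state <- structure(list(
    dataset_id = s$dataset_id,
    dataset_hash = s$dataset_hash,
    displayed = displayed,
    rules = lapply(s$rules, as_rule),
    layout_engine = s$layout_engine,
    layout_params = as_layout_params(s$layout_params),
    history = lapply(s$history, function(e)
      list(index = as.integer(e$index), op = e$op, params = e$params))),
    class = "pinv_session")
  state
}

#' HTML snippet embedding a shared view
#'
#' Returns a single `<iframe>` element pointing at a shared-state URL, with
#' attribute-escaped URL and integer dimensions.
#' @param state_url non-empty URL of the shared view.
#' @param width,height iframe dimensions in pixels.
#' @export
embed_snippet <- function(state_url, width = 600, height = 400) {
  if (!is.character(state_url) || length(state_url) != 1 || !nzchar(state_url)) {
    stop("state_url must be a non-empty string")
  }
  sprintf('<iframe src="%s" width="%d" height="%d" frameborder="0"></iframe>',
          xml_escape(state_url), as.integer(width), as.integer(height))
}

#' @export
print.pinv_session <- function(x, ...) {
  cat(sprintf("Session on '%s' (hash %s): %d displayed proteins, %d rules, %s layout, %d history entries\n",
              x$dataset_id, x$dataset_hash, length(x$displayed$proteins),
              length(x$rules), x$layout_engine, length(x$history)))
  invisible(x)
}

#' Format the provenance history for display
#' @param state a `pinv_session`.
#' @return character vector, one line per entry.
#' @export
format_history <- function(state) {
  vapply(state$history, function(e) {
    p <- vapply(names(e$params), function(nm) {
      v <- e$params[[nm]]
      paste0(nm, "=", paste(utils::capture.output(utils::str(v, give.head = FALSE))[1],
                            collapse = ""))
    }, "")
    sprintf("[%d] %s %s", e$index, e$op, paste(p, collapse = " "))
  }, "")
}
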