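#' @title Graph statistics for the displayed subnetwork
#' @description
#' Degree, shortest-path betweenness centrality, connected components and
#' the organism partition. These feed the rule engine (conditions such as
#' "more than 2 interactions"), node sizing by betweenness, and the layout
#' engine's per-organism gravity wells. All statistics are computed on the
#' unweighted simple graph: edge scores do not affect shortest paths and
#' self-interactions are excluded.
#' @name network_metrics
NULL

# igraph object over the subnetwork's non-loop edges; every displayed
# protein is a vertex (isolated ones included)
sub_igraph <- function(sub) {
  ints <- sub$interactions
  ints <- ints[ints$a != ints$b, c("a", "b"), drop = FALSE]
  igraph::graph_from_data_frame(ints, directed = FALSE,
                                vertices = data.frame(name = sub$proteins))
}

#' Degree of displayed proteins
#'
#' Number of incident non-loop interactions.
#' @param sub a `pinv_subnetwork`.
#' @param accession optional single accession; if given, returns its degree,
#'   otherwise a named vector for all displayed proteins.
#' @export
node_degree <- function(sub, accession = NULL) {
  g <- sub_igraph(sub)
  d <- igraph::degree(g)
  if (is.null(accession)) return(d)
  if (!accession %in% sub$proteins) stop(sprintf("unknown accession '%s'", accession))
  unname(d[accession])
}

#' Betweenness centrality of displayed proteins
#'
#' Shortest-path betweenness on the unweighted graph. Unnormalised values
#' count unordered vertex pairs whose shortest paths pass through the node
#' (fractionally when several shortest paths exist); `normalized = TRUE`
#' divides by `(n-1)(n-2)/2`. Disconnected pairs contribute nothing.
#' @param sub a `pinv_subnetwork`.
#' @param normalized logical.
#' @return named numeric vector over displayed proteins.
#' @export
node_betweenness <- function(sub, normalized = FALSE) {
  g <- sub_igraph(sub)
  igraph::betweenness(g, directed = FALSE, weights = NA, normalized = normalized)
}

#' Connected components
#'
#' Component ids `0..k-1`, ordered by decreasing component size with ties
#' broken by the lexicographically smallest member accession.
#' @param sub a `pinv_subnetwork`.
#' @return named integer vector accession -> component id.
#' @export
connected_components <- function(sub) {
  if (length(sub$proteins) == 0) return(stats::setNames(integer(0), character(0)))
  g <- sub_igraph(sub)
  comp <- igraph::components(g)
  raw <- comp$membership
  k <- comp$no
  size <- as.integer(comp$csize)
  minacc <- vapply(seq_len(k), function(i) {
    min(sort(names(raw)[raw == i], method = "radix"))
  }, "")
  new_id <- integer(k)
  new_id[order(-size, minacc, method = "radix")] <- seq_len(k) - 1L
  out <- new_id[raw]
  stats::setNames(as.integer(out), names(raw))[sub$proteins]
}

#' Organisms present in the displayed selection
#'
#' Distinct organisms of the displayed proteins, sorted lexicographically so
#' that gravity-well assignment is stable.
#' @param sub a `pinv_subnetwork`.
#' @param dataset the `pinv_dataset` the subnetwork came from.
#' @export
organisms_of <- function(sub, dataset) {
  if (length(sub$proteins) == 0) return(character(0))
  orgs <- dataset$proteins$organism[match(sub$proteins, dataset$proteins$accession)]
  sort(unique(orgs), method = "radix")
}

#' Metric table for the displayed subnetwork
#'
#' One row per displayed protein with `degree`, `betweenness` and
#' `component_id`, the statistics the rule engine and exports consume.
#' @param sub a `pinv_subnetwork`.
#' @param normalized passed to [node_betweenness()].
#' @return data.frame ordered by accession.
#' @export
metric_table <- function(sub, normalized = FALSE) {
  acc <- sort(sub$proteins, method = "radix")
  if (length(acc) == 0) {
    return(data.frame(accession = character(0), degree = integer(0),
                      betweenness = numeric(0), component_id = integer(0)))
  }
  deg <- node_degree(sub)
  btw <- node_betweenness(sub, normalized = normalized)
  comp <- connected_components(sub)
  data.frame(accession = acc,
             degree = as.integer(unname(deg[acc])),
             betweenness = unname(btw[acc]),
             component_id = unname(comp[acc]),
             stringsAsFactors = FALSE)
}
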