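# Independent brute-force oracles used to validate the query engine, the
# prefilters and betweenness. Deliberately written as plain loops over the
# edge list / adjacency structure, sharing no code with the implementation.

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# set-comprehension oracle for the three search modes; returns sorted edge keys
oracle_search_keys <- function(dataset, q, mode, displayed_keys = character(0),
                               displayed_proteins = character(0)) {
  ints <- dataset$interactions
  q <- intersect(q, dataset$proteins$accession)
  keep <- character(0)
  if (mode == "normal") {
    for (i in seq_len(nrow(ints))) {
      if (ints$a[i] %in% q || ints$b[i] %in% q) keep <- c(keep, edge_key(ints$a[i], ints$b[i]))
    }
  } else if (mode == "explicit") {
    for (i in seq_len(nrow(ints))) {
      a <- ints$a[i]; b <- ints$b[i]
      if ((a %in% q && b %in% q) ||
          (a %in% q && b %in% displayed_proteins) ||
          (b %in% q && a %in% displayed_proteins)) {
        keep <- c(keep, edge_key(a, b))
      }
    }
  } else if (mode == "recursive") {
    nb <- character(0)
    for (i in seq_len(nrow(ints))) {
      if (ints$a[i] %in% q) nb <- c(nb, ints$b[i])
      if (ints$b[i] %in% q) nb <- c(nb, ints$a[i])
    }
    closure <- union(q, nb)
    for (i in seq_len(nrow(ints))) {
      if (ints$a[i] %in% closure && ints$b[i] %in% closure) {
        keep <- c(keep, edge_key(ints$a[i], ints$b[i]))
      }
    }
  }
  sort(unique(c(keep, displayed_keys)))
}

# all-pairs BFS path-counting betweenness oracle (unweighted, undirected,
# fractional over multiple shortest paths, unnormalised, unordered pairs)
oracle_betweenness <- function(sub) {
  nodes <- sub$proteins
  n <- length(nodes)
  adj <- stats::setNames(vector("list", n), nodes)
  ints <- sub$interactions
  for (i in seq_len(nrow(ints))) {
    a <- ints$a[i]; b <- ints$b[i]
    if (a == b) next
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  bfs <- function(src) {
    dist <- stats::setNames(rep(Inf, n), nodes)
    sigma <- stats::setNames(rep(0, n), nodes)
    dist[src] <- 0; sigma[src] <- 1
    queue <- src
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) { dist[v] <- dist[u] + 1; queue <- c(queue, v) }
        if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
      }
    }
    list(dist = dist, sigma = sigma)
  }
  sp <- lapply(stats::setNames(nodes, nodes), bfs)
  btw <- stats::setNames(rep(0, n), nodes)
  for (si in seq_len(n - 1)) for (ti in seq(si + 1, n)) {
    s <- nodes[si]; t <- nodes[ti]
    dst <- sp[[s]]$dist[t]
    if (is.infinite(dst)) next
    for (v in nodes) {
      if (v == s || v == t) next
      if (sp[[s]]$dist[v] + sp[[t]]$dist[v] == dst) {
        btw[v] <- btw[v] + sp[[s]]$sigma[v] * sp[[t]]$sigma[v] / sp[[s]]$sigma[t]
      }
    }
  }
  btw
}

# one-line-per-condition filter oracle: loops over interactions applying
# each condition independently of the engine's vectorised path
oracle_filter_count <- function(dataset, conditions) {
  ints <- dataset$interactions
  prot <- dataset$proteins
  passes <- function(cond, i) {
    test_one <- function(x) {
      if (cond$op == "contains") grepl(tolower(cond$value), tolower(x), fixed = TRUE)
      else if (cond$op == "equals") {
        if (is.numeric(x)) !is.na(x) && x == as.numeric(cond$value)
        else identical(as.character(x), as.character(cond$value))
      }
      else if (cond$op == "present") !is.na(x) && (!is.character(x) || nzchar(x))
      else {
        xv <- suppressWarnings(as.numeric(x)); vv <- as.numeric(cond$value)
        !is.na(xv) && switch(cond$op, gt = xv > vv, ge = xv >= vv,
                             lt = xv < vv, le = xv <= vv)
      }
    }
    if (cond$scope == "interaction") {
      if (cond$field %in% c("protein", "accession")) {
        test_one(ints$a[i]) || test_one(ints$b[i])
      } else {
        test_one(ints[[cond$field]][i])
      }
    } else {
      endpoint_ok <- function(acc) {
        r <- prot[prot$accession == acc, , drop = FALSE]
        val <- if (cond$field %in% colnames(r)) r[[cond$field]][1]
               else dataset$expression[acc, cond$field]
        test_one(val)
      }
      endpoint_ok(ints$a[i]) || endpoint_ok(ints$b[i])
    }
  }
  counts <- integer(0)
  keep <- rep(TRUE, nrow(ints))
  for (cond in conditions) {
    for (i in seq_len(nrow(ints))) {
      if (keep[i] && !passes(cond, i)) keep[i] <- FALSE
    }
    counts <- c(counts, sum(keep))
  }
  counts
}

# small random dataset via the package generator (fixed seed)
rand_ppi <- function(n, seed, p_in = 0.25, p_cross = 0.1, expression = FALSE) {
  generate_pinv_dataset(
    generator_spec(n, edge_probability = p_in,
                   cross_organism_probability = p_cross, seed = seed),
    expression = expression)
}

full_subnetwork <- function(dataset) {
  subnetwork(dataset$proteins$accession, dataset$interactions)
}

expect_dataset_equal <- function(x, y) {
  ox <- order(x$proteins$accession); oy <- order(y$proteins$accession)
  px <- x$proteins[ox, , drop = FALSE]; py <- y$proteins[oy, , drop = FALSE]
  rownames(px) <- rownames(py) <- NULL
  expect_equal(px, py)
  kx <- order(paste(x$interactions$a, x$interactions$b))
  ky <- order(paste(y$interactions$a, y$interactions$b))
  ix <- x$interactions[kx, , drop = FALSE]; iy <- y$interactions[ky, , drop = FALSE]
  rownames(ix) <- rownames(iy) <- NULL
  expect_equal(ix, iy)
  expect_equal(x$evidence_columns, y$evidence_columns)
  expect_equal(x$feature_columns, y$feature_columns)
}
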