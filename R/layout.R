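#' @title Force-directed and circle layouts
#' @description
#' Two deterministic layout engines. The force layout is a
#' Fruchterman-Reingold-style simulation (all-pairs repulsion `k^2/d`,
#' spring attraction `d^2/k` along edges, with `k = sqrt(area/n)`) extended
#' with one linear gravity well per organism in the displayed selection,
#' which pulls each protein toward its organism's anchor and so separates
#' species visually. The circle layout places all nodes on one circle in
#' contiguous per-organism arcs. Coordinates follow the SVG convention:
#' origin top-left, y growing downward; angles are measured
#' counter-clockwise in the conventional (y-up) orientation, i.e.
#' `x = cx + r cos(theta)`, `y = cy - r sin(theta)`.
#' @name layout_engine
NULL

#' Layout parameters
#'
#' @param width,height canvas size in pixels.
#' @param repulsion_strength multiplier on the `k^2/d` pairwise repulsion.
#' @param attraction_strength multiplier on the `d^2/k` edge springs.
#' @param gravity_strength linear pull toward the node's organism anchor,
#'   per unit distance per iteration.
#' @param max_iterations iteration cap.
#' @param displacement_tolerance convergence threshold on the maximum
#'   per-node displacement (pixels).
#' @param cooling_factor geometric decay of the displacement cap per
#'   iteration, in (0, 1).
#' @param seed integer seed for the portable generator ([lcg_rng()]) used
#'   for initial jitter.
#' @return an object of class `pinv_layout_params` (a validated list).
#' @export
layout_params <- function(width = 1000, height = 1000,
                          repulsion_strength = 0.05,
                          attraction_strength = 1.0,
                          gravity_strength = 0.5,
                          max_iterations = 1000L,
                          displacement_tolerance = 0.05,
                          cooling_factor = 0.99,
                          seed = 42L) {
  stopifnot(width > 0, height > 0, max_iterations >= 1,
            displacement_tolerance > 0,
            cooling_factor > 0, cooling_factor < 1)
  structure(list(width = width, height = height,
                 repulsion_strength = repulsion_strength,
                 attraction_strength = attraction_strength,
                 gravity_strength = gravity_strength,
                 max_iterations = as.integer(max_iterations),
                 displacement_tolerance = displacement_tolerance,
                 cooling_factor = cooling_factor,
                 seed = as.integer(seed)),
            class = "pinv_layout_params")
}

as_layout_params <- function(x) {
  if (inherits(x, "pinv_layout_params")) return(x)
  do.call(layout_params, x[names(x) %in% names(formals(layout_params))])
}

#' Gravity anchor per organism
#'
#' No organisms: empty. One organism: the canvas center. k >= 2 organisms:
#' anchors evenly spaced, in list order, on a circle of radius
#' `min(width, height)/4` around the canvas center, starting at angle 0
#' (east) and proceeding counter-clockwise.
#' @param organisms ordered character vector (use [organisms_of()] for the
#'   stable lexicographic order).
#' @param params a `pinv_layout_params`.
#' @return numeric matrix with one row per organism, columns `x`, `y`.
#' @examples
#' gravity_centers(c("A", "B"), layout_params(width = 100, height = 100))
#' @export
gravity_centers <- function(organisms, params) {
  params <- as_layout_params(params)
  k <- length(organisms)
  cx <- params$width / 2; cy <- params$height / 2
  if (k == 0) {
    return(matrix(numeric(0), 0, 2, dimnames = list(character(0), c("x", "y"))))
  }
  if (k == 1) {
    m <- matrix(c(cx, cy), 1, 2, dimnames = list(organisms, c("x", "y")))
    return(m)
  }
  r <- min(params$width, params$height) / 4
  theta <- 2 * pi * (seq_len(k) - 1) / k
  m <- cbind(x = cx + r * cos(theta), y = cy - r * sin(theta))
  rownames(m) <- organisms
  m
}

#' Force-directed layout with organism gravity wells
#'
#' Initial positions are jittered around each protein's organism anchor
#' using the portable seeded generator, then iterated: all-pairs repulsion,
#' edge springs, and the gravity pull, with per-node displacement capped by
#' a geometrically cooling temperature (initially `min(width, height)/10`).
#' The simulation stops when the maximum displacement drops below
#' `displacement_tolerance` or after `max_iterations`. Self-interactions
#' exert no force. Identical inputs and seed give bit-identical positions.
#'
#' @param sub a non-empty `pinv_subnetwork`.
#' @param dataset the `pinv_dataset` (for organisms).
#' @param params a `pinv_layout_params`.
#' @return an object of class `pinv_layout`: list with `positions` (matrix,
#'   rownames = accessions, columns `x`, `y`), `iterations_run`,
#'   `converged`, `gravity_centers`, `engine`, `params`.
#' @examples
#' d <- toy6()
#' sub <- search_network(d, "P3", mode = "recursive")
#' force_layout(sub, d, layout_params(seed = 42))
#' @export
force_layout <- function(sub, dataset, params = layout_params()) {
  params <- as_layout_params(params)
  n <- length(sub$proteins)
  if (n == 0) stop("cannot lay out an empty subnetwork")
  acc <- sub$proteins
  orgs_all <- organisms_of(sub, dataset)
  centers <- gravity_centers(orgs_all, params)
  node_org <- dataset$proteins$organism[match(acc, dataset$proteins$accession)]
  cx <- centers[node_org, "x"]; cy <- centers[node_org, "y"]

  rng <- lcg_rng(params$seed)
  jitter_amp <- if (n == 1) 0 else min(params$width, params$height) / 20
  x <- cx + (rng(n) * 2 - 1) * jitter_amp
  y <- cy + (rng(n) * 2 - 1) * jitter_amp

  ed <- sub$interactions[sub$interactions$a != sub$interactions$b, , drop = FALSE]
  ea <- match(ed$a, acc); eb <- match(ed$b, acc)

  area <- params$width * params$height
  k <- sqrt(area / n)
  eps <- 1e-4
  temp <- min(params$width, params$height) / 10
  iter <- 0L
  converged <- FALSE

  while (iter < params$max_iterations) {
    iter <- iter + 1L
    # all-pairs repulsion k^2/d (capped implicitly by the temperature)
    dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
    d <- sqrt(dx * dx + dy * dy)
    d[d < eps] <- eps
    f_rep <- params$repulsion_strength * (k * k) / d
    diag(f_rep) <- 0
    dispx <- rowSums(dx / d * f_rep)
    dispy <- rowSums(dy / d * f_rep)
    # spring attraction d^2/k along edges
    if (length(ea)) {
      exd <- x[ea] - x[eb]; eyd <- y[ea] - y[eb]
      edist <- sqrt(exd * exd + eyd * eyd)
      edist[edist < eps] <- eps
      f_att <- params$attraction_strength * edist * edist / k
      fx <- exd / edist * f_att; fy <- eyd / edist * f_att
      racc <- rowsum(c(-fx, fx, -fy, fy), c(ea, eb, ea + n, eb + n))
      ridx <- as.integer(rownames(racc))
      nodes <- ridx[ridx <= n]
      dispx[nodes] <- dispx[nodes] + racc[ridx <= n, 1]
      nodes2 <- ridx[ridx > n] - n
      dispy[nodes2] <- dispy[nodes2] + racc[ridx > n, 1]
    }
    # gravity toward the organism anchor
    dispx <- dispx + params$gravity_strength * (cx - x)
    dispy <- dispy + params$gravity_strength * (cy - y)
    # displacement capped by the cooling temperature
    dl <- sqrt(dispx * dispx + dispy * dispy)
    scale <- ifelse(dl > temp, temp / dl, 1)
    nx <- pmin(params$width, pmax(0, x + dispx * scale))
    ny <- pmin(params$height, pmax(0, y + dispy * scale))
    moved <- sqrt((nx - x)^2 + (ny - y)^2)
    x <- nx; y <- ny
    if (max(moved) < params$displacement_tolerance) { converged <- TRUE; break }
    temp <- temp * params$cooling_factor
  }

  pos <- cbind(x = unname(x), y = unname(y))
  rownames(pos) <- acc
  structure(list(positions = pos, iterations_run = iter, converged = converged,
                 gravity_centers = centers, engine = "force", params = params),
            class = "pinv_layout")
}

#' Circle layout with contiguous organism arcs
#'
#' All nodes sit on one circle of radius `0.4 * min(width, height)` around
#' the canvas center, so no protein is favoured. Organisms occupy
#' contiguous arcs in lexicographic order, separated by a one-slot gap each
#' (no gaps when a single organism is displayed); within an arc nodes are
#' ordered lexicographically by accession. Slot 0 is at angle 0 (east),
#' slots proceed counter-clockwise. Fully deterministic.
#' @inheritParams force_layout
#' @export
circle_layout <- function(sub, dataset, params = layout_params()) {
  params <- as_layout_params(params)
  n <- length(sub$proteins)
  if (n == 0) stop("cannot lay out an empty subnetwork")
  orgs <- organisms_of(sub, dataset)
  node_org <- dataset$proteins$organism[match(sub$proteins, dataset$proteins$accession)]
  m <- length(orgs)
  gaps <- if (m > 1) m else 0L
  slots <- n + gaps
  R <- 0.4 * min(params$width, params$height)
  cx <- params$width / 2; cy <- params$height / 2

  pos <- matrix(NA_real_, n, 2, dimnames = list(character(n), c("x", "y")))
  slot <- 0L
  row <- 1L
  for (org in orgs) {
    members <- sort(sub$proteins[node_org == org], method = "radix")
    for (a in members) {
      theta <- 2 * pi * slot / slots
      pos[row, ] <- c(cx + R * cos(theta), cy - R * sin(theta))
      rownames(pos)[row] <- a
      row <- row + 1L
      slot <- slot + 1L
    }
    if (m > 1) slot <- slot + 1L  # one empty slot between organism arcs
  }
  structure(list(positions = pos, iterations_run = 0L, converged = TRUE,
                 gravity_centers = gravity_centers(orgs, params),
                 engine = "circle", params = params),
            class = "pinv_layout")
}

#' @export
print.pinv_layout <- function(x, ...) {
  cat(sprintf("%s layout: %d nodes, %d iterations, converged = %s\n",
              x$engine, nrow(x$positions), x$iterations_run, x$converged))
  invisible(x)
}
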