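#' @title Synthetic datasets and the TOY6 fixture
#' @description
#' A deterministic generator of synthetic two-organism-style datasets (used
#' throughout the tests and documentation in place of hosted reference
#' datasets) plus TOY6, a fixed six-protein, five-interaction network small
#' enough to verify every operation by hand.
#' @name fixtures
NULL

TOY6_INTERACTIONS <- paste(
  "accession_a\taccession_b\tscore\tstring",
  "P1\tP2\t0.9\t",
  "P1\tP3\t0.8\t",
  "P2\tP3\t0.7\t",
  "P3\tP4\t0.6\t0.5",
  "P4\tP5\t0.5\t",
  "", sep = "\n")

TOY6_FEATURES <- paste(
  "accession\torganism\tdescription",
  "P1\tA\tkinase alpha",
  "P2\tA\tkinase beta",
  "P3\tA\tSensor histidine kinase",
  "P4\tB\tSensor regulator",
  "P5\tB\ttransporter",
  "P6\tB\torphan",
  "", sep = "\n")

#' The TOY6 fixture dataset
#'
#' Six proteins (P1-P3 organism "A", P4-P6 organism "B") with a
#' `description` feature, five scored interactions (P1-P2 0.9, P1-P3 0.8,
#' P2-P3 0.7, P3-P4 0.6, P4-P5 0.5) and one evidence source `string`
#' present (0.5) only on P3-P4. P6 is isolated. Built through the parsers,
#' so it also exercises the file format.
#' @return a `pinv_dataset`.
#' @examples
#' toy6()
#' @export
toy6 <- function() {
  build_dataset(parse_interactions(TOY6_INTERACTIONS),
                parse_features(TOY6_FEATURES))
}

#' Specification for the synthetic dataset generator
#'
#' @param n_proteins number of proteins (>= 1).
#' @param organisms named numeric vector of organism proportions summing to
#'   1 (default two organisms at 0.5 each). Block sizes use largest-remainder
#'   rounding.
#' @param edge_probability probability of an interaction between two
#'   proteins of the same organism.
#' @param cross_organism_probability probability of an interaction between
#'   proteins of different organisms.
#' @param n_evidence_sources number of evidence columns; each cell is
#'   present with probability 0.5.
#' @param feature_vocab named list: feature column -> vector of values to
#'   sample uniformly.
#' @param n_conditions number of expression conditions (values uniform on
#'   (0, 10)).
#' @param seed integer seed for the portable generator.
#' @return an object of class `pinv_generator_spec`.
#' @export
generator_spec <- function(n_proteins,
                           organisms = c(ORG1 = 0.5, ORG2 = 0.5),
                           edge_probability = 0.2,
                           cross_organism_probability = 0.05,
                           n_evidence_sources = 2L,
                           feature_vocab = list(
                             description = c("kinase", "transporter", "regulator",
                                             "sensor", "chaperone")),
                           n_conditions = 2L,
                           seed = 1L) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  if (abs(sum(organisms) - 1) > 1e-9) stop("organism proportions must sum to 1")
  if (edge_probability < 0 || edge_probability > 1 ||
      cross_organism_probability < 0 || cross_organism_probability > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  structure(list(n_proteins = as.integer(n_proteins), organisms = organisms,
                 edge_probability = edge_probability,
                 cross_organism_probability = cross_organism_probability,
                 n_evidence_sources = as.integer(n_evidence_sources),
                 feature_vocab = feature_vocab,
                 n_conditions = as.integer(n_conditions),
                 seed = as.integer(seed)),
            class = "pinv_generator_spec")
}

# largest-remainder apportionment of n into blocks by proportion
apportion <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic dataset
#'
#' Produces the three TSV file contents (interactions, features,
#' expression) for a random network: proteins split into organism blocks by
#' proportion, within-organism pairs joined with `edge_probability`,
#' cross-organism pairs with `cross_organism_probability`, scores uniform
#' on (0, 1], evidence cells present with probability 0.5. Deterministic
#' for a fixed seed; output parses cleanly (zero warnings) through the
#' dataset parsers.
#' @param spec a `pinv_generator_spec`.
#' @return list with `interactions`, `features`, `expression` (TSV
#'   strings).
#' @examples
#' g <- generate_dataset(generator_spec(10, seed = 7))
#' build_dataset(parse_interactions(g$interactions), parse_features(g$features))
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "pinv_generator_spec"))
  rng <- lcg_rng(spec$seed)
  n <- spec$n_proteins
  pad <- nchar(as.character(n))
  acc <- sprintf(paste0("P%0", pad, "d"), seq_len(n))
  sizes <- apportion(n, spec$organisms)
  org <- rep(names(spec$organisms), sizes)

  # features file
  ft_names <- names(spec$feature_vocab)
  ft_lines <- paste(c("accession", "organism", ft_names), collapse = "\t")
  for (i in seq_len(n)) {
    vals <- vapply(ft_names, function(f) {
      vocab <- spec$feature_vocab[[f]]
      vocab[1L + floor(rng(1) * length(vocab))]
    }, "")
    ft_lines <- c(ft_lines, paste(c(acc[i], org[i], vals), collapse = "\t"))
  }

  # interactions: iterate unordered pairs i < j in row-major order
  ev_names <- if (spec$n_evidence_sources > 0)
    paste0("evidence", seq_len(spec$n_evidence_sources)) else character(0)
  int_lines <- paste(c("accession_a", "accession_b", "score", ev_names),
                     collapse = "\t")
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        p <- if (org[i] == org[j]) spec$edge_probability
             else spec$cross_organism_probability
        if (rng(1) < p) {
          score <- 1 - rng(1)  # uniform on (0, 1]
          ev <- vapply(seq_len(spec$n_evidence_sources), function(s) {
            pres <- rng(1) < 0.5
            val <- rng(1)  # always drawn, keeps the stream aligned
            if (pres) sprintf("%.6f", val) else ""
          }, "")
          int_lines <- c(int_lines,
                         paste(c(acc[i], acc[j], sprintf("%.6f", score), ev),
                               collapse = "\t"))
        }
      }
    }
  }

  # expression file
  ex_lines <- character(0)
  if (spec$n_conditions > 0) {
    ex_lines <- paste(c("id", paste0("cond", seq_len(spec$n_conditions))),
                      collapse = "\t")
    for (i in seq_len(n)) {
      vals <- sprintf("%.4f", rng(spec$n_conditions) * 10)
      ex_lines <- c(ex_lines, paste(c(acc[i], vals), collapse = "\t"))
    }
  }

  list(interactions = paste0(paste(int_lines, collapse = "\n"), "\n"),
       features = paste0(paste(ft_lines, collapse = "\n"), "\n"),
       expression = if (length(ex_lines))
         paste0(paste(ex_lines, collapse = "\n"), "\n") else "")
}

#' Generate and assemble a synthetic dataset in one step
#' @param spec a `pinv_generator_spec`.
#' @param expression attach the generated expression matrix?
#' @return a `pinv_dataset`.
#' @export
generate_pinv_dataset <- function(spec, expression = TRUE) {
  g <- generate_dataset(spec)
  build_dataset(parse_interactions(g$interactions),
                parse_features(g$features),
                if (expression && nzchar(g$expression))
                  parse_expression(g$expression) else NULL)
}
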