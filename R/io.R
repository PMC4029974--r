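#' @title Parsing and writing the two-file PPI dataset format
#'
#' @description
#' The dataset format is two (optionally three) UTF-8 tab-separated files:
#'
#' * interactions: accession A, accession B, aggregate confidence score,
#'   then optional per-source evidence score columns;
#' * features: accession, organism, then arbitrary annotation columns;
#' * expression (optional): accession, then one numeric column per condition.
#'
#' Lines starting with `#` and trailing blank lines are ignored. A first line
#' whose third field is non-numeric is treated as a header naming the
#' evidence columns (interactions file); for the features file, where every
#' cell is text, a first line whose first field is one of `id`, `accession`,
#' `protein`, `protein_id` (case-insensitive) is taken as the header. The
#' expression file always carries a header naming the conditions.
#'
#' @name ppi_io
NULL

# split one TSV line keeping trailing empty fields (strsplit drops them)
split_tsv <- function(line) {
  f <- strsplit(paste0(line, "\x01"), "\t", fixed = TRUE)[[1]]
  f[length(f)] <- sub("\x01$", "", f[length(f)])
  f
}

# returns data.frame(line = original line number, text), comments/blanks gone
tsv_lines <- function(text) {
  raw <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  raw <- sub("\r$", "", raw)
  keep <- nzchar(trimws(raw)) & !startsWith(trimws(raw), "#")
  data.frame(line = which(keep), text = raw[keep], stringsAsFactors = FALSE)
}

is_num <- function(x) {
  # NaN counts as numeric here (it parses, then fails the finiteness check)
  !is.na(suppressWarnings(as.numeric(x))) | grepl("^[-+]?nan$", tolower(trimws(x)))
}

#' Parse an interactions TSV
#'
#' Columns: accession A, accession B, aggregate score, then evidence scores.
#' Endpoints are canonicalised so that `a <= b`; duplicate unordered pairs
#' keep the record with the highest aggregate score (warning); self
#' interactions are kept and flagged. Empty evidence cells become `NA`
#' ("absent"). Score range is not validated, only finiteness.
#'
#' @param text TSV content (single string or character vector of lines).
#' @param evidence_names optional character vector naming evidence columns;
#'   overrides a header line; otherwise `evidence1`, `evidence2`, ... are used.
#' @return list with `interactions` (data.frame `a`, `b`, `score`, one numeric
#'   column per evidence source), `evidence_columns`, `warnings`.
#' @examples
#' parse_interactions("P2\tP1\t0.9\n")$interactions
#' @export
parse_interactions <- function(text, evidence_names = NULL) {
  ll <- tsv_lines(text)
  warnings <- character(0)
  header_ev <- NULL
  if (nrow(ll) > 0) {
    f1 <- split_tsv(ll$text[1])
    if (length(f1) >= 3 && !is_num(f1[3])) {
      header_ev <- if (length(f1) > 3) f1[-(1:3)] else character(0)
      ll <- ll[-1, , drop = FALSE]
    }
  }
  n <- nrow(ll)
  recs <- vector("list", n)
  max_ev <- 0L
  for (i in seq_len(n)) {
    f <- split_tsv(ll$text[i])
    if (length(f) < 3) {
      stop(sprintf("interactions line %d: expected at least 3 tab-separated fields, got %d",
                   ll$line[i], length(f)))
    }
    score <- suppressWarnings(as.numeric(f[3]))
    if (is.na(score) || !is.finite(score)) {
      stop(sprintf("interactions line %d: score '%s' is not a finite number",
                   ll$line[i], f[3]))
    }
    ev <- if (length(f) > 3) f[-(1:3)] else character(0)
    max_ev <- max(max_ev, length(ev))
    a <- f[1]; b <- f[2]
    if (!nzchar(a) || !nzchar(b)) {
      stop(sprintf("interactions line %d: empty accession", ll$line[i]))
    }
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    recs[[i]] <- list(a = a, b = b, score = score, ev = ev, line = ll$line[i])
  }
  ev_names <- if (!is.null(evidence_names)) as.character(evidence_names)
              else if (!is.null(header_ev)) header_ev
              else if (max_ev > 0) paste0("evidence", seq_len(max_ev))
              else character(0)
  n_ev <- max(length(ev_names), max_ev)
  if (length(ev_names) < n_ev) {
    ev_names <- c(ev_names, paste0("evidence", seq(length(ev_names) + 1, n_ev)))
  }
  df <- data.frame(a = character(n), b = character(n), score = numeric(n),
                   stringsAsFactors = FALSE)
  ev_mat <- matrix(NA_real_, nrow = n, ncol = length(ev_names),
                   dimnames = list(NULL, ev_names))
  for (i in seq_len(n)) {
    r <- recs[[i]]
    df$a[i] <- r$a; df$b[i] <- r$b; df$score[i] <- r$score
    for (j in seq_along(r$ev)) {
      cell <- r$ev[j]
      if (nzchar(cell)) {
        v <- suppressWarnings(as.numeric(cell))
        if (is.na(v) || !is.finite(v)) {
          stop(sprintf("interactions line %d: evidence value '%s' is not a finite number",
                       r$line, cell))
        }
        ev_mat[i, j] <- v
      }
    }
    if (r$a == r$b) {
      warnings <- c(warnings, sprintf("self-interaction %s-%s kept (skipped by layouts)",
                                      r$a, r$b))
    }
  }
  df <- cbind(df, as.data.frame(ev_mat, stringsAsFactors = FALSE))
  # duplicate unordered pairs: keep the highest aggregate score
  key <- paste(df$a, df$b, sep = "\t")
  if (anyDuplicated(key)) {
    keep <- rep(TRUE, n)
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[which.max(df$score[idx])]
      keep[setdiff(idx, best)] <- FALSE
      warnings <- c(warnings, sprintf(
        "duplicate interaction %s: kept highest score %g of %d records",
        gsub("\t", "-", k), df$score[best], length(idx)))
    }
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  list(interactions = df, evidence_columns = ev_names, warnings = warnings)
}

#' Parse a features TSV
#'
#' Columns: accession, organism, then annotation columns. A duplicated
#' accession keeps the last record seen (warning); an empty organism cell is
#' replaced by the `"unspecified"` placeholder (warning).
#'
#' @param text TSV content.
#' @param feature_names optional names for columns 3+; otherwise taken from a
#'   header line or auto-named `feature1`, ...
#' @return list with `proteins` (data.frame `accession`, `organism`, one
#'   character column per feature), `feature_columns`, `warnings`.
#' @export
parse_features <- function(text, feature_names = NULL) {
  ll <- tsv_lines(text)
  warnings <- character(0)
  header_ft <- NULL
  if (nrow(ll) > 0) {
    f1 <- split_tsv(ll$text[1])
    if (tolower(f1[1]) %in% c("id", "accession", "protein", "protein_id")) {
      header_ft <- if (length(f1) > 2) f1[-(1:2)] else character(0)
      ll <- ll[-1, , drop = FALSE]
    }
  }
  n <- nrow(ll)
  acc <- character(n); org <- character(n)
  feats <- vector("list", n)
  max_ft <- 0L
  for (i in seq_len(n)) {
    f <- split_tsv(ll$text[i])
    if (length(f) < 2) {
      stop(sprintf("features line %d: missing organism column (need at least 2 fields)",
                   ll$line[i]))
    }
    if (!nzchar(f[1])) stop(sprintf("features line %d: empty accession", ll$line[i]))
    acc[i] <- f[1]
    if (!nzchar(f[2])) {
      org[i] <- "unspecified"
      warnings <- c(warnings, sprintf("protein %s: empty organism replaced by 'unspecified'", f[1]))
    } else org[i] <- f[2]
    feats[[i]] <- if (length(f) > 2) f[-(1:2)] else character(0)
    max_ft <- max(max_ft, length(feats[[i]]))
  }
  ft_names <- if (!is.null(feature_names)) as.character(feature_names)
              else if (!is.null(header_ft)) header_ft
              else if (max_ft > 0) paste0("feature", seq_len(max_ft))
              else character(0)
  n_ft <- max(length(ft_names), max_ft)
  if (length(ft_names) < n_ft) {
    ft_names <- c(ft_names, paste0("feature", seq(length(ft_names) + 1, n_ft)))
  }
  ft_mat <- matrix("", nrow = n, ncol = length(ft_names),
                   dimnames = list(NULL, ft_names))
  for (i in seq_len(n)) {
    v <- feats[[i]]
    if (length(v)) ft_mat[i, seq_along(v)] <- v
  }
  df <- data.frame(accession = acc, organism = org, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ft_mat, stringsAsFactors = FALSE))
  if (anyDuplicated(df$accession)) {
    dups <- unique(df$accession[duplicated(df$accession)])
    for (d in dups) {
      warnings <- c(warnings, sprintf("duplicate accession %s: last record kept", d))
    }
    df <- df[!duplicated(df$accession, fromLast = TRUE), , drop = FALSE]
    rownames(df) <- NULL
  }
  list(proteins = df, feature_columns = ft_names, warnings = warnings)
}

#' Parse an expression TSV
#'
#' First column accession, remaining columns numeric; the first line is the
#' header naming the conditions. Returns a numeric matrix with accessions as
#' row names and conditions as column names; empty input yields a 0 x 0
#' matrix.
#'
#' @param text TSV content.
#' @export
parse_expression <- function(text) {
  ll <- tsv_lines(text)
  if (nrow(ll) == 0) {
    return(matrix(numeric(0), 0, 0))
  }
  hdr <- split_tsv(ll$text[1])
  conds <- if (length(hdr) > 1) hdr[-1] else character(0)
  ll <- ll[-1, , drop = FALSE]
  n <- nrow(ll)
  m <- matrix(NA_real_, nrow = n, ncol = length(conds),
              dimnames = list(NULL, conds))
  acc <- character(n)
  for (i in seq_len(n)) {
    f <- split_tsv(ll$text[i])
    acc[i] <- f[1]
    vals <- if (length(f) > 1) f[-1] else character(0)
    if (length(vals) != length(conds)) {
      stop(sprintf("expression line %d: expected %d value columns, got %d",
                   ll$line[i], length(conds), length(vals)))
    }
    for (j in seq_along(vals)) {
      v <- suppressWarnings(as.numeric(vals[j]))
      if (is.na(v)) {
        stop(sprintf("expression row %d, column %s: non-numeric value '%s'",
                     i, conds[j], vals[j]))
      }
      m[i, j] <- v
    }
  }
  if (anyDuplicated(acc)) {
    m <- m[!duplicated(acc, fromLast = TRUE), , drop = FALSE]
    acc <- acc[!duplicated(acc, fromLast = TRUE)]
  }
  rownames(m) <- acc
  m
}

#' Assemble a dataset from parsed interactions and features
#'
#' Repairs rather than rejects: interaction endpoints absent from the
#' features file get a stub protein record with organism `"unspecified"`;
#' every repair is logged in `warnings`. Proteins present only in the
#' features file are kept (they are reachable by search and autocomplete).
#'
#' @param interactions result of [parse_interactions()] (or a compatible
#'   data.frame).
#' @param proteins result of [parse_features()] (or a compatible data.frame).
#' @param expression optional matrix from [parse_expression()].
#' @return an object of class `pinv_dataset`: list with `proteins`,
#'   `interactions`, `evidence_columns`, `feature_columns`, `expression`,
#'   `warnings`.
#' @examples
#' d <- build_dataset(parse_interactions("P1\tP2\t0.9\n"),
#'                    parse_features("P1\torgA\n"))
#' d$warnings  # stub record for P2
#' @export
build_dataset <- function(interactions, proteins, expression = NULL) {
  warnings <- character(0)
  if (is.data.frame(interactions)) {
    ev_cols <- setdiff(colnames(interactions), c("a", "b", "score"))
    interactions <- list(interactions = interactions, evidence_columns = ev_cols,
                         warnings = character(0))
  }
  if (is.data.frame(proteins)) {
    ft_cols <- setdiff(colnames(proteins), c("accession", "organism"))
    proteins <- list(proteins = proteins, feature_columns = ft_cols,
                     warnings = character(0))
  }
  warnings <- c(interactions$warnings, proteins$warnings)
  ints <- interactions$interactions
  prot <- proteins$proteins

  # defensive dedup (keep max score) in case records were assembled by hand
  key <- paste(ints$a, ints$b, sep = "\t")
  if (anyDuplicated(key)) {
    keep <- rep(TRUE, nrow(ints))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      best <- idx[which.max(ints$score[idx])]
      keep[setdiff(idx, best)] <- FALSE
      warnings <- c(warnings, sprintf("duplicate interaction %s: kept highest score",
                                      gsub("\t", "-", k)))
    }
    ints <- ints[keep, , drop = FALSE]
    rownames(ints) <- NULL
  }

  missing <- setdiff(unique(c(ints$a, ints$b)), prot$accession)
  if (length(missing)) {
    stub <- prot[0, , drop = FALSE]
    stub[seq_along(missing), ] <- ""
    stub$accession <- missing
    stub$organism <- "unspecified"
    prot <- rbind(prot, stub)
    rownames(prot) <- NULL
    warnings <- c(warnings, sprintf(
      "protein %s appears in interactions but not in features; stub record added",
      missing))
  }
  if (!is.null(expression) && nrow(expression) > 0) {
    unknown <- setdiff(rownames(expression), prot$accession)
    if (length(unknown)) {
      warnings <- c(warnings, sprintf(
        "expression row %s does not match any protein; dropped", unknown))
      expression <- expression[!rownames(expression) %in% unknown, , drop = FALSE]
    }
  }
  structure(list(
    proteins = prot,
    interactions = ints,
    evidence_columns = interactions$evidence_columns,
    feature_columns = proteins$feature_columns,
    expression = expression,
    warnings = warnings
  ), class = "pinv_dataset")
}

#' Load a dataset from files
#'
#' Convenience wrapper reading the interactions, features and optional
#' expression files and assembling the dataset.
#' @param interactions_path,features_path,expression_path file paths.
#' @export
read_dataset <- function(interactions_path, features_path, expression_path = NULL) {
  ints <- parse_interactions(readChar(interactions_path, file.size(interactions_path)))
  prot <- parse_features(readChar(features_path, file.size(features_path)))
  expr <- NULL
  if (!is.null(expression_path)) {
    expr <- parse_expression(readChar(expression_path, file.size(expression_path)))
  }
  build_dataset(ints, prot, expr)
}

fmt_cell <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) format(v, digits = 15, scientific = FALSE), ""))
}

#' Serialise a dataset back to its TSV files
#'
#' Writes the same tab-separated dialect the parsers read (header line
#' included), so that a parse -> write -> parse round trip is the identity.
#' @param dataset a `pinv_dataset`.
#' @return a single TSV string.
#' @export
write_interactions_tsv <- function(dataset) {
  ints <- dataset$interactions
  ev <- dataset$evidence_columns
  header <- paste(c("accession_a", "accession_b", "score", ev), collapse = "\t")
  rows <- vapply(seq_len(nrow(ints)), function(i) {
    paste(c(ints$a[i], ints$b[i], fmt_cell(ints$score[i]),
            if (length(ev)) fmt_cell(unlist(ints[i, ev, drop = TRUE]))),
          collapse = "\t")
  }, "")
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' @rdname write_interactions_tsv
#' @export
write_features_tsv <- function(dataset) {
  prot <- dataset$proteins
  ft <- dataset$feature_columns
  header <- paste(c("accession", "organism", ft), collapse = "\t")
  rows <- vapply(seq_len(nrow(prot)), function(i) {
    paste(c(prot$accession[i], prot$organism[i],
            if (length(ft)) as.character(unlist(prot[i, ft, drop = TRUE]))),
          collapse = "\t")
  }, "")
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' @rdname write_interactions_tsv
#' @export
write_expression_tsv <- function(dataset) {
  ex <- dataset$expression
  if (is.null(ex) || nrow(ex) == 0) return("")
  header <- paste(c("id", colnames(ex)), collapse = "\t")
  rows <- vapply(seq_len(nrow(ex)), function(i) {
    paste(c(rownames(ex)[i], fmt_cell(ex[i, ])), collapse = "\t")
  }, "")
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' Write rows as RFC 4180 CSV
#'
#' Header row first, CRLF record separators, fields quoted only when they
#' contain a comma, quote, CR or LF (quotes doubled). Missing row entries
#' become empty cells.
#'
#' @param rows a data.frame or list of named lists.
#' @param columns ordered character vector of column names.
#' @return a single CSV string.
#' @examples
#' write_table_csv(data.frame(a = 1, b = 2), c("a", "b"))
#' @export
write_table_csv <- function(rows, columns) {
  quote_field <- function(x) {
    x <- ifelse(is.na(x), "", as.character(x))
    need <- grepl('[",\r\n]', x)
    x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
    x
  }
  if (is.data.frame(rows)) {
    rows <- lapply(seq_len(nrow(rows)), function(i) as.list(rows[i, , drop = FALSE]))
  }
  lines <- paste(quote_field(columns), collapse = ",")
  for (r in rows) {
    cells <- vapply(columns, function(cn) {
      v <- r[[cn]]
      if (is.null(v) || length(v) == 0 || is.na(v)) "" else
        if (is.numeric(v)) format(v, digits = 15, scientific = FALSE) else as.character(v)
    }, "")
    lines <- c(lines, paste(quote_field(cells), collapse = ","))
  }
  paste0(paste(lines, collapse = "\r\n"), "\r\n")
}

#' @export
print.pinv_dataset <- function(x, ...) {
  cat(sprintf("PPI dataset: %d proteins (%d organisms), %d interactions\n",
              nrow(x$proteins), length(unique(x$proteins$organism)),
              nrow(x$interactions)))
  if (length(x$evidence_columns))
    cat("  evidence sources:", paste(x$evidence_columns, collapse = ", "), "\n")
  if (length(x$feature_columns))
    cat("  feature columns: ", paste(x$feature_columns, collapse = ", "), "\n")
  if (!is.null(x$expression) && nrow(x$expression))
    cat(sprintf("  expression: %d proteins x %d conditions\n",
                nrow(x$expression), ncol(x$expression)))
  if (length(x$warnings))
    cat(sprintf("  %d warning(s); see $warnings\n", length(x$warnings)))
  invisible(x)
}
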