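#' @title SVG / PNG / table export
#' @description
#' Renders the styled, laid-out subnetwork: edges as `<line>` elements
#' beneath nodes as `<circle>` elements, optional `<text>` labels, and a
#' legend group on the right-hand side. Output is byte-stable for fixed
#' inputs (no timestamps, fixed number formatting, fixed element ordering:
#' edges by canonical key, nodes by accession). Self-interactions appear
#' only in the table/CSV view, never in the drawing.
#' @name render_export
NULL

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

fmt_coord <- function(x) sprintf("%.3f", x)

ORGANISM_SHAPES <- c("circle", "square", "diamond")

#' Render the displayed subnetwork as SVG
#'
#' @param sub the displayed `pinv_subnetwork`.
#' @param layout a `pinv_layout` covering every displayed protein.
#' @param style a `pinv_style` from [apply_rules()].
#' @param options list; `shape_by_organism = TRUE` draws organisms as
#'   circle/square/diamond in lexicographic order (requires `dataset`);
#'   `dataset` the source dataset (only needed for shapes).
#' @return an object of class `pinv_svg` (a single SVG 1.1 string).
#' @examples
#' d <- toy6()
#' sub <- search_network(d, "P3", mode = "recursive")
#' svg <- render_svg(sub, circle_layout(sub, d), apply_rules(sub, list(), d))
#' @export
render_svg <- function(sub, layout, style, options = list()) {
  pos <- layout$positions
  missing <- setdiff(sub$proteins, rownames(pos))
  if (length(missing)) {
    stop(sprintf("no layout position for displayed protein(s): %s",
                 paste(missing, collapse = ", ")))
  }
  ns <- style$node_style
  es <- style$edge_style
  visible_nodes <- ns$accession[ns$visible]
  w <- layout$params$width; h <- layout$params$height

  shapes <- NULL
  if (isTRUE(options$shape_by_organism)) {
    if (is.null(options$dataset)) stop("shape_by_organism requires options$dataset")
    orgs <- organisms_of(sub, options$dataset)
    shape_of_org <- stats::setNames(
      ORGANISM_SHAPES[((seq_along(orgs) - 1L) %% length(ORGANISM_SHAPES)) + 1L], orgs)
    node_org <- options$dataset$proteins$organism[
      match(ns$accession, options$dataset$proteins$accession)]
    shapes <- stats::setNames(shape_of_org[node_org], ns$accession)
  }

  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
                   fmt_coord(w), fmt_coord(h), fmt_coord(w), fmt_coord(h)))

  # edges beneath nodes; drawn only when the edge and both endpoints are
  # visible; self-loops skipped; ordered by canonical key
  ekey <- paste(es$a, es$b, sep = "|")
  eord <- order(ekey, method = "radix")
  out <- c(out, '<g id="edges">')
  for (i in eord) {
    if (!es$visible[i]) next
    if (es$a[i] == es$b[i]) next
    if (!(es$a[i] %in% visible_nodes && es$b[i] %in% visible_nodes)) next
    out <- c(out, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
                          fmt_coord(pos[es$a[i], "x"]), fmt_coord(pos[es$a[i], "y"]),
                          fmt_coord(pos[es$b[i], "x"]), fmt_coord(pos[es$b[i], "y"]),
                          es$color[i], fmt_coord(es$width[i])))
  }
  out <- c(out, "</g>", '<g id="nodes">')
  nord <- order(ns$accession, method = "radix")
  for (i in nord) {
    if (!ns$visible[i]) next
    a <- ns$accession[i]
    x <- pos[a, "x"]; y <- pos[a, "y"]; r <- ns$size[i]
    shape <- if (is.null(shapes)) "circle" else shapes[[a]]
    if (shape == "circle") {
      out <- c(out, sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s" data-accession="%s"/>',
                            fmt_coord(x), fmt_coord(y), fmt_coord(r), ns$color[i],
                            xml_escape(a)))
    } else if (shape == "square") {
      out <- c(out, sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" data-accession="%s"/>',
                            fmt_coord(x - r), fmt_coord(y - r), fmt_coord(2 * r),
                            fmt_coord(2 * r), ns$color[i], xml_escape(a)))
    } else {  # diamond
      pts <- sprintf("%s,%s %s,%s %s,%s %s,%s",
                     fmt_coord(x), fmt_coord(y - r), fmt_coord(x + r), fmt_coord(y),
                     fmt_coord(x), fmt_coord(y + r), fmt_coord(x - r), fmt_coord(y))
      out <- c(out, sprintf('<polygon points="%s" fill="%s" data-accession="%s"/>',
                            pts, ns$color[i], xml_escape(a)))
    }
  }
  out <- c(out, "</g>", '<g id="labels" font-family="sans-serif" font-size="10">')
  for (i in nord) {
    if (!ns$visible[i] || is.na(ns$label[i])) next
    a <- ns$accession[i]
    out <- c(out, sprintf('<text x="%s" y="%s">%s</text>',
                          fmt_coord(pos[a, "x"] + ns$size[i] + 3),
                          fmt_coord(pos[a, "y"] + 3),
                          xml_escape(ns$label[i])))
  }
  out <- c(out, "</g>")
  if (nrow(style$legend) > 0) {
    out <- c(out, '<g id="legend" font-family="sans-serif" font-size="10">')
    lx <- w - 150
    for (i in seq_len(nrow(style$legend))) {
      ly <- 20 + 16 * (i - 1)
      out <- c(out, sprintf('<rect x="%s" y="%s" width="10" height="10" fill="%s"/>',
                            fmt_coord(lx), fmt_coord(ly), style$legend$color[i]),
               sprintf('<text x="%s" y="%s">%s</text>',
                       fmt_coord(lx + 14), fmt_coord(ly + 9),
                       xml_escape(style$legend$value[i])))
    }
    out <- c(out, "</g>")
  }
  out <- c(out, "</svg>")
  structure(paste(out, collapse = "\n"), class = "pinv_svg")
}

#' @export
print.pinv_svg <- function(x, ...) {
  doc <- xml2::read_xml(unclass(x))
  cat(sprintf("SVG document: %d nodes, %d edges, %d labels, %d legend entries\n",
              length(xml2::xml_find_all(doc, "//*[local-name()='g'][@id='nodes']/*")),
              length(xml2::xml_find_all(doc, "//*[local-name()='g'][@id='edges']/*")),
              length(xml2::xml_find_all(doc, "//*[local-name()='g'][@id='labels']/*")),
              length(xml2::xml_find_all(doc, "//*[local-name()='g'][@id='legend']/*[local-name()='text']"))))
  invisible(x)
}

#' Write an SVG document to a file byte-for-byte
#' @param svg a `pinv_svg`.
#' @param path output path.
#' @export
write_svg <- function(svg, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(unclass(svg), con, eos = NULL)
  invisible(path)
}

#' Table view of the displayed interactions
#'
#' One row per displayed interaction (self-interactions included) with the
#' endpoints, their organisms, the aggregate score and the evidence columns.
#' Sorting is stable; ties on `accession` are broken by the second endpoint.
#' @param sub the displayed `pinv_subnetwork`.
#' @param dataset the `pinv_dataset`.
#' @param sort_by `"accession"`, `"score"`, an evidence column, or a feature
#'   column (sorts on endpoint A's value, ties on endpoint B's).
#' @param descending logical.
#' @return data.frame.
#' @export
render_table <- function(sub, dataset, sort_by = "accession", descending = FALSE) {
  ints <- sub$interactions
  prot <- dataset$proteins
  df <- data.frame(accession_a = ints$a, accession_b = ints$b,
                   organism_a = prot$organism[match(ints$a, prot$accession)],
                   organism_b = prot$organism[match(ints$b, prot$accession)],
                   score = ints$score, stringsAsFactors = FALSE)
  for (ev in dataset$evidence_columns) df[[ev]] <- ints[[ev]]
  ord <- if (sort_by == "accession") {
    order(df$accession_a, df$accession_b, method = "radix",
          decreasing = descending)
  } else if (sort_by == "score" || sort_by %in% dataset$evidence_columns) {
    order(df[[if (sort_by == "score") "score" else sort_by]],
          method = "radix", decreasing = descending)
  } else if (sort_by %in% dataset$feature_columns) {
    va <- prot[[sort_by]][match(ints$a, prot$accession)]
    vb <- prot[[sort_by]][match(ints$b, prot$accession)]
    order(va, vb, method = "radix", decreasing = descending)
  } else {
    stop(sprintf("unknown sort column '%s'; available: accession, score, %s",
                 sort_by, paste(c(dataset$evidence_columns,
                                  dataset$feature_columns), collapse = ", ")))
  }
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

# parse "#rrggbb" to numeric rgb in [0,1]
hex_rgb <- function(hex) as.numeric(grDevices::col2rgb(hex)[, 1]) / 255

#' Rasterize an SVG document to PNG
#'
#' A small deterministic scanline rasterizer for the documents this package
#' emits: it draws the `<line>`, `<circle>`, `<rect>` and `<polygon>`
#' elements onto a white canvas (text is not rasterized) and encodes the
#' result with the `png` package. Contractually the PNG has dimensions
#' `scale` times the SVG canvas.
#' @param svg a `pinv_svg`.
#' @param scale positive scale factor.
#' @return raw vector of PNG bytes.
#' @export
rasterize_png <- function(svg, scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1 || is.na(scale) || scale <= 0) {
    stop("scale must be a positive number")
  }
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("PNG rasterization unavailable (package 'png' not installed); export SVG instead")
  }
  doc <- xml2::read_xml(unclass(svg))
  w <- as.numeric(xml2::xml_attr(doc, "width"))
  h <- as.numeric(xml2::xml_attr(doc, "height"))
  W <- max(1L, as.integer(round(w * scale)))
  H <- max(1L, as.integer(round(h * scale)))
  img <- array(1, dim = c(H, W, 3))

  paint_disc <- function(cx, cy, r, rgb) {
    x0 <- max(1L, as.integer(floor(cx - r))); x1 <- min(W, as.integer(ceiling(cx + r)))
    y0 <- max(1L, as.integer(floor(cy - r))); y1 <- min(H, as.integer(ceiling(cy + r)))
    if (x0 > x1 || y0 > y1) return()
    xs <- x0:x1; ys <- y0:y1
    dx2 <- (xs - cx)^2
    for (yy in ys) {
      hit <- xs[dx2 + (yy - cy)^2 <= r * r]
      if (length(hit)) for (ch in 1:3) img[yy, hit, ch] <<- rgb[ch]
    }
  }

  for (el in xml2::xml_find_all(doc, "//*[local-name()='line']")) {
    a <- xml2::xml_attrs(el)
    rgb <- hex_rgb(a[["stroke"]])
    x1 <- as.numeric(a[["x1"]]) * scale; y1 <- as.numeric(a[["y1"]]) * scale
    x2 <- as.numeric(a[["x2"]]) * scale; y2 <- as.numeric(a[["y2"]]) * scale
    lw <- max(1, as.numeric(a[["stroke-width"]]) * scale)
    len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    steps <- max(2L, as.integer(ceiling(len * 2)))
    for (t in seq(0, 1, length.out = steps)) {
      paint_disc(x1 + t * (x2 - x1), y1 + t * (y2 - y1), lw / 2, rgb)
    }
  }
  for (el in xml2::xml_find_all(doc, "//*[local-name()='circle']")) {
    a <- xml2::xml_attrs(el)
    paint_disc(as.numeric(a[["cx"]]) * scale, as.numeric(a[["cy"]]) * scale,
               as.numeric(a[["r"]]) * scale, hex_rgb(a[["fill"]]))
  }
  for (el in xml2::xml_find_all(doc, "//*[local-name()='rect']")) {
    a <- xml2::xml_attrs(el)
    rgb <- hex_rgb(a[["fill"]])
    x0 <- max(1L, as.integer(round(as.numeric(a[["x"]]) * scale)))
    y0 <- max(1L, as.integer(round(as.numeric(a[["y"]]) * scale)))
    x1 <- min(W, as.integer(round((as.numeric(a[["x"]]) + as.numeric(a[["width"]])) * scale)))
    y1 <- min(H, as.integer(round((as.numeric(a[["y"]]) + as.numeric(a[["height"]])) * scale)))
    if (x0 <= x1 && y0 <= y1) for (ch in 1:3) img[y0:y1, x0:x1, ch] <- rgb[ch]
  }
  for (el in xml2::xml_find_all(doc, "//*[local-name()='polygon']")) {
    a <- xml2::xml_attrs(el)
    rgb <- hex_rgb(a[["fill"]])
    pts <- do.call(rbind, lapply(strsplit(strsplit(a[["points"]], " ")[[1]], ","),
                                 as.numeric)) * scale
    # fill via the disc painter around the centroid (good enough for glyphs)
    ctr <- colMeans(pts)
    r <- max(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2))
    paint_disc(ctr[1], ctr[2], r / sqrt(2), rgb)
  }
  png::writePNG(img, raw())
}
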