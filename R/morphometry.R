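#' Cell-contact geometry graph
#'
#' Junction vertices and the polyline geometry of each cell-cell contact
#' ("side" of the polygonal cell outline), in micrometres. Each edge runs
#' between two junction vertices; its polyline endpoints must coincide with
#' those vertices.
#'
#' @param vertices Data frame with columns `id`, `x`, `y` (micrometres).
#' @param edges List of `list(v1 = , v2 = , polyline = )` entries; `polyline`
#'   is an n x 2 matrix (n >= 2) whose first and last rows equal the
#'   coordinates of vertices `v1` and `v2`.
#' @param field Field of view as `c(xmin, xmax, ymin, ymax)` in micrometres.
#' @return Object of class `contact_graph`.
#' @export
contact_graph <- function(vertices, edges, field) {
  stopifnot(all(c("id", "x", "y") %in% names(vertices)),
            length(field) == 4, field[2] > field[1], field[4] > field[3])
  vx <- stats::setNames(vertices$x, vertices$id)
  vy <- stats::setNames(vertices$y, vertices$id)
  for (e in edges) {
    p <- e$polyline
    stopifnot(is.matrix(p), ncol(p) == 2, nrow(p) >= 2)
    for (end in list(list(1L, e$v1), list(nrow(p), e$v2))) {
      i <- end[[1]]; v <- as.character(end[[2]])
      if (!v %in% names(vx))
        stop("edge references unknown vertex ", v)
      if (max(abs(c(p[i, 1] - vx[[v]], p[i, 2] - vy[[v]]))) > 1e-6)
        stop("polyline endpoint does not coincide with vertex ", v)
    }
  }
  structure(list(vertices = vertices, edges = edges,
                 field = as.numeric(field)),
            class = "contact_graph")
}

.polyline_length <- function(p) {
  sum(sqrt(rowSums(diff(p)^2)))
}

.chord_length <- function(p) {
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}

#' Zigzag index of a set of cell-contact edges
#'
#' The tortuosity of the traced junctions: the ratio of the summed traced
#' contour lengths (L_TJ) to the summed straight endpoint-to-endpoint
#' lengths (L_St), index = L_TJ / L_St. This is a ratio of sums over all
#' sides, not a mean of per-side ratios, so long sides carry proportionally
#' more weight. An index of 1 means perfectly linear junctions; jagged
#' junctions give > 1.
#'
#' Edges with a zero-length chord (coincident endpoints, e.g. a closed
#' loop) are excluded with a warning.
#'
#' @param edges A `contact_graph` or a list of edges as in
#'   [contact_graph()].
#' @return List of class `zigzag_result` with `l_tj`, `l_st` (micrometres),
#'   `index`, `n_sides`.
#' @export
zigzag_index <- function(edges) {
  if (inherits(edges, "contact_graph")) edges <- edges$edges
  if (!length(edges)) stop("no edges to measure")
  arc <- vapply(edges, function(e) .polyline_length(e$polyline), numeric(1))
  chord <- vapply(edges, function(e) .chord_length(e$polyline), numeric(1))
  bad <- chord <= 1e-12
  if (any(bad)) {
    warning(sum(bad), " edge(s) with coincident endpoints excluded from ",
            "the zigzag index")
    arc <- arc[!bad]; chord <- chord[!bad]
  }
  if (!length(arc)) stop("no measurable edges (all chords degenerate)")
  structure(list(l_tj = sum(arc), l_st = sum(chord),
                 index = sum(arc) / sum(chord), n_sides = length(arc)),
            class = "zigzag_result")
}

#' @export
print.zigzag_result <- function(x, ...) {
  cat(sprintf("zigzag index %.4f (L_TJ = %.2f um, L_St = %.2f um, n = %d sides)\n",
              x$index, x$l_tj, x$l_st, x$n_sides))
  invisible(x)
}

#' Randomly sample analysis windows from a contact graph
#'
#' Places `n_windows` axis-aligned square windows of the given area
#' uniformly at random inside the field of view (seeded, reproducible) and
#' returns, per window, the edges contained in it. A side is "contained"
#' when both of its junction vertices fall inside the window; sides are
#' taken whole, never clipped.
#'
#' @param graph A [contact_graph()].
#' @param n_windows Number of windows (default 5).
#' @param window_area Window area in square micrometres (default 815, a
#'   square of side ~28.5 um).
#' @param seed Integer seed.
#' @return List of length `n_windows`; each element is a list with `window`
#'   (`c(xmin, xmax, ymin, ymax)`) and `edges`.
#' @export
sample_windows <- function(graph, n_windows = 5, window_area = 815,
                           seed = 1L) {
  stopifnot(inherits(graph, "contact_graph"), n_windows >= 1,
            window_area > 0)
  side <- sqrt(window_area)
  f <- graph$field
  if (side > f[2] - f[1] || side > f[4] - f[3])
    stop(sprintf("window side %.2f um exceeds the field extent", side))
  vx <- stats::setNames(graph$vertices$x, graph$vertices$id)
  vy <- stats::setNames(graph$vertices$y, graph$vertices$id)
  .with_seed(seed, {
    lapply(seq_len(n_windows), function(i) {
      x0 <- stats::runif(1, f[1], f[2] - side)
      y0 <- stats::runif(1, f[3], f[4] - side)
      inside <- function(v) {
        v <- as.character(v)
        vx[[v]] >= x0 & vx[[v]] <= x0 + side &
          vy[[v]] >= y0 & vy[[v]] <= y0 + side
      }
      keep <- vapply(graph$edges,
                     function(e) inside(e$v1) && inside(e$v2), logical(1))
      list(window = c(x0, x0 + side, y0, y0 + side),
           edges = graph$edges[keep])
    })
  })
}

#' Per-sample zigzag index with the window-sampling protocol
#'
#' Randomly captures `n_windows` areas of `window_area` from the field,
#' pools all contained sides across windows and computes a single zigzag
#' index for the sample (per-window results are attached). Emits a protocol
#' warning when fewer than `min_sides` sides were pooled, since the index
#' of a small side set is noisy.
#'
#' @inheritParams sample_windows
#' @param min_sides Minimum pooled side count before warning (default 80).
#' @return A `zigzag_result` with attribute `windows` (per-window
#'   `zigzag_result`s, `NULL` where a window caught no edge).
#' @export
zigzag_per_sample <- function(graph, n_windows = 5, window_area = 815,
                              seed = 1L, min_sides = 80) {
  wins <- sample_windows(graph, n_windows, window_area, seed)
  pooled <- do.call(c, lapply(wins, `[[`, "edges"))
  if (!length(pooled))
    stop("no edges captured by any window")
  res <- zigzag_index(pooled)
  if (res$n_sides < min_sides)
    warning("only ", res$n_sides, " sides pooled (protocol calls for > ",
            min_sides, "); index may be noisy")
  attr(res, "windows") <- lapply(wins, function(w)
    if (length(w$edges)) zigzag_index(w$edges) else NULL)
  res
}
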