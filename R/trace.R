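#' Trace cell-cell boundaries from a labeled segmentation mask
#'
#' Extracts the shared boundaries between adjacent labeled regions of an
#' integer mask (background = 0) as a [contact_graph()]. The boundary is
#' followed along the "cracks" between 4-adjacent pixels of differing
#' nonzero labels; corners where three or more labels meet become junction
#' vertices, and each boundary chain between junctions (or image-border
#' endpoints) becomes one edge. Polyline interior points are the crack
#' midpoints (half-pixel coordinates), which removes the staircase length
#' bias of corner-following for diagonal boundaries; the traversal order is
#' deterministic.
#'
#' @param mask Integer matrix; 0 is background, positive values are cell
#'   labels. Row index is y (downwards), column index is x.
#' @param pixel_size Physical size of one pixel in micrometres (default 1).
#' @return A [contact_graph()]; empty (no edges) when the mask contains
#'   fewer than two labels in contact.
#' @examples
#' m <- cbind(matrix(1L, 4, 3), matrix(2L, 4, 3))
#' g <- trace_boundaries(m)
#' zigzag_index(g)  # straight boundary, index 1
#' @export
trace_boundaries <- function(mask, pixel_size = 1) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  mode(mask) <- "integer"
  nr <- nrow(mask); nc <- ncol(mask)
  ncorner <- nc + 1L  # corner (i, j) -> key i * (nc + 1) + j, i in 0..nr, j in 0..nc

  # cracks between differing nonzero 4-neighbours
  n1 <- integer(0); n2 <- integer(0); pa <- integer(0); pb <- integer(0)
  # vertical cracks: pixel (r, c) | (r, c + 1)
  if (nc > 1) {
    l <- mask[, -nc, drop = FALSE]; rgt <- mask[, -1, drop = FALSE]
    idx <- which(l > 0 & rgt > 0 & l != rgt, arr.ind = TRUE)
    if (nrow(idx)) {
      r <- idx[, 1]; cc <- idx[, 2]
      n1 <- c(n1, (r - 1L) * ncorner + cc)
      n2 <- c(n2, r * ncorner + cc)
      pa <- c(pa, pmin(l[idx], rgt[idx])); pb <- c(pb, pmax(l[idx], rgt[idx]))
    }
  }
  # horizontal cracks: pixel (r, c) over (r + 1, c)
  if (nr > 1) {
    up <- mask[-nr, , drop = FALSE]; dn <- mask[-1, , drop = FALSE]
    idx <- which(up > 0 & dn > 0 & up != dn, arr.ind = TRUE)
    if (nrow(idx)) {
      r <- idx[, 1]; cc <- idx[, 2]
      n1 <- c(n1, r * ncorner + (cc - 1L))
      n2 <- c(n2, r * ncorner + cc)
      pa <- c(pa, pmin(up[idx], dn[idx])); pb <- c(pb, pmax(up[idx], dn[idx]))
    }
  }

  field <- c(0, nc * pixel_size, 0, nr * pixel_size)
  if (!length(n1)) {
    return(contact_graph(data.frame(id = character(0), x = numeric(0),
                                    y = numeric(0)),
                         list(), field))
  }

  corner_xy <- function(key) {
    c(x = (key %% ncorner) * pixel_size,
      y = (key %/% ncorner) * pixel_size)
  }

  # full-graph degree -> junction corners (>= 3 cracks meeting)
  deg_full <- table(c(n1, n2))
  junction <- as.integer(names(deg_full)[deg_full >= 3L])

  edges <- list()
  endpoints <- integer(0)
  pairkey <- pa * (max(pb) + 1L) + pb
  for (pk in sort(unique(pairkey))) {
    sel <- which(pairkey == pk)
    a <- n1[sel]; b <- n2[sel]
    nodes <- sort(unique(c(a, b)))
    adj <- lapply(stats::setNames(nodes, nodes), function(nd)
      sort(sel[a == nd | b == nd]))
    degree <- lengths(adj)
    breakpts <- nodes[degree != 2L | nodes %in% junction]
    used <- logical(length(n1))

    walk <- function(start, crack) {
      chain <- integer(0); node <- start
      repeat {
        used[crack] <<- TRUE
        chain <- c(chain, crack)
        node <- if (n1[crack] == node) n2[crack] else n1[crack]
        if (node %in% breakpts || node == start) break
        nxt <- adj[[as.character(node)]]
        nxt <- nxt[!used[nxt]]
        if (!length(nxt)) break
        crack <- nxt[1]
      }
      list(end = node, chain = chain)
    }

    emit <- function(start, res) {
      mids <- t(vapply(res$chain, function(cr)
        (corner_xy(n1[cr]) + corner_xy(n2[cr])) / 2, numeric(2)))
      poly <- rbind(corner_xy(start), mids, corner_xy(res$end))
      colnames(poly) <- NULL
      edges[[length(edges) + 1L]] <<-
        list(v1 = paste0("c", start), v2 = paste0("c", res$end),
             polyline = poly)
      endpoints <<- c(endpoints, start, res$end)
    }

    for (bp in sort(breakpts)) {
      for (cr in adj[[as.character(bp)]]) {
        if (used[cr]) next
        emit(bp, walk(bp, cr))
      }
    }
    # closed loops with no breakpoint (two-label island)
    remaining <- sel[!used[sel]]
    while (length(remaining)) {
      start_node <- min(n1[remaining], n2[remaining])
      cr <- remaining[n1[remaining] == start_node |
                        n2[remaining] == start_node][1]
      emit(start_node, walk(start_node, cr))
      remaining <- sel[!used[sel]]
    }
  }

  endpoints <- sort(unique(endpoints))
  verts <- data.frame(
    id = paste0("c", endpoints),
    x = (endpoints %% ncorner) * pixel_size,
    y = (endpoints %/% ncorner) * pixel_size)
  contact_graph(verts, edges, field)
}
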