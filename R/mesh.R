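#' Specification of a synthetic epithelial mesh
#'
#' Parameters of the synthetic monolayer geometry: a seeded Voronoi
#' tessellation of `n_cells` random points in a rectangular field, with each
#' cell-cell edge optionally replaced by a symmetric triangular zigzag.
#'
#' Jaggedness is set by the peak-to-peak amplitude `jag_amplitude` (a) and
#' period `jag_period` (p): every zigzag segment has perpendicular slope
#' 2a/p, so the arc/chord ratio of each jagged edge — and hence the pooled
#' ground-truth zigzag index — is sqrt(1 + (2a/p)^2). `jag_amplitude = 0`
#' gives straight edges (index 1).
#'
#' @param n_cells Number of cells (>= 2). Default 150 in a 120 x 120 um
#'   field, i.e. ~96 um^2 per cell, a confluent-MDCK-like density that puts
#'   more than 80 sides into five 815-um^2 sampling windows.
#' @param field `c(xmin, xmax, ymin, ymax)` in micrometres.
#' @param jag_amplitude Peak-to-peak zigzag amplitude a, um (>= 0).
#' @param jag_period Zigzag period p along the edge, um (> 0).
#' @param jag_jitter Relative SD of per-edge amplitude variation (Gaussian
#'   multiplier, truncated at 0). 0 (default) gives every edge exactly the
#'   nominal arc/chord ratio; a small value (~0.1) emulates the side-to-side
#'   variability of real traced junctions.
#' @param seed Integer seed.
#' @return Object of class `mesh_spec`.
#' @export
mesh_spec <- function(n_cells = 150, field = c(0, 120, 0, 120),
                      jag_amplitude = 1, jag_period = 2, jag_jitter = 0,
                      seed = 1L) {
  stopifnot(n_cells >= 2, length(field) == 4, field[2] > field[1],
            field[4] > field[3], jag_amplitude >= 0, jag_period > 0,
            jag_jitter >= 0)
  structure(list(n_cells = n_cells, field = as.numeric(field),
                 jag_amplitude = jag_amplitude, jag_period = jag_period,
                 jag_jitter = jag_jitter, seed = as.integer(seed)),
            class = "mesh_spec")
}

# Sutherland-Hodgman-style half-plane clip of a convex polygon that tracks,
# per edge, which neighbour's bisector (or 0 for the field border) created it
.clip_halfplane <- function(V, labs, a, b, newlab, eps = 1e-9) {
  n <- nrow(V)
  d <- V %*% a - b
  kept <- list()
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    dP <- d[k]; dQ <- d[k2]
    P <- V[k, ]; Q <- V[k2, ]
    if (dP <= eps && dQ <= eps) {
      kept[[length(kept) + 1L]] <- list(P = P, Q = Q, lab = labs[k])
    } else if (dP <= eps && dQ > eps) {
      t <- dP / (dP - dQ)
      kept[[length(kept) + 1L]] <- list(P = P, Q = P + t * (Q - P),
                                        lab = labs[k])
    } else if (dP > eps && dQ <= eps) {
      t <- dP / (dP - dQ)
      kept[[length(kept) + 1L]] <- list(P = P + t * (Q - P), Q = Q,
                                        lab = labs[k])
    }
  }
  if (!length(kept)) return(NULL)
  verts <- NULL; vlabs <- integer(0)
  prevQ <- NULL
  for (e in kept) {
    if (is.null(prevQ)) {
      verts <- rbind(verts, e$P); vlabs <- c(vlabs, e$lab)
    } else {
      if (sqrt(sum((prevQ - e$P)^2)) > eps) {
        verts <- rbind(verts, prevQ); vlabs <- c(vlabs, newlab)
      }
      verts <- rbind(verts, e$P); vlabs <- c(vlabs, e$lab)
    }
    prevQ <- e$Q
  }
  if (sqrt(sum((prevQ - verts[1, ])^2)) > eps) {
    verts <- rbind(verts, prevQ); vlabs <- c(vlabs, newlab)
  }
  list(V = verts, labs = vlabs)
}

# Voronoi diagram of pts clipped to the field rectangle; returns per cell
# the polygon and, per polygon edge, the neighbour index (0 = field border)
.voronoi_cells <- function(pts, field) {
  n <- nrow(pts)
  rect <- rbind(c(field[1], field[3]), c(field[2], field[3]),
                c(field[2], field[4]), c(field[1], field[4]))
  lapply(seq_len(n), function(i) {
    V <- rect; labs <- rep(0L, 4)
    di <- sqrt(rowSums((pts - matrix(pts[i, ], n, 2, byrow = TRUE))^2))
    ord <- order(di)
    for (j in ord) {
      if (j == i) next
      # once every remaining site is more than twice the cell's radius away
      # its bisector cannot cut the cell
      rad <- sqrt(max(rowSums((V - matrix(pts[i, ], nrow(V), 2,
                                          byrow = TRUE))^2)))
      if (di[j] > 2 * rad) break
      a <- 2 * (pts[j, ] - pts[i, ])
      b <- sum(pts[j, ]^2) - sum(pts[i, ]^2)
      res <- .clip_halfplane(V, labs, a, b, j)
      if (is.null(res)) return(NULL)
      V <- res$V; labs <- res$labs
    }
    list(V = V, labs = labs)
  })
}

# symmetric triangular zigzag between P and Q: integer number of periods
# m = max(1, round(L/p)), per-edge period h = L/m, amplitude rescaled to
# a h / p so that every segment's perpendicular slope is exactly 2a/p
.zigzag_polyline <- function(P, Q, a, p) {
  if (a == 0) return(rbind(P, Q))
  L <- sqrt(sum((Q - P)^2))
  m <- max(1L, round(L / p))
  h <- L / m
  ae <- a * h / p
  u <- (Q - P) / L
  nv <- c(-u[2], u[1])
  k <- 0:(4L * m)
  s <- k * h / 4
  off <- c(0, ae / 2, 0, -ae / 2)[(k %% 4L) + 1L]
  cbind(P[1] + u[1] * s + nv[1] * off,
        P[2] + u[2] * s + nv[2] * off)
}

#' Generate a synthetic epithelial contact mesh
#'
#' Seeded Voronoi tessellation of uniform random cell centres in the field;
#' every shared (cell-cell) Voronoi edge becomes a contact-graph edge whose
#' polyline is a symmetric triangular zigzag (see [mesh_spec()]). Edges on
#' the field border are not cell-cell contacts and are dropped. The
#' analytic pooled zigzag index sqrt(1 + (2a/p)^2) is attached as attribute
#' `truth_index`.
#'
#' @param spec A [mesh_spec()].
#' @return A [contact_graph()] with attribute `truth_index`.
#' @examples
#' g <- generate_mesh(mesh_spec(n_cells = 40, seed = 7))
#' zigzag_index(g)
#' attr(g, "truth_index")
#' @export
generate_mesh <- function(spec) {
  stopifnot(inherits(spec, "mesh_spec"))
  f <- spec$field
  .with_seed(spec$seed, {
  cells <- NULL
  for (try in 1:10) {
    pts <- cbind(stats::runif(spec$n_cells, f[1], f[2]),
                 stats::runif(spec$n_cells, f[3], f[4]))
    if (min(stats::dist(pts)) < 1e-6) {
      warning("near-coincident cell centres drawn; resampling")
      next
    }
    cells <- .voronoi_cells(pts, f)
    if (!any(vapply(cells, is.null, logical(1)))) break
    warning("degenerate tessellation; resampling")
    cells <- NULL
  }
  if (is.null(cells)) stop("failed to build a non-degenerate tessellation")

  # shared edges, taken once from the lower-index cell
  vkey <- function(p) paste(round(p[1], 6), round(p[2], 6))
  vert_env <- new.env(parent = emptyenv())
  vid <- function(p) {
    k <- vkey(p)
    if (is.null(vert_env[[k]]))
      vert_env[[k]] <- list(id = sprintf("v%d", length(ls(vert_env)) + 1L),
                            x = p[1], y = p[2])
    vert_env[[k]]$id
  }
  edges <- list()
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    nv <- nrow(cell$V)
    for (k in seq_len(nv)) {
      j <- cell$labs[k]
      if (j <= i) next  # border (0) or already taken from the other side
      P <- cell$V[k, ]; Q <- cell$V[if (k == nv) 1L else k + 1L, ]
      if (sqrt(sum((Q - P)^2)) < 1e-8) next
      a_edge <- spec$jag_amplitude
      if (spec$jag_jitter > 0)
        a_edge <- a_edge * max(0, stats::rnorm(1, 1, spec$jag_jitter))
      edges[[length(edges) + 1L]] <- list(
        v1 = vid(P), v2 = vid(Q),
        polyline = .zigzag_polyline(P, Q, a_edge, spec$jag_period))
    }
  }
  vs <- eapply(vert_env, identity)
  verts <- data.frame(
    id = vapply(vs, `[[`, character(1), "id"),
    x = vapply(vs, `[[`, numeric(1), "x"),
    y = vapply(vs, `[[`, numeric(1), "y"))
  g <- contact_graph(verts, edges, f)
  attr(g, "truth_index") <-
    sqrt(1 + (2 * spec$jag_amplitude / spec$jag_period)^2)
  g
  })
}
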