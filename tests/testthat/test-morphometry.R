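# small hand-built graphs
straight_edge <- function(v1, v2, p1, p2) {
  list(v1 = v1, v2 = v2, polyline = rbind(p1, p2))
}

test_that("straight polylines give index exactly 1", {
  verts <- data.frame(id = c("a", "b", "c"), x = c(0, 10, 10),
                      y = c(0, 0, 10))
  edges <- list(straight_edge("a", "b", c(0, 0), c(10, 0)),
                straight_edge("b", "c", c(10, 0), c(10, 10)))
  g <- contact_graph(verts, edges, c(0, 20, 0, 20))
  expect_identical(zigzag_index(g)$index, 1)
})

test_that("a symmetric sawtooth has the Pythagorean arc/chord ratio", {
  # slope 2a/p with a = p/2 gives sqrt(2); built from quarter-period nodes
  p <- 2; a <- 1
  x <- seq(0, 10, by = p / 4)
  off <- c(0, a / 2, 0, -a / 2)[(seq_along(x) - 1) %% 4 + 1]
  verts <- data.frame(id = c("a", "b"), x = c(0, 10), y = c(0, 0))
  g <- contact_graph(verts,
                     list(list(v1 = "a", v2 = "b",
                               polyline = cbind(x, off))),
                     c(0, 10, -2, 2))
  expect_equal(zigzag_index(g)$index, sqrt(2), tolerance = 1e-12)
})

test_that("the pooled index is a ratio of sums, not a mean of per-edge
           ratios", {
  # straight chord of 20 plus a sqrt(2)-tortuous chord of 10:
  # ratio of sums (20 + 14.142) / 30 = 1.1381, mean of ratios 1.2071
  p <- 2; a <- 1
  x <- seq(0, 10, by = p / 4)
  off <- c(0, a / 2, 0, -a / 2)[(seq_along(x) - 1) %% 4 + 1]
  verts <- data.frame(id = c("a", "b", "c"), x = c(0, 10, 30),
                      y = c(0, 0, 0))
  edges <- list(list(v1 = "a", v2 = "b", polyline = cbind(x, off)),
                straight_edge("b", "c", c(10, 0), c(30, 0)))
  g <- contact_graph(verts, edges, c(0, 30, -2, 2))
  res <- zigzag_index(g)
  expect_equal(res$index, (10 * sqrt(2) + 20) / 30, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(res$index, (sqrt(2) + 1) / 2)))
  # pooled index lies between the per-edge extremes
  expect_gt(res$index, 1)
  expect_lt(res$index, sqrt(2))
})

test_that("edges with coincident endpoints are excluded with a warning", {
  verts <- data.frame(id = c("a", "b"), x = c(0, 10), y = c(0, 0))
  loop <- list(v1 = "a", v2 = "a",
               polyline = rbind(c(0, 0), c(1, 1), c(0, 2), c(0, 0)))
  edges <- list(straight_edge("a", "b", c(0, 0), c(10, 0)), loop)
  g <- contact_graph(verts, edges, c(0, 10, 0, 10))
  expect_warning(res <- zigzag_index(g), "coincident")
  expect_identical(res$n_sides, 1L)
  expect_identical(res$index, 1)
})

test_that("index is invariant under rigid motion and uniform scaling", {
  g <- generate_mesh(mesh_spec(n_cells = 40, seed = 5))
  base <- zigzag_index(g)$index
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  for (s in c(1, 3.5)) {
    tg <- g
    tg$edges <- lapply(g$edges, function(e) {
      e$polyline <- s * (e$polyline %*% R) +
        matrix(c(5, -2), nrow(e$polyline), 2, byrow = TRUE)
      e
    })
    expect_equal(zigzag_index(tg$edges)$index, base, tolerance = 1e-12)
  }
})

test_that("a window covering the whole field returns every edge", {
  g <- generate_mesh(mesh_spec(n_cells = 30, field = c(0, 25, 0, 25),
                               seed = 2))
  wins <- sample_windows(g, n_windows = 1, window_area = 625, seed = 1)
  expect_identical(length(wins[[1]]$edges), length(g$edges))
})

test_that("window sampling is seeded and reproducible", {
  g <- generate_mesh(mesh_spec(seed = 4))
  w1 <- sample_windows(g, seed = 99)
  w2 <- sample_windows(g, seed = 99)
  expect_identical(w1, w2)
  w3 <- sample_windows(g, seed = 100)
  expect_false(identical(w1[[1]]$window, w3[[1]]$window))
})

test_that("an edge is contained iff both junction vertices are inside", {
  g <- generate_mesh(mesh_spec(seed = 4))
  vx <- setNames(g$vertices$x, g$vertices$id)
  vy <- setNames(g$vertices$y, g$vertices$id)
  for (w in sample_windows(g, n_windows = 3, seed = 8)) {
    win <- w$window
    keep <- vapply(g$edges, function(e) {
      all(vx[c(e$v1, e$v2)] >= win[1] & vx[c(e$v1, e$v2)] <= win[2] &
            vy[c(e$v1, e$v2)] >= win[3] & vy[c(e$v1, e$v2)] <= win[4])
    }, logical(1))
    expect_identical(length(w$edges), sum(keep))
  }
})

test_that("window edge counts match the analytic placement expectation", {
  g <- generate_mesh(mesh_spec(n_cells = 100, seed = 12))
  exp_stats <- expected_window_edges(g, 815)
  wins <- sample_windows(g, n_windows = 200, window_area = 815, seed = 3)
  counts <- lengths(lapply(wins, `[[`, "edges"))
  se <- sqrt(exp_stats$var / 200)
  expect_lt(abs(mean(counts) - exp_stats$mean), 5 * se)
})

test_that("per-sample pooling warns below the protocol side count", {
  g <- generate_mesh(mesh_spec(n_cells = 20, field = c(0, 60, 0, 60),
                               seed = 6))
  expect_warning(zigzag_per_sample(g, n_windows = 1, seed = 1), "sides")
})
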