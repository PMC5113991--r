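#' Read raw electrical measurements from CSV
#'
#' Expected columns: `filter_id`, `role` (`sample` or `blank`), `time_min`,
#' `potential_mV`, and either `resistance_ohm_cm2` or `resistance_ohm`
#' (raw meter ohms, converted with `area_cm2`).
#'
#' @param path CSV file path.
#' @param area_cm2 Filter growth area used to convert raw ohm readings
#'   (default 1.12 cm^2, a 12-mm Transwell insert); ignored when the file
#'   already carries `resistance_ohm_cm2`.
#' @return Named list (by `filter_id`) of lists with `role` and `series`
#'   ([measurement_series()]).
#' @export
read_measurements <- function(path, area_cm2 = 1.12) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("filter_id", "role", "time_min", "potential_mV")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("measurement CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if ("resistance_ohm_cm2" %in% names(d)) {
    r <- d$resistance_ohm_cm2
  } else if ("resistance_ohm" %in% names(d)) {
    r <- d$resistance_ohm * area_cm2
  } else {
    stop("measurement CSV is missing column(s): ",
         "resistance_ohm_cm2 (or resistance_ohm)")
  }
  if (!all(d$role %in% c("sample", "blank")))
    stop("`role` must be 'sample' or 'blank'")
  d$.r <- r
  lapply(split(d, d$filter_id), function(g)
    list(role = g$role[1],
         series = measurement_series(g$time_min, g$.r, g$potential_mV)))
}

#' Write a measurement series to CSV
#'
#' @param series A [measurement_series()].
#' @param path Output path.
#' @param filter_id,role Identity columns written alongside the readings.
#' @param append Append without header (to stack several filters in one
#'   file).
#' @export
write_measurements <- function(series, path, filter_id, role,
                               append = FALSE) {
  d <- data.frame(filter_id = filter_id, role = role,
                  time_min = series$time,
                  resistance_ohm_cm2 = series$resistance,
                  potential_mV = series$potential)
  utils::write.table(d, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
}

#' Write a permeability series to CSV
#'
#' Columns: `time_min`, `ter_ohm_cm2`, `dilution_potential_mV`, `beta`,
#' `p_na_cm_s`, `p_cl_cm_s`, `flags`.
#'
#' @param series Output of [compute_permeability_series()].
#' @param path Output path.
#' @export
write_permeability_csv <- function(series, path) {
  d <- data.frame(time_min = series$time, ter_ohm_cm2 = series$ter,
                  dilution_potential_mV = series$dilution_potential,
                  beta = series$beta, p_na_cm_s = series$p_na,
                  p_cl_cm_s = series$p_cl,
                  flags = ifelse(series$flagged, "nonpositive_ter", ""))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}

#' Serialize a contact graph to CSV
#'
#' One row per polyline point: `edge_id`, `v1`, `v2`, `point_index`, `x`,
#' `y`.
#'
#' @param graph A [contact_graph()].
#' @param path Output path.
#' @export
write_contact_graph <- function(graph, path) {
  stopifnot(inherits(graph, "contact_graph"))
  rows <- do.call(rbind, lapply(seq_along(graph$edges), function(i) {
    e <- graph$edges[[i]]
    data.frame(edge_id = i, v1 = e$v1, v2 = e$v2,
               point_index = seq_len(nrow(e$polyline)),
               x = e$polyline[, 1], y = e$polyline[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
}

#' Read a contact graph from CSV
#'
#' Inverse of [write_contact_graph()]. The field extent is taken from
#' `field`, or from the bounding box of all points when omitted.
#'
#' @param path CSV path with columns `edge_id`, `v1`, `v2`, `point_index`,
#'   `x`, `y`.
#' @param field Optional `c(xmin, xmax, ymin, ymax)`.
#' @return A [contact_graph()].
#' @export
read_contact_graph <- function(path, field = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("edge_id", "v1", "v2", "point_index", "x", "y")
  if (!all(need %in% names(d)))
    stop("contact-graph CSV is missing column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  edges <- lapply(split(d, d$edge_id), function(g) {
    g <- g[order(g$point_index), ]
    list(v1 = g$v1[1], v2 = g$v2[1],
         polyline = cbind(g$x, g$y))
  })
  vert_rows <- do.call(rbind, lapply(edges, function(e)
    data.frame(id = c(e$v1, e$v2),
               x = c(e$polyline[1, 1], e$polyline[nrow(e$polyline), 1]),
               y = c(e$polyline[1, 2], e$polyline[nrow(e$polyline), 2]))))
  verts <- vert_rows[!duplicated(vert_rows$id), ]
  if (is.null(field))
    field <- c(min(d$x), max(d$x), min(d$y), max(d$y))
  contact_graph(verts, unname(edges), field)
}
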