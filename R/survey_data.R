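# Survey data model: validated individual-level datasets, per-cluster
# aggregates, the admin-2-in-admin-1 hierarchy, cluster-to-area assignment and
# stage-1 design diagnostics.

#' Build an area hierarchy
#'
#' Stores the ordered admin-1 and admin-2 labels and the nesting map, together
#' with the internal dense 0-based ids used throughout the package.
#'
#' @param admin2 character/integer vector of admin-2 labels (one per area).
#' @param admin1 vector of the admin-1 label each admin-2 area nests in.
#' @return an object of class `area_hierarchy` with components `admin1`
#'   (ordered unique labels), `admin2` (ordered labels), `a_of_i` (0-based
#'   admin-1 index of each admin-2 area), and label-to-index dictionaries.
#' @export
area_hierarchy <- function(admin2, admin1) {
  if (length(admin2) != length(admin1)) {
    stop_prevmapr("admin2 and admin1 must have equal length",
                  class = "prevmapr_schema_error")
  }
  admin2 <- as.character(admin2)
  admin1 <- as.character(admin1)
  if (anyDuplicated(admin2)) {
    stop_prevmapr("duplicated admin2 labels in hierarchy",
                  class = "prevmapr_schema_error")
  }
  a1 <- unique(admin1)
  structure(
    list(
      admin1 = a1,
      admin2 = admin2,
      a_of_i = match(admin1, a1) - 1L,
      admin1_index = stats::setNames(seq_along(a1) - 1L, a1),
      admin2_index = stats::setNames(seq_along(admin2) - 1L, admin2)
    ),
    class = "area_hierarchy"
  )
}

#' Read an area hierarchy from a CSV with columns `admin2,admin1`
#' @param path file path.
#' @return an `area_hierarchy`.
#' @export
read_hierarchy <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("admin2", "admin1"), "hierarchy CSV")
  area_hierarchy(df$admin2, df$admin1)
}

#' @export
print.area_hierarchy <- function(x, ...) {
  cat("Area hierarchy:", length(x$admin1), "admin-1 areas,",
      length(x$admin2), "admin-2 areas\n")
  invisible(x)
}

#' Load and validate an individual-level survey table
#'
#' Expects columns `cluster, stratum, admin1, admin2, urban, y, weight`
#' (an `id` column is optional). Every cluster must map to exactly one stratum
#' and one (admin1, admin2) pair, admin2 must nest in admin1 per the hierarchy,
#' weights must be strictly positive and `y` binary.
#'
#' @param table a data.frame (or path to a CSV file) of individual rows.
#' @param hierarchy an [area_hierarchy()].
#' @return a `survey_dataset`: the validated data.frame with internal 0-based
#'   `admin1_id`/`admin2_id` columns and the hierarchy attached as an attribute.
#' @export
load_survey <- function(table, hierarchy) {
  if (is.character(table)) table <- utils::read.csv(table, stringsAsFactors = FALSE)
  stopifnot(inherits(hierarchy, "area_hierarchy"))
  check_columns(table, c("cluster", "stratum", "admin1", "admin2", "urban", "y", "weight"),
                "survey table")
  df <- as.data.frame(table)
  if (is.null(df$id)) df$id <- seq_len(nrow(df))

  bad_w <- which(!is.finite(df$weight) | df$weight <= 0)
  if (length(bad_w)) {
    stop_prevmapr("non-positive or non-finite weights in rows: ",
                  paste(utils::head(df$id[bad_w], 20), collapse = ", "),
                  class = "prevmapr_validation_error")
  }
  bad_y <- which(!(df$y %in% c(0, 1)))
  if (length(bad_y)) {
    stop_prevmapr("non-binary outcomes in rows: ",
                  paste(utils::head(df$id[bad_y], 20), collapse = ", "),
                  class = "prevmapr_validation_error")
  }
  a2 <- as.character(df$admin2)
  a1 <- as.character(df$admin1)
  i2 <- hierarchy$admin2_index[a2]
  if (anyNA(i2)) {
    stop_prevmapr("unknown admin2 labels: ",
                  paste(unique(a2[is.na(i2)]), collapse = ", "),
                  class = "prevmapr_validation_error")
  }
  i1 <- hierarchy$admin1_index[a1]
  if (anyNA(i1)) {
    stop_prevmapr("unknown admin1 labels: ",
                  paste(unique(a1[is.na(i1)]), collapse = ", "),
                  class = "prevmapr_validation_error")
  }
  nest_ok <- hierarchy$a_of_i[i2 + 1L] == i1
  if (!all(nest_ok)) {
    stop_prevmapr("admin2 not nested in recorded admin1 for rows: ",
                  paste(utils::head(df$id[!nest_ok], 20), collapse = ", "),
                  class = "prevmapr_nesting_error")
  }
  # every cluster maps to one stratum and one area pair
  key <- paste(df$stratum, a1, a2)
  n_keys <- tapply(key, df$cluster, function(k) length(unique(k)))
  if (any(n_keys > 1)) {
    stop_prevmapr("cluster(s) mapped to multiple strata/areas: ",
                  paste(names(n_keys)[n_keys > 1], collapse = ", "),
                  class = "prevmapr_validation_error")
  }
  df$admin1_id <- unname(i1)
  df$admin2_id <- unname(i2)
  df$y <- as.integer(df$y)
  df$urban <- as.logical(df$urban) | df$urban == 1
  structure(df, class = c("survey_dataset", "data.frame"),
            hierarchy = hierarchy)
}

#' Aggregate a survey dataset to the cluster level
#'
#' @param survey a `survey_dataset`.
#' @return a `cluster_table` data.frame with one row per cluster: `cluster`,
#'   `stratum`, `admin1_id`, `admin2_id`, `urban`, `Y` (positive outcomes),
#'   `n` (sampled individuals), `sum_w` (summed design weights), `phantom`.
#' @export
cluster_table <- function(survey) {
  stopifnot(inherits(survey, "survey_dataset"))
  sp <- split(seq_len(nrow(survey)), survey$cluster)
  rows <- lapply(sp, function(idx) {
    data.frame(
      cluster = survey$cluster[idx[1]],
      stratum = survey$stratum[idx[1]],
      admin1_id = survey$admin1_id[idx[1]],
      admin2_id = survey$admin2_id[idx[1]],
      urban = survey$urban[idx[1]],
      Y = sum(survey$y[idx]),
      n = length(idx),
      sum_w = sum(survey$weight[idx]),
      phantom = isTRUE(survey$phantom[idx[1]])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("cluster_table", "data.frame"),
            hierarchy = attr(survey, "hierarchy"))
}

#' Assign cluster points to area polygons
#'
#' Plain planar point-in-polygon containment. Points on a shared boundary are
#' assigned deterministically to the lowest polygon index; points outside all
#' polygons are labelled unassigned (`NA`).
#'
#' @param cluster_points data.frame with columns `cluster`, `x`, `y`
#'   (lon/lat).
#' @param area_polygons list of polygons as returned by
#'   [read_geojson_areas()].
#' @return data.frame `cluster`, `polygon` (index or NA), `admin1`, `admin2`,
#'   `boundary` (logical: was the point on an edge).
#' @export
assign_clusters_to_areas <- function(cluster_points, area_polygons) {
  if (length(area_polygons) == 0) {
    stop_prevmapr("empty polygon set", class = "prevmapr_validation_error")
  }
  check_columns(cluster_points, c("cluster", "x", "y"), "cluster points")
  props <- polygon_properties(area_polygons)
  out <- data.frame(
    cluster = cluster_points$cluster,
    polygon = NA_integer_,
    admin1 = NA_character_,
    admin2 = NA_character_,
    boundary = FALSE
  )
  for (r in seq_len(nrow(cluster_points))) {
    x <- cluster_points$x[r]; y <- cluster_points$y[r]
    hit <- NA_integer_; on_boundary <- FALSE
    for (p in seq_along(area_polygons)) {
      pos <- point_in_polygon(x, y, area_polygons[[p]])
      if (pos == "boundary") { hit <- p; on_boundary <- TRUE; break }
      if (pos == "inside") { hit <- p; break }
    }
    if (!is.na(hit)) {
      out$polygon[r] <- hit
      out$admin1[r] <- props$admin1[hit]
      out$admin2[r] <- props$admin2[hit]
      out$boundary[r] <- on_boundary
    }
  }
  out
}

#' Reconcile polygon-derived assignments with recorded admin-1 labels
#'
#' Clusters whose polygon-derived admin-1 disagrees with the admin-1 recorded
#' in the survey (GPS jitter, imprecise boundaries) are flagged and snapped to
#' the nearest admin-2 polygon *within* the recorded admin-1, by boundary
#' distance. Unassigned clusters with a recorded label are treated the same
#' way. Clusters without a recorded label are reported but left unchanged.
#'
#' @param assignment output of [assign_clusters_to_areas()].
#' @param recorded_admin1 vector of recorded admin-1 labels aligned with
#'   `assignment` rows (NA where no label exists).
#' @param cluster_points the points used for assignment (for snap distances).
#' @param area_polygons the polygon set used for assignment.
#' @return list with `assignment` (corrected) and `report` (data.frame of
#'   flagged clusters: `cluster, recorded, derived, action, snap_polygon`).
#' @export
reconcile_assignments <- function(assignment, recorded_admin1,
                                  cluster_points, area_polygons) {
  props <- polygon_properties(area_polygons)
  rep_rows <- list()
  for (r in seq_len(nrow(assignment))) {
    rec <- recorded_admin1[r]
    if (is.na(rec)) next
    der <- assignment$admin1[r]
    if (!is.na(der) && der == rec) next
    candidates <- which(props$admin1 == rec)
    if (!length(candidates)) {
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        cluster = assignment$cluster[r], recorded = rec,
        derived = der %||% NA_character_, action = "no polygon in recorded admin1",
        snap_polygon = NA_integer_)
      next
    }
    x <- cluster_points$x[r]; y <- cluster_points$y[r]
    d <- vapply(candidates, function(p)
      point_polygon_distance(x, y, area_polygons[[p]]), numeric(1))
    best <- candidates[which.min(d)]
    assignment$polygon[r] <- best
    assignment$admin1[r] <- props$admin1[best]
    assignment$admin2[r] <- props$admin2[best]
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      cluster = assignment$cluster[r], recorded = rec,
      derived = if (is.na(der)) "unassigned" else der,
      action = "snapped to nearest admin2 in recorded admin1",
      snap_polygon = best)
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(cluster = character(0), recorded = character(0),
               derived = character(0), action = character(0),
               snap_polygon = integer(0))
  list(assignment = assignment, report = report)
}

#' Cluster and sample-size availability by area
#'
#' Tabulates clusters and individuals per area at both admin levels, with
#' medians and the list of areas with zero or one sampled cluster — the
#' sparse-data screen run before any modelling.
#'
#' @param clusters a `cluster_table`.
#' @param hierarchy an `area_hierarchy` (defaults to the one attached to
#'   `clusters`).
#' @return list with `admin1`, `admin2` per-area tables (`area`, `n_clusters`,
#'   `n_individuals`), `medians`, and `sparse_areas` (zero- or one-cluster
#'   admin-2 areas).
#' @export
availability_summary <- function(clusters, hierarchy = attr(clusters, "hierarchy")) {
  stopifnot(!is.null(hierarchy))
  tab_level <- function(ids, labels) {
    n_cl <- tabulate(ids + 1L, nbins = length(labels))
    n_ind <- vapply(seq_along(labels) - 1L, function(i)
      sum(clusters$n[clusters[[if (identical(labels, hierarchy$admin1)) "admin1_id" else "admin2_id"]] == i]),
      numeric(1))
    data.frame(area = labels, n_clusters = n_cl, n_individuals = n_ind)
  }
  a1 <- tab_level(clusters$admin1_id, hierarchy$admin1)
  a2 <- tab_level(clusters$admin2_id, hierarchy$admin2)
  list(
    admin1 = a1,
    admin2 = a2,
    medians = c(
      clusters_admin1 = stats::median(a1$n_clusters),
      clusters_admin2 = stats::median(a2$n_clusters),
      individuals_admin1 = stats::median(a1$n_individuals),
      individuals_admin2 = stats::median(a2$n_individuals)
    ),
    sparse_areas = list(
      zero_cluster = a2$area[a2$n_clusters == 0],
      one_cluster = a2$area[a2$n_clusters == 1]
    )
  )
}

#' Urban over-sampling diagnostic
#'
#' Compares, per admin-1 area, the fraction of sampled clusters that are urban
#' with the population urban fraction (from the census/survey report). A
#' systematically positive difference indicates urban over-sampling, in which
#' case unweighted/unstratified estimators are biased whenever prevalence is
#' associated with urbanicity.
#'
#' @param clusters a `cluster_table`.
#' @param population_urban_fractions numeric vector in [0,1], one entry per
#'   admin-1 area (ordered as in the hierarchy).
#' @param hierarchy an `area_hierarchy`.
#' @return data.frame `area, sampled_urban_fraction, population_urban_fraction,
#'   difference`; areas without clusters get NA sampled fractions.
#' @export
urban_sampling_diagnostic <- function(clusters, population_urban_fractions,
                                      hierarchy = attr(clusters, "hierarchy")) {
  stopifnot(!is.null(hierarchy))
  if (any(population_urban_fractions < 0 | population_urban_fractions > 1)) {
    stop_prevmapr("population urban fractions must be in [0,1]",
                  class = "prevmapr_validation_error")
  }
  M <- length(hierarchy$admin1)
  stopifnot(length(population_urban_fractions) == M)
  sampled <- rep(NA_real_, M)
  for (i in seq_len(M) - 1L) {
    sel <- clusters$admin1_id == i
    if (any(sel)) sampled[i + 1L] <- mean(clusters$urban[sel])
  }
  data.frame(
    area = hierarchy$admin1,
    sampled_urban_fraction = sampled,
    population_urban_fraction = population_urban_fractions,
    difference = sampled - population_urban_fractions
  )
}
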