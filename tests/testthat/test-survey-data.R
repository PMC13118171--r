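test_that("load_survey validates and preserves a toy table", {
  h <- toy_hierarchy()
  sv <- load_survey(toy_survey_df(), h)
  expect_s3_class(sv, "survey_dataset")
  expect_equal(nrow(sv), 4)
  expect_equal(sv$admin1_id, c(0L, 0L, 1L, 1L))
  expect_equal(sv$admin2_id, c(0L, 0L, 2L, 2L))

  bad <- toy_survey_df()
  bad$weight[3] <- 0
  err <- expect_error(load_survey(bad, h), class = "prevmapr_validation_error")
  expect_match(conditionMessage(err), "3")

  nn <- toy_survey_df()
  nn$admin2[3] <- "d1"  # d1 nests in a1, row claims a2
  expect_error(load_survey(nn, h), class = "prevmapr_nesting_error")

  expect_error(load_survey(toy_survey_df()[, -1], h),
               class = "prevmapr_schema_error")
})

test_that("cluster aggregation round-trips individual totals exactly", {
  set.seed(11)
  h <- toy_hierarchy()
  df <- data.frame(
    cluster = sample(sprintf("c%d", 1:8), 200, TRUE),
    y = rbinom(200, 1, 0.4),
    weight = runif(200, 0.5, 3)
  )
  map <- data.frame(cluster = sprintf("c%d", 1:8),
                    admin2 = rep(c("d1", "d2", "d3", "d4"), 2))
  df$admin2 <- map$admin2[match(df$cluster, map$cluster)]
  df$admin1 <- c(d1 = "a1", d2 = "a1", d3 = "a2", d4 = "a2")[df$admin2]
  df$stratum <- df$admin1
  df$urban <- df$admin2 %in% c("d1", "d3")
  sv <- load_survey(df, h)
  ct <- cluster_table(sv)
  for (cl in unique(df$cluster)) {
    idx <- sv$cluster == cl
    expect_identical(ct$Y[ct$cluster == cl], sum(sv$y[idx]))
    expect_identical(ct$n[ct$cluster == cl], sum(idx))
    expect_equal(ct$sum_w[ct$cluster == cl], sum(sv$weight[idx]))
  }
  expect_equal(sum(ct$n), nrow(sv))
})

test_that("GeoJSON feature collections and hierarchy CSVs load", {
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(admin1 = "a1", admin2 = "d1"),
           geometry = list(type = "Polygon",
                           coordinates = list(list(
                             list(0, 0), list(1, 0), list(1, 1), list(0, 1),
                             list(0, 0))))),
      list(type = "Feature",
           properties = list(admin1 = "a2", admin2 = "d3"),
           geometry = list(type = "MultiPolygon",
                           coordinates = list(list(list(
                             list(1, 0), list(2, 0), list(2, 1), list(1, 1),
                             list(1, 0))))))
    )
  )
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  polys <- read_geojson_areas(path)
  expect_length(polys, 2)
  props <- attr(polys, "properties")
  expect_equal(props$admin2, c("d1", "d3"))
  asg <- assign_clusters_to_areas(
    data.frame(cluster = "p", x = 1.5, y = 0.5), polys)
  expect_equal(asg$admin2, "d3")
  unlink(path)

  hpath <- tempfile(fileext = ".csv")
  write.csv(data.frame(admin2 = c("d1", "d2"), admin1 = c("a1", "a1")),
            hpath, row.names = FALSE)
  h <- read_hierarchy(hpath)
  expect_equal(h$admin1, "a1")
  expect_equal(h$a_of_i, c(0L, 0L))
  unlink(hpath)
})

test_that("point-to-polygon assignment partitions points with a tie rule", {
  polys <- list(square_poly(0, 0), square_poly(1, 0))
  attr(polys, "properties") <- data.frame(
    admin1 = c("a1", "a2"), admin2 = c("d1", "d3"), feature = 1:2)
  pts <- data.frame(cluster = c("p1", "p2", "p3"),
                    x = c(0.5, 2.5, 1.0),   # inside, outside, shared edge
                    y = c(0.5, 2.5, 0.5))
  asg <- assign_clusters_to_areas(pts, polys)
  expect_equal(asg$polygon, c(1L, NA, 1L))  # tie -> lowest id
  expect_true(asg$boundary[3])
  expect_true(is.na(asg$admin1[2]))
  # exactly one label or unassigned
  expect_true(all(is.na(asg$polygon) | asg$polygon %in% 1:2))
  expect_error(assign_clusters_to_areas(pts, list()),
               class = "prevmapr_validation_error")
})

test_that("reconciliation snaps jittered clusters into the recorded admin1", {
  polys <- list(square_poly(0, 0), square_poly(1, 0), square_poly(2, 0))
  attr(polys, "properties") <- data.frame(
    admin1 = c("a1", "a2", "a2"), admin2 = c("d1", "d3", "d4"), feature = 1:3)
  pts <- data.frame(cluster = c("p1", "p2", "p3"),
                    x = c(0.5, 0.9, 5.0),   # ok, jittered across border, lost
                    y = c(0.5, 0.5, 0.5))
  asg <- assign_clusters_to_areas(pts, polys)
  rec <- c("a1", "a2", "a2")
  out <- reconcile_assignments(asg, rec, pts, polys)
  expect_equal(nrow(out$report), 2)
  # brute-force nearest-polygon oracle for the jittered point (0.9, 0.5):
  # candidate polygons in a2 are squares at x in [1,2] and [2,3];
  # boundary distances 0.1 and 1.1 -> polygon 2
  expect_equal(out$assignment$polygon[2], 2L)
  expect_equal(out$assignment$admin2[2], "d3")
  # unassigned point (5, 0.5): distances 2 and 1 -> polygon 3
  expect_equal(out$assignment$polygon[3], 3L)
  expect_equal(out$assignment$admin2[3], "d4")

  # agreement everywhere -> empty report
  out2 <- reconcile_assignments(out$assignment, rec, pts, polys)
  expect_equal(nrow(out2$report), 0)
})

test_that("availability summary matches direct tabulation", {
  h <- area_hierarchy(c("d1", "d2", "d3"), c("a1", "a2", "a3"))
  cls <- list()
  for (k in seq_len(2)) cls[[length(cls) + 1]] <-
    list(admin1 = "a1", admin2 = "d1", stratum = "s1", y = rep(0:1, 3))
  for (k in seq_len(4)) cls[[length(cls) + 1]] <-
    list(admin1 = "a2", admin2 = "d2", stratum = "s2", y = rep(0:1, 2))
  for (k in seq_len(6)) cls[[length(cls) + 1]] <-
    list(admin1 = "a3", admin2 = "d3", stratum = "s3", y = 0:1)
  sv <- survey_from_clusters(cls, h)
  av <- availability_summary(cluster_table(sv))
  expect_equal(av$admin1$n_clusters, c(2, 4, 6))
  expect_equal(av$medians[["clusters_admin1"]], 4)
  expect_equal(length(av$sparse_areas$zero_cluster), 0)

  # drop one area entirely -> listed under zero clusters
  sv2 <- survey_from_clusters(cls[1:6], h)
  av2 <- availability_summary(cluster_table(sv2))
  expect_equal(av2$sparse_areas$zero_cluster, "d3")

  # synthetic DHS-like frame: medians match brute-force tabulation
  fr <- generate_frame(sim_config(n_admin1 = 8, n_admin2 = 40,
                                  eas_per_admin2 = 30), seed = 3)
  sv3 <- draw_survey(fr, design_config(clusters_per_admin1 = 12), seed = 4)
  ct3 <- cluster_table(sv3)
  av3 <- availability_summary(ct3)
  brute <- as.numeric(median(table(factor(ct3$admin2_id, levels = 0:39))))
  expect_equal(av3$medians[["clusters_admin2"]], brute)
})

test_that("urban sampling diagnostic exposes configured over-sampling", {
  h <- area_hierarchy(c("d1", "d2"), c("a1", "a2"))
  cls <- list(
    list(admin1 = "a1", admin2 = "d1", stratum = "s1u", urban = TRUE, y = 0:1),
    list(admin1 = "a1", admin2 = "d1", stratum = "s1u", urban = TRUE, y = 0:1),
    list(admin1 = "a1", admin2 = "d1", stratum = "s1r", urban = FALSE, y = 0:1),
    list(admin1 = "a1", admin2 = "d1", stratum = "s1r", urban = FALSE, y = 0:1),
    list(admin1 = "a2", admin2 = "d2", stratum = "s2r", urban = FALSE, y = 0:1)
  )
  sv <- survey_from_clusters(cls, h)
  diag <- urban_sampling_diagnostic(cluster_table(sv), c(0.3, 0.0))
  expect_equal(diag$sampled_urban_fraction, c(0.5, 0))
  expect_equal(diag$difference[1], 0.2)

  # simulated design with 2x urban over-sampling: positive mean difference
  fr <- generate_frame(sim_config(n_admin1 = 10, n_admin2 = 40,
                                  n_fully_urban = 0, eas_per_admin2 = 40),
                       seed = 5)
  sv2 <- draw_survey(fr, design_config(clusters_per_admin1 = 16,
                                       oversample_urban = 2), seed = 6)
  pop_frac <- vapply(fr$hierarchy$admin1, function(a) {
    eas <- fr$eas[fr$eas$admin1 == a, ]
    sum(eas$households[eas$urban]) / sum(eas$households)
  }, numeric(1))
  d2 <- urban_sampling_diagnostic(cluster_table(sv2), unname(pop_frac))
  expect_gt(mean(d2$difference, na.rm = TRUE), 0)
})
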