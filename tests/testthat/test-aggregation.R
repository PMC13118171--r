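grid_hierarchy <- function() area_hierarchy(c("d1", "d2"), c("a1", "a1"))

test_that("thresholding selects the smallest prefix reaching the target", {
  h <- grid_hierarchy()
  vals <- matrix(c(10, 20, 30, 40), 2, 2)
  a1 <- matrix(0L, 2, 2)
  r <- pop_raster(vals, a1)
  part <- urban_threshold_partition(r, 0.4)
  expect_equal(sum(part$urban), 1)
  expect_true(part$urban[vals == 40])
  expect_equal(part$achieved[1], 0.4)

  # first crossing overshoots: target 0.5 -> {40, 30}, achieved 0.7
  part2 <- urban_threshold_partition(r, 0.5)
  expect_equal(sort(vals[part2$urban]), c(30, 40))
  expect_equal(part2$achieved[1], 0.7)
  expect_equal(part2$threshold[1], 30)

  # equal densities: ties broken by pixel index order
  r3 <- pop_raster(matrix(25, 2, 2), a1)
  part3 <- urban_threshold_partition(r3, 0.5)
  expect_equal(which(part3$urban), c(1L, 2L))

  # zero population is an error; target 0 -> no urban pixels
  expect_error(urban_threshold_partition(pop_raster(matrix(0, 2, 2), a1), 0.5),
               class = "prevmapr_validation_error")
  expect_equal(sum(urban_threshold_partition(r, 0)$urban), 0)
})

test_that("target-population fractions match a brute-force double loop", {
  set.seed(81)
  h <- grid_hierarchy()
  a1 <- matrix(0L, 20, 20)
  a2 <- matrix(rep(c(0L, 1L), each = 200), 20, 20)
  pop0 <- matrix(rexp(400, 0.1), 20, 20)
  popT <- matrix(rexp(400, 0.2), 20, 20)
  part <- urban_threshold_partition(pop_raster(pop0, a1), 0.35)
  fr <- target_population_fractions(part, pop_raster(popT, a1, a2), h)
  # brute force over pixels
  urb_pop <- tot_pop <- c(0, 0)
  for (r in 1:20) for (c in 1:20) {
    k <- a2[r, c] + 1
    tot_pop[k] <- tot_pop[k] + popT[r, c]
    if (part$urban[r, c]) urb_pop[k] <- urb_pop[k] + popT[r, c]
  }
  expect_equal(fr$admin2$q, urb_pop / tot_pop, tolerance = 1e-12)
  expect_equal(fr$admin1$q[1], sum(popT[part$urban]) / sum(popT),
               tolerance = 1e-12)
  # q' weights sum to one within each area
  for (k in 0:1) {
    expect_equal(sum(fr$qprime[a2 == k]), 1, tolerance = 1e-9)
  }
  # all pixels urban -> q = 1; half of a uniform surface -> 0.5
  all_urb <- urban_threshold_partition(pop_raster(pop0, a1), 1)
  expect_equal(target_population_fractions(all_urb, pop_raster(popT, a1, a2),
                                           h)$admin1$q, 1)
  unif <- pop_raster(matrix(1, 20, 20), a1, a2)
  half <- part
  half$urban <- matrix(rep(c(TRUE, FALSE), 200), 20, 20)
  expect_equal(target_population_fractions(half, unif, h)$admin1$q, 0.5)
})

test_that("stratified area aggregation mixes the two stratum surfaces", {
  h <- toy_hierarchy()
  S <- 5
  fit <- fake_cluster_fit(
    alpha = matrix(0, S, 2), gamma = matrix(-0.5, S, 1),
    u = matrix(0, S, 4), hierarchy = h)
  # hand-computed: (1-q) expit(-0.5) + q expit(0) with q = 0.3
  fld <- aggregate_stratified_area(fit, rep(0.3, 4))
  expect_equal(fld$draws[1, 1], 0.7 * expit(-0.5) + 0.3 * 0.5,
               tolerance = 1e-12)
  expect_equal(round(fld$draws[1, 1], 5), 0.41428)
  # q = 1 -> pure urban expression
  fld1 <- aggregate_stratified_area(fit, rep(1, 4))
  expect_equal(unique(as.vector(fld1$draws)), 0.5)
  # gamma = 0 draws -> q is irrelevant
  fit0 <- fake_cluster_fit(alpha = matrix(0.4, S, 2),
                           gamma = matrix(0, S, 1),
                           u = matrix(0.1, S, 4), hierarchy = h)
  fa <- aggregate_stratified_area(fit0, rep(0.2, 4))
  fb <- aggregate_stratified_area(fit0, rep(0.9, 4))
  expect_equal(fa$draws, fb$draws, tolerance = 1e-12)
  # convexity: the mix lies between the stratum surfaces
  set.seed(5)
  fitr <- fake_cluster_fit(alpha = matrix(rnorm(S * 2), S, 2),
                           gamma = matrix(rnorm(S), S, 1),
                           u = matrix(rnorm(S * 4, 0, 0.3), S, 4),
                           hierarchy = h)
  q <- runif(4)
  mix <- aggregate_stratified_area(fitr, q)$draws
  lo <- pmin(expit(prevmapr:::fit_eta_draws(fitr, TRUE)),
             expit(prevmapr:::fit_eta_draws(fitr, FALSE)))
  hi <- pmax(expit(prevmapr:::fit_eta_draws(fitr, TRUE)),
             expit(prevmapr:::fit_eta_draws(fitr, FALSE)))
  expect_true(all(mix >= lo - 1e-12 & mix <= hi + 1e-12))
  # aggregation commutes with draw subsetting
  sub <- aggregate_stratified_area(fitr, q)$draws[1:3, ]
  fit_sub <- fitr
  for (nm in c("alpha", "gamma", "u")) fit_sub[[nm]] <- fitr[[nm]][1:3, , drop = FALSE]
  expect_equal(aggregate_stratified_area(fit_sub, q)$draws, sub,
               tolerance = 1e-12)
})

test_that("pixel-level aggregation reduces to the area formula and to
           hand-computed weighted sums", {
  h <- grid_hierarchy()
  S <- 4
  fit <- fake_cluster_fit(
    alpha = matrix(c(0.2, 0.1, 0, -0.1), S, 1), gamma = matrix(-0.5, S, 1),
    u = matrix(seq(-0.2, 0.4, length.out = S * 2), S, 2), hierarchy = h,
    variant = "stratified_nonnested")
  # 3-pixel area with weights (0.2, 0.3, 0.5): one urban, two rural pixels
  vals <- matrix(c(2, 3, 5, 1, 1, 1), 1, 6)   # area d1: first 3 pixels
  a1m <- matrix(0L, 1, 6)
  a2m <- matrix(c(0L, 0L, 0L, 1L, 1L, 1L), 1, 6)
  rT <- pop_raster(vals, a1m, a2m, epoch = "T")
  part <- list(urban = matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE), 1, 6))
  fld <- aggregate_pixel_level(fit, part, NULL, rT)
  eta_u <- fit$alpha[, 1] + fit$u[, 1]
  eta_r <- eta_u + fit$gamma[, 1]
  hand <- 0.2 * expit(eta_u) + 0.3 * expit(eta_r) + 0.5 * expit(eta_r)
  expect_equal(fld$draws[, 1], hand, tolerance = 1e-12)
  # all-urban area equals the stratified aggregate with q = 1
  expect_warning(agg_area <- aggregate_stratified_area(fit, c(NA, 1)),
                 "missing urban fraction")
  expect_equal(fld$draws[, 2], agg_area$draws[, 2], tolerance = 1e-12)
  # single-pixel area: theta equals the expit at that pixel
  rT1 <- pop_raster(matrix(c(2, 7), 1, 2), matrix(0L, 1, 2),
                    matrix(c(0L, 1L), 1, 2), epoch = "T")
  part1 <- list(urban = matrix(c(TRUE, TRUE), 1, 2))
  fld1 <- aggregate_pixel_level(fit, part1, NULL, rT1)
  expect_equal(fld1$draws[, 1], expit(fit$alpha[, 1] + fit$u[, 1]),
               tolerance = 1e-12)
  # covariate nodata on a populated pixel is an error
  fitX <- fake_cluster_fit(
    alpha = matrix(0, S, 1), gamma = matrix(-0.5, S, 1),
    u = matrix(0, S, 2), hierarchy = h, variant = "stratified_nonnested",
    beta = matrix(1, S, 1), X = matrix(0, 2, 1))
  covr <- matrix(c(NA, 1, 1, 1, 1, 1), 1, 6)
  expect_error(aggregate_pixel_level(fitX, part, list(covr), rT),
               class = "prevmapr_validation_error")
})

test_that("text raster round-trips through the headered format", {
  set.seed(91)
  m <- matrix(rpois(12, 30), 3, 4)
  m[2, 2] <- NA
  path <- tempfile(fileext = ".grd")
  write_text_raster(m, path, origin = c(34, -4), step = c(0.1, 0.1))
  r <- read_text_raster(path)
  expect_equal(r$values, m)
  expect_equal(r$origin, c(34, -4))
  unlink(path)
})
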