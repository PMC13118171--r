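test_that("beta-binomial log-pmf matches its limits and a quadrature oracle", {
  # single trial: Bernoulli for any d
  for (d in c(0, 0.2, 0.7)) {
    expect_equal(betabinomial_logpmf(1, 1, 0.3, d), log(0.3), tolerance = 1e-12)
    expect_equal(betabinomial_logpmf(0, 1, 0.3, d), log(0.7), tolerance = 1e-12)
  }
  # d -> 0 limit equals the binomial
  expect_equal(betabinomial_logpmf(4, 12, 0.35, 1e-8),
               dbinom(4, 12, 0.35, log = TRUE), tolerance = 1e-5)
  # quadrature oracle: integrate Binomial(n, q) over the Beta(a, b) density
  Y <- 3; n <- 10; p <- 0.4; d <- 0.2
  a <- p * (1 - d) / d; b <- (1 - p) * (1 - d) / d
  orc <- integrate(function(q) dbinom(Y, n, q) * dbeta(q, a, b), 0, 1,
                   rel.tol = 1e-12)$value
  expect_equal(betabinomial_logpmf(Y, n, p, d), log(orc), tolerance = 1e-6)
  expect_error(betabinomial_logpmf(5, 3, 0.4, 0.1),
               class = "prevmapr_validation_error")
  expect_error(betabinomial_logpmf(1, 3, 1.4, 0.1),
               class = "prevmapr_validation_error")
})

test_that("beta-binomial moments show the stated variance inflation", {
  # enumeration oracle from the implemented pmf itself
  n <- 20; p <- 0.3; d <- 0.2
  pr <- exp(betabinomial_logpmf(0:n, rep(n, n + 1), p, d))
  expect_equal(sum(pr), 1, tolerance = 1e-10)
  mu <- sum((0:n) * pr)
  v <- sum((0:n)^2 * pr) - mu^2
  expect_equal(mu, n * p, tolerance = 1e-10)
  expect_equal(v, n * p * (1 - p) * (1 + (n - 1) * d), tolerance = 1e-8)
})

test_that("linear predictor evaluates each variant", {
  h <- toy_hierarchy()
  cls <- list(
    list(admin1 = "a1", admin2 = "d1", stratum = "s1", urban = TRUE, y = 0:1),
    list(admin1 = "a1", admin2 = "d2", stratum = "s1", urban = FALSE, y = 0:1),
    list(admin1 = "a2", admin2 = "d3", stratum = "s2", urban = FALSE, y = 0:1)
  )
  ct <- cluster_table(survey_from_clusters(cls, h))
  # unstratified, alpha = 0, u = 0 -> p = 0.5 everywhere
  p0 <- linear_predictor(ct, cluster_model_spec("unstratified"),
                         list(alpha = 0))
  expect_equal(p0, rep(0.5, 3))
  # nested stratified, rural cluster: expit(0.2 - 0.45 + 0.1) = expit(-0.15)
  p1 <- linear_predictor(ct, cluster_model_spec("stratified_nested"),
                         list(alpha = c(0.2, 0.2), gamma = -0.45,
                              u = c(0.1, 0.1, 0.1, 0.1)))
  expect_equal(p1[2], expit(-0.15))
  expect_equal(p1[1], expit(0.3))    # urban: no gamma
  # interaction with equal slopes reproduces the nested variant exactly
  p2 <- linear_predictor(ct, cluster_model_spec("stratified_nested_interaction"),
                         list(alpha = c(0.2, 0.2), gamma = c(-0.45, -0.45),
                              u = rep(0.1, 4)))
  expect_equal(p2, p1)
  expect_error(
    linear_predictor(ct, cluster_model_spec("stratified_nested"),
                     list(alpha = 0.2, gamma = -0.45)),
    class = "prevmapr_validation_error")
})

test_that("single-area flat-prior fit matches the conjugate Beta posterior", {
  h <- area_hierarchy("d1", "a1")
  cls <- list(
    list(admin1 = "a1", admin2 = "d1", stratum = "s1", y = c(rep(1, 9), rep(0, 16))),
    list(admin1 = "a1", admin2 = "d1", stratum = "s1", y = c(rep(1, 8), rep(0, 17)))
  )
  ct <- cluster_table(survey_from_clusters(cls, h))
  fit <- fit_cluster_model(ct, spec = cluster_model_spec(
    variant = "unstratified", effect = "none", fix_d = 0,
    p_prior = "uniform", n_draws = 6000, burn_in = 1000, seed = 3))
  p_draws <- expit(fit$alpha[, 1])
  Y <- sum(ct$Y); n <- sum(ct$n)
  qs <- quantile(p_draws, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  expect_lt(max(abs(qs - qbeta(c(0.1, 0.25, 0.5, 0.75, 0.9), 1 + Y, 1 + n - Y))),
            0.01)
})

test_that("the sampler is seed-reproducible and flags unidentified gamma", {
  h <- toy_hierarchy()
  cls <- list(
    list(admin1 = "a1", admin2 = "d1", stratum = "s1", urban = TRUE,
         y = rbinom(20, 1, 0.6)),
    list(admin1 = "a1", admin2 = "d2", stratum = "s1", urban = TRUE,
         y = rbinom(20, 1, 0.5)),
    list(admin1 = "a2", admin2 = "d3", stratum = "s2", urban = TRUE,
         y = rbinom(20, 1, 0.4))
  )
  ct <- cluster_table(survey_from_clusters(cls, h))
  expect_error(fit_cluster_model(ct, spec = cluster_model_spec(
    "stratified_nested", effect = "none")), class = "prevmapr_validation_error")
  s1 <- fit_cluster_model(ct, spec = cluster_model_spec(
    "nested_unstratified", effect = "none", n_draws = 200, burn_in = 100,
    seed = 11))
  s2 <- fit_cluster_model(ct, spec = cluster_model_spec(
    "nested_unstratified", effect = "none", n_draws = 200, burn_in = 100,
    seed = 11))
  expect_identical(s1$alpha, s2$alpha)
  expect_identical(s1$d, s2$d)
})

test_that("stratified and unstratified variants agree when gamma = 0", {
  cfg <- sim_config(n_admin1 = 6, n_admin2 = 24, n_fully_urban = 1,
                    eas_per_admin2 = 30, gamma = 0)
  fr <- generate_frame(cfg, seed = 41)
  sv <- draw_survey(fr, design_config(clusters_per_admin1 = 14), seed = 42)
  ct <- cluster_table(sv)
  f_u <- fit_cluster_model(ct, fr$graph, cluster_model_spec(
    "unstratified", n_draws = 1500, burn_in = 800, seed = 43))
  f_s <- fit_cluster_model(ct, fr$graph, cluster_model_spec(
    "stratified_nonnested", n_draws = 1500, burn_in = 800, seed = 44))
  # gamma posterior concentrates near 0
  expect_lt(abs(mean(f_s$gamma)), 3 * sd(f_s$gamma))
  # aggregated area means agree within Monte-Carlo error
  q <- rep(0.5, 24)
  m_u <- summary(aggregate_stratified_area(f_u, q))$mean
  m_s <- summary(aggregate_stratified_area(f_s, q))$mean
  mcse <- apply(aggregate_stratified_area(f_s, q)$draws, 2, sd) /
    sqrt(prevmapr:::ess(f_s$sigma))
  expect_lt(mean(abs(m_u - m_s) / pmax(2 * mcse, 0.02)), 1)
})

test_that("richer variants do not fit worse in WAIC on stratified data", {
  cfg <- sim_config(n_admin1 = 6, n_admin2 = 24, n_fully_urban = 1,
                    eas_per_admin2 = 30, gamma = -0.6)
  fr <- generate_frame(cfg, seed = 51)
  sv <- draw_survey(fr, design_config(clusters_per_admin1 = 14), seed = 52)
  ct <- cluster_table(sv)
  w <- numeric(0)
  for (variant in c("unstratified", "stratified_nonnested",
                    "stratified_nested")) {
    fit <- fit_cluster_model(ct, fr$graph, cluster_model_spec(
      variant, n_draws = 800, burn_in = 600, seed = 53))
    w[variant] <- waic(cluster_loglik_draws(fit, ct))$waic
  }
  # generous MC tolerance on the nesting direction
  expect_lt(w["stratified_nonnested"], w["unstratified"] + 10)
  expect_lt(w["stratified_nested"], w["stratified_nonnested"] + 10)
})

test_that("cluster-level covariates are recovered by the sampler", {
  cfg <- sim_config(n_admin1 = 6, n_admin2 = 24, n_fully_urban = 1,
                    eas_per_admin2 = 30, beta = 0.6, sigma = 0.2)
  fr <- generate_frame(cfg, seed = 81)
  sv <- draw_survey(fr, design_config(clusters_per_admin1 = 20), seed = 82)
  ct <- cluster_table(sv)
  # observed per-cluster covariate values from the frame
  x <- fr$eas$x[match(as.integer(sub("^c", "", ct$cluster)), fr$eas$ea)]
  fit <- fit_cluster_model(ct, fr$graph, cluster_model_spec(
    "stratified_nested", X = cbind(x = x), covariate_level = "cluster",
    n_draws = 1500, burn_in = 1000, seed = 83))
  qb <- quantile(fit$beta[, 1], c(0.025, 0.975))
  expect_gt(mean(fit$beta[, 1]), 0.2)
  expect_true(qb[1] <= 0.6 + 0.2 && qb[2] >= 0.6 - 0.2)
})

test_that("WAIC matches brute-force evaluation and is additive", {
  set.seed(61)
  ll <- matrix(rnorm(200 * 3, -5, 0.3), 200, 3)
  out <- waic(ll)
  # direct recomputation
  lpd <- log(colMeans(exp(ll)))
  pw <- apply(ll, 2, var)
  expect_equal(out$waic, -2 * (sum(lpd) - sum(pw)), tolerance = 1e-9)
  expect_equal(out$p_waic, sum(pw), tolerance = 1e-12)
  # identical likelihood across draws -> zero penalty
  ll0 <- matrix(rep(c(-3, -4, -5), each = 150), 150, 3)
  expect_equal(waic(ll0)$waic, -2 * sum(ll0[1, ]), tolerance = 1e-9)
  # duplicating a cluster adds exactly its contribution
  ll4 <- cbind(ll, ll[, 2])
  expect_equal(waic(ll4)$waic, out$waic + out$contributions[2],
               tolerance = 1e-9)
  expect_error(waic(ll[1:50, ]), class = "prevmapr_validation_error")
  ll_bad <- ll; ll_bad[3, 2] <- -Inf
  expect_error(waic(ll_bad), class = "prevmapr_validation_error")
})

test_that("the likelihood is invariant to cluster ordering", {
  h <- toy_hierarchy()
  set.seed(71)
  cls <- lapply(1:6, function(k) list(
    admin1 = c("a1", "a2")[1 + k %% 2], admin2 = c("d1", "d3")[1 + k %% 2],
    stratum = c("s1", "s2")[1 + k %% 2], urban = k %% 3 == 0,
    y = rbinom(15, 1, 0.4)))
  ct <- cluster_table(survey_from_clusters(cls, h))
  perm <- sample(nrow(ct))
  ct2 <- ct[perm, ]
  p <- runif(nrow(ct), 0.2, 0.8)
  ll1 <- sum(betabinomial_logpmf(ct$Y, ct$n, p, 0.15))
  ll2 <- sum(betabinomial_logpmf(ct2$Y, ct2$n, p[perm], 0.15))
  expect_equal(ll1, ll2, tolerance = 1e-12)
})
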