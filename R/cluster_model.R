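# Cluster-level beta-binomial prevalence models: the likelihood, the five
# linear-predictor variants, the MCMC front-end (sampler in compiled code),
# and WAIC model comparison.

#' Beta-binomial log probability mass
#'
#' Mean/intra-cluster-correlation parameterization: for p in (0,1) and
#' d in [0,1), Y ~ BetaBinomial(n, a, b) with a = p(1-d)/d, b = (1-p)(1-d)/d,
#' so E[Y] = n p and Var[Y] = n p (1-p) (1 + (n-1) d). At d = 0 this is the
#' binomial log-pmf.
#'
#' @param Y,n counts, 0 <= Y <= n.
#' @param p mean prevalence in (0,1).
#' @param d overdispersion (intra-cluster correlation) in [0,1).
#' @return log probability (vectorized over Y, n, p).
#' @export
betabinomial_logpmf <- function(Y, n, p, d) {
  if (any(Y < 0 | Y > n) || any(n < 1)) {
    stop_prevmapr("need 0 <= Y <= n, n >= 1", class = "prevmapr_validation_error")
  }
  if (any(p <= 0 | p >= 1)) {
    stop_prevmapr("p must be in (0,1)", class = "prevmapr_validation_error")
  }
  if (any(d < 0 | d >= 1)) {
    stop_prevmapr("d must be in [0,1)", class = "prevmapr_validation_error")
  }
  if (all(d < 1e-12)) {
    return(stats::dbinom(Y, n, p, log = TRUE))
  }
  a <- p * (1 - d) / d
  b <- (1 - p) * (1 - d) / d
  lchoose(n, Y) + lbeta(Y + a, n - Y + b) - lbeta(a, b)
}

#' Cluster-model specification
#'
#' @param variant one of `"unstratified"`, `"nested_unstratified"`,
#'   `"stratified_nonnested"`, `"stratified_nested"`,
#'   `"stratified_nested_interaction"`.
#' @param X optional covariate matrix with one row per cluster (area-level
#'   covariates are entered as their per-cluster values; tag the level with
#'   `covariate_level`).
#' @param covariate_level `"none"`, `"area"` or `"cluster"`.
#' @param effect spatial random effect: `"bym2"`, `"iid"`, or `"none"`.
#' @param priors a [pc_prior_spec()].
#' @param d_prob_half prior tail P(d > 0.5) for the truncated exponential
#'   prior on the overdispersion (default 0.1); configurable sensitivity
#'   switch.
#' @param n_draws,burn_in,seed inference settings.
#' @param fix_d,fix_sigma,fix_phi optionally fix a parameter (conjugate
#'   checks and submodel collapses).
#' @param p_prior `"vague"` (normal on the intercept, sd 31.6) or
#'   `"uniform"` (uniform on the prevalence scale; only meaningful for the
#'   unstratified variant without random effects).
#' @return a `cluster_model_spec`.
#' @export
cluster_model_spec <- function(variant = c("stratified_nested", "unstratified",
                                           "nested_unstratified",
                                           "stratified_nonnested",
                                           "stratified_nested_interaction"),
                               X = NULL, covariate_level = c("none", "area", "cluster"),
                               effect = c("bym2", "iid", "none"),
                               priors = pc_prior_spec(), d_prob_half = 0.1,
                               n_draws = 2000, burn_in = 1000, seed = 1,
                               fix_d = NULL, fix_sigma = NULL, fix_phi = NULL,
                               p_prior = c("vague", "uniform")) {
  structure(list(variant = match.arg(variant), X = X,
                 covariate_level = match.arg(covariate_level),
                 effect = match.arg(effect), priors = priors,
                 d_prob_half = d_prob_half,
                 n_draws = n_draws, burn_in = burn_in, seed = seed,
                 fix_d = fix_d, fix_sigma = fix_sigma, fix_phi = fix_phi,
                 p_prior = match.arg(p_prior)),
            class = "cluster_model_spec")
}

variant_modes <- function(variant) {
  switch(variant,
    unstratified = c(alpha = 0L, gamma = 0L),
    nested_unstratified = c(alpha = 1L, gamma = 0L),
    stratified_nonnested = c(alpha = 0L, gamma = 1L),
    stratified_nested = c(alpha = 1L, gamma = 1L),
    stratified_nested_interaction = c(alpha = 1L, gamma = 2L)
  )
}

# rate of the exponential prior on d truncated to (0,1) with P(d > 0.5) = prob
d_prior_rate <- function(prob = 0.1) {
  f <- function(l) {
    (exp(-l / 2) - exp(-l)) / (1 - exp(-l)) - prob
  }
  stats::uniroot(f, c(1e-6, 200))$root
}

#' Per-cluster prevalence from a parameter set
#'
#' Evaluates the selected linear-predictor variant,
#' logit(p_c) = alpha[_{a[c]}] + gamma[_{a[c]}] 1{c rural} + x_c' beta + u_{i[c]},
#' for one concrete parameter assignment.
#'
#' @param clusters a `cluster_table`.
#' @param spec a [cluster_model_spec()].
#' @param parameters list with `alpha` (scalar or per-admin1 vector), `gamma`
#'   (absent/scalar/per-admin1), `beta` (per covariate) and `u` (per area at
#'   the model's resolution; optional).
#' @param level model resolution, `"admin2"` (default) or `"admin1"`.
#' @return numeric vector p_c.
#' @export
linear_predictor <- function(clusters, spec, parameters, level = "admin2") {
  modes <- variant_modes(spec$variant)
  a1 <- clusters$admin1_id
  ai <- if (level == "admin2") clusters$admin2_id else clusters$admin1_id
  alpha <- parameters$alpha
  if (modes["alpha"] == 1L) {
    if (length(alpha) <= max(a1)) {
      stop_prevmapr("alpha must have one entry per admin1",
                    class = "prevmapr_validation_error")
    }
    eta <- alpha[a1 + 1L]
  } else {
    stopifnot(length(alpha) == 1)
    eta <- rep(alpha, nrow(clusters))
  }
  if (modes["gamma"] > 0L) {
    g <- parameters$gamma
    if (modes["gamma"] == 2L) {
      if (length(g) <= max(a1)) {
        stop_prevmapr("gamma must have one entry per admin1",
                      class = "prevmapr_validation_error")
      }
      eta <- eta + ifelse(clusters$urban, 0, g[a1 + 1L])
    } else {
      stopifnot(length(g) == 1)
      eta <- eta + ifelse(clusters$urban, 0, g)
    }
  }
  if (!is.null(spec$X)) {
    X <- as.matrix(spec$X)
    if (nrow(X) != nrow(clusters) || length(parameters$beta) != ncol(X)) {
      stop_prevmapr("covariate/beta dimensions do not match clusters",
                    class = "prevmapr_validation_error")
    }
    eta <- eta + drop(X %*% parameters$beta)
  }
  if (!is.null(parameters$u)) {
    if (length(parameters$u) <= max(ai)) {
      stop_prevmapr("u must have one entry per area",
                    class = "prevmapr_validation_error")
    }
    eta <- eta + parameters$u[ai + 1L]
  }
  expit(eta)
}

#' Fit a cluster-level beta-binomial model
#'
#' Adaptive Metropolis-within-Gibbs (compiled sampler), seed-reproducible.
#' Admin-1 intercepts and interaction slopes are fixed effects with vague
#' normal priors (sd 31.6); sigma gets the PC prior, phi the tabulated PC
#' prior, and d a truncated exponential calibrated by `d_prob_half`.
#'
#' @param clusters a `cluster_table`.
#' @param graph `adjacency_graph` at the model's area resolution (required
#'   for the BYM2 effect).
#' @param spec a [cluster_model_spec()].
#' @param level `"admin2"` (default) or `"admin1"`: resolution of the random
#'   effect and of area prevalences.
#' @return a `cluster_fit` with draw matrices `alpha`, `gamma`, `beta`, `u`,
#'   vectors `sigma`, `phi`, `d`, and sampler diagnostics.
#' @export
fit_cluster_model <- function(clusters, graph = NULL,
                              spec = cluster_model_spec(),
                              level = c("admin2", "admin1")) {
  level <- match.arg(level)
  stopifnot(inherits(clusters, "cluster_table"))
  hierarchy <- attr(clusters, "hierarchy")
  if (nrow(clusters) < 2) {
    stop_prevmapr("need at least 2 clusters", class = "prevmapr_validation_error")
  }
  modes <- variant_modes(spec$variant)
  n_admin1 <- length(hierarchy$admin1)
  if (modes["gamma"] > 0L && length(unique(clusters$urban)) == 1L) {
    stop_prevmapr("all clusters share one urban/rural status: ",
                  "the stratum effect gamma is unidentified",
                  class = "prevmapr_validation_error")
  }
  if (spec$variant == "stratified_nested_interaction" && n_admin1 < 2) {
    stop_prevmapr("interaction variant requires >= 2 admin1 areas",
                  class = "prevmapr_validation_error")
  }
  areas <- if (level == "admin2") hierarchy$admin2 else hierarchy$admin1
  n_area <- length(areas)
  ai <- if (level == "admin2") clusters$admin2_id else clusters$admin1_id

  use_re <- spec$effect != "none"
  if (spec$effect == "bym2") {
    if (is.null(graph)) {
      stop_prevmapr("BYM2 effect requires an adjacency graph",
                    class = "prevmapr_validation_error")
    }
    if (graph$n != n_area) {
      stop_prevmapr("graph resolution (", graph$n, ") does not match ",
                    level, " (", n_area, ")", class = "prevmapr_validation_error")
    }
    icar <- scaled_icar(graph)
    nb0 <- lapply(graph$nb, function(v) as.integer(v - 1L))
    area_scale <- icar$scale[graph$component]
    area_scale[is.na(area_scale)] <- 0
    comp <- as.integer(graph$component - 1L)
    singleton <- icar$singleton
    fix_phi <- spec$fix_phi
    if (all(singleton)) fix_phi <- 0
    phi_prior <- if (is.null(fix_phi)) {
      pc_prior_phi(icar, spec$priors$threshold_phi, spec$priors$alpha_phi)
    } else NULL
  } else {
    nb0 <- rep(list(integer(0)), n_area)
    area_scale <- rep(0, n_area)
    comp <- seq_len(n_area) - 1L
    singleton <- rep(TRUE, n_area)
    fix_phi <- 0
    phi_prior <- NULL
  }
  X <- if (is.null(spec$X)) matrix(0, nrow(clusters), 0) else as.matrix(spec$X)
  if (nrow(X) != nrow(clusters)) {
    stop_prevmapr("covariate rows do not align with clusters",
                  class = "prevmapr_validation_error")
  }

  set.seed(spec$seed)
  res <- bb_mcmc_cpp(
    Y = as.integer(clusters$Y), n = as.integer(clusters$n),
    rural = as.integer(!clusters$urban),
    a1 = as.integer(clusters$admin1_id), a2 = as.integer(ai),
    X = X, n_admin1 = n_admin1, n_area = n_area,
    nb = nb0, area_scale = area_scale, comp = comp, singleton = singleton,
    alpha_mode = modes[["alpha"]], gamma_mode = modes[["gamma"]],
    use_re = as.integer(use_re),
    intercept_logistic = as.integer(spec$p_prior == "uniform"),
    lambda_sigma = pc_prior_sd(spec$priors$U_sigma, spec$priors$alpha_sigma)$lambda,
    phi_grid = phi_prior$phi %||% c(0, 1),
    phi_logdens = if (is.null(phi_prior)) c(0, 0) else log(phi_prior$density),
    lambda_d = d_prior_rate(spec$d_prob_half),
    fix_d = spec$fix_d %||% -1, fix_sigma = spec$fix_sigma %||% -1,
    fix_phi = fix_phi %||% -1,
    n_iter = spec$burn_in + spec$n_draws, burn_in = spec$burn_in
  )
  fit <- structure(
    list(
      alpha = res$alpha, gamma = res$gamma, beta = res$beta,
      u = if (use_re) res$u else NULL,
      sigma = drop(res$sigma), phi = drop(res$phi), d = drop(res$d),
      level = level, areas = areas, admin1 = hierarchy$admin1,
      hierarchy = hierarchy, spec = spec,
      diagnostics = list(accept_sigma = res$accept_sigma,
                         ess_sigma = ess(drop(res$sigma)))
    ),
    class = "cluster_fit"
  )
  fit
}

#' @export
print.cluster_fit <- function(x, ...) {
  cat("Cluster-level beta-binomial fit (", x$spec$variant, ", ",
      x$spec$effect, " effect) at ", x$level, " level\n", sep = "")
  cat("  ", nrow(x$alpha), " draws; posterior median d: ",
      signif(stats::median(x$d), 3), sep = "")
  if (!is.null(x$u)) cat("  sigma:", signif(stats::median(x$sigma), 3))
  cat("\n")
  invisible(x)
}

#' Per-draw per-cluster prevalences from a fit
#'
#' @param fit a `cluster_fit`.
#' @param clusters the `cluster_table` the model was fitted to (or new
#'   clusters with the same id spaces).
#' @return S x C matrix of p_c draws.
#' @export
cluster_prevalence_draws <- function(fit, clusters) {
  modes <- variant_modes(fit$spec$variant)
  a1 <- clusters$admin1_id + 1L
  ai <- (if (fit$level == "admin2") clusters$admin2_id else clusters$admin1_id) + 1L
  S <- nrow(fit$alpha)
  eta <- if (modes["alpha"] == 1L) fit$alpha[, a1, drop = FALSE] else
    matrix(fit$alpha[, 1], S, nrow(clusters))
  if (modes["gamma"] > 0L) {
    gmat <- if (modes["gamma"] == 2L) fit$gamma[, a1, drop = FALSE] else
      matrix(fit$gamma[, 1], S, nrow(clusters))
    eta <- eta + sweep(gmat, 2, as.numeric(!clusters$urban), `*`)
  }
  if (!is.null(fit$spec$X) && ncol(fit$beta) > 0) {
    eta <- eta + fit$beta %*% t(as.matrix(fit$spec$X))
  }
  if (!is.null(fit$u)) eta <- eta + fit$u[, ai, drop = FALSE]
  expit(eta)
}

#' Per-draw cluster log-likelihoods
#'
#' @inheritParams cluster_prevalence_draws
#' @return S x C matrix of beta-binomial log-likelihoods (inputs to [waic()]).
#' @export
cluster_loglik_draws <- function(fit, clusters) {
  p <- cluster_prevalence_draws(fit, clusters)
  S <- nrow(p)
  Y <- matrix(clusters$Y, S, nrow(clusters), byrow = TRUE)
  n <- matrix(clusters$n, S, nrow(clusters), byrow = TRUE)
  ll <- matrix(NA_real_, S, ncol(p))
  for (s in seq_len(S)) {
    ll[s, ] <- betabinomial_logpmf(clusters$Y, clusters$n, p[s, ],
                                   max(fit$d[s], 0))
  }
  ll
}

#' Watanabe-Akaike information criterion
#'
#' waic = -2 [ sum_c log mean_s L_cs - sum_c var_s log L_cs ].
#'
#' @param loglik S x C matrix of per-draw, per-cluster log-likelihoods
#'   (S >= 100 draws).
#' @return list `waic`, `p_waic`, `contributions` (per-cluster -2 elpd).
#' @export
waic <- function(loglik) {
  if (nrow(loglik) < 100) {
    stop_prevmapr("need >= 100 draws for WAIC", class = "prevmapr_validation_error")
  }
  if (any(!is.finite(loglik))) {
    stop_prevmapr("non-finite log-likelihoods", class = "prevmapr_validation_error")
  }
  # log mean exp by column, stabilized
  mx <- apply(loglik, 2, max)
  lpd <- mx + log(colMeans(exp(sweep(loglik, 2, mx))))
  p_waic <- apply(loglik, 2, stats::var)
  list(
    waic = -2 * (sum(lpd) - sum(p_waic)),
    p_waic = sum(p_waic),
    contributions = -2 * (lpd - p_waic)
  )
}
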