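# Area-level (Fay-Herriot) smoothing of logit-scale direct estimates:
#   sampling model  theta_hat_i | theta_i ~ N(theta_i, V_hat_i)
#   linking model   theta_i = alpha + x_i' beta + u_i
# with u either IID normal or BYM2, PC priors on (sigma, phi), and a
# Gibbs/Metropolis sampler (conjugate updates for the Gaussian components,
# adaptive random-walk Metropolis for the hyperparameters marginalized over u).

#' Identify areas whose direct estimates cannot feed a Fay-Herriot model
#'
#' The trigger mirrors the rescue rule: the design variance is missing or
#' below the floor (1e-12), which covers areas with 0/1 prevalence (variance
#' exactly zero), unusably small variances, and areas without an estimate.
#'
#' @param de a `direct_estimates` data.frame (admin-2 level).
#' @return character vector of failing area labels.
#' @export
phantom_failing_areas <- function(de) {
  as.character(de$area[is.na(de$var_p) | de$var_p < VAR_FLOOR | de$degenerate])
}

#' Supplement failing areas with phantom clusters
#'
#' For each failing admin-2 area, appends one synthetic ("phantom") cluster
#' whose prevalence equals the direct estimate of the parent admin-1 area and
#' whose summed weight equals the average cluster weight-sum across observed
#' clusters in that admin-1 area. The phantom is realized as a pseudo-cluster
#' of n = round(mean cluster size in the admin-1) individuals with
#' Y = round(n * p_hat_admin1) positive outcomes, each carrying weight
#' sum_w_bar / n; provenance is flagged in a `phantom` column.
#'
#' @param survey a `survey_dataset`.
#' @param direct_admin1 admin-1 level `direct_estimates`.
#' @param failing_areas admin-2 labels to rescue (see
#'   [phantom_failing_areas()]).
#' @return the augmented `survey_dataset`.
#' @export
add_phantom_clusters <- function(survey, direct_admin1, failing_areas) {
  if (!length(failing_areas)) return(survey)
  hierarchy <- attr(survey, "hierarchy")
  if (is.null(survey$phantom)) survey$phantom <- FALSE
  new_rows <- list()
  for (area in as.character(failing_areas)) {
    i2 <- hierarchy$admin2_index[[area]]
    if (is.null(i2) || is.na(i2)) {
      stop_prevmapr("unknown admin2 area: ", area,
                    class = "prevmapr_validation_error")
    }
    i1 <- hierarchy$a_of_i[i2 + 1L]
    row1 <- which(as.character(direct_admin1$area) == hierarchy$admin1[i1 + 1L])
    if (!length(row1) || direct_admin1$degenerate[row1]) {
      stop_prevmapr("admin1 direct estimate degenerate or missing for ",
                    hierarchy$admin1[i1 + 1L], "; cannot rescue ", area,
                    class = "prevmapr_validation_error")
    }
    p1 <- direct_admin1$p_hat[row1]
    sel <- survey$admin1_id == i1 & !survey$phantom
    if (!any(sel)) {
      stop_prevmapr("no observed clusters in admin1 of ", area,
                    class = "prevmapr_validation_error")
    }
    cl_w <- tapply(survey$weight[sel], survey$cluster[sel], sum)
    cl_n <- tapply(rep(1, sum(sel)), survey$cluster[sel], sum)
    n <- max(2L, as.integer(round(mean(cl_n))))
    Y <- as.integer(round(n * p1))
    sum_w <- mean(cl_w)
    # place the phantom in the modal stratum of the parent admin-1
    strat <- names(which.max(table(survey$stratum[sel])))
    urb <- survey$urban[sel][match(strat, survey$stratum[sel])]
    new_rows[[area]] <- data.frame(
      cluster = paste0("phantom_", area),
      stratum = strat,
      admin1 = hierarchy$admin1[i1 + 1L],
      admin2 = area,
      urban = urb,
      y = c(rep(1L, Y), rep(0L, n - Y)),
      weight = sum_w / n,
      id = NA_integer_,
      admin1_id = i1,
      admin2_id = unname(i2),
      phantom = TRUE
    )
  }
  out <- rbind(as.data.frame(survey), do.call(rbind, new_rows))
  rownames(out) <- NULL
  structure(out, class = c("survey_dataset", "data.frame"),
            hierarchy = hierarchy)
}

#' Fay-Herriot model specification
#'
#' @param effect `"bym2"` or `"iid"` random effect.
#' @param X optional area-level covariate matrix (rows aligned with areas).
#' @param priors a [pc_prior_spec()].
#' @param n_draws posterior draws kept (default 4000).
#' @param burn_in burn-in iterations (default 2000).
#' @param seed RNG seed honored end-to-end.
#' @param fix_sigma,fix_phi optionally collapse a hyperprior to a fixed value
#'   (used for conjugate checks).
#' @param intercept_prior_sd vague normal sd for alpha and beta.
#' @return an `fh_model_spec` list.
#' @export
fh_model_spec <- function(effect = c("bym2", "iid"), X = NULL,
                          priors = pc_prior_spec(), n_draws = 4000,
                          burn_in = 2000, seed = 1,
                          fix_sigma = NULL, fix_phi = NULL,
                          intercept_prior_sd = 31.6) {
  structure(list(effect = match.arg(effect), X = X, priors = priors,
                 n_draws = n_draws, burn_in = burn_in, seed = seed,
                 fix_sigma = fix_sigma, fix_phi = fix_phi,
                 intercept_prior_sd = intercept_prior_sd),
            class = "fh_model_spec")
}

#' Fit the Fay-Herriot model
#'
#' Degenerate areas contribute no likelihood term and are predicted from the
#' linking model. Hyperparameters (sigma, and phi for BYM2) are updated by
#' adaptive random-walk Metropolis on the marginal likelihood (random effects
#' integrated out); (alpha, beta) and u have conjugate Gaussian updates.
#'
#' @param de a `direct_estimates` data.frame.
#' @param graph an `adjacency_graph` (required for the BYM2 effect).
#' @param spec an [fh_model_spec()].
#' @return an `fh_fit` with parameter draws, the latent `theta` draws (logit
#'   scale), a `posterior_field` of prevalences, and sampler diagnostics.
#' @export
fit_fay_herriot <- function(de, graph = NULL, spec = fh_model_spec()) {
  th <- de$theta_hat
  Vh <- de$V_hat
  obs <- !de$degenerate
  if (any(!is.finite(th[obs])) || any(!is.finite(Vh[obs])) ||
      any(Vh[obs] <= 0)) {
    stop_prevmapr("non-finite inputs for non-degenerate areas",
                  class = "prevmapr_validation_error")
  }
  if (sum(obs) < 2) {
    stop_prevmapr("need non-degenerate direct estimates for >= 2 areas",
                  class = "prevmapr_validation_error")
  }
  M <- nrow(de)
  X <- spec$X
  W <- cbind(intercept = rep(1, M), X)
  p <- ncol(W)
  tau2 <- spec$intercept_prior_sd^2

  bym2 <- spec$effect == "bym2"
  if (bym2) {
    if (is.null(graph)) {
      stop_prevmapr("BYM2 effect requires an adjacency graph",
                    class = "prevmapr_validation_error")
    }
    icar <- scaled_icar(graph)
    Vs <- icar$V
    phi_prior <- if (is.null(spec$fix_phi)) {
      pc_prior_phi(icar, spec$priors$threshold_phi, spec$priors$alpha_phi)
    } else NULL
  } else {
    Vs <- diag(M) * 0   # pure IID: covariance sigma^2 I
  }
  sd_prior <- pc_prior_sd(spec$priors$U_sigma, spec$priors$alpha_sigma)

  set.seed(spec$seed)
  # state
  sigma <- spec$fix_sigma %||% 0.3
  phi <- if (bym2) (spec$fix_phi %||% 0.5) else 0
  delta <- rep(0, p)

  I_M <- diag(M)
  cov_u <- function(sigma, phi) {
    if (bym2) sigma^2 * ((1 - phi) * I_M + phi * Vs) else sigma^2 * I_M
  }
  Wo <- W[obs, , drop = FALSE]
  tho <- th[obs]
  Dfull <- rep(0, M); Dfull[obs] <- 1 / Vh[obs]

  marg_ll <- function(sigma, phi, delta) {
    K <- cov_u(sigma, phi)[obs, obs, drop = FALSE]
    diag(K) <- diag(K) + Vh[obs]
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    r <- tho - Wo %*% delta
    z <- backsolve(ch, forwardsolve(t(ch), r))
    -sum(log(diag(ch))) - 0.5 * sum(r * z)
  }
  log_prior_hyper <- function(lsig, lphi) {
    sigma <- exp(lsig)
    lp <- sd_prior$log_density(sigma) + lsig   # Jacobian d sigma / d lsig
    if (bym2 && is.null(spec$fix_phi)) {
      ph <- expit(lphi)
      lp <- lp + phi_prior$log_density(ph) + log(ph * (1 - ph))
    }
    lp
  }

  n_iter <- spec$burn_in + spec$n_draws
  upd_sigma <- is.null(spec$fix_sigma)
  upd_phi <- bym2 && is.null(spec$fix_phi)
  step <- 0.4
  acc <- 0; n_prop <- 0

  keep_theta <- matrix(NA_real_, spec$n_draws, M)
  keep_u <- matrix(NA_real_, spec$n_draws, M)
  keep_delta <- matrix(NA_real_, spec$n_draws, p)
  keep_sigma <- numeric(spec$n_draws)
  keep_phi <- numeric(spec$n_draws)

  cur_ll <- marg_ll(sigma, phi, delta)
  for (it in seq_len(n_iter)) {
    # --- hyperparameters (joint RW on transformed scale) ---
    if (upd_sigma || upd_phi) {
      lsig <- log(sigma); lphi <- if (bym2) logit(min(max(phi, 1e-8), 1 - 1e-8)) else 0
      prop_lsig <- if (upd_sigma) lsig + step * stats::rnorm(1) else lsig
      prop_lphi <- if (upd_phi) lphi + step * stats::rnorm(1) else lphi
      prop_sigma <- exp(prop_lsig)
      prop_phi <- if (bym2) expit(prop_lphi) else 0
      prop_ll <- marg_ll(prop_sigma, prop_phi, delta)
      lr <- prop_ll + log_prior_hyper(prop_lsig, prop_lphi) -
        cur_ll - log_prior_hyper(lsig, lphi)
      n_prop <- n_prop + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        sigma <- prop_sigma; phi <- prop_phi; cur_ll <- prop_ll
        acc <- acc + 1
      }
      if (it <= spec$burn_in) {   # diminishing adaptation toward 0.3 accept
        step <- exp(log(step) + (min(1, exp(min(lr, 0))) - 0.3) / sqrt(it))
      }
    }
    # --- (alpha, beta) conjugate given hypers, u marginalized ---
    K <- cov_u(sigma, phi)[obs, obs, drop = FALSE]
    diag(K) <- diag(K) + Vh[obs]
    ch <- chol(K)
    KiW <- backsolve(ch, forwardsolve(t(ch), Wo))
    Kith <- backsolve(ch, forwardsolve(t(ch), tho))
    A <- crossprod(Wo, KiW) + diag(p) / tau2
    b <- crossprod(Wo, Kith)
    chA <- chol(A)
    mu_d <- backsolve(chA, forwardsolve(t(chA), b))
    delta <- drop(mu_d + backsolve(chA, stats::rnorm(p)))
    cur_ll <- marg_ll(sigma, phi, delta)
    # --- u | rest (conjugate Gaussian) ---
    C <- cov_u(sigma, phi)
    Ci <- chol2inv(chol(C + 1e-12 * I_M))
    Lam <- Ci; diag(Lam) <- diag(Lam) + Dfull
    chL <- chol(Lam)
    r <- rep(0, M); r[obs] <- (th[obs] - (W %*% delta)[obs]) / Vh[obs]
    mu_u <- backsolve(chL, forwardsolve(t(chL), r))
    u <- drop(mu_u + backsolve(chL, stats::rnorm(M)))

    if (it > spec$burn_in) {
      s <- it - spec$burn_in
      theta <- drop(W %*% delta) + u
      keep_theta[s, ] <- theta
      keep_u[s, ] <- u
      keep_delta[s, ] <- delta
      keep_sigma[s] <- sigma
      keep_phi[s] <- phi
    }
  }

  field <- posterior_field(expit(keep_theta), as.character(de$area),
                           level = attr(de, "level") %||% "area")
  structure(
    list(
      theta = keep_theta,
      u = keep_u,
      alpha = keep_delta[, 1],
      beta = if (p > 1) keep_delta[, -1, drop = FALSE] else NULL,
      sigma = keep_sigma,
      phi = if (bym2) keep_phi else NULL,
      field = field,
      areas = as.character(de$area),
      observed = obs,
      spec = spec,
      diagnostics = list(
        accept_hyper = if (n_prop) acc / n_prop else NA_real_,
        ess_sigma = ess(keep_sigma)
      )
    ),
    class = "fh_fit"
  )
}

#' @export
print.fh_fit <- function(x, ...) {
  cat("Fay-Herriot fit (", x$spec$effect, " effect): ",
      length(x$areas), " areas, ", length(x$sigma), " draws\n", sep = "")
  cat("  posterior median sigma:", signif(stats::median(x$sigma), 3))
  if (!is.null(x$phi)) cat("  phi:", signif(stats::median(x$phi), 3))
  cat("\n  hyper acceptance:", signif(x$diagnostics$accept_hyper, 2),
      " ESS(sigma):", round(x$diagnostics$ess_sigma), "\n")
  invisible(x)
}

# crude effective sample size from the autocorrelation function
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)[1]
  if (is.na(pos)) pos <- length(ac)
  n / (1 + 2 * sum(ac[seq_len(pos)]))
}

#' Construct a posterior field of area prevalences
#'
#' @param draws S x M matrix of prevalences in (0,1).
#' @param areas area labels (length M).
#' @param level resolution tag ("admin1"/"admin2").
#' @return a `posterior_field`.
#' @export
posterior_field <- function(draws, areas, level = "area") {
  stopifnot(ncol(draws) == length(areas))
  if (any(!is.na(draws) & (draws <= 0 | draws >= 1))) {
    stop_prevmapr("posterior field entries must be in (0,1)",
                  class = "prevmapr_validation_error")
  }
  structure(list(draws = draws, areas = as.character(areas), level = level),
            class = "posterior_field")
}

#' @export
print.posterior_field <- function(x, ...) {
  cat("Posterior field (", x$level, "): ", ncol(x$draws), " areas x ",
      nrow(x$draws), " draws\n", sep = "")
  invisible(x)
}

#' Summarize a posterior field
#'
#' @param object a `posterior_field`.
#' @param ... unused.
#' @return data.frame `area, mean, median, q05, q95, cv, width`.
#' @export
summary.posterior_field <- function(object, ...) {
  s <- draw_summary(object$draws)
  data.frame(
    area = object$areas,
    mean = s$mean, median = s$median, q05 = s$q05, q95 = s$q95,
    cv = apply(object$draws, 2, stats::sd) / s$mean,
    width = s$q95 - s$q05
  )
}
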