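# Synthetic population frames and stratified two-stage PPS surveys with known
# truth. The default configuration emulates a DHS-style national design:
# 47 admin-1 areas containing 300 admin-2 areas on a lattice, urban/rural
# strata within each admin-1 (two admin-1 areas purely urban, giving 92
# strata), PPS cluster sampling with households as the size variable, a fixed
# individual take per cluster, and inverse-inclusion-probability design
# weights with urban over-sampling.

#' Simulation configuration for the population frame
#'
#' Truth is generated from the nested stratified cluster-level model:
#' logit(p_c) = alpha_{a[c]} + gamma 1{c rural} + x_c beta + u_{i[c]}, with u a
#' BYM2 effect on a lattice adjacency over admin-2 areas, and outcomes drawn
#' beta-binomially with overdispersion d at survey time.
#'
#' @param n_admin1,n_admin2 number of areas (default 47 / 300).
#' @param n_fully_urban number of purely urban admin-1 areas (default 2, so
#'   the default stratum count is 2 * 47 - 2 = 92).
#' @param eas_per_admin2 enumeration areas per admin-2 area (default 40).
#' @param urban_ea_frac mean fraction of urban EAs in mixed admin-1 areas.
#' @param hh_meanlog,hh_sdlog log-normal household counts per EA.
#' @param eligible_mean Poisson mean of eligible individuals per EA.
#' @param alpha_mean,alpha_sd admin-1 intercepts alpha_a ~ N(mean, sd^2) on
#'   the logit scale.
#' @param gamma rural log-odds effect (default -0.45).
#' @param sigma,phi,d BYM2 total sd, spatial proportion, overdispersion.
#' @param beta covariate coefficient (a smooth spatial covariate surface is
#'   generated when non-NULL).
#' @return a `sim_config`.
#' @export
sim_config <- function(n_admin1 = 47, n_admin2 = 300, n_fully_urban = 2,
                       eas_per_admin2 = 40, urban_ea_frac = 0.3,
                       hh_meanlog = log(100), hh_sdlog = 0.5,
                       eligible_mean = 60,
                       alpha_mean = 0.9, alpha_sd = 0.35,
                       gamma = -0.45, sigma = 0.3, phi = 0.5, d = 0.15,
                       beta = NULL) {
  if (n_admin2 < n_admin1 || eas_per_admin2 < 1 || eligible_mean <= 0 ||
      sigma < 0 || phi < 0 || phi > 1 || d < 0 || d >= 1) {
    stop_prevmapr("invalid simulation configuration",
                  class = "prevmapr_validation_error")
  }
  structure(as.list(environment()), class = "sim_config")
}

# lattice of n_admin2 cells, snake-ordered so consecutive cells (and hence the
# admin-1 blocks) are contiguous
lattice_layout <- function(n_admin2, n_admin1) {
  ncol <- ceiling(sqrt(n_admin2))
  nrow <- ceiling(n_admin2 / ncol)
  cells <- data.frame(idx = seq_len(n_admin2))
  r <- (cells$idx - 1) %/% ncol
  k <- (cells$idx - 1) %% ncol
  cells$row <- r
  cells$col <- ifelse(r %% 2 == 0, k, ncol - 1 - k)   # snake order
  sizes <- rep(n_admin2 %/% n_admin1, n_admin1)
  extra <- n_admin2 %% n_admin1
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  cells$admin1 <- rep(seq_len(n_admin1), sizes)
  edges <- list()
  pos <- matrix(NA_integer_, nrow, ncol)
  pos[cbind(cells$row + 1, cells$col + 1)] <- cells$idx
  for (i in seq_len(n_admin2)) {
    rr <- cells$row[i]; cc <- cells$col[i]
    if (cc + 2 <= ncol && !is.na(pos[rr + 1, cc + 2])) {
      edges[[length(edges) + 1]] <- c(i, pos[rr + 1, cc + 2])
    }
    if (rr + 2 <= nrow && !is.na(pos[rr + 2, cc + 1])) {
      edges[[length(edges) + 1]] <- c(i, pos[rr + 2, cc + 1])
    }
  }
  list(cells = cells,
       edges = do.call(rbind, edges))
}

#' Generate a population frame with known truth
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (bit-identical frames for identical seeds).
#' @return a `population_frame`: `eas` data.frame (admin1, admin2, urban,
#'   households, eligible, true prevalence p, optional covariate x), the
#'   `hierarchy`, the admin-2 `graph`, the generating `params`, and the
#'   `config`.
#' @export
generate_frame <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  lay <- lattice_layout(config$n_admin2, config$n_admin1)
  admin1_labels <- sprintf("a%02d", seq_len(config$n_admin1))
  admin2_labels <- sprintf("d%03d", seq_len(config$n_admin2))
  hierarchy <- area_hierarchy(admin2_labels, admin1_labels[lay$cells$admin1])
  graph <- build_adjacency(
    data.frame(area_a = admin2_labels[lay$edges[, 1]],
               area_b = admin2_labels[lay$edges[, 2]]),
    labels = admin2_labels
  )
  icar <- scaled_icar(graph)
  e1 <- stats::rnorm(config$n_admin2)
  e2 <- drop(sample_scaled_icar(icar, 1))
  u <- bym2_effect(config$sigma, config$phi, e1, e2, icar$singleton)
  alpha_a <- stats::rnorm(config$n_admin1, config$alpha_mean, config$alpha_sd)

  fully_urban <- seq_len(config$n_fully_urban)
  urb_frac <- stats::rbeta(config$n_admin2, 10 * config$urban_ea_frac,
                           10 * (1 - config$urban_ea_frac))
  urb_frac[lay$cells$admin1 %in% fully_urban] <- 1

  n_ea <- config$n_admin2 * config$eas_per_admin2
  admin2_of_ea <- rep(seq_len(config$n_admin2), each = config$eas_per_admin2)
  admin1_of_ea <- lay$cells$admin1[admin2_of_ea]
  urban <- stats::runif(n_ea) < urb_frac[admin2_of_ea]
  households <- pmax(10, round(stats::rlnorm(n_ea, config$hh_meanlog,
                                             config$hh_sdlog)))
  eligible <- pmax(1L, stats::rpois(n_ea, config$eligible_mean))
  x <- NULL
  eta <- alpha_a[admin1_of_ea] + config$gamma * (!urban) + u[admin2_of_ea]
  if (!is.null(config$beta)) {
    # smooth low-order spatial surface + EA noise
    rr <- lay$cells$row[admin2_of_ea] / max(1, max(lay$cells$row))
    cc <- lay$cells$col[admin2_of_ea] / max(1, max(lay$cells$col))
    x <- rr + cc - rr * cc - 0.5 + stats::rnorm(n_ea, 0, 0.1)
    eta <- eta + config$beta * x
  }
  eas <- data.frame(
    ea = seq_len(n_ea),
    admin1 = admin1_labels[admin1_of_ea],
    admin2 = admin2_labels[admin2_of_ea],
    urban = urban,
    households = households,
    eligible = eligible,
    p = expit(eta)
  )
  if (!is.null(x)) eas$x <- x
  structure(
    list(eas = eas, hierarchy = hierarchy, graph = graph, config = config,
         params = list(alpha_a = alpha_a, gamma = config$gamma,
                       sigma = config$sigma, phi = config$phi, d = config$d,
                       beta = config$beta, u = u)),
    class = "population_frame"
  )
}

#' @export
print.population_frame <- function(x, ...) {
  cat("Population frame:", nrow(x$eas), "EAs in",
      length(x$hierarchy$admin2), "admin-2 /",
      length(x$hierarchy$admin1), "admin-1 areas\n")
  invisible(x)
}

#' True area prevalence of a frame
#'
#' Eligible-population-weighted mean of the EA prevalences at the requested
#' level (the expectation version of the finite-population prevalence).
#'
#' @param frame a `population_frame`.
#' @param level `"admin1"` or `"admin2"`.
#' @return data.frame `area, truth`.
#' @export
true_area_prevalence <- function(frame, level = c("admin1", "admin2")) {
  level <- match.arg(level)
  labels <- level_labels(frame$hierarchy, level)
  g <- frame$eas[[level]]
  num <- tapply(frame$eas$eligible * frame$eas$p, g, sum)
  den <- tapply(frame$eas$eligible, g, sum)
  data.frame(area = labels, truth = as.numeric((num / den)[labels]))
}

#' Two-stage survey design configuration
#'
#' @param clusters_per_admin1 total clusters sampled per admin-1 area
#'   (default 36, split between the urban and rural strata).
#' @param oversample_urban urban allocation multiplier (> 0; 1 = proportional
#'   to stratum household counts, default 2).
#' @param take individuals sampled per cluster (default 25, capped at
#'   availability).
#' @param nonresponse individual nonresponse rate in [0, 1); weights carry the
#'   standard nonresponse inflation 1/(1 - rate).
#' @return a `design_config`.
#' @export
design_config <- function(clusters_per_admin1 = 36, oversample_urban = 2,
                          take = 25, nonresponse = 0) {
  if (clusters_per_admin1 < 2 || oversample_urban <= 0 || take < 1 ||
      nonresponse < 0 || nonresponse >= 1) {
    stop_prevmapr("invalid design configuration",
                  class = "prevmapr_validation_error")
  }
  structure(list(clusters_per_admin1 = clusters_per_admin1,
                 oversample_urban = oversample_urban,
                 take = take, nonresponse = nonresponse),
            class = "design_config")
}

# systematic PPS without replacement: m hits on the cumulative size scale
systematic_pps <- function(sizes, m) {
  tot <- sum(sizes)
  step <- tot / m
  pts <- stats::runif(1) * step + (seq_len(m) - 1) * step
  idx <- findInterval(pts, cumsum(sizes), left.open = TRUE) + 1L
  idx
}

#' Draw a stratified two-stage PPS survey from a frame
#'
#' Strata are admin-1 x urban/rural. Within each stratum, clusters (EAs) are
#' drawn by systematic PPS with household counts as the size variable; `take`
#' individuals are sampled per cluster (capped at availability); individual
#' outcomes are drawn beta-binomially from the EA prevalence and the frame's
#' overdispersion d. Design weights are inverse inclusion probabilities
#' (cluster pi_c = m_h HH_c / HH_h, within-cluster take fraction), inflated
#' for nonresponse.
#'
#' @param frame a `population_frame`.
#' @param design a [design_config()].
#' @param seed RNG seed.
#' @return a `survey_dataset`.
#' @export
draw_survey <- function(frame, design = design_config(), seed = 1) {
  stopifnot(inherits(frame, "population_frame"),
            inherits(design, "design_config"))
  set.seed(seed)
  eas <- frame$eas
  d <- frame$params$d
  hit_all <- integer(0)
  pi_all <- numeric(0)
  for (a in frame$hierarchy$admin1) {
    in_a <- eas$admin1 == a
    hh_u <- sum(eas$households[in_a & eas$urban])
    hh_r <- sum(eas$households[in_a & !eas$urban])
    for (urb in c(TRUE, FALSE)) {
      sel <- which(in_a & eas$urban == urb)
      other <- sum(in_a & eas$urban != urb)
      if (!length(sel)) next
      # allocation: household-proportional with urban multiplier
      m_tot <- design$clusters_per_admin1
      if (other == 0) {
        m <- m_tot
      } else {
        share_u <- design$oversample_urban * hh_u /
          (design$oversample_urban * hh_u + hh_r)
        m_u <- min(m_tot - 1L, max(1L, round(m_tot * share_u)))
        m <- if (urb) m_u else m_tot - m_u
      }
      if (length(sel) < m) {
        stop_prevmapr("stratum ", a, if (urb) " urban" else " rural",
                      " has ", length(sel), " EAs but ", m, " requested",
                      class = "prevmapr_validation_error")
      }
      sizes <- eas$households[sel]
      hit <- sel[systematic_pps(sizes, m)]
      hit_all <- c(hit_all, hit)
      pi_all <- c(pi_all, pmin(1, m * eas$households[hit] / sum(sizes)))
    }
  }
  n_el <- eas$eligible[hit_all]
  t_c <- pmin(design$take, n_el)
  p_c <- eas$p[hit_all]
  p_tilde <- if (d > 0) {
    stats::rbeta(length(hit_all), p_c * (1 - d) / d, (1 - p_c) * (1 - d) / d)
  } else p_c
  idx <- rep(seq_along(hit_all), t_c)
  y <- stats::rbinom(length(idx), 1, p_tilde[idx])
  if (design$nonresponse > 0) {
    keep <- stats::runif(length(idx)) >= design$nonresponse
    # never lose a whole cluster to nonresponse
    keep[match(seq_along(hit_all), idx)] <- TRUE
    idx <- idx[keep]
    y <- y[keep]
  }
  df <- data.frame(
    cluster = paste0("c", eas$ea[hit_all[idx]]),
    stratum = paste0(eas$admin1[hit_all[idx]],
                     ifelse(eas$urban[hit_all[idx]], "_urban", "_rural")),
    admin1 = eas$admin1[hit_all[idx]],
    admin2 = eas$admin2[hit_all[idx]],
    urban = eas$urban[hit_all[idx]],
    y = y,
    weight = (1 / (pi_all[idx] * (t_c[idx] / n_el[idx]))) /
      (1 - design$nonresponse)
  )
  load_survey(df, frame$hierarchy)
}
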