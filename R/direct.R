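# Design-based direct estimation: weighted (Hajek ratio) prevalence per area,
# stratified with-replacement-PSU Taylor-linearization variances, the logit
# transform with delta-method variances, and logit-scale intervals and CVs.

level_id <- function(level) {
  level <- match.arg(level, c("admin1", "admin2"))
  paste0(level, "_id")
}

level_labels <- function(hierarchy, level) {
  if (level == "admin1") hierarchy$admin1 else hierarchy$admin2
}

#' Design-weighted prevalence per area
#'
#' The Hajek ratio estimator: p_hat_i = sum(w_j y_j) / sum(w_j) over the
#' sampled individuals of area i. Areas with no data get NA.
#'
#' @param survey a `survey_dataset`.
#' @param level `"admin1"` or `"admin2"`.
#' @return numeric vector of prevalences, one per area in hierarchy order.
#' @export
weighted_prevalence <- function(survey, level = c("admin1", "admin2")) {
  level <- match.arg(level)
  hierarchy <- attr(survey, "hierarchy")
  ids <- survey[[level_id(level)]]
  M <- length(level_labels(hierarchy, level))
  p <- rep(NA_real_, M)
  num <- tapply(survey$weight * survey$y, ids, sum)
  den <- tapply(survey$weight, ids, sum)
  p[as.integer(names(num)) + 1L] <- num / den
  p
}

# per-area variance work-horse; returns list(var, n_clusters, lonely)
area_design_variance <- function(w, y, cluster, stratum) {
  Nhat <- sum(w)
  p <- sum(w * y) / Nhat
  cl <- split(seq_along(w), cluster)
  n_cl <- length(cl)
  z <- vapply(cl, function(idx) sum(w[idx] * (y[idx] - p)) / Nhat, numeric(1))
  cl_stratum <- vapply(cl, function(idx) as.character(stratum[idx[1]]), character(1))
  if (n_cl == 1L) {
    # single-PSU area: clustering cannot be estimated; fall back to an
    # individual-level with-replacement approximation (documented)
    n <- length(w)
    if (n < 2) return(list(var = NA_real_, n_clusters = n_cl, lonely = TRUE))
    zj <- w * (y - p) / Nhat
    return(list(var = n / (n - 1) * sum((zj - mean(zj))^2),
                n_clusters = n_cl, lonely = TRUE))
  }
  v <- 0
  lonely <- FALSE
  zbar_all <- mean(z)
  for (h in unique(cl_stratum)) {
    zh <- z[cl_stratum == h]
    nh <- length(zh)
    if (nh == 1L) {
      # lonely PSU: deviation from the overall area mean, factor 1
      v <- v + (zh - zbar_all)^2
      lonely <- TRUE
    } else {
      v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
    }
  }
  list(var = v, n_clusters = n_cl, lonely = lonely)
}

#' Design-based variance of the weighted prevalence per area
#'
#' Stratified, with-replacement-PSU Taylor linearization of the ratio
#' estimator, restricted to each area's strata and clusters: with
#' z_c = sum_{j in c} w_j (y_j - p_hat) / N_hat,
#' var = sum_h n_h/(n_h - 1) sum_{c in h} (z_c - zbar_h)^2.
#' A stratum contributing a single cluster to an area enters as its squared
#' deviation from the area-wide mean of cluster residuals (with a warning);
#' an area with a single cluster falls back to an individual-level
#' with-replacement approximation. Failures are flags, never exceptions.
#'
#' @inheritParams weighted_prevalence
#' @return data.frame `area, p_hat, var_p, n_clusters, degenerate` in
#'   hierarchy order. `degenerate` is TRUE iff the area has no clusters, the
#'   prevalence is 0 or 1, or the variance is missing or below the floor
#'   (1e-12).
#' @export
design_variance <- function(survey, level = c("admin1", "admin2")) {
  level <- match.arg(level)
  hierarchy <- attr(survey, "hierarchy")
  labels <- level_labels(hierarchy, level)
  ids <- survey[[level_id(level)]]
  M <- length(labels)
  out <- data.frame(
    area = labels, p_hat = NA_real_, var_p = NA_real_,
    n_clusters = 0L, degenerate = TRUE
  )
  lonely_any <- FALSE
  for (i in seq_len(M) - 1L) {
    sel <- which(ids == i)
    if (!length(sel)) next
    w <- survey$weight[sel]; y <- survey$y[sel]
    out$p_hat[i + 1L] <- sum(w * y) / sum(w)
    res <- area_design_variance(w, y, survey$cluster[sel], survey$stratum[sel])
    out$var_p[i + 1L] <- res$var
    out$n_clusters[i + 1L] <- res$n_clusters
    lonely_any <- lonely_any || res$lonely
    p <- out$p_hat[i + 1L]
    out$degenerate[i + 1L] <-
      is.na(res$var) || p <= 0 || p >= 1 || res$var < VAR_FLOOR
  }
  if (lonely_any) {
    warning("lonely-PSU strata encountered; adjust-style variance used",
            call. = FALSE)
  }
  out
}

#' Direct estimates with logit transform, intervals and CV
#'
#' Convenience wrapper running [weighted_prevalence()], [design_variance()],
#' [logit_delta()] and [intervals_and_cv()].
#'
#' @inheritParams weighted_prevalence
#' @param level_prob interval coverage level (default 0.95).
#' @return a `direct_estimates` data.frame.
#' @export
direct_estimates <- function(survey, level = c("admin1", "admin2"),
                             level_prob = 0.95) {
  level <- match.arg(level)
  de <- design_variance(survey, level)
  de$theta_hat <- NA_real_
  de$V_hat <- NA_real_
  de$ci_lower <- NA_real_
  de$ci_upper <- NA_real_
  de$cv <- NA_real_
  de$width <- NA_real_
  de <- structure(de, class = c("direct_estimates", "data.frame"),
                  level = level, hierarchy = attr(survey, "hierarchy"))
  de <- logit_delta(de)
  intervals_and_cv(de, level_prob)
}

#' Logit transform with delta-method variance
#'
#' Fills `theta_hat = logit(p_hat)` and `V_hat = var_p / [p_hat (1-p_hat)]^2`
#' for non-degenerate rows; degenerate rows are skipped with a warning.
#'
#' @param de a `direct_estimates` data.frame (from [design_variance()] with the
#'   extra columns, or [direct_estimates()]).
#' @return the updated `direct_estimates`.
#' @export
logit_delta <- function(de) {
  ok <- !de$degenerate
  if (any(de$degenerate & !is.na(de$p_hat))) {
    warning("degenerate areas skipped in logit transform", call. = FALSE)
  }
  de$theta_hat[ok] <- logit(de$p_hat[ok])
  de$V_hat[ok] <- de$var_p[ok] / (de$p_hat[ok] * (1 - de$p_hat[ok]))^2
  de
}

#' Uncertainty intervals and coefficients of variation
#'
#' Intervals are built on the logit scale, theta_hat +/- z * sqrt(V_hat), and
#' back-transformed, so they respect [0,1]. CV = sqrt(var_p) / p_hat.
#'
#' @param de a `direct_estimates` data.frame with `theta_hat`/`V_hat` filled.
#' @param level_prob interval coverage level.
#' @return the updated `direct_estimates` with `ci_lower, ci_upper, cv, width`.
#' @export
intervals_and_cv <- function(de, level_prob = 0.95) {
  z <- stats::qnorm(1 - (1 - level_prob) / 2)
  ok <- !de$degenerate
  se <- sqrt(de$V_hat[ok])
  de$ci_lower[ok] <- expit(de$theta_hat[ok] - z * se)
  de$ci_upper[ok] <- expit(de$theta_hat[ok] + z * se)
  de$cv[ok] <- sqrt(de$var_p[ok]) / de$p_hat[ok]
  de$width[ok] <- de$ci_upper[ok] - de$ci_lower[ok]
  de
}

#' @export
print.direct_estimates <- function(x, ...) {
  cat("Direct estimates at", attr(x, "level") %||% "?", "level:",
      nrow(x), "areas,", sum(x$degenerate), "degenerate\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Write direct estimates to CSV
#' @param de a `direct_estimates`.
#' @param path output file.
#' @export
write_direct_estimates <- function(de, path) {
  cols <- c("area", "p_hat", "var_p", "theta_hat", "V_hat", "ci_lower",
            "ci_upper", "cv", "width", "n_clusters", "degenerate")
  utils::write.csv(as.data.frame(de)[, cols], path, row.names = FALSE)
  invisible(path)
}
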