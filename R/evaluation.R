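# Stage-3/4 diagnostics and summaries: the between-area variation statistic v
# (over-smoothing screen), coarse-to-fine field population, exceedance
# probabilities, and cross-model comparison tables.

#' Posterior between-area variation v
#'
#' Per draw s, v_s = (1/(M-1)) sum_i (theta_is - mean_s)^2: the sample variance
#' of the prevalence surface. Comparing v of a fine-level model against v of a
#' coarse model populated to the fine level screens for over-smoothing (a
#' fine-level model with materially *smaller* v than its coarse counterpart is
#' suspect).
#'
#' @param field a `posterior_field` with M >= 2 areas.
#' @return list `draws` (v per draw), `mean`, `ci` (95% quantile interval).
#' @export
between_area_variation <- function(field) {
  draws <- field$draws
  if (ncol(draws) < 2) {
    stop_prevmapr("need >= 2 areas", class = "prevmapr_validation_error")
  }
  v <- apply(draws, 1, stats::var)
  list(draws = v, mean = mean(v),
       ci = stats::quantile(v, c(0.025, 0.975), names = FALSE))
}

#' Populate a fine level from a coarse posterior field
#'
#' Every admin-2 area inherits the draws of its parent admin-1 area verbatim
#' (prevalence assumed constant within the parent), producing the coarse
#' benchmark for the over-smoothing screen.
#'
#' @param field a `posterior_field` at admin-1 level (columns = admin-1
#'   areas in hierarchy order).
#' @param hierarchy an `area_hierarchy` covering all fine areas.
#' @return a `posterior_field` at admin-2 level.
#' @export
populate_finer_level <- function(field, hierarchy) {
  ia <- match(field$areas, hierarchy$admin1)
  if (anyNA(ia)) {
    stop_prevmapr("field areas not found among admin1 labels",
                  class = "prevmapr_validation_error")
  }
  parent <- match(hierarchy$a_of_i + 1L, ia)
  if (anyNA(parent)) {
    stop_prevmapr("unmapped fine area(s): ",
                  paste(hierarchy$admin2[is.na(parent)], collapse = ", "),
                  class = "prevmapr_validation_error")
  }
  posterior_field(field$draws[, parent, drop = FALSE], hierarchy$admin2,
                  level = "admin2")
}

#' Exceedance probabilities
#'
#' Fraction of posterior draws with theta_i above the threshold — progress
#' screens against policy targets.
#'
#' @param field a `posterior_field`.
#' @param threshold prevalence threshold in (0,1).
#' @return data.frame `area, prob`.
#' @export
exceedance_probability <- function(field, threshold) {
  if (!(threshold > 0 && threshold < 1)) {
    stop_prevmapr("threshold must be in (0,1)",
                  class = "prevmapr_validation_error")
  }
  data.frame(area = field$areas,
             prob = colMeans(field$draws > threshold))
}

# point estimates + intervals in a common shape
estimate_rows <- function(x, name) {
  if (inherits(x, "direct_estimates")) {
    data.frame(
      area = as.character(x$area), model = name,
      mean = x$p_hat, median = x$p_hat, q05 = NA_real_, q95 = NA_real_,
      ci_lower = x$ci_lower, ci_upper = x$ci_upper,
      cv = x$cv, width = x$width, degenerate = x$degenerate
    )
  } else if (inherits(x, "posterior_field")) {
    s <- summary(x)
    lo <- apply(x$draws, 2, stats::quantile, probs = 0.025, na.rm = TRUE)
    hi <- apply(x$draws, 2, stats::quantile, probs = 0.975, na.rm = TRUE)
    data.frame(
      area = s$area, model = name,
      mean = s$mean, median = s$median, q05 = s$q05, q95 = s$q95,
      ci_lower = lo, ci_upper = hi, cv = s$cv, width = s$width,
      degenerate = FALSE
    )
  } else {
    stop_prevmapr("unsupported estimate set: ", class(x)[1],
                  class = "prevmapr_validation_error")
  }
}

#' Cross-model comparison table
#'
#' Aligns named estimate sets (direct estimates and/or posterior fields) on
#' shared areas into a long table, and summarizes each model pair: correlation
#' of point estimates, the shrinkage slope (regression of the second model's
#' points on the first's — slopes < 1 indicate attenuation toward the grand
#' mean), and counts of areas where one model's 95% interval excludes the
#' other's point. Degenerate direct-estimate areas stay in the table, flagged.
#'
#' @param estimates named list of `direct_estimates` / `posterior_field`
#'   objects sharing area ids.
#' @return list `table` (long data.frame) and `pairs` (pairwise summary).
#' @export
comparison_table <- function(estimates) {
  stopifnot(is.list(estimates), !is.null(names(estimates)))
  rows <- Map(estimate_rows, estimates, names(estimates))
  areas <- Reduce(intersect, lapply(rows, function(r) r$area))
  if (!length(areas)) {
    stop_prevmapr("estimate sets share no areas",
                  class = "prevmapr_validation_error")
  }
  tab <- do.call(rbind, lapply(rows, function(r) r[r$area %in% areas, ]))
  rownames(tab) <- NULL
  nm <- names(estimates)
  pairs <- list()
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i == j && length(nm) > 1) next
      ri <- rows[[i]][match(areas, rows[[i]]$area), ]
      rj <- rows[[j]][match(areas, rows[[j]]$area), ]
      ok <- is.finite(ri$mean) & is.finite(rj$mean)
      slope <- if (sum(ok) >= 2)
        unname(stats::coef(stats::lm(rj$mean[ok] ~ ri$mean[ok]))[2]) else NA_real_
      pairs[[length(pairs) + 1L]] <- data.frame(
        model_x = nm[i], model_y = nm[j],
        correlation = if (sum(ok) >= 2)
          stats::cor(ri$mean[ok], rj$mean[ok]) else NA_real_,
        slope = slope,
        n_y_point_outside_x_interval = sum(
          rj$mean[ok] < ri$ci_lower[ok] | rj$mean[ok] > ri$ci_upper[ok],
          na.rm = TRUE)
      )
      if (i == j) break
    }
  }
  list(table = tab, pairs = do.call(rbind, pairs))
}

#' CV screening against a reporting threshold
#'
#' Flags areas whose coefficient of variation exceeds the release threshold
#' (default 16.7%, the common official-statistics cut-off below which
#' estimates can be used without restriction).
#'
#' @param tab a long comparison table or any data.frame with `area` and `cv`.
#' @param threshold CV threshold (default 0.167).
#' @return the input with a logical `cv_ok` column.
#' @export
cv_screen <- function(tab, threshold = 0.167) {
  tab$cv_ok <- !is.na(tab$cv) & tab$cv < threshold
  tab
}
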