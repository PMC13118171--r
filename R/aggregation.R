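# Urban-fraction reconstruction by population-raster thresholding, and
# aggregation of stratified cluster-model posteriors to area prevalences,
# either with area-level covariates (closed-form stratum mix) or pixel by
# pixel (pixels standing in for the unknown population clusters).

#' Construct a labelled population raster
#'
#' Plain gridded arrays with an affine origin/step header. `admin1` / `admin2`
#' carry the 0-based internal area id of each pixel (NA outside the study
#' region); labelled pixels partition the region.
#'
#' @param values numeric matrix of non-negative population counts (NA =
#'   nodata).
#' @param admin1 integer matrix of admin-1 ids (same shape).
#' @param admin2 optional integer matrix of admin-2 ids.
#' @param origin,step affine georeference (x, y) of the grid.
#' @param epoch free-form tag (`"T0"` frame year or `"T"` survey year).
#' @return a `pop_raster`.
#' @export
pop_raster <- function(values, admin1, admin2 = NULL, origin = c(0, 0),
                       step = c(1, 1), epoch = "T0") {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) {
    stop_prevmapr("population values must be >= 0",
                  class = "prevmapr_validation_error")
  }
  stopifnot(all(dim(admin1) == dim(values)))
  if (!is.null(admin2)) stopifnot(all(dim(admin2) == dim(values)))
  structure(list(values = values, admin1 = admin1, admin2 = admin2,
                 origin = origin, step = step, epoch = epoch),
            class = "pop_raster")
}

#' Read a headered text grid
#'
#' Format: header lines `ncols`, `nrows`, `xorigin`, `yorigin`, `xstep`,
#' `ystep`, `nodata`, followed by `nrows` rows of values.
#'
#' @param path file path.
#' @return list with `values` matrix and the georeference fields.
#' @export
read_text_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[a-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[kv[1]]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata)) m[m == hdr$nodata] <- NA
  list(values = m, origin = c(hdr$xorigin %||% 0, hdr$yorigin %||% 0),
       step = c(hdr$xstep %||% 1, hdr$ystep %||% 1))
}

#' Write a headered text grid
#' @param values numeric matrix.
#' @param path output file.
#' @param origin,step georeference.
#' @param nodata nodata sentinel.
#' @export
write_text_raster <- function(values, path, origin = c(0, 0), step = c(1, 1),
                              nodata = -9999) {
  v <- values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)), paste("nrows", nrow(values)),
    paste("xorigin", origin[1]), paste("yorigin", origin[2]),
    paste("xstep", step[1]), paste("ystep", step[2]),
    paste("nodata", nodata)
  ), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Urban/rural partition of a population raster by density thresholding
#'
#' Per admin-1 area, pixels are sorted by population (density, on an equal-area
#' grid) in decreasing order, ties broken by pixel index; the urban set is the
#' smallest prefix whose population share first reaches the reported urban
#' fraction. An exact match is generally impossible on a discrete grid: the
#' achieved fraction and the gap are recorded. The partition is frozen at the
#' sampling-frame epoch (T0) and reused at prediction time.
#'
#' @param raster_T0 a [pop_raster()] for the frame year.
#' @param admin1_urban_fracs target urban population fractions in [0,1], one
#'   per admin-1 id (in id order).
#' @return an `urban_partition`: logical `urban` matrix, per-admin1
#'   `threshold` (population of the last urban pixel), `achieved` fraction and
#'   `target`.
#' @export
urban_threshold_partition <- function(raster_T0, admin1_urban_fracs) {
  if (any(admin1_urban_fracs < 0 | admin1_urban_fracs > 1, na.rm = TRUE)) {
    stop_prevmapr("urban fractions must be in [0,1]",
                  class = "prevmapr_validation_error")
  }
  v <- raster_T0$values
  a1 <- raster_T0$admin1
  M <- length(admin1_urban_fracs)
  urban <- matrix(FALSE, nrow(v), ncol(v))
  threshold <- rep(NA_real_, M)
  achieved <- rep(NA_real_, M)
  for (i in seq_len(M) - 1L) {
    idx <- which(a1 == i & !is.na(v))
    tot <- sum(v[idx])
    if (!length(idx) || tot <= 0) {
      stop_prevmapr("admin1 id ", i, " has zero population",
                    class = "prevmapr_validation_error")
    }
    target <- admin1_urban_fracs[i + 1L]
    ord <- idx[order(-v[idx], idx)]
    share <- cumsum(v[ord]) / tot
    K <- which(share >= target - 1e-12)[1]
    if (target <= 0) K <- 0L
    if (K > 0) {
      urban[ord[seq_len(K)]] <- TRUE
      threshold[i + 1L] <- v[ord[K]]
      achieved[i + 1L] <- share[K]
    } else {
      achieved[i + 1L] <- 0
    }
  }
  structure(list(urban = urban, threshold = threshold, achieved = achieved,
                 target = admin1_urban_fracs),
            class = "urban_partition")
}

#' Target-population urban fractions and pixel weights
#'
#' Applies the frozen T0 urban partition to the target population at survey
#' year T: q_i = urban pop_T / total pop_T per area, and q' = per-pixel pop_T
#' share within its area (the aggregation weights of the pixel-level step).
#'
#' @param partition an [urban_threshold_partition()] result.
#' @param raster_T target-population [pop_raster()] at year T, co-registered
#'   with the partition.
#' @param hierarchy an `area_hierarchy`.
#' @return an `urban_fractions`: data.frames `admin1` and `admin2` (`area`,
#'   `q`), and `qprime` matrix of within-admin2 pixel weights.
#' @export
target_population_fractions <- function(partition, raster_T, hierarchy) {
  v <- raster_T$values
  stopifnot(all(dim(partition$urban) == dim(v)))
  frac_level <- function(ids, labels) {
    q <- rep(NA_real_, length(labels))
    for (i in seq_along(labels) - 1L) {
      idx <- which(ids == i & !is.na(v))
      tot <- sum(v[idx])
      if (!length(idx) || tot <= 0) {
        warning("area ", labels[i + 1L], " has zero target population",
                call. = FALSE)
        next
      }
      q[i + 1L] <- sum(v[idx][partition$urban[idx]]) / tot
    }
    data.frame(area = labels, q = q)
  }
  qprime <- matrix(NA_real_, nrow(v), ncol(v))
  if (!is.null(raster_T$admin2)) {
    for (i in seq_along(hierarchy$admin2) - 1L) {
      idx <- which(raster_T$admin2 == i & !is.na(v))
      tot <- sum(v[idx])
      if (tot > 0) qprime[idx] <- v[idx] / tot
    }
  }
  structure(
    list(
      admin1 = frac_level(raster_T$admin1, hierarchy$admin1),
      admin2 = if (is.null(raster_T$admin2)) NULL else
        frac_level(raster_T$admin2, hierarchy$admin2),
      qprime = qprime
    ),
    class = "urban_fractions"
  )
}

# draws of the area-level linear predictor pieces for aggregation
fit_eta_draws <- function(fit, rural, X_area = NULL) {
  modes <- variant_modes(fit$spec$variant)
  hierarchy <- fit$hierarchy
  M <- length(fit$areas)
  a_of <- if (fit$level == "admin2") hierarchy$a_of_i + 1L else seq_len(M)
  S <- nrow(fit$alpha)
  eta <- if (modes["alpha"] == 1L) fit$alpha[, a_of, drop = FALSE] else
    matrix(fit$alpha[, 1], S, M)
  if (rural && modes["gamma"] > 0L) {
    g <- if (modes["gamma"] == 2L) fit$gamma[, a_of, drop = FALSE] else
      matrix(fit$gamma[, 1], S, M)
    eta <- eta + g
  }
  if (!is.null(X_area)) {
    X_area <- as.matrix(X_area)
    if (nrow(X_area) != M || ncol(X_area) != ncol(fit$beta)) {
      stop_prevmapr("area covariates do not match fit dimensions",
                    class = "prevmapr_validation_error")
    }
    eta <- eta + fit$beta %*% t(X_area)
  }
  if (!is.null(fit$u)) eta <- eta + fit$u
  eta
}

#' Aggregate a stratified cluster fit to area prevalences (area covariates)
#'
#' Per posterior draw,
#' theta_i = (1 - q_i) expit(alpha_{a[i]} + gamma + x_i' beta + u_i)
#'         +      q_i  expit(alpha_{a[i]}         + x_i' beta + u_i),
#' i.e. a q_i-weighted mix of the rural and urban stratum prevalences.
#'
#' @param fit a `cluster_fit` from a stratified (or unstratified) variant with
#'   area-level or no covariates.
#' @param q urban fractions: an `urban_fractions` object or a numeric vector
#'   aligned with the fit's areas.
#' @param X_area optional area-level covariate matrix (rows = areas).
#' @return a `posterior_field` at the fit's level; areas with missing q are
#'   skipped with a warning (NA columns).
#' @export
aggregate_stratified_area <- function(fit, q, X_area = NULL) {
  if (inherits(q, "urban_fractions")) {
    q <- if (fit$level == "admin2") q$admin2$q else q$admin1$q
  }
  stopifnot(length(q) == length(fit$areas))
  if (any(is.na(q))) {
    warning("areas with missing urban fraction skipped: ",
            paste(fit$areas[is.na(q)], collapse = ", "), call. = FALSE)
  }
  p_rural <- expit(fit_eta_draws(fit, rural = TRUE, X_area = X_area))
  p_urban <- expit(fit_eta_draws(fit, rural = FALSE, X_area = X_area))
  theta <- sweep(p_rural, 2, 1 - q, `*`) + sweep(p_urban, 2, q, `*`)
  posterior_field(theta, fit$areas, level = fit$level)
}

#' Aggregate a cluster fit pixel by pixel (cluster/pixel covariates)
#'
#' Per posterior draw,
#' theta_i = sum_{pixels in i} q'_pix expit(alpha_a + gamma 1{pix rural}
#'           + x_pix' beta + u_i),
#' the grid standing in for the unknown population clusters. Pixel urban/rural
#' status comes from the frozen T0 partition; q' weights from the target
#' population at year T.
#'
#' @param fit a `cluster_fit` at admin-2 level.
#' @param partition an `urban_partition`.
#' @param covariate_rasters list of numeric matrices (one per covariate, in
#'   the order of the fit's covariates), or NULL.
#' @param raster_T target-population `pop_raster` at year T (must carry
#'   `admin2` labels).
#' @return a `posterior_field` at admin-2 level.
#' @export
aggregate_pixel_level <- function(fit, partition, covariate_rasters = NULL,
                                  raster_T = NULL) {
  stopifnot(!is.null(raster_T$admin2))
  v <- raster_T$values
  hierarchy <- fit$hierarchy
  M <- length(fit$areas)
  S <- nrow(fit$alpha)
  modes <- variant_modes(fit$spec$variant)
  n_cov <- if (is.null(fit$beta)) 0 else ncol(fit$beta)
  theta <- matrix(NA_real_, S, M)
  for (i in seq_len(M) - 1L) {
    idx <- which(raster_T$admin2 == i & !is.na(v) & v > 0)
    if (!length(idx)) next
    w <- v[idx] / sum(v[idx])
    a1 <- hierarchy$a_of_i[i + 1L] + 1L
    rural <- !partition$urban[idx]
    if (n_cov > 0) {
      Xp <- vapply(covariate_rasters, function(r) r[idx], numeric(length(idx)))
      Xp <- matrix(Xp, nrow = length(idx))
      if (any(is.na(Xp))) {
        stop_prevmapr("covariate nodata on populated pixels in area ",
                      fit$areas[i + 1L], ": ",
                      paste(utils::head(idx[rowSums(is.na(Xp)) > 0], 10),
                            collapse = ", "),
                      class = "prevmapr_validation_error")
      }
    }
    eta <- if (modes["alpha"] == 1L) matrix(fit$alpha[, a1], S, length(idx)) else
      matrix(fit$alpha[, 1], S, length(idx))
    if (modes["gamma"] > 0L) {
      g <- if (modes["gamma"] == 2L) fit$gamma[, a1] else fit$gamma[, 1]
      eta <- eta + outer(g, as.numeric(rural))
    }
    if (n_cov > 0) eta <- eta + fit$beta %*% t(Xp)
    if (!is.null(fit$u)) eta <- eta + fit$u[, i + 1L]
    theta[, i + 1L] <- drop(expit(eta) %*% w)
  }
  posterior_field(theta, fit$areas, level = fit$level)
}
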