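# Spatial structure: adjacency graphs, the scaled ICAR structured effect, the
# BYM2 reparameterization u = sigma * (sqrt(1-phi) e_iid + sqrt(phi) e_icar),
# and penalised-complexity priors for sigma (total sd) and phi (spatial
# proportion).

#' Build a neighbourhood (adjacency) graph
#'
#' Queen contiguity for polygons (two areas are neighbours if their boundaries
#' share at least one point) or a symmetric-completed edge list. Islands are
#' allowed; connected components are labelled.
#'
#' @param x either a list of polygons ([read_geojson_areas()]) or a data.frame
#'   with columns `area_a, area_b` (labels or 1-based indices).
#' @param labels optional area labels; for an edge list, supplying `labels`
#'   includes areas with no edges as islands.
#' @param tol coordinate tolerance for shared-boundary detection.
#' @return an `adjacency_graph`: list with `n`, `labels`, `nb` (list of
#'   1-based neighbour indices) and `component` (component label per area).
#' @export
build_adjacency <- function(x, labels = NULL, tol = 1e-9) {
  if (is.data.frame(x) || is.matrix(x)) {
    x <- as.data.frame(x)
    check_columns(x, c("area_a", "area_b"), "edge list")
    labs <- labels %||% sort(unique(c(as.character(x$area_a), as.character(x$area_b))))
    labs <- as.character(labs)
    n <- length(labs)
    ia <- match(as.character(x$area_a), labs)
    ib <- match(as.character(x$area_b), labs)
    if (anyNA(ia) || anyNA(ib)) {
      stop_prevmapr("edge list refers to unknown areas",
                    class = "prevmapr_validation_error")
    }
    nb <- vector("list", n)
    for (k in seq_along(ia)) {
      if (ia[k] == ib[k]) next  # no self-loops
      nb[[ia[k]]] <- union(nb[[ia[k]]], ib[k])
      nb[[ib[k]]] <- union(nb[[ib[k]]], ia[k])
    }
    nb <- lapply(nb, function(v) sort(as.integer(v %||% integer(0))))
  } else {
    polys <- x
    props <- polygon_properties(polys)
    labs <- labels %||% (if (all(is.na(props$admin2))) props$admin1 else props$admin2)
    n <- length(polys)
    verts <- lapply(polys, function(p) {
      v <- do.call(rbind, c(list(close_ring(p$outer)), lapply(p$holes %||% list(), close_ring)))
      unique(round(v / tol) * tol)
    })
    nb <- vector("list", n)
    for (i in seq_len(n)) nb[[i]] <- integer(0)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (polygons_touch(polys[[i]], polys[[j]], verts[[i]], verts[[j]], tol)) {
          nb[[i]] <- c(nb[[i]], j)
          nb[[j]] <- c(nb[[j]], i)
        }
      }
    }
    nb <- lapply(nb, sort)
  }
  structure(
    list(n = length(nb), labels = labs, nb = nb,
         component = graph_components(nb)),
    class = "adjacency_graph"
  )
}

# queen contiguity: shared vertex (within tol) or a vertex on the other's edge
polygons_touch <- function(pa, pb, va, vb, tol) {
  # cheap bounding-box reject
  if (max(va[, 1]) < min(vb[, 1]) - tol || max(vb[, 1]) < min(va[, 1]) - tol ||
      max(va[, 2]) < min(vb[, 2]) - tol || max(vb[, 2]) < min(va[, 2]) - tol) {
    return(FALSE)
  }
  for (k in seq_len(nrow(va))) {
    d <- sqrt((vb[, 1] - va[k, 1])^2 + (vb[, 2] - va[k, 2])^2)
    if (any(d <= 10 * tol)) return(TRUE)
  }
  on_edge <- function(pts, poly) {
    rings <- c(list(poly$outer), poly$holes %||% list())
    for (ring in rings) {
      ring <- close_ring(ring)
      for (s in seq_len(nrow(ring) - 1L)) {
        for (k in seq_len(nrow(pts))) {
          if (point_segment_distance(pts[k, 1], pts[k, 2],
                                     ring[s, 1], ring[s, 2],
                                     ring[s + 1, 1], ring[s + 1, 2]) <= 10 * tol) {
            return(TRUE)
          }
        }
      }
    }
    FALSE
  }
  on_edge(va, pb) || on_edge(vb, pa)
}

graph_components <- function(nb) {
  n <- length(nb)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (u in nb[[v]]) {
        if (is.na(comp[u])) { comp[u] <- cur; queue <- c(queue, u) }
      }
    }
  }
  comp
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("Adjacency graph:", x$n, "areas,",
      sum(lengths(x$nb)) / 2, "edges,",
      max(x$component), "component(s),",
      sum(lengths(x$nb) == 0), "island(s)\n")
  invisible(x)
}

#' Scaled ICAR structure
#'
#' Builds the intrinsic CAR precision (D - A) with a sum-to-zero constraint per
#' connected component, and the per-component scaling factor such that the
#' geometric mean of the marginal variances of the constrained generalized
#' inverse equals 1. Island (singleton) areas carry no structured effect; by
#' convention their structured marginal variance is set to 1 so the BYM2
#' effect reduces to a pure unstructured effect with full standard deviation.
#'
#' @param graph an `adjacency_graph`.
#' @return a `scaled_icar`: list with the `graph`, `scale` (per component),
#'   `V` (dense scaled structured covariance, singleton diagonal = 1),
#'   `eigen` (eigendecomposition of `V` used for simulation and the phi
#'   prior), `marginal_var` and `singleton` flags.
#' @export
scaled_icar <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  n <- graph$n
  if (n == 0) stop_prevmapr("empty graph", class = "prevmapr_validation_error")
  deg <- lengths(graph$nb)
  singleton <- deg == 0
  V <- matrix(0, n, n)
  scale <- rep(NA_real_, max(graph$component))
  for (k in seq_len(max(graph$component))) {
    idx <- which(graph$component == k)
    m <- length(idx)
    if (m == 1) { V[idx, idx] <- 1; next }
    Q <- matrix(0, m, m)
    for (a in seq_len(m)) {
      Q[a, a] <- deg[idx[a]]
      nbk <- match(graph$nb[[idx[a]]], idx)
      Q[a, nbk] <- -1
    }
    # generalized inverse under the sum-to-zero constraint = Moore-Penrose
    # pseudoinverse (null space is the constant vector on the component)
    eg <- eigen(Q, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-10
    Vk <- eg$vectors[, pos, drop = FALSE] %*%
      (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
    s <- exp(mean(log(diag(Vk))))
    scale[k] <- s
    V[idx, idx] <- Vk / s
  }
  egV <- eigen(V, symmetric = TRUE)
  structure(
    list(graph = graph, scale = scale, V = V, eigen = egV,
         marginal_var = diag(V), singleton = singleton),
    class = "scaled_icar"
  )
}

#' Draw structured effects from the scaled ICAR
#'
#' Hard sum-to-zero per component; singleton areas get independent standard
#' normal draws (their structured slot is a stand-in, see [scaled_icar()]).
#'
#' @param icar a `scaled_icar`.
#' @param n_draws number of draws.
#' @return matrix n_draws x n_areas.
#' @export
sample_scaled_icar <- function(icar, n_draws) {
  eg <- icar$eigen
  lam <- pmax(eg$values, 0)
  z <- matrix(stats::rnorm(n_draws * length(lam)), n_draws)
  z %*% (t(eg$vectors) * sqrt(lam))
}

#' PC prior for a standard deviation
#'
#' Exponential-type penalised-complexity prior on sigma with rate
#' lambda = -log(alpha) / U, so that P(sigma > U) = alpha.
#'
#' @param U threshold (logit-scale sd units), > 0.
#' @param alpha tail probability in (0, 1).
#' @return a `pc_prior_sd` object with `lambda`, a `density` function and a
#'   `log_density` function.
#' @export
pc_prior_sd <- function(U = 1, alpha = 0.01) {
  if (!(U > 0)) stop_prevmapr("U must be > 0", class = "prevmapr_validation_error")
  if (!(alpha > 0 && alpha < 1)) {
    stop_prevmapr("alpha must be in (0,1)", class = "prevmapr_validation_error")
  }
  lambda <- -log(alpha) / U
  structure(
    list(U = U, alpha = alpha, lambda = lambda,
         density = function(s) ifelse(s < 0, 0, lambda * exp(-lambda * s)),
         log_density = function(s) log(lambda) - lambda * s),
    class = "pc_prior_sd"
  )
}

# Kullback-Leibler divergence of the BYM2 effect at mixing parameter phi from
# the base model phi = 0, from the eigenvalues gamma of the scaled structured
# covariance on the constrained subspace.
bym2_kld <- function(phi, gamma) {
  vapply(phi, function(ph) {
    a <- ph * (gamma - 1)
    0.5 * sum(a - log1p(a))
  }, numeric(1))
}

constrained_struct_eigenvalues <- function(icar) {
  # drop one (numerically) zero eigenvalue per non-singleton component;
  # singleton slots have eigenvalue 1 and contribute no divergence
  lam <- sort(icar$eigen$values)
  n_drop <- sum(!is.na(icar$scale))
  if (n_drop > 0) lam <- lam[-seq_len(n_drop)]
  pmax(lam, 1e-12)
}

#' PC prior for the BYM2 mixing parameter phi
#'
#' Numerically tabulated prior on phi in (0,1) built from the distance
#' d(phi) = sqrt(2 KLD(phi)) to the base model phi = 0, with density
#' proportional to exp(-lambda d(phi)) d'(phi). The rate lambda is calibrated
#' so that P(phi > threshold) = alpha. Probability statements putting most
#' mass on the spatial side (as here, alpha = 2/3 above 0.5 by default) lead
#' to a negative rate, i.e. an exponentially tilted distance prior favouring
#' the spatial model; the calibration machinery is identical.
#'
#' @param icar a `scaled_icar` (supplies the graph-specific eigenvalues).
#' @param threshold phi threshold of the calibration statement.
#' @param alpha required upper-tail probability P(phi > threshold).
#' @param n_grid number of tabulation points (default 513).
#' @return a `pc_prior_phi`: `phi` grid, normalized `density`, `lambda`,
#'   `log_density` (spline interpolant) and `tail` (function giving
#'   P(phi > t)).
#' @export
pc_prior_phi <- function(icar, threshold = 0.5, alpha = 2 / 3, n_grid = 513) {
  if (!(alpha > 0 && alpha < 1) || !(threshold > 0 && threshold < 1)) {
    stop_prevmapr("threshold and alpha must be in (0,1)",
                  class = "prevmapr_validation_error")
  }
  gamma <- constrained_struct_eigenvalues(icar)
  if (!length(gamma) || all(abs(gamma - 1) < 1e-10)) {
    stop_prevmapr("no non-singleton component: phi is not identified",
                  class = "prevmapr_validation_error")
  }
  eps <- 1e-7
  phi <- seq(eps, 1 - eps, length.out = n_grid)
  d <- sqrt(2 * bym2_kld(phi, gamma))
  dspl <- stats::splinefun(phi, d, method = "hyman")
  dprime <- dspl(phi, deriv = 1)
  if (any(dprime <= 0)) {
    stop_prevmapr("distance d(phi) not increasing; calibration failed",
                  class = "prevmapr_calibration_error")
  }
  trapz <- function(y) {
    cums <- c(0, cumsum((y[-1] + y[-length(y)]) / 2 * diff(phi)))
    cums
  }
  tail_prob <- function(lambda) {
    f <- exp(-lambda * (d - min(d))) * dprime
    cdf <- trapz(f)
    tot <- cdf[length(cdf)]
    1 - stats::approx(phi, cdf / tot, xout = threshold)$y
  }
  g <- function(lambda) tail_prob(lambda) - alpha
  lo <- -1; hi <- 1
  while (g(lo) < 0 && lo > -1e4) lo <- lo * 2
  while (g(hi) > 0 && hi < 1e4) hi <- hi * 2
  if (g(lo) < 0 || g(hi) > 0) {
    stop_prevmapr(
      "PC prior calibration failed: cannot achieve P(phi > ", threshold,
      ") = ", signif(alpha, 4), " (base-measure tail ",
      signif(tail_prob(0), 4), ")",
      class = "prevmapr_calibration_error"
    )
  }
  lambda <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  dens <- exp(-lambda * (d - min(d))) * dprime
  cdf <- trapz(dens)
  dens <- dens / cdf[length(cdf)]
  cdf <- cdf / cdf[length(cdf)]
  logdens_spl <- stats::splinefun(phi, log(dens))
  cdf_spl <- stats::splinefun(phi, cdf, method = "hyman")
  structure(
    list(phi = phi, density = dens, cdf = cdf, lambda = lambda,
         threshold = threshold, alpha = alpha,
         log_density = function(p) logdens_spl(pmin(pmax(p, eps), 1 - eps)),
         tail = function(t) 1 - cdf_spl(t)),
    class = "pc_prior_phi"
  )
}

#' Assemble a BYM2 random effect from its components
#'
#' u = sigma * (sqrt(1 - phi) * e_unstruct + sqrt(phi) * e_struct); singleton
#' areas (no neighbours) receive a pure unstructured effect sigma * e_unstruct.
#'
#' @param sigma total standard deviation (> 0).
#' @param phi spatial proportion in [0, 1].
#' @param e_unstruct iid standard normal vector.
#' @param e_struct scaled-ICAR vector (same length).
#' @param singleton logical vector flagging island areas (default none).
#' @return numeric vector u.
#' @export
bym2_effect <- function(sigma, phi, e_unstruct, e_struct,
                        singleton = rep(FALSE, length(e_unstruct))) {
  if (phi < 0 || phi > 1) {
    stop_prevmapr("phi must be in [0,1]", class = "prevmapr_validation_error")
  }
  stopifnot(length(e_unstruct) == length(e_struct))
  s <- sqrt(1 - phi) * e_unstruct + sqrt(phi) * e_struct
  s[singleton] <- e_unstruct[singleton]
  sigma * s
}

#' PC prior specification for BYM2 hyperparameters
#'
#' @param U_sigma,alpha_sigma calibration of P(sigma > U_sigma) = alpha_sigma.
#' @param threshold_phi,alpha_phi calibration of P(phi > threshold_phi) =
#'   alpha_phi.
#' @return a `pc_prior_spec` list (defaults: P(sigma > 1) = 0.01,
#'   P(phi > 0.5) = 2/3).
#' @export
pc_prior_spec <- function(U_sigma = 1, alpha_sigma = 0.01,
                          threshold_phi = 0.5, alpha_phi = 2 / 3) {
  if (!(U_sigma > 0) || !(alpha_sigma > 0 && alpha_sigma < 1) ||
      !(threshold_phi > 0 && threshold_phi < 1) ||
      !(alpha_phi > 0 && alpha_phi < 1)) {
    stop_prevmapr("invalid PC prior specification",
                  class = "prevmapr_validation_error")
  }
  structure(list(U_sigma = U_sigma, alpha_sigma = alpha_sigma,
                 threshold_phi = threshold_phi, alpha_phi = alpha_phi),
            class = "pc_prior_spec")
}
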