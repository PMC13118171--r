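# Shared fixtures, all built in code.

# unit square polygon at (x0, y0)
square_poly <- function(x0, y0, side = 1) {
  list(outer = rbind(c(x0, y0), c(x0 + side, y0),
                     c(x0 + side, y0 + side), c(x0, y0 + side)))
}

# tiny 2-admin1 / 4-admin2 hierarchy
toy_hierarchy <- function() {
  area_hierarchy(admin2 = c("d1", "d2", "d3", "d4"),
                 admin1 = c("a1", "a1", "a2", "a2"))
}

# individual-level survey table with explicit values
toy_survey_df <- function() {
  data.frame(
    cluster = c("c1", "c1", "c2", "c2"),
    stratum = c("a1_u", "a1_u", "a2_r", "a2_r"),
    admin1 = c("a1", "a1", "a2", "a2"),
    admin2 = c("d1", "d1", "d3", "d3"),
    urban = c(TRUE, TRUE, FALSE, FALSE),
    y = c(1, 0, 1, 0),
    weight = c(1, 1, 1, 3)
  )
}

# survey dataset from per-cluster specs: list of lists with fields
# admin1, admin2, stratum, urban, y (vector), w (vector)
survey_from_clusters <- function(clusters, hierarchy) {
  rows <- lapply(seq_along(clusters), function(k) {
    cl <- clusters[[k]]
    data.frame(
      cluster = sprintf("c%02d", k),
      stratum = cl$stratum,
      admin1 = cl$admin1,
      admin2 = cl$admin2,
      urban = cl$urban %||% FALSE,
      y = cl$y,
      weight = cl$w %||% rep(1, length(cl$y))
    )
  })
  load_survey(do.call(rbind, rows), hierarchy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# an admin-1 adjacency graph derived from a frame's admin-2 lattice
admin1_graph_of <- function(frame) {
  h <- frame$hierarchy
  g <- frame$graph
  edges <- list()
  for (i in seq_len(g$n)) {
    for (j in g$nb[[i]]) {
      if (j <= i) next
      a <- h$a_of_i[i] + 1L
      b <- h$a_of_i[j] + 1L
      if (a != b) edges[[length(edges) + 1L]] <- c(h$admin1[a], h$admin1[b])
    }
  }
  e <- unique(do.call(rbind, edges))
  build_adjacency(data.frame(area_a = e[, 1], area_b = e[, 2]),
                  labels = h$admin1)
}

# random connected graph: spanning tree + extra random edges
random_graph <- function(n, extra = n %/% 2) {
  perm <- sample(n)
  edges <- cbind(perm[-1], perm[vapply(2:n, function(i) sample(i - 1, 1), 1L)])
  more <- cbind(sample(n, extra, TRUE), sample(n, extra, TRUE))
  more <- more[more[, 1] != more[, 2], , drop = FALSE]
  e <- rbind(edges, more)
  build_adjacency(data.frame(area_a = e[, 1], area_b = e[, 2]),
                  labels = as.character(seq_len(n)))
}

# minimal synthetic cluster_fit for aggregation arithmetic (hand-set draws)
fake_cluster_fit <- function(alpha, gamma, u, hierarchy,
                             variant = "stratified_nested",
                             level = "admin2", beta = NULL, X = NULL) {
  S <- nrow(alpha)
  structure(list(
    alpha = alpha, gamma = gamma,
    beta = beta %||% matrix(0, S, 0),
    u = u,
    sigma = rep(0.3, S), phi = rep(0.5, S), d = rep(0.1, S),
    level = level,
    areas = if (level == "admin2") hierarchy$admin2 else hierarchy$admin1,
    admin1 = hierarchy$admin1, hierarchy = hierarchy,
    spec = cluster_model_spec(variant = variant, X = X),
    diagnostics = list()
  ), class = "cluster_fit")
}
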