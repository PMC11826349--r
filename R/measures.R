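#' @useDynLib siteharm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# All shortest-path measures convert weights to lengths l = 1/w (the usual
# convention for streamline-count connectomes: stronger connections are
# "closer"); absent edges have infinite length.
length_matrix <- function(conn) {
  w <- conn$weights
  l <- ifelse(w > 0, 1 / w, 0)
  l
}

dijkstra_all <- function(conn) .cpp_dijkstra_all(length_matrix(conn))

binary_degree <- function(conn) rowSums(conn$weights > 0)

# Runs `expr` under a fixed RNG seed and restores the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' The twelve network measures, in their canonical order
#'
#' This ordering is fixed: it is the column order of measure tables and the
#' output order of the model's network-measure prediction head.
#' @return character vector of length 12.
#' @export
measure_names <- function() {
  c("modularity", "avg_betweenness", "assortativity", "avg_participation",
    "avg_clustering", "avg_strength", "avg_local_efficiency",
    "global_efficiency", "density", "rich_club", "char_path_length",
    "edge_count")
}

#' Connection density
#'
#' Fraction of possible region pairs carrying at least one streamline:
#' (number of strictly positive upper-triangle entries) / (n(n-1)/2).
#' @param conn a validated [connectome()].
#' @return density in \[0, 1\].
#' @export
net_density <- function(conn) {
  stopifnot(is_connectome(conn))
  n <- conn$n
  if (n < 2) stop("density needs at least 2 nodes", call. = FALSE)
  sum(conn$weights[upper.tri(conn$weights)] > 0) / (n * (n - 1) / 2)
}

#' Average node strength
#'
#' Node strength is the total streamline count incident to a region (row sum
#' of the weight matrix); the measure is its mean over nodes.
#' @inheritParams net_density
#' @export
avg_strength <- function(conn) {
  stopifnot(is_connectome(conn))
  mean(rowSums(conn$weights))
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse weighted shortest-path
#' distance (lengths 1/w on weights normalized by the matrix maximum, so the
#' result lies in \[0, 1\]); disconnected pairs contribute 0. Captures the
#' capacity for parallel information transfer across the whole network.
#' @inheritParams net_density
#' @export
global_efficiency <- function(conn) {
  stopifnot(is_connectome(conn))
  n <- conn$n
  if (n < 2) stop("global efficiency needs at least 2 nodes", call. = FALSE)
  mx <- max(conn$weights)
  if (mx == 0) return(0)
  efficiency_of_matrix(conn$weights / mx)
}

efficiency_of_matrix <- function(w) {
  # mean inverse distance over ordered pairs of a weight matrix
  n <- nrow(w)
  if (n < 2) return(0)
  l <- ifelse(w > 0, 1 / w, 0)
  d <- .cpp_dijkstra_all(l)$dist
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length and path edge count
#'
#' Characteristic path length is the mean weighted shortest-path distance
#' (lengths 1/w) over unordered pairs with a finite distance; the edge count
#' is the mean number of hops along those same geodesics (ties on total
#' length broken toward the fewest hops). Both are `NA` when no finite pair
#' exists.
#' @inheritParams net_density
#' @return named numeric: `char_path_length`, `edge_count`.
#' @export
char_path_and_edge_count <- function(conn) {
  stopifnot(is_connectome(conn))
  dh <- dijkstra_all(conn)
  up <- upper.tri(dh$dist)
  d <- dh$dist[up]
  h <- dh$hops[up]
  ok <- is.finite(d) & d > 0
  if (!any(ok))
    return(c(char_path_length = NA_real_, edge_count = NA_real_))
  c(char_path_length = mean(d[ok]), edge_count = mean(h[ok]))
}

#' Average weighted clustering coefficient (Onnela)
#'
#' Weights are normalized by the matrix maximum; each node's coefficient is
#' the geometric-mean triangle intensity
#' \eqn{C_i = \sum_{jh} (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3} / (k_i(k_i-1))}
#' with binary degree \eqn{k_i}, and 0 where \eqn{k_i < 2}.
#' @inheritParams net_density
#' @export
avg_clustering <- function(conn) {
  stopifnot(is_connectome(conn))
  w <- conn$weights
  mx <- max(w)
  if (mx == 0) return(0)
  wh <- (w / mx)^(1 / 3)
  cyc3 <- diag(wh %*% wh %*% wh)
  k <- binary_degree(conn)
  ci <- ifelse(k >= 2, cyc3 / (k * (k - 1)), 0)
  mean(ci)
}

#' Average local efficiency
#'
#' For each node, the efficiency (mean inverse weighted shortest-path
#' distance, weights normalized by the whole-matrix maximum) of the
#' subnetwork induced on its neighbors; 0 for nodes with fewer than two
#' neighbors. Reflects fault tolerance of local circuits.
#' @inheritParams net_density
#' @export
avg_local_efficiency <- function(conn) {
  stopifnot(is_connectome(conn))
  mx <- max(conn$weights)
  if (mx == 0) return(0)
  w <- conn$weights / mx
  eloc <- vapply(seq_len(conn$n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    efficiency_of_matrix(w[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(eloc)
}

modularity_value <- function(w, membership, gamma = 1) {
  m2 <- sum(w)
  if (m2 == 0) return(NA_real_)
  s <- rowSums(w)
  q <- 0
  for (com in unique(membership)) {
    idx <- membership == com
    q <- q + sum(w[idx, idx]) / m2 - gamma * (sum(s[idx]) / m2)^2
  }
  q
}

#' Louvain modularity
#'
#' Community structure by the Louvain algorithm on the weighted graph,
#' best of `n_restarts` seeded runs; returns the winning partition and its
#' modularity \eqn{Q} (weighted generalization, resolution `gamma`).
#' Deterministic given `seed`; the caller's RNG state is untouched.
#' @inheritParams net_density
#' @param gamma resolution parameter (1 = standard modularity).
#' @param n_restarts number of independent Louvain restarts.
#' @param seed integer seed controlling the restarts.
#' @return list with `partition` (list: `assignment` integer vector,
#'   `n_communities`) and `modularity`; both `NA`/`NULL` on an empty graph.
#' @export
modularity_louvain <- function(conn, gamma = 1, n_restarts = 10, seed = 1) {
  stopifnot(is_connectome(conn))
  w <- conn$weights
  if (sum(w) == 0)
    return(list(partition = NULL, modularity = NA_real_))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best_q <- -Inf
  best_mem <- NULL
  for (r in seq_len(n_restarts)) {
    mem <- with_seed(seed + r - 1, {
      cl <- igraph::cluster_louvain(g, resolution = gamma)
      as.integer(igraph::membership(cl))
    })
    q <- modularity_value(w, mem, gamma)
    if (q > best_q) {
      best_q <- q
      best_mem <- mem
    }
  }
  list(partition = list(assignment = best_mem,
                        n_communities = length(unique(best_mem))),
       modularity = best_q)
}

#' Average participation coefficient
#'
#' \eqn{P_i = 1 - \sum_c (s_{i,c}/s_i)^2} with strengths \eqn{s}: the
#' diversity of a node's connections across communities; 0 for isolated
#' nodes and for nodes connecting into a single community.
#' @inheritParams net_density
#' @param partition a partition as returned by [modularity_louvain()].
#' @export
avg_participation <- function(conn, partition) {
  stopifnot(is_connectome(conn))
  w <- conn$weights
  n <- conn$n
  if (is.null(partition)) return(0)
  mem <- partition$assignment
  stopifnot(length(mem) == n)
  s <- rowSums(w)
  coms <- sort(unique(mem))
  # strength of node i into each community
  sic <- vapply(coms, function(cm) rowSums(w[, mem == cm, drop = FALSE]),
                numeric(n))
  p <- ifelse(s > 0, 1 - rowSums((sic / pmax(s, .Machine$double.xmin))^2), 0)
  mean(p)
}

#' Average weighted betweenness centrality
#'
#' Brandes betweenness on lengths 1/w with exact fractional counting of
#' tied geodesics; raw (unnormalized) counts, averaged over nodes.
#' @inheritParams net_density
#' @export
avg_betweenness <- function(conn) {
  stopifnot(is_connectome(conn))
  mean(.cpp_betweenness_w(length_matrix(conn), 1e-10))
}

#' Degree assortativity
#'
#' Pearson correlation of the binary degrees at the two endpoints of every
#' edge (each edge counted in both orientations). `NA` when the endpoint
#' degrees have zero variance (e.g. any regular graph).
#' @inheritParams net_density
#' @export
assortativity_binary <- function(conn) {
  stopifnot(is_connectome(conn))
  w <- conn$weights
  k <- binary_degree(conn)
  idx <- which(w > 0, arr.ind = TRUE)  # both orientations
  if (nrow(idx) == 0) return(NA_real_)
  x <- k[idx[, 1]]
  y <- k[idx[, 2]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Weighted rich-club coefficient
#'
#' For each degree level k, the subgraph over nodes of binary degree > k has
#' some number of edges E_k and total weight W_k; the coefficient is
#' \eqn{\phi^w(k) = W_k / \sum \text{(the } E_k \text{ largest weights in the
#' whole network)}}. Levels with no edges are undefined. The scalar summary
#' reduces the curve by its mean (default), its value at the largest defined
#' k, or at a fixed k.
#' @inheritParams net_density
#' @param reduction `"mean"` (default), `"max_k"` or `"fixed_k"`.
#' @param k degree level used when `reduction = "fixed_k"`.
#' @return scalar coefficient, or `NA` when no level is defined; the full
#'   curve is attached as attribute `"curve"`.
#' @export
rich_club <- function(conn, reduction = c("mean", "max_k", "fixed_k"),
                      k = NULL) {
  stopifnot(is_connectome(conn))
  reduction <- match.arg(reduction)
  w <- conn$weights
  deg <- binary_degree(conn)
  kmax <- max(deg)
  if (kmax < 1) return(structure(NA_real_, curve = numeric(0)))
  wrank <- sort(w[upper.tri(w)][w[upper.tri(w)] > 0], decreasing = TRUE)
  phi <- rep(NA_real_, kmax)
  for (kk in seq_len(kmax)) {
    keep <- deg > kk
    if (sum(keep) < 2) next
    sub <- w[keep, keep, drop = FALSE]
    ek <- sum(sub[upper.tri(sub)] > 0)
    if (ek == 0) next
    wk <- sum(sub[upper.tri(sub)])
    phi[kk] <- wk / sum(wrank[seq_len(ek)])
  }
  names(phi) <- seq_len(kmax)
  defined <- which(!is.na(phi))
  val <- if (!length(defined)) {
    NA_real_
  } else if (reduction == "mean") {
    mean(phi[defined])
  } else if (reduction == "max_k") {
    phi[[max(defined)]]
  } else {
    if (is.null(k)) stop("`k` required for reduction = 'fixed_k'", call. = FALSE)
    if (k > length(phi) || is.na(phi[k])) NA_real_ else phi[[k]]
  }
  structure(val, curve = phi)
}

#' Compute all twelve network measures
#'
#' Assembles the full measure vector in the canonical [measure_names()]
#' order. The Louvain partition behind `modularity` is reused for the
#' participation coefficient. Undefined measures (disconnected or degenerate
#' graphs) come back as `NA` rather than raising. Deterministic given `seed`.
#' @param conn a validated, thresholded [connectome()].
#' @param gamma Louvain resolution.
#' @param seed seed for the Louvain restarts.
#' @param rich_club_reduction passed to [rich_club()].
#' @return named numeric vector of length 12.
#' @export
all_measures <- function(conn, gamma = 1, seed = 1,
                         rich_club_reduction = "mean") {
  stopifnot(is_connectome(conn))
  ml <- modularity_louvain(conn, gamma = gamma, seed = seed)
  cpl <- char_path_and_edge_count(conn)
  out <- c(
    modularity = ml$modularity,
    avg_betweenness = avg_betweenness(conn),
    assortativity = assortativity_binary(conn),
    avg_participation = avg_participation(conn, ml$partition),
    avg_clustering = avg_clustering(conn),
    avg_strength = avg_strength(conn),
    avg_local_efficiency = avg_local_efficiency(conn),
    global_efficiency = global_efficiency(conn),
    density = net_density(conn),
    rich_club = as.numeric(rich_club(conn, reduction = rich_club_reduction)),
    char_path_length = unname(cpl["char_path_length"]),
    edge_count = unname(cpl["edge_count"]))
  out[measure_names()]
}

#' Network measures for every subject of a cohort
#'
#' @param x a [cohort()].
#' @param threshold apply [threshold_connectome()] first (default `TRUE`).
#' @param total_streamlines,fraction threshold parameters.
#' @inheritParams all_measures
#' @return data.frame: `subject_id`, `site`, then the 12 measure columns in
#'   canonical order; undefined values are `NA`.
#' @export
measures_table <- function(x, threshold = TRUE, total_streamlines = 1e7,
                           fraction = 1e-7, gamma = 1, seed = 1,
                           rich_club_reduction = "mean") {
  stopifnot(inherits(x, "cohort"))
  rows <- lapply(x$records, function(r) {
    conn <- r$connectome
    if (threshold)
      conn <- threshold_connectome(conn, total_streamlines, fraction)
    m <- all_measures(conn, gamma = gamma, seed = seed,
                      rich_club_reduction = rich_club_reduction)
    cbind(data.frame(subject_id = r$subject_id, site = r$site,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(m)))
  })
  do.call(rbind, rows)
}

#' Write a measures table as TSV (undefined values as NA)
#' @param tab data.frame from [measures_table()].
#' @param path output path.
#' @export
write_measures_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}
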