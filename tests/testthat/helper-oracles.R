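# Brute-force oracles for small graphs: exhaustive path enumeration and
# triangle enumeration, independent of the package's Dijkstra/Brandes code.

conn_from <- function(m) connectome(m)

# all simple paths between a and b as lists of node indices
enumerate_paths <- function(w, a, b) {
  n <- nrow(w)
  out <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == b) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (w[u, v] > 0 && !(v %in% path)) walk(c(path, v))
    }
  }
  walk(a)
  out
}

path_length <- function(w, path) {
  if (length(path) < 2) return(0)
  sum(1 / w[cbind(path[-length(path)], path[-1])])
}

# shortest distance, min hops among (near-)tied geodesics, and the tied set
oracle_shortest <- function(w, a, b, tol = 1e-9) {
  paths <- enumerate_paths(w, a, b)
  if (!length(paths)) return(list(dist = Inf, hops = NA, tied = list()))
  lens <- vapply(paths, function(p) path_length(w, p), numeric(1))
  dmin <- min(lens)
  tied <- paths[lens <= dmin * (1 + tol) + tol]
  list(dist = dmin, hops = min(lengths(tied)) - 1, tied = tied)
}

oracle_all_pairs <- function(w, tol = 1e-9) {
  n <- nrow(w)
  dist <- matrix(0, n, n); hops <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    sp <- oracle_shortest(w, a, b, tol)
    dist[a, b] <- sp$dist
    hops[a, b] <- sp$hops
  }
  list(dist = dist, hops = hops)
}

oracle_global_efficiency <- function(w) {
  mx <- max(w)
  if (mx == 0) return(0)
  d <- oracle_all_pairs(w / mx)$dist
  inv <- 1 / d; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
  n <- nrow(w)
  sum(inv) / (n * (n - 1))
}

oracle_char_path <- function(w) {
  ap <- oracle_all_pairs(w)
  up <- upper.tri(ap$dist)
  d <- ap$dist[up]; h <- ap$hops[up]
  ok <- is.finite(d) & d > 0
  if (!any(ok)) return(c(NA_real_, NA_real_))
  c(mean(d[ok]), mean(h[ok]))
}

# fractional betweenness by enumerating tied geodesics
oracle_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  bc <- numeric(n)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    sp <- oracle_shortest(w, a, b, tol)
    if (!length(sp$tied)) next
    for (p in sp$tied) {
      inner <- setdiff(p, c(a, b))
      bc[inner] <- bc[inner] + 1 / length(sp$tied)
    }
  }
  bc
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(0)
  wh <- w / mx
  k <- rowSums(w > 0)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
    }
    ci[i] <- acc / (k[i] * (k[i] - 1))
  }
  mean(ci)
}

oracle_local_efficiency <- function(w) {
  mx <- max(w)
  if (mx == 0) return(0)
  wn <- w / mx
  n <- nrow(w)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(wn[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- wn[nb, nb, drop = FALSE]
    d <- oracle_all_pairs(sub)$dist
    inv <- 1 / d; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
    sum(inv) / (length(nb) * (length(nb) - 1))
  }, numeric(1)))
}

oracle_assortativity <- function(w) {
  k <- rowSums(w > 0)
  idx <- which(w > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(NA_real_)
  x <- k[idx[, 1]]; y <- k[idx[, 2]]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

# maximum-cardinality bipartite matching size by exhaustive recursion
oracle_max_matching <- function(adj) {
  na <- nrow(adj)
  best <- 0
  rec <- function(i, used_b, count) {
    if (count + (na - i + 1) <= best) return(invisible())
    if (i > na) {
      best <<- max(best, count)
      return(invisible())
    }
    rec(i + 1, used_b, count)  # leave i unmatched
    for (j in which(adj[i, ])) {
      if (!used_b[j]) {
        used_b[j] <- TRUE
        rec(i + 1, used_b, count + 1)
        used_b[j] <- FALSE
      }
    }
  }
  rec(1, rep(FALSE, ncol(adj)), 0)
  best
}

# random symmetric integer-weight graph
random_graph <- function(n, p = 0.5, wmax = 3) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  vals <- ifelse(runif(sum(up)) < p, sample.int(wmax, sum(up), replace = TRUE),
                 0)
  w[up] <- vals
  w + t(w)
}
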