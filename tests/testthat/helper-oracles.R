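# Independent brute-force oracles for the graph-centrality contract and
# small shared fixtures. Everything here is deliberately written by a
# different route than the package implementation (Floyd-Warshall instead
# of igraph distances, explicit path enumeration instead of Brandes,
# power iteration instead of eigen, edge counting instead of degree sums).

ext_fixture <- function(f) {
  path <- system.file("extdata", f, package = "qamskit")
  if (!nzchar(path)) path <- file.path("..", "..", "inst", "extdata", f)
  path
}

# 14 x 4 batch-content matrix from the reference content table (ESM column)
gall_content_matrix <- function() {
  cont <- utils::read.csv(ext_fixture("gall_contents.csv"))
  ids <- paste0("S", 1:14)
  m <- sapply(c("GA", "TEGG", "EA", "PEGG"), function(an) {
    d <- cont[cont$analyte == an, ]
    d$w_esm_pct[match(ids, d$batch_id)]
  })
  rownames(m) <- ids
  m
}

gall_curves <- function() {
  tab <- utils::read.csv(ext_fixture("gall_calibration.csv"))
  curves <- lapply(seq_len(nrow(tab)), function(i)
    calibration_curve(tab$analyte[i], tab$slope[i], tab$intercept[i],
                      tab$r2[i], tab$range_low[i], tab$range_high[i], 6L))
  names(curves) <- tab$analyte
  curves
}

oracle_adjacency <- function(net) {
  n <- length(net$nodes)
  A <- matrix(FALSE, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges))
    for (i in seq_len(nrow(net$edges))) {
      A[net$edges[i, 1], net$edges[i, 2]] <- TRUE
      A[net$edges[i, 2], net$edges[i, 1]] <- TRUE
    }
  A
}

oracle_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# all shortest paths between s and t by exhaustive simple-path enumeration
oracle_shortest_paths <- function(A, s, t) {
  n <- nrow(A)
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (u in which(A[v, ]))
      if (!(u %in% path)) walk(c(path, u))
  }
  walk(s)
  if (!length(paths)) return(list())
  lens <- vapply(paths, length, integer(1))
  paths[lens == min(lens)]
}

oracle_centralities <- function(net) {
  A <- oracle_adjacency(net)
  n <- nrow(A)
  deg <- rowSums(A)
  d <- oracle_distances(A)
  cc <- bc <- lac <- nc <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(d[v, ]) & seq_len(n) != v)
    cc[v] <- if (length(reach)) length(reach) / sum(d[v, reach]) else 0
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(d[s, t])) next
    sp <- oracle_shortest_paths(A, s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(sp, function(p) v %in% p, logical(1)))
      bc[v] <- bc[v] + through / length(sp)
    }
  }
  if (n == 1) {
    ec <- 1
  } else {
    # shifted power iteration (A + nI keeps the eigenvectors but makes the
    # principal eigenvalue strictly dominant, so bipartite graphs converge)
    x <- rep(1, n)
    for (i in 1:5000) {
      x_new <- as.numeric(A %*% x) + n * x
      x <- x_new / sqrt(sum(x_new^2))
    }
    ec <- abs(x)
  }
  for (v in seq_len(n)) {
    nb <- which(A[v, ])
    if (!length(nb)) next
    # edges inside the induced neighbor subgraph, counted pairwise
    e_in <- 0
    if (length(nb) > 1)
      for (i in seq_along(nb)) for (j in seq_along(nb))
        if (i < j && A[nb[i], nb[j]]) e_in <- e_in + 1
    lac[v] <- 2 * e_in / length(nb)
    for (u in nb) {
      den <- min(deg[v] - 1, deg[u] - 1)
      if (den <= 0) next
      z <- 0
      for (w in seq_len(n)) if (A[v, w] && A[u, w]) z <- z + 1
      nc[v] <- nc[v] + z / den
    }
  }
  data.frame(node = net$nodes, DC = as.integer(deg), CC = cc, BC = bc,
             EC = ec, LAC = lac, NC = nc,
             stringsAsFactors = FALSE, row.names = NULL)
}

# simulation config with 3-sd group separation on 2 of 4 variables
# (TEGG, PEGG), 14 batches in two groups of 7, no outliers; the design of
# the discriminant-analysis examples
planted_config <- function(seed, noise_cv = 0.01) {
  sim_config(
    seed = seed,
    noise_cv = noise_cv,
    batches = 14,
    group_means = rbind(
      g1 = c(GA = 4.0, TEGG = 4.5, EA = 0.60, PEGG = 2.60),
      g2 = c(GA = 4.0, TEGG = 5.7, EA = 0.60, PEGG = 3.35)),
    group_sizes = c(7, 7),
    group_sd = c(GA = 0.30, TEGG = 0.40, EA = 0.06, PEGG = 0.25),
    n_outliers = 0)
}

# recovery-world config: every analyte separated by 3 within-group sds
planted_config_full <- function(seed, noise_cv = 0.01) {
  sim_config(
    seed = seed,
    noise_cv = noise_cv,
    batches = 14,
    group_means = rbind(
      g1 = c(GA = 3.6, TEGG = 4.5, EA = 0.53, PEGG = 2.60),
      g2 = c(GA = 4.5, TEGG = 5.7, EA = 0.71, PEGG = 3.35)),
    group_sizes = c(7, 7),
    group_sd = c(GA = 0.30, TEGG = 0.40, EA = 0.06, PEGG = 0.25),
    n_outliers = 0)
}

oracle_connected <- function(net) {
  A <- oracle_adjacency(net)
  all(is.finite(oracle_distances(A)))
}

# agreement of two binary labelings up to label swap
labels_agree <- function(a, b) {
  a <- as.integer(as.factor(a))
  b <- as.integer(as.factor(b))
  all(a == b) || all(a == 3L - b)
}
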