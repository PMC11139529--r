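# PPI target screening: target-set intersection, six node-centrality
# measures with median-threshold screening, and a hypergeometric
# over-representation test.
#
# Centrality contract (CytoNCA-style):
#   DC  degree
#   CC  (n_comp - 1) / sum of shortest-path distances within the component
#   BC  shortest-path betweenness, unnormalized, each unordered pair once
#   EC  principal adjacency eigenvector, unit Euclidean norm, entries >= 0
#   LAC mean degree of v's neighbors within the subgraph induced by N(v)
#   NC  sum over neighbors u of ECC(v,u) = z(v,u) / min(d_v - 1, d_u - 1),
#       where z is the number of triangles on edge (v,u); ECC = 0 when the
#       denominator is 0.

#' Normalized target set
#'
#' @param ids Character vector of gene/target symbols.
#' @param label Optional label.
#' @return List of class `target_set` with unique, upper-cased `ids`.
#' @export
target_set <- function(ids, label = "") {
  ids <- unique(toupper(trimws(as.character(ids))))
  ids <- ids[nzchar(ids)]
  structure(list(label = label, ids = ids), class = "target_set")
}

#' Intersect two target sets
#'
#' @param a,b `target_set`s (or bare character vectors).
#' @return `target_set` of the shared symbols, labels concatenated.
#' @export
intersect_targets <- function(a, b) {
  if (!inherits(a, "target_set")) a <- target_set(a)
  if (!inherits(b, "target_set")) b <- target_set(b)
  target_set(intersect(a$ids, b$ids),
             label = paste(a$label, b$label, sep = " & "))
}

#' Build an undirected interaction network
#'
#' Self-loops and duplicate edges are dropped; isolated nodes may be added
#' through `nodes`.
#'
#' @param edges Two-column matrix or data.frame of symbol pairs.
#' @param nodes Optional extra node symbols.
#' @return List of class `interaction_network` with `nodes` (character)
#'   and `edges` (two-column character matrix, lexicographically ordered
#'   within each row, unique).
#' @export
interaction_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edge list must have two columns")
  mode(edges) <- "character"
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE] # no self-loops
  if (nrow(edges)) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1]
    edges <- unique(edges)
  }
  nodes <- sort(unique(c(as.vector(edges), as.character(nodes))))
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_network")
}

#' Read a whitespace-separated edge-list file
#'
#' @param path File with two symbols per line.
#' @return `interaction_network`.
#' @export
read_edgelist <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  interaction_network(tab[, 1:2])
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = net$nodes)
}

#' Mean node degree
#'
#' @param net `interaction_network`.
#' @return `2 |E| / |V|`.
#' @export
mean_degree <- function(net) {
  if (!length(net$nodes)) stop("empty graph")
  2 * nrow(net$edges) / length(net$nodes)
}

#' Six node centralities
#'
#' Degree (DC), closeness (CC, per connected component), betweenness (BC),
#' eigenvector (EC, unit Euclidean norm), local average connectivity (LAC)
#' and edge-clustering-based network centrality (NC). See the file header
#' for the exact definitions.
#'
#' @param net `interaction_network` with at least one node.
#' @return data.frame with one row per node and columns
#'   `node, DC, CC, BC, EC, LAC, NC`.
#' @export
centralities <- function(net) {
  n <- length(net$nodes)
  if (!n) stop("empty graph")
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  # adjacency as a logical matrix; graphs here are small (tens of nodes)
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  d <- igraph::distances(g)
  # closeness within each component
  comp <- igraph::components(g)$membership
  cc <- vapply(seq_len(n), function(v) {
    same <- which(comp == comp[v])
    if (length(same) < 2) return(0)
    (length(same) - 1) / sum(d[v, same])
  }, numeric(1))
  bc <- igraph::betweenness(g, directed = FALSE)
  # principal eigenvector of the adjacency matrix, non-negative, ||.||2 = 1
  if (n == 1L) {
    ec <- 1
  } else {
    es <- eigen(A * 1, symmetric = TRUE)
    v1 <- es$vectors[, 1]
    if (sum(v1) < 0) v1 <- -v1
    v1[abs(v1) < 1e-12] <- 0
    ec <- abs(v1) / sqrt(sum(v1^2))
  }
  lac <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ])
    if (!length(nb)) return(0)
    sub <- A[nb, nb, drop = FALSE]
    mean(rowSums(sub))
  }, numeric(1))
  nc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ])
    if (!length(nb)) return(0)
    sum(vapply(nb, function(u) {
      den <- min(deg[v] - 1, deg[u] - 1)
      if (den <= 0) return(0)
      z <- sum(A[v, ] & A[u, ]) # triangles on edge (v,u)
      z / den
    }, numeric(1)))
  }, numeric(1))
  data.frame(node = net$nodes, DC = as.integer(deg), CC = cc, BC = bc,
             EC = ec, LAC = lac, NC = nc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Median-threshold screening of a centrality table
#'
#' A node survives when every centrality measure is greater than or equal
#' to that measure's median across nodes (inclusive thresholding, so e.g.
#' a median betweenness of 0 removes nobody on that measure).
#'
#' @param table Output of [centralities()] (>= 2 rows).
#' @param measures Columns to screen on.
#' @param rounds Number of screening rounds (each round recomputes medians
#'   on the survivors); default 1.
#' @return List with `survivors` (node names), `thresholds` (per-measure
#'   medians of the final round), and `rounds`.
#' @export
median_screen <- function(table,
                          measures = c("DC", "CC", "BC", "EC", "LAC", "NC"),
                          rounds = 1) {
  stopifnot(nrow(table) >= 2, all(measures %in% names(table)))
  current <- table
  thr <- NULL
  for (r in seq_len(rounds)) {
    thr <- vapply(measures, function(m) stats::median(current[[m]]),
                  numeric(1))
    keep <- rep(TRUE, nrow(current))
    for (m in measures) keep <- keep & current[[m]] >= thr[[m]]
    current <- current[keep, , drop = FALSE]
    if (!nrow(current)) break
  }
  list(survivors = current$node, thresholds = thr, rounds = rounds)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value of the overlap between a query set and
#' each gene set, restricted to a common universe, with Benjamini-Hochberg
#' adjustment across sets.
#'
#' @param query `target_set` or character vector (subset of `universe`).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of all assayable symbols.
#' @return data.frame `set, set_size, overlap, p, p_adj`, ordered by `p`.
#' @export
ora_enrichment <- function(query, gene_sets, universe) {
  if (inherits(query, "target_set")) query <- query$ids
  query <- unique(toupper(query))
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe")
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(gene_sets), function(nm) {
    K_set <- intersect(unique(toupper(gene_sets[[nm]])), universe)
    if (!length(K_set)) stop("gene set has no overlap with universe: ", nm)
    k <- length(intersect(query, K_set))
    K <- length(K_set)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}

#' Read a GMT-style gene-set file
#'
#' Each line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t"), function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  sets
}
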