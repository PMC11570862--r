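# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the package's own code paths.

# minimal atom data.frame builder
mk_atoms <- function(coords, name = "CA", element = "C", res_name = "ALA",
                     chain = "A", res_seq = NULL, is_hetero = FALSE) {
  coords <- matrix(coords, ncol = 3, byrow = TRUE)
  n <- nrow(coords)
  if (is.null(res_seq)) res_seq <- seq_len(n)
  data.frame(serial = seq_len(n), name = rep_len(name, n), altloc = "",
             res_name = rep_len(res_name, n), chain = chain,
             res_seq = rep_len(res_seq, n), icode = "",
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             occupancy = 1, element = rep_len(element, n),
             is_hetero = rep_len(is_hetero, n), stringsAsFactors = FALSE)
}

mk_structure <- function(atoms, id = "tst") alloscan:::new_structure(id, atoms)

# brute-force minimum pairwise distance (double loop, no linear algebra)
oracle_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

# BFS hop distances from one node over an edge list (1-based indices)
oracle_bfs <- function(n, edges, from) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  dist <- rep(NA_integer_, n); dist[from] <- 0L
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (is.na(dist[w])) {
      dist[w] <- dist[v] + 1L; queue <- c(queue, w)
    }
  }
  dist
}

oracle_eccentricity <- function(n, edges, from) {
  d <- oracle_bfs(n, edges, from)
  max(d[!is.na(d)])
}

# exhaustive betweenness: enumerate all shortest paths by DFS over the
# BFS predecessor structure; normalised by (n-1)(n-2), ordered pairs
oracle_betweenness <- function(n, edges, node) {
  if (n < 3) return(0)
  count_paths <- function(s, t) {
    ds <- oracle_bfs(n, edges, s)
    if (is.na(ds[t])) return(c(total = 0, through = 0))
    adj <- vector("list", n)
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    total <- 0; through <- 0
    walk <- function(v, path) {
      if (v == t) {
        total <<- total + 1
        if (node %in% setdiff(path, c(s, t))) through <<- through + 1
        return(invisible())
      }
      for (w in adj[[v]]) if (!is.na(ds[w]) && ds[w] == ds[v] + 1)
        walk(w, c(path, w))
    }
    walk(s, s)
    c(total = total, through = through)
  }
  b <- 0
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || s == node || t == node) next
    ct <- count_paths(s, t)
    if (ct[["total"]] > 0) b <- b + ct[["through"]] / ct[["total"]]
  }
  unname(b) / ((n - 1) * (n - 2))
}

# wrap an arbitrary edge list as the package's contact-graph structure
mk_contact_graph <- function(n, edges, ids = sprintf("n%02d", seq_len(n))) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(as.matrix(edges[, 1:2])))
  list(nodes = ids,
       edges = data.frame(i = edges[, 1], j = edges[, 2],
                          distance = rep(1, nrow(edges))),
       graph = g)
}

random_graph <- function(seed) {
  set.seed(seed)
  n <- sample(4:12, 1)
  p <- runif(1, 0.2, 0.6)
  pairs <- t(combn(n, 2))
  edges <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  list(n = n, edges = edges)
}

# tiny PDB text fixtures built in code
pdb_line <- function(record, serial, name, res_name, chain, res_seq, x, y, z,
                     occ = 1, element = substr(name, 1, 1), altloc = " ") {
  nm <- if (nchar(element) == 1) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, res_name, chain, res_seq, x, y, z,
          occ, 0, element)
}

write_tiny_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}
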