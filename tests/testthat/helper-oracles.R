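# Independent brute-force oracles. Everything here works from first
# principles (set arithmetic, exhaustive enumeration, double loops) and
# shares no code with the package internals it checks.

oracle_neighbors <- function(net, id) {
  e <- net$edges
  sort(unique(c(e$drug_b[e$drug_a == id], e$drug_a[e$drug_b == id])))
}

oracle_jaccard <- function(x, y) {
  u <- union(x, y)
  if (!length(u)) 0 else length(intersect(x, y)) / length(u)
}

oracle_neighbor_jaccard <- function(net, i, j) {
  oracle_jaccard(setdiff(oracle_neighbors(net, i), c(i, j)),
                 setdiff(oracle_neighbors(net, j), c(i, j)))
}

oracle_top2_mean <- function(v) {
  if (!length(v)) return(0)
  v <- sort(v, decreasing = TRUE)
  mean(v[seq_len(min(2, length(v)))])
}

oracle_jaccard_max2_mean <- function(net, i, j) {
  si <- oracle_top2_mean(vapply(setdiff(oracle_neighbors(net, j), i),
                                function(u) oracle_neighbor_jaccard(net, i, u),
                                numeric(1)))
  sj <- oracle_top2_mean(vapply(setdiff(oracle_neighbors(net, i), j),
                                function(u) oracle_neighbor_jaccard(net, j, u),
                                numeric(1)))
  (si + sj) / 2
}

# All shortest paths between s and t by recursive enumeration over a BFS
# distance map; used for the betweenness oracle on tiny graphs.
oracle_bfs_dist <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) for (w in adj[[v]]) if (d[w] > d[v] + 1) {
      d[w] <- d[v] + 1
      nxt <- c(nxt, w)
    }
    frontier <- unique(nxt)
  }
  d
}

oracle_all_shortest_paths <- function(adj, s, t, d) {
  if (s == t) return(list(s))
  paths <- list()
  for (w in adj[[t]]) {
    if (d[w] == d[t] - 1) {
      for (p in oracle_all_shortest_paths(adj, s, w, d))
        paths[[length(paths) + 1L]] <- c(p, t)
    }
  }
  paths
}

# Normalized betweenness: sum over (s,t) pairs of the fraction of shortest
# paths through v, times 2 / ((n-1)(n-2)).
oracle_betweenness <- function(net) {
  ids <- sort(net$drugs$drug_id)
  n <- length(ids)
  adj <- lapply(ids, function(id) match(oracle_neighbors(net, id), ids))
  btw <- stats::setNames(rep(0, n), ids)
  if (n < 3) return(btw)
  for (s in seq_len(n - 1)) {
    d <- oracle_bfs_dist(adj, s)
    for (t in seq((s + 1), n)) {
      if (!is.finite(d[t])) next
      paths <- oracle_all_shortest_paths(adj, s, t, d)
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner)) {
        tab <- table(inner)
        vi <- as.integer(names(tab))
        btw[vi] <- btw[vi] + as.integer(tab) / length(paths)
      }
    }
  }
  btw * 2 / ((n - 1) * (n - 2))
}

oracle_local_clustering <- function(net, id) {
  nb <- oracle_neighbors(net, id)
  k <- length(nb)
  if (k < 2) return(0)
  keys <- with(net$edges, paste(pmin(drug_a, drug_b), pmax(drug_a, drug_b)))
  links <- 0L
  for (a in seq_len(k - 1)) for (b in seq((a + 1), k))
    if (paste(min(nb[a], nb[b]), max(nb[a], nb[b])) %in% keys)
      links <- links + 1L
  2 * links / (k * (k - 1))
}

# Taxonomy distance by explicit lowest-common-ancestor search over the
# prefix ladder.
oracle_code_distance <- function(c1, c2, prefixes = c(1, 3, 4, 5, 7)) {
  depth <- length(prefixes)
  shared <- 0
  for (k in seq_len(depth)) {
    if (substr(c1, 1, prefixes[k]) == substr(c2, 1, prefixes[k])) shared <- k
    else break
  }
  2 * (depth - shared)
}

oracle_atc_min <- function(codes1, codes2, prefixes = c(1, 3, 4, 5, 7)) {
  best <- Inf
  for (a in codes1) for (b in codes2)
    best <- min(best, oracle_code_distance(a, b, prefixes))
  best
}

oracle_atc_min_prod <- function(net, i, j, d_max, prefixes = c(1, 3, 4, 5, 7)) {
  codes <- stats::setNames(net$drugs$atc_codes, net$drugs$drug_id)
  side <- function(a, b) {
    nb <- setdiff(oracle_neighbors(net, b), a)
    if (!length(nb)) return(d_max)
    min(vapply(nb, function(u) oracle_atc_min(codes[[a]], codes[[u]], prefixes),
               numeric(1)))
  }
  side(i, j) * side(j, i)
}

oracle_str_max_prod <- function(net, i, j) {
  subs <- stats::setNames(net$drugs$substructures, net$drugs$drug_id)
  side <- function(a, b) {
    nb <- setdiff(oracle_neighbors(net, b), a)
    if (!length(nb)) return(0)
    max(vapply(nb, function(u) oracle_jaccard(subs[[a]], subs[[u]]),
               numeric(1)))
  }
  side(i, j) * side(j, i)
}

# AUROC by exhaustive pairwise comparison: (concordant + ties/2) / (n1*n0).
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Operating point by exhaustive threshold sweep over all distinct scores.
oracle_operating_point <- function(scores, labels, target) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  best <- NULL
  for (thr in sort(unique(scores))) {
    pred <- scores >= thr
    fp <- sum(pred & labels == 0)
    if (1 - fp / n0 >= target) {
      best <- list(threshold = thr,
                   tp = sum(pred & labels == 1), fp = fp)
      break  # smallest qualifying threshold (ascending sweep)
    }
  }
  if (is.null(best)) best <- list(threshold = Inf, tp = 0L, fp = 0L)
  best$fn <- n1 - best$tp
  best$tn <- n0 - best$fp
  best$sensitivity <- best$tp / n1
  best
}

oracle_nearest_rank_percentile <- function(x, p) {
  sort(x)[max(1, ceiling(p * length(x)))]
}

oracle_type_counts <- function(net, i, j) {
  counts <- list()
  for (r in seq_len(nrow(net$edges))) {
    e <- net$edges[r, ]
    if (setequal(c(e$drug_a, e$drug_b), c(i, j))) next
    if (e$drug_a %in% c(i, j) || e$drug_b %in% c(i, j)) {
      t <- e$type_label
      counts[[t]] <- (if (is.null(counts[[t]])) 0L else counts[[t]]) + 1L
    }
  }
  unlist(counts)
}
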