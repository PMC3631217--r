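# Pair covariates. Nine covariates in three families:
#   network:   degree_prod, betw_prod, cccnw_max, jackard, jackard_max2_mean
#   taxonomic: atc_min, atc_min_prod
#   intrinsic: str_jackard, str_max_prod
# "0th-order" covariates use only the two drugs' own properties; "1st-order"
# covariates additionally use the properties of their network neighbors.
#
# A key convention used throughout: when a similarity between a candidate
# pair (i, j) is computed, i and j are removed from each other's
# neighborhoods first, so a training edge (i, j) cannot leak into its own
# covariate.

jaccard_sets <- function(x, y) {
  u <- length(union(x, y))
  if (u == 0L) return(0)
  length(intersect(x, y)) / u
}

#' Neighborhood Jaccard similarity of a drug pair ("jackard")
#'
#' `|N'(i) n N'(j)| / |N'(i) u N'(j)|` where `N'(x)` is the interaction
#' neighborhood of `x` with `i` and `j` themselves removed. Returns 0 when
#' both reduced neighborhoods are empty.
#'
#' @param net A `ddi_network`.
#' @param i,j Distinct drug ids in `net`.
#' @return Real in \[0, 1\].
#' @export
neighbor_jaccard <- function(net, i, j) {
  stopifnot(i != j)
  ni <- setdiff(neighbors_of(net, i), c(i, j))
  nj <- setdiff(neighbors_of(net, j), c(i, j))
  jaccard_sets(ni, nj)
}

top2_mean <- function(v) {
  if (!length(v)) return(0)
  if (length(v) == 1L) return(unname(v[1L]))
  m1 <- which.max(v)
  unname((v[m1] + max(v[-m1])) / 2)
}

#' Mean of top-2 neighbor Jaccard similarities ("jackard_max2_mean")
#'
#' For pair `(i, j)`: `s_i` is the mean of the two largest values of
#' `neighbor_jaccard(i, u)` over `u` in `N(j) \ {i}` (the mean of whatever
#' exists when fewer than two neighbors, 0 when none); `s_j` symmetrically;
#' the covariate is `(s_i + s_j) / 2`. This first-order covariate asks
#' whether each drug closely resembles some interaction partner of the
#' other.
#'
#' @inheritParams neighbor_jaccard
#' @return Real in \[0, 1\].
#' @export
jaccard_max2_mean <- function(net, i, j) {
  stopifnot(i != j)
  side <- function(a, b) {
    nb <- setdiff(neighbors_of(net, b), a)
    top2_mean(vapply(nb, function(u) neighbor_jaccard(net, a, u), numeric(1)))
  }
  (side(i, j) + side(j, i)) / 2
}

#' Non-similarity topology covariates of a pair
#'
#' * `degree_prod`: product of the two degrees (popularity);
#' * `betw_prod`: product of normalized shortest-path betweenness
#'   centralities (centrality), normalization `2 / ((n-1)(n-2))`;
#' * `cccnw_max`: the larger of the two local clustering coefficients
#'   (network clustering); nodes with degree < 2 have clustering 0.
#'
#' @inheritParams neighbor_jaccard
#' @return Named numeric vector `degree_prod`, `betw_prod`, `cccnw_max`.
#' @export
topology_covariates <- function(net, i, j) {
  stopifnot(i != j)
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, normalized = TRUE)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  cc[deg < 2] <- 0
  if (!all(c(i, j) %in% names(deg))) stop("unknown drug id")
  c(degree_prod = unname(deg[i] * deg[j]),
    betw_prod = unname(btw[i] * btw[j]),
    cccnw_max = unname(max(cc[i], cc[j])))
}

#' First-order taxonomy covariate ("atc_min_prod")
#'
#' `t_i` is the minimum taxonomy distance from drug `i` to any neighbor of
#' `j` (excluding `i` itself); when `j` has no other neighbors, `t_i` falls
#' back to the maximum possible tree distance, so an empty neighborhood
#' reads as maximally dissimilar. The covariate is `t_i * t_j`.
#'
#' @param net A `ddi_network` whose drugs carry `atc_codes`.
#' @param tax An `atc_taxonomy`.
#' @param i,j Distinct drug ids in `net`.
#' @return Nonnegative real.
#' @export
atc_min_prod <- function(net, tax, i, j) {
  stopifnot(i != j)
  codes <- stats::setNames(net$drugs$atc_codes, net$drugs$drug_id)
  side <- function(a, b) {
    nb <- setdiff(neighbors_of(net, b), a)
    if (!length(nb)) return(atc_max_distance(tax))
    min(vapply(nb, function(u) atc_min_distance(tax, codes[[a]], codes[[u]]),
               numeric(1)))
  }
  side(i, j) * side(j, i)
}

#' Chemical substructure Jaccard (Tanimoto) similarity ("str_jackard")
#'
#' @param s1,s2 Character vectors: the "on" substructure features of each
#'   drug (a binary fingerprint as a feature set).
#' @return Real in \[0, 1\]; 0 when both sets are empty.
#' @export
structural_jaccard <- function(s1, s2) {
  jaccard_sets(as.character(s1), as.character(s2))
}

#' First-order intrinsic covariate ("str_max_prod")
#'
#' `m_i` is the maximum structural Jaccard between drug `i` and any neighbor
#' of `j` (excluding `i`); 0 when `j` has no other neighbors; the covariate
#' is `m_i * m_j`. It is large when each drug is chemically close to some
#' known interaction partner of the other.
#'
#' @inheritParams neighbor_jaccard
#' @return Real in \[0, 1\].
#' @export
str_max_prod <- function(net, i, j) {
  stopifnot(i != j)
  subs <- stats::setNames(net$drugs$substructures, net$drugs$drug_id)
  side <- function(a, b) {
    nb <- setdiff(neighbors_of(net, b), a)
    if (!length(nb)) return(0)
    max(vapply(nb, function(u) structural_jaccard(subs[[a]], subs[[u]]),
               numeric(1)))
  }
  side(i, j) * side(j, i)
}

#' Names of the standard pair covariates
#'
#' @return Character vector of the nine covariate names in canonical order.
#' @export
ppin_covariates <- function() {
  c("degree_prod", "betw_prod", "cccnw_max", "jackard", "jackard_max2_mean",
    "atc_min", "atc_min_prod", "str_jackard", "str_max_prod")
}

# ---- vectorized computation over a pair table ------------------------------

# Precompute everything the per-pair covariate builders need.
covariate_context <- function(net, tax) {
  ids <- drug_ids(net)
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    ia <- match(net$edges$drug_a, ids)
    ib <- match(net$edges$drug_b, ids)
    A[cbind(ia, ib)] <- 1L
    A[cbind(ib, ia)] <- 1L
  }
  deg <- rowSums(A)
  g <- as_igraph(net)
  btw <- igraph::betweenness(g, normalized = TRUE)[ids]
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  cc <- cc[ids]
  cc[deg < 2] <- 0

  # Pairwise neighborhood Jaccard with the endpoint-removal convention:
  # common neighbors of (i,j) never include i or j (no self-loops), so only
  # the union size needs the adjustment  deg_i - A_ij + deg_j - A_ij - common.
  common <- A %*% A
  un <- outer(deg, deg, "+") - 2 * A - common
  J <- ifelse(un > 0, common / un, 0)
  diag(J) <- 0

  # Structural Jaccard matrix from the fingerprint feature sets.
  feats <- sort(unique(unlist(net$drugs$substructures)))
  if (length(feats)) {
    F <- matrix(0L, n, length(feats), dimnames = list(ids, feats))
    for (k in seq_len(n)) F[k, net$drugs$substructures[[k]]] <- 1L
    inter <- F %*% t(F)
    sizes <- rowSums(F)
    unS <- outer(sizes, sizes, "+") - inter
    S <- ifelse(unS > 0, inter / unS, 0)
  } else {
    S <- matrix(0, n, n, dimnames = list(ids, ids))
  }

  D <- if (!is.null(tax)) {
    atc_distance_matrix(tax, stats::setNames(net$drugs$atc_codes, ids))
  } else NULL
  if (!is.null(D) && anyNA(D))
    stop("drug(s) without a resolvable taxonomy code: ",
         paste(utils::head(ids[is.na(diag(D))], 5), collapse = ", "))

  nbrs <- lapply(seq_len(n), function(k) which(A[k, ] > 0L))
  list(ids = ids, A = A, deg = deg, btw = btw, cc = cc,
       J = J, S = S, D = D, d_max = if (is.null(tax)) NA else atc_max_distance(tax),
       nbrs = nbrs)
}

# The covariate registry: each entry maps a covariate name to a builder
# f(ctx, ia, ib) returning one value per pair, where ia/ib are integer drug
# indices. Alternative covariate definitions can be swapped in by passing a
# modified registry to build_covariate_table().
default_covariate_registry <- function() {
  first_order <- function(mat, reduce, empty_value) {
    force(mat); force(reduce); force(empty_value)
    function(ctx, ia, ib) {
      M <- ctx[[mat]]
      side <- function(a, b) {
        nb <- ctx$nbrs[[b]]
        nb <- nb[nb != a]
        if (!length(nb)) {
          if (identical(empty_value, "d_max")) ctx$d_max else empty_value
        } else reduce(M[a, nb])
      }
      vapply(seq_along(ia), function(k) {
        side(ia[k], ib[k]) * side(ib[k], ia[k])
      }, numeric(1))
    }
  }
  list(
    degree_prod = function(ctx, ia, ib) ctx$deg[ia] * ctx$deg[ib],
    betw_prod = function(ctx, ia, ib) ctx$btw[ia] * ctx$btw[ib],
    cccnw_max = function(ctx, ia, ib) pmax(ctx$cc[ia], ctx$cc[ib]),
    jackard = function(ctx, ia, ib) ctx$J[cbind(ia, ib)],
    jackard_max2_mean = function(ctx, ia, ib) {
      vapply(seq_along(ia), function(k) {
        i <- ia[k]; j <- ib[k]
        nj <- ctx$nbrs[[j]]; nj <- nj[nj != i]
        ni <- ctx$nbrs[[i]]; ni <- ni[ni != j]
        (top2_mean(ctx$J[i, nj]) + top2_mean(ctx$J[j, ni])) / 2
      }, numeric(1))
    },
    atc_min = function(ctx, ia, ib) ctx$D[cbind(ia, ib)],
    atc_min_prod = first_order("D", min, "d_max"),
    str_jackard = function(ctx, ia, ib) ctx$S[cbind(ia, ib)],
    str_max_prod = first_order("S", max, 0)
  )
}

#' Build the pair-level covariate table
#'
#' Computes all (or a chosen subset of) pair covariates for a set of
#' unordered drug pairs of a training network, together with the binary
#' response (1 iff the pair is an edge of `net`). Rows are ordered by the
#' canonical pair key (lexicographically sorted endpoints), so the table is
#' deterministic and joins exactly against scores and labels.
#'
#' @param net A `ddi_network`.
#' @param tax An `atc_taxonomy` resolving every drug's `atc_codes`; may be
#'   `NULL` if no taxonomy covariates are requested.
#' @param pairs `"all"` (every unordered pair), `"edges"`, `"nonedges"`, or
#'   a data frame with columns `drug_a`, `drug_b`.
#' @param covariates Covariate names to compute (default all nine).
#' @param registry Covariate registry, a named list of builder functions;
#'   see [ppin_covariates()]. Intended for swapping in alternative covariate
#'   definitions.
#' @return Data frame with columns `drug_a`, `drug_b`, `response`, and one
#'   column per covariate.
#' @export
build_covariate_table <- function(net, tax = NULL,
                                  pairs = "all",
                                  covariates = ppin_covariates(),
                                  registry = default_covariate_registry()) {
  if (is.character(pairs) && length(pairs) == 1L) {
    pairs <- switch(match.arg(pairs, c("all", "edges", "nonedges")),
                    all = {
                      ne <- non_edges(net)
                      ed <- net$edges[, c("drug_a", "drug_b")]
                      rbind(ed, ne)
                    },
                    edges = net$edges[, c("drug_a", "drug_b")],
                    nonedges = non_edges(net))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_a", "drug_b") %in% names(pairs)))
  unknown <- setdiff(unique(c(pairs$drug_a, pairs$drug_b)), drug_ids(net))
  if (length(unknown))
    stop("pair(s) reference drug(s) outside the network: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (any(pairs$drug_a == pairs$drug_b)) stop("self-pairs are not allowed")
  missing_cov <- setdiff(covariates, names(registry))
  if (length(missing_cov))
    stop("covariate(s) not in registry: ", paste(missing_cov, collapse = ", "))

  cp <- canonical_pairs(pairs$drug_a, pairs$drug_b)
  cp <- cp[!duplicated(pair_key(cp$drug_a, cp$drug_b)), , drop = FALSE]
  cp <- cp[order(cp$drug_a, cp$drug_b), , drop = FALSE]
  rownames(cp) <- NULL
  needs_tax <- any(c("atc_min", "atc_min_prod") %in% covariates)
  if (needs_tax && is.null(tax))
    stop("taxonomy covariates requested but no taxonomy supplied")
  ctx <- covariate_context(net, if (needs_tax) tax else NULL)

  out <- cp
  out$response <- as.integer(pair_key(cp$drug_a, cp$drug_b) %in%
                               pair_key(net$edges$drug_a, net$edges$drug_b))
  if (nrow(cp)) {
    ia <- match(cp$drug_a, ctx$ids)
    ib <- match(cp$drug_b, ctx$ids)
    for (cv in covariates) out[[cv]] <- unname(registry[[cv]](ctx, ia, ib))
  } else {
    for (cv in covariates) out[[cv]] <- numeric()
  }
  out
}
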