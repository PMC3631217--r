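# Severity classes, ordered from least to most severe. "unspecified" ranks
# below every named class so that conflict resolution never downgrades a
# named severity.
SEVERITY_LEVELS <- c("unspecified", "minor", "moderate", "major", "contraindicated")

#' Severity classes recognised by ppinet
#'
#' @return Character vector of severity levels in increasing order of
#'   clinical significance, with `"unspecified"` first.
#' @export
ddi_severity_levels <- function() SEVERITY_LEVELS

# Canonical unordered-pair key: lexicographically sorted endpoints joined by
# "|". All joins between covariate tables, scores and labels go through it.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Canonicalize endpoint columns so drug_a < drug_b lexicographically.
canonical_pairs <- function(a, b) {
  swap <- a > b
  data.frame(drug_a = ifelse(swap, b, a),
             drug_b = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

#' Build a drug-drug interaction network
#'
#' Constructs an undirected, severity-labelled DDI network from interaction
#' records and a per-drug attribute table. Nodes are exactly the drugs of the
#' attribute table; duplicate records of the same unordered pair collapse to
#' a single edge. When duplicated records disagree on severity, the most
#' severe class is kept (contraindicated > major > moderate > minor >
#' unspecified) and a warning is emitted.
#'
#' @param edge_records Data frame with columns `drug_a`, `drug_b` and
#'   optionally `severity` (one of [ddi_severity_levels()]) and `type_label`.
#' @param attributes Data frame with column `drug_id` and optionally
#'   `atc_codes` and `substructures`. These may be character columns with
#'   semicolon-separated entries, or list columns of character vectors.
#' @param snapshot_label Free-text label for the snapshot (e.g. `"2009"`).
#' @return An object of class `ddi_network`: a list with elements `drugs`
#'   (data frame with `drug_id` plus list columns `atc_codes`,
#'   `substructures`), `edges` (data frame `drug_a`, `drug_b`, `severity`,
#'   `type_label`, canonically ordered) and `snapshot_label`.
#' @examples
#' attrs <- data.frame(drug_id = c("A", "B", "C"))
#' recs <- data.frame(drug_a = c("A", "B"), drug_b = c("B", "A"),
#'                    severity = "major", type_label = "t1")
#' net <- build_network(recs, attrs)
#' n_edges(net)  # 1: the two records describe the same unordered pair
#' @export
build_network <- function(edge_records, attributes, snapshot_label = "") {
  stopifnot(is.data.frame(attributes), "drug_id" %in% names(attributes))
  drug_id <- as.character(attributes$drug_id)
  if (anyNA(drug_id) || any(!nzchar(drug_id)))
    stop("attributes: drug_id must be nonempty")
  if (anyDuplicated(drug_id))
    stop("attributes: duplicated drug_id: ",
         paste(unique(drug_id[duplicated(drug_id)]), collapse = ", "))
  if (any(grepl("[|\t]", drug_id)))
    stop("drug_id must not contain '|' or tab characters")

  drugs <- data.frame(drug_id = sort(drug_id), stringsAsFactors = FALSE)
  drugs$atc_codes <- split_attr_column(attributes, "atc_codes", drugs$drug_id)
  drugs$substructures <- split_attr_column(attributes, "substructures", drugs$drug_id)

  if (is.null(edge_records) || nrow(as.data.frame(edge_records)) == 0L) {
    edges <- data.frame(drug_a = character(), drug_b = character(),
                        severity = character(), type_label = character(),
                        stringsAsFactors = FALSE)
    return(new_ddi_network(drugs, edges, snapshot_label))
  }

  er <- as.data.frame(edge_records, stringsAsFactors = FALSE)
  stopifnot(all(c("drug_a", "drug_b") %in% names(er)))
  er$drug_a <- as.character(er$drug_a)
  er$drug_b <- as.character(er$drug_b)
  if (is.null(er$severity)) er$severity <- "unspecified"
  er$severity <- as.character(er$severity)
  if (is.null(er$type_label)) er$type_label <- "unspecified"
  er$type_label <- as.character(er$type_label)

  bad_sev <- setdiff(unique(er$severity), SEVERITY_LEVELS)
  if (length(bad_sev))
    stop("unknown severity level(s): ", paste(bad_sev, collapse = ", "))
  self <- er$drug_a == er$drug_b
  if (any(self))
    stop("self-loop record(s) rejected: ",
         paste(utils::head(er$drug_a[self], 5), collapse = ", "))
  missing <- setdiff(unique(c(er$drug_a, er$drug_b)), drugs$drug_id)
  if (length(missing))
    stop("edge record(s) reference unknown drug(s): ",
         paste(missing, collapse = ", "))

  cp <- canonical_pairs(er$drug_a, er$drug_b)
  er$drug_a <- cp$drug_a
  er$drug_b <- cp$drug_b
  key <- pair_key(er$drug_a, er$drug_b)

  # Deduplicate: keep the most severe record per pair; warn on conflicts.
  sev_rank <- match(er$severity, SEVERITY_LEVELS)
  ord <- order(key, -sev_rank)
  er <- er[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  dup_conflict <- tapply(er$severity, key, function(s) length(unique(s)) > 1L)
  if (any(dup_conflict))
    warning(sum(dup_conflict),
            " duplicated pair(s) with conflicting severities; ",
            "kept the most severe record")
  edges <- er[first, c("drug_a", "drug_b", "severity", "type_label")]
  edges <- edges[order(edges$drug_a, edges$drug_b), , drop = FALSE]
  rownames(edges) <- NULL
  new_ddi_network(drugs, edges, snapshot_label)
}

split_attr_column <- function(attributes, column, ordered_ids) {
  idx <- match(ordered_ids, as.character(attributes$drug_id))
  if (!column %in% names(attributes))
    return(rep(list(character()), length(ordered_ids)))
  col <- attributes[[column]][idx]
  if (is.list(col)) {
    lapply(col, function(x) sort(unique(as.character(x[!is.na(x) & nzchar(x)]))))
  } else {
    lapply(strsplit(ifelse(is.na(col), "", as.character(col)), ";", fixed = TRUE),
           function(x) sort(unique(x[nzchar(x)])))
  }
}

new_ddi_network <- function(drugs, edges, snapshot_label) {
  structure(list(drugs = drugs, edges = edges,
                 snapshot_label = as.character(snapshot_label)),
            class = "ddi_network")
}

#' @export
print.ddi_network <- function(x, ...) {
  cat(sprintf("ddi_network%s: %d drugs, %d interactions\n",
              if (nzchar(x$snapshot_label)) paste0(" [", x$snapshot_label, "]") else "",
              nrow(x$drugs), nrow(x$edges)))
  invisible(x)
}

#' @rdname network_counts
#' @export
n_drugs <- function(net) nrow(net$drugs)

#' Node and edge counts of a DDI network
#'
#' @param net A `ddi_network`.
#' @return Integer count.
#' @name network_counts
#' @export
n_edges <- function(net) nrow(net$edges)

drug_ids <- function(net) net$drugs$drug_id

# Neighbor id list for every drug, named by drug_id.
neighbor_list <- function(net) {
  ids <- drug_ids(net)
  nbr <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_along(ids)) nbr[[k]] <- character()
  if (nrow(net$edges)) {
    sp_a <- split(net$edges$drug_b, net$edges$drug_a)
    sp_b <- split(net$edges$drug_a, net$edges$drug_b)
    for (nm in names(sp_a)) nbr[[nm]] <- c(nbr[[nm]], sp_a[[nm]])
    for (nm in names(sp_b)) nbr[[nm]] <- c(nbr[[nm]], sp_b[[nm]])
  }
  lapply(nbr, sort)
}

#' Neighbors of a drug
#'
#' @param net A `ddi_network`.
#' @param id A drug identifier present in `net`.
#' @return Character vector of interacting drugs.
#' @export
neighbors_of <- function(net, id) {
  if (!id %in% drug_ids(net)) stop("unknown drug: ", id)
  e <- net$edges
  sort(c(e$drug_b[e$drug_a == id], e$drug_a[e$drug_b == id]))
}

#' Convert a DDI network to an igraph graph
#'
#' Nodes carry the drug ids; edges carry `severity` and `type_label`.
#'
#' @param net A `ddi_network`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n_drugs(net), name = drug_ids(net))
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(net$edges$drug_a, net$edges$drug_b),
                           severity = net$edges$severity,
                           type_label = net$edges$type_label)
  }
  g
}

#' Sub-network induced by a severity class
#'
#' Keeps exactly the edges with the requested severity together with the
#' drugs incident to at least one such edge; isolated drugs are dropped.
#' An empty severity class yields an empty network.
#'
#' @param net A `ddi_network`.
#' @param severity One of [ddi_severity_levels()].
#' @return A `ddi_network`.
#' @export
induce_severity_subnetwork <- function(net, severity) {
  severity <- match.arg(severity, SEVERITY_LEVELS)
  edges <- net$edges[net$edges$severity == severity, , drop = FALSE]
  keep <- unique(c(edges$drug_a, edges$drug_b))
  drugs <- net$drugs[net$drugs$drug_id %in% keep, , drop = FALSE]
  rownames(edges) <- rownames(drugs) <- NULL
  new_ddi_network(drugs, edges,
                  paste0(net$snapshot_label,
                         if (nzchar(net$snapshot_label)) "/" else "", severity))
}

#' All unordered non-edges of a network
#'
#' Enumerates every unordered drug pair that is not an edge. The count
#' always satisfies `choose(n, 2) - n_edges(net)`.
#'
#' @param net A `ddi_network`.
#' @return Data frame with columns `drug_a`, `drug_b` (canonically ordered).
#' @export
non_edges <- function(net) {
  ids <- drug_ids(net)  # already sorted
  n <- length(ids)
  if (n < 2L)
    return(data.frame(drug_a = character(), drug_b = character()))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  all_pairs <- data.frame(drug_a = ids[idx[, "row"]], drug_b = ids[idx[, "col"]],
                          stringsAsFactors = FALSE)
  if (nrow(net$edges)) {
    edge_keys <- pair_key(net$edges$drug_a, net$edges$drug_b)
    all_pairs <- all_pairs[!(pair_key(all_pairs$drug_a, all_pairs$drug_b)
                             %in% edge_keys), , drop = FALSE]
  }
  all_pairs <- all_pairs[order(all_pairs$drug_a, all_pairs$drug_b), , drop = FALSE]
  rownames(all_pairs) <- NULL
  all_pairs
}

#' Simulated-prospective validation split
#'
#' The candidate set is every non-edge of the training snapshot; positives
#' are those candidates that appear as edges in the later snapshot. The drug
#' universe is fixed at the training snapshot: later-only drugs are ignored.
#' Pairs already edges in training are never positives even if re-reported.
#'
#' @param train Training `ddi_network`.
#' @param later Later-snapshot `ddi_network` over (at least) the same drugs.
#' @return A `validation_split`: list with `train`, `candidate_pairs` (data
#'   frame), and `positives` (data frame with `severity`, `type_label` taken
#'   from the later snapshot).
#' @export
make_validation_split <- function(train, later) {
  miss <- setdiff(drug_ids(train), drug_ids(later))
  if (length(miss))
    warning("later snapshot is missing training drug(s): ",
            paste(utils::head(miss, 5), collapse = ", "),
            "; their candidate pairs can contribute no positives")
  candidates <- non_edges(train)
  cand_key <- pair_key(candidates$drug_a, candidates$drug_b)
  later_edges <- later$edges
  later_key <- pair_key(later_edges$drug_a, later_edges$drug_b)
  hit <- match(cand_key, later_key)
  pos <- which(!is.na(hit))
  positives <- cbind(candidates[pos, , drop = FALSE],
                     later_edges[hit[pos], c("severity", "type_label"),
                                 drop = FALSE])
  rownames(positives) <- NULL
  structure(list(train = train, candidate_pairs = candidates,
                 positives = positives),
            class = "validation_split")
}

#' @export
print.validation_split <- function(x, ...) {
  cat(sprintf("validation_split: %d candidate pairs, %d positives (%.2f%%)\n",
              nrow(x$candidate_pairs), nrow(x$positives),
              100 * nrow(x$positives) / max(1L, nrow(x$candidate_pairs))))
  invisible(x)
}

#' Binary response vector for a validation split
#'
#' @param split A `validation_split`.
#' @return Integer vector (0/1) aligned with `split$candidate_pairs` rows.
#' @export
split_labels <- function(split) {
  as.integer(pair_key(split$candidate_pairs$drug_a, split$candidate_pairs$drug_b)
             %in% pair_key(split$positives$drug_a, split$positives$drug_b))
}

#' Summary of a DDI network
#'
#' @param object A `ddi_network`.
#' @param ... Unused.
#' @return A list with `n_drugs`, `n_edges`, `n_non_edges`, `density`
#'   (`n_edges / choose(n_drugs, 2)`) and `severity_counts`.
#' @export
summary.ddi_network <- function(object, ...) {
  n <- n_drugs(object)
  m <- n_edges(object)
  total <- if (n >= 2) choose(n, 2) else 0
  out <- list(
    snapshot_label = object$snapshot_label,
    n_drugs = n,
    n_edges = m,
    n_non_edges = total - m,
    density = if (total > 0) m / total else 0,
    severity_counts = table(factor(object$edges$severity,
                                   levels = SEVERITY_LEVELS))
  )
  class(out) <- "summary.ddi_network"
  out
}

#' @export
print.summary.ddi_network <- function(x, ...) {
  cat(sprintf("DDI network%s\n",
              if (nzchar(x$snapshot_label)) paste0(" [", x$snapshot_label, "]") else ""))
  cat(sprintf("  drugs:     %d\n  edges:     %d\n  non-edges: %d\n  density:   %.4f (%.1f%%)\n",
              x$n_drugs, x$n_edges, x$n_non_edges, x$density, 100 * x$density))
  nz <- x$severity_counts[x$severity_counts > 0]
  if (length(nz))
    cat("  severities:", paste(sprintf("%s=%d", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}
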