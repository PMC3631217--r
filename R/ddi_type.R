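# Interaction-type suggestion by neighborhood type frequency: the types of
# the edges incident to either endpoint of a predicted pair, ranked by how
# often they occur. The hypothesis is that a newly reported interaction
# tends to share its type with the interactions its drugs already have.

#' Neighborhood type ranking for a drug pair
#'
#' Counts the type labels of all edges incident to `i` or `j` (excluding
#' the edge `(i, j)` itself if present) and ranks them by descending
#' frequency, breaking frequency ties lexicographically by type label.
#'
#' @param net A `ddi_network`.
#' @param i,j Distinct drug ids in `net`.
#' @return List of class `ppin_type_ranking`: `pair`, `ranked_types`
#'   (character), `counts` (named integer, same order). An isolated pair
#'   yields an empty ranking.
#' @export
neighborhood_type_ranking <- function(net, i, j) {
  stopifnot(i != j)
  if (!all(c(i, j) %in% drug_ids(net)))
    stop("unknown drug id: ", paste(setdiff(c(i, j), drug_ids(net)),
                                    collapse = ", "))
  e <- net$edges
  incident <- (e$drug_a %in% c(i, j)) | (e$drug_b %in% c(i, j))
  focal <- pair_key(e$drug_a, e$drug_b) == pair_key(i, j)
  types <- e$type_label[incident & !focal]
  if (!length(types)) {
    counts <- integer(0)
  } else {
    tab <- table(types)
    ord <- order(-as.integer(tab), names(tab))  # frequency desc, label asc
    counts <- stats::setNames(as.integer(tab)[ord], names(tab)[ord])
  }
  structure(list(pair = sort(c(i, j)), ranked_types = names(counts),
                 counts = counts),
            class = "ppin_type_ranking")
}

#' @export
print.ppin_type_ranking <- function(x, ...) {
  cat(sprintf("type ranking for (%s, %s): %d neighborhood types\n",
              x$pair[1], x$pair[2], length(x$ranked_types)))
  if (length(x$counts)) print(utils::head(x$counts, 10))
  invisible(x)
}

#' Rank of the true interaction type within a neighborhood ranking
#'
#' Competition ("1224") ranking over the frequency-sorted types: all types
#' tied at a frequency share the rank of the first of them. Returns `NA`
#' when the true type does not occur in the neighborhood at all.
#'
#' @param ranking A `ppin_type_ranking`.
#' @param true_type The type label observed later for the pair.
#' @return Integer rank (1-based) or `NA_integer_` when absent.
#' @export
true_type_rank <- function(ranking, true_type) {
  pos <- match(as.character(true_type), ranking$ranked_types)
  if (is.na(pos)) return(NA_integer_)
  # competition rank: 1 + number of types with strictly greater count
  as.integer(1L + sum(ranking$counts > ranking$counts[[pos]]))
}

#' Cumulative distribution of true-type ranks
#'
#' @param ranks Integer vector of true-type ranks; `NA` entries (true type
#'   absent from the neighborhood) are excluded and reported separately.
#' @param at Ranks at which to report the CDF (default 1, 3, 5).
#' @return List: `cdf` (function rank -> fraction with true rank <= rank),
#'   `at` (named vector of the CDF at the requested ranks), `n_ranked`,
#'   `n_absent`.
#' @export
rank_cdf <- function(ranks, at = c(1L, 3L, 5L)) {
  n_absent <- sum(is.na(ranks))
  ranks <- ranks[!is.na(ranks)]
  if (!length(ranks)) stop("no ranked pairs (all true types absent)")
  n <- length(ranks)
  cdf <- function(r) vapply(r, function(k) mean(ranks <= k), numeric(1))
  list(cdf = cdf,
       at = stats::setNames(cdf(at), paste0("top", at)),
       n_ranked = n, n_absent = n_absent)
}

#' Evaluate type suggestion on a set of pairs
#'
#' For each pair, ranks the neighborhood types in the training network and
#' locates the later-observed true type within that ranking.
#'
#' @param net Training `ddi_network`.
#' @param pairs Data frame `drug_a`, `drug_b`, `type_label` (the true type
#'   from the later snapshot), e.g. `split$positives` restricted to the
#'   predictions of a model.
#' @return Data frame `drug_a`, `drug_b`, `true_type`, `rank` (NA when the
#'   true type is absent from the neighborhood), `n_types`.
#' @export
evaluate_type_prediction <- function(net, pairs) {
  stopifnot(all(c("drug_a", "drug_b", "type_label") %in% names(pairs)))
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    rk <- neighborhood_type_ranking(net, pairs$drug_a[k], pairs$drug_b[k])
    data.frame(drug_a = pairs$drug_a[k], drug_b = pairs$drug_b[k],
               true_type = pairs$type_label[k],
               rank = true_type_rank(rk, pairs$type_label[k]),
               n_types = length(rk$ranked_types),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
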