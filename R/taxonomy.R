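# ATC-style taxonomy: a rooted tree defined implicitly by nested code
# prefixes. The real WHO ATC coding has 5 levels at character offsets
# 1/3/4/5/7 of the 7-character code; synthetic taxonomies may use any
# prefix-length ladder.

#' Build a hierarchical drug taxonomy from full codes
#'
#' The tree is defined by prefix nesting: level `k` of a code is its first
#' `level_prefixes[k]` characters, and two codes share an ancestor at level
#' `k` iff their level-`k` prefixes agree. A virtual root joins the level-1
#' classes, so the path length between two leaves is
#' `2 * (depth - deepest shared level)`.
#'
#' @param codes Character vector of full (leaf) codes.
#' @param level_prefixes Integer vector of cumulative prefix lengths, one
#'   per level, strictly increasing; the last must equal the code length.
#'   Defaults to the WHO ATC convention `c(1, 3, 4, 5, 7)`.
#' @return An object of class `atc_taxonomy`.
#' @examples
#' tax <- atc_taxonomy(c("A01AA01", "A01AA02", "B02BC05"))
#' atc_code_distance(tax, "A01AA01", "A01AA02")  # siblings: 2
#' @export
atc_taxonomy <- function(codes, level_prefixes = c(1L, 3L, 4L, 5L, 7L)) {
  codes <- unique(as.character(codes))
  level_prefixes <- as.integer(level_prefixes)
  if (length(level_prefixes) < 1L || any(diff(level_prefixes) <= 0L))
    stop("level_prefixes must be strictly increasing")
  if (!length(codes)) stop("no codes supplied")
  width <- max(level_prefixes)
  if (any(nchar(codes) != width))
    stop("all codes must have ", width, " characters (full-depth codes)")
  structure(list(codes = sort(codes),
                 level_prefixes = level_prefixes,
                 depth = length(level_prefixes)),
            class = "atc_taxonomy")
}

#' @export
print.atc_taxonomy <- function(x, ...) {
  cat(sprintf("atc_taxonomy: %d leaf codes, %d levels (prefix lengths %s)\n",
              length(x$codes), x$depth,
              paste(x$level_prefixes, collapse = "/")))
  invisible(x)
}

#' Maximum possible tree distance in a taxonomy
#'
#' Two codes sharing no level pass through the virtual root: distance
#' `2 * depth`.
#'
#' @param tax An `atc_taxonomy`.
#' @return Integer.
#' @export
atc_max_distance <- function(tax) 2L * tax$depth

# Deepest shared level of two equal-width code vectors (vectorized).
shared_level <- function(tax, c1, c2) {
  lvl <- integer(length(c1))
  for (k in seq_along(tax$level_prefixes)) {
    p <- tax$level_prefixes[k]
    agree <- substr(c1, 1L, p) == substr(c2, 1L, p)
    lvl[agree] <- k
    if (!any(agree)) break
  }
  lvl
}

#' Tree-path distance between two full codes
#'
#' @param tax An `atc_taxonomy`.
#' @param c1,c2 Full codes (vectorized, recycled).
#' @return Integer vector of path lengths (steps up to the lowest common
#'   ancestor plus steps down); 0 for identical codes.
#' @export
atc_code_distance <- function(tax, c1, c2) {
  2L * (tax$depth - shared_level(tax, as.character(c1), as.character(c2)))
}

#' Minimum taxonomy distance between two drugs ("atc_min")
#'
#' A drug may occupy several taxonomy positions (multiple codes); the
#' distance between two drugs is the minimum tree-path length over all code
#' pairs.
#'
#' @param tax An `atc_taxonomy`.
#' @param codes1,codes2 Character vectors: the full codes of each drug.
#' @return Nonnegative integer.
#' @export
atc_min_distance <- function(tax, codes1, codes2) {
  codes1 <- as.character(codes1); codes2 <- as.character(codes2)
  if (!length(codes1) || !length(codes2))
    stop("both drugs must have at least one taxonomy code")
  grid <- expand.grid(c1 = codes1, c2 = codes2, stringsAsFactors = FALSE)
  min(atc_code_distance(tax, grid$c1, grid$c2))
}

# Drug-by-drug minimum taxonomy distance matrix. code_sets is a list of
# code vectors aligned with its names. Drugs with no codes get NA rows.
atc_distance_matrix <- function(tax, code_sets) {
  n <- length(code_sets)
  ids <- names(code_sets)
  ncodes <- lengths(code_sets)
  # pad every drug to the maximum code count by repeating its first code;
  # the min over padded pairs equals the min over true pairs.
  maxc <- max(1L, max(ncodes))
  codes <- matrix(NA_character_, n, maxc)
  for (k in seq_len(maxc)) {
    codes[, k] <- vapply(code_sets, function(cs) {
      if (!length(cs)) NA_character_ else cs[min(k, length(cs))]
    }, character(1))
  }
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  for (a in seq_len(maxc)) {
    for (b in seq_len(maxc)) {
      ca <- codes[, a]; cb <- codes[, b]
      # shared level per (i,j) via prefix group ids: compare group labels
      dk <- matrix(2L * tax$depth, n, n)
      for (k in seq_along(tax$level_prefixes)) {
        p <- tax$level_prefixes[k]
        ga <- substr(ca, 1L, p); gb <- substr(cb, 1L, p)
        agree <- outer(ga, gb, "==")
        agree[is.na(agree)] <- FALSE
        dk[agree] <- 2L * (tax$depth - k)
      }
      D <- pmin(D, dk)
    }
  }
  no_codes <- ncodes == 0L
  D[no_codes, ] <- NA_real_
  D[, no_codes] <- NA_real_
  D
}
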