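# Fixtures built in code: tiny deterministic networks and randomized small
# instances for oracle-equivalence sweeps.

toy_attrs <- function(ids, atc = NULL, subs = NULL) {
  df <- data.frame(drug_id = ids, stringsAsFactors = FALSE)
  if (!is.null(atc)) df$atc_codes <- atc
  if (!is.null(subs)) df$substructures <- subs
  df
}

toy_net <- function(edges, ids = NULL, ...) {
  if (is.null(ids))
    ids <- sort(unique(c(edges$drug_a, edges$drug_b)))
  build_network(edges, toy_attrs(ids, ...))
}

edge_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(drug_a = m[, 1], drug_b = m[, 2], stringsAsFactors = FALSE)
}

# A small taxonomy whose codes span a range of shared depths.
toy_taxonomy <- function() {
  atc_taxonomy(c("A01AA01", "A01AA02", "A01AB01", "A02AA01",
                 "B01AA01", "B01BA01", "C01AA01", "C02CC02"))
}

# Random small network with random attributes; n <= 12 keeps the
# brute-force oracles instant.
random_small_net <- function(n = 8, p = 0.4, tax = toy_taxonomy(),
                             n_feats = 6) {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- data.frame(drug_a = pairs[keep, 1], drug_b = pairs[keep, 2],
                      severity = sample(ddi_severity_levels(), sum(keep),
                                        replace = TRUE),
                      type_label = sample(paste0("t", 1:4), sum(keep),
                                          replace = TRUE),
                      stringsAsFactors = FALSE)
  n_codes <- sample(1:2, n, replace = TRUE)
  atc <- vapply(n_codes, function(k)
    paste(sample(tax$codes, k), collapse = ";"), character(1))
  subs <- vapply(seq_len(n), function(k) {
    on <- sample(0:n_feats, 1)
    paste(sample(sprintf("f%d", seq_len(n_feats)), on), collapse = ";")
  }, character(1))
  build_network(edges, toy_attrs(ids, atc = atc, subs = subs))
}

# Default-benchmark objects shared across test files (computed once per
# test run; kept at a fixed seed distinct from the acceptance script's).
bench_cache <- new.env(parent = emptyenv())
default_benchmark <- function(seed = 424L) {
  key <- paste0("b", seed)
  if (is.null(bench_cache[[key]]))
    bench_cache[[key]] <- generate_benchmark(generator_config(seed = seed))
  bench_cache[[key]]
}
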