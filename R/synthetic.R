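# Synthetic drug universes and DDI snapshots with planted structure.
#
# The generator emulates the statistical shape of a real drug-safety
# snapshot pair: a few hundred to ~1000 drugs, ~15% interaction density,
# heavy-tailed degrees (per-drug Gaussian propensities on the logit
# scale), taxonomy- and fingerprint-driven edge probabilities, severity
# labels, leaf-class-clustered interaction types, and a later snapshot in
# which ~1.4% of the training non-edges appear as new interactions drawn
# from the same planted model (the premise being that earlier network
# structure predicts later reports).

#' Configuration for the synthetic-data generator
#'
#' Defaults define the package's standard benchmark: 300 drugs on a
#' 5-level binary taxonomy (32 leaf classes of ~9 drugs), 32-bit
#' fingerprints that are nearly identical within a leaf class, strong
#' planted effects for taxonomy and structural similarity, per-drug degree
#' heterogeneity (SD 0.8 on the logit scale), 15% training density and a
#' 1.4% future-edge rate among non-edges. The class granularity and effect
#' sizes are calibrated once so that the attainable prospective AUROC of
#' the benchmark matches the magnitude reported for real drug-safety
#' snapshot pairs (around 0.75-0.8); see the methods vignette.
#'
#' @param n_drugs Number of drugs.
#' @param taxonomy_shape Integer branching factor per taxonomy level
#'   (5 levels; leaves = product).
#' @param fingerprint_bits Number of binary substructure features.
#' @param class_bias Within-class fingerprint correlation in \[0, 1\]: each
#'   drug copies its leaf-class template bit with probability
#'   `1 - (1 - class_bias) / 2`.
#' @param beta Planted log-odds coefficients, named `taxonomy` (on
#'   `exp(-atc_min / 2)`) and `structure` (on the structural Jaccard).
#' @param propensity_sd SD of per-drug Gaussian propensities (degree
#'   heterogeneity); 0 gives a homogeneous graph.
#' @param target_density Expected edge density of the training snapshot.
#' @param future_rate Expected fraction of training non-edges that appear
#'   as new edges in the later snapshot.
#' @param severity_mix Named probability vector over severity classes.
#' @param n_types Number of interaction-type labels.
#' @param type_clustering Probability that an edge draws its type from the
#'   leaf class of one of its endpoints rather than uniformly.
#' @param second_code_prob Probability a drug carries a second taxonomy code.
#' @param template_density Probability a leaf-template fingerprint bit is on.
#' @param seed Integer RNG seed; every stage derives its stream from it.
#' @return List of class `ppin_generator_config`.
#' @export
generator_config <- function(n_drugs = 300L,
                             taxonomy_shape = c(2L, 2L, 2L, 2L, 2L),
                             fingerprint_bits = 32L,
                             class_bias = 0.95,
                             beta = c(taxonomy = 8, structure = 10),
                             propensity_sd = 0.8,
                             target_density = 0.15,
                             future_rate = 0.014,
                             severity_mix = c(minor = 0.076, moderate = 0.751,
                                              major = 0.131,
                                              contraindicated = 0.042),
                             n_types = 20L,
                             type_clustering = 0.7,
                             second_code_prob = 0.15,
                             template_density = 0.2,
                             seed = 1L) {
  stopifnot(n_drugs >= 3L, all(taxonomy_shape >= 1L),
            fingerprint_bits >= 1L,
            class_bias >= 0, class_bias <= 1,
            length(beta) == 2L,
            propensity_sd >= 0,
            target_density > 0, target_density < 1,
            future_rate > 0, future_rate < 1,
            n_types >= 1L,
            type_clustering >= 0, type_clustering <= 1,
            abs(sum(severity_mix) - 1) < 1e-8,
            all(names(severity_mix) %in% ddi_severity_levels()))
  structure(list(n_drugs = as.integer(n_drugs),
                 taxonomy_shape = as.integer(taxonomy_shape),
                 fingerprint_bits = as.integer(fingerprint_bits),
                 class_bias = class_bias,
                 beta = stats::setNames(as.numeric(beta),
                                        c("taxonomy", "structure")),
                 propensity_sd = propensity_sd,
                 target_density = target_density,
                 future_rate = future_rate,
                 severity_mix = severity_mix,
                 n_types = as.integer(n_types),
                 type_clustering = type_clustering,
                 second_code_prob = second_code_prob,
                 template_density = template_density,
                 seed = as.integer(seed)),
            class = "ppin_generator_config")
}

#' Generate a complete synthetic taxonomy
#'
#' Builds the complete rooted tree with the configured per-level branching
#' and assigns every leaf an ATC-style 7-character code (letter / 2 digits
#' / letter / letter / 2 digits), so codes parse at the standard prefix
#' offsets 1/3/4/5/7.
#'
#' @param config A `ppin_generator_config` (or an integer branching vector).
#' @return An `atc_taxonomy` whose leaf count is the product of the
#'   branching factors.
#' @export
generate_taxonomy <- function(config) {
  shape <- if (inherits(config, "ppin_generator_config"))
    config$taxonomy_shape else as.integer(config)
  if (length(shape) != 5L) stop("taxonomy_shape must have 5 levels")
  if (any(shape < 1L)) stop("branching factors must be >= 1")
  if (shape[1] > 26L || shape[3] > 26L || shape[4] > 26L ||
      shape[2] > 99L || shape[5] > 99L)
    stop("branching factor exceeds code alphabet")
  lv <- list(LETTERS[seq_len(shape[1])],
             sprintf("%02d", seq_len(shape[2])),
             LETTERS[seq_len(shape[3])],
             LETTERS[seq_len(shape[4])],
             sprintf("%02d", seq_len(shape[5])))
  grid <- expand.grid(lv[[5]], lv[[4]], lv[[3]], lv[[2]], lv[[1]],
                      stringsAsFactors = FALSE)
  codes <- paste0(grid[[5]], grid[[4]], grid[[3]], grid[[2]], grid[[1]])
  atc_taxonomy(codes)
}

#' Generate synthetic drug attributes
#'
#' Each drug is assigned a primary taxonomy leaf uniformly at random (and,
#' with probability `second_code_prob`, a second leaf), plus a binary
#' fingerprint derived from its primary leaf's class template: template
#' bits (on with probability `template_density`) are copied and flipped
#' independently with probability `(1 - class_bias) / 2`, so drugs sharing
#' a leaf class have elevated structural Jaccard similarity.
#'
#' @param config A `ppin_generator_config`.
#' @param tax The taxonomy from [generate_taxonomy()].
#' @return Data frame with columns `drug_id`, `atc_codes` (semicolon
#'   separated), `substructures` (semicolon separated), and `primary_leaf`
#'   (integer leaf index, used downstream for type clustering).
#' @export
generate_drugs <- function(config, tax) {
  set.seed(config$seed)
  n <- config$n_drugs
  leaves <- tax$codes
  width <- max(2L, nchar(as.character(n)))
  ids <- sprintf(paste0("D%0", width, "d"), seq_len(n))
  primary <- sample.int(length(leaves), n, replace = TRUE)
  second <- ifelse(stats::runif(n) < config$second_code_prob,
                   sample.int(length(leaves), n, replace = TRUE), NA_integer_)
  atc <- ifelse(is.na(second) | second == primary,
                leaves[primary],
                paste(leaves[primary], leaves[second], sep = ";"))
  bits <- config$fingerprint_bits
  templates <- matrix(stats::runif(length(leaves) * bits) <
                        config$template_density,
                      nrow = length(leaves))
  flip <- matrix(stats::runif(n * bits) < (1 - config$class_bias) / 2,
                 nrow = n)
  fp <- xor(templates[primary, , drop = FALSE], flip)
  feat <- sprintf("f%03d", seq_len(bits))
  subs <- apply(fp, 1L, function(row) paste(feat[row], collapse = ";"))
  data.frame(drug_id = ids, atc_codes = atc, substructures = subs,
             primary_leaf = primary, stringsAsFactors = FALSE)
}

# Structural Jaccard matrix from a list of feature-set vectors.
str_jaccard_matrix <- function(sub_list) {
  n <- length(sub_list)
  feats <- sort(unique(unlist(sub_list)))
  if (!length(feats)) return(matrix(0, n, n))
  F <- matrix(0L, n, length(feats), dimnames = list(NULL, feats))
  for (k in seq_len(n)) F[k, sub_list[[k]]] <- 1L
  inter <- F %*% t(F)
  sizes <- rowSums(F)
  un <- outer(sizes, sizes, "+") - inter
  ifelse(un > 0, inter / un, 0)
}

# Planted pair-probability model shared by the snapshot and future-edge
# stages: logit p_ij = b0 + beta_tax * exp(-d_ATC/2) + beta_str * S_ij
#                      + a_i + a_j.
planted_eta <- function(config, drugs, tax) {
  sub_list <- lapply(strsplit(drugs$substructures, ";", fixed = TRUE),
                     function(x) x[nzchar(x)])
  code_sets <- lapply(strsplit(drugs$atc_codes, ";", fixed = TRUE),
                      function(x) x[nzchar(x)])
  names(code_sets) <- drugs$drug_id
  D <- atc_distance_matrix(tax, code_sets)
  S <- str_jaccard_matrix(sub_list)
  tax_sim <- exp(-D / 2)
  a <- if (config$propensity_sd > 0)
    stats::rnorm(nrow(drugs), 0, config$propensity_sd) else rep(0, nrow(drugs))
  eta <- config$beta[["taxonomy"]] * tax_sim +
    config$beta[["structure"]] * S + outer(a, a, "+")
  list(eta = eta, propensity = stats::setNames(a, drugs$drug_id),
       tax_sim = tax_sim, str_sim = S)
}

# Calibrate an additive intercept so that mean(f(b0)) over the upper
# triangle hits the target, by bisection to 1e-4 relative tolerance.
calibrate_intercept <- function(eta_upper, target, lower = -30, upper = 30) {
  f <- function(b0) mean(inv_logit(b0 + eta_upper)) - target
  if (f(lower) > 0 || f(upper) < 0) stop("unattainable target rate")
  for (it in 1:200) {
    mid <- (lower + upper) / 2
    if (f(mid) > 0) upper <- mid else lower <- mid
    if (abs(f(mid)) < 1e-4 * target) break
  }
  (lower + upper) / 2
}

sample_edge_labels <- function(config, drugs, ia, ib) {
  n_new <- length(ia)
  severity <- sample(names(config$severity_mix), n_new, replace = TRUE,
                     prob = config$severity_mix)
  leaf_type <- function(leaf) sprintf("T%02d", (leaf - 1L) %% config$n_types + 1L)
  clustered <- stats::runif(n_new) < config$type_clustering
  pick_a <- stats::runif(n_new) < 0.5
  leaf <- ifelse(pick_a, drugs$primary_leaf[ia], drugs$primary_leaf[ib])
  type_label <- ifelse(clustered, leaf_type(leaf),
                       sprintf("T%02d", sample.int(config$n_types, n_new,
                                                   replace = TRUE)))
  data.frame(severity = severity, type_label = type_label,
             stringsAsFactors = FALSE)
}

#' Generate the training DDI snapshot
#'
#' Samples every unordered pair independently with probability
#' `inv_logit(b0 + beta.tax * exp(-atc_min/2) + beta.str * str_jaccard +
#' a_i + a_j)`, where the per-drug propensities `a` are Gaussian and the
#' intercept `b0` is calibrated by bisection so the expected density equals
#' `target_density`. Severities are drawn from `severity_mix`; each edge's
#' type label is, with probability `type_clustering`, the label linked to
#' the leaf class of a random endpoint, and uniform otherwise.
#'
#' @param config A `ppin_generator_config`.
#' @param drugs Output of [generate_drugs()].
#' @param tax Output of [generate_taxonomy()].
#' @return List: `net` (the training `ddi_network`) and `truth` (class
#'   `synthetic_truth`: planted `beta`, `b0`, per-drug `propensity`,
#'   per-pair true probability matrix `p`, and the similarity matrices).
#' @export
generate_snapshot <- function(config, drugs, tax) {
  set.seed(config$seed + 1L)
  pl <- planted_eta(config, drugs, tax)
  n <- nrow(drugs)
  ut <- upper.tri(pl$eta)
  b0 <- calibrate_intercept(pl$eta[ut], config$target_density)
  p <- inv_logit(b0 + pl$eta)
  diag(p) <- 0
  draw <- matrix(FALSE, n, n)
  draw[ut] <- stats::runif(sum(ut)) < p[ut]
  idx <- which(draw, arr.ind = TRUE)
  labels <- sample_edge_labels(config, drugs, idx[, 1L], idx[, 2L])
  records <- data.frame(drug_a = drugs$drug_id[idx[, 1L]],
                        drug_b = drugs$drug_id[idx[, 2L]],
                        severity = labels$severity,
                        type_label = labels$type_label,
                        stringsAsFactors = FALSE)
  net <- build_network(records, drugs, snapshot_label = "train")
  truth <- structure(list(beta = config$beta, b0 = b0,
                          propensity = pl$propensity,
                          p = `dimnames<-`(p, list(drugs$drug_id,
                                                   drugs$drug_id)),
                          tax_sim = pl$tax_sim, str_sim = pl$str_sim,
                          config = config),
                     class = "synthetic_truth")
  list(net = net, truth = truth)
}

#' Generate the later snapshot with new ("future") edges
#'
#' Samples training non-edges with probability proportional to their true
#' planted edge probability, scaled (with capping at 1) so the expected
#' fraction of non-edges that convert equals `future_rate`. The returned
#' network is the training network plus the new edges, so new-edge
#' reporting is autocorrelated with the planted structure.
#'
#' @param truth A `synthetic_truth` from [generate_snapshot()].
#' @param net The training `ddi_network`.
#' @param config The same `ppin_generator_config`.
#' @param drugs The drug attribute table (for type clustering).
#' @return The later `ddi_network` (training edges plus new edges).
#' @export
generate_future_edges <- function(truth, net, config, drugs) {
  set.seed(config$seed + 2L)
  ne <- non_edges(net)
  if (!nrow(ne)) stop("no non-edges available for future sampling")
  ia <- match(ne$drug_a, drugs$drug_id)
  ib <- match(ne$drug_b, drugs$drug_id)
  p <- truth$p[cbind(ia, ib)]
  g <- function(scale) mean(pmin(1, scale * p)) - config$future_rate
  if (g(0) > 0 || g(1e6) < 0) stop("future_rate unattainable for this network")
  lo <- 0; hi <- 1e6
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (abs(g(mid)) < 1e-4 * config$future_rate) break
  }
  q <- pmin(1, ((lo + hi) / 2) * p)
  new_idx <- which(stats::runif(length(q)) < q)
  labels <- sample_edge_labels(config, drugs, ia[new_idx], ib[new_idx])
  new_records <- data.frame(drug_a = ne$drug_a[new_idx],
                            drug_b = ne$drug_b[new_idx],
                            severity = labels$severity,
                            type_label = labels$type_label,
                            stringsAsFactors = FALSE)
  all_records <- rbind(net$edges, new_records)
  build_network(all_records, drugs, snapshot_label = "later")
}

#' Generate a full synthetic benchmark
#'
#' Runs all generator stages under one seed: taxonomy, drugs, training
#' snapshot, later snapshot, and the validation split between them.
#'
#' @param config A `ppin_generator_config`.
#' @return List: `config`, `tax`, `drugs`, `train`, `truth`, `later`,
#'   `split`.
#' @export
generate_benchmark <- function(config = generator_config()) {
  tax <- generate_taxonomy(config)
  drugs <- generate_drugs(config, tax)
  snap <- generate_snapshot(config, drugs, tax)
  later <- generate_future_edges(snap$truth, snap$net, config, drugs)
  split <- make_validation_split(snap$net, later)
  list(config = config, tax = tax, drugs = drugs, train = snap$net,
       truth = snap$truth, later = later, split = split)
}

#' Run the full prospective pipeline on a snapshot pair
#'
#' Covariate table on the training network, model fit, scoring of the
#' validation candidates, and prospective evaluation.
#'
#' @param train Training `ddi_network`.
#' @param later Later `ddi_network` (or a ready `validation_split` via
#'   `split`).
#' @param tax An `atc_taxonomy`.
#' @param covariates Covariate names for the model.
#' @param model `"lr"` or `"glmm"`.
#' @param split Optional precomputed `validation_split`.
#' @param table Optional precomputed covariate table (all pairs).
#' @return List of class `ppin_pipeline`: `split`, `table`, `fit`,
#'   `scored`, `evaluation`.
#' @export
ppin_prospective <- function(train, later = NULL, tax = NULL,
                             covariates = ppin_covariates(),
                             model = c("lr", "glmm"),
                             split = NULL, table = NULL) {
  model <- match.arg(model)
  if (is.null(split)) split <- make_validation_split(train, later)
  if (is.null(table))
    table <- build_covariate_table(train, tax, pairs = "all",
                                   covariates = covariates)
  fit <- if (model == "lr") fit_logistic(table, covariates)
         else fit_glmm(table, covariates)
  scored <- score_pairs(fit, table, split$candidate_pairs)
  ev <- evaluate_split(scored, split)
  structure(list(split = split, table = table, fit = fit, scored = scored,
                 evaluation = ev),
            class = "ppin_pipeline")
}

#' @export
print.ppin_pipeline <- function(x, ...) {
  print(x$fit)
  print(x$evaluation)
  invisible(x)
}
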