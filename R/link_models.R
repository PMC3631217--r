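# Logistic and random-intercept mixed models for link scoring.
#
# The LR model represents each unordered pair once. The GLMM represents
# each pair twice — once keyed to each endpoint — so that drug-specific
# random intercepts can be estimated; scoring averages the two per-drug
# predicted probabilities. The duplicated-row likelihood double-counts each
# pair by design; no weighting correction is applied.

inv_logit <- function(x) 1 / (1 + exp(-x))

new_ppin_fit <- function(model_class, covariates, coefficients, se, p_values,
                         aic, loglik, converged, diagnostic = NULL,
                         varcomp = NA_real_, ranef = NULL, n_rows = NA_integer_) {
  structure(list(model_class = model_class, covariates = covariates,
                 coefficients = coefficients, se = se, p_values = p_values,
                 aic = aic, loglik = loglik, converged = converged,
                 diagnostic = diagnostic, varcomp = varcomp, ranef = ranef,
                 n_rows = n_rows),
            class = "ppin_fit")
}

#' @export
print.ppin_fit <- function(x, ...) {
  cat(sprintf("%s fit: %s | AIC %.2f | converged: %s\n",
              x$model_class, paste(x$covariates, collapse = " + "),
              x$aic, x$converged))
  est <- data.frame(estimate = x$coefficients, se = x$se, p = x$p_values)
  print(round(est, 4))
  if (x$model_class == "GLMM")
    cat(sprintf("random-intercept variance: %.4f (%d drugs)\n",
                x$varcomp, length(x$ranef)))
  invisible(x)
}

check_table <- function(table, covariates) {
  stopifnot(is.data.frame(table), "response" %in% names(table))
  if (!length(covariates)) stop("covariate subset must be nonempty")
  missing <- setdiff(covariates, names(table))
  if (length(missing))
    stop("covariate(s) missing from table: ", paste(missing, collapse = ", "))
  if (anyDuplicated(covariates))
    stop("singular design: covariate(s) duplicated in subset: ",
         paste(unique(covariates[duplicated(covariates)]), collapse = ", "))
  if (anyDuplicated(pair_key(table$drug_a, table$drug_b)))
    stop("each unordered pair must appear exactly once in the table")
  invisible(TRUE)
}

#' Fit a multivariate logistic link model
#'
#' Maximum-likelihood logistic regression of the pair response on a
#' covariate subset, with each unordered pair represented once. P-values
#' are per-coefficient Wald chi-square tests. Perfect or quasi-perfect
#' separation is flagged as non-convergence with a diagnostic rather than
#' silently returning divergent estimates.
#'
#' @param table A covariate table from [build_covariate_table()].
#' @param covariates Names of covariate columns to include.
#' @return A `ppin_fit` with `model_class = "LR"`.
#' @export
fit_logistic <- function(table, covariates) {
  check_table(table, covariates)
  X <- as.matrix(table[, covariates, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    dropped <- c("(Intercept)", covariates)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("singular design: collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  dat <- data.frame(.y = table$response, X, check.names = FALSE)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stats::reformulate(sprintf("`%s`", covariates), response = ".y"),
               family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 200)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  degenerate <- length(unique(dat$.y)) < 2L
  converged <- fit$converged && !sep_warn && !degenerate
  new_ppin_fit(
    model_class = "LR",
    covariates = covariates,
    coefficients = stats::setNames(co[, "Estimate"], rownames(co)),
    se = stats::setNames(co[, "Std. Error"], rownames(co)),
    p_values = stats::setNames(co[, "Pr(>|z|)"], rownames(co)),
    aic = stats::AIC(fit), loglik = as.numeric(stats::logLik(fit)),
    converged = converged,
    diagnostic = if (!converged)
      "possible separation or degenerate response (no finite MLE)",
    n_rows = nrow(table))
}

#' Univariate screening of all covariates
#'
#' Fits one single-covariate logistic model per covariate column and
#' reports the slope estimate, Wald p-value, and training-set AUROC of the
#' fitted scores against the response.
#'
#' @param table A covariate table.
#' @param covariates Covariate columns to screen (default: all nine present).
#' @return Data frame with one row per covariate: `covariate`, `estimate`,
#'   `se`, `p_value`, `auroc_train`, `aic`, `converged`.
#' @export
univariate_screen <- function(table, covariates = intersect(ppin_covariates(),
                                                            names(table))) {
  stopifnot(nrow(table) > 0)
  rows <- lapply(covariates, function(cv) {
    fit <- fit_logistic(table, cv)
    sc <- score_pairs(fit, table)
    data.frame(covariate = cv,
               estimate = unname(fit$coefficients[cv]),
               se = unname(fit$se[cv]),
               p_value = unname(fit$p_values[cv]),
               auroc_train = roc_auroc(sc$score, table$response)$auroc,
               aic = fit$aic,
               converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exhaustive all-subsets model search by AIC
#'
#' Fits a logistic model for every nonempty subset of the candidate
#' covariates and ranks the fits by ascending AIC, breaking ties by fewer
#' covariates and then lexicographic covariate names. Non-converged subsets
#' are excluded from the ranking and recorded.
#'
#' @param table A covariate table.
#' @param candidates Candidate covariate names (at most 20; the search is
#'   exhaustive over `2^k - 1` subsets).
#' @param model `"lr"` (default) or `"glmm"` for the final refit class of
#'   the ranked subsets (all search fits are LR for tractability).
#' @return List of class `ppin_aic_search`: `table` (ranked data frame with
#'   `subset`, `k`, `aic`), `fits` (the `ppin_fit` objects, same order) and
#'   `excluded` (character vector of non-converged subsets).
#' @export
subset_search_aic <- function(table, candidates = intersect(ppin_covariates(),
                                                            names(table)),
                              model = c("lr", "glmm")) {
  model <- match.arg(model)
  if (length(candidates) > 20L) stop("at most 20 candidate covariates")
  if (!length(candidates)) stop("no candidate covariates")
  subsets <- unlist(lapply(seq_along(candidates), function(k)
    utils::combn(sort(candidates), k, simplify = FALSE)), recursive = FALSE)
  fits <- vector("list", length(subsets))
  ok <- logical(length(subsets))
  for (s in seq_along(subsets)) {
    fits[[s]] <- tryCatch(fit_logistic(table, subsets[[s]]),
                          error = function(e) NULL)
    ok[s] <- !is.null(fits[[s]]) && fits[[s]]$converged
  }
  excluded <- vapply(subsets[!ok], paste, character(1), collapse = "+")
  if (length(excluded))
    message("excluded ", length(excluded), " non-converged subset(s)")
  subsets <- subsets[ok]; fits <- fits[ok]
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ks <- lengths(subsets)
  labels <- vapply(subsets, paste, character(1), collapse = "+")
  ord <- order(aics, ks, labels)
  ranked <- data.frame(subset = labels[ord], k = ks[ord], aic = aics[ord],
                       stringsAsFactors = FALSE)
  rownames(ranked) <- NULL
  fits <- fits[ord]
  if (model == "glmm")
    fits[[1L]] <- fit_glmm(table, subsets[ord][[1L]])
  structure(list(table = ranked, fits = fits, excluded = excluded),
            class = "ppin_aic_search")
}

#' @export
print.ppin_aic_search <- function(x, ...) {
  cat("AIC subset search:", nrow(x$table), "converged fits\n")
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Fit the drug-specific random-intercept mixed model
#'
#' Same fixed effects as the logistic model, plus a Gaussian random
#' intercept per drug. Each unordered pair is represented twice in the
#' training data — once keyed to each endpoint — so that every drug's
#' intercept sees all the pairs it participates in; per-drug intercepts are
#' estimated by their conditional modes (BLUPs). Estimation is Laplace
#' maximum likelihood via `lme4::glmer`.
#'
#' @param table A covariate table (one row per unordered pair; the
#'   duplication is performed internally).
#' @param covariates Names of fixed-effect covariate columns.
#' @return A `ppin_fit` with `model_class = "GLMM"`, carrying the estimated
#'   random-intercept variance (`varcomp`) and per-drug BLUPs (`ranef`). A
#'   variance estimate at the boundary (0) is flagged in `diagnostic`; the
#'   fixed effects then coincide with the logistic fit up to tolerance.
#' @export
fit_glmm <- function(table, covariates) {
  check_table(table, covariates)
  dup <- rbind(
    data.frame(.key = table$drug_a, table[, c("response", covariates),
                                          drop = FALSE], check.names = FALSE),
    data.frame(.key = table$drug_b, table[, c("response", covariates),
                                          drop = FALSE], check.names = FALSE))
  dup$.key <- factor(dup$.key)
  form <- stats::as.formula(paste(
    "response ~", paste(sprintf("`%s`", covariates), collapse = " + "),
    "+ (1 | .key)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(form, data = dup, family = stats::binomial(), nAGQ = 1L,
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE))))
  sm <- summary(fit)
  co <- sm$coefficients
  vc <- as.numeric(lme4::VarCorr(fit)$.key[1L])
  re <- lme4::ranef(fit)$.key
  ranef <- stats::setNames(re[, 1L], rownames(re))
  boundary <- vc < 1e-8
  new_ppin_fit(
    model_class = "GLMM",
    covariates = covariates,
    coefficients = stats::setNames(co[, "Estimate"], rownames(co)),
    se = stats::setNames(co[, "Std. Error"], rownames(co)),
    p_values = stats::setNames(co[, "Pr(>|z|)"], rownames(co)),
    aic = stats::AIC(fit), loglik = as.numeric(stats::logLik(fit)),
    converged = TRUE,
    diagnostic = if (boundary) "random-intercept variance at boundary (0)",
    varcomp = vc, ranef = ranef, n_rows = 2L * nrow(table))
}

#' Score drug pairs with a fitted link model
#'
#' LR: the score of a pair is the inverse-logit of its linear predictor.
#' GLMM: two probabilities are formed — `pest_ij` using the BLUP intercept
#' of drug `i` and `pest_ji` using that of drug `j` — and the score is
#' their arithmetic mean. Drugs without an estimated intercept (unseen in
#' training) use the prior mean 0.
#'
#' @param fit A `ppin_fit`.
#' @param table A covariate table containing the fit's covariates.
#' @param pairs Optional data frame (`drug_a`, `drug_b`) restricting and
#'   ordering the scored pairs; defaults to all rows of `table`.
#' @return Data frame `drug_a`, `drug_b`, `score`.
#' @export
score_pairs <- function(fit, table, pairs = NULL) {
  missing <- setdiff(fit$covariates, names(table))
  if (length(missing))
    stop("covariate column(s) missing from table: ",
         paste(missing, collapse = ", "))
  if (!is.null(pairs)) {
    idx <- match(pair_key(pairs$drug_a, pairs$drug_b),
                 pair_key(table$drug_a, table$drug_b))
    if (anyNA(idx)) stop("pair(s) not present in covariate table")
    table <- table[idx, , drop = FALSE]
  }
  X <- as.matrix(table[, fit$covariates, drop = FALSE])
  eta <- drop(X %*% fit$coefficients[fit$covariates]) +
    fit$coefficients[["(Intercept)"]]
  if (fit$model_class == "GLMM") {
    b_a <- fit$ranef[table$drug_a]
    b_b <- fit$ranef[table$drug_b]
    b_a[is.na(b_a)] <- 0
    b_b[is.na(b_b)] <- 0
    score <- (inv_logit(eta + b_a) + inv_logit(eta + b_b)) / 2
  } else {
    score <- inv_logit(eta)
  }
  data.frame(drug_a = table$drug_a, drug_b = table$drug_b,
             score = unname(score), stringsAsFactors = FALSE)
}
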