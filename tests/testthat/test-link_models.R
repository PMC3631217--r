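# Synthetic pair table with a planted logistic response over given columns.
planted_table <- function(n, beta, intercept = -1, seed = 1) {
  set.seed(seed)
  ids_a <- sprintf("a%06d", seq_len(n))
  ids_b <- sprintf("b%06d", seq_len(n))
  X <- matrix(stats::runif(n * length(beta)), n,
              dimnames = list(NULL, names(beta)))
  eta <- intercept + drop(X %*% beta)
  data.frame(drug_a = ids_a, drug_b = ids_b,
             response = stats::rbinom(n, 1, 1 / (1 + exp(-eta))),
             X, stringsAsFactors = FALSE)
}

test_that("logistic fit recovers a planted coefficient within 3 SE", {
  tab <- planted_table(50000, c(x = 1.5), seed = 101)
  fit <- fit_logistic(tab, "x")
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients["x"] - 1.5), 3 * fit$se["x"])
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 2)
})

test_that("degenerate and singular designs are diagnosed", {
  tab <- planted_table(200, c(x = 1), seed = 3)
  tab$response <- 0L
  fit <- fit_logistic(tab, "x")
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "separation|degenerate")
  # duplicated covariate -> singular design error naming the column
  tab2 <- planted_table(200, c(x = 1), seed = 4)
  tab2$x2 <- tab2$x
  expect_error(fit_logistic(tab2, c("x", "x2")), "collinear.*x")
  expect_error(fit_logistic(tab2, c("x", "x")), "duplicated")
  expect_error(fit_logistic(tab2, character()), "nonempty")
})

test_that("univariate screen reports AUROC with rank invariance", {
  tab <- planted_table(400, c(x = 2, z = 0), seed = 7)
  tab$perfect <- tab$response
  scr <- univariate_screen(tab, c("x", "z", "perfect"))
  expect_equal(scr$auroc_train[scr$covariate == "perfect"], 1.0)
  # monotone transformation leaves the training AUROC unchanged
  tab$xcube <- tab$x^3
  scr2 <- univariate_screen(tab, c("x", "xcube"))
  expect_equal(scr2$auroc_train[1], scr2$auroc_train[2], tolerance = 1e-10)
})

test_that("independent covariates screen near AUROC 0.5", {
  set.seed(31)
  aurocs <- replicate(5, {
    tab <- planted_table(10000, c(z = 0), seed = sample.int(1e6, 1))
    univariate_screen(tab, "z")$auroc_train
  })
  expect_lt(abs(mean(aurocs) - 0.5), 0.02)
})

test_that("AIC search is exhaustive, noise-excluding, and order-invariant", {
  tab <- planted_table(20000, c(x = 2, noise = 0), seed = 11)
  res <- subset_search_aic(tab, c("x", "noise"))
  expect_equal(nrow(res$table), 3L)  # 2^2 - 1
  expect_equal(res$table$subset[1], "x")  # noise excluded from the top
  # full model can never beat the ranked best
  expect_gte(res$table$aic[res$table$subset == "noise+x"],
             res$table$aic[1])
  # k = 3 candidates -> 7 fits
  tab$w <- stats::runif(nrow(tab))
  res3 <- subset_search_aic(tab, c("x", "noise", "w"))
  expect_equal(nrow(res3$table), 7L)
  # invariance to candidate order
  res3b <- subset_search_aic(tab, c("w", "x", "noise"))
  expect_equal(res3$table, res3b$table)
})

test_that("GLMM duplication contract and boundary behaviour hold", {
  # pair table over a shared drug set so random intercepts are meaningful
  set.seed(13)
  ids <- sprintf("d%02d", 1:30)
  pairs <- t(utils::combn(ids, 2))
  x <- stats::runif(nrow(pairs))
  eta <- -1 + 2 * x  # no drug effect: variance component should hit 0
  tab <- data.frame(drug_a = pairs[, 1], drug_b = pairs[, 2],
                    response = stats::rbinom(nrow(pairs), 1,
                                             1 / (1 + exp(-eta))),
                    x = x, stringsAsFactors = FALSE)
  glmm <- fit_glmm(tab, "x")
  lr <- fit_logistic(tab, "x")
  expect_equal(glmm$n_rows, 2L * nrow(tab))
  expect_lt(glmm$varcomp, 0.05)
  expect_lt(abs(glmm$coefficients["x"] - lr$coefficients["x"]),
            2 * lr$se["x"])
  # near the boundary the estimated GLMM scores track the LR scores
  s_glmm <- score_pairs(glmm, tab)
  s_lr <- score_pairs(lr, tab)
  expect_equal(s_glmm$score, s_lr$score, tolerance = 0.05)
  # with the variance fixed at exactly 0 (all intercepts at the prior
  # mean), GLMM scoring reduces to LR scoring
  glmm0 <- lr
  glmm0$model_class <- "GLMM"
  glmm0$varcomp <- 0
  glmm0$ranef <- stats::setNames(rep(0, length(ids)), ids)
  expect_equal(score_pairs(glmm0, tab)$score, s_lr$score, tolerance = 1e-6)
})

test_that("scores follow the documented probability arithmetic", {
  tab <- planted_table(50, c(x = 1, z = 1), seed = 17)
  fit <- fit_logistic(tab, c("x", "z"))
  # hand-computed inverse-logit for one row
  r <- 7
  eta <- fit$coefficients[["(Intercept)"]] +
    fit$coefficients[["x"]] * tab$x[r] + fit$coefficients[["z"]] * tab$z[r]
  sc <- score_pairs(fit, tab)
  expect_equal(sc$score[r], 1 / (1 + exp(-eta)), tolerance = 1e-10)
  # all-zero coefficients -> every score 0.5
  null_fit <- fit
  null_fit$coefficients[] <- 0
  expect_true(all(score_pairs(null_fit, tab)$score == 0.5))
  # permuting rows never changes a pair's score
  perm <- sample(nrow(tab))
  sc_perm <- score_pairs(fit, tab[perm, ])
  expect_equal(sc_perm$score[order(perm)], sc$score)
  # scores strictly increase with the linear predictor
  ord <- order(eta_all <- with(tab, fit$coefficients[["(Intercept)"]] +
                                 fit$coefficients[["x"]] * x +
                                 fit$coefficients[["z"]] * z))
  expect_true(all(diff(sc$score[ord]) > 0))
})

test_that("GLMM scoring averages the two endpoint probabilities", {
  fit <- ppinet:::new_ppin_fit(
    model_class = "GLMM", covariates = "x",
    coefficients = c("(Intercept)" = -1, x = 2),
    se = c("(Intercept)" = .1, x = .1), p_values = c("(Intercept)" = 0, x = 0),
    aic = 0, loglik = 0, converged = TRUE,
    varcomp = 1, ranef = c(A = 0.5, B = -0.5, C = 0.2))
  tab <- data.frame(drug_a = c("A", "A"), drug_b = c("B", "C"),
                    response = c(0L, 0L), x = c(0.3, 0.6))
  sc <- score_pairs(fit, tab)
  eta1 <- -1 + 2 * 0.3
  expect_equal(sc$score[1],
               (1 / (1 + exp(-(eta1 + 0.5))) + 1 / (1 + exp(-(eta1 - 0.5)))) / 2)
  # equal intercepts reduce to the single-sided probability
  fit$ranef <- c(A = 0.2, B = 0.2, C = 0.2)
  sc2 <- score_pairs(fit, tab)
  expect_equal(sc2$score[1], 1 / (1 + exp(-(eta1 + 0.2))))
  # unseen drugs shrink to the prior mean 0
  tab3 <- data.frame(drug_a = "A", drug_b = "ZZ", response = 0L, x = 0.3)
  sc3 <- score_pairs(fit, tab3)
  expect_equal(sc3$score,
               (1 / (1 + exp(-(eta1 + 0.2))) + 1 / (1 + exp(-eta1))) / 2)
  expect_error(score_pairs(fit, tab[, c("drug_a", "drug_b", "response")]),
               "missing")
})
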