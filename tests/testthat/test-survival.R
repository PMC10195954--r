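test_that("KM equals the empirical survival curve without censoring", {
  cl <- toy_clinical(time = c(1, 2, 3), status = c(1, 1, 1))
  km <- km_curve(cl)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$S(0.5), 1)
  expect_equal(km$S(2.5), 1 / 3)

  set.seed(1)
  t_ <- sort(rexp(40))
  cl2 <- toy_clinical(t_, rep(1L, 40))
  km2 <- km_curve(cl2)
  emp <- vapply(km2$time, function(u) mean(t_ > u), numeric(1))
  expect_equal(km2$surv, emp)
})

test_that("log-rank is null on identical groups and powered under HR = 2", {
  cl <- toy_clinical(time = rep(c(1, 2, 3, 4), 2), status = rep(1L, 8))
  lr <- logrank(cl, rep(c("a", "b"), each = 4))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_error(logrank(cl, rep("a", 8)), "group")

  set.seed(0)
  n <- 200
  tt <- c(rexp(n, 1), rexp(n, 2))   # HR = 2
  cl2 <- toy_clinical(tt, rep(1L, 2 * n))
  expect_lt(logrank(cl2, rep(c("a", "b"), each = n))$p_value, 0.01)
})

test_that("optimal cut-point recovers a perfectly separating marker", {
  set.seed(2)
  n <- 40
  marker <- c(runif(n / 2, 0, 0.4), runif(n / 2, 0.6, 1))
  time <- ifelse(marker > 0.5, rexp(n, 1 / 10), rexp(n, 1)) + 0.01
  cl <- toy_clinical(time, rep(1L, n))
  cp <- optimal_cutpoint(cl, marker)
  expect_gte(cp$threshold, max(marker[marker < 0.5]) - 1e-12)
  expect_lt(cp$threshold, min(marker[marker > 0.5]))

  # exhaustive scan oracle: the returned chi2 is the maximum over candidates
  expect_equal(cp$chi2, max(cp$scan$chi2, na.rm = TRUE))

  # flipping the marker sign yields the same partition
  cp2 <- optimal_cutpoint(cl, -marker)
  expect_setequal(which(marker > cp$threshold), which(-marker <= cp2$threshold))

  expect_error(optimal_cutpoint(cl, rep(1, n)), "constant|candidate")
  expect_error(optimal_cutpoint(cl[1:10, ], marker[1:10]), ">= 20")
})

test_that("univariate Cox matches a grid-search partial-likelihood maximizer", {
  cl <- toy_clinical(time = c(1, 2, 3, 4), status = rep(1L, 4))
  x <- c(1, 0, 1, 0)
  fit <- cox_univariate(cl, x)
  grid <- seq(-5, 5, by = 1e-3)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1),
               time = cl$time, status = cl$status, x = x)
  expect_lt(abs(fit$beta - grid[which.max(ll)]), 1e-3)

  # negation symmetry and input validation
  fit2 <- cox_univariate(cl, -x)
  expect_equal(fit2$beta, -fit$beta, tolerance = 1e-9)
  expect_error(cox_univariate(cl, rep(2, 4)), "constant")
})

test_that("risk scores are the exact linear combination", {
  model <- structure(data.frame(gene = c("g1", "g2"), coefficient = c(2, 0)),
                     class = c("risk_model", "data.frame"))
  m <- toy_expr(rbind(g1 = c(3, 1), g2 = c(10, 10)))
  expect_equal(unname(risk_score(model, m)), c(6, 2))

  model2 <- model; model2$coefficient <- model$coefficient * 2
  expect_equal(risk_score(model2, m), 2 * risk_score(model, m))

  model3 <- model; model3$gene <- c("g1", "MISSING")
  expect_error(risk_score(model3, m), "MISSING")
})

test_that("concordance matches exhaustive pair enumeration and is antisymmetric", {
  cl <- toy_clinical(time = c(2, 5, 3, 8, 6), status = c(1, 1, 1, 0, 1))
  risk <- c(0.9, 0.3, 0.6, 0.1, 0.2)
  expect_equal(c_index(cl, risk),
               oracle_c_index(cl$time, cl$status, risk))
  expect_equal(c_index(cl, risk) + c_index(cl, -risk), 1)
  expect_equal(c_index(cl, rep(0.5, 5)), 0.5)

  # perfectly anti-ordered risk (higher risk, earlier death)
  cl2 <- toy_clinical(time = 1:6, status = rep(1L, 6))
  expect_equal(c_index(cl2, 6:1), 1)

  # agrees with the survival package on a censored simulation
  set.seed(4)
  n <- 80
  tt <- rexp(n); cc <- rbinom(n, 1, 0.7); rk <- -tt + rnorm(n, 0, 0.3)
  cl3 <- toy_clinical(ifelse(cc == 1, tt, tt * runif(n)), cc)
  ref <- survival::concordance(survival::Surv(cl3$time, cl3$status) ~ rk,
                               reverse = TRUE)$concordance
  expect_equal(c_index(cl3, rk), unname(ref), tolerance = 1e-12)
})

test_that("time-dependent AUC is exact without censoring and null-calibrated", {
  cl <- toy_clinical(time = c(1, 2, 3, 10, 11, 12), status = rep(1L, 6))
  risk <- c(5, 4, 6, 1, 2, 0)
  expect_equal(td_auc(cl, risk, t = 5), 1)
  set.seed(3)
  n <- 60
  tt <- rexp(n); rk <- rnorm(n)
  cl2 <- toy_clinical(tt, rep(1L, n))
  expect_equal(td_auc(cl2, rk, t = median(tt)),
               oracle_cd_auc(tt, rep(1L, n), rk, median(tt)))

  set.seed(0)
  n <- 500
  tt <- rexp(n); cc <- rbinom(n, 1, 0.75)
  cl3 <- toy_clinical(ifelse(cc == 1, tt, tt * runif(n)), cc)
  auc <- td_auc(cl3, rnorm(n), t = stats::quantile(cl3$time, 0.6))
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)

  expect_error(td_auc(cl, risk, t = 0.5), "no events")
  expect_error(td_auc(cl, risk, t = 20), "beyond")
})

test_that("screen_and_fit recovers planted prognostic genes and names failing stages", {
  cfg <- sim_config(n_genes = 500L, n_signature_genes = 50L,
                    n_immune_genes = 50L, n_bulk = 300L, seed = 0)
  bulk <- simulate_bulk_cohort(cfg)
  model <- screen_and_fit(bulk$expr, bulk$clinical, seed = 0)
  planted <- attr(bulk$truth, "prognostic_genes")
  expect_gte(sum(planted %in% model$gene), 4)
  st <- attr(model, "stage_sizes")
  expect_true(all(diff(st) <= 0))   # each stage only narrows the set

  expect_error(screen_and_fit(bulk$expr, bulk$clinical, mad_min = Inf),
               "MAD")
})

test_that("the index pre-filter stage restricts the candidate set", {
  cfg <- small_sim(seed = 5)
  bulk <- simulate_bulk_cohort(cfg)
  model <- screen_and_fit(bulk$expr, bulk$clinical, seed = 1,
                          index = bulk$truth$ne_fraction, top_k = 30)
  st <- attr(model, "stage_sizes")
  expect_lte(st[["index_prefilter"]], 30)
  expect_lte(st[["lasso"]], st[["cox_screen"]])
})

test_that("soft-threshold fit finds a scale-free power on the hub generator", {
  m <- simulate_scale_free(seed = 1)
  sf <- scale_free_fit(m, betas = 1:10)
  expect_false(is.na(sf$beta))
  expect_gte(sf$table$r2[sf$table$beta == sf$beta], 0.9)
  expect_true(all(diff(sf$table$mean_k) < 0))  # connectivity shrinks with beta

  flat <- toy_expr(rbind(matrix(rnorm(60 * 10), 60), rep(1, 10)))
  expect_error(scale_free_fit(flat, betas = 1:3), "constant")
})

test_that("multivariable Cox reduces to the univariate fit and recovers known effects", {
  cl <- toy_clinical(time = c(3, 1, 4, 2, 6, 5), status = rep(1L, 6))
  x <- c(0.2, 1.5, 0.1, 1.2, 0.05, 0.3)
  mv <- multivariable_cox(cl, cbind(x = x))
  uni <- cox_univariate(cl, x)
  expect_equal(mv$coefficients$beta, uni$beta, tolerance = 1e-9)

  expect_error(multivariable_cox(cl, cbind(a = x, b = x)), "rank")

  set.seed(0)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  tt <- rexp(n, rate = 0.1 * exp(1.0 * x1 - 0.5 * x2))
  cl2 <- toy_clinical(tt, rep(1L, n))
  mv2 <- multivariable_cox(cl2, cbind(x1 = x1, x2 = x2))
  expect_lt(abs(mv2$coefficients$beta[1] - 1.0), 0.15)
  expect_lt(abs(mv2$coefficients$beta[2] + 0.5), 0.15)
  expect_equal(mv2$lp, drop(cbind(x1, x2) %*% mv2$coefficients$beta))
})
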