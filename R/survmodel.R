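#' Kaplan-Meier curve
#'
#' Product-limit estimate of the survival function.
#'
#' @param data a [clinical_table()] (columns `time`, `status`).
#' @return list with `time`, `surv`, `n_risk`, `n_event`, the fitted
#'   `survival::survfit` object (`fit`) and a right-continuous step
#'   function `S` with S(0) = 1.
#' @export
km_curve <- function(data) {
  stopifnot(inherits(data, "data.frame"), sum(data$status) >= 1)
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = data)
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, fit = fit,
       S = stats::stepfun(fit$time, c(1, fit$surv)))
}

#' Log-rank test between groups
#'
#' @param data a [clinical_table()].
#' @param groups vector of group labels aligned with the rows of `data`.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
logrank <- function(data, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0L) || nlevels(groups) < 2L)
    stop("every group needs at least one sample", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(data$time, data$status) ~ groups)
  df <- length(sd_$n) - 1L
  list(chi2 = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Optimal survival cut-point for a continuous marker
#'
#' Scans every distinct marker value inside the [10%, 90%] quantile window
#' as a candidate threshold (split: marker > threshold) and returns the
#' one maximizing the log-rank statistic; ties resolve to the lower
#' threshold.
#'
#' @param data a [clinical_table()] with >= 20 rows.
#' @param marker finite numeric vector aligned with `data`.
#' @return list with `threshold`, `chi2`, `p_value`, and the scanned
#'   candidate table.
#' @export
optimal_cutpoint <- function(data, marker) {
  stopifnot(length(marker) == nrow(data), all(is.finite(marker)))
  if (nrow(data) < 20L) stop("need >= 20 samples for cut-point search", call. = FALSE)
  q <- stats::quantile(marker, c(0.1, 0.9), names = FALSE)
  cand <- sort(unique(marker[marker >= q[1] & marker <= q[2]]))
  cand <- cand[cand < max(marker)]       # 'marker > threshold' must split
  if (length(cand) == 0L)
    stop("no valid cut-point candidates (constant marker?)", call. = FALSE)
  chi2 <- vapply(cand, function(th) {
    g <- marker > th
    if (!any(g) || all(g)) return(NA_real_)
    unname(survival::survdiff(
      survival::Surv(data$time, data$status) ~ g)$chisq)
  }, numeric(1))
  ok <- which(is.finite(chi2))
  if (length(ok) == 0L) stop("no candidate produced a valid split", call. = FALSE)
  best <- ok[which.max(chi2[ok])]        # which.max -> first (lowest threshold)
  list(threshold = cand[best], chi2 = chi2[best],
       p_value = stats::pchisq(chi2[best], 1L, lower.tail = FALSE),
       scan = data.frame(threshold = cand, chi2 = chi2))
}

#' Univariate Cox proportional-hazards fit
#'
#' Newton-Raphson partial-likelihood maximization with Efron tie handling
#' (via `survival::coxph`) and the Wald test.
#'
#' @param data a [clinical_table()] with >= 1 event.
#' @param covariate numeric vector aligned with `data`; must vary.
#' @return list with `beta`, `hr`, `se`, `p_value`.
#' @export
cox_univariate <- function(data, covariate) {
  stopifnot(length(covariate) == nrow(data))
  if (sum(data$status) < 1L) stop("no events", call. = FALSE)
  if (stats::sd(covariate) == 0) stop("covariate is constant", call. = FALSE)
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(data$time, data$status) ~ covariate,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        stop("monotone partial likelihood (perfect separation); ",
             "use a penalized fit", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  list(beta = unname(stats::coef(fit)), hr = unname(exp(stats::coef(fit))),
       se = unname(s$coefficients[, "se(coef)"]),
       p_value = unname(s$coefficients[, "Pr(>|z|)"]))
}

#' Screen genes and fit a penalized Cox risk signature
#'
#' The prognostic-signature pipeline: (1) keep genes with raw median
#' absolute deviation (no consistency constant) above `mad_min`;
#' (2) optionally keep the `top_k` genes most rank-correlated (absolute
#' Spearman) with a per-sample index, the stand-in for co-expression
#' module selection; (3) univariate Cox screen at `p_max`; (4) lasso Cox
#' with `cv_folds`-fold cross-validation, taking lambda at minimum partial
#' likelihood deviance. Nonzero coefficients form the risk model; when a
#' single gene survives screening its unpenalized Cox coefficient is used.
#'
#' @param mat an [expression_matrix()]; columns must cover `data$sample`.
#' @param data a [clinical_table()].
#' @param mad_min MAD filter threshold (default 0.5).
#' @param p_max univariate screen threshold (default 0.05).
#' @param cv_folds cross-validation folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param index optional numeric per-sample index (aligned with
#'   `data$sample`) enabling the correlation pre-filter.
#' @param top_k pre-filter size when `index` is given (default 774).
#' @return A `risk_model`: data.frame (`gene`, `coefficient`) with
#'   attributes `lambda`, `cv_folds`, `seed`, `stage_sizes`.
#' @export
screen_and_fit <- function(mat, data, mad_min = 0.5, p_max = 0.05,
                           cv_folds = 10L, seed = 1L, index = NULL,
                           top_k = 774L) {
  stopifnot(is_expression_matrix(mat))
  miss <- setdiff(data$sample, colnames(mat))
  if (length(miss))
    stop("samples missing from expression matrix: ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  X <- unclass(mat)[, data$sample, drop = FALSE]
  stage_sizes <- c(input = nrow(X))

  mads <- apply(X, 1L, stats::mad, constant = 1)
  X <- X[mads > mad_min, , drop = FALSE]
  stage_sizes["mad_filter"] <- nrow(X)
  if (nrow(X) == 0L) stop("no genes pass the MAD filter", call. = FALSE)

  if (!is.null(index)) {
    stopifnot(length(index) == nrow(data))
    rc <- abs(apply(X, 1L, function(g) stats::cor(g, index, method = "spearman")))
    keep <- utils::head(order(rc, decreasing = TRUE), top_k)
    X <- X[sort(keep), , drop = FALSE]
    stage_sizes["index_prefilter"] <- nrow(X)
  }

  pvals <- apply(X, 1L, function(g) {
    if (stats::sd(g) == 0) return(1)
    tryCatch(cox_univariate(data, g)$p_value, error = function(e) 1)
  })
  X <- X[pvals < p_max, , drop = FALSE]
  stage_sizes["cox_screen"] <- nrow(X)
  if (nrow(X) == 0L)
    stop("no genes pass the univariate Cox screen (stage 'cox_screen')",
         call. = FALSE)

  y <- survival::Surv(data$time, data$status)
  if (nrow(X) == 1L) {
    cf <- stats::setNames(cox_univariate(data, X[1, ])$beta, rownames(X))
    lambda <- NA_real_
  } else {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(t(X), y, family = "cox", alpha = 1,
                            nfolds = cv_folds)
    co <- as.matrix(stats::coef(cv, s = "lambda.min"))
    nz <- co[, 1] != 0
    cf <- stats::setNames(co[nz, 1], rownames(co)[nz])
    lambda <- cv$lambda.min
  }
  stage_sizes["lasso"] <- length(cf)
  if (length(cf) == 0L)
    stop("lasso selected no genes (stage 'lasso')", call. = FALSE)
  structure(data.frame(gene = names(cf), coefficient = unname(cf),
                       stringsAsFactors = FALSE),
            lambda = lambda, cv_folds = cv_folds, seed = seed,
            stage_sizes = stage_sizes,
            class = c("risk_model", "data.frame"))
}

#' Per-sample risk score
#'
#' The linear predictor of the risk model:
#' \eqn{\mathrm{risk} = \sum_g \mathrm{expression}_g \times \mathrm{coefficient}_g}.
#'
#' @param model a `risk_model` (or data.frame with `gene`, `coefficient`).
#' @param mat an [expression_matrix()] containing every model gene.
#' @return named numeric vector of scores, one per sample.
#' @export
risk_score <- function(model, mat) {
  miss <- setdiff(model$gene, rownames(mat))
  if (length(miss))
    stop("model gene(s) missing from matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  drop(crossprod(unclass(mat)[model$gene, , drop = FALSE], model$coefficient))
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs in which the higher-risk sample fails first,
#' with half credit for risk ties. A pair is usable iff the member with
#' the shorter follow-up experienced the event and the two times differ;
#' an optional horizon truncates usable pairs to those whose shorter time
#' is at most `horizon` (a time-dependent variant).
#'
#' @param data a [clinical_table()].
#' @param risk numeric risk scores aligned with `data`.
#' @param horizon optional truncation time.
#' @return concordance in [0, 1].
#' @export
c_index <- function(data, risk, horizon = NULL) {
  stopifnot(length(risk) == nrow(data))
  t_ <- data$time; d <- data$status
  n <- length(t_)
  conc <- comp <- 0
  for (i in seq_len(n)) {
    if (d[i] != 1L) next
    if (!is.null(horizon) && t_[i] > horizon) next
    usable <- t_ > t_[i]
    if (!any(usable)) next
    comp <- comp + sum(usable)
    conc <- conc + sum(risk[i] > risk[usable]) + 0.5 * sum(risk[i] == risk[usable])
  }
  if (comp == 0) stop("no comparable pairs", call. = FALSE)
  conc / comp
}

#' Time-dependent AUC (cumulative/dynamic, IPCW)
#'
#' AUC at horizon `t`: cases are samples with an event by `t`, controls
#' those still under observation after `t`; both are weighted by the
#' inverse of the Kaplan-Meier estimate of the censoring distribution
#' (cases at their own event time, controls at `t`). Without censoring
#' this equals the empirical cumulative/dynamic AUC by direct pair
#' counting.
#'
#' @param data a [clinical_table()].
#' @param risk numeric risk scores aligned with `data`.
#' @param t horizon within follow-up; events before `t` must exist.
#' @return AUC(t) in [0, 1].
#' @export
td_auc <- function(data, risk, t) {
  stopifnot(length(risk) == nrow(data))
  case <- data$time <= t & data$status == 1L
  ctrl <- data$time > t
  if (!any(case)) stop("no events before the horizon", call. = FALSE)
  if (!any(ctrl)) stop("no samples at risk beyond the horizon", call. = FALSE)
  cens_fit <- survival::survfit(
    survival::Surv(data$time, 1L - data$status) ~ 1)
  G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv))
  eps <- 1e-9 * max(data$time)
  wc <- 1 / pmax(G(data$time[case] - eps), 1e-12)   # G at T-
  wk <- rep(1 / pmax(G(t), 1e-12), sum(ctrl))
  rc <- risk[case]; rk <- risk[ctrl]
  num <- 0
  for (i in seq_along(rc))
    num <- num + wc[i] * sum(wk * ((rc[i] > rk) + 0.5 * (rc[i] == rk)))
  num / (sum(wc) * sum(wk))
}

#' Soft-threshold scale-free topology fit
#'
#' For each candidate power beta, gene connectivity is
#' \eqn{k_i = \sum_{j \ne i} |cor(i,j)|^\beta}; connectivities are binned
#' into 10 equal-width bins on log10(k), and the R-squared of the linear
#' fit of log10(bin frequency) on log10(mean bin connectivity) measures
#' how closely the degree distribution follows a power law. The chosen
#' beta is the smallest reaching `r2_min`.
#'
#' @param mat an [expression_matrix()] with >= 50 genes and no constant
#'   gene.
#' @param betas positive integer ladder of candidate powers.
#' @param r2_min scale-free fit threshold (default 0.9).
#' @param n_bins histogram bins (default 10).
#' @return list of class `scale_free_fit` with `table` (beta, r2, slope,
#'   mean_k) and `beta` (chosen power, NA with a warning if none
#'   qualifies).
#' @export
scale_free_fit <- function(mat, betas = 1:10, r2_min = 0.9, n_bins = 10L) {
  stopifnot(is_expression_matrix(mat), all(betas > 0))
  if (nrow(mat) < 50L) stop("need >= 50 genes", call. = FALSE)
  v <- unclass(mat)
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant gene row(s); correlations undefined", call. = FALSE)
  A <- abs(stats::cor(t(v)))
  diag(A) <- 0
  tab <- data.frame(beta = betas, r2 = NA_real_, slope = NA_real_,
                    mean_k = NA_real_)
  for (i in seq_along(betas)) {
    k <- rowSums(A^betas[i])
    tab$mean_k[i] <- mean(k)
    lk <- log10(pmax(k, .Machine$double.xmin))
    brk <- seq(min(lk), max(lk), length.out = n_bins + 1L)
    bin <- cut(lk, brk, include.lowest = TRUE)
    freq <- tabulate(bin, nbins = n_bins)
    km <- tapply(k, bin, mean)
    ok <- freq > 0 & !is.na(km)
    if (sum(ok) < 3L) next
    fit <- stats::lm(log10(freq[ok] / length(k)) ~ log10(km[ok]))
    tab$r2[i] <- summary(fit)$r.squared
    tab$slope[i] <- stats::coef(fit)[2]
  }
  hit <- which(!is.na(tab$r2) & tab$r2 >= r2_min)
  beta <- if (length(hit)) betas[hit[1]] else NA_integer_
  if (is.na(beta))
    warning("no candidate power reaches R^2 >= ", r2_min, call. = FALSE)
  structure(list(table = tab, beta = beta, r2_min = r2_min),
            class = "scale_free_fit")
}

#' Multivariable Cox fit and linear predictor
#'
#' Efron-tie Cox regression on a full-rank covariate matrix; the returned
#' per-sample linear predictor (`sum covariate * coefficient`, uncentered)
#' is the quantity a prognostic nomogram tabulates.
#'
#' @param data a [clinical_table()].
#' @param covariates numeric matrix/data.frame, one row per sample.
#' @return list with `coefficients` (data.frame: term, beta, hr, se,
#'   p_value), `lp` (per-sample linear predictor), `fit`.
#' @export
multivariable_cox <- function(data, covariates) {
  Xc <- as.matrix(covariates)
  stopifnot(nrow(Xc) == nrow(data))
  if (is.null(colnames(Xc))) colnames(Xc) <- paste0("x", seq_len(ncol(Xc)))
  if (qr(Xc)$rank < ncol(Xc))
    stop("covariate matrix is rank-deficient", call. = FALSE)
  fit <- survival::coxph(survival::Surv(data$time, data$status) ~ Xc,
                         ties = "efron")
  s <- summary(fit)$coefficients
  coefs <- data.frame(term = colnames(Xc), beta = unname(stats::coef(fit)),
                      hr = unname(exp(stats::coef(fit))),
                      se = unname(s[, "se(coef)"]),
                      p_value = unname(s[, "Pr(>|z|)"]),
                      stringsAsFactors = FALSE)
  list(coefficients = coefs, lp = drop(Xc %*% stats::coef(fit)), fit = fit)
}
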