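#' One-class logistic regression (OCLR) configuration
#'
#' Controls the elastic-net one-class objective
#' \deqn{f(w) = \frac{1}{n}\sum_i \log(1+e^{-w^\top x_i}) + \lambda_1\|w\|_1
#'       + \frac{\lambda_2}{2}\|w\|_2^2,}
#' i.e. logistic loss with every training sample treated as the positive
#' class and no intercept. Defaults (`l1 = 0`, `l2 = 1`) follow the
#' established one-class stemness-index workflow.
#'
#' @param l1 ridge-free lasso penalty weight, >= 0.
#' @param l2 ridge penalty weight; must be > 0 unless `l1 > 0`.
#' @param tol relative objective-change convergence threshold.
#' @param max_iter maximum iterations.
#' @param seed integer; recorded for provenance (the cold start at w = 0
#'   makes the fit deterministic regardless).
#' @return list of class `oclr_config`.
#' @export
oclr_config <- function(l1 = 0, l2 = 1, tol = 1e-6, max_iter = 1000L, seed = 1L) {
  stopifnot(l1 >= 0, tol > 0, max_iter >= 1)
  if (l2 <= 0 && l1 <= 0)
    stop("l2 must be > 0 unless l1 > 0 (objective otherwise unbounded below)",
         call. = FALSE)
  structure(list(l1 = l1, l2 = l2, tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "oclr_config")
}

# overflow-safe log(1 + exp(z))
softplus <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Evaluate the OCLR objective
#'
#' @param w numeric weight vector (length = genes).
#' @param X numeric genes-by-samples training matrix.
#' @param l1,l2 penalty weights.
#' @return scalar objective value.
#' @export
oclr_objective <- function(w, X, l1 = 0, l2 = 1) {
  s <- drop(crossprod(X, w))
  mean(softplus(-s)) + l1 * sum(abs(w)) + (l2 / 2) * sum(w^2)
}

#' Train the one-class logistic regression model
#'
#' Minimizes the convex OCLR objective over per-gene weights, cold-started
#' at w = 0. With `l1 = 0` the minimizer lies in the span of the training
#' profiles, so the fit runs as a damped Newton iteration in the
#' n-dimensional sample space (exact for any gene count); with `l1 > 0` a
#' monotone proximal-gradient iteration with a Lipschitz step is used.
#'
#' @param train an [expression_matrix()] of the reference-class
#'   (neuroendocrine) samples; expected mean-centered (a warning is issued
#'   if gene means are visibly nonzero).
#' @param cfg an [oclr_config()].
#' @return A `weight_vector`: data.frame with columns `gene`, `weight`, and
#'   attributes `n_train`, `objective`, `trace` (objective per iteration),
#'   `config`.
#' @export
train_oclr <- function(train, cfg = oclr_config()) {
  stopifnot(is_expression_matrix(train), inherits(cfg, "oclr_config"))
  X <- unclass(train)
  n <- ncol(X)
  if (n < 2L) stop("need >= 2 training samples", call. = FALSE)
  # raw log2 expression has gene means of several units; a centered panel
  # (even after subsetting to the reference class) keeps most near zero
  if (stats::median(abs(rowMeans(X))) > 0.5)
    warning("training matrix does not look mean-centered; ",
            "call center_genes() on the panel first", call. = FALSE)

  if (cfg$l1 == 0) {
    fit <- oclr_fit_kernel(X, cfg)
  } else {
    fit <- oclr_fit_prox(X, cfg)
  }
  wv <- data.frame(gene = rownames(X), weight = fit$w, stringsAsFactors = FALSE)
  structure(wv, n_train = n, objective = fit$obj, trace = fit$trace,
            converged = fit$converged, config = cfg,
            class = c("weight_vector", "data.frame"))
}

# l1 = 0: minimize over a in sample space with w = X a, K = X'X.
oclr_fit_kernel <- function(X, cfg) {
  n <- ncol(X)
  K <- crossprod(X)                      # n x n
  a <- rep(0, n)
  obj_a <- function(a) {
    s <- drop(K %*% a)
    mean(softplus(-s)) + (cfg$l2 / 2) * drop(crossprod(a, K %*% a))
  }
  trace <- obj_a(a)
  if (max(abs(K)) == 0)                  # degenerate all-zero training data
    return(list(w = rep(0, nrow(X)), obj = trace, trace = trace, converged = TRUE))
  converged <- FALSE
  ridge <- 1e-10 * mean(diag(K))
  for (it in seq_len(cfg$max_iter)) {
    s <- drop(K %*% a)
    p <- sigmoid(-s)                     # = 1 - sigma(s)
    grad <- drop(K %*% (-p / n + cfg$l2 * a))
    Wd <- (p * sigmoid(s)) / n           # logistic curvature
    H <- K %*% (Wd * K) + cfg$l2 * K
    diag(H) <- diag(H) + ridge
    step <- tryCatch(solve(H, grad), error = function(e) grad / max(diag(H)))
    f_old <- trace[length(trace)]
    t_ <- 1
    repeat {                             # damping keeps the trace monotone
      a_new <- a - t_ * step
      f_new <- obj_a(a_new)
      if (f_new <= f_old || t_ < 1e-12) break
      t_ <- t_ / 2
    }
    if (f_new > f_old) { converged <- TRUE; break }   # no descent direction left
    a <- a_new
    trace <- c(trace, f_new)
    if (abs(f_old - f_new) <= cfg$tol * max(1e-12, abs(f_old))) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("OCLR did not converge in ", cfg$max_iter,
         " iterations; last objectives: ",
         paste(signif(utils::tail(trace, 3), 8), collapse = ", "), call. = FALSE)
  list(w = drop(X %*% a), obj = trace[length(trace)], trace = trace,
       converged = TRUE)
}

# l1 > 0: monotone proximal gradient with fixed Lipschitz step.
oclr_fit_prox <- function(X, cfg) {
  n <- ncol(X)
  p <- nrow(X)
  smax2 <- if (min(dim(X)) <= 400) norm(X, "2")^2 else sum(X^2)  # spectral or Frobenius bound
  L <- cfg$l2 + smax2 / (4 * n)
  if (L <= 0) L <- 1
  step <- 1 / L
  w <- rep(0, p)
  obj <- function(w) oclr_objective(w, X, cfg$l1, cfg$l2)
  trace <- obj(w)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    s <- drop(crossprod(X, w))
    grad <- drop(X %*% (-sigmoid(-s) / n)) + cfg$l2 * w
    w_new <- soft(w - step * grad, step * cfg$l1)
    f_new <- obj(w_new)
    f_old <- trace[length(trace)]
    if (f_new > f_old) { converged <- TRUE; break }
    w <- w_new
    trace <- c(trace, f_new)
    if (abs(f_old - f_new) <= cfg$tol * max(1e-12, abs(f_old))) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("OCLR (l1 > 0) did not converge in ", cfg$max_iter,
         " iterations; last objectives: ",
         paste(signif(utils::tail(trace, 3), 8), collapse = ", "), call. = FALSE)
  list(w = w, obj = trace[length(trace)], trace = trace, converged = TRUE)
}

#' Train the index signature from a labelled cell-line panel
#'
#' Canonical training workflow: the full panel is gene-centered, the
#' reference-class (neuroendocrine) columns are extracted, and the
#' one-class model is fitted on them. Centering before subsetting is what
#' lets the reference-class shift survive into the weights.
#'
#' @param panel an [expression_matrix()] of the full cell-line panel.
#' @param labels vector aligned with the panel columns.
#' @param reference_label label of the reference (positive) class.
#' @param cfg an [oclr_config()].
#' @return A `weight_vector` (see [train_oclr()]).
#' @export
train_index_model <- function(panel, labels, reference_label = "NE",
                              cfg = oclr_config()) {
  stopifnot(length(labels) == ncol(panel))
  ref <- colnames(panel)[labels == reference_label]
  if (length(ref) < 2L)
    stop("need >= 2 reference-class samples", call. = FALSE)
  train_oclr(subset_samples(center_genes(panel), ref), cfg)
}

#' Write / read a trained weight vector as TSV
#'
#' Header comment lines (`#`) carry the training metadata; weights are
#' serialized at full double precision so the round-trip is bit-exact.
#'
#' @param wv a `weight_vector` from [train_oclr()].
#' @param path file path.
#' @return `path` (write) or the restored `weight_vector` (read).
#' @export
write_weights <- function(wv, path) {
  cfg <- attr(wv, "config")
  hdr <- c(sprintf("# n_train=%d", attr(wv, "n_train")),
           sprintf("# objective=%s", format_full(attr(wv, "objective"))),
           sprintf("# l1=%s l2=%s tol=%s max_iter=%d seed=%d",
                   format_full(cfg$l1), format_full(cfg$l2),
                   format_full(cfg$tol), cfg$max_iter, cfg$seed))
  body <- c("gene\tweight",
            paste(wv$gene, vapply(wv$weight, format_full, character(1)), sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  con <- textConnection(body)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, stringsAsFactors = FALSE)
  n_train <- obj <- NA
  for (m in meta) {
    if (grepl("^# n_train=", m)) n_train <- as.integer(sub("^# n_train=", "", m))
    if (grepl("^# objective=", m)) obj <- as.numeric(sub("^# objective=", "", m))
  }
  structure(df, n_train = n_train, objective = obj,
            class = c("weight_vector", "data.frame"))
}

# full-precision decimal rendering (round-trips doubles exactly)
format_full <- function(x) sprintf("%.17g", x)
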