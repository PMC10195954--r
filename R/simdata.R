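#' Synthetic-cohort configuration
#'
#' Defines the study conditions the generator emulates: a two-class
#' cell-line panel (neuroendocrine vs non-neuroendocrine, 50/135 lines as
#' in a CCLE-style lung panel), bulk tumours mixed from the two mean
#' profiles with a latent NE fraction, survival whose log-hazard falls
#' with the NE fraction (high NE, better prognosis) and rises with planted
#' prognostic genes, and per-sample mutation counts increasing with the NE
#' fraction.
#'
#' @param n_ne_lines,n_nonne_lines cell-line counts (defaults 50 / 135).
#' @param n_genes total genes (default 2000).
#' @param n_signature_genes genes up-shifted in NE lines (default 100).
#' @param n_immune_genes genes expressed in the non-NE compartment
#'   (default 100); their bulk abundance falls as the NE fraction rises.
#' @param signature_effect NE shift in log2 units (default 2).
#' @param noise_sd residual log2 noise (default 0.5).
#' @param n_bulk bulk tumour count (default 300).
#' @param ne_frac_a,ne_frac_b Beta parameters of the latent NE fraction
#'   (default Beta(2, 2)).
#' @param fixed_ne_fraction optional scalar/vector overriding the Beta
#'   draw (construction checks).
#' @param hazard_coef_ne log-hazard coefficient of the NE fraction
#'   (default -1: high NE, better prognosis).
#' @param baseline_hazard exponential baseline event rate per day
#'   (default 1/500).
#' @param censor_rate expected censored fraction (default 0.3).
#' @param tmb_base,tmb_ne_slope Poisson mutation-count intercept/slope in
#'   the NE fraction (defaults 100 and 200).
#' @param n_mut_genes size of the mutable gene pool (default 200).
#' @param n_diff_mut_genes planted group-differential mutated genes
#'   (default 10).
#' @param diff_mut_p_high,diff_mut_p_low planted per-sample mutation
#'   probabilities above/below the median NE fraction (0.5 / 0.05).
#' @param n_prognostic_genes planted prognostic genes (default 5).
#' @param prognostic_coefs their log-hazard coefficients (alternating
#'   +/-0.7 by default).
#' @param seed integer RNG seed; every generator output is a deterministic
#'   function of the config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_ne_lines = 50L, n_nonne_lines = 135L,
                       n_genes = 2000L, n_signature_genes = 100L,
                       n_immune_genes = 100L, signature_effect = 2,
                       noise_sd = 0.5, n_bulk = 300L,
                       ne_frac_a = 2, ne_frac_b = 2,
                       fixed_ne_fraction = NULL,
                       hazard_coef_ne = -1, baseline_hazard = 1 / 500,
                       censor_rate = 0.3,
                       tmb_base = 100, tmb_ne_slope = 200,
                       n_mut_genes = 200L, n_diff_mut_genes = 10L,
                       diff_mut_p_high = 0.5, diff_mut_p_low = 0.05,
                       n_prognostic_genes = 5L,
                       prognostic_coefs = 0.7 * c(1, -1)[(seq_len(n_prognostic_genes) + 1) %% 2 + 1],
                       seed = 1L) {
  cfg <- list(n_ne_lines = as.integer(n_ne_lines),
              n_nonne_lines = as.integer(n_nonne_lines),
              n_genes = as.integer(n_genes),
              n_signature_genes = as.integer(n_signature_genes),
              n_immune_genes = as.integer(n_immune_genes),
              signature_effect = signature_effect, noise_sd = noise_sd,
              n_bulk = as.integer(n_bulk),
              ne_frac_a = ne_frac_a, ne_frac_b = ne_frac_b,
              fixed_ne_fraction = fixed_ne_fraction,
              hazard_coef_ne = hazard_coef_ne,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              tmb_base = tmb_base, tmb_ne_slope = tmb_ne_slope,
              n_mut_genes = as.integer(n_mut_genes),
              n_diff_mut_genes = as.integer(n_diff_mut_genes),
              diff_mut_p_high = diff_mut_p_high,
              diff_mut_p_low = diff_mut_p_low,
              n_prognostic_genes = as.integer(n_prognostic_genes),
              prognostic_coefs = prognostic_coefs, seed = as.integer(seed))
  with(cfg, stopifnot(
    n_ne_lines > 0, n_nonne_lines > 0, n_genes > 0, n_bulk > 0,
    n_signature_genes + n_immune_genes + n_prognostic_genes <= n_genes,
    n_diff_mut_genes <= n_mut_genes, n_mut_genes <= n_genes,
    length(prognostic_coefs) == n_prognostic_genes,
    censor_rate >= 0, censor_rate < 1, noise_sd >= 0,
    is.finite(signature_effect), is.finite(hazard_coef_ne)))
  structure(cfg, class = "sim_config")
}

# Seed-deterministic gene architecture shared by panel and bulk generators:
# baseline means, gene roles, mutation pool. Uses its own RNG stream.
sim_architecture <- function(cfg) {
  set.seed(cfg$seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  mu <- stats::runif(cfg$n_genes, 2, 8)
  roles <- sample.int(cfg$n_genes)      # random disjoint role assignment
  sig <- roles[seq_len(cfg$n_signature_genes)]
  imm <- roles[cfg$n_signature_genes + seq_len(cfg$n_immune_genes)]
  prog <- roles[cfg$n_signature_genes + cfg$n_immune_genes +
                seq_len(cfg$n_prognostic_genes)]
  mut_pool <- sort(sample.int(cfg$n_genes, cfg$n_mut_genes))
  diff_mut <- mut_pool[seq_len(cfg$n_diff_mut_genes)]
  # background mutations avoid the planted genes so the planted group
  # contrast is the only mechanism acting on them
  bg_pool <- setdiff(mut_pool, diff_mut)
  mut_wt <- stats::rexp(length(bg_pool)) + 0.1   # skewed background gene usage
  mean_ne <- mu; mean_ne[sig] <- mean_ne[sig] + cfg$signature_effect
  mean_nonne <- mu; mean_nonne[imm] <- mean_nonne[imm] + cfg$signature_effect
  list(genes = genes, mu = mu,
       signature_genes = genes[sig], immune_genes = genes[imm],
       prognostic_genes = genes[prog], sig_idx = sig, imm_idx = imm,
       prog_idx = prog, mut_pool = genes[bg_pool],
       mut_wt = mut_wt / sum(mut_wt), diff_mut_genes = genes[diff_mut],
       mean_ne = mean_ne, mean_nonne = mean_nonne)
}

#' Simulate the two-class cell-line panel
#'
#' Log2-scale Gaussian expression; signature genes shifted up by
#' `signature_effect` in NE lines and immune-compartment genes shifted up
#' in non-NE lines. Deterministic per seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` (an [expression_matrix()], platform
#'   `rnaseq_log2tpm`), `labels` (`"NE"` / `"nonNE"` per column) and
#'   `truth` (the planted gene lists).
#' @export
simulate_cell_panel <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  arch <- sim_architecture(cfg)
  set.seed(cfg$seed + 1L)
  n <- cfg$n_ne_lines + cfg$n_nonne_lines
  labels <- rep(c("NE", "nonNE"), c(cfg$n_ne_lines, cfg$n_nonne_lines))
  base <- cbind(matrix(arch$mean_ne, cfg$n_genes, cfg$n_ne_lines),
                matrix(arch$mean_nonne, cfg$n_genes, cfg$n_nonne_lines))
  vals <- pmax(base + matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd),
                             cfg$n_genes, n), 0)
  dimnames(vals) <- list(arch$genes,
                         sprintf("%s_%03d", ifelse(labels == "NE", "NEL", "NNL"),
                                 seq_len(n)))
  list(expr = expression_matrix(vals, platform = "rnaseq_log2tpm"),
       labels = labels,
       truth = arch[c("signature_genes", "immune_genes", "prognostic_genes",
                      "diff_mut_genes")])
}

#' Simulate a bulk tumour cohort with survival and mutations
#'
#' Each bulk profile is a convex mixture of the panel's mean NE and
#' non-NE profiles at a latent NE fraction `f ~ Beta(a, b)` plus Gaussian
#' noise; prognostic genes additionally carry an independent unit-variance
#' component that enters the log-hazard. Event times are exponential with
#' log-hazard `hazard_coef_ne * f + sum(prognostic_coefs * z)`; a sample
#' is censored with probability `censor_rate`, in which case its observed
#' time is uniform on (0, T). Mutation counts are Poisson in `f` and are
#' scattered over a skewed background gene pool, with planted genes
#' mutated preferentially above the median NE fraction.
#'
#' @param cfg a [sim_config()].
#' @return list with `expr` ([expression_matrix()]), `clinical`
#'   ([clinical_table()]), `maf` (`maf_table`), and `truth` (data.frame
#'   `sample`, `ne_fraction`, `risk_lp`, plus planted-gene attributes
#'   `signature_genes`, `immune_genes`, `prognostic_genes`,
#'   `prognostic_coefs`, `diff_mut_genes`).
#' @export
simulate_bulk_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  arch <- sim_architecture(cfg)
  set.seed(cfg$seed + 2L)
  n <- cfg$n_bulk
  f <- if (is.null(cfg$fixed_ne_fraction)) {
    stats::rbeta(n, cfg$ne_frac_a, cfg$ne_frac_b)
  } else rep_len(cfg$fixed_ne_fraction, n)
  samples <- sprintf("BULK_%04d", seq_len(n))

  vals <- outer(arch$mean_ne, f) + outer(arch$mean_nonne, 1 - f) +
    matrix(stats::rnorm(cfg$n_genes * n, 0, cfg$noise_sd), cfg$n_genes, n)
  z <- matrix(stats::rnorm(cfg$n_prognostic_genes * n), ncol = n)
  if (cfg$n_prognostic_genes > 0) vals[arch$prog_idx, ] <- vals[arch$prog_idx, ] + z
  vals <- pmax(vals, 0)
  dimnames(vals) <- list(arch$genes, samples)
  expr <- expression_matrix(vals, platform = "rnaseq_log2tpm")

  lp <- cfg$hazard_coef_ne * f +
    if (cfg$n_prognostic_genes > 0) drop(crossprod(z, cfg$prognostic_coefs)) else 0
  t_event <- stats::rexp(n, rate = cfg$baseline_hazard * exp(lp))
  censored <- stats::rbinom(n, 1L, cfg$censor_rate) == 1L
  time <- ifelse(censored, t_event * stats::runif(n), t_event)
  clinical <- clinical_table(data.frame(sample = samples, time = time,
                                        status = as.integer(!censored),
                                        stringsAsFactors = FALSE))

  counts <- stats::rpois(n, cfg$tmb_base + cfg$tmb_ne_slope * f)
  high <- f > stats::median(f)
  maf <- sim_maf(cfg, arch, samples, counts, high)

  truth <- data.frame(sample = samples, ne_fraction = f, risk_lp = lp,
                      stringsAsFactors = FALSE)
  attr(truth, "signature_genes") <- arch$signature_genes
  attr(truth, "immune_genes") <- arch$immune_genes
  attr(truth, "prognostic_genes") <- arch$prognostic_genes
  attr(truth, "prognostic_coefs") <- cfg$prognostic_coefs
  attr(truth, "diff_mut_genes") <- arch$diff_mut_genes
  list(expr = expr, clinical = clinical, maf = maf, truth = truth)
}

#' Simulate a co-expression matrix with scale-free connectivity
#'
#' Builds gene vectors \eqn{x_i = a_i u + \sqrt{1-a_i^2}\, v_i} from an
#' exactly orthonormal, centered basis, so the sample correlation matrix
#' is exactly \eqn{a_i a_j}. Loadings follow a stratified power-law
#' density (\eqn{p(a) \propto a^{-\eta}}), which makes the connectivity
#' \eqn{k_i = \sum_{j\ne i}|cor|^\beta} power-law distributed at every
#' soft-threshold power: a hub structure with a few highly connected
#' genes and many peripheral ones.
#'
#' @param n_genes number of genes (default 300).
#' @param n_samples number of samples; must exceed `n_genes + 1`
#'   (default 320).
#' @param a_min,a_max loading range (defaults 0.25, 0.95).
#' @param eta power-law exponent of the loading density (default 5).
#' @param seed RNG seed for the orthonormal basis.
#' @return an [expression_matrix()].
#' @export
simulate_scale_free <- function(n_genes = 300L, n_samples = 320L,
                                a_min = 0.25, a_max = 0.95, eta = 5,
                                seed = 1L) {
  stopifnot(n_samples > n_genes + 1L, a_min > 0, a_max < 1, eta > 1)
  set.seed(seed)
  q <- (seq_len(n_genes) - 0.5) / n_genes
  e <- eta - 1
  a <- (a_min^(-e) - q * (a_min^(-e) - a_max^(-e)))^(-1 / e)
  Z <- cbind(1, matrix(stats::rnorm(n_samples * (n_genes + 1L)), n_samples))
  Q <- qr.Q(qr(Z))[, -1, drop = FALSE]  # orthonormal and centered
  u <- Q[, 1]
  V <- Q[, -1, drop = FALSE]
  g <- t(u %o% a + V %*% diag(sqrt(1 - a^2)))
  dimnames(g) <- list(sprintf("HUB%04d", seq_len(n_genes)),
                      sprintf("S%04d", seq_len(n_samples)))
  expression_matrix(5 + g, platform = "rnaseq_log2tpm")
}

# six pyrimidine-reference classes with a C>A-dominant spectrum
SNV_CLASS_P <- c("C>A" = 0.35, "C>G" = 0.10, "C>T" = 0.25,
                 "T>A" = 0.08, "T>C" = 0.15, "T>G" = 0.07)

sim_maf <- function(cfg, arch, samples, counts, high) {
  recs <- vector("list", length(samples) + 1L)
  for (i in seq_along(samples)) {
    k <- counts[i]
    if (k == 0L) k <- 1L                # keep every sample present in the MAF
    gene <- sample(arch$mut_pool, k, replace = TRUE, prob = arch$mut_wt)
    vt <- sample(c("SNP", "INS", "DEL"), k, replace = TRUE,
                 prob = c(0.90, 0.05, 0.05))
    cls <- sample(names(SNV_CLASS_P), k, replace = TRUE, prob = SNV_CLASS_P)
    ref <- substr(cls, 1L, 1L)
    alt <- substr(cls, 3L, 3L)
    flip <- stats::runif(k) < 0.5       # report half on the purine strand
    ref[flip] <- COMPLEMENT[ref[flip]]
    alt[flip] <- COMPLEMENT[alt[flip]]
    ref[vt == "INS"] <- "-"
    alt[vt == "INS"] <- "AT"
    ref[vt == "DEL"] <- "CT"
    alt[vt == "DEL"] <- "-"
    vc <- ifelse(vt == "INS", "Frame_Shift_Ins",
          ifelse(vt == "DEL", "Frame_Shift_Del",
                 sample(c("Missense_Mutation", "Silent", "Nonsense_Mutation"),
                        k, replace = TRUE, prob = c(0.78, 0.12, 0.10))))
    recs[[i]] <- data.frame(
      Hugo_Symbol = gene, Tumor_Sample_Barcode = samples[i],
      Variant_Classification = vc, Variant_Type = vt,
      Reference_Allele = ref, Tumor_Seq_Allele2 = alt,
      Chromosome = as.character(sample.int(22L, k, replace = TRUE)),
      Start_Position = sample.int(100000000L, k, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  # planted group-differential genes
  p <- ifelse(high, cfg$diff_mut_p_high, cfg$diff_mut_p_low)
  extra <- list()
  for (g in arch$diff_mut_genes) {
    hit <- which(stats::runif(length(samples)) < p)
    if (length(hit))
      extra[[g]] <- data.frame(
        Hugo_Symbol = g, Tumor_Sample_Barcode = samples[hit],
        Variant_Classification = "Missense_Mutation", Variant_Type = "SNP",
        Reference_Allele = "C", Tumor_Seq_Allele2 = "A",
        Chromosome = "1",
        Start_Position = sample.int(100000000L, length(hit), replace = TRUE),
        stringsAsFactors = FALSE)
  }
  maf_table(do.call(rbind, c(recs[lengths(recs) > 0], extra)))
}
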