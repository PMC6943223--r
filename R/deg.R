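#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over genes of
#' `count_ij / g_i`, where `g_i` is the geometric mean of gene i across
#' all samples; only genes with strictly positive counts in every sample
#' enter the median. No further rescaling is applied.
#'
#' @param cm a [count_matrix()].
#' @return Named positive numeric vector of size factors (one per
#'   sample).
#' @export
estimate_size_factors <- function(cm) {
  size_factors_matrix(cm$counts)
}

# the estimator on a bare matrix; conditions play no role here
size_factors_matrix <- function(counts) {
  loggeo <- rowMeans(log(counts))
  usable <- is.finite(loggeo)          # genes positive in all samples
  if (!any(usable))
    stop2("cannot estimate size factors: no gene has strictly ",
          "positive counts in every sample")
  sf <- apply(counts[usable, , drop = FALSE], 2, function(x)
    exp(stats::median(log(x) - loggeo[usable])))
  sf
}

#' Per-gene negative-binomial dispersion
#'
#' Method-of-moments on normalized counts pooled within condition:
#' `alpha_raw = (v - m) / m^2` with `m` the pooled mean and `v` the
#' within-condition pooled variance. Because the raw per-gene estimate
#' is extremely noisy at small replicate numbers, a mean-dispersion
#' trend `alpha(m) = a0 + a1/m` is fitted across genes and, under the
#' default `"maximum"` sharing, each gene is assigned the larger of its
#' raw estimate and the fitted value — the conservative choice the
#' classical NB exact-test workflow uses. All estimates are floored at
#' `floor`.
#'
#' @param cm a [count_matrix()].
#' @param sf size factors from [estimate_size_factors()].
#' @param floor lower bound avoiding degenerate zero-variance genes.
#' @param sharing `"maximum"` (default), `"gene-est"` (raw per-gene
#'   only) or `"fitted"` (trend only).
#' @return Named non-negative numeric vector of dispersions, with
#'   attributes `raw` (per-gene MoM) and `trend_coef` (a0, a1).
#' @export
estimate_dispersion <- function(cm, sf = estimate_size_factors(cm),
                                floor = 1e-8,
                                sharing = c("maximum", "gene-est",
                                            "fitted")) {
  sharing <- match.arg(sharing)
  norm <- sweep(cm$counts, 2, sf, "/")
  m <- rowMeans(norm)
  lv <- cm_condition_levels(cm)
  a <- norm[, cm$condition == lv[1], drop = FALSE]
  b <- norm[, cm$condition == lv[2], drop = FALSE]
  ssq <- rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)
  v <- ssq / (ncol(a) + ncol(b) - 2)
  raw <- ifelse(m > 0, (v - m) / m^2, 0)

  use <- is.finite(raw) & raw > 0 & m > 0
  co <- c(0, 0)
  if (sum(use) >= 10) {
    fit <- stats::lm.fit(cbind(1, 1 / m[use]), raw[use])
    co <- pmax(fit$coefficients, 0)
  } else if (sharing != "gene-est") {
    co <- c(max(stats::median(raw[use]), 0), 0)   # few genes: flat trend
  }
  trend <- co[1] + co[2] / pmax(m, .Machine$double.eps)

  disp <- switch(sharing,
                 maximum = pmax(raw, trend),
                 `gene-est` = raw,
                 fitted = trend)
  disp <- pmax(disp, floor)
  names(disp) <- rownames(cm$counts)
  attr(disp, "raw") <- stats::setNames(pmax(raw, 0),
                                       rownames(cm$counts))
  attr(disp, "trend_coef") <- stats::setNames(co, c("a0", "a1"))
  disp
}

#' Exact conditional NB test for a two-condition comparison
#'
#' Tests whether the condition count sums `k_a`, `k_b` are compatible
#' with a common expression level. Conditional on the total
#' `T = k_a + k_b`, the two-sided p-value sums the probabilities of all
#' splits `(a, T - a)` no more likely than the observed one:
#' `p = sum_{P(a, T-a) <= P(k_a, k_b)} P(a, T-a) / sum_a P(a, T-a)`,
#' where `P` is the product of two NB pmfs with the supplied means and
#' variances (Poisson when variance <= mean). For totals above
#' `max_total` the enumeration is replaced by a Gaussian approximation
#' to the conditional law of `k_a` (flagged in the `approx` attribute).
#'
#' @param k_a,k_b observed condition sums (non-negative integers).
#' @param mu_a,mu_b null expected condition sums.
#' @param var_a,var_b null variances of the condition sums
#'   (`mu + alpha_sum * mu^2` for an NB sum).
#' @param max_total largest total enumerated exactly.
#' @return p-value in [0, 1]; attribute `approx` is TRUE when the
#'   Gaussian fallback was used.
#' @export
nb_exact_test <- function(k_a, k_b, mu_a, mu_b, var_a, var_b,
                          max_total = 1e5) {
  assert_scalar_number(k_a, "k_a", min = 0, integer = TRUE)
  assert_scalar_number(k_b, "k_b", min = 0, integer = TRUE)
  assert_scalar_number(mu_a, "mu_a", min = 0)
  assert_scalar_number(mu_b, "mu_b", min = 0)
  total <- k_a + k_b
  if (total == 0) return(structure(1, approx = FALSE))

  if (total > max_total) {
    # Gaussian approximation to k_a | total
    w <- var_a / (var_a + var_b)
    m_c <- mu_a + (total - mu_a - mu_b) * w
    s_c <- sqrt(var_a * var_b / (var_a + var_b))
    p <- 2 * min(stats::pnorm(k_a + 0.5, m_c, s_c),
                 stats::pnorm(k_a - 0.5, m_c, s_c, lower.tail = FALSE))
    return(structure(min(1, max(p, 0)), approx = TRUE))
  }

  a <- 0:total
  lp <- nb_logpmf(a, mu_a, var_a) + nb_logpmf(total - a, mu_b, var_b)
  pr <- exp(lp - max(lp))
  p_obs <- pr[k_a + 1L]
  p <- sum(pr[pr <= p_obs * (1 + 1e-7)]) / sum(pr)
  structure(min(1, max(p, 0)), approx = FALSE)
}

# log pmf of an NB with given mean/variance; Poisson when var <= mean
nb_logpmf <- function(x, mu, v) {
  if (mu == 0) return(ifelse(x == 0, 0, -Inf))
  if (v > mu * (1 + 1e-8))
    stats::dnbinom(x, mu = mu, size = mu^2 / (v - mu), log = TRUE)
  else
    stats::dpois(x, mu, log = TRUE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `q_(i) = min_(j >= i) p_(j) * m / j`,
#' clamped at 1 and returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Vector of q-values of the same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop2("p-values must be numbers in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression screen
#'
#' Composes the full DESeq-style screen: genes with zero counts in all
#' samples are dropped (and listed in the `dropped_genes` attribute),
#' size factors are estimated by median-of-ratios, per-gene dispersions
#' by moment estimation with trend sharing, each gene is tested with the
#' exact conditional NB test on its condition sums under the pooled
#' expression level, p-values are BH-adjusted, and genes are called
#' `up` / `down` / `ns` by the dual threshold
#' `fdr <= fdr_max & |log2fc| >= lfc_min`. The fold change is
#' `log2((mean_B + pseudocount) / (mean_A + pseudocount))` on normalized
#' condition means, so condition B (treatment) is compared against A
#' (control).
#'
#' @param cm a [count_matrix()].
#' @param lfc_min minimum absolute log2 fold change (default 0.585,
#'   i.e. 1.5-fold).
#' @param fdr_max FDR cutoff (default 0.05).
#' @param pseudocount added to both normalized means before the ratio.
#' @param dispersion_floor,dispersion_sharing passed to
#'   [estimate_dispersion()].
#' @param max_total passed to [nb_exact_test()].
#' @return A data.frame of class `deg_table` with columns `gene`,
#'   `base_mean_A`, `base_mean_B`, `log2fc`, `p_value`, `fdr`, `call`;
#'   attributes `metadata` (thresholds, sidedness, dispersion mode,
#'   number of Gaussian-fallback genes), `dropped_genes`, and
#'   `size_factors`.
#' @export
call_degs <- function(cm, lfc_min = 0.585, fdr_max = 0.05,
                      pseudocount = 1, dispersion_floor = 1e-8,
                      dispersion_sharing = "maximum",
                      max_total = 1e5) {
  assert_scalar_number(lfc_min, "lfc_min", min = 0)
  assert_scalar_number(fdr_max, "fdr_max", min = 0, max = 1)
  nonzero <- rowSums(cm$counts) > 0
  dropped <- rownames(cm$counts)[!nonzero]
  if (!all(nonzero))
    cm <- count_matrix(cm$counts[nonzero, , drop = FALSE],
                       cm$condition)
  sf <- estimate_size_factors(cm)
  disp <- estimate_dispersion(cm, sf, floor = dispersion_floor,
                              sharing = dispersion_sharing)
  lv <- cm_condition_levels(cm)
  in_a <- cm$condition == lv[1]
  norm <- sweep(cm$counts, 2, sf, "/")
  mean_a <- rowMeans(norm[, in_a, drop = FALSE])
  mean_b <- rowMeans(norm[, !in_a, drop = FALSE])
  q0 <- rowMeans(norm)                     # pooled expression level
  sfa <- sf[in_a]; sfb <- sf[!in_a]
  k_a <- rowSums(cm$counts[, in_a, drop = FALSE])
  k_b <- rowSums(cm$counts[, !in_a, drop = FALSE])

  ng <- nrow(cm$counts)
  p <- numeric(ng)
  n_approx <- 0L
  for (i in seq_len(ng)) {
    mu_a <- q0[i] * sum(sfa)
    mu_b <- q0[i] * sum(sfb)
    v_a <- mu_a + disp[i] * q0[i]^2 * sum(sfa^2)
    v_b <- mu_b + disp[i] * q0[i]^2 * sum(sfb^2)
    p_i <- nb_exact_test(k_a[i], k_b[i], mu_a, mu_b, v_a, v_b,
                         max_total = max_total)
    if (attr(p_i, "approx")) n_approx <- n_approx + 1L
    p[i] <- p_i
  }
  fdr <- bh_adjust(p)
  log2fc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  call <- ifelse(fdr <= fdr_max & log2fc >= lfc_min, "up",
                 ifelse(fdr <= fdr_max & log2fc <= -lfc_min, "down",
                        "ns"))
  out <- data.frame(gene = rownames(cm$counts),
                    base_mean_A = mean_a, base_mean_B = mean_b,
                    log2fc = log2fc, p_value = p, fdr = fdr,
                    call = call, row.names = NULL)
  class(out) <- c("deg_table", "data.frame")
  attr(out, "metadata") <- list(
    lfc_min = lfc_min, fdr_max = fdr_max, pseudocount = pseudocount,
    test = "exact conditional NB, two-sided",
    dispersion_sharing = dispersion_sharing,
    dispersion_floor = dispersion_floor,
    n_gaussian_fallback = n_approx,
    condition_A = lv[1], condition_B = lv[2])
  attr(out, "dropped_genes") <- dropped
  attr(out, "size_factors") <- sf
  out
}

#' Write / read a DEG table as TSV
#' @param degs a `deg_table`.
#' @param path file path.
#' @name deg_io
#' @export
write_deg_table <- function(degs, path) {
  write_tsv(as.data.frame(degs), path)
}

#' @rdname deg_io
#' @export
read_deg_table <- function(path) {
  out <- read_tsv(path)
  class(out) <- c("deg_table", "data.frame")
  out
}
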