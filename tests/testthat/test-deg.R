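test_that("size factors match the median-of-ratios definition", {
  sf <- difnet:::size_factors_matrix
  # identical columns -> (1, 1)
  expect_equal(unname(sf(cbind(c(5, 10, 20), c(5, 10, 20)))),
               c(1, 1))
  # doubled column -> (1/sqrt(2), sqrt(2))
  expect_equal(unname(sf(cbind(c(5, 10, 20), c(10, 20, 40)))),
               c(1 / sqrt(2), sqrt(2)))
  # hand-evaluated 3 x 2 case: per-gene ratios to the geometric mean
  m <- cbind(c(10, 30, 100), c(20, 30, 50))
  geo <- sqrt(m[, 1] * m[, 2])
  expected <- c(median(m[, 1] / geo), median(m[, 2] / geo))
  expect_equal(unname(sf(m)), expected)
  # and through the count-matrix interface
  m4 <- cbind(c(5, 10, 20), c(5, 10, 20), c(10, 20, 40),
              c(10, 20, 40))
  expect_equal(unname(estimate_size_factors(make_cm(m4))),
               c(1 / sqrt(2), 1 / sqrt(2), sqrt(2), sqrt(2)))
})

test_that("size factors fail loudly without an all-positive gene", {
  cm <- make_cm(cbind(c(0, 5), c(3, 0), c(1, 1), c(2, 2)),
                condition = c("A", "A", "B", "B"))
  cm$counts[, 3:4] <- cbind(c(0, 1), c(1, 0))
  expect_error(estimate_size_factors(cm), "strictly positive")
})

test_that("scaling one sample scales its size factor equivariantly", {
  # multiplying sample 3 by c multiplies s_3 by c relative to every
  # other sample (the per-gene geometric means absorb a common
  # c^(1/n), so only the ratios are scale-free)
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(rpois(60, 50) + 1, nrow = 10)
    sf0 <- estimate_size_factors(make_cm(m))
    m2 <- m
    m2[, 3] <- m[, 3] * 3   # integer multiplier keeps counts integral
    sf1 <- estimate_size_factors(make_cm(m2))
    expect_equal(unname(sf1[3] / sf1[-3]),
                 unname(3 * sf0[3] / sf0[-3]), tolerance = 1e-12)
  }
})

test_that("size factors agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(37)
  m <- matrix(rnbinom(200, mu = 80, size = 10) + 1, nrow = 20)
  cm <- make_cm(m, condition = rep(c("A", "B"), each = 5))
  expect_equal(unname(estimate_size_factors(cm)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("dispersion estimation clamps, recovers, and shrinks", {
  # zero-variance gene clamps to the floor
  cm <- make_cm(rbind(rep(7, 6), c(3, 6, 9, 12, 9, 6)))
  disp <- estimate_dispersion(cm, sf = setNames(rep(1, 6),
                                                colnames(cm$counts)),
                              sharing = "gene-est")
  expect_equal(unname(disp[1]), 1e-8)
  # NB(mu = 100, alpha = 0.2), n = 50/condition: moment recovery
  set.seed(41)
  m <- matrix(rnbinom(200 * 100, mu = 100, size = 5), nrow = 200)
  cm2 <- make_cm(m, condition = rep(c("A", "B"), each = 50))
  d2 <- estimate_dispersion(cm2)
  expect_lt(abs(median(d2) - 0.2) / 0.2, 0.5)
  expect_lt(abs(median(attr(d2, "raw")) - 0.2) / 0.2, 0.5)
  # Poisson gene: estimate approaches the floor for most genes
  set.seed(43)
  mp <- matrix(rpois(100 * 400, 100), nrow = 100)
  cmp <- make_cm(mp, condition = rep(c("A", "B"), each = 200))
  dp <- estimate_dispersion(cmp, sharing = "gene-est")
  expect_lt(median(dp), 0.005)
})

test_that("the exact NB test matches enumeration oracles", {
  # balanced observed split at equal means is the mode -> p = 1
  expect_equal(as.numeric(nb_exact_test(10, 10, 10, 10, 30, 30)), 1)
  # T = 4, Poisson both sides: equals the exact binomial two-sided p
  for (ka in 0:4) {
    p <- nb_exact_test(ka, 4 - ka, 2, 2, 2, 2)
    expect_equal(as.numeric(p),
                 binom.test(ka, 4, 0.5)$p.value, tolerance = 1e-12)
  }
  # T = 20, mu = 10, alpha = 0.1 each side, observed (18, 2)
  v <- 10 + 0.1 * 100
  expect_equal(as.numeric(nb_exact_test(18, 2, 10, 10, v, v)),
               oracle_nb_exact(18, 2, 10, 10, v, v),
               tolerance = 1e-12)
  # random unbalanced configurations vs the oracle
  set.seed(47)
  for (i in 1:25) {
    mu_a <- runif(1, 2, 30); mu_b <- runif(1, 2, 30)
    al <- runif(1, 0, 0.3)
    va <- mu_a + al * mu_a^2; vb <- mu_b + al * mu_b^2
    ka <- rpois(1, mu_a); kb <- rpois(1, mu_b)
    expect_equal(as.numeric(nb_exact_test(ka, kb, mu_a, mu_b,
                                          va, vb)),
                 oracle_nb_exact(ka, kb, mu_a, mu_b, va, vb),
                 tolerance = 1e-10)
    # label symmetry
    expect_equal(as.numeric(nb_exact_test(ka, kb, mu_a, mu_b,
                                          va, vb)),
                 as.numeric(nb_exact_test(kb, ka, mu_b, mu_a,
                                          vb, va)),
                 tolerance = 1e-12)
  }
  expect_error(nb_exact_test(1.5, 2, 3, 3, 4, 4), "whole number")
})

test_that("the Gaussian fallback engages above the enumeration cap", {
  p <- nb_exact_test(600, 400, 500, 500, 800, 800, max_total = 100)
  expect_true(attr(p, "approx"))
  expect_lte(as.numeric(p), 1)
  # and roughly tracks the exact enumeration for a large-ish total
  pe <- nb_exact_test(600, 400, 500, 500, 800, 800)
  expect_false(attr(pe, "approx"))
  expect_lt(abs(log10(as.numeric(p)) - log10(as.numeric(pe))), 1)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  set.seed(53)
  for (m in c(1, 2, 10, 100)) {
    p <- runif(m)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))          # monotone step-up property
  }
  expect_error(bh_adjust(c(0.2, 1.3)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.2, -0.1)), "\\[0, 1\\]")
})

test_that("calls implement the dual threshold and drop all-zero genes", {
  set.seed(59)
  m <- matrix(rnbinom(400 * 6, mu = 100, size = 20), nrow = 400)
  m[1:30, 4:6] <- matrix(rnbinom(30 * 3, mu = 400, size = 20), 30)
  m[7, ] <- 0                         # all-zero gene
  cm <- make_cm(m)
  degs <- call_degs(cm)
  expect_equal(attr(degs, "dropped_genes"), "g07")
  expect_equal(nrow(degs), 399)
  expect_identical(degs$call == "up",
                   degs$fdr <= 0.05 & degs$log2fc >= 0.585)
  expect_identical(degs$call == "down",
                   degs$fdr <= 0.05 & degs$log2fc <= -0.585)
  expect_true(all(degs$fdr >= degs$p_value))
  # direction convention: B (treatment) over A -> planted gains are up
  expect_gt(sum(degs$call[1:29] == "up"), 20)
  # lfc threshold binds independently of the fdr threshold
  strict <- call_degs(cm, lfc_min = 10)
  expect_true(all(strict$call == "ns"))
})

test_that("detection is monotone in the planted effect size", {
  detected <- vapply(c(0.8, 1.2, 2), function(lfc) {
    gen <- generate_counts(simulation_config(
      n_genes = 600, deg_fraction = 0.1, lfc_magnitude = lfc,
      n_modules = 0, seed = 61))
    degs <- call_degs(gen$cm)
    truth <- c(gen$truth$deg_ids_up, gen$truth$deg_ids_down)
    length(intersect(degs$gene[degs$call != "ns"], truth))
  }, numeric(1))
  expect_true(all(diff(detected) >= 0))
})
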