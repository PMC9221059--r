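two_group_matrix <- function(tumor, healthy, proteins = NULL) {
  nt <- ncol(tumor); nh <- ncol(healthy)
  v <- cbind(tumor, healthy)
  if (is.null(proteins)) proteins <- sprintf("P%03d", seq_len(nrow(v)))
  dimnames(v) <- list(proteins,
                      c(sprintf("T%02d", seq_len(nt)),
                        sprintf("H%02d", seq_len(nh))))
  expression_matrix(v, rep(c("tumor", "healthy"), c(nt, nh)))
}

test_that("two-group fit reproduces hand-computed contrasts", {
  m <- two_group_matrix(matrix(c(2, 2, 1, 3), 2, 2, byrow = TRUE),
                        matrix(c(1, 1, 0, 2), 2, 2, byrow = TRUE))
  fit <- fit_two_group(m)
  expect_equal(fit$lfc, c(1, 1))
  expect_equal(fit$s2, c(0, 2))  # pooled: (2 + 2) / 2 for the second row
  expect_equal(attr(fit, "df_resid"), 2)
  # identical group means give zero effect
  m0 <- two_group_matrix(matrix(c(1, 3), 1), matrix(c(0, 4), 1))
  expect_equal(fit_two_group(m0)$lfc, 0)
  expect_error(fit_two_group(two_group_matrix(matrix(1:4, 1),
                                              matrix(1, 1, 1))),
               "2 samples")
})

test_that("hyperparameter estimation recovers a known variance prior", {
  set.seed(5)
  d0 <- 4; s0 <- 1; df <- 10
  s2 <- s0 * (rchisq(5000, df) / df) / (rchisq(5000, d0) / d0)
  h <- estimate_hyperparams(s2, df)
  expect_gte(h$d0, 3); expect_lte(h$d0, 5)
  expect_gte(h$s0_sq, 0.9); expect_lte(h$s0_sq, 1.1)
  # homogeneous variances give an infinite prior
  h_inf <- estimate_hyperparams(rep(2, 100), 10)
  expect_identical(h_inf$d0, Inf)
  expect_equal(h_inf$s0_sq, 2, tolerance = 0.2)
  expect_error(estimate_hyperparams(rep(1, 5), 10), "10")
})

test_that("trigamma inversion matches a bisection oracle and is monotone", {
  ys <- c(0.01, 0.1, 0.5, 2, 10)
  ours <- pcnet:::trigamma_inverse(ys)
  oracle <- vapply(ys, trigamma_inverse_bisect, numeric(1))
  expect_equal(ours, oracle, tolerance = 1e-6)
  # larger spread of log-variances -> smaller prior df
  d0_of <- function(evar, df = 10) {
    2 * pcnet:::trigamma_inverse(evar - trigamma(df / 2))
  }
  expect_true(all(diff(d0_of(trigamma(5) + c(0.5, 1, 2, 4))) < 0))
})

test_that("moderated t matches the stated formula and its limit cases", {
  # hand case: posterior variance 1, t = 1 / sqrt(2/3), 8 df
  h <- structure(list(d0 = 4, s0_sq = 1), class = "ebayes_hyper")
  r <- moderated_t(lfc = 1, s2 = 1, df_resid = 4, hyper = h, n1 = 3, n2 = 3)
  expect_equal(r$t_mod, 1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$p, 2 * pt(-1 / sqrt(2 / 3), df = 8), tolerance = 1e-12)
  # d0 = 0: ordinary pooled two-sample t
  set.seed(1)
  x <- matrix(rnorm(40), 4, 10)
  m <- two_group_matrix(x[, 1:5], x[, 6:10])
  fit <- fit_two_group(m)
  h0 <- structure(list(d0 = 0, s0_sq = 1), class = "ebayes_hyper")
  r0 <- moderated_t(fit$lfc, fit$s2, 8, h0, 5, 5)
  tt <- apply(x, 1, function(row) {
    t.test(row[1:5], row[6:10], var.equal = TRUE)$statistic
  })
  expect_equal(r0$t_mod, unname(tt), tolerance = 1e-10)
  # d0 = Inf: fixed-variance z-like statistic
  hinf <- structure(list(d0 = Inf, s0_sq = 2), class = "ebayes_hyper")
  rinf <- moderated_t(fit$lfc, fit$s2, 8, hinf, 5, 5)
  expect_equal(rinf$t_mod, fit$lfc / sqrt(2 * (1 / 5 + 1 / 5)),
               tolerance = 1e-12)
  expect_equal(rinf$p, 2 * pnorm(-abs(rinf$t_mod)), tolerance = 1e-12)
  # moderated |t| lies between the two limits
  hm <- structure(list(d0 = 3, s0_sq = median(fit$s2)),
                  class = "ebayes_hyper")
  rm_ <- moderated_t(fit$lfc, fit$s2, 8, hm, 5, 5)
  lo <- pmin(abs(r0$t_mod), abs(fit$lfc / sqrt(hm$s0_sq * 2 / 5)))
  hi <- pmax(abs(r0$t_mod), abs(fit$lfc / sqrt(hm$s0_sq * 2 / 5)))
  expect_true(all(abs(rm_$t_mod) >= lo - 1e-12 &
                  abs(rm_$t_mod) <= hi + 1e-12))
})

test_that("moderated t agrees with an independent moderation implementation", {
  skip_if_not_installed("limma")
  set.seed(42)
  ds <- generate_dataset(synthetic_config(n_proteins = 300, n_tumor = 20,
                                          n_healthy = 10, n_modules = 1,
                                          submodules_per_module = 1,
                                          module_loading = 0, noise_sd = 1,
                                          de_fraction = 0.2, de_effect = 1,
                                          missing_rate = 0, seed = 42))
  de <- de_analysis(ds$matrix)
  design <- cbind(1, as.integer(ds$matrix$group == "tumor"))
  lf <- limma::eBayes(limma::lmFit(ds$matrix$values, design))
  expect_equal(de$t_mod, unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(de$p, unname(lf$p.value[, 2]), tolerance = 1e-6)
  h <- attr(de, "hyper")
  expect_equal(h$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(h$s0_sq, lf$s2.prior, tolerance = 1e-6)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.07), 0.07)
  p <- c(0.001, 0.02, 0.9)
  expect_equal(bh_adjust(p), c(0.003, 0.03, 0.9))
  set.seed(3)
  p50 <- runif(50)
  q <- bh_adjust(p50)
  expect_true(all(q >= p50) && all(q <= 1))
  expect_true(all(diff(q[order(p50)]) >= 0))  # monotone in p-rank
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("p-values are calibrated on null data and FDR is controlled", {
  # type-I error on a fully null synthetic matrix
  ds <- generate_dataset(synthetic_config(n_proteins = 5000, n_tumor = 100,
                                          n_healthy = 3, n_modules = 1,
                                          submodules_per_module = 1,
                                          module_loading = 0, noise_sd = 1,
                                          de_fraction = 0, missing_rate = 0,
                                          seed = 21))
  de <- de_analysis(ds$matrix)
  expect_true(abs(mean(de$p < 0.05) - 0.05) <= 0.01)
  # realized false-discovery proportion at q < 0.05
  ds2 <- generate_dataset(synthetic_config(n_proteins = 2000, n_tumor = 100,
                                           n_healthy = 3, n_modules = 1,
                                           submodules_per_module = 1,
                                           module_loading = 0, noise_sd = 1,
                                           de_fraction = 0.2, de_effect = 2,
                                           missing_rate = 0, seed = 22))
  de2 <- de_analysis(ds2$matrix)
  null_protein <- ds2$truth$de_sign[match(de2$protein,
                                          ds2$truth$protein)] == 0
  disc <- de2$q < 0.05
  expect_gt(sum(disc), 100)  # the planted effects are found
  expect_lte(sum(disc & null_protein) / max(1, sum(disc)), 0.10)
  # q >= p and sign convention
  expect_true(all(de2$q >= de2$p))
  expect_identical(de2$sign, ifelse(de2$lfc >= 0, 1L, -1L))
})
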