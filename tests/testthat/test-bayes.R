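test_that("conjugate posterior matches limits and hand linear algebra", {
  # one study A vs B anchored at A: d_B = -y; nearly flat prior
  net <- mk_network("A", "B", -0.5, 0.2)
  post <- conjugate_fixed_posterior(net, prior_variance = 1e12)
  expect_identical(names(post$mean), "B")
  expect_equal(unname(post$mean), 0.5, tolerance = 1e-6)
  expect_equal(unname(post$cov[1, 1]), 0.04, tolerance = 1e-4)
  # chain A-B-C with unit se: var(d_C | ref A) = 2 up to prior shrinkage
  chain <- contrast_network(
    mk_records(c("B", "C"), c("A", "B"), c(0.1, 0.2), 1), "PFS",
    reference = "A")
  post <- conjugate_fixed_posterior(chain, prior_variance = 1e8)
  expect_equal(post$cov["C", "C"], 2, tolerance = 1e-4)
  expect_equal(unname(post$mean["C"]), 0.3, tolerance = 1e-4)
})

test_that("conjugate posterior agrees with weighted least squares", {
  set.seed(31)
  net <- mk_network(c("B", "C", "D", "C"), c("A", "A", "B", "B"),
                    rnorm(4), runif(4, 0.1, 0.3))
  des <- contrastnma:::network_design(net)
  X <- matrix(0, 4, 3)
  for (i in 1:4) {
    if (des$a[i] > 1) X[i, des$a[i] - 1] <- 1
    if (des$b[i] > 1) X[i, des$b[i] - 1] <- -1
  }
  ls <- lm(des$y ~ 0 + X, weights = des$w)
  post <- conjugate_fixed_posterior(net, prior_variance = 1e10)
  expect_equal(unname(post$mean), unname(coef(ls)), tolerance = 1e-6)
})

test_that("Gibbs sampler recovers the conjugate fixed-effects posterior", {
  net <- mk_network("A", "B", -0.5, 0.2)
  fit <- nma(net, "bayes", "fixed", quick_control(seed = 3))
  # single-datum limit (reference A, so d_B = -y): median ~ 0.5,
  # CrI ~ 0.5 +/- 1.96 se
  b <- fit$basic[fit$basic$treatment == "B", ]
  expect_lt(abs(b$median - 0.5), 0.01)
  expect_lt(abs(b$lower - (0.5 - 1.959964 * 0.2)), 0.03)
  expect_lt(abs(b$upper - (0.5 + 1.959964 * 0.2)), 0.03)
  expect_equal(predict(fit, "A", "B")$estimate, exp(-0.5), tolerance = 0.01)

  # multi-node network: every posterior mean within 3 MC standard errors
  trials <- tnbc_trials()
  os <- contrast_network(trials, "OS")
  fit <- nma(os, "bayes", "fixed", quick_control(seed = 17))
  post <- conjugate_fixed_posterior(os)
  free <- names(post$mean)
  got <- colMeans(fit$draws$d[, free])
  mcse <- fit$convergence$mc_error_ratio[free] *
    apply(fit$draws$d[, free], 2, sd)
  expect_true(all(abs(got - post$mean) < 3 * mcse + 1e-8))
  # and the posterior sd matches the exact covariance
  expect_equal(unname(apply(fit$draws$d[, free], 2, sd)),
               unname(sqrt(diag(post$cov))), tolerance = 0.05)
})

test_that("identical seeds reproduce draws; reference relabelling is inert", {
  net <- mk_network(c("B", "C"), c("A", "A"), c(-0.3, 0.2), c(0.1, 0.2))
  f1 <- nma(net, "bayes", "fixed", quick_control(seed = 8))
  f2 <- nma(net, "bayes", "fixed", quick_control(seed = 8))
  expect_identical(f1$draws$d, f2$draws$d)
  f3 <- nma(net, "bayes", "fixed", quick_control(seed = 9))
  expect_false(identical(f1$draws$d, f3$draws$d))

  # same records anchored at a different reference: contrasts unchanged
  rec <- mk_records(c("B", "C"), c("A", "A"), c(-0.3, 0.2), c(0.1, 0.2))
  alt <- contrast_network(rec, "PFS", reference = "C")
  f4 <- nma(alt, "bayes", "fixed", quick_control(seed = 8))
  bc1 <- predict(f1, "B", "C")$estimate
  bc2 <- predict(f4, "B", "C")$estimate
  expect_equal(log(bc1), log(bc2), tolerance = 0.02)
})

test_that("league tables are antisymmetric and flag significance", {
  trials <- tnbc_trials()
  fit <- nma(contrast_network(trials, "OS"), "bayes", "fixed",
             quick_control(seed = 2))
  lg <- league_table(fit)
  expect_equal(log(lg$estimate), -t(log(lg$estimate)), tolerance = 1e-12)
  expect_equal(log(lg$lower), -t(log(lg$upper)), tolerance = 1e-12)
  expect_identical(lg$significant, t(lg$significant))
  expect_true(all(diag(lg$estimate) == 1))
  expect_true(all(lg$lower <= lg$estimate & lg$estimate <= lg$upper))
  # iniparib + CT vs CT is the one significant OS gain
  expect_true(lg$significant["Iniparib + CT", "CT"])
  expect_lt(lg$upper["Iniparib + CT", "CT"], 1)
})

test_that("rank probabilities, cumulative curves and SUCRA are coherent", {
  trials <- tnbc_trials()
  fit <- nma(contrast_network(trials, "PFS"), "bayes", "fixed",
             quick_control(seed = 4))
  rk <- treatment_ranks(fit)
  n <- length(fit$nodes)
  expect_equal(unname(rowSums(rk$rank_probabilities)), rep(1, n),
               tolerance = 1e-12)
  expect_true(all(diff(t(rk$cumulative)) >= -1e-12))
  expect_equal(unname(rk$cumulative[, n]), rep(1, n), tolerance = 1e-12)
  expect_equal(sum(rk$sucra), n / 2, tolerance = 1e-9)
  expect_equal(unname(rk$sucra[fit$nodes]),
               unname((n - rk$mean_rank[fit$nodes]) / (n - 1)),
               tolerance = 1e-12)
  # flipping the direction of benefit mirrors every SUCRA
  flip <- treatment_ranks(fit, direction = "higher")
  expect_equal(unname(flip$sucra[fit$nodes]),
               unname(1 - rk$sucra[fit$nodes]), tolerance = 1e-12)

  # a treatment certainly better than the other gets SUCRA 1 vs 0
  sure <- nma(mk_network("A", "B", -3, 0.05), "bayes", "fixed",
              quick_control(seed = 5))
  rk2 <- treatment_ranks(sure)
  expect_equal(unname(rk2$sucra[c("A", "B")]), c(1, 0), tolerance = 1e-9)
})

test_that("split-chain PSRF separates converged from divergent chains", {
  expect_error(gelman_rubin(list(rnorm(100))), "at least two")
  set.seed(12)
  same <- list(rnorm(5000), rnorm(5000))
  expect_lt(gelman_rubin(same)[[1]], 1.05)
  apart <- list(rnorm(5000), rnorm(5000, 10))
  expect_gt(gelman_rubin(apart)[[1]], 1.1)
  # two copies of one chain: no between-chain variance inflation
  x <- rnorm(2000)
  expect_equal(unname(gelman_rubin(list(x, x))[1]), 1, tolerance = 0.05)
})

test_that("DIC accounting is exact and penalises one parameter per node", {
  net <- mk_network("A", "B", -0.5, 0.2)
  fit <- nma(net, "bayes", "fixed", quick_control(seed = 6))
  d <- dic(fit)
  expect_equal(d$dic, d$dbar + d$pd, tolerance = 1e-12)
  expect_equal(d$pd, d$dbar - d$dhat, tolerance = 1e-12)
  # one free basic parameter with a vague prior: pd ~ 1
  expect_equal(d$pd, 1, tolerance = 0.15)
})

test_that("random-effects model collapses to fixed on homogeneous data and recovers tau", {
  set.seed(21)
  # homogeneous: tau posterior small, contrasts match the fixed model
  rec <- mk_records(rep(c("B", "C"), each = 4), "A",
                    rep(c(-0.4, 0.3), each = 4) + rnorm(8, 0, 0.02),
                    0.15)
  net <- contrast_network(rec, "PFS", reference = "A")
  ff <- nma(net, "bayes", "fixed", quick_control(seed = 10))
  fr <- nma(net, "bayes", "random", quick_control(seed = 10))
  expect_lt(fr$tau[["median"]], 0.25)
  expect_equal(coef(fr)[-1], coef(ff)[-1], tolerance = 0.08)
  # no decisive DIC gain from random effects, so the fixed model is kept
  expect_gt(dic(fr)$dic, dic(ff)$dic - 2)

  # 40 heterogeneous studies generated with tau = 0.3
  design <- nma_design(paste0("T", 1:5),
                       true_d = c(T2 = -0.5, T3 = 0.2, T4 = -0.1, T5 = 0.4),
                       edges = data.frame(node_a = paste0("T", 2:5),
                                          node_b = "T1", n_studies = 10L),
                       tau = 0.3, se = 0.1)
  dat <- simulate_contrasts(design, seed = 33)
  fit <- nma(contrast_network(dat, "PFS", reference = "T1"),
             "bayes", "random", quick_control(seed = 13))
  expect_gt(fit$tau[["median"]], 0.1)
  expect_lt(fit$tau[["median"]], 0.6)
  expect_true(convergence(fit)$pass)
})
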