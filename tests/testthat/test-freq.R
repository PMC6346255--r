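test_that("graph-theoretical estimates obey chain identities", {
  # single edge: network estimate is the direct pooled estimate exactly
  rec <- mk_records("B", "A", c(-0.4, -0.2), c(0.1, 0.2))
  net <- contrast_network(rec, "PFS", reference = "A")
  fit <- nma(net, engine = "freq")
  direct <- pool_contrasts(rec)
  expect_equal(unname(fit$theta["B"]), direct$log_effect, tolerance = 1e-12)
  expect_equal(contrastnma:::contrast_se(fit$laplacian_pinv, "B", "A"),
               direct$se, tolerance = 1e-10)

  # loop-free chain: effects add, variances add
  chain <- contrast_network(
    mk_records(c("B", "C"), c("A", "B"), c(-0.3, -0.2), c(0.15, 0.25)),
    "PFS", reference = "A")
  cf <- nma(chain, engine = "freq")
  expect_equal(unname(cf$theta["C"]), -0.5, tolerance = 1e-10)
  expect_equal(contrastnma:::contrast_se(cf$laplacian_pinv, "C", "A")^2,
               0.15^2 + 0.25^2, tolerance = 1e-10)
})

test_that("network estimates satisfy consistency and match the WLS oracle", {
  trials <- tnbc_trials()
  fit <- nma(contrast_network(trials, "PFS"), engine = "freq")
  th <- fit$theta
  nodes <- fit$nodes
  for (i in 1:10) {
    tri <- sample(nodes, 3)
    expect_equal((th[tri[1]] - th[tri[2]]) + (th[tri[2]] - th[tri[3]]),
                 th[tri[1]] - th[tri[3]], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # independent route: stacked weighted regression on the incidence matrix
  des <- contrastnma:::network_design(fit$network)
  X <- matrix(0, length(des$y), length(nodes) - 1)
  for (i in seq_along(des$y)) {
    if (des$a[i] > 1) X[i, des$a[i] - 1] <- 1
    if (des$b[i] > 1) X[i, des$b[i] - 1] <- -1
  }
  ls <- lm(des$y ~ 0 + X, weights = des$w)
  expect_equal(unname(th[-1]), unname(coef(ls)), tolerance = 1e-8)
  # ... and the conjugate Bayesian posterior with a vague prior
  post <- conjugate_fixed_posterior(fit$network)
  expect_lt(max(abs(th[-1] - post$mean)), 1e-3)
})

test_that("P-scores are symmetric, conserved and direction-aware", {
  tie <- nma(mk_network("A", "B", 0, 0.2), engine = "freq")
  expect_equal(unname(p_scores(tie)$p_score), c(0.5, 0.5), tolerance = 1e-12)

  trials <- tnbc_trials()
  for (ep in c("OS", "PFS", "ORR")) {
    fit <- nma(contrast_network(trials, ep), engine = "freq")
    ps <- p_scores(fit)
    n <- length(fit$nodes)
    expect_equal(sum(ps$p_score), n / 2, tolerance = 1e-9)
    rev <- p_scores(fit, direction = if (fit$network$direction == "lower")
      "higher" else "lower")
    expect_equal(unname(rev$p_score[fit$nodes]),
                 unname(1 - ps$p_score[fit$nodes]), tolerance = 1e-12)
  }
})

test_that("contribution rows decompose each network comparison", {
  one <- nma(mk_network("A", "B", -0.2, 0.1), engine = "freq")
  cm1 <- contribution_matrix(one)
  expect_equal(unname(cm1[1, 1]), 100, tolerance = 1e-9)

  # equal-weight chain: the indirect A vs C estimate draws 50/50
  chain <- contrast_network(
    mk_records(c("B", "C"), c("A", "B"), c(-0.3, -0.2), 0.2),
    "PFS", reference = "A")
  cm <- contribution_matrix(nma(chain, engine = "freq"))
  expect_equal(unname(cm["A vs C", ]), c(50, 50), tolerance = 1e-9,
               ignore_attr = TRUE)

  trials <- tnbc_trials()
  cm <- contribution_matrix(nma(contrast_network(trials, "PFS"),
                                engine = "freq"))
  expect_equal(unname(rowSums(cm)), rep(100, nrow(cm)), tolerance = 1e-6)
  expect_true(all(cm >= 0))
  expect_gt(cm["Bevacizumab + CT vs CT + Placebo",
               "Bevacizumab + CT vs CT + Placebo"], 50)
})

test_that("funnel coordinates center on the comparison estimate", {
  # identical studies: every centered effect is zero
  same <- contrast_network(mk_records("B", "A", rep(-0.3, 4), 0.2),
                           "PFS", reference = "A")
  fd <- funnel_coordinates(nma(same, engine = "freq"))
  expect_equal(fd$x, rep(0, 4), tolerance = 1e-12)

  # inverse-variance weighted mean of x vanishes within each comparison
  # wherever direct evidence alone determines the edge; the one closed loop
  # in the PFS network (CT, CT + Placebo, bevacizumab + CT, veliparib + CT)
  # lets indirect evidence pull those four edges slightly off their direct
  # pooled estimates
  trials <- tnbc_trials()
  fit <- nma(contrast_network(trials, "PFS"), engine = "freq")
  fd <- funnel_coordinates(fit)
  wmean <- tapply(seq_len(nrow(fd)), fd$comparison, function(i)
    sum(fd$x[i] / fd$se[i]^2) / sum(1 / fd$se[i]^2))
  loop <- c("CT", "CT + Placebo", "Bevacizumab + CT", "Veliparib + CT")
  on_loop <- vapply(strsplit(names(wmean), " vs ", fixed = TRUE),
                    function(p) all(p %in% loop), TRUE)
  expect_lt(max(abs(wmean[!on_loop])), 1e-10)
  expect_lt(max(abs(wmean)), 0.05)

  # injected small-study effect shows up as an x-se correlation
  set.seed(61)
  se <- runif(40, 0.05, 0.6)
  y <- -0.3 + 1.2 * se + rnorm(40, 0, 0.05)
  biased <- contrast_network(mk_records("B", "A", y, se), "PFS",
                             reference = "A")
  fb <- funnel_coordinates(nma(biased, engine = "freq"),
                           assumed_order = c("B", "A"))
  expect_gt(cor(fb$x, fb$se), 0.5)
})
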