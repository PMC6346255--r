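test_that("fixed-effect pooling has the exact inverse-variance form", {
  # two identical studies: same estimate, se shrinks by sqrt(2)
  rec <- mk_records("A", "B", c(-0.4, -0.4), c(0.2, 0.2))
  p <- pool_contrasts(rec)
  expect_equal(p$log_effect, -0.4, tolerance = 1e-12)
  expect_equal(p$se, 0.2 / sqrt(2), tolerance = 1e-12)
  # single study is the identity
  one <- mk_records("A", "B", -0.4, 0.2)
  p1 <- pool_contrasts(one)
  expect_equal(p1$log_effect, one$log_effect, tolerance = 1e-12)
  expect_equal(p1$se, one$se, tolerance = 1e-12)
  expect_identical(p1$i_squared, 0)
  # pooled FE se never exceeds the best single study
  set.seed(5)
  rec <- mk_records("A", "B", rnorm(6), runif(6, 0.1, 0.5))
  expect_lte(pool_contrasts(rec)$se, min(rec$se))
})

test_that("DerSimonian-Laird and heterogeneity match closed forms", {
  rec <- mk_records("A", "B", c(0, 1), c(0.1, 0.1))
  het <- heterogeneity(rec)
  expect_equal(het$q, 50, tolerance = 1e-9)
  expect_equal(het$i_squared, 98, tolerance = 1e-9)
  p <- pool_contrasts(rec, model = "random")
  expect_equal(p$tau_squared, 49 / 100, tolerance = 1e-9)
  expect_equal(p$log_effect, 0.5, tolerance = 1e-12)
  # zero dispersion regardless of weights
  rec3 <- mk_records("A", "B", rep(0.1, 3), c(0.1, 0.2, 0.3))
  expect_equal(heterogeneity(rec3)$q, 0, tolerance = 1e-12)
  # homogeneous data collapse random to fixed
  pr <- pool_contrasts(rec3, model = "random")
  pf <- pool_contrasts(rec3, model = "fixed")
  expect_identical(pr$tau_squared, 0)
  expect_equal(pr$log_effect, pf$log_effect, tolerance = 1e-12)
  expect_error(pool_contrasts(mk_records("A", "B", 0, 0.1), "random"),
               "at least two")
})

test_that("pooling agrees with metafor on random data", {
  skip_if_not_installed("metafor")
  set.seed(99)
  for (i in 1:5) {
    k <- sample(2:8, 1)
    y <- rnorm(k, -0.3, 0.4)
    se <- runif(k, 0.08, 0.4)
    rec <- mk_records("A", "B", y, se)
    fe <- pool_contrasts(rec, "fixed")
    re <- pool_contrasts(rec, "random")
    m_fe <- metafor::rma(yi = y, sei = se, method = "FE")
    m_re <- metafor::rma(yi = y, sei = se, method = "DL")
    expect_equal(fe$log_effect, unname(m_fe$beta[1]), tolerance = 1e-10)
    expect_equal(fe$se, m_fe$se, tolerance = 1e-10)
    expect_equal(re$tau_squared, m_re$tau2, tolerance = 1e-10)
    expect_equal(re$log_effect, unname(m_re$beta[1]), tolerance = 1e-10)
    expect_equal(fe$q, m_fe$QE, tolerance = 1e-10)
  }
})

test_that("pooling invariances hold", {
  set.seed(7)
  y <- rnorm(6); se <- runif(6, 0.1, 0.4)
  rec <- mk_records("A", "B", y, se)
  # order invariance
  perm <- as_contrasts(rec[sample(6), ])
  expect_equal(pool_contrasts(perm)$log_effect,
               pool_contrasts(rec)$log_effect, tolerance = 1e-12)
  # hierarchical pooling with exact weights equals one-shot pooling
  p1 <- pool_contrasts(as_contrasts(rec[1:3, ]))
  p2 <- pool_contrasts(as_contrasts(rec[4:6, ]))
  w <- c(1 / p1$se^2, 1 / p2$se^2)
  expect_equal(sum(w * c(p1$log_effect, p2$log_effect)) / sum(w),
               pool_contrasts(rec)$log_effect, tolerance = 1e-12)
  # orientation flip leaves Q unchanged
  flipped <- mk_records("B", "A", -y, se)
  expect_equal(heterogeneity(flipped)$q, heterogeneity(rec)$q,
               tolerance = 1e-12)
  # random-effects interval contains the fixed-effects interval
  pf <- pool_contrasts(rec, "fixed"); pr <- pool_contrasts(rec, "random")
  expect_lte(pr$ci[1], pf$ci[1])
  expect_gte(pr$ci[2], pf$ci[2])
  # mixed measures or endpoints refuse to pool
  bad <- rec; bad$measure[1] <- "RR"
  expect_error(pool_contrasts(bad), "mixed effect measures")
  bad <- rec; bad$endpoint[1] <- "OS"
  expect_error(pool_contrasts(bad), "mixed endpoints")
})

test_that("consistency table keeps repeated comparisons and matches direct", {
  trials <- tnbc_trials()
  fit <- nma(contrast_network(trials, "PFS"), engine = "freq")
  tab <- consistency_table(fit)
  expect_true(all(tab$k >= 2))
  # single-study comparisons (e.g. olaparib vs CT) are excluded
  expect_false(any(grepl("Olaparib", tab$comparison)))
  row <- tab[tab$comparison == "Bevacizumab + CT vs CT + Placebo", ]
  expect_equal(row$direct, 0.66, tolerance = 0.01)
  expect_equal(row$network, 0.66, tolerance = 0.01)
  # this edge dominates its own evidence, so direct and network agree
  expect_equal(row$ratio, 1, tolerance = 0.05)
})
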