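#' Control parameters for the Bayesian engine
#'
#' Defaults follow a conventional WinBUGS-style schedule for contrast-level
#' models: two chains, a burn-in of 40 000 iterations, 200 000 further
#' iterations per chain thinned every 20th draw (10 000 retained per
#' chain), and a vague Normal(0, 1e6) prior on each basic parameter.  The
#' between-study standard deviation of the random-effects model gets a
#' Uniform(0, `tau_max`) prior on the log-ratio scale; `tau_max = 2` is far
#' above any heterogeneity plausible for log hazard or risk ratios.
#'
#' @param n_chains number of MCMC chains (at least 2 for convergence
#'   diagnostics).
#' @param burn_in discarded initial iterations per chain.
#' @param samples_per_chain post-burn-in iterations per chain.
#' @param thin keep every `thin`-th draw.
#' @param prior_mean,prior_variance normal prior on each basic parameter.
#' @param tau_max upper bound of the uniform prior on tau.
#' @param seed master seed; per-chain seeds are derived deterministically,
#'   so the same seed reproduces the retained draws exactly.
#' @return A list of class `"nma_control"`.
#' @export
nma_control <- function(n_chains = 2L, burn_in = 40000L,
                        samples_per_chain = 200000L, thin = 20L,
                        prior_mean = 0, prior_variance = 1e6,
                        tau_max = 2, seed = 1L) {
  stopifnot(n_chains >= 1L, burn_in > 0L, samples_per_chain > 0L, thin > 0L,
            samples_per_chain %% thin == 0L, prior_variance > 0, tau_max > 0)
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 samples_per_chain = as.integer(samples_per_chain),
                 thin = as.integer(thin),
                 prior_mean = prior_mean, prior_variance = prior_variance,
                 tau_max = tau_max, seed = as.integer(seed)),
            class = "nma_control")
}

#' Fit a network meta-analysis model
#'
#' The model is contrast-based: each two-arm record contributes a normal
#' likelihood `y_i ~ N(d[a_i] - d[b_i], se_i^2)` on the log-ratio scale,
#' where `d` are basic parameters relative to the reference regimen
#' (`d[reference] = 0`).  Under consistency every pairwise contrast is a
#' difference of basic parameters.
#'
#' Two engines are available.  `engine = "bayes"` samples the posterior by
#' a component-wise Gibbs sampler (exact full conditionals; the
#' random-effects model adds study-level effects `delta_i ~ N(d_a - d_b,
#' tau^2)` with a slice-sampling step for `tau`), and reports posterior
#' medians with 95% credible intervals, Brooks-Gelman-Rubin diagnostics,
#' Monte-Carlo error ratios, and DIC.  `engine = "freq"` solves the
#' fixed-effects weighted least-squares problem through the Moore-Penrose
#' pseudoinverse of the network Laplacian (edges pre-pooled by inverse
#' variance, which is algebraically identical to stacking) and reports
#' Wald intervals; it supports P-scores, contribution matrices and funnel
#' coordinates.
#'
#' @param network a [contrast_network()]; must be connected.
#' @param engine `"bayes"` or `"freq"`.
#' @param model `"fixed"` or `"random"` (the frequentist engine is
#'   fixed-effects only, matching its use as a sensitivity analysis).
#' @param control an [nma_control()] list (Bayesian engine).
#' @return An object of class `c("nma_bayes", "nma_fit")` or
#'   `c("nma_freq", "nma_fit")` with methods `print`, `summary`, `coef`,
#'   `vcov`, `fitted`, `residuals`, `predict`, `simulate` and `plot`, plus
#'   [league_table()], [treatment_ranks()], [dic()], [convergence()].
#' @examples
#' net <- contrast_network(tnbc_trials(), "PCR_BREAST")
#' fit <- nma(net, engine = "freq")
#' league_table(fit)
#' @export
nma <- function(network, engine = c("bayes", "freq"),
                model = c("fixed", "random"), control = nma_control()) {
  stopifnot(inherits(network, "contrast_network"))
  engine <- match.arg(engine)
  model <- match.arg(model)
  assert_connected(network)
  if (engine == "freq") {
    if (model == "random")
      stop("the graph-theoretical engine is fixed-effects only")
    fit <- fit_graph_engine(network)
  } else {
    fit <- fit_bayes_engine(network, model, control)
  }
  fit$call <- match.call()
  fit
}

## ---- Bayesian engine -----------------------------------------------------

fit_bayes_engine <- function(network, model, control) {
  des <- network_design(network)
  n_nodes <- length(des$nodes)
  m <- length(des$y)
  prior_prec <- 1 / control$prior_variance
  keep <- control$samples_per_chain %/% control$thin

  chains_d <- vector("list", control$n_chains)
  chains_tau <- vector("list", control$n_chains)
  chains_delta <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    set.seed((control$seed %% 1000000L) + 1000003L * (ch - 1L))
    if (model == "fixed") {
      chains_d[[ch]] <- gibbs_fixed_cpp(
        des$a - 1L, des$b - 1L, des$y, des$w, n_nodes,
        control$samples_per_chain, control$burn_in, control$thin, prior_prec)
    } else {
      res <- gibbs_random_cpp(
        des$a - 1L, des$b - 1L, des$y, des$w, n_nodes,
        control$samples_per_chain, control$burn_in, control$thin, prior_prec,
        control$tau_max, 0.1)
      chains_d[[ch]] <- res$d
      chains_tau[[ch]] <- res$tau
      chains_delta[[ch]] <- res$delta
    }
  }

  free <- des$nodes[-1L]
  d_all <- do.call(rbind, chains_d)
  colnames(d_all) <- free
  chain_id <- rep(seq_len(control$n_chains), each = keep)
  d_full <- cbind(matrix(0, nrow(d_all), 1,
                         dimnames = list(NULL, des$nodes[1L])), d_all)

  # convergence: split-chain PSRF and batch-means MC error per parameter
  mon <- chains_d
  par_names <- free
  if (model == "random") {
    mon <- Map(function(dm, tv) cbind(dm, tau = tv), chains_d, chains_tau)
    par_names <- c(free, "tau")
  }
  mon <- lapply(mon, function(x) {
    colnames(x) <- par_names
    x
  })
  r_hat <- gelman_rubin(mon)
  mc_ratio <- vapply(seq_along(par_names), function(j) {
    mcse <- sqrt(mean(vapply(mon, function(ch) batch_mcse(ch[, j])^2, 0)) /
                   length(mon))
    mcse / sd(unlist(lapply(mon, function(ch) ch[, j])))
  }, 0)
  names(mc_ratio) <- par_names
  convergence <- list(
    r_hat = r_hat,
    mc_error_ratio = mc_ratio,
    pass = all(r_hat <= 1.05) && all(mc_ratio < 0.05)
  )

  # posterior summaries of the basic parameters (and tau)
  summarise <- function(x) {
    qs <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    c(mean = mean(x), sd = sd(x), lower = qs[1], median = qs[2], upper = qs[3])
  }
  basic <- t(apply(d_full, 2, summarise))
  basic <- data.frame(treatment = rownames(basic), basic,
                      row.names = NULL, check.names = FALSE)
  tau_summary <- NULL
  tau_all <- NULL
  delta_all <- NULL
  if (model == "random") {
    tau_all <- unlist(chains_tau)
    tau_summary <- summarise(tau_all)
    delta_all <- do.call(rbind, chains_delta)
  }

  # DIC from the per-draw deviance of the records' normal likelihood
  mu <- if (model == "fixed") d_full[, des$a, drop = FALSE] -
          d_full[, des$b, drop = FALSE] else delta_all
  const <- log(2 * pi * des$se^2)
  dev <- rowSums(sweep((sweep(mu, 2, des$y))^2, 2, des$se^2, "/")) +
    sum(const)
  mu_bar <- colMeans(mu)
  dbar <- mean(dev)
  dhat <- sum(const + (des$y - mu_bar)^2 / des$se^2)
  dic_report <- list(dbar = dbar, dhat = dhat, pd = dbar - dhat,
                     dic = dbar + (dbar - dhat))

  structure(list(
    engine = "bayes", model = model, network = network, control = control,
    nodes = des$nodes,
    draws = list(d = d_full, chain = chain_id, tau = tau_all,
                 delta = delta_all),
    basic = basic, tau = tau_summary,
    convergence = convergence, dic = dic_report
  ), class = c("nma_bayes", "nma_fit"))
}

batch_mcse <- function(x) {
  n <- length(x)
  b <- max(2L, floor(sqrt(n)))
  nb <- n %/% b
  bm <- colMeans(matrix(x[seq_len(nb * b)], nrow = b))
  sd(bm) / sqrt(nb)
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Split-chain PSRF: each chain is halved, and the classical between/within
#' variance ratio is computed over the resulting sequences, so the
#' diagnostic also detects trends within a single chain.  Values at or
#' below 1.05 are conventionally taken as converged.
#'
#' @param chains a list (one element per chain) of numeric vectors or of
#'   matrices with one column per parameter; at least two chains of equal
#'   length.
#' @return Named vector of PSRF values, one per parameter.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least two chains")
  chains <- lapply(chains, function(x) {
    x <- as.matrix(x)
    if (is.null(colnames(x)))
      colnames(x) <- paste0("par", seq_len(ncol(x)))
    x
  })
  n <- unique(vapply(chains, nrow, 0L))
  if (length(n) != 1L) stop("chains must have equal length")
  half <- n %/% 2L
  seqs <- unlist(lapply(chains, function(x) {
    list(x[seq_len(half), , drop = FALSE],
         x[(n - half + 1L):n, , drop = FALSE])
  }), recursive = FALSE)
  vapply(colnames(chains[[1L]]), function(p) {
    means <- vapply(seqs, function(s) mean(s[, p]), 0)
    vars <- vapply(seqs, function(s) var(s[, p]), 0)
    W <- mean(vars)
    B <- half * var(means)
    if (W == 0) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, 0)
}

#' Exact posterior of the fixed-effects model (conjugate oracle)
#'
#' The fixed-effects contrast model with normal priors is fully conjugate:
#' the posterior of the basic parameters is multivariate normal with
#' precision `X'WX + I/prior_variance` and mean `(X'WX + I/v)^-1 X'Wy`.
#' Used as an analytic cross-check of the Gibbs sampler (and, with a vague
#' prior, of the graph-theoretical engine).
#'
#' @param network a connected [contrast_network()].
#' @param prior_mean,prior_variance normal prior on each basic parameter.
#' @return A list with `mean` (named, free nodes), `cov`, and `nodes`.
#' @export
conjugate_fixed_posterior <- function(network, prior_mean = 0,
                                      prior_variance = 1e6) {
  assert_connected(network)
  des <- network_design(network)
  n_free <- length(des$nodes) - 1L
  X <- matrix(0, length(des$y), n_free)
  ia <- des$a - 1L; ib <- des$b - 1L
  for (i in seq_along(des$y)) {
    if (ia[i] > 0L) X[i, ia[i]] <- 1
    if (ib[i] > 0L) X[i, ib[i]] <- -1
  }
  P <- crossprod(X * sqrt(des$w)) + diag(1 / prior_variance, n_free)
  rhs <- crossprod(X, des$w * des$y) + prior_mean / prior_variance
  cov <- tryCatch(solve(P), error = function(e)
    stop("singular posterior precision (disconnected network?)"))
  mu <- drop(cov %*% rhs)
  names(mu) <- des$nodes[-1L]
  dimnames(cov) <- list(des$nodes[-1L], des$nodes[-1L])
  list(mean = mu, cov = cov, nodes = des$nodes)
}

#' DIC report of a Bayesian fit
#'
#' Deviance is the exact normal log-likelihood times -2, including the
#' `log(2 pi se^2)` constants; `pd = dbar - dhat` and `dic = dbar + pd`.
#' Absolute DIC values depend on the deviance constant convention, so model
#' selection should use differences only (differences above 2 between the
#' random- and fixed-effects model are conventionally taken as important).
#'
#' @param fit an `"nma_bayes"` fit.
#' @return A list with `dbar`, `dhat`, `pd`, `dic`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "nma_bayes"))
  fit$dic
}

#' Convergence report of a Bayesian fit
#'
#' @param fit an `"nma_bayes"` fit.
#' @return A list with per-parameter `r_hat`, `mc_error_ratio` (Monte-Carlo
#'   standard error over posterior sd), and `pass` (all `r_hat <= 1.05` and
#'   all ratios below 5%).
#' @export
convergence <- function(fit) {
  stopifnot(inherits(fit, "nma_bayes"))
  fit$convergence
}

## ---- shared methods ------------------------------------------------------

#' @export
print.nma_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Network meta-analysis (%s, %s effects): endpoint %s\n",
              if (x$engine == "bayes") "Bayesian" else "graph-theoretical",
              x$model, x$network$endpoint))
  cat("  ", length(x$nodes), " regimens, reference ", x$nodes[1L], ", ",
      nrow(x$network$records), " records\n", sep = "")
  est <- coef(x)[-1L]
  lab <- if (x$network$measure == "HR") "HR" else "RR"
  cat(sprintf("  %s vs %s (%s):\n", "basic parameters", x$nodes[1L], lab))
  print(round(exp(est), digits))
  if (x$engine == "bayes") {
    cat(sprintf("  DIC %.3f (pd %.2f); convergence %s\n", x$dic$dic,
                x$dic$pd, if (x$convergence$pass) "passed" else "FAILED"))
  }
  invisible(x)
}

#' @export
coef.nma_fit <- function(object, ...) {
  if (object$engine == "bayes") {
    stats::setNames(object$basic$median, object$basic$treatment)
  } else {
    object$theta
  }
}

#' @export
vcov.nma_fit <- function(object, ...) {
  if (object$engine == "bayes") {
    var(object$draws$d[, -1L, drop = FALSE])
  } else {
    object$laplacian_pinv
  }
}

#' @export
fitted.nma_fit <- function(object, ...) {
  des <- network_design(object$network)
  d <- coef(object)
  unname(d[des$a] - d[des$b])
}

#' @export
residuals.nma_fit <- function(object, ...) {
  object$network$records$log_effect - fitted(object)
}

#' Relative effect of arbitrary treatment pairs
#'
#' @param object a fitted [nma()] model.
#' @param treatment_a,treatment_b character vectors of regimen labels
#'   (recycled); the effect is `treatment_a` versus `treatment_b`.
#' @param ... unused.
#' @return A data frame with ratio-scale estimate and 95% interval bounds.
#' @export
predict.nma_fit <- function(object, treatment_a, treatment_b, ...) {
  stopifnot(all(c(treatment_a, treatment_b) %in% object$nodes))
  n <- max(length(treatment_a), length(treatment_b))
  treatment_a <- rep_len(treatment_a, n)
  treatment_b <- rep_len(treatment_b, n)
  lg <- league_table(object)
  idx <- cbind(match(treatment_a, object$nodes),
               match(treatment_b, object$nodes))
  data.frame(treatment_a = treatment_a, treatment_b = treatment_b,
             measure = object$network$measure,
             estimate = lg$estimate[idx],
             lower = lg$lower[idx], upper = lg$upper[idx])
}

#' @export
summary.nma_fit <- function(object, ...) {
  ref <- object$nodes[1L]
  others <- object$nodes[-1L]
  pr <- predict(object, others, ref)
  out <- list(engine = object$engine, model = object$model,
              endpoint = object$network$endpoint,
              measure = object$network$measure,
              reference = ref, versus_reference = pr)
  if (object$engine == "bayes") {
    out$tau <- object$tau
    out$dic <- object$dic
    out$convergence <- object$convergence
  }
  class(out) <- "summary.nma_fit"
  out
}

#' @export
print.summary.nma_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s network meta-analysis, %s effects (%s, %s)\n",
              if (x$engine == "bayes") "Bayesian" else "Graph-theoretical",
              x$model, x$endpoint, x$measure))
  pr <- x$versus_reference
  cat("Relative effects versus ", x$reference, ":\n", sep = "")
  pr$estimate <- round(pr$estimate, digits)
  pr$lower <- round(pr$lower, digits)
  pr$upper <- round(pr$upper, digits)
  print(pr, row.names = FALSE)
  if (!is.null(x$tau))
    cat(sprintf("Between-study sd tau: median %.3f (95%% CrI %.3f-%.3f)\n",
                x$tau["median"], x$tau["lower"], x$tau["upper"]))
  if (!is.null(x$dic))
    cat(sprintf("DIC %.3f (dbar %.3f, pd %.2f); max r_hat %.3f\n",
                x$dic$dic, x$dic$dbar, x$dic$pd, max(x$convergence$r_hat)))
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Draws new contrast records with the fitted basic parameters as truth,
#' the observed design (same comparisons and standard errors), and, for a
#' random-effects fit, the posterior median between-study sd.
#'
#' @param object a fitted [nma()] model.
#' @param nsim number of replicate datasets.
#' @param seed seed passed to [simulate_contrasts()].
#' @param ... unused.
#' @return A list of `nsim` `"nma_contrasts"` data frames.
#' @export
simulate.nma_fit <- function(object, nsim = 1, seed = 1L, ...) {
  net <- object$network
  d <- coef(object)
  tau <- if (!is.null(object$tau)) unname(object$tau["median"]) else 0
  design <- nma_design(
    treatments = object$nodes,
    true_d = d,
    edges = data.frame(node_a = net$records$treatment_a,
                       node_b = net$records$treatment_b,
                       n_studies = 1L),
    se = net$records$se, tau = tau,
    endpoint = net$endpoint, measure = net$measure
  )
  lapply(seq_len(nsim), function(i)
    simulate_contrasts(design, seed = seed + i - 1L))
}
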