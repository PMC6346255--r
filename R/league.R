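`%||%` <- function(a, b) if (is.null(a)) b else a

#' League table of all pairwise relative effects
#'
#' Entry `[A, B]` is the relative effect of A versus B on the ratio scale
#' (median and 95% interval for the Bayesian engine, computed per retained
#' draw so the table is exactly antisymmetric on the log scale; Wald
#' estimate and interval for the frequentist engine).  A comparison is
#' flagged significant when its interval excludes 1.
#'
#' @param fit a fitted [nma()] model.
#' @return An object of class `"nma_league"`: matrices `estimate`, `lower`,
#'   `upper`, `significant` over all ordered pairs, plus endpoint metadata.
#' @export
league_table <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  nodes <- fit$nodes
  n <- length(nodes)
  est <- lo <- hi <- matrix(1, n, n, dimnames = list(nodes, nodes))
  if (fit$engine == "bayes") {
    d <- fit$draws$d
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      diff <- d[, i] - d[, j]
      qs <- quantile(diff, c(0.025, 0.5, 0.975), names = FALSE)
      est[i, j] <- exp(qs[2L]); lo[i, j] <- exp(qs[1L]); hi[i, j] <- exp(qs[3L])
      est[j, i] <- exp(-qs[2L]); lo[j, i] <- exp(-qs[3L]); hi[j, i] <- exp(-qs[1L])
    }
  } else {
    Lp <- fit$laplacian_pinv
    z <- qnorm(0.975)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      th <- fit$theta[i] - fit$theta[j]
      se <- contrast_se(Lp, i, j)
      est[i, j] <- exp(th); lo[i, j] <- exp(th - z * se); hi[i, j] <- exp(th + z * se)
      est[j, i] <- exp(-th); lo[j, i] <- exp(-th - z * se); hi[j, i] <- exp(-th + z * se)
    }
  }
  sig <- lo > 1 | hi < 1
  diag(sig) <- FALSE
  structure(list(endpoint = fit$network$endpoint,
                 measure = fit$network$measure,
                 engine = fit$engine, model = fit$model,
                 nodes = nodes, estimate = est, lower = lo, upper = hi,
                 significant = sig),
            class = "nma_league")
}

#' @export
print.nma_league <- function(x, digits = 2, ...) {
  cat(sprintf("League table (%s, %s engine, %s effects); %s of column vs row\n",
              x$endpoint, x$engine, x$model, x$measure))
  n <- length(x$nodes)
  cells <- matrix("", n, n, dimnames = list(x$nodes, x$nodes))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) cells[i, j] <- x$nodes[i]
    else if (j > i)
      cells[i, j] <- sprintf("%.*f (%.*f-%.*f)%s", digits, x$estimate[j, i],
                             digits, x$lower[j, i], digits, x$upper[j, i],
                             if (x$significant[j, i]) "*" else "")
  }
  print(as.data.frame(cells[, , drop = FALSE]), right = FALSE)
  cat("* interval excludes 1\n")
  invisible(x)
}

#' As a long data frame
#' @param x an `"nma_league"`.
#' @param ... unused.
#' @export
as.data.frame.nma_league <- function(x, ...) {
  n <- length(x$nodes)
  idx <- expand.grid(a = seq_len(n), b = seq_len(n))
  idx <- idx[idx$a != idx$b, ]
  data.frame(treatment_a = x$nodes[idx$a], treatment_b = x$nodes[idx$b],
             estimate = x$estimate[cbind(idx$a, idx$b)],
             lower = x$lower[cbind(idx$a, idx$b)],
             upper = x$upper[cbind(idx$a, idx$b)],
             significant = x$significant[cbind(idx$a, idx$b)],
             stringsAsFactors = FALSE)
}

#' Treatment rankings: rank probabilities, cumulative curves and SUCRA
#'
#' For the Bayesian engine, treatments are ranked best-to-worst at every
#' retained draw under the endpoint's direction of benefit; rank
#' probabilities are the empirical frequencies, cumulative ranking curves
#' their running sums, and SUCRA the surface under the cumulative curve,
#' `sum(cum[1:(n-1)]) / (n-1) = (n - mean_rank) / (n - 1)`.  SUCRA values
#' sum to n/2.  For the frequentist engine this dispatches to
#' [p_scores()], the resampling-free analogue.
#'
#' @param fit a fitted [nma()] model.
#' @param direction override the endpoint's direction of benefit
#'   (`"lower"`/`"higher"`).
#' @return An object of class `"nma_ranks"`; Bayesian fits carry
#'   `rank_probabilities` (treatment x rank), `cumulative`, `sucra` and
#'   `mean_rank`, frequentist fits carry `p_score` and `z`.
#' @export
treatment_ranks <- function(fit, direction = NULL) {
  stopifnot(inherits(fit, "nma_fit"))
  if (fit$engine == "freq") return(p_scores(fit, direction))
  direction <- direction %||% fit$network$direction
  d <- fit$draws$d
  if (direction == "higher") d <- -d
  n <- ncol(d)
  rk <- t(apply(d, 1L, rank, ties.method = "first"))
  prob <- vapply(seq_len(n), function(r) colMeans(rk == r),
                 numeric(n))                     # treatment x rank
  dimnames(prob) <- list(colnames(d), paste0("rank", seq_len(n)))
  cum <- t(apply(prob, 1L, cumsum))
  mean_rank <- colMeans(rk)
  sucra <- (n - mean_rank) / (n - 1)
  structure(list(method = "SUCRA", direction = direction,
                 rank_probabilities = prob, cumulative = cum,
                 mean_rank = mean_rank,
                 sucra = sort(sucra, decreasing = TRUE),
                 treatments = colnames(d)),
            class = "nma_ranks")
}

#' @export
print.nma_ranks <- function(x, digits = 4, ...) {
  if (x$method == "SUCRA") {
    cat("SUCRA (", x$direction, " is better):\n", sep = "")
    print(round(x$sucra, digits))
  } else {
    cat("P-scores (", x$direction, " is better):\n", sep = "")
    print(round(x$p_score, digits))
  }
  invisible(x)
}

#' @export
plot.nma_bayes <- function(x, ...) {
  rk <- treatment_ranks(x)
  cum <- rk$cumulative
  n <- ncol(cum)
  graphics::matplot(seq_len(n), t(cum), type = "l", lty = 1,
                    xlab = "rank", ylab = "cumulative probability",
                    main = paste("Cumulative rankograms:",
                                 x$network$endpoint), ...)
  graphics::legend("bottomright", legend = rownames(cum), col = seq_len(n),
                   lty = 1, cex = 0.6, bty = "n")
  invisible(rk)
}
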