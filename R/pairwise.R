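#' Inverse-variance pairwise meta-analysis of one direct comparison
#'
#' Pools the log-scale effects of studies that compared the same pair of
#' regimens.  The fixed-effect pool uses weights `1/se^2`; the
#' random-effects pool adds the DerSimonian-Laird moment estimate of the
#' between-study variance `tau^2` to every study variance.  Cochran's Q and
#' I-squared quantify heterogeneity; following common practice the
#' combination I-squared > 50% with P < 0.05 is flagged as significant.
#'
#' @param records an `"nma_contrasts"` data frame holding one comparison of
#'   one endpoint, all rows oriented the same way.
#' @param model `"fixed"` or `"random"`; `"random"` needs at least two
#'   studies.
#' @param conf_level coverage of the pooled interval.
#' @return An object of class `"pooled_contrast"`: `k`, `log_effect`, `se`,
#'   `estimate` (ratio scale), `ci`, `q`, `df`, `p_value`, `i_squared`,
#'   `tau_squared`, `model`, `significant_heterogeneity`.
#' @examples
#' trials <- tnbc_trials()
#' bev <- trials[trials$endpoint == "PFS" &
#'               trials$treatment_a == "Bevacizumab + CT" &
#'               trials$treatment_b == "CT + Placebo", ]
#' pool_contrasts(bev)  # pooled HR about 0.66 (0.55-0.80)
#' @export
pool_contrasts <- function(records, model = c("fixed", "random"),
                           conf_level = 0.95) {
  model <- match.arg(model)
  rec <- as.data.frame(records)
  k <- nrow(rec)
  if (!k) stop("no records to pool")
  if (length(unique(rec$endpoint)) > 1L)
    stop("mixed endpoints in one pool: ",
         paste(unique(rec$endpoint), collapse = ", "))
  if (length(unique(rec$measure)) > 1L)
    stop("mixed effect measures in one pool: ",
         paste(unique(rec$measure), collapse = ", "))
  pair <- unique(paste(rec$treatment_a, rec$treatment_b, sep = " vs "))
  if (length(pair) > 1L)
    stop("records span several comparisons or orientations: ",
         paste(pair, collapse = "; "))
  if (model == "random" && k < 2L)
    stop("random-effects pooling needs at least two studies")

  y <- rec$log_effect
  w <- 1 / rec$se^2
  het <- heterogeneity_stats(y, w)

  tau2 <- 0
  if (model == "random") {
    # DerSimonian-Laird moment estimator
    tau2 <- max(0, (het$q - het$df) / (sum(w) - sum(w^2) / sum(w)))
    w <- 1 / (rec$se^2 + tau2)
  }
  pooled <- sum(w * y) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    comparison = pair,
    endpoint = unique(rec$endpoint),
    measure = unique(rec$measure),
    k = k,
    log_effect = pooled,
    se = se,
    estimate = exp(pooled),
    ci = exp(pooled + c(-1, 1) * z * se),
    q = het$q,
    df = het$df,
    p_value = het$p_value,
    i_squared = het$i_squared,
    tau_squared = tau2,
    significant_heterogeneity = het$i_squared > 50 && het$p_value < 0.05,
    model = model
  ), class = "pooled_contrast")
}

heterogeneity_stats <- function(y, w) {
  k <- length(y)
  pooled <- sum(w * y) / sum(w)
  q <- sum(w * (y - pooled)^2)
  df <- k - 1L
  p <- if (df > 0) pchisq(q, df, lower.tail = FALSE) else NA_real_
  i2 <- if (df > 0 && q > 0) max(0, 100 * (q - df) / q) else 0
  list(q = q, df = df, p_value = p, i_squared = i2)
}

#' Heterogeneity statistics for a set of studies of one comparison
#'
#' @param records as in [pool_contrasts()], `k >= 2`.
#' @return A list with Cochran's `q`, `df`, `p_value` (chi-squared) and
#'   `i_squared` (percent).
#' @export
heterogeneity <- function(records) {
  rec <- as.data.frame(records)
  if (nrow(rec) < 2L) stop("heterogeneity needs at least two studies")
  heterogeneity_stats(rec$log_effect, 1 / rec$se^2)
}

#' @export
print.pooled_contrast <- function(x, digits = 3, ...) {
  cat(sprintf("%s pooled %s (%s, %s): %s = %.*f (%.*f-%.*f), k = %d\n",
              x$model, x$comparison, x$endpoint, x$measure, x$measure,
              digits, x$estimate, digits, x$ci[1], digits, x$ci[2], x$k))
  cat(sprintf("  Q = %.3f (df %d, p = %s), I2 = %.1f%%, tau2 = %.4f\n",
              x$q, x$df, format.pval(x$p_value, digits = 3), x$i_squared,
              x$tau_squared))
  invisible(x)
}

#' Direct versus network consistency table
#'
#' For every direct comparison observed in at least `min_studies` studies,
#' tabulates the classical fixed-effect pooled estimate next to the network
#' estimate from a fitted model, plus their ratio.  The networks here have
#' no closed loops, so consistency is assessed descriptively (interval
#' overlap), not by a node-splitting test.
#'
#' @param fit an [nma()] fit (either engine).
#' @param min_studies minimum number of studies for a row, default 2.
#' @param model pooling model for the direct estimate.
#' @return A data frame with direct and network estimates, intervals,
#'   heterogeneity, and the direct/network ratio, all on the ratio scale.
#' @export
consistency_table <- function(fit, min_studies = 2L,
                              model = c("fixed", "random")) {
  stopifnot(inherits(fit, "nma_fit"))
  model <- match.arg(model)
  network <- fit$network
  rec <- network$records
  edges <- network$edges
  edges <- edges[edges$n_studies >= min_studies, , drop = FALSE]
  if (!nrow(edges)) return(data.frame())
  lg <- league_table(fit)
  out <- lapply(seq_len(nrow(edges)), function(i) {
    a <- edges$node_a[i]; b <- edges$node_b[i]
    sub <- rec[(rec$treatment_a == a & rec$treatment_b == b) |
               (rec$treatment_a == b & rec$treatment_b == a), , drop = FALSE]
    # orient every record as a vs b before pooling
    flip <- sub$treatment_a == b
    sub$log_effect[flip] <- -sub$log_effect[flip]
    est <- sub$ci_upper
    sub$ci_upper[flip] <- 1 / sub$ci_lower[flip]
    sub$ci_lower[flip] <- 1 / est[flip]
    sub$estimate[flip] <- 1 / sub$estimate[flip]
    tmp <- sub$treatment_a[flip]
    sub$treatment_a[flip] <- sub$treatment_b[flip]
    sub$treatment_b[flip] <- tmp
    direct <- pool_contrasts(sub, model = model)
    data.frame(
      endpoint = network$endpoint,
      comparison = paste(a, "vs", b),
      k = direct$k,
      direct = direct$estimate,
      direct_lower = direct$ci[1], direct_upper = direct$ci[2],
      network = lg$estimate[a, b],
      network_lower = lg$lower[a, b], network_upper = lg$upper[a, b],
      ratio = direct$estimate / lg$estimate[a, b],
      i_squared = direct$i_squared,
      q_p_value = direct$p_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
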