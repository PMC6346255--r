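# Graph-theoretical fixed-effects engine: studies on the same edge are
# pre-pooled by inverse variance (identical to stacking for FE WLS), the
# network Laplacian L = B' W B is inverted by Moore-Penrose pseudoinverse,
# and node potentials give every contrast; var(theta_AB) = L+_AA + L+_BB -
# 2 L+_AB.

fit_graph_engine <- function(network) {
  des <- network_design(network)
  rec <- network$records
  a <- pmin(rec$treatment_a, rec$treatment_b)
  b <- pmax(rec$treatment_a, rec$treatment_b)
  # orient each record along its sorted edge before pooling
  yo <- ifelse(rec$treatment_a == a, des$y, -des$y)
  key <- paste(a, b, sep = " | ")
  agg_w <- tapply(des$w, key, sum)
  agg_y <- tapply(yo * des$w, key, sum) / agg_w
  ek <- names(agg_w)
  ea <- sub(" \\| .*$", "", ek)
  eb <- sub("^.* \\| ", "", ek)
  nodes <- network$nodes
  B <- matrix(0, length(ek), length(nodes), dimnames = list(ek, nodes))
  B[cbind(seq_along(ek), match(ea, nodes))] <- 1
  B[cbind(seq_along(ek), match(eb, nodes))] <- -1
  W <- diag(as.numeric(agg_w), length(agg_w))
  L <- t(B) %*% W %*% B
  Lp <- MASS::ginv(L)
  Lp <- (Lp + t(Lp)) / 2
  dimnames(Lp) <- list(nodes, nodes)
  theta <- drop(Lp %*% t(B) %*% (agg_w * agg_y))
  theta <- theta - theta[1L]          # anchor the reference at zero
  names(theta) <- nodes
  structure(list(
    engine = "freq", model = "fixed", network = network, nodes = nodes,
    theta = theta, laplacian = L, laplacian_pinv = Lp,
    incidence = B,
    edges_pooled = data.frame(node_a = ea, node_b = eb,
                              y = as.numeric(agg_y), w = as.numeric(agg_w),
                              stringsAsFactors = FALSE)
  ), class = c("nma_freq", "nma_fit"))
}

contrast_se <- function(Lp, i, j) {
  ii <- Lp[cbind(i, i)]
  jj <- Lp[cbind(j, j)]
  ij <- Lp[cbind(i, j)]
  sqrt(pmax(0, ii + jj - 2 * ij))
}

#' P-scores: frequentist treatment ranking without resampling
#'
#' For every ordered pair the z statistic of the network contrast is
#' oriented so that positive means the first treatment is better under the
#' endpoint's direction of benefit; the P-score of a treatment is the mean
#' one-sided normal probability that it beats each competitor,
#' `mean(pnorm(z))`.  P-scores sum to n/2 and reversing the direction of
#' benefit maps each score p to 1 - p.
#'
#' @param fit an `"nma_freq"` fit.
#' @param direction `"lower"` or `"higher"` is better; defaults to the
#'   endpoint's direction.
#' @return A list of class `"nma_ranks"` with `p_score` (named, sorted
#'   best first) and the oriented `z` matrix.
#' @export
p_scores <- function(fit, direction = NULL) {
  stopifnot(inherits(fit, "nma_freq"))
  direction <- direction %||% fit$network$direction
  nodes <- fit$nodes
  n <- length(nodes)
  Lp <- fit$laplacian_pinv
  se <- sqrt(pmax(outer(diag(Lp), diag(Lp), "+") - 2 * Lp, 0))
  z <- outer(fit$theta, fit$theta, "-") / ifelse(se > 0, se, 1)
  z[se == 0] <- 0                       # ties resolved as Phi(0) = 0.5
  if (direction == "lower") z <- -z
  diag(z) <- NA
  p <- rowMeans(pnorm(z), na.rm = TRUE)
  structure(list(method = "P-score", direction = direction,
                 p_score = sort(p, decreasing = TRUE), z = z,
                 treatments = nodes),
            class = "nma_ranks")
}

#' Contribution of each direct comparison to each network estimate
#'
#' Row `c` of the hat matrix expresses the network estimate of comparison
#' `c` as a linear combination of the pooled direct estimates; the
#' percentage contribution of direct comparison `e` is `|h_ce|` normalized
#' to 100 across `e`.  (This simple normalized-hat-row rule reproduces the
#' flow decomposition exactly on loop-free networks, where every
#' contribution is a path weight.)
#'
#' @param fit an `"nma_freq"` fit.
#' @return A matrix of class `"nma_contribution"`: rows are all unordered
#'   network comparisons, columns the direct comparisons, entries
#'   percentages summing to 100 per row.
#' @export
contribution_matrix <- function(fit) {
  stopifnot(inherits(fit, "nma_freq"))
  nodes <- fit$nodes
  B <- fit$incidence
  W <- fit$edges_pooled$w
  proj <- fit$laplacian_pinv %*% t(B) %*% diag(W, length(W))  # node x edge
  pairs <- utils::combn(nodes, 2)
  H <- t(apply(pairs, 2, function(p) proj[p[1L], ] - proj[p[2L], ]))
  rownames(H) <- apply(pairs, 2, paste, collapse = " vs ")
  colnames(H) <- sub(" \\| ", " vs ", rownames(B))
  pct <- abs(H) / rowSums(abs(H)) * 100
  structure(pct, class = c("nma_contribution", class(pct)))
}

#' Comparison-adjusted funnel plot coordinates
#'
#' Centers every study's log effect on the network estimate of its own
#' comparison, orienting each record so that the treatment appearing
#' earlier in `assumed_order` comes first (the conventional assumption
#' being that experimental regimens are favoured in small studies).  With
#' no small-study effects the points scatter symmetrically around zero at
#' every standard error; the inverse-variance weighted mean of the centered
#' effects is zero within each comparison by construction.
#'
#' @param fit an `"nma_freq"` fit.
#' @param assumed_order character vector ranking treatments from most
#'   experimental to comparator; defaults to the network's non-reference
#'   nodes first with `CT + Placebo` and the reference last.
#' @return A data frame of class `"nma_funnel"`: one row per record with
#'   the oriented centered effect `x`, its `se` (plotted inverted on the
#'   y axis), and the comparison label.
#' @export
funnel_coordinates <- function(fit, assumed_order = NULL) {
  stopifnot(inherits(fit, "nma_freq"))
  net <- fit$network
  nodes <- fit$nodes
  if (is.null(assumed_order)) {
    tail_nodes <- intersect(c("CT + Placebo", net$reference), nodes)
    assumed_order <- c(setdiff(nodes, tail_nodes), tail_nodes)
  }
  stopifnot(all(nodes %in% assumed_order))
  rec <- net$records
  rk <- match(rec$treatment_a, assumed_order) <=
    match(rec$treatment_b, assumed_order)
  first <- ifelse(rk, rec$treatment_a, rec$treatment_b)
  second <- ifelse(rk, rec$treatment_b, rec$treatment_a)
  y <- ifelse(rk, rec$log_effect, -rec$log_effect)
  theta <- fit$theta[first] - fit$theta[second]
  out <- data.frame(
    study_id = rec$study_id,
    comparison = paste(first, "vs", second),
    x = y - theta,
    se = rec$se,
    stringsAsFactors = FALSE
  )
  class(out) <- c("nma_funnel", "data.frame")
  out
}

#' @export
plot.nma_freq <- function(x, assumed_order = NULL, ...) {
  fd <- funnel_coordinates(x, assumed_order)
  plot(fd$x, fd$se, ylim = rev(range(fd$se)),
       xlab = "centered log effect", ylab = "standard error",
       main = paste("Comparison-adjusted funnel:", x$network$endpoint), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(fd)
}
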