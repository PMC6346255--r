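#' Assemble the evidence network for one endpoint
#'
#' Nodes are treatment regimens, edges are direct head-to-head comparisons,
#' each edge holding the contrast records that observed it.  The direction
#' of benefit follows the effect measure: hazard-ratio endpoints (OS, PFS)
#' are lower-is-better, risk-ratio endpoints (ORR, pCR) higher-is-better.
#' `CT` and `CT + Placebo` are deliberately distinct nodes.
#'
#' @param data an `"nma_contrasts"` data frame (see [read_contrasts()]).
#' @param endpoint one of `OS`, `PFS`, `ORR`, `PCR_BREAST_AXILLA`,
#'   `PCR_BREAST`.
#' @param reference reference regimen; defaults to `"CT"` when present,
#'   otherwise the first node alphabetically.
#' @return An object of class `"contrast_network"` with components `nodes`
#'   (reference first), `edges` (one row per direct comparison with study
#'   multiplicities), `records`, `endpoint`, `direction`
#'   (`"lower"`/`"higher"`), and `reference`.
#' @examples
#' net <- contrast_network(tnbc_trials(), "OS")
#' net
#' @export
contrast_network <- function(data, endpoint, reference = "CT") {
  stopifnot(inherits(data, "nma_contrasts") || is.data.frame(data))
  endpoint <- match.arg(endpoint, ENDPOINTS)
  rec <- as.data.frame(data)[data$endpoint == endpoint, , drop = FALSE]
  if (!nrow(rec)) stop("no records for endpoint ", endpoint)
  measures <- unique(rec$measure)
  if (length(measures) > 1L)
    stop("mixed effect measures within endpoint ", endpoint, ": ",
         paste(measures, collapse = ", "))
  nodes <- sort(unique(c(rec$treatment_a, rec$treatment_b)))
  if (!reference %in% nodes) reference <- nodes[1L]
  nodes <- c(reference, setdiff(nodes, reference))

  a <- pmin(rec$treatment_a, rec$treatment_b)
  b <- pmax(rec$treatment_a, rec$treatment_b)
  key <- paste(a, b, sep = " | ")
  uk <- !duplicated(key)
  edges <- data.frame(
    node_a = a[uk], node_b = b[uk],
    n_studies = as.integer(table(key)[key[uk]]),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  rownames(rec) <- NULL
  structure(list(
    endpoint = endpoint,
    measure = measures,
    direction = if (endpoint %in% HR_ENDPOINTS) "lower" else "higher",
    reference = reference,
    nodes = nodes,
    edges = edges,
    records = rec
  ), class = "contrast_network")
}

#' Connected components of an evidence network
#'
#' Network estimates only exist within the component containing the
#' reference; fits reject disconnected networks.
#'
#' @param network a `"contrast_network"`.
#' @return A list of character vectors of node labels, the component holding
#'   the reference first.
#' @export
network_components <- function(network) {
  stopifnot(inherits(network, "contrast_network"))
  nodes <- network$nodes
  comp <- seq_along(nodes)
  names(comp) <- nodes
  for (i in seq_len(nrow(network$edges))) {
    ca <- comp[[network$edges$node_a[i]]]
    cb <- comp[[network$edges$node_b[i]]]
    if (ca != cb) comp[comp == cb] <- ca
  }
  out <- unname(split(nodes, comp[nodes]))
  ref_first <- order(!vapply(out, function(s) network$reference %in% s, TRUE))
  out[ref_first]
}

#' @rdname network_components
#' @export
is_connected <- function(network) length(network_components(network)) == 1L

assert_connected <- function(network) {
  comps <- network_components(network)
  if (length(comps) > 1L) {
    stranded <- unlist(comps[-1L])
    stop(structure(class = c("nma_disconnected", "error", "condition"),
                   list(message = paste0(
                     "evidence network for ", network$endpoint,
                     " is disconnected; stranded regimen(s): ",
                     paste(stranded, collapse = ", ")),
                     call = sys.call(-1))))
  }
  invisible(network)
}

# distinct randomized trials: sub-studies that split one registration by
# chemotherapy backbone carry a parenthesised tag, e.g. "Robert (Cape)-2011"
trial_label <- function(study_id) gsub("\\s*\\([^)]*\\)", "", study_id)

#' @export
print.contrast_network <- function(x, ...) {
  cat("Evidence network:", x$endpoint, "(", x$measure, ",",
      if (x$direction == "lower") "lower is better" else "higher is better",
      ")\n")
  cat("  ", length(x$nodes), " regimens, ", nrow(x$edges),
      " direct comparisons, ", nrow(x$records), " records; reference: ",
      x$reference, "\n", sep = "")
  invisible(x)
}

#' Summarize an evidence network
#'
#' @param object a `"contrast_network"`.
#' @param ... unused.
#' @return A list with node/edge/record counts, the number of distinct
#'   trials, per-edge study multiplicities and randomized patient totals
#'   (each study counted once; arm sizes are metadata and never enter the
#'   likelihood).
#' @export
summary.contrast_network <- function(object, ...) {
  rec <- object$records
  first <- rec[!duplicated(rec$study_id), , drop = FALSE]
  patients <- sum(first$n_a, first$n_b, na.rm = TRUE)
  edges <- object$edges
  key <- paste(pmin(rec$treatment_a, rec$treatment_b),
               pmax(rec$treatment_a, rec$treatment_b), sep = " | ")
  ekey <- paste(edges$node_a, edges$node_b, sep = " | ")
  edges$n_patients <- vapply(ekey, function(k) {
    r <- rec[key == k, , drop = FALSE]
    r <- r[!duplicated(r$study_id), , drop = FALSE]
    sum(r$n_a, r$n_b, na.rm = TRUE)
  }, 0)
  structure(list(
    endpoint = object$endpoint,
    n_nodes = length(object$nodes),
    n_edges = nrow(edges),
    n_records = nrow(rec),
    n_studies = length(unique(rec$study_id)),
    n_trials = length(unique(trial_label(rec$study_id))),
    n_patients = patients,
    connected = is_connected(object),
    edges = edges
  ), class = "summary.contrast_network")
}

#' @export
print.summary.contrast_network <- function(x, ...) {
  cat("Evidence network summary (", x$endpoint, ")\n", sep = "")
  cat("  regimens:           ", x$n_nodes, "\n")
  cat("  direct comparisons: ", x$n_edges, "\n")
  cat("  records / studies / trials:", x$n_records, "/", x$n_studies, "/",
      x$n_trials, "\n")
  cat("  randomized patients:", x$n_patients, "\n")
  cat("  connected:          ", x$connected, "\n")
  print(x$edges, row.names = FALSE)
  invisible(x)
}

# map records of a network to 1-based node indices, oriented a vs b
network_design <- function(network) {
  rec <- network$records
  list(
    a = match(rec$treatment_a, network$nodes),
    b = match(rec$treatment_b, network$nodes),
    y = rec$log_effect,
    se = rec$se,
    w = 1 / rec$se^2,
    nodes = network$nodes
  )
}
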