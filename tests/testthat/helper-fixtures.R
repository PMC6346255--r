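# Build contrast records from log-scale effects with log-symmetric CIs, so
# ingest recovers (y, se) exactly.
mk_records <- function(a, b, y, se, endpoint = "PFS", measure = NULL,
                       study = NULL) {
  n <- max(length(a), length(b), length(y), length(se))
  a <- rep_len(a, n); b <- rep_len(b, n)
  y <- rep_len(y, n); se <- rep_len(se, n)
  z <- qnorm(0.975)
  if (is.null(measure)) measure <- if (endpoint %in% c("OS", "PFS")) "HR" else "RR"
  df <- data.frame(
    study_id = study %||% sprintf("S%03d", seq_len(n)),
    treatment_a = a, treatment_b = b, n_a = NA_real_, n_b = NA_real_,
    endpoint = endpoint, measure = measure,
    estimate = exp(y), ci_lower = exp(y - z * se), ci_upper = exp(y + z * se),
    stringsAsFactors = FALSE
  )
  as_contrasts(df)
}

mk_network <- function(a, b, y, se, endpoint = "PFS", ...) {
  contrast_network(mk_records(a, b, y, se, endpoint = endpoint, ...), endpoint)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# short MCMC schedule for unit tests; reporting-quality runs use defaults
quick_control <- function(seed = 1L, ...) {
  nma_control(burn_in = 2000L, samples_per_chain = 20000L, thin = 10L,
              seed = seed, ...)
}
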