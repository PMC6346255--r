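#' Convert a ratio-scale estimate with 95% CI to a log-scale effect and SE
#'
#' Published hazard or risk ratios with confidence intervals are the only
#' information contrast-level meta-analysis has about a trial.  The point
#' estimate maps to `log(estimate)` and the standard error is recovered from
#' the interval width on the log scale,
#' `se = (log(ci_upper) - log(ci_lower)) / (2 * z)`, where `z` is the
#' standard-normal quantile for the interval's coverage (1.959964 at 95%).
#'
#' Intervals that are not symmetric about the estimate on the log scale
#' (which happens with rounded or non-Wald intervals) are accepted with a
#' warning: the SE is still taken from the interval width and the estimate is
#' not recentred.
#'
#' @param estimate positive ratio-scale point estimate (HR or RR).
#' @param ci_lower,ci_upper positive confidence bounds, `ci_lower <= ci_upper`.
#' @param conf_level coverage of the interval, default 0.95.
#' @param warn warn on log-asymmetric intervals.
#' @return A list with components `log_effect` and `se` (vectorised).
#' @examples
#' log_scale_effect(0.43, 0.29, 0.63)  # log_effect -0.844, se 0.198
#' @export
log_scale_effect <- function(estimate, ci_lower, ci_upper,
                             conf_level = 0.95, warn = TRUE) {
  stopifnot(is.numeric(estimate), is.numeric(ci_lower), is.numeric(ci_upper),
            length(conf_level) == 1L, conf_level > 0, conf_level < 1)
  if (any(estimate <= 0 | ci_lower <= 0 | ci_upper <= 0, na.rm = TRUE))
    stop("estimates and confidence bounds must be positive (ratio scale)")
  if (any(ci_upper < ci_lower, na.rm = TRUE))
    stop("ci_upper < ci_lower: malformed confidence interval")
  z <- qnorm(1 - (1 - conf_level) / 2)
  log_effect <- log(estimate)
  se <- (log(ci_upper) - log(ci_lower)) / (2 * z)
  if (any(se == 0, na.rm = TRUE))
    stop("degenerate confidence interval (zero width) gives se = 0")
  mid <- (log(ci_upper) + log(ci_lower)) / 2
  asym <- abs(mid - log_effect) > 0.2 * se
  if (warn && any(asym, na.rm = TRUE))
    warning(sum(asym, na.rm = TRUE),
            " interval(s) not log-symmetric about the estimate; ",
            "se taken from the interval width, estimate not recentred")
  list(log_effect = log_effect, se = se)
}

validate_contrasts <- function(df, conf_level = 0.95) {
  required <- c("study_id", "treatment_a", "treatment_b", "n_a", "n_b",
                "endpoint", "measure", "estimate", "ci_lower", "ci_upper")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[required]

  num_cols <- c("n_a", "n_b", "estimate", "ci_lower", "ci_upper")
  for (col in num_cols) {
    raw <- df[[col]]
    if (is.character(raw)) raw[!nzchar(trimws(raw))] <- NA
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad))
      stop("malformed numeric field '", col, "' in row(s) ",
           paste(bad, collapse = ", "))
    df[[col]] <- val
  }
  for (col in c("study_id", "treatment_a", "treatment_b", "endpoint", "measure"))
    df[[col]] <- trimws(as.character(df[[col]]))

  bad_ep <- setdiff(unique(df$endpoint), ENDPOINTS)
  if (length(bad_ep))
    stop("unknown endpoint label(s): ", paste(bad_ep, collapse = ", "),
         " (expected ", paste(ENDPOINTS, collapse = ", "), ")")
  bad_m <- setdiff(unique(df$measure), MEASURES)
  if (length(bad_m))
    stop("unknown effect measure(s): ", paste(bad_m, collapse = ", "))
  if (any(df$treatment_a == df$treatment_b))
    stop("treatment_a equals treatment_b in row(s) ",
         paste(which(df$treatment_a == df$treatment_b), collapse = ", "))

  # rows lacking the effect cell for an endpoint simply carry no record
  skip <- is.na(df$estimate) | is.na(df$ci_lower) | is.na(df$ci_upper)
  if (any(skip)) {
    warning("skipping ", sum(skip), " row(s) with missing estimate or CI")
    df <- df[!skip, , drop = FALSE]
  }

  pair <- ifelse(df$treatment_a < df$treatment_b,
                 paste(df$treatment_a, df$treatment_b, sep = " | "),
                 paste(df$treatment_b, df$treatment_a, sep = " | "))
  key <- paste(df$study_id, df$endpoint, pair, sep = " / ")
  if (anyDuplicated(key))
    stop("duplicate (study_id, endpoint, treatment pair): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  # >2 arms per study within an endpoint would need a multi-arm likelihood
  se_key <- paste(df$study_id, df$endpoint, sep = " / ")
  multi <- tapply(pair, se_key, function(p) length(unique(p)))
  if (any(multi > 1))
    stop("study contributes more than one treatment pair to an endpoint ",
         "(multi-arm trials are not supported): ",
         paste(names(multi)[multi > 1], collapse = "; "))

  eff <- log_scale_effect(df$estimate, df$ci_lower, df$ci_upper, conf_level)
  df$log_effect <- eff$log_effect
  df$se <- eff$se
  rownames(df) <- NULL
  class(df) <- c("nma_contrasts", "data.frame")
  df
}

#' Read contrast-level trial records from a CSV file
#'
#' Expects a comma-delimited UTF-8 file with header columns `study_id`,
#' `treatment_a`, `treatment_b`, `n_a`, `n_b`, `endpoint`, `measure`,
#' `estimate`, `ci_lower`, `ci_upper`; one row per study x endpoint.
#' Endpoints are `OS`, `PFS`, `ORR`, `PCR_BREAST_AXILLA`, `PCR_BREAST`;
#' measures are `HR` or `RR`.  Effects are oriented as arm 1 versus arm 2:
#' HR < 1 means arm 1 had better survival, RR > 1 means arm 1 responded
#' more.  Rows with a missing estimate or interval are skipped with a
#' warning; malformed numerics and duplicated (study, endpoint, pair)
#' records are errors.  Log-scale effects and standard errors are derived on
#' load (see [log_scale_effect()]).
#'
#' @param path file path.
#' @param conf_level coverage of the reported intervals, default 0.95.
#' @return A `data.frame` of class `"nma_contrasts"` with derived columns
#'   `log_effect` and `se`.
#' @seealso [tnbc_trials()] for the packaged dataset, [write_contrasts()].
#' @export
read_contrasts <- function(path, conf_level = 0.95) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, colClasses = "character", check.names = TRUE,
                 fileEncoding = "UTF-8")
  validate_contrasts(df, conf_level = conf_level)
}

#' Coerce a data frame of trial records to validated contrasts
#'
#' @param df data frame following the schema of [read_contrasts()].
#' @param conf_level interval coverage used to derive standard errors.
#' @return A validated `"nma_contrasts"` data frame.
#' @export
as_contrasts <- function(df, conf_level = 0.95) {
  validate_contrasts(as.data.frame(df), conf_level = conf_level)
}

#' Write contrast records back to the CSV dialect read by [read_contrasts()]
#'
#' Derived columns are dropped; reloading reproduces `log_effect` and `se`
#' from the stored estimate and interval.
#'
#' @param x an `"nma_contrasts"` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contrasts <- function(x, path) {
  cols <- c("study_id", "treatment_a", "treatment_b", "n_a", "n_b",
            "endpoint", "measure", "estimate", "ci_lower", "ci_upper")
  out <- as.data.frame(x)[cols]
  # 17 significant digits so doubles survive the round trip exactly
  for (col in c("n_a", "n_b", "estimate", "ci_lower", "ci_upper")) {
    v <- sprintf("%.17g", out[[col]])
    v[is.na(out[[col]])] <- NA
    out[[col]] <- v
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8",
            na = "")
  invisible(path)
}

#' Targeted therapies versus chemotherapy in triple-negative breast cancer
#'
#' Contrast-level records of 27 randomized controlled trials (6924 patients)
#' comparing targeted agents, alone or added to chemotherapy, against
#' chemotherapy with or without placebo in triple-negative breast cancer.
#' Effects are hazard ratios (OS, PFS) or risk ratios (ORR, pCR) with 95%
#' confidence intervals as published.  Chemotherapy backbones are pooled
#' into a single `CT` node, and `CT + Placebo` is a distinct regimen because
#' placebo-controlled trials were blinded while the others were open label.
#' Two trials (Robert 2011 and Sikov 2015) each randomized two chemotherapy
#' backbones separately and appear as two sub-studies; Gray 2009 printed
#' only the combined arm total (232), stored once in `n_a`.
#'
#' @param conf_level interval coverage used to derive standard errors.
#' @return An `"nma_contrasts"` data frame with 56 records.
#' @examples
#' trials <- tnbc_trials()
#' table(trials$endpoint)
#' @export
tnbc_trials <- function(conf_level = 0.95) {
  path <- system.file("extdata", "tnbc_trials.csv", package = "contrastnma",
                      mustWork = TRUE)
  suppressWarnings(read_contrasts(path, conf_level = conf_level))
}

#' @export
print.nma_contrasts <- function(x, ...) {
  cat("Contrast-level trial records: ", nrow(x), " records, ",
      length(unique(x$study_id)), " studies, ",
      length(unique(c(x$treatment_a, x$treatment_b))), " treatments\n",
      sep = "")
  ep <- table(factor(x$endpoint, levels = ENDPOINTS))
  cat("Endpoints:", paste(names(ep)[ep > 0], ep[ep > 0], sep = "=",
                          collapse = ", "), "\n")
  NextMethod()
}
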