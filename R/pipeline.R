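#' Run the full evidence-synthesis pipeline and export every table
#'
#' For each requested endpoint: builds the evidence network (rejecting
#' disconnected ones with an error naming the stranded regimens), fits the
#' requested engines, and writes plot-ready CSV/JSON files to
#' `out_dir/<endpoint>/`: the network summary, league tables, basic
#' parameters, rankings (SUCRA and/or P-scores), rankogram coordinates,
#' the direct-versus-network consistency table, funnel and contribution
#' coordinates, and convergence/DIC reports.  A `manifest.json` at
#' `out_dir` records the seed, versions and MD5 checksum of every file, so
#' a rerun with the same inputs and seed is byte-identical.
#'
#' With `model = "auto"` both Bayesian models are fitted and the fixed-
#' effects model is kept unless the random-effects DIC is better by more
#' than 2 and its convergence diagnostics pass.
#'
#' @param data path to a contrasts CSV or an `"nma_contrasts"` data frame.
#' @param out_dir output directory (created if needed).
#' @param endpoints endpoints to analyse; default all present in the data.
#' @param engine `"both"`, `"bayes"` or `"freq"`.
#' @param model `"auto"`, `"fixed"` or `"random"` (Bayesian engine).
#' @param control Bayesian sampler schedule; `seed` overrides its seed.
#' @param seed master seed for all randomness in the run.
#' @param min_studies minimum direct evidence for a consistency-table row.
#' @return The manifest, invisibly.
#' @export
nma_run <- function(data, out_dir, endpoints = NULL,
                    engine = c("both", "bayes", "freq"),
                    model = c("auto", "fixed", "random"),
                    control = nma_control(), seed = control$seed,
                    min_studies = 2L) {
  engine <- match.arg(engine)
  model <- match.arg(model)
  contrasts <- if (is.character(data)) read_contrasts(data)
    else if (inherits(data, "nma_contrasts")) data
    else as_contrasts(data)
  endpoints <- endpoints %||% intersect(ENDPOINTS, unique(contrasts$endpoint))
  bad <- setdiff(endpoints, ENDPOINTS)
  if (length(bad)) stop("unknown endpoint label(s): ",
                        paste(bad, collapse = ", "))
  control$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  files <- character()
  selected <- list()
  emit_csv <- function(obj, path) {
    write.csv(obj, path, row.names = FALSE)
    files <<- c(files, path)
  }
  emit_json <- function(obj, path) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, path)
  }

  for (ep in endpoints) {
    net <- contrast_network(contrasts, ep)
    assert_connected(net)
    dir_ep <- file.path(out_dir, ep)
    dir.create(dir_ep, showWarnings = FALSE)
    ns <- summary(net)
    emit_csv(data.frame(endpoint = ep, n_nodes = ns$n_nodes,
                        n_edges = ns$n_edges, n_records = ns$n_records,
                        n_studies = ns$n_studies, n_trials = ns$n_trials,
                        n_patients = ns$n_patients),
             file.path(dir_ep, "network_summary.csv"))
    emit_csv(ns$edges, file.path(dir_ep, "edges.csv"))

    bfit <- NULL
    ffit <- NULL
    if (engine %in% c("both", "bayes")) {
      if (model == "auto") {
        fit_f <- nma(net, "bayes", "fixed", control)
        fit_r <- nma(net, "bayes", "random", control)
        use_random <- fit_r$dic$dic < fit_f$dic$dic - 2 &&
          fit_r$convergence$pass
        bfit <- if (use_random) fit_r else fit_f
        selected[[ep]] <- list(model = bfit$model,
                               dic_fixed = fit_f$dic$dic,
                               dic_random = fit_r$dic$dic)
      } else {
        bfit <- nma(net, "bayes", model, control)
        selected[[ep]] <- list(model = model, dic = bfit$dic$dic)
      }
      emit_csv(bfit$basic, file.path(dir_ep, "basic_parameters.csv"))
      emit_csv(as.data.frame(league_table(bfit)),
               file.path(dir_ep, "league_bayes.csv"))
      rk <- treatment_ranks(bfit)
      emit_csv(export_rankograms(rk), file.path(dir_ep, "rankograms.csv"))
      emit_csv(data.frame(treatment = names(rk$sucra),
                          sucra = unname(rk$sucra),
                          mean_rank = unname(rk$mean_rank[names(rk$sucra)])),
               file.path(dir_ep, "sucra.csv"))
      emit_csv(consistency_table(bfit, min_studies = min_studies),
               file.path(dir_ep, "consistency.csv"))
      emit_json(bfit$convergence, file.path(dir_ep, "convergence.json"))
      emit_json(bfit$dic, file.path(dir_ep, "dic.json"))
    }
    if (engine %in% c("both", "freq")) {
      ffit <- nma(net, "freq")
      emit_csv(as.data.frame(league_table(ffit)),
               file.path(dir_ep, "league_freq.csv"))
      ps <- p_scores(ffit)
      emit_csv(data.frame(treatment = names(ps$p_score),
                          p_score = unname(ps$p_score)),
               file.path(dir_ep, "pscores.csv"))
      cm <- contribution_matrix(ffit)
      emit_csv(data.frame(comparison = rownames(cm),
                          as.data.frame(unclass(cm), check.names = FALSE),
                          check.names = FALSE),
               file.path(dir_ep, "contribution.csv"))
      emit_csv(as.data.frame(funnel_coordinates(ffit)),
               file.path(dir_ep, "funnel.csv"))
      if (is.null(bfit))
        emit_csv(consistency_table(ffit, min_studies = min_studies),
                 file.path(dir_ep, "consistency.csv"))
    }
  }

  prefix <- paste0(sub("/+$", "", out_dir), "/")
  rel <- ifelse(startsWith(files, prefix),
                substring(files, nchar(prefix) + 1L), files)
  manifest <- list(
    seed = control$seed,
    engine = engine, model = model,
    endpoints = endpoints,
    model_selection = selected,
    package_version = as.character(utils::packageVersion("contrastnma")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    files = lapply(stats::setNames(seq_along(files), rel), function(i)
      list(md5 = unname(tools::md5sum(files[i]))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Rankogram coordinates in long format
#'
#' @param ranks an `"nma_ranks"` object from a Bayesian fit.
#' @param path optional CSV output path.
#' @return A data frame with columns `treatment`, `rank`, `probability`,
#'   `cumulative` (the coordinates of the rankogram and cumulative ranking
#'   curves).
#' @export
export_rankograms <- function(ranks, path = NULL) {
  stopifnot(inherits(ranks, "nma_ranks"), ranks$method == "SUCRA")
  prob <- ranks$rank_probabilities
  n <- ncol(prob)
  out <- data.frame(
    treatment = rep(rownames(prob), each = n),
    rank = rep(seq_len(n), times = nrow(prob)),
    probability = as.vector(t(prob)),
    cumulative = as.vector(t(ranks$cumulative))
  )
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
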