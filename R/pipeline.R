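#' Pipeline configuration
#'
#' Collects every option of the corpus -> panel -> fit -> networks ->
#' topics pipeline. Either a corpus (JSONL path or records data.frame) or
#' a ready panel (directory or [panel_data()]) must be supplied.
#'
#' @param corpus JSONL path or data.frame with id/date/text, or NULL.
#' @param panel panel directory (see [write_panel()]) or a [panel_data()],
#'   or NULL.
#' @param out_dir output directory.
#' @param stopwords character vector, or path to a one-per-line file.
#' @param merge_map named character vector raw -> canonical, or path to a
#'   two-column CSV `raw,canonical`.
#' @param lexicon a [topic_lexicon()], YAML path, or NULL.
#' @param K number of TF-IDF-ranked terms kept before synonym merging.
#' @param scale adjusted-term-frequency scale constant.
#' @param lambda1,lambda2 fixed penalty weights; when NULL, selected by
#'   [aic_select()] over `lambda1_grid`/`lambda2_grid`.
#' @param lambda1_grid,lambda2_grid optional tuning grids.
#' @param fit a [fit_config()] carrying solver options.
#' @param edge_threshold absolute precision threshold for edges.
#' @param resolution Louvain resolution.
#' @param min_module_size modules below this are flagged omitted.
#' @param hub_k hubs reported per phase per measure.
#' @param seed master seed (Louvain node order etc.).
#' @return Object of class `run_config`.
#' @export
run_config <- function(corpus = NULL, panel = NULL, out_dir = "fusedtgm_out",
                       stopwords = character(), merge_map = character(),
                       lexicon = NULL, K = 100, scale = 1000,
                       lambda1 = NULL, lambda2 = NULL,
                       lambda1_grid = NULL, lambda2_grid = NULL,
                       fit = fit_config(), edge_threshold = 1e-8,
                       resolution = 1, min_module_size = 3, hub_k = 5,
                       seed = 0) {
  if (is.null(corpus) && is.null(panel))
    stop("either a corpus or a panel must be supplied")
  structure(as.list(environment()), class = "run_config")
}

.load_config_inputs <- function(config) {
  sw <- config$stopwords
  if (is.character(sw) && length(sw) == 1 && file.exists(sw))
    sw <- readLines(sw, warn = FALSE)
  mm <- config$merge_map
  if (is.character(mm) && length(mm) == 1 && is.null(names(mm)) &&
      file.exists(mm)) {
    df <- utils::read.csv(mm, stringsAsFactors = FALSE)
    mm <- stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
  }
  lex <- config$lexicon
  if (is.character(lex)) lex <- read_lexicon_yaml(lex)
  docs <- NULL
  if (!is.null(config$corpus)) {
    docs <- if (is.data.frame(config$corpus)) make_documents(config$corpus)
            else read_corpus_jsonl(config$corpus)
  }
  list(stopwords = sw, merge_map = mm, lexicon = lex, documents = docs)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: corpus preparation (TF-IDF keyword ranking, synonym
#' merging, per-quarter adjusted-term-frequency panel) unless a panel is
#' supplied directly; joint fitting with tuning selection; per-phase
#' network construction; indicators, hubs, modules and topic assignment;
#' and topic-strength series when a corpus and lexicon are available.
#' Writes per-phase edge lists and GraphML, an indicator table, hub and
#' module tables, the strength series, and a JSON run manifest under
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `panel`, `fit`, `selection`, `phases`
#'   (per-phase networks/indicators/partitions), `strengths`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- .load_config_inputs(config)
  timings <- list()

  # --- prep ---------------------------------------------------------------
  tic <- Sys.time()
  if (!is.null(config$panel)) {
    panel <- if (inherits(config$panel, "panel_data")) config$panel
             else read_panel(config$panel)
  } else {
    tc <- count_terms(inputs$documents, inputs$stopwords)
    ranked <- tfidf_rank(tc, config$K)
    terms <- ranked$term
    canon <- terms
    hit <- canon %in% names(inputs$merge_map)
    canon[hit] <- unname(inputs$merge_map[canon[hit]])
    ks <- keyword_set(unique(canon),
                      inputs$merge_map[names(inputs$merge_map) %in% terms])
    panel <- build_panel(inputs$documents, ks, inputs$stopwords,
                         scale = config$scale)
    write_panel(panel, file.path(config$out_dir, "panel"),
                scale = config$scale)
  }
  timings$prep <- as.numeric(Sys.time() - tic, units = "secs")

  # --- fit ----------------------------------------------------------------
  tic <- Sys.time()
  selection <- NULL
  if (!is.null(config$lambda1) && !is.null(config$lambda2)) {
    cfg <- config$fit
    cfg$lambda1 <- config$lambda1
    cfg$lambda2 <- config$lambda2
    fit <- fit_joint(panel, cfg)
  } else {
    selection <- aic_select(panel, config$lambda1_grid, config$lambda2_grid,
                            config$fit)
    fit <- selection$fit
    utils::write.csv(selection$table,
                     file.path(config$out_dir, "lambda_selection.csv"),
                     row.names = FALSE)
  }
  phase_tab <- data.frame(
    phase = seq_along(fit$phases),
    first_period = panel$periods[vapply(fit$phases, min, 0L)],
    last_period = panel$periods[vapply(fit$phases, max, 0L)])
  utils::write.csv(phase_tab, file.path(config$out_dir, "phases.csv"),
                   row.names = FALSE)
  timings$fit <- as.numeric(Sys.time() - tic, units = "secs")

  # --- networks, hubs, modules -------------------------------------------
  tic <- Sys.time()
  phases <- vector("list", length(fit$phases))
  ind_rows <- hub_rows <- mod_rows <- list()
  for (i in seq_along(fit$phases)) {
    mm <- fit$phases[[i]]
    label <- if (length(mm) > 1)
      paste(panel$periods[min(mm)], panel$periods[max(mm)], sep = "-")
    else panel$periods[mm]
    net <- build_network(fit$estimates[[mm[1]]]$Theta,
                         threshold = config$edge_threshold)
    ind <- cbind(phase = label, network_indicators(net))
    ind_rows[[i]] <- ind
    res <- list(label = label, network = net, indicators = ind)
    el <- igraph::as_edgelist(net$graph)
    utils::write.csv(data.frame(from = el[, 1], to = el[, 2]),
                     file.path(config$out_dir,
                               sprintf("edges_phase%02d.csv", i)),
                     row.names = FALSE)
    igraph::write_graph(net$graph,
                        file.path(config$out_dir,
                                  sprintf("network_phase%02d.graphml", i)),
                        format = "graphml")
    if (net$q >= 1) {
      cent <- centralities(net)
      hub_rows[[i]] <- data.frame(
        phase = label,
        measure = rep(c("degree", "eigenvector"), each = config$hub_k),
        rank = rep(seq_len(config$hub_k), 2),
        keyword = c(top_hubs(cent, config$hub_k, "degree"),
                    top_hubs(cent, config$hub_k, "eigenvector")))
      part <- filter_small_modules(
        louvain(net, config$resolution, seed = config$seed),
        config$min_module_size)
      shares <- module_shares(part)
      topics <- if (!is.null(inputs$lexicon))
        assign_topics(part, inputs$lexicon) else NULL
      mod_rows[[i]] <- cbind(phase = label, shares,
                             topic = if (is.null(topics)) NA
                                     else topics$topic,
                             modularity = part$modularity)
      res$centralities <- cent
      res$partition <- part
      res$topics <- topics
    }
    phases[[i]] <- res
  }
  utils::write.csv(do.call(rbind, ind_rows),
                   file.path(config$out_dir, "indicators.csv"),
                   row.names = FALSE)
  if (length(hub_rows))
    utils::write.csv(do.call(rbind, hub_rows),
                     file.path(config$out_dir, "hubs.csv"),
                     row.names = FALSE)
  if (length(mod_rows))
    utils::write.csv(do.call(rbind, mod_rows),
                     file.path(config$out_dir, "modules.csv"),
                     row.names = FALSE)
  timings$networks <- as.numeric(Sys.time() - tic, units = "secs")

  # --- topic strengths ----------------------------------------------------
  strengths <- NULL
  if (!is.null(inputs$documents) && !is.null(inputs$lexicon)) {
    tic <- Sys.time()
    strengths <- topic_strengths(inputs$documents, inputs$lexicon)
    utils::write.csv(strengths,
                     file.path(config$out_dir, "topic_strengths.csv"),
                     row.names = FALSE)
    timings$strengths <- as.numeric(Sys.time() - tic, units = "secs")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("fusedtgm")),
    seed = config$seed,
    lambda1 = fit$lambda1, lambda2 = fit$lambda2,
    lambda_selected = !is.null(selection),
    n_periods = panel$M, p = panel$p,
    phases = lapply(fit$phases, range),
    change_points = fit$change_points,
    timings_sec = timings,
    total_sec = as.numeric(Sys.time() - t0, units = "secs"))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(panel = panel, fit = fit, selection = selection,
                 phases = phases, strengths = strengths,
                 manifest = manifest))
}
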