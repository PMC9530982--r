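#' Pipeline commands: simulate, build, describe, fit
#'
#' Composable steps mirroring the analysis workflow; each writes its
#' outputs plus a JSON run manifest (command, configuration hash, seed,
#' package version, paths, dropped-record counts) so any artifact is
#' traceable. A thin command-line wrapper over these functions ships at
#' `system.file("scripts", "confnet-cli.R", package = "confnet")`.
#'
#' @param config A [community_config()], or the path of a YAML/JSON file
#'   of its fields.
#' @param out_dir Output directory.
#' @param seed Optional integer overriding the config seed.
#' @return Invisibly, a list with the main in-memory objects and the
#'   written paths.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_simulate <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    fields <- read_config_file(config)
    if (!is.null(seed)) fields$seed <- seed
    fields <- fields[intersect(names(fields),
                               names(formals(community_config)))]
    config <- do.call(community_config, fields)
  } else if (!is.null(seed)) {
    fields <- unclass(config)
    fields$theta_terms <- paste0(
      ifelse(is.na(fields$theta_terms$attribute), fields$theta_terms$kind,
             paste0(fields$theta_terms$kind, ":",
                    fields$theta_terms$attribute)))
    fields$seed <- seed
    config <- do.call(community_config, fields)
  }
  sim <- simulate_community(config)
  paths <- write_survey(sim$survey, out_dir)
  manifest_path <- file.path(out_dir, "manifest.json")
  cfg <- unclass(config)
  cfg$theta_terms <- cfg$theta_terms$label
  write_manifest(manifest_path, "simulate", cfg, config$seed,
                 outputs = as.list(paths),
                 extra = list(n_participants = nrow(
                   sim$survey$participants)))
  invisible(list(simulation = sim, paths = c(paths,
                                             manifest = manifest_path)))
}

#' @rdname pipeline
#' @param survey_dir Directory holding `participants.csv`,
#'   `household_members.csv` and `nominations.csv` (as written by
#'   [cmd_simulate()] / [write_survey()]).
#' @param rules A [tie_rules()] object.
#' @export
cmd_build <- function(survey_dir, out_dir, rules = tie_rules()) {
  tables <- read_survey(survey_dir)
  built <- build_network(tables$participants, tables$household_members,
                         tables$nominations, rules = rules)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(edges = file.path(out_dir, "edges.tsv"),
             node_data = file.path(out_dir, "node_data.csv"),
             match_report = file.path(out_dir, "match_report.jsonl"))
  write_edge_list(built$network$edges, paths["edges"])
  write_utf8_csv(built$network$node_data, paths["node_data"])
  write_match_report(built$match_report, paths["match_report"])
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest_path, "build", list(rules = unclass(rules)),
                 seed = NULL, inputs = list(survey_dir = survey_dir),
                 outputs = as.list(paths),
                 extra = list(n_nodes = network_size(built$network),
                              n_edges = nrow(built$network$edges),
                              n_excluded = built$n_excluded))
  invisible(list(built = built, paths = c(paths,
                                          manifest = manifest_path)))
}

#' @rdname pipeline
#' @param network_dir Directory holding `edges.tsv` and `node_data.csv`
#'   (as written by [cmd_build()]).
#' @export
cmd_describe <- function(network_dir, out_dir) {
  net <- read_network_dir(network_dir)
  desc <- describe_network(net)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(json = file.path(out_dir, "descriptives.json"),
             csv = file.path(out_dir, "descriptives.csv"))
  flat <- unclass(desc)
  jsonlite::write_json(flat, paths["json"], auto_unbox = TRUE,
                       digits = NA, na = "null")
  write_utf8_csv(as.data.frame(desc), paths["csv"])
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest_path, "describe", list(), seed = NULL,
                 inputs = list(network_dir = network_dir),
                 outputs = as.list(paths))
  invisible(list(descriptives = desc, paths = c(paths,
                                                manifest = manifest_path)))
}

#' @rdname pipeline
#' @param model Term specification: a character vector, an
#'   [ergm_terms()] object, or the path of a YAML/JSON file with a
#'   `terms` field (and optionally `method`).
#' @param method Estimation method: "exact" (default), "mple" or
#'   "mcmle".
#' @export
cmd_fit <- function(network_dir, model, out_dir,
                    method = c("exact", "mple", "mcmle"), seed = NULL) {
  if (is.character(model) && length(model) == 1 &&
        file.exists(model)) {
    cfg <- read_config_file(model)
    if (!is.null(cfg$method) && missing(method)) method <- cfg$method
    model <- unlist(cfg$terms)
  }
  method <- match.arg(method)
  net <- read_network_dir(network_dir)
  fit <- switch(method,
                exact = fit_exact(net, model),
                mple = fit_mple(net, model),
                mcmle = fit_mcmle(net, model, seed = seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(out_dir, "fit_table.csv"),
             json = file.path(out_dir, "fit.json"))
  write_utf8_csv(format_fit_table(fit), paths["table"])
  jsonlite::write_json(
    list(method = fit$method, converged = fit$converged,
         loglik = fit$loglik, n_nodes = fit$n_nodes,
         n_dropped = fit$n_dropped,
         estimates = as.data.frame(fit)),
    paths["json"], auto_unbox = TRUE, digits = NA, na = "null")
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(manifest_path, "fit",
                 list(terms = ergm_terms(model)$label, method = method),
                 seed = seed, inputs = list(network_dir = network_dir),
                 outputs = as.list(paths),
                 extra = list(n_dropped = fit$n_dropped,
                              converged = fit$converged))
  invisible(list(fit = fit, paths = c(paths, manifest = manifest_path)))
}

read_network_dir <- function(network_dir) {
  edges <- read_edge_list(file.path(network_dir, "edges.tsv"))
  node_data <- read_utf8_csv(file.path(network_dir, "node_data.csv"))
  confidant_network(node_data$participant_id, edges,
                    node_data = node_data)
}
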