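#' Read and write the survey-table dialect
#'
#' The pipeline exchanges plain UTF-8 delimited text: participants,
#' household members and nominations as CSV, edge lists as TSV
#' (`source`, `target`, `provenance`), match reports as JSON lines. The
#' column dictionary shipped at
#' `system.file("extdata", "column_dictionary.csv", package = "confnet")`
#' documents every column.
#'
#' @param survey A `community_survey` (from [emit_survey()]).
#' @param dir Output directory (created if needed).
#' @return `write_survey` invisibly returns the written file paths.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "community_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    participants = file.path(dir, "participants.csv"),
    household_members = file.path(dir, "household_members.csv"),
    nominations = file.path(dir, "nominations.csv"),
    truth_edges = file.path(dir, "truth_edges.tsv")
  )
  write_utf8_csv(survey$participants, paths["participants"])
  write_utf8_csv(survey$household_members, paths["household_members"])
  write_utf8_csv(survey$nominations, paths["nominations"])
  write_edge_list(survey$truth_edges, paths["truth_edges"])
  invisible(paths)
}

#' @rdname write_survey
#' @export
read_survey <- function(dir) {
  list(
    participants = read_utf8_csv(file.path(dir, "participants.csv")),
    household_members = read_utf8_csv(file.path(dir,
                                                "household_members.csv")),
    nominations = read_utf8_csv(file.path(dir, "nominations.csv"))
  )
}

write_utf8_csv <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE)
}

read_utf8_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Write / read a directed edge list (TSV)
#' @param edges Data frame with `from`, `to` and optionally `provenance`.
#' @param path File path.
#' @export
write_edge_list <- function(edges, path) {
  out <- data.frame(source = edges$from, target = edges$to,
                    provenance = if ("provenance" %in% names(edges))
                      edges$provenance else NA_character_)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  data.frame(from = as.character(df$source), to = as.character(df$target),
             provenance = if ("provenance" %in% names(df))
               as.character(df$provenance) else NA_character_,
             stringsAsFactors = FALSE)
}

#' Write a match report as JSON lines
#' @param report Match-report data frame (see [match_nomination()]).
#' @param path File path.
#' @export
write_match_report <- function(report, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in seq_len(nrow(report))) {
    writeLines(jsonlite::toJSON(as.list(report[k, , drop = FALSE]),
                                auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

#' Export a network to GraphML with node attributes
#'
#' Optional plumbing for external visualisation tools; layout and
#' aesthetics are left to the consumer.
#'
#' @param net A [confidant_network()].
#' @param path Output file.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  if (!is.null(net$node_data)) {
    for (col in setdiff(names(net$node_data), "participant_id")) {
      v <- net$node_data[[col]]
      if (!anyNA(v)) g <- igraph::set_vertex_attr(g, col, value = v)
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# model / community configuration files: YAML or JSON by extension
read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

write_manifest <- function(path, command, config, seed, inputs = NULL,
                           outputs = NULL, extra = NULL) {
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              na = "null"), cfg_file)
  manifest <- c(list(
    command = command,
    package_version = as.character(utils::packageVersion("confnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    config = config,
    inputs = inputs,
    outputs = outputs
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(path)
}
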