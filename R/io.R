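# CSV schemas shared by all pipeline stages. Files are UTF-8, "." decimal,
# header required; an optional leading comment line "#schema=<name>" records
# the schema version.

.schemas <- list(
  track = c(player_id = "character", t = "numeric", x = "numeric",
            y = "numeric", period = "character"),
  ball = c(kick_id = "character", t = "numeric", x = "numeric",
           y = "numeric", z = "numeric", is_contact = "integer"),
  crossings = c(kick_id = "character", x = "numeric", z = "numeric"),
  force = c(t = "numeric", force_N = "numeric", stim = "integer"),
  emg = c(t = "numeric", mv = "numeric", stim = "integer"),
  breaths = c(t = "numeric", vo2 = "numeric", vco2 = "numeric",
              hr = "numeric", stage_kmh = "numeric"),
  lactate = c(period = "character", mmol = "numeric"),
  hr = c(t = "numeric", bpm = "numeric", period = "character"),
  paired = c(subject = "character", variable = "character",
             before = "numeric", after = "numeric"),
  running_summary = c(player_id = "character", scope = "character",
                      DC_m = "numeric", DCmin_m_per_min = "numeric",
                      S_N = "integer", S_T_s = "numeric"),
  kicks = c(kick_id = "character", set = "integer", speed_kmh = "numeric",
            vx = "numeric", vy = "numeric", vz = "numeric",
            cross_x = "numeric", cross_z = "numeric",
            accuracy_m = "numeric", flags = "character"),
  effects = c(variable = "character", mean_before = "numeric",
              sd_before = "numeric", mean_after = "numeric",
              sd_after = "numeric", delta_mean = "numeric",
              delta_sd = "numeric", t = "numeric", p = "numeric",
              d = "numeric", magnitude = "character", swc = "numeric",
              positive = "numeric", trivial = "numeric",
              negative = "numeric", inference = "character")
)

#' List the pipeline CSV schemas
#'
#' @return Named list mapping schema name to its column-name/type vector.
#' @export
pipeline_schemas <- function() .schemas

#' Read a pipeline CSV, validating its schema
#'
#' @param path file path.
#' @param schema schema name (see [pipeline_schemas()]).
#' @return Data frame with the schema's columns, in schema order.
#' @export
read_pipeline_csv <- function(path, schema) {
  sch <- .schemas[[schema]]
  if (is.null(sch)) stop_config("unknown schema '%s'", schema)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  miss <- setdiff(names(sch), names(df))
  if (length(miss)) {
    stop_config("%s: missing column(s): %s", path,
                paste(miss, collapse = ", "))
  }
  for (cn in names(sch)) {
    want <- sch[[cn]]
    if (want %in% c("numeric", "integer")) {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      bad <- which(is.na(v) & !is.na(df[[cn]]) & df[[cn]] != "NA")
      if (length(bad)) {
        stop_config("%s: column '%s' fails numeric parse at row %d (value '%s')",
                    path, cn, bad[1], df[[cn]][bad[1]])
      }
      df[[cn]] <- if (want == "integer") as.integer(round(v)) else v
    } else {
      df[[cn]] <- as.character(df[[cn]])
    }
  }
  df[, names(sch), drop = FALSE]
}

#' Write a pipeline CSV with its schema tag
#'
#' @param df data frame carrying at least the schema's columns.
#' @param path output path.
#' @param schema schema name.
#' @return `path`, invisibly.
#' @export
write_pipeline_csv <- function(df, path, schema) {
  sch <- .schemas[[schema]]
  if (is.null(sch)) stop_config("unknown schema '%s'", schema)
  miss <- setdiff(names(sch), names(df))
  if (length(miss)) stop_config("missing column(s) for schema '%s': %s",
                                schema, paste(miss, collapse = ", "))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#schema=%s/1", schema), con)
  utils::write.csv(df[, names(sch), drop = FALSE], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Load a JSON study configuration
#'
#' Reads a JSON file of [study_config()] arguments; a `seed` entry is
#' mandatory so that every simulation step is reproducible.
#'
#' @param path JSON file path.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$seed)) stop_config("config must declare a seed")
  do.call(study_config, raw)
}
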