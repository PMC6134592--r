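#' Persist a datacube as a single-file relational database
#'
#' The cube is stored in the SQLite3 file format with a relational layout of
#' five tables — `environments`, `organisms`, `metabolites`, `projects` and
#' `observations` — where each observation row references the three dimension
#' tables (and optionally a project) by integer foreign key, with a uniqueness
#' constraint on the (metabolite, organism, environment) triple. The file can
#' be opened by any standard SQLite tooling.
#'
#' @param cube a [datacube()].
#' @param path database file to create (overwritten if present).
#' @return `path`, invisibly.
#' @seealso [load_db()]
#' @examples
#' f <- tempfile(fileext = ".sqlite")
#' save_db(worked_example_fixture(), f)
#' cube <- load_db(f)
#' @export
save_db <- function(cube, path) {
  stopifnot(inherits(cube, "datacube"))
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")

  DBI::dbExecute(con, "CREATE TABLE environments (
    id INTEGER PRIMARY KEY, name TEXT NOT NULL UNIQUE, description TEXT)")
  DBI::dbExecute(con, "CREATE TABLE organisms (
    id INTEGER PRIMARY KEY, name TEXT NOT NULL UNIQUE,
    is_control INTEGER NOT NULL, description TEXT)")
  DBI::dbExecute(con, "CREATE TABLE metabolites (
    id INTEGER PRIMARY KEY, name TEXT NOT NULL UNIQUE,
    putative INTEGER NOT NULL, annotation TEXT, msi_level INTEGER)")
  DBI::dbExecute(con, "CREATE TABLE projects (
    id INTEGER PRIMARY KEY, name TEXT NOT NULL UNIQUE)")
  DBI::dbExecute(con, "CREATE TABLE observations (
    id INTEGER PRIMARY KEY,
    metabolite_id INTEGER NOT NULL REFERENCES metabolites(id),
    organism_id INTEGER NOT NULL REFERENCES organisms(id),
    environment_id INTEGER NOT NULL REFERENCES environments(id),
    action TEXT NOT NULL, log2fc REAL, confidence REAL NOT NULL,
    p_value REAL, project_id INTEGER REFERENCES projects(id),
    UNIQUE (metabolite_id, organism_id, environment_id))")

  with_id <- function(df) {
    df <- df[.lex_order(df$name), , drop = FALSE]
    cbind(id = seq_len(nrow(df)), df)
  }
  env <- with_id(cube$environments)
  org <- with_id(cube$organisms)
  met <- with_id(cube$metabolites)
  projects <- .lex_sort(unique(stats::na.omit(cube$observations$project)))
  prj <- data.frame(id = seq_along(projects), name = projects,
                    stringsAsFactors = FALSE)

  DBI::dbWriteTable(con, "environments", env, append = TRUE)
  DBI::dbWriteTable(con, "organisms",
                    transform(org, is_control = as.integer(is_control)),
                    append = TRUE)
  DBI::dbWriteTable(con, "metabolites",
                    transform(met, putative = as.integer(putative)),
                    append = TRUE)
  if (nrow(prj) > 0) DBI::dbWriteTable(con, "projects", prj, append = TRUE)

  obs <- .sorted_observations(cube)
  lookup <- function(tab, x) tab$id[match(x, tab$name)]
  obs_rows <- data.frame(
    id = seq_len(nrow(obs)),
    metabolite_id = lookup(met, obs$metabolite),
    organism_id = lookup(org, obs$organism),
    environment_id = lookup(env, obs$environment),
    action = obs$action, log2fc = obs$log2fc, confidence = obs$confidence,
    p_value = obs$p_value, project_id = lookup(prj, obs$project))
  if (nrow(obs_rows) > 0)
    DBI::dbWriteTable(con, "observations", obs_rows, append = TRUE)
  invisible(path)
}

#' Load a datacube from its relational database file
#'
#' Reads the five-table SQLite layout written by [save_db()] back into a
#' [datacube()]. Referential integrity is checked: an observation pointing at
#' a missing metabolite, organism, environment or project raises an integrity
#' error.
#'
#' @param path database file.
#' @return A [datacube()].
#' @export
load_db <- function(path) {
  if (!file.exists(path)) stop("no such database file: ", path, call. = FALSE)
  con <- tryCatch(DBI::dbConnect(RSQLite::SQLite(), path),
                  error = function(e) stop("cannot open database: ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(DBI::dbDisconnect(con))
  need <- c("environments", "organisms", "metabolites", "observations")
  have <- DBI::dbListTables(con)
  if (!all(need %in% have))
    stop("not a datacube database; missing table(s): ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)

  env <- DBI::dbReadTable(con, "environments")
  org <- DBI::dbReadTable(con, "organisms")
  met <- DBI::dbReadTable(con, "metabolites")
  prj <- if ("projects" %in% have) DBI::dbReadTable(con, "projects") else
    data.frame(id = integer(), name = character())
  obs <- DBI::dbReadTable(con, "observations")

  resolve <- function(ids, tab, what, optional = FALSE) {
    out <- tab$name[match(ids, tab$id)]
    dangling <- if (optional) !is.na(ids) & is.na(out) else is.na(out)
    if (any(dangling))
      stop("integrity error: observation references missing ", what,
           " id ", paste(unique(ids[dangling]), collapse = ", "),
           call. = FALSE)
    out
  }
  observations <- data.frame(
    metabolite = resolve(obs$metabolite_id, met, "metabolite"),
    organism = resolve(obs$organism_id, org, "organism"),
    environment = resolve(obs$environment_id, env, "environment"),
    action = obs$action, log2fc = obs$log2fc, confidence = obs$confidence,
    p_value = obs$p_value,
    project = if ("project_id" %in% names(obs))
      resolve(obs$project_id, prj, "project", optional = TRUE) else
        NA_character_,
    stringsAsFactors = FALSE)

  datacube(observations = observations,
           metabolites = transform(met[, c("name", "putative", "annotation",
                                           "msi_level")],
                                   putative = putative == 1),
           organisms = org[, c("name", "description")],
           environments = env[, c("name", "description")])
}
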