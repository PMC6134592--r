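#' Upload file dialect
#'
#' Observation uploads are delimited text with a header row and, at a minimum,
#' columns for metabolites, organisms, environments and action assertions; the
#' optional columns carry the fold change, confidence, p-value and project
#' tag. Header matching is case-insensitive and extra synonyms can be
#' supplied. The native separator is the tab; CSV is accepted by setting
#' `sep = ","`.
#'
#' @param sep field separator: `"\t"` (default) or `","`.
#' @param strict in strict mode any row-level problem (unknown action string,
#'   duplicate observation key) rejects the whole file; in lenient mode
#'   offending rows are dropped (duplicates keep the first occurrence) with a
#'   warning.
#' @param synonyms named list mapping canonical column names
#'   (`metabolites`, `organisms`, `environments`, `action assertions`,
#'   `log2fc`, `confidence`, `p_value`, `project`) to extra accepted header
#'   spellings.
#' @return An object of class `"upload_dialect"`.
#' @seealso [parse_upload()], [write_upload()]
#' @export
upload_dialect <- function(sep = "\t", strict = TRUE, synonyms = list()) {
  stopifnot(sep %in% c("\t", ","), is.logical(strict), length(strict) == 1L)
  canon <- .upload_columns
  bad <- setdiff(names(synonyms), canon)
  if (length(bad) > 0)
    stop("synonyms for unknown column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(sep = sep, strict = strict, synonyms = synonyms),
            class = "upload_dialect")
}

.upload_columns <- c("metabolites", "organisms", "environments",
                     "action assertions", "log2fc", "confidence", "p_value",
                     "project")
.required_columns <- .upload_columns[1:4]

.match_headers <- function(headers, dialect) {
  norm <- function(x) gsub("[[:space:]_]+", " ", tolower(trimws(x)))
  hnorm <- norm(headers)
  idx <- stats::setNames(rep(NA_integer_, length(.upload_columns)),
                         .upload_columns)
  for (col in .upload_columns) {
    accepted <- norm(c(col, unlist(dialect$synonyms[[col]])))
    hit <- which(hnorm %in% accepted)
    if (length(hit) > 0) idx[[col]] <- hit[[1]]
  }
  idx
}

#' Read an observation upload file into a datacube
#'
#' Parses a delimited assertion upload: one observation per data row. Action
#' strings are matched case-insensitively against the upload vocabulary
#' (increase, decrease, no change, detected, not detected, not investigated).
#' Rows for the control pseudo-organism `"The Environment"` may only assert
#' detected / not detected; organism rows only the remaining four actions.
#' Metabolite names written in parentheses mark putative identifications; the
#' parentheses are stripped and the `putative` flag set. Metabolites,
#' organisms and environments are auto-registered as they appear.
#'
#' @param path file to read.
#' @param dialect an [upload_dialect()].
#' @return A [datacube()].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(paste(
#'   c("metabolites\torganisms\tenvironments\taction assertions",
#'     "adenine\tThe Environment\tR2A\tdetected",
#'     "adenine\tOrgA\tR2A\tdecrease"), collapse = "\n"), f)
#' parse_upload(f)
#' @export
parse_upload <- function(path, dialect = upload_dialect()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = dialect$sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "", fill = FALSE,
                           blank.lines.skip = FALSE, fileEncoding = "UTF-8")
  idx <- .match_headers(names(raw), dialect)
  miss <- .required_columns[is.na(idx[.required_columns])]
  if (length(miss) > 0)
    stop("upload format error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  n <- nrow(raw)
  get <- function(col) {
    if (is.na(idx[[col]])) rep(NA_character_, n) else raw[[idx[[col]]]]
  }
  met_raw <- trimws(get("metabolites"))
  putative <- grepl("^\\(.*\\)$", met_raw)
  met <- ifelse(putative, sub("^\\((.*)\\)$", "\\1", met_raw), met_raw)
  org <- trimws(get("organisms"))
  env <- trimws(get("environments"))
  action <- .parse_action(get("action assertions"))
  line <- seq_len(n) + 1L  # header is line 1

  problems <- character()
  bad_action <- is.na(action)
  if (any(bad_action))
    problems <- c(problems, sprintf(
      "line %d: action '%s' outside the upload vocabulary",
      line[bad_action], get("action assertions")[bad_action]))
  is_ctrl <- org == control_name()
  bad_ctrl <- !bad_action &
    ((is_ctrl & !action %in% control_actions()) |
       (!is_ctrl & action %in% control_actions()))
  if (any(bad_ctrl))
    problems <- c(problems, sprintf(
      "line %d: action '%s' is not legal for organism '%s'",
      line[bad_ctrl], action[bad_ctrl], org[bad_ctrl]))

  drop <- bad_action | bad_ctrl
  key <- paste(met, org, env, sep = "\r")
  dup <- duplicated(key) & !drop
  if (any(dup))
    problems <- c(problems, sprintf(
      "line %d: duplicate observation key (%s, %s, %s)",
      line[dup], met[dup], org[dup], env[dup]))

  if (length(problems) > 0) {
    if (dialect$strict)
      stop("upload rejected:\n  - ", paste(problems, collapse = "\n  - "),
           call. = FALSE)
    warning("dropped ", sum(drop | dup), " row(s):\n  - ",
            paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  keep <- !(drop | dup)

  num <- function(col) suppressWarnings(as.numeric(get(col)))
  obs <- data.frame(metabolite = met, organism = org, environment = env,
                    action = action, log2fc = num("log2fc"),
                    confidence = num("confidence"), p_value = num("p_value"),
                    project = get("project"), stringsAsFactors = FALSE)
  obs$project[!is.na(obs$project) & !nzchar(trimws(obs$project))] <-
    NA_character_
  obs <- obs[keep, , drop = FALSE]

  met_tab <- unique(data.frame(name = met[keep], putative = putative[keep],
                               stringsAsFactors = FALSE))
  conflict <- unique(met_tab$name[duplicated(met_tab$name)])
  if (length(conflict) > 0)  # same compound both plain and parenthesised
    met_tab <- met_tab[!(met_tab$name %in% conflict & !met_tab$putative), ,
                       drop = FALSE]
  datacube(observations = obs, metabolites = met_tab)
}

#' Write a datacube as an observation upload file
#'
#' Serialises every observation in the canonical upload dialect: header row
#' with the canonical column names, rows ordered lexicographically by
#' (environment, organism, metabolite), actions in the upload vocabulary,
#' putative metabolite names wrapped in parentheses, missing numeric fields
#' left empty. `parse_upload(write_upload(cube))` reproduces the cube
#' observation-for-observation.
#'
#' @param cube a [datacube()].
#' @param path file to write.
#' @param dialect an [upload_dialect()] (only the separator is used).
#' @return `path`, invisibly.
#' @export
write_upload <- function(cube, path, dialect = upload_dialect()) {
  stopifnot(inherits(cube, "datacube"))
  obs <- .sorted_observations(cube)
  putative <- stats::setNames(cube$metabolites$putative, cube$metabolites$name)
  met <- ifelse(isTRUE_vec(putative[obs$metabolite]),
                paste0("(", obs$metabolite, ")"), obs$metabolite)
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15, trim = TRUE,
                                                 scientific = FALSE))
  out <- data.frame(met, obs$organism, obs$environment,
                    unname(.action_file_form[obs$action]),
                    fmt(obs$log2fc), fmt(obs$confidence), fmt(obs$p_value),
                    ifelse(is.na(obs$project), "", obs$project),
                    stringsAsFactors = FALSE)
  names(out) <- .upload_columns
  utils::write.table(out, path, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
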