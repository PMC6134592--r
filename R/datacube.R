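#' Assemble an exometabolomics assertion datacube
#'
#' A datacube is the three-dimensional object at the heart of curated
#' exometabolomics data: every observation asserts the action of one organism
#' (or of the untransformed control, the reserved pseudo-organism
#' `"The Environment"`) on one metabolite in one environment. The cube holds
#' keyed record tables for the three dimensions plus the observation table
#' that ties them together; all slice views, compatibility scores and webs are
#' computed from it.
#'
#' Records referenced by `observations` but absent from the record tables are
#' auto-registered with default attributes. A control organism record is
#' always present.
#'
#' @param observations data frame with columns `metabolite`, `organism`,
#'   `environment`, `action` (canonical codes, see [action_codes()]) and
#'   optionally `log2fc`, `confidence`, `p_value`, `project`. When
#'   `confidence` is missing it is derived: `min(abs(log2fc), 5)` for
#'   directional actions with a fold change, the cap of 5 for directional
#'   actions without one, and 0 otherwise.
#' @param metabolites data frame with column `name` and optionally `putative`
#'   (logical; putative identifications are serialised with the name in
#'   parentheses), `annotation`, `msi_level`.
#' @param organisms data frame with column `name` and optionally
#'   `description`. The control record is added automatically.
#' @param environments data frame with column `name` and optionally
#'   `description`.
#' @param check validate the assembled cube and fail on violations.
#' @return An object of class `"datacube"`: a list with elements
#'   `metabolites`, `organisms`, `environments`, `observations`.
#' @seealso [validate_cube()], [parse_upload()], [generate_cube()]
#' @examples
#' obs <- data.frame(
#'   metabolite  = c("adenine", "adenine"),
#'   organism    = c(control_name(), "OrgA"),
#'   environment = "R2A",
#'   action      = c("detected", "decreased"),
#'   log2fc      = c(NA, -1.5)
#' )
#' cube <- datacube(obs)
#' cube
#' @export
datacube <- function(observations = NULL, metabolites = NULL,
                     organisms = NULL, environments = NULL, check = TRUE) {
  obs <- .canonical_observations(observations)

  met <- .canonical_records(metabolites,
                            list(putative = FALSE, annotation = NA_character_,
                                 msi_level = NA_integer_))
  org <- .canonical_records(organisms,
                            list(is_control = FALSE,
                                 description = NA_character_))
  env <- .canonical_records(environments, list(description = NA_character_))

  # auto-register references
  met <- .register_names(met, obs$metabolite,
                         list(putative = FALSE, annotation = NA_character_,
                              msi_level = NA_integer_))
  org <- .register_names(org, obs$organism,
                         list(is_control = FALSE, description = NA_character_))
  env <- .register_names(env, obs$environment,
                         list(description = NA_character_))

  if (!control_name() %in% org$name) {
    org <- rbind(org, data.frame(name = control_name(), is_control = TRUE,
                                 description = "untransformed control pool",
                                 stringsAsFactors = FALSE))
  }
  org$is_control <- org$name == control_name()

  cube <- structure(
    list(metabolites = met, organisms = org, environments = env,
         observations = obs),
    class = "datacube")
  if (check) {
    bad <- validate_cube(cube)
    if (length(bad) > 0)
      stop("invalid datacube:\n  - ", paste(bad, collapse = "\n  - "),
           call. = FALSE)
  }
  cube
}

.obs_columns <- c("metabolite", "organism", "environment", "action",
                  "log2fc", "confidence", "p_value", "project")

.canonical_observations <- function(observations) {
  if (is.null(observations) || nrow(as.data.frame(observations)) == 0) {
    return(data.frame(metabolite = character(), organism = character(),
                      environment = character(), action = character(),
                      log2fc = numeric(), confidence = numeric(),
                      p_value = numeric(), project = character(),
                      stringsAsFactors = FALSE))
  }
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  need <- c("metabolite", "organism", "environment", "action")
  miss <- setdiff(need, names(obs))
  if (length(miss) > 0)
    stop("observations lack required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(obs$log2fc)) obs$log2fc <- NA_real_
  if (is.null(obs$p_value)) obs$p_value <- NA_real_
  if (is.null(obs$project)) obs$project <- NA_character_
  if (is.null(obs$confidence)) obs$confidence <- NA_real_
  obs$log2fc <- as.numeric(obs$log2fc)
  obs$p_value <- as.numeric(obs$p_value)
  obs$confidence <- as.numeric(obs$confidence)
  derive <- is.na(obs$confidence)
  directional <- obs$action %in% c("increased", "decreased")
  obs$confidence[derive] <- ifelse(
    directional[derive],
    ifelse(is.na(obs$log2fc[derive]), 5, pmin(abs(obs$log2fc[derive]), 5)),
    0)
  obs[, .obs_columns]
}

.canonical_records <- function(df, defaults) {
  cols <- c("name", names(defaults))
  if (is.null(df) || nrow(as.data.frame(df)) == 0) {
    out <- as.data.frame(stats::setNames(
      c(list(character()), lapply(defaults, function(d) d[0])), cols),
      stringsAsFactors = FALSE)
    return(out)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (is.null(df$name)) stop("record table lacks a 'name' column", call. = FALSE)
  for (f in names(defaults)) {
    if (is.null(df[[f]])) df[[f]] <- defaults[[f]]
  }
  if ("putative" %in% cols) df$putative <- isTRUE_vec(df$putative)
  if ("msi_level" %in% cols) df$msi_level <- as.integer(df$msi_level)
  df[, cols]
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

.register_names <- function(records, referenced, defaults) {
  new <- setdiff(unique(referenced), records$name)
  new <- new[!is.na(new) & nzchar(new)]
  if (length(new) > 0) {
    add <- data.frame(name = new, stringsAsFactors = FALSE)
    for (f in names(defaults)) add[[f]] <- defaults[[f]]
    records <- rbind(records, add[, names(records)])
  }
  records
}

#' @export
print.datacube <- function(x, ...) {
  n_org <- sum(!x$organisms$is_control)
  cat(sprintf(
    "Exometabolomics datacube: %d metabolites x %d organisms (+ control) x %d environments\n",
    nrow(x$metabolites), n_org, nrow(x$environments)))
  tab <- table(factor(x$observations$action, levels = action_codes()))
  cat(sprintf("%d observations (%s)\n", nrow(x$observations),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Validate a datacube
#'
#' Checks every structural invariant of the assertion data model and reports
#' each violation found: key uniqueness of the record tables, presence of
#' exactly one control organism record, referential integrity of the
#' observation table, uniqueness of (metabolite, organism, environment)
#' triples, legality of the action for the organism type (the control may only
#' be `detected`/`not_detected`; transformed organisms only the remaining four
#' codes), confidence within `[0, 5]` and 0 exactly for the non-directional
#' actions, consistency of the fold-change sign with the action, and p-values
#' within `[0, 1]`.
#'
#' @param cube a [datacube()].
#' @return Character vector of human-readable violations; empty when valid.
#' @examples
#' cube <- worked_example_fixture()
#' validate_cube(cube)  # character(0)
#' @export
validate_cube <- function(cube) {
  stopifnot(inherits(cube, "datacube"))
  v <- character()
  note <- function(...) v[[length(v) + 1]] <<- sprintf(...)

  for (tab in c("metabolites", "organisms", "environments")) {
    nm <- cube[[tab]]$name
    if (anyNA(nm) || any(!nzchar(nm)))
      note("%s: empty or missing name", tab)
    dup <- unique(nm[duplicated(nm)])
    for (d in dup) note("%s: duplicate key '%s'", tab, d)
  }
  ctrl <- cube$organisms$name[cube$organisms$is_control]
  if (length(ctrl) != 1L || !identical(ctrl, control_name()))
    note("organisms: expected exactly one control record named '%s'",
         control_name())

  obs <- cube$observations
  if (nrow(obs) == 0) return(v)

  for (ref in c("metabolite", "organism", "environment")) {
    tab <- paste0(ref, "s")
    bad <- setdiff(unique(obs[[ref]]), cube[[tab]]$name)
    for (b in bad) note("observation references unregistered %s '%s'", ref, b)
  }

  key <- paste(obs$metabolite, obs$organism, obs$environment, sep = "\r")
  dup <- unique(key[duplicated(key)])
  for (d in dup)
    note("duplicate observation key (%s)",
         paste(strsplit(d, "\r", fixed = TRUE)[[1]], collapse = ", "))

  bad_code <- !obs$action %in% action_codes()
  for (i in which(bad_code)) note("unknown action code '%s'", obs$action[i])

  is_ctrl <- obs$organism == control_name()
  for (i in which(is_ctrl & !obs$action %in% control_actions()))
    note("control observation on '%s' in '%s' has non-control action '%s'",
         obs$metabolite[i], obs$environment[i], obs$action[i])
  for (i in which(!is_ctrl & obs$action %in% control_actions()))
    note("organism '%s' carries control-only action '%s' on '%s'",
         obs$organism[i], obs$action[i], obs$metabolite[i])

  bad_conf <- is.na(obs$confidence) | obs$confidence < 0 | obs$confidence > 5
  for (i in which(bad_conf))
    note("confidence %s outside [0, 5] for (%s, %s, %s)",
         format(obs$confidence[i]), obs$metabolite[i], obs$organism[i],
         obs$environment[i])

  nondir <- obs$action %in% c("no_change", "not_investigated",
                              "detected", "not_detected")
  for (i in which(nondir & !is.na(obs$confidence) & obs$confidence != 0))
    note("non-directional action '%s' must have confidence 0 (%s, %s, %s)",
         obs$action[i], obs$metabolite[i], obs$organism[i], obs$environment[i])

  for (i in which(obs$action == "increased")) {
    ok <- (!is.na(obs$log2fc[i]) && obs$log2fc[i] > 0) ||
      (is.na(obs$log2fc[i]) && identical(obs$confidence[i], 5))
    if (!ok)
      note("'increased' needs log2fc > 0, or confidence 5 with log2fc absent (%s, %s, %s)",
           obs$metabolite[i], obs$organism[i], obs$environment[i])
  }
  for (i in which(obs$action == "decreased")) {
    ok <- (!is.na(obs$log2fc[i]) && obs$log2fc[i] < 0) ||
      (is.na(obs$log2fc[i]) && identical(obs$confidence[i], 5))
    if (!ok)
      note("'decreased' needs log2fc < 0, or confidence 5 with log2fc absent (%s, %s, %s)",
           obs$metabolite[i], obs$organism[i], obs$environment[i])
  }

  bad_p <- !is.na(obs$p_value) & (obs$p_value < 0 | obs$p_value > 1)
  for (i in which(bad_p))
    note("p_value %s outside [0, 1] for (%s, %s, %s)", format(obs$p_value[i]),
         obs$metabolite[i], obs$organism[i], obs$environment[i])

  v
}

#' Search metabolites by name fragment
#'
#' Case-insensitive substring search over metabolite names, as used to pick a
#' compound for the one-metabolite view: the fragment `"aden"` matches
#' adenine, adenosine, methyladenosine and so on. The empty query matches
#' everything.
#'
#' @param cube a [datacube()].
#' @param query character fragment; matching is case-insensitive and literal
#'   (no regular expressions).
#' @return The matching rows of the metabolite record table, ordered
#'   lexicographically by name. Zero rows when nothing matches.
#' @examples
#' cube <- datacube(metabolites = data.frame(
#'   name = c("adenine", "adenosine", "methyladenosine", "glycine")))
#' search_metabolites(cube, "aden")$name
#' @export
search_metabolites <- function(cube, query) {
  stopifnot(inherits(cube, "datacube"), is.character(query),
            length(query) == 1L, !is.na(query))
  hit <- grepl(tolower(query), tolower(cube$metabolites$name), fixed = TRUE)
  out <- cube$metabolites[hit, , drop = FALSE]
  out <- out[.lex_order(out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Observation table in canonical (environment, organism, metabolite) order,
# used by writers and equality checks.
.sorted_observations <- function(cube) {
  obs <- cube$observations
  obs <- obs[.lex_order(obs$environment, obs$organism, obs$metabolite), ,
             drop = FALSE]
  rownames(obs) <- NULL
  obs
}

#' Observation-level equality of two datacubes
#'
#' Compares the observation tables (and the putative flags of referenced
#' metabolites) irrespective of row order. Used for round-trip checks of the
#' upload and database formats.
#'
#' @param a,b datacubes.
#' @return `TRUE` or `FALSE`.
#' @export
same_observations <- function(a, b) {
  oa <- .sorted_observations(a)
  ob <- .sorted_observations(b)
  if (!isTRUE(all.equal(oa, ob, tolerance = 1e-12))) return(FALSE)
  pa <- a$metabolites[.lex_order(a$metabolites$name), c("name", "putative")]
  pb <- b$metabolites[.lex_order(b$metabolites$name), c("name", "putative")]
  rownames(pa) <- rownames(pb) <- NULL
  identical(pa, pb)
}
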