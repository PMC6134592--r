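# Shared cell rule: one place decides what any view shows for a
# (metabolite, organism, environment) triple, so the three slice views can
# never disagree. Missing combinations render as "not investigated"
# (checkered) for transformed organisms and "not detected" (gray) for the
# control column, whose only states are detected/not detected.
.cell_for <- function(obs, metabolite, organism, environment) {
  idx <- match(paste(metabolite, organism, environment, sep = "\r"),
               paste(obs$metabolite, obs$organism, obs$environment,
                     sep = "\r"))
  .fill_cells(obs, idx, organism)
}

# Vectorised cell fill: idx indexes matched observation rows (NA = missing).
.fill_cells <- function(obs, idx, organism) {
  action <- ifelse(organism == control_name(), "not_detected",
                   "not_investigated")
  shade <- rep(0, length(idx))
  hit <- !is.na(idx)
  action[hit] <- obs$action[idx[hit]]
  shade[hit] <- obs$confidence[idx[hit]] / 5
  data.frame(action = action, shade = shade,
             color = unname(action_colors()[action]),
             stringsAsFactors = FALSE)
}

.slice_table <- function(dimension, value, rows, cols, obs, row_is, col_is) {
  grid <- expand.grid(column = cols, row = rows, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)[, c("row", "column")]
  pick <- function(axis) {
    if (row_is == axis) grid$row else if (col_is == axis) grid$column else
      rep(value, nrow(grid))
  }
  m <- pick("metabolite")
  o <- pick("organism")
  e <- pick("environment")
  idx <- match(paste(m, o, e, sep = "\r"),
               paste(obs$metabolite, obs$organism, obs$environment,
                     sep = "\r"))
  cells_df <- cbind(grid, .fill_cells(obs, idx, o))
  rownames(cells_df) <- NULL
  structure(list(dimension = dimension, value = value, row_labels = rows,
                 column_labels = cols, cells = cells_df),
            class = "slice_table")
}

#' @export
print.slice_table <- function(x, ...) {
  cat(sprintf("slice table (one %s: %s): %d rows x %d columns\n",
              x$dimension, x$value, length(x$row_labels),
              length(x$column_labels)))
  if (length(x$row_labels) > 0 && length(x$column_labels) > 0) {
    wide <- matrix(x$cells$action, nrow = length(x$row_labels),
                   byrow = TRUE,
                   dimnames = list(x$row_labels, x$column_labels))
    print(as.data.frame(wide))
  }
  invisible(x)
}

#' One-environment slice view
#'
#' Constrains the cube to a single environment: rows are the metabolites
#' observed there, columns are the control pool (`"The Environment"`, always
#' first, shown tan/gray) followed by the transformed organisms in
#' lexicographic order (red/blue/white/checkered cells). Cell shade is
#' `confidence / 5` in `[0, 1]`; it encodes certainty of the call, never raw
#' abundance.
#'
#' @param cube a [datacube()].
#' @param environment environment name.
#' @return An object of class `"slice_table"`: list with the constrained
#'   dimension and value, `row_labels`, `column_labels` and a `cells` data
#'   frame (`row`, `column`, `action`, `shade`, `color`) in row-major order.
#' @seealso [one_organism()], [one_metabolite()], [build_web()]
#' @examples
#' one_environment(worked_example_fixture(), "R2A")$column_labels
#' @export
one_environment <- function(cube, environment) {
  stopifnot(inherits(cube, "datacube"))
  if (!environment %in% cube$environments$name)
    stop("unknown environment: ", environment, call. = FALSE)
  obs <- cube$observations[cube$observations$environment == environment, ,
                           drop = FALSE]
  rows <- .lex_sort(unique(obs$metabolite))
  orgs <- .lex_sort(setdiff(unique(obs$organism), control_name()))
  .slice_table("environment", environment, rows,
               c(control_name(), orgs), obs,
               row_is = "metabolite", col_is = "organism")
}

#' One-organism slice view
#'
#' Constrains the cube to a single organism: rows are the metabolites it was
#' assayed on, columns the environments in which it was observed. Selecting
#' the control pseudo-organism compares the compositions of the untransformed
#' control pools across environments (tan/gray cells only) — useful for
#' finding an environment containing desired metabolites. When the
#' environments cover different metabolite panels the row set is their union
#' and absent combinations render as not investigated (not detected for the
#' control).
#'
#' @param cube a [datacube()].
#' @param organism organism name or [control_name()].
#' @return A `"slice_table"` (see [one_environment()]).
#' @export
one_organism <- function(cube, organism) {
  stopifnot(inherits(cube, "datacube"))
  if (!organism %in% cube$organisms$name)
    stop("unknown organism: ", organism, call. = FALSE)
  obs <- cube$observations[cube$observations$organism == organism, ,
                           drop = FALSE]
  rows <- .lex_sort(unique(obs$metabolite))
  cols <- .lex_sort(unique(obs$environment))
  .slice_table("organism", organism, rows, cols, obs,
               row_is = "metabolite", col_is = "environment")
}

#' One-metabolite slice view
#'
#' Selects a single compound via [search_metabolites()] — a name fragment
#' suffices — and shows its actions across all environments (rows) and
#' organisms (columns, control first) where it was observed. A fragment
#' matching nothing raises an error of class `exocube_empty_result`; a
#' fragment matching several compounds without an exact name among them
#' raises `exocube_ambiguous_match` listing the candidates.
#'
#' @param cube a [datacube()].
#' @param query metabolite name or fragment; an exact (case-insensitive) name
#'   match resolves ambiguity.
#' @return A `"slice_table"` (see [one_environment()]); zero rows when the
#'   metabolite was observed nowhere.
#' @export
one_metabolite <- function(cube, query) {
  stopifnot(inherits(cube, "datacube"))
  matches <- search_metabolites(cube, query)$name
  if (length(matches) == 0)
    stop(structure(class = c("exocube_empty_result", "error", "condition"),
                   list(message = paste0("no metabolite matches '", query,
                                         "'"),
                        call = NULL)))
  exact <- matches[tolower(matches) == tolower(query)]
  if (length(matches) > 1 && length(exact) != 1)
    stop(structure(class = c("exocube_ambiguous_match", "error", "condition"),
                   list(message = paste0(
                     "query '", query, "' is ambiguous; candidates: ",
                     paste(matches, collapse = ", ")),
                     call = NULL)))
  metabolite <- if (length(matches) == 1) matches else exact
  obs <- cube$observations[cube$observations$metabolite == metabolite, ,
                           drop = FALSE]
  rows <- .lex_sort(unique(obs$environment))
  orgs <- .lex_sort(setdiff(unique(obs$organism), control_name()))
  cols <- if (nrow(obs) > 0) c(control_name(), orgs) else character(0)
  .slice_table("metabolite", metabolite, rows, cols, obs,
               row_is = "environment", col_is = "organism")
}

#' Export a slice table as delimited text
#'
#' One line per cell in row-major order, with the colour code and shade as
#' auxiliary columns next to the action.
#'
#' @param table a `"slice_table"`.
#' @param path file to write.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
export_table <- function(table, path, sep = "\t") {
  stopifnot(inherits(table, "slice_table"))
  utils::write.table(table$cells, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
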