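#' Action vocabulary
#'
#' Qualitative assertions attached to one (metabolite, organism, environment)
#' triple. The untransformed control pool is represented by the reserved
#' pseudo-organism `"The Environment"`, whose observations may only state
#' whether a metabolite was `detected` or `not_detected`. Observations on real
#' (transformed) organisms state the net effect of the organism on the
#' metabolite: `increased`, `decreased`, `no_change`, or `not_investigated`
#' when the metabolite was not assessed in that experiment.
#'
#' @return `action_codes()` returns the six canonical codes;
#'   `control_actions()` and `organism_actions()` the subsets legal for the
#'   control pseudo-organism and for transformed organisms respectively;
#'   `control_name()` the reserved control organism name.
#' @examples
#' action_codes()
#' control_name()
#' @export
action_codes <- function() {
  c("increased", "decreased", "no_change", "not_investigated",
    "detected", "not_detected")
}

#' @rdname action_codes
#' @export
control_actions <- function() c("detected", "not_detected")

#' @rdname action_codes
#' @export
organism_actions <- function() {
  c("increased", "decreased", "no_change", "not_investigated")
}

#' @rdname action_codes
#' @export
control_name <- function() "The Environment"

# Strings accepted in upload files (normalised: lower case, single spaces).
# Both the upload vocabulary ("increase") and the display tense ("increased",
# "not changed") are accepted; writers always emit the upload vocabulary.
.file_action_map <- c(
  "increase"         = "increased",
  "increased"        = "increased",
  "decrease"         = "decreased",
  "decreased"        = "decreased",
  "no change"        = "no_change",
  "not changed"      = "no_change",
  "detected"         = "detected",
  "not detected"     = "not_detected",
  "not investigated" = "not_investigated"
)

# Canonical serialisation of each action code in upload files.
.action_file_form <- c(
  increased        = "increase",
  decreased        = "decrease",
  no_change        = "no change",
  not_investigated = "not investigated",
  detected         = "detected",
  not_detected     = "not detected"
)

.normalise_action_string <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]_]+", " ", x)
}

# Parse file action strings to canonical codes; NA where not in vocabulary.
.parse_action <- function(x) {
  unname(.file_action_map[.normalise_action_string(x)])
}

#' Cell colour scheme
#'
#' Fixed colour coding used by every table and web view: control cells are
#' `tan` (detected) or `gray` (not detected); transformed cells are `red`
#' (increased), `blue` (decreased), `white` (no net change) or `checkered`
#' (not investigated).
#'
#' @return Named character vector mapping action codes to colour names.
#' @examples
#' action_colors()
#' @export
action_colors <- function() {
  c(detected         = "tan",
    not_detected     = "gray",
    increased        = "red",
    decreased        = "blue",
    no_change        = "white",
    not_investigated = "checkered")
}

# Locale-independent lexicographic order, used everywhere a deterministic
# row/column order is promised.
.lex_order <- function(...) order(..., method = "radix")

.lex_sort <- function(x) x[.lex_order(x)]
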