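#' Action sets of one environment
#'
#' Collects, for a single environment, the operand sets of the compatibility
#' scores: `P`, the metabolites detected in the untransformed control pool,
#' and per transformed organism the sets `D` (metabolites it decreased) and
#' `I` (metabolites it increased). Metabolites asserted `no_change` or
#' `not_investigated` belong to neither `D` nor `I` and never enter a score.
#'
#' @param cube a [datacube()].
#' @param environment environment name.
#' @return An object of class `"action_sets"`: list with `environment`, `P`
#'   (character vector) and `organisms`, a named list of `list(D =, I =)` for
#'   every transformed organism observed in the environment.
#' @seealso [eus()], [fmc()], [fme()], [compatibility_table()]
#' @export
action_sets <- function(cube, environment) {
  stopifnot(inherits(cube, "datacube"))
  if (!environment %in% cube$environments$name)
    stop("unknown environment: ", environment, call. = FALSE)
  obs <- cube$observations[cube$observations$environment == environment, ,
                           drop = FALSE]
  ctrl <- obs$organism == control_name()
  P <- .lex_sort(obs$metabolite[ctrl & obs$action == "detected"])
  orgs <- .lex_sort(unique(obs$organism[!ctrl]))
  sets <- lapply(orgs, function(o) {
    mine <- obs[obs$organism == o, , drop = FALSE]
    list(D = .lex_sort(mine$metabolite[mine$action == "decreased"]),
         I = .lex_sort(mine$metabolite[mine$action == "increased"]))
  })
  names(sets) <- orgs
  structure(list(environment = environment, P = P,
                 metabolites = .lex_sort(unique(obs$metabolite)),
                 organisms = sets),
            class = "action_sets")
}

.score_result <- function(kind, scored, reference, numerator, denominator) {
  data.frame(kind = kind, scored = scored, reference = reference,
             numerator = as.integer(numerator),
             denominator = as.integer(denominator),
             value = if (denominator > 0) numerator / denominator else
               NA_real_,
             stringsAsFactors = FALSE)
}

.get_org_sets <- function(sets, organism, role) {
  stopifnot(inherits(sets, "action_sets"))
  if (organism == control_name())
    stop(role, " organism must not be the control", call. = FALSE)
  if (!organism %in% names(sets$organisms))
    stop("unknown ", role, " organism in environment '", sets$environment,
         "': ", organism, call. = FALSE)
  sets$organisms[[organism]]
}

#' Environmental Uptake Score (EUS)
#'
#' Fraction of the control pool's metabolites that the scored organism
#' consumes: the number of metabolites the organism decreased that are present
#' in the control, over the number of metabolites present in the control. A
#' high EUS indicates heavy use of the existing resources of the environment.
#'
#' @param sets an [action_sets()] object.
#' @param scored transformed organism to score.
#' @return One-row score data frame with `kind`, `scored`, `reference`,
#'   `numerator`, `denominator`, `value`. With an empty control pool the
#'   value is undefined and reported as `NA`, never 0.
#' @examples
#' sets <- action_sets(worked_example_fixture(), "R2A")
#' eus(sets, "GW123-8A04")
#' @export
eus <- function(sets, scored) {
  s <- .get_org_sets(sets, scored, "scored")
  .score_result("EUS", scored, control_name(),
                length(intersect(s$D, sets$P)), length(sets$P))
}

#' Organismal compatibility: fraction of metabolites under competition (FMC)
#'
#' Of the metabolites the scored organism decreases, the fraction also
#' decreased by the reference organism: `|D_scored ∩ D_reference| /
#' |D_scored|`. Shared decreases flag potential competition for the same
#' resources. With `D_scored` empty the score is undefined (`NA`).
#'
#' @param sets an [action_sets()] object.
#' @param scored,reference two distinct transformed organisms.
#' @return One-row score data frame (see [eus()]).
#' @examples
#' sets <- action_sets(worked_example_fixture(), "R2A")
#' fmc(sets, "GW123-8A04", "FW300-N2A2")  # 25/50 = 0.5
#' @export
fmc <- function(sets, scored, reference) {
  if (scored == reference)
    stop("scored and reference organisms must differ", call. = FALSE)
  s <- .get_org_sets(sets, scored, "scored")
  r <- .get_org_sets(sets, reference, "reference")
  .score_result("FMC", scored, reference,
                length(intersect(s$D, r$D)), length(s$D))
}

#' Organismal compatibility: fraction of metabolites for potential exchange
#' (FME)
#'
#' Of the metabolites the scored organism decreases, the fraction increased by
#' the reference organism: `|D_scored ∩ I_reference| / |D_scored|`.
#' Anti-correlated actions mark metabolites the reference may provide and the
#' scored organism consume, i.e. potential exchange benefitting the scored
#' organism. With `D_scored` empty the score is undefined (`NA`).
#'
#' @inheritParams fmc
#' @return One-row score data frame (see [eus()]).
#' @examples
#' sets <- action_sets(worked_example_fixture(), "R2A")
#' fme(sets, "GW123-8A04", "FW300-N2A2")  # 8/50 = 0.16
#' @export
fme <- function(sets, scored, reference) {
  if (scored == reference)
    stop("scored and reference organisms must differ", call. = FALSE)
  s <- .get_org_sets(sets, scored, "scored")
  r <- .get_org_sets(sets, reference, "reference")
  .score_result("FME", scored, reference,
                length(intersect(s$D, r$I)), length(s$D))
}

#' Compatibility score table for one environment
#'
#' Reproduces the reference-column scoring of the one-environment view:
#' selecting the control (`"The Environment"`) as the reference yields one
#' [eus()] row per transformed organism; selecting an organism yields an
#' [fmc()] and an [fme()] row for every other organism scored against that
#' reference. Rows are ordered lexicographically by scored organism.
#'
#' @param cube a [datacube()].
#' @param environment environment name.
#' @param reference reference column: an organism of the environment or
#'   [control_name()].
#' @return Score data frame, one row per score (see [eus()]).
#' @examples
#' compatibility_table(worked_example_fixture(), "R2A", "GW123-8A04")
#' @export
compatibility_table <- function(cube, environment,
                                reference = control_name()) {
  sets <- action_sets(cube, environment)
  orgs <- names(sets$organisms)
  if (reference == control_name()) {
    rows <- lapply(orgs, function(o) eus(sets, o))
  } else {
    if (!reference %in% orgs)
      stop("unknown reference organism in environment '", environment, "': ",
           reference, call. = FALSE)
    rows <- lapply(setdiff(orgs, reference), function(o)
      rbind(fmc(sets, o, reference), fme(sets, o, reference)))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- .score_result("EUS", character(0), character(0),
                                         integer(0), integer(0))[0, ]
  out
}

#' Competition and exchange marks per metabolite
#'
#' The cell symbols of the scored-versus-reference comparison: a metabolite
#' decreased by both organisms is marked `competition`; one decreased by the
#' scored organism and increased by the reference is marked `exchange`; all
#' other metabolites of the environment are `none`. The number of
#' `competition` marks equals the [fmc()] numerator and the number of
#' `exchange` marks the [fme()] numerator.
#'
#' @inheritParams fmc
#' @return Named character vector over the metabolites observed in the
#'   environment, values in `c("competition", "exchange", "none")`.
#' @export
interaction_marks <- function(sets, scored, reference) {
  if (scored == reference)
    stop("scored and reference organisms must differ", call. = FALSE)
  s <- .get_org_sets(sets, scored, "scored")
  r <- .get_org_sets(sets, reference, "reference")
  marks <- stats::setNames(rep("none", length(sets$metabolites)),
                           sets$metabolites)
  marks[intersect(s$D, r$I)] <- "exchange"
  marks[intersect(s$D, r$D)] <- "competition"
  marks
}
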