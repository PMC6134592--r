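#' Configuration of the assertion pipeline
#'
#' Controls how replicate control-versus-spent abundance measurements are
#' turned into action assertions. The detection rule asks for at least
#' `min_detected_replicates` replicate values strictly above
#' `detection_threshold` (same arbitrary units as the abundances). The
#' statistical comparison is a two-sided Welch t-test by default, with a
#' Mann-Whitney (Wilcoxon rank-sum) alternative for designs where normality
#' on the log scale is doubtful. Significance is judged against `alpha`,
#' optionally after Benjamini-Hochberg correction across all metabolites of an
#' experiment batch. Confidence for shading is `min(|log2 fold change|, cap)`
#' with a fixed cap of 5; detections on only one side score exactly the cap.
#'
#' @param detection_threshold abundance below or at which a replicate does not
#'   count as detected (strict inequality). Default 0: any positive signal.
#' @param min_detected_replicates replicates that must exceed the threshold
#'   for a pool to count as detected. Default 1.
#' @param test `"welch_t"` or `"mann_whitney"`.
#' @param alpha two-sided significance level in (0, 1).
#' @param mtc multiple-testing correction applied per experiment batch:
#'   `"none"` or `"benjamini_hochberg"`.
#' @param confidence_cap cap on the confidence score; fixed at 5 in the data
#'   model, exposed for completeness.
#' @return An object of class `"assertion_config"`.
#' @seealso [assert_action()], [process_experiment()]
#' @export
assertion_config <- function(detection_threshold = 0,
                             min_detected_replicates = 1L,
                             test = c("welch_t", "mann_whitney"),
                             alpha = 0.05,
                             mtc = c("none", "benjamini_hochberg"),
                             confidence_cap = 5) {
  test <- match.arg(test)
  mtc <- match.arg(mtc)
  stopifnot(is.numeric(detection_threshold), detection_threshold >= 0,
            min_detected_replicates >= 1,
            is.numeric(alpha), alpha > 0, alpha < 1,
            is.numeric(confidence_cap), confidence_cap > 0)
  structure(list(detection_threshold = detection_threshold,
                 min_detected_replicates = as.integer(min_detected_replicates),
                 test = test, alpha = alpha, mtc = mtc,
                 confidence_cap = confidence_cap),
            class = "assertion_config")
}

#' Detection call for one replicate pool
#'
#' A metabolite counts as detected in a pool when at least
#' `min_detected_replicates` of its replicate values lie strictly above the
#' detection threshold.
#'
#' @param values non-negative replicate abundances (non-empty).
#' @param config an [assertion_config()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' cfg <- assertion_config(detection_threshold = 10)
#' detect_presence(c(0, 0, 0), cfg)    # FALSE
#' detect_presence(c(50, 60, 0), cfg)  # TRUE
#' @export
detect_presence <- function(values, config = assertion_config()) {
  .check_abundances(values)
  sum(values > config$detection_threshold) >= config$min_detected_replicates
}

.check_abundances <- function(values) {
  if (length(values) == 0)
    stop("replicate abundance vector is empty", call. = FALSE)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)) ||
      any(values < 0))
    stop("abundances must be finite, non-negative numbers", call. = FALSE)
  invisible(values)
}

# Detection, raw p-value and pool means for one metabolite. The p-value is NA
# when neither pool is detected (no test is run). Degenerate zero-variance
# pairs, where the test statistic is undefined, fall back to an exact rule:
# identical constant pools are non-significant (p = 1), different constant
# pools are significant (p = 0).
.compare_pools <- function(control, spent, config) {
  .check_abundances(control)
  .check_abundances(spent)
  det_c <- detect_presence(control, config)
  det_s <- detect_presence(spent, config)
  mean_c <- mean(control)
  mean_s <- mean(spent)
  p <- NA_real_
  if (det_c || det_s) {
    exact_rule <- function() if (isTRUE(all.equal(mean_c, mean_s)) &&
                                 stats::var(c(control, spent)) == 0) 1 else 0
    if (stats::sd(control) == 0 && stats::sd(spent) == 0) {
      p <- if (control[1] == spent[1]) 1 else 0
    } else {
      p <- tryCatch(
        switch(config$test,
               welch_t = stats::t.test(spent, control,
                                       alternative = "two.sided")$p.value,
               mann_whitney = suppressWarnings(
                 stats::wilcox.test(spent, control, alternative = "two.sided",
                                    exact = FALSE))$p.value),
        error = function(e) exact_rule())
      if (is.na(p)) p <- exact_rule()
    }
  }
  list(det_c = det_c, det_s = det_s, p = p, mean_c = mean_c, mean_s = mean_s)
}

# Turn a pool comparison plus (possibly batch-corrected) p-value into the
# final assertion.
.finalise_assertion <- function(cmp, p_adj, config) {
  cap <- config$confidence_cap
  if (!cmp$det_c && !cmp$det_s) {
    res <- list(action = "not_investigated", log2fc = NA_real_,
                confidence = 0, p_value = NA_real_)
  } else if (p_adj >= config$alpha || cmp$mean_s == cmp$mean_c) {
    res <- list(action = "no_change", log2fc = NA_real_, confidence = 0,
                p_value = cmp$p)
  } else {
    action <- if (cmp$mean_s > cmp$mean_c) "increased" else "decreased"
    if (cmp$det_c && cmp$det_s) {
      l2fc <- log2(cmp$mean_s / cmp$mean_c)
      res <- list(action = action, log2fc = l2fc,
                  confidence = min(abs(l2fc), cap), p_value = cmp$p)
    } else {
      # one-sided detection: a fold change against zero is undefined
      res <- list(action = action, log2fc = NA_real_, confidence = cap,
                  p_value = cmp$p)
    }
  }
  structure(res, class = "assertion_result")
}

#' Assert the action of an organism on one metabolite
#'
#' Compares the control and spent replicate pools of a single metabolite.
#' When neither pool passes the detection rule no assertion is possible
#' (`not_investigated`). Otherwise the configured two-sided test is run: a
#' non-significant difference is asserted as `no_change`; a significant one as
#' `increased` or `decreased` by the direction of the spent-over-control ratio
#' of replicate means, with `log2fc = log2(mean(spent)/mean(control))` and
#' confidence `min(|log2fc|, 5)`. A significant difference with detection on
#' only one side scores the cap of exactly 5 and reports no fold change.
#'
#' @param control,spent non-empty vectors of replicate abundances.
#' @param config an [assertion_config()].
#' @return An `"assertion_result"`: list with `action`, `log2fc`,
#'   `confidence`, `p_value`.
#' @examples
#' cfg <- assertion_config(detection_threshold = 10)
#' assert_action(c(100, 110, 90), c(400, 380, 420), cfg)
#' @export
assert_action <- function(control, spent, config = assertion_config()) {
  cmp <- .compare_pools(control, spent, config)
  p_adj <- if (is.na(cmp$p)) 1 else cmp$p
  .finalise_assertion(cmp, p_adj, config)
}

#' @export
print.assertion_result <- function(x, ...) {
  cat(sprintf("assertion: %s (log2fc = %s, confidence = %g, p = %s)\n",
              x$action,
              if (is.na(x$log2fc)) "NA" else format(x$log2fc, digits = 4),
              x$confidence,
              if (is.na(x$p_value)) "NA" else format(x$p_value, digits = 4)))
  invisible(x)
}

#' Replicate abundance experiment for one organism in one environment
#'
#' Bundles, per metabolite, the replicate relative abundances of the
#' uninoculated control pool and of the spent pool after growth of one
#' organism, in arbitrary instrument units.
#'
#' @param environment,organism names of the environment and the transformed
#'   organism.
#' @param abundances named list (one entry per metabolite) of lists with
#'   numeric elements `control` and `spent`, each a non-empty vector of
#'   finite, non-negative replicate values.
#' @return An object of class `"replicate_experiment"`.
#' @seealso [process_experiment()], [read_abundances()]
#' @export
replicate_experiment <- function(environment, organism, abundances) {
  stopifnot(is.character(environment), length(environment) == 1L,
            is.character(organism), length(organism) == 1L,
            organism != control_name(),
            is.list(abundances), length(abundances) > 0,
            !is.null(names(abundances)), all(nzchar(names(abundances))))
  if (anyDuplicated(names(abundances)))
    stop("duplicate metabolite names in abundance table", call. = FALSE)
  for (m in names(abundances)) {
    a <- abundances[[m]]
    if (!is.list(a) || !all(c("control", "spent") %in% names(a)))
      stop("abundances[['", m, "']] needs 'control' and 'spent' replicate ",
           "vectors", call. = FALSE)
    .check_abundances(a$control)
    .check_abundances(a$spent)
  }
  structure(list(environment = environment, organism = organism,
                 abundances = abundances),
            class = "replicate_experiment")
}

#' @export
print.replicate_experiment <- function(x, ...) {
  nrep <- range(vapply(x$abundances,
                       function(a) length(a$control) + length(a$spent),
                       integer(1)))
  cat(sprintf(
    "replicate experiment: %s in %s, %d metabolites, %s replicate values each\n",
    x$organism, x$environment, length(x$abundances),
    if (nrep[1] == nrep[2]) nrep[1] else paste(nrep, collapse = "-")))
  invisible(x)
}

#' Read a long-format replicate abundance table
#'
#' Expects delimited text with columns `metabolite`, `group`
#' (`control`/`spent`), `replicate`, `abundance`; alternatively a wide
#' per-metabolite matrix whose first column is the metabolite name and whose
#' remaining column names start with `control` or `spent`.
#'
#' @param path file to read.
#' @param environment,organism names attached to the experiment.
#' @param sep field separator.
#' @param wide set to `TRUE` for the wide layout.
#' @return A [replicate_experiment()].
#' @export
read_abundances <- function(path, environment, organism, sep = "\t",
                            wide = FALSE) {
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (wide) {
    names(df)[1] <- "metabolite"
    grp <- ifelse(grepl("^control", tolower(names(df))), "control",
                  ifelse(grepl("^spent", tolower(names(df))), "spent", NA))
    ab <- lapply(seq_len(nrow(df)), function(i) list(
      control = as.numeric(df[i, which(grp == "control")]),
      spent = as.numeric(df[i, which(grp == "spent")])))
    names(ab) <- df$metabolite
  } else {
    need <- c("metabolite", "group", "abundance")
    if (!all(need %in% tolower(names(df))))
      stop("abundance table needs columns metabolite | group | replicate | ",
           "abundance", call. = FALSE)
    names(df) <- tolower(names(df))
    df$group <- tolower(trimws(df$group))
    if (!all(df$group %in% c("control", "spent")))
      stop("group must be 'control' or 'spent'", call. = FALSE)
    ab <- lapply(split(df, df$metabolite), function(d) list(
      control = as.numeric(d$abundance[d$group == "control"]),
      spent = as.numeric(d$abundance[d$group == "spent"])))
  }
  replicate_experiment(environment, organism, ab)
}

#' Run the assertion pipeline over a whole experiment
#'
#' Applies [assert_action()] to every metabolite of a replicate experiment and
#' returns the resulting observation table: one transformed observation per
#' metabolite for the organism, plus one control observation per metabolite
#' (`detected` / `not_detected` from the control pool alone). With
#' `mtc = "benjamini_hochberg"` the p-values of all metabolites on which a
#' test was run are corrected jointly before comparison with `alpha`.
#' Per-metabolite failures are collected in the `"errors"` attribute rather
#' than aborting the batch.
#'
#' @param exp a [replicate_experiment()].
#' @param config an [assertion_config()].
#' @return Observation data frame (columns as in [datacube()] observations),
#'   ready to assemble into a cube.
#' @examples
#' exp <- replicate_experiment("R2A", "OrgA", list(
#'   adenine = list(control = c(100, 110, 90), spent = c(24, 26, 25))))
#' process_experiment(exp, assertion_config(detection_threshold = 10))
#' @export
process_experiment <- function(exp, config = assertion_config()) {
  stopifnot(inherits(exp, "replicate_experiment"),
            inherits(config, "assertion_config"))
  mets <- names(exp$abundances)
  errors <- character()
  cmps <- vector("list", length(mets))
  names(cmps) <- mets
  for (m in mets) {
    cmps[m] <- list(tryCatch(
      .compare_pools(exp$abundances[[m]]$control, exp$abundances[[m]]$spent,
                     config),
      error = function(e) {
        errors[[length(errors) + 1]] <<- paste0(m, ": ", conditionMessage(e))
        NULL
      }))
  }
  ok <- !vapply(cmps, is.null, logical(1))
  raw_p <- vapply(cmps[ok], function(cmp) cmp$p, numeric(1))
  adj_p <- raw_p
  tested <- !is.na(raw_p)
  if (config$mtc == "benjamini_hochberg" && any(tested))
    adj_p[tested] <- stats::p.adjust(raw_p[tested], method = "BH")

  rows <- lapply(mets[ok], function(m) {
    cmp <- cmps[[m]]
    p_adj <- adj_p[[m]]
    res <- .finalise_assertion(cmp, if (is.na(p_adj)) 1 else p_adj, config)
    rbind(
      data.frame(metabolite = m, organism = exp$organism,
                 environment = exp$environment, action = res$action,
                 log2fc = res$log2fc, confidence = res$confidence,
                 p_value = res$p_value, project = NA_character_,
                 stringsAsFactors = FALSE),
      data.frame(metabolite = m, organism = control_name(),
                 environment = exp$environment,
                 action = if (cmp$det_c) "detected" else "not_detected",
                 log2fc = NA_real_, confidence = 0, p_value = NA_real_,
                 project = NA_character_, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- .canonical_observations(NULL)
  attr(out, "errors") <- errors
  out
}
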