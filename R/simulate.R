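# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification of a random assertion datacube
#'
#' Parameters of the seeded datacube generator: dimension sizes, the
#' probability that the control pool contains (detects) a metabolite, and the
#' action mix of the transformed cells. The four transformed-action
#' probabilities must sum to 1. A small fraction of directional cells is
#' generated as one-sided detections (no fold change, confidence capped at 5)
#' and a fraction of metabolites as putative identifications, so that
#' round-trip tests exercise those paths.
#'
#' @param n_metabolites,n_organisms,n_environments dimension sizes (≥ 1).
#' @param p_detected probability a metabolite is detected in a control pool.
#' @param p_increase,p_decrease,p_nochange,p_notinvestigated transformed-cell
#'   action probabilities, summing to 1.
#' @param p_onesided fraction of directional cells reported without a fold
#'   change at the confidence cap.
#' @param p_putative fraction of metabolites flagged putative.
#' @param seed integer seed making the cube reproducible.
#' @return An object of class `"cube_spec"`.
#' @seealso [generate_cube()]
#' @export
cube_spec <- function(n_metabolites = 20, n_organisms = 3,
                      n_environments = 2, p_detected = 0.8,
                      p_increase = 0.2, p_decrease = 0.25, p_nochange = 0.45,
                      p_notinvestigated = 0.1, p_onesided = 0.05,
                      p_putative = 0.1, seed = 1L) {
  p <- c(p_increase, p_decrease, p_nochange, p_notinvestigated)
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
    stop("transformed-action probabilities must lie in [0,1] and sum to 1",
         call. = FALSE)
  stopifnot(n_metabolites >= 1, n_organisms >= 1, n_environments >= 1,
            p_detected >= 0, p_detected <= 1, p_onesided >= 0,
            p_onesided <= 1, p_putative >= 0, p_putative <= 1)
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_organisms = as.integer(n_organisms),
                 n_environments = as.integer(n_environments),
                 p_detected = p_detected, p_increase = p_increase,
                 p_decrease = p_decrease, p_nochange = p_nochange,
                 p_notinvestigated = p_notinvestigated,
                 p_onesided = p_onesided, p_putative = p_putative,
                 seed = as.integer(seed)),
            class = "cube_spec")
}

#' Generate a random valid datacube
#'
#' Seeded generator producing a complete assertion datacube: every
#' (metabolite, environment) pair gets one control observation (detected with
#' probability `p_detected`) and every (metabolite, organism, environment)
#' triple one transformed observation with the configured action mix, so the
#' observation count is `n_metabolites * (n_organisms + 1) * n_environments`.
#' Directional cells carry a fold change of the matching sign and confidence
#' `min(|log2fc|, 5)`, except the one-sided fraction which carries confidence
#' 5 and no fold change. The output always passes [validate_cube()] and is
#' identical for identical seeds.
#'
#' @param spec a [cube_spec()].
#' @return A [datacube()].
#' @examples
#' cube <- generate_cube(cube_spec(n_metabolites = 5, seed = 42))
#' validate_cube(cube)
#' @export
generate_cube <- function(spec = cube_spec()) {
  stopifnot(inherits(spec, "cube_spec"))
  .with_seed(spec$seed, {
    mets <- sprintf("M%03d", seq_len(spec$n_metabolites))
    orgs <- sprintf("Org%02d", seq_len(spec$n_organisms))
    envs <- sprintf("Env%d", seq_len(spec$n_environments))

    ctrl <- expand.grid(metabolite = mets, environment = envs,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ctrl_detected <- stats::runif(nrow(ctrl)) < spec$p_detected
    ctrl_obs <- data.frame(
      metabolite = ctrl$metabolite, organism = control_name(),
      environment = ctrl$environment,
      action = ifelse(ctrl_detected, "detected", "not_detected"),
      log2fc = NA_real_, confidence = 0, p_value = NA_real_,
      project = NA_character_, stringsAsFactors = FALSE)

    cell <- expand.grid(metabolite = mets, organism = orgs,
                        environment = envs, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    n <- nrow(cell)
    action <- sample(organism_actions()[c(1, 2, 3, 4)], n, replace = TRUE,
                     prob = c(spec$p_increase, spec$p_decrease,
                              spec$p_nochange, spec$p_notinvestigated))
    directional <- action %in% c("increased", "decreased")
    onesided <- directional & stats::runif(n) < spec$p_onesided
    magnitude <- stats::runif(n, 0.1, 6)
    sign <- ifelse(action == "increased", 1, -1)
    log2fc <- ifelse(directional & !onesided, sign * magnitude, NA_real_)
    confidence <- ifelse(directional,
                         ifelse(onesided, 5, pmin(abs(log2fc), 5)), 0)
    p_value <- ifelse(directional, stats::runif(n, 0, 0.049),
                      ifelse(action == "no_change",
                             stats::runif(n, 0.05, 1), NA_real_))
    org_obs <- data.frame(
      metabolite = cell$metabolite, organism = cell$organism,
      environment = cell$environment, action = action, log2fc = log2fc,
      confidence = confidence, p_value = p_value, project = NA_character_,
      stringsAsFactors = FALSE)

    met_tab <- data.frame(
      name = mets, putative = stats::runif(length(mets)) < spec$p_putative,
      stringsAsFactors = FALSE)
    datacube(observations = rbind(ctrl_obs, org_obs), metabolites = met_tab)
  })
}

#' Specification of a simulated replicate abundance experiment
#'
#' Parameters of the ground-truth abundance simulator. Per-metabolite
#' baseline abundances are drawn log-normally (`baseline_meanlog`,
#' `baseline_sdlog`, natural-log scale, arbitrary units); replicate noise is
#' multiplicative log-normal with standard deviation `sigma` on the log2
#' scale, the conventional model for LCMS relative abundances. A fraction of
#' metabolites is spiked up or down by a factor `2^effect_log2` in the spent
#' pool; the rest are null.
#'
#' @param n_metabolites number of metabolites.
#' @param n_replicates replicates per side (≥ 2 for test-based assertions).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-metabolite baseline abundance.
#' @param frac_increased,frac_decreased fractions of metabolites spiked up /
#'   down.
#' @param effect_log2 absolute log2 effect size of spiked metabolites.
#' @param sigma replicate noise standard deviation on the log2 scale.
#' @param detection_threshold threshold handed to the assertion engine.
#' @param environment,organism names attached to the generated experiment.
#' @param seed integer seed.
#' @return An object of class `"experiment_spec"`.
#' @seealso [generate_experiment()]
#' @export
experiment_spec <- function(n_metabolites = 100, n_replicates = 5,
                            baseline_meanlog = log(1000),
                            baseline_sdlog = 0.5, frac_increased = 0.1,
                            frac_decreased = 0.1, effect_log2 = 2,
                            sigma = 0.1, detection_threshold = 10,
                            environment = "SimEnv", organism = "SimOrg",
                            seed = 1L) {
  stopifnot(n_metabolites >= 1, n_replicates >= 1, baseline_sdlog > 0,
            sigma >= 0, frac_increased >= 0, frac_decreased >= 0,
            frac_increased + frac_decreased <= 1, detection_threshold >= 0)
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_replicates = as.integer(n_replicates),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 frac_increased = frac_increased,
                 frac_decreased = frac_decreased,
                 effect_log2 = effect_log2, sigma = sigma,
                 detection_threshold = detection_threshold,
                 environment = environment, organism = organism,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

#' Simulate a replicate experiment with known ground truth
#'
#' Draws control and spent replicate pools for every metabolite: spent means
#' equal control means times `2^(+effect_log2)` for metabolites spiked up,
#' `2^(-effect_log2)` for metabolites spiked down, and are identical for null
#' metabolites. Returns the experiment together with the intended action per
#' metabolite, for parameter-recovery and calibration testing of the
#' assertion pipeline.
#'
#' @param spec an [experiment_spec()].
#' @return List with `experiment` (a [replicate_experiment()]) and `truth`
#'   (named character vector: `increased`, `decreased` or `no_change` per
#'   metabolite).
#' @examples
#' sim <- generate_experiment(experiment_spec(n_metabolites = 10, seed = 7))
#' table(sim$truth)
#' @export
generate_experiment <- function(spec = experiment_spec()) {
  stopifnot(inherits(spec, "experiment_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_metabolites
    mets <- sprintf("M%04d", seq_len(n))
    n_up <- round(spec$frac_increased * n)
    n_dn <- round(spec$frac_decreased * n)
    delta <- rep(0, n)
    spiked <- sample.int(n, n_up + n_dn)
    delta[spiked[seq_len(n_up)]] <- spec$effect_log2
    delta[spiked[seq_len(n_dn) + n_up]] <- -spec$effect_log2
    truth <- stats::setNames(
      ifelse(delta > 0, "increased",
             ifelse(delta < 0, "decreased", "no_change")), mets)

    baseline <- stats::rlnorm(n, spec$baseline_meanlog, spec$baseline_sdlog)
    noise <- function(k) 2^stats::rnorm(k, 0, spec$sigma)
    ab <- lapply(seq_len(n), function(i) list(
      control = baseline[i] * noise(spec$n_replicates),
      spent = baseline[i] * 2^delta[i] * noise(spec$n_replicates)))
    names(ab) <- mets
    list(experiment = replicate_experiment(spec$environment, spec$organism,
                                           ab),
         truth = truth)
  })
}

#' Two-isolate compatibility demonstration cube
#'
#' A fixed, fully synthetic datacube emulating a reference demonstration of
#' the compatibility scoring system: two soil isolates, *Phenylobacterium*
#' sp. GW123-8A04 and *Pseudomonas* sp. FW300-N2A2, mono-cultured in R2A
#' medium. Set sizes are back-solved from the reported scores: a control pool
#' of 100 detected metabolites; GW123-8A04 decreases 50 of them, FW300-N2A2
#' decreases 26, 25 of these shared; FW300-N2A2 increases 8 metabolites that
#' GW123-8A04 decreases, while GW123-8A04's 5 increases are products absent
#' from the control and untouched by FW300-N2A2. Metabolite names are
#' synthetic placeholders. On this cube `fmc` gives 25/50 = 0.5 and
#' 25/26 ≈ 0.96, `fme` gives 8/50 = 0.16 and 0/26 = 0, and `eus` gives
#' 50/100 = 0.5 and 26/100 = 0.26.
#'
#' @return A [datacube()] with one environment (`"R2A"`), two organisms and
#'   the control pool.
#' @examples
#' sets <- action_sets(worked_example_fixture(), "R2A")
#' fmc(sets, "GW123-8A04", "FW300-N2A2")
#' @export
worked_example_fixture <- function() {
  mets <- sprintf("M%03d", 1:105)
  P <- mets[1:100]        # control pool
  products <- mets[101:105]
  GW <- "GW123-8A04"
  FW <- "FW300-N2A2"
  D_gw <- mets[1:50]
  I_gw <- products        # one-sided: absent from control
  D_fw <- mets[c(1:25, 51)]
  I_fw <- mets[26:33]

  obs_for <- function(organism, D, I, onesided_I = FALSE) {
    investigated <- mets[seq_len(if (organism == GW) 105 else 100)]
    action <- rep("no_change", length(investigated))
    names(action) <- investigated
    action[D] <- "decreased"
    action[I] <- "increased"
    l2fc <- ifelse(action == "decreased", -1,
                   ifelse(action == "increased",
                          if (onesided_I) NA_real_ else 1, NA_real_))
    conf <- ifelse(action == "decreased", 1,
                   ifelse(action == "increased", if (onesided_I) 5 else 1, 0))
    data.frame(metabolite = investigated, organism = organism,
               environment = "R2A", action = unname(action), log2fc = l2fc,
               confidence = conf, p_value = NA_real_,
               project = "R2A soil isolates", stringsAsFactors = FALSE)
  }
  ctrl <- data.frame(metabolite = mets, organism = control_name(),
                     environment = "R2A",
                     action = ifelse(mets %in% P, "detected", "not_detected"),
                     log2fc = NA_real_, confidence = 0, p_value = NA_real_,
                     project = "R2A soil isolates", stringsAsFactors = FALSE)
  datacube(observations = rbind(ctrl, obs_for(GW, D_gw, I_gw, TRUE),
                                obs_for(FW, D_fw, I_fw, FALSE)))
}
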