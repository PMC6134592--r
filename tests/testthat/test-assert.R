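cfg10 <- assertion_config(detection_threshold = 10)

test_that("detection needs enough replicates strictly above the threshold", {
  expect_false(detect_presence(c(0, 0, 0), cfg10))
  expect_true(detect_presence(
    c(50, 60, 0), assertion_config(detection_threshold = 10,
                                   min_detected_replicates = 2)))
  # strict inequality at the boundary
  expect_false(detect_presence(11, assertion_config(detection_threshold = 11)))
  expect_error(detect_presence(numeric(0), cfg10), "empty")
  expect_error(detect_presence(c(1, -2), cfg10), "non-negative")
})

test_that("undetected on both sides yields not_investigated, never a division error", {
  res <- assert_action(c(0, 0, 0), c(0, 0, 0), cfg10)
  expect_identical(res$action, "not_investigated")
  expect_identical(res$confidence, 0)
  expect_true(is.na(res$log2fc))
  expect_true(is.na(res$p_value))
})

test_that("a clear increase is called with the exact log2 ratio of means", {
  res <- assert_action(c(100, 110, 90), c(400, 380, 420), cfg10)
  expect_identical(res$action, "increased")
  expect_equal(res$log2fc, 2)           # log2(400/100)
  expect_equal(res$confidence, 2)
  # p-value equals the closed-form Welch p computed independently
  expect_equal(res$p_value, welch_p(c(400, 380, 420), c(100, 110, 90)))
})

test_that("near-identical pools are asserted as no change", {
  res <- assert_action(c(100, 101, 99), c(100, 99, 101), cfg10)
  expect_identical(res$action, "no_change")
  expect_identical(res$confidence, 0)
})

test_that("one-sided detections score exactly the cap with no fold change", {
  res <- assert_action(c(0, 0, 0), c(500, 520, 480), cfg10)
  expect_identical(res$action, "increased")
  expect_identical(res$confidence, 5)
  expect_true(is.na(res$log2fc))
  res <- assert_action(c(500, 520, 480), c(0, 0, 0), cfg10)
  expect_identical(res$action, "decreased")
  expect_identical(res$confidence, 5)
})

test_that("degenerate zero-variance pools follow the exact comparison rule", {
  expect_identical(assert_action(c(50, 50), c(50, 50), cfg10)$action,
                   "no_change")
  res <- assert_action(c(50, 50), c(200, 200), cfg10)
  expect_identical(res$action, "increased")
  expect_equal(res$log2fc, 2)
})

test_that("confidence never exceeds the cap and is monotone in |log2fc|", {
  fold <- 2^seq(0.5, 8, by = 0.5)
  conf <- vapply(fold, function(f) {
    assert_action(c(100, 101, 99), f * c(100, 101, 99) + c(0, 1, -1),
                  cfg10)$confidence
  }, numeric(1))
  expect_true(all(diff(conf) >= -1e-12))
  expect_true(all(conf <= 5))
  expect_equal(max(conf), 5)
})

test_that("swapping control and spent flips the call and negates log2fc", {
  set.seed(401)
  for (i in 1:20) {
    a <- rlnorm(5, log(100), 0.2)
    b <- rlnorm(5, log(100) + sample(c(-2, 0, 2), 1), 0.2)
    r1 <- assert_action(a, b, cfg10)
    r2 <- assert_action(b, a, cfg10)
    flip <- c(increased = "decreased", decreased = "increased",
              no_change = "no_change", not_investigated = "not_investigated")
    expect_identical(r2$action, unname(flip[r1$action]))
    if (!is.na(r1$log2fc)) expect_equal(r2$log2fc, -r1$log2fc)
    if (!is.na(r1$p_value)) expect_equal(r2$p_value, r1$p_value)
  }
})

test_that("rescaling all abundances (and the threshold) changes nothing", {
  set.seed(402)
  for (i in 1:10) {
    a <- rlnorm(5, log(100), 0.3)
    b <- rlnorm(5, log(100) + sample(c(-1, 0, 3), 1), 0.3)
    k <- runif(1, 0.01, 100)
    r1 <- assert_action(a, b, cfg10)
    r2 <- assert_action(k * a, k * b,
                        assertion_config(detection_threshold = 10 * k))
    expect_identical(r2$action, r1$action)
    if (!is.na(r1$log2fc)) expect_equal(r2$log2fc, r1$log2fc)
  }
})

test_that("the Mann-Whitney alternative matches the rank-sum oracle", {
  cfg <- assertion_config(detection_threshold = 10, test = "mann_whitney")
  a <- c(100, 110, 90, 105, 95)
  b <- c(400, 380, 420, 390, 410)
  res <- assert_action(a, b, cfg)
  expect_identical(res$action, "increased")
  expect_equal(res$p_value,
               wilcox.test(b, a, exact = FALSE)$p.value)
})

test_that("process_experiment emits paired organism and control observations", {
  exp <- replicate_experiment("E1", "OrgA", list(
    up = list(control = c(100, 110, 90), spent = c(400, 380, 420)),
    down = list(control = c(400, 380, 420), spent = c(100, 110, 90)),
    null = list(control = c(200, 210, 190), spent = c(205, 195, 200)),
    absent = list(control = c(0, 0, 1), spent = c(0, 1, 0))))
  obs <- process_experiment(exp, cfg10)
  expect_equal(nrow(obs), 8)
  org <- obs[obs$organism == "OrgA", ]
  expect_identical(
    setNames(org$action, org$metabolite)[c("up", "down", "null", "absent")],
    c(up = "increased", down = "decreased", null = "no_change",
      absent = "not_investigated"))
  ctrl <- obs[obs$organism == control_name(), ]
  expect_identical(
    setNames(ctrl$action, ctrl$metabolite)[c("up", "absent")],
    c(up = "detected", absent = "not_detected"))
  # the result assembles into a valid datacube
  expect_length(validate_cube(datacube(obs)), 0)
})

test_that("Benjamini-Hochberg correction is applied across the batch", {
  # two metabolites with the same raw p just below alpha: BH halves the
  # threshold for the better-ranked one only if both survive; with one clear
  # null added, the marginal p must lose significance after correction.
  marginal <- list(control = c(100, 104, 96, 102, 98),
                   spent = c(106, 110, 102, 108, 104))
  cfgA <- assertion_config(detection_threshold = 10, alpha = 0.05)
  raw <- assert_action(marginal$control, marginal$spent, cfgA)
  expect_identical(raw$action, "increased")  # significant uncorrected

  exp <- replicate_experiment("E1", "OrgA", list(
    m1 = marginal,
    m2 = list(control = c(100, 104, 96, 102, 98),
              spent = c(101, 97, 103, 99, 100)),
    m3 = list(control = c(98, 102, 100, 97, 103),
              spent = c(100, 98, 102, 101, 99))))
  cfgBH <- assertion_config(detection_threshold = 10, alpha = 0.05,
                            mtc = "benjamini_hochberg")
  obs <- process_experiment(exp, cfgBH)
  m1 <- obs[obs$metabolite == "m1" & obs$organism == "OrgA", ]
  # BH-adjusted p = raw p * 3 (it is the only small one of three)
  expect_identical(m1$action,
                   if (raw$p_value * 3 < 0.05) "increased" else "no_change")
  expect_identical(m1$action, "no_change")
})

test_that("per-metabolite failures are collected, not fatal", {
  ab <- list(ok = list(control = c(100, 110, 90), spent = c(20, 22, 18)))
  exp <- replicate_experiment("E1", "OrgA", ab)
  # sneak an invalid entry past the constructor to exercise collection
  exp$abundances$bad <- list(control = c(-1, 2), spent = c(1, 2))
  obs <- process_experiment(exp, cfg10)
  expect_equal(sort(unique(obs$metabolite)), "ok")
  expect_match(attr(obs, "errors"), "bad", all = FALSE)
})
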