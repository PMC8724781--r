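test_that("ICC(3,k) equals the explicit sums-of-squares oracle on random matrices", {
  set.seed(101)
  for (r in 1:100) {
    n <- sample(4:15, 1)
    k <- sample(2:8, 1)
    x <- matrix(rnorm(n * k, 10, 2), n, k) + rnorm(n, 0, runif(1, 0.1, 3))
    got <- icc3k(x)
    ora <- oracle_icc3k(x)
    expect_lt(abs(got$icc - ora$icc), 1e-10)
    expect_lt(abs(got$f - ora$f), 1e-8 * max(1, ora$f))
    # CI brackets the point estimate
    expect_lte(got$ci[1], got$icc)
    expect_gte(got$ci[2], got$icc)
  }
})

test_that("ICC of duplicated columns is exactly 1 and degenerate input errors", {
  v <- rnorm(12, 5, 2)
  r <- icc3k(cbind(v, v, v, v, v))
  expect_identical(r$icc, 1)
  expect_equal(r$ci, c(1, 1))
  expect_error(icc3k(matrix(3, 6, 4)), "degenerate")
  expect_error(icc3k(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(icc3k(matrix(rnorm(4), 1, 4)), "at least 2")
})

test_that("ICC is invariant to shifting and positive rescaling of all cells", {
  set.seed(7)
  x <- matrix(rnorm(60, 10, 2), 12, 5) + rnorm(12, 0, 2)
  base <- icc3k(x)$icc
  expect_equal(icc3k(x + 100)$icc, base, tolerance = 1e-10)
  expect_equal(icc3k(x * 3.5)$icc, base, tolerance = 1e-10)
})

test_that("ICC reliability bands follow the 0.5 / 0.75 / 0.9 boundaries", {
  expect_equal(icc_band(c(0.2, 0.49999)), c("poor", "poor"))
  expect_equal(icc_band(c(0.5, 0.6, 0.74)), rep("moderate", 3))
  expect_equal(icc_band(c(0.75, 0.86, 0.9)), rep("good", 3))
  expect_equal(icc_band(c(0.90001, 0.97, 1)), rep("excellent", 3))
})

test_that("repeated-measures ANOVA equals both the SS oracle and base aov", {
  set.seed(202)
  for (r in 1:100) {
    n <- sample(4:15, 1)
    s <- sample(2:5, 1)
    x <- matrix(rnorm(n * s, 20, 3), n, s) + rnorm(n, 0, 2)
    got <- rm_anova(x)
    ora <- oracle_rm_anova(x)
    expect_lt(abs(got$f - ora$f), 1e-8 * max(1, ora$f))
    expect_lt(abs(got$p - ora$p), 1e-8)
    # SS decomposition conserves total variance
    ss <- ora$ss
    expect_lt(abs(ss[["subject"]] + ss[["session"]] + ss[["residual"]] -
                    ss[["total"]]) / ss[["total"]], 1e-8)
  }
  # spot-check against the aov procedure with a subject error stratum
  set.seed(9)
  x <- matrix(rnorm(36, 10, 2), 12, 3) + rnorm(12, 0, 3)
  got <- rm_anova(x)
  df <- data.frame(y = as.vector(x), subj = factor(rep(1:12, 3)),
                   sess = factor(rep(1:3, each = 12)))
  ref <- summary(aov(y ~ sess + Error(subj/sess), data = df))[[2]][[1]]
  expect_equal(got$f, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(got$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("degenerate ANOVA inputs error; pure subject effects give F near 0", {
  subj <- rnorm(8, 10, 3)
  x <- cbind(subj, subj, subj)          # zero residual after removing blocks
  expect_error(rm_anova(x), "degenerate")
  x2 <- x + matrix(rnorm(24, 0, 1e-6), 8, 3)
  a <- rm_anova(x2)
  expect_lt(a$f, 5)                     # no session effect signal
  expect_gt(a$p, 0.01)
  expect_error(rm_anova(matrix(c(1, 2, NA, 4), 2, 2)), "incomplete")
})

test_that("cohort reliability report has the expected structure", {
  cfg <- small_sim_config()
  ft <- simulate_cohort_features(cfg, n_animals = 12, n_sessions = 3,
                                 n_events = 5, rng_seed = 12)
  tab <- do.call(rbind, lapply(stuc_features(), function(f) {
    data.frame(animal_id = ft$animal_id, session_id = ft$session_id,
               event_index = ft$event_index, feature = f, value = ft[[f]])
  }))
  rel <- stuc_reliability(tab, n_events = 5)
  expect_s3_class(rel, "stuc_reliability")
  expect_named(rel$features, stuc_features())
  cf <- coef(rel)
  expect_equal(dim(cf), c(6, 5))
  expect_true(all(cf[, "anova_p"] >= 0 & cf[, "anova_p"] <= 1))
  for (f in stuc_features()) {
    e <- rel$features[[f]]
    expect_equal(e$icc$df1, 11)
    expect_equal(e$icc$df2, 44)
    expect_equal(e$anova$df1, 2)
    expect_equal(e$anova$df2, 22)
    expect_length(e$session_means, 3)
  }
  # markdown mirrors the two-table layout: 6 ICC rows + 6 ANOVA rows
  md <- report_markdown(rel)
  expect_length(grep("^\\| (peak|threshold|min|volume|burst)", md), 12)
  # JSON round-trip
  path <- withr::local_tempfile(fileext = ".json")
  report_json(rel, path)
  parsed <- jsonlite::read_json(path)
  expect_named(parsed, stuc_features())
  expect_equal(parsed$volume_threshold$icc,
               rel$features$volume_threshold$icc$icc, tolerance = 1e-12)
})

test_that("animals with missing events are excluded with a warning", {
  ft <- simulate_cohort_features(small_sim_config(), n_animals = 4,
                                 n_sessions = 1, n_events = 5, rng_seed = 3)
  tab <- data.frame(animal_id = ft$animal_id, session_id = ft$session_id,
                    event_index = ft$event_index, feature = "peak_pressure",
                    value = ft$peak_pressure)
  short <- tab[!(tab$animal_id == "a04" & tab$event_index > 2), ]
  expect_warning(rel <- stuc_reliability(short, n_events = 5),
                 "excluding animal")
  expect_equal(rel$features$peak_pressure$n_animals, 3)
  # fewer than 2 complete animals is an insufficiency error
  tiny <- tab[tab$animal_id %in% c("a01", "a02") &
                !(tab$animal_id == "a02" & tab$event_index > 2), ]
  expect_warning(expect_error(stuc_reliability(tiny, n_events = 5),
                              "fewer than 2 animals"))
  expect_error(stuc_reliability(tab[0, ]), "empty")
})
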