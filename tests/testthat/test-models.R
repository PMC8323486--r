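# a measured paper-scale cohort shared by the model tests
models_cache <- new.env(parent = emptyenv())

paper_scale_table <- function() {
  if (is.null(models_cache$tab)) {
    cohort <- generate_cohort(cohort_spec(seed = 11L))
    meas <- measure_cohort(cohort)
    models_cache$meas <- meas
    models_cache$tab <- assemble_table(meas$cov_table, meas$duration_table,
                                       meas$severity)
  }
  models_cache$tab
}

test_that("the assembled table has one CoV row per cell with missingness explicit", {
  meas <- { paper_scale_table(); models_cache$meas }
  expect_equal(nrow(meas$cov_table), 48 * 5 * 3)  # 720 at paper scale
  tab <- paper_scale_table()
  expect_lte(nrow(tab$cov), 720)
  excluded_words <- sum(!meas$cov_table$included) / 3
  expect_equal(nrow(tab$cov),
               720 - 3 * excluded_words - sum(is.na(meas$cov_table$cov) &
                                              meas$cov_table$included))
  # duplicate keys are rejected
  dup <- meas$cov_table[c(1, 1, 2), ]
  expect_error(assemble_table(dup, meas$duration_table), "duplicate")
})

test_that("variability models detect the programmed group effect", {
  fit <- fit_variability_model(paper_scale_table(), "length")
  expect_s3_class(fit, "vt_model_fit")
  a <- fit$anova
  expect_true(all(c("group", "word", "articulator", "group:articulator")
                  %in% a$term))
  expect_lt(a$p[a$term == "group"], 0.05)
  expect_true(all(a$p >= 0 & a$p <= 1))
  expect_true(all(a$partial_eta2 >= 0 & a$partial_eta2 <= 1))
  es <- effect_sizes(fit)
  expect_gt(es$group_d, 0)  # pws-like group more variable
  expect_gte(es$r2["conditional"], es$r2["marginal"])
  # complexity-subset model also runs
  fitc <- fit_variability_model(paper_scale_table(), "complexity")
  expect_gte(fitc$r2["conditional"], fitc$r2["marginal"])
})

test_that("duration models expose the group x complexity interaction", {
  fit <- fit_duration_model(paper_scale_table(), "complexity")
  a <- fit$anova
  expect_true(all(c("group", "word", "group:word") %in% a$term))
  expect_lt(a$p[a$term == "group:word"], 0.05)
  # the word main effect on duration is overwhelming by design
  fitl <- fit_duration_model(paper_scale_table(), "length")
  expect_lt(fitl$anova$p[fitl$anova$term == "word"], 1e-10)
})

test_that("model reports serialize to JSON", {
  fit <- fit_variability_model(paper_scale_table(), "length",
                               random = "intercept")
  f <- tempfile(fileext = ".json")
  write_model_report(fit, f)
  rep <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(rep$anova$term, fit$anova$term)
  expect_equal(rep$r2$marginal, unname(fit$r2["marginal"]),
               tolerance = 1e-9)
  unlink(f)
})

test_that("model fits are deterministic for identical data", {
  tab <- paper_scale_table()
  f1 <- fit_variability_model(tab, "length", random = "intercept")
  f2 <- fit_variability_model(tab, "length", random = "intercept")
  expect_equal(f1$anova, f2$anova)
  expect_equal(effect_sizes(f1)$partial_eta2, effect_sizes(f2)$partial_eta2)
})

test_that("degenerate outcomes raise a zero-variance error", {
  tab <- paper_scale_table()
  flat <- tab$cov
  flat$cov <- 0.2
  flat2 <- tab
  flat2$cov <- flat
  expect_error(fit_variability_model(flat2, "length"), "degenerate")
})

test_that("group needs at least two participants per side", {
  tab <- paper_scale_table()
  few <- tab
  keep <- levels(tab$cov$participant)[c(1, 29)]  # one pws, one control
  few$cov <- droplevels(tab$cov[tab$cov$participant %in% keep, ])
  expect_error(fit_variability_model(few, "length"), "2 participants")
})

test_that("Cohen's d matches its closed form on a hand-built contrast", {
  # two groups with pooled SD 2 and mean difference 2 -> d = 1
  x <- c(4, 6, 8); y <- c(2, 4, 6)
  expect_equal(cohens_d(x, y), 1)
  expect_equal(cohens_d(y, x), -1)
})

test_that("severity is uncorrelated by construction but linear mappings give r = 1", {
  tab <- paper_scale_table()
  sc <- severity_correlation(tab)
  expect_lt(abs(sc$r), 0.5)
  expect_gte(sc$n, 20)
  sc2 <- severity_correlation(tab, words = "length_mean")
  expect_true(is.finite(sc2$r))
  # severity defined as a linear function of the variability summary
  rigged <- tab
  d <- tab$cov[tab$cov$word == "mabshaytiedoib" &
                 tab$cov$articulator == "lips" & tab$cov$group == "pws", ]
  rigged$severity <- data.frame(
    participant = as.character(d$participant),
    group = "pws", severity = 10 + 5 * d$cov
  )
  expect_equal(severity_correlation(rigged)$r, 1, tolerance = 1e-9)
  # too few participants is a precondition error
  tiny <- rigged
  tiny$severity <- rigged$severity[1:2, ]
  expect_error(severity_correlation(tiny), "at least 3")
})

test_that("fixed effects are stable under a realistic missingness regime", {
  tab <- paper_scale_table()
  fit <- fit_variability_model(tab, "length", random = "intercept")
  vtkin:::with_seed(17, {
    drop <- sample(nrow(tab$cov), round(0.06 * nrow(tab$cov)))
  })
  tab2 <- tab
  tab2$cov <- tab$cov[-drop, ]
  fit2 <- fit_variability_model(tab2, "length", random = "intercept")
  delta <- abs(fit$std_beta - fit2$std_beta[names(fit$std_beta)])
  expect_lt(max(delta, na.rm = TRUE), 0.2)
})

test_that("operating characteristics respond monotonically to the group multiplier", {
  mk <- function(mult) cohort_spec(
    n_per_group = c(pws = 14L, control = 10L),
    group_cv_multiplier = c(pws = mult, control = 1),
    group_duration_slope = c(pws = 0, control = 0),
    disfluency_prob = c(pws = 0.04, control = 0.04)
  )
  oc <- simulate_operating_characteristics(
    list(null = mk(1), mid = mk(1.6), strong = mk(2.4)),
    n_sims = 12L, seed = 91L
  )
  # extreme multipliers can occasionally draw an utterance that overruns
  # the 3.5-s trial window; such cohorts are dropped, not fabricated
  expect_lte(max(oc$n_failed), 2)
  expect_true(all(diff(oc$rejection_rate) >= 0))
  expect_gt(oc$rejection_rate[3], oc$rejection_rate[1])
  # same seed reproduces the same table
  oc2 <- simulate_operating_characteristics(list(null = mk(1)),
                                            n_sims = 3L, seed = 91L)
  oc3 <- simulate_operating_characteristics(list(null = mk(1)),
                                            n_sims = 3L, seed = 91L)
  expect_identical(oc2, oc3)
})
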