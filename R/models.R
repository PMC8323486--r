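# Group-level linear mixed models, effect sizes and operating
# characteristics.

word_subset_levels <- function(subset) {
  wi <- word_info()
  switch(subset,
    length = wi$word[wi$syllables <= 3],
    complexity = wi$word[wi$syllables == 4],
    stop("subset must be 'length' or 'complexity'", call. = FALSE)
  )
}

#' Assemble the long-format measurement table
#'
#' Combines variability results, duration statistics and cohort metadata
#' into the table consumed by the model stage, with explicit missingness
#' (excluded words are absent rows). Word is coded as a factor in
#' syllable order; group and articulator as factors; sum-to-zero
#' contrasts are applied at fit time for Type III tests.
#'
#' @param cov_table,duration_table,severity Data frames as produced by
#'   [measure_cohort()].
#' @return An object of class `vt_measurement_table` with elements `cov`,
#'   `duration`, `severity`.
#' @export
assemble_table <- function(cov_table, duration_table, severity = NULL) {
  needed <- c("participant", "group", "word", "articulator", "cov")
  stopifnot(all(needed %in% names(cov_table)))
  stopifnot(all(c("participant", "group", "word", "mean_frames") %in%
                  names(duration_table)))
  key <- with(cov_table, paste(participant, word, articulator))
  if (anyDuplicated(key)) {
    stop("duplicate participant x word x articulator rows", call. = FALSE)
  }
  dkey <- with(duration_table, paste(participant, word))
  if (anyDuplicated(dkey)) {
    stop("duplicate participant x word duration rows", call. = FALSE)
  }
  wlev <- word_info()$word[order(word_info()$complexity_index)]
  code <- function(d) {
    d$participant <- factor(d$participant)
    # keep cohort order (stuttering-like group first), not alphabetical
    d$group <- factor(d$group, levels = unique(d$group))
    d$word <- factor(d$word, levels = wlev)
    if ("articulator" %in% names(d)) {
      d$articulator <- factor(d$articulator,
                              levels = c("lips", "tongue", "velum"))
    }
    d
  }
  cov_table <- code(cov_table)
  duration_table <- code(duration_table)
  if ("included" %in% names(cov_table)) {
    cov_table <- cov_table[cov_table$included & !is.na(cov_table$cov), ]
  }
  if ("included" %in% names(duration_table)) {
    duration_table <- duration_table[duration_table$included &
                                       !is.na(duration_table$mean_frames), ]
  }
  structure(list(cov = cov_table, duration = duration_table,
                 severity = severity),
            class = "vt_measurement_table")
}

sum_contrasts <- function(data, vars) {
  out <- list()
  for (v in vars) {
    if (nlevels(data[[v]]) >= 2) out[[v]] <- "contr.sum"
  }
  out
}

fit_ladder <- function(formulas, data, contr) {
  notes <- character(0)
  for (i in seq_along(formulas)) {
    fit <- withCallingHandlers(
      tryCatch(
        lmerTest::lmer(stats::as.formula(formulas[i]), data = data,
                       contrasts = contr,
                       control = lme4::lmerControl(calc.derivs = FALSE)),
        error = function(e) e
      ),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage")
    )
    if (inherits(fit, "error")) {
      notes <- c(notes, sprintf("step %d failed: %s", i, conditionMessage(fit)))
      next
    }
    singular <- lme4::isSingular(fit, tol = 1e-4)
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
    if ((conv && !singular) || i == length(formulas)) {
      return(list(fit = fit, formula = formulas[i], step = i,
                  singular = singular, converged = conv, notes = notes))
    }
    notes <- c(notes, sprintf(
      "step %d (%s) %s; simplifying", i, formulas[i],
      if (!conv) "did not converge" else "was singular"))
  }
  stop("all random-effects structures failed: ",
       paste(notes, collapse = "; "), call. = FALSE)
}

make_model_fit <- function(label, lad, data, outcome) {
  a <- stats::anova(lad$fit, type = 3, ddf = "Satterthwaite")
  atab <- data.frame(
    term = rownames(a),
    F = a[["F value"]], df1 = a[["NumDF"]], df2 = a[["DenDF"]],
    p = a[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  atab$partial_eta2 <- atab$F * atab$df1 / (atab$F * atab$df1 + atab$df2)
  std_beta <- lme4::fixef(lad$fit) / stats::sd(data[[outcome]])
  structure(
    list(label = label, fit = lad$fit, anova = atab,
         formula = lad$formula, random_step = lad$step,
         converged = lad$converged, singular = lad$singular,
         notes = lad$notes, std_beta = std_beta,
         r2 = nakagawa_r2(lad$fit), data = data, outcome = outcome),
    class = "vt_model_fit"
  )
}

#' @export
print.vt_model_fit <- function(x, ...) {
  cat(sprintf("vt_model_fit '%s': %s\n", x$label, x$formula))
  cat(sprintf("  marginal R2 = %.3f, conditional R2 = %.3f%s\n",
              x$r2["marginal"], x$r2["conditional"],
              if (x$singular) " (singular fit)" else ""))
  print(x$anova, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Fit a movement-variability mixed model
#'
#' Outcome: CoV of movement size per participant x word x articulator.
#' Fixed effects: group, word, articulator and all interactions. Random
#' effects: by-participant intercept plus word and articulator
#' adjustments, simplified automatically on non-convergence or
#' singularity (intercept + word + articulator slopes, then intercept +
#' articulator, then intercept only). Omnibus tests are Type III F tests
#' with Satterthwaite denominator degrees of freedom, on sum-to-zero
#' contrasts.
#'
#' @param table A `vt_measurement_table` (or the `cov_table` data.frame).
#' @param subset `"length"` (1-3-syllable words) or `"complexity"`
#'   (the two 4-syllable words).
#' @param random `"auto"` (simplification ladder) or `"intercept"`
#'   (random intercept only; the fast path used in large simulation
#'   sweeps).
#' @return A `vt_model_fit`: the lmerTest fit, Type III anova table with
#'   partial eta squared per term, standardized betas, Nakagawa marginal
#'   and conditional R2, and convergence notes.
#' @export
fit_variability_model <- function(table, subset = c("length", "complexity"),
                                  random = c("auto", "intercept")) {
  subset <- match.arg(subset)
  random <- match.arg(random)
  d <- if (inherits(table, "vt_measurement_table")) table$cov else table
  d <- d[d$word %in% word_subset_levels(subset) & !is.na(d$cov), ]
  d <- droplevels(d)
  if (length(unique(d$participant[d$group == levels(d$group)[1]])) < 2 ||
      length(unique(d$participant[d$group == levels(d$group)[2]])) < 2) {
    stop("need at least 2 participants per group", call. = FALSE)
  }
  if (stats::sd(d$cov) < 1e-12) {
    stop("degenerate outcome: all CoV values equal", call. = FALSE)
  }
  fixed <- "cov ~ group * word * articulator"
  formulas <- if (random == "intercept") {
    paste(fixed, "+ (1 | participant)")
  } else {
    paste(fixed, c("+ (1 + word + articulator | participant)",
                   "+ (1 + articulator | participant)",
                   "+ (1 | participant)"))
  }
  lad <- fit_ladder(formulas, d,
                    sum_contrasts(d, c("group", "word", "articulator")))
  make_model_fit(paste0("variability-", subset), lad, d, "cov")
}

#' Fit a movement-duration mixed model
#'
#' Outcome: per-participant x word mean utterance duration (frames).
#' Fixed effects: group, word and their interaction (no articulator
#' factor; duration is shared across articulators). Random effects:
#' by-participant intercept plus word adjustment, simplified to intercept
#' only on non-convergence.
#'
#' @inheritParams fit_variability_model
#' @return A `vt_model_fit`.
#' @export
fit_duration_model <- function(table, subset = c("length", "complexity"),
                               random = c("auto", "intercept")) {
  subset <- match.arg(subset)
  random <- match.arg(random)
  d <- if (inherits(table, "vt_measurement_table")) table$duration else table
  d <- d[d$word %in% word_subset_levels(subset) & !is.na(d$mean_frames), ]
  d <- droplevels(d)
  if (stats::sd(d$mean_frames) < 1e-12) {
    stop("degenerate outcome: all durations equal", call. = FALSE)
  }
  d$duration <- d$mean_frames
  fixed <- "duration ~ group * word"
  formulas <- if (random == "intercept") {
    paste(fixed, "+ (1 | participant)")
  } else {
    paste(fixed, c("+ (1 + word | participant)", "+ (1 | participant)"))
  }
  lad <- fit_ladder(formulas, d, sum_contrasts(d, c("group", "word")))
  make_model_fit(paste0("duration-", subset), lad, d, "duration")
}

#' Nakagawa marginal and conditional R-squared
#'
#' Variance-decomposition R2 for a Gaussian mixed model: marginal R2 is
#' the variance explained by the fixed effects, conditional R2 by fixed
#' plus random effects. Random-effect variance is summarized by the mean
#' diagonal of each grouping factor's covariance matrix.
#'
#' @param fit A merMod.
#' @return Named vector `c(marginal, conditional)`.
#' @export
nakagawa_r2 <- function(fit) {
  var_f <- stats::var(stats::predict(fit, re.form = NA))
  vc <- lme4::VarCorr(fit)
  var_r <- sum(vapply(vc, function(m) mean(diag(m)), numeric(1)))
  var_e <- stats::sigma(fit)^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

#' Cohen's d for two independent samples
#'
#' Mean difference divided by the pooled (n - 1 weighted) standard
#' deviation.
#'
#' @param x,y Numeric vectors.
#' @return Cohen's d (positive when `mean(x) > mean(y)`).
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Effect sizes for a fitted model
#'
#' Partial eta squared per omnibus term (from the Type III F table),
#' Cohen's d for the two-group contrast on participant-level means, and
#' the marginal / conditional R2 pair.
#'
#' @param fit A `vt_model_fit`.
#' @return A list: `partial_eta2` (named vector), `group_d`, `r2`.
#' @export
effect_sizes <- function(fit) {
  stopifnot(inherits(fit, "vt_model_fit"))
  if (!fit$converged) {
    stop("refusing effect sizes for an unconverged fit", call. = FALSE)
  }
  d <- fit$data
  pm <- tapply(d[[fit$outcome]], d$participant, mean, na.rm = TRUE)
  pg <- tapply(as.character(d$group), d$participant, `[`, 1)
  gl <- levels(d$group)
  gd <- cohens_d(pm[pg == gl[1]], pm[pg == gl[2]])
  eta <- stats::setNames(fit$anova$partial_eta2, fit$anova$term)
  list(partial_eta2 = eta, group_d = gd, r2 = fit$r2)
}

#' Correlation between movement variability and severity
#'
#' Pearson correlation, within the stuttering-like group, between a
#' participant-level variability summary and the severity score. The
#' a-priori summary is the lip CoV for the most complex pseudoword
#' ("mabshaytiedoib"); `words = "length_mean"` averages the lip CoV over
#' the one- to three-syllable words instead.
#'
#' @param table A `vt_measurement_table` (with `severity`).
#' @param words A pseudoword label or `"length_mean"`.
#' @param articulator Articulator to summarize (default lips).
#' @param group Group whose severity is analyzed (default the first group
#'   level, the stuttering-like one).
#' @return A list: `r`, `p`, `n`, `words`.
#' @export
severity_correlation <- function(table, words = "mabshaytiedoib",
                                 articulator = "lips", group = NULL) {
  stopifnot(inherits(table, "vt_measurement_table"))
  if (is.null(table$severity)) stop("no severity scores in table")
  d <- table$cov
  if (is.null(group)) group <- levels(d$group)[1]
  sel_words <- if (identical(words, "length_mean")) {
    word_subset_levels("length")
  } else words
  d <- d[d$group == group & d$articulator == articulator &
           d$word %in% sel_words & !is.na(d$cov), ]
  summ <- tapply(d$cov, droplevels(d$participant), mean)
  sev <- table$severity
  sev <- sev[match(names(summ), sev$participant), "severity"]
  ok <- !is.na(sev) & !is.na(summ)
  if (sum(ok) < 3) stop("need at least 3 participants with both values",
                        call. = FALSE)
  if (stats::sd(summ[ok]) == 0 || stats::sd(sev[ok]) == 0) {
    stop("zero variance in variability or severity", call. = FALSE)
  }
  ct <- stats::cor.test(summ[ok], sev[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), words = words)
}

#' Operating characteristics of the end-to-end pipeline
#'
#' For each cohort scenario, repeatedly generates a trajectory-only
#' cohort, measures it, fits the requested mixed model and records the
#' omnibus p value of one term. Reports the rejection rate at `alpha`.
#' Fits use the random-intercept fast path.
#'
#' @param scenarios A named list of `vt_cohort_spec` objects (seeds inside
#'   are ignored; per-simulation seeds derive from `seed`).
#' @param n_sims Simulated cohorts per scenario.
#' @param seed Master seed.
#' @param model `"variability"` or `"duration"`.
#' @param subset Passed to the fit function.
#' @param term Row of the anova table to test (default `"group"`).
#' @param alpha Significance level (default 0.05).
#' @param acq A `vt_acquisition`.
#' @return A data.frame: scenario, n_sims, rejections, rejection_rate,
#'   mean_p, n_failed, seed.
#' @export
simulate_operating_characteristics <- function(scenarios, n_sims = 100L,
                                               seed = 1L,
                                               model = c("variability",
                                                         "duration"),
                                               subset = "length",
                                               term = "group",
                                               alpha = 0.05,
                                               acq = acquisition_params()) {
  model <- match.arg(model)
  stopifnot(is.list(scenarios), length(names(scenarios)) == length(scenarios))
  sim_seeds <- with_seed(seed, {
    matrix(sample.int(.Machine$integer.max - 1L,
                      n_sims * length(scenarios)),
           nrow = n_sims)
  })
  out <- list()
  for (j in seq_along(scenarios)) {
    sc <- scenarios[[j]]
    stopifnot(inherits(sc, "vt_cohort_spec"))
    pvals <- rep(NA_real_, n_sims)
    ests <- rep(NA_real_, n_sims)
    for (i in seq_len(n_sims)) {
      sc$seed <- sim_seeds[i, j]
      res <- tryCatch({
        cohort <- generate_cohort(sc, acq, mode = "trajectories")
        meas <- measure_cohort(cohort)
        tab <- assemble_table(meas$cov_table, meas$duration_table,
                              meas$severity)
        fit <- if (model == "variability") {
          fit_variability_model(tab, subset, random = "intercept")
        } else {
          fit_duration_model(tab, subset, random = "intercept")
        }
        fe <- lme4::fixef(fit$fit)
        # with sum contrasts, twice the group1 coefficient is the
        # estimated group difference
        est <- if ("group1" %in% names(fe)) 2 * unname(fe["group1"])
               else NA_real_
        list(p = fit$anova$p[fit$anova$term == term], est = est)
      }, error = function(e) NULL)
      if (!is.null(res) && length(res$p) == 1) {
        pvals[i] <- res$p
        ests[i] <- res$est
      }
    }
    ok <- !is.na(pvals)
    out[[j]] <- data.frame(
      scenario = names(scenarios)[j], n_sims = n_sims,
      rejections = sum(pvals[ok] < alpha),
      rejection_rate = mean(pvals[ok] < alpha),
      mean_p = mean(pvals[ok]),
      mean_group_estimate = mean(ests[ok]),
      n_failed = sum(!ok), seed = seed,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
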