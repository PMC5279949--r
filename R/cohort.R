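# Cohort simulation and end-to-end experiment orchestration.
#
# A cohort is a list of subject records, each carrying a group label and the
# generative parameters used for that subject. Experiment runners generate
# the raw synthetic data per subject, push it through the analysis modules,
# and return tidy per-subject tables plus per-subject decay fits. Group
# comparisons use conservative nonparametric tests.

ACTIVE_ITIS <- c(1.4, 2.9, 5.9, 8.9)
ACTIVE_SOAS <- c(2, 3.5, 6.5, 9.5)
PASSIVE_ISIS <- c(2, 3.5, 6.5, 9.5)

#' Published-group generative parameter presets
#'
#' Decay-curve parameters of the behavioral context effect and of N1/P2
#' adaptation recovery (active and passive), and reading-benefit parameters,
#' for a control-like and a dyslexic-like group. Behavioral and ERP decay
#' triplets are group-mean estimates; reading-benefit parameters are chosen
#' so that the generated sessions reproduce the reported short-lag (<2 s)
#' and long-lag (>2 s) percentage benefits under the default lag plan.
#'
#' @param group `"control"` or `"dyslexic"`.
#' @return A list of per-measure parameter lists.
#' @export
group_params <- function(group = c("control", "dyslexic")) {
  group <- match.arg(group)
  if (group == "control") {
    list(
      group = group,
      behavior = list(alpha = 0.7, beta = 2.3, tau = 6),
      erp_active = list(n1 = list(alpha = -131, beta = 497, tau = 5.1),
                        p2 = list(alpha = 396, beta = -696, tau = 8.5)),
      erp_passive = list(n1 = list(alpha = -132, beta = 497, tau = 7.2),
                         p2 = list(alpha = 490, beta = -750, tau = 5.4)),
      reading = list(rt_base_mean = 725, rt_between_sd = 150,
                     error_rate = 0.014, benefit0 = 30,
                     benefit_floor = 12, tau_read = 6)
    )
  } else {
    list(
      group = group,
      behavior = list(alpha = 0.5, beta = 4, tau = 2.9),
      erp_active = list(n1 = list(alpha = -109, beta = 750, tau = 1.3),
                        p2 = list(alpha = 322, beta = -696, tau = 4.4)),
      erp_passive = list(n1 = list(alpha = -114, beta = 615, tau = 4.1),
                         p2 = list(alpha = 410, beta = -724, tau = 3.3)),
      reading = list(rt_base_mean = 929, rt_between_sd = 225,
                     error_rate = 0.04, benefit0 = 40,
                     benefit_floor = 6, tau_read = 2.9)
    )
  }
}

# Draw a per-subject decay triplet around group values with a truncated
# normal of coefficient of variation `cv`, respecting the sign convention.
draw_triplet <- function(tr, cv) {
  draw1 <- function(v, lo_frac = 0.2) {
    if (v == 0 || cv == 0) return(v)
    x <- stats::rnorm(1, v, cv * abs(v))
    # keep the draw on the parameter's side of zero
    if (sign(x) != sign(v) || abs(x) < lo_frac * abs(v)) {
      x <- lo_frac * v
    }
    x
  }
  list(alpha = draw1(tr$alpha), beta = draw1(tr$beta), tau = draw1(tr$tau))
}

#' Simulate a two-group cohort
#'
#' Draws per-subject generative parameters from the group presets and logs
#' the per-subject seeds derived from the master seed. Behavioral decay
#' parameters are shared within a group (per-subject estimation noise alone
#' reproduces realistic between-subject spread); ERP and reading parameters
#' are drawn around the group values with coefficient of variation `erp_cv`
#' and `reading_cv`.
#'
#' @param n_control,n_dyslexic Group sizes.
#' @param seed Master seed; every downstream draw is reproducible from it.
#' @param erp_cv,reading_cv Between-subject coefficients of variation.
#' @param params Optional named list overriding [group_params()] per group.
#' @return A `cohort`: list of subject records with `subject_id`, `group`,
#'   `params`, `seed`.
#' @export
#' @examples
#' co <- simulate_cohort(n_control = 2, n_dyslexic = 2, seed = 1)
#' sapply(co, function(s) s$group)
simulate_cohort <- function(n_control = 23, n_dyslexic = 25, seed = 1,
                            erp_cv = 0.15, reading_cv = 0.1,
                            params = NULL) {
  if (n_control < 0 || n_dyslexic < 0) {
    stop_config("group sizes must be non-negative")
  }
  n <- n_control + n_dyslexic
  groups <- rep(c("control", "dyslexic"), c(n_control, n_dyslexic))
  seeds <- child_seeds(seed, n)
  cohort <- lapply(seq_len(n), function(i) {
    gp <- params[[groups[i]]] %||% group_params(groups[i])
    with_seed(seeds[i], {
      subj <- gp
      subj$erp_active <- lapply(gp$erp_active, draw_triplet, cv = erp_cv)
      subj$erp_passive <- lapply(gp$erp_passive, draw_triplet, cv = erp_cv)
      rd <- gp$reading
      rd$rt_base_mean <- max(stats::rnorm(1, rd$rt_base_mean,
                                          rd$rt_between_sd), 350)
      rd$benefit0 <- clamp(stats::rnorm(1, rd$benefit0,
                                        reading_cv * rd$benefit0), c(1, 95))
      rd$benefit_floor <- clamp(stats::rnorm(1, rd$benefit_floor,
                                             reading_cv * rd$benefit_floor),
                                c(0, rd$benefit0))
      rd$tau_read <- max(stats::rnorm(1, rd$tau_read,
                                      reading_cv * rd$tau_read), 0.3)
      subj$reading <- rd
      list(subject_id = sprintf("S%03d", i), group = groups[i],
           params = subj, seed = seeds[i])
    })
  })
  structure(cohort, class = "cohort", master_seed = seed)
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(vapply(x, function(s) s$group, character(1)))
  cat("<cohort>", paste(names(tab), tab, collapse = ", "),
      sprintf("(master seed %s)\n", attr(x, "master_seed")))
  invisible(x)
}

# Shared, lazily built delta d' calibration map (fixed internal seed).
.map_cache <- new.env(parent = emptyenv())

default_ddprime_map <- function() {
  if (is.null(.map_cache$map)) {
    .map_cache$map <- calibrate_ddprime_map()
  }
  .map_cache$map
}

subject_observer <- function(subject, times = ACTIVE_ITIS) {
  b <- subject$params$behavior
  observer_from_decay(b$alpha, b$beta, b$tau, times = times,
                      map = default_ddprime_map())
}

run_exp2_active_behavior <- function(subject, trials_per_block = 100L) {
  seeds <- child_seeds(subject$seed + 1L, 8L)
  obs <- subject_observer(subject)
  # block order counterbalanced across subjects by rotating the ITI order
  ord_shift <- (as.integer(sub("S", "", subject$subject_id)) - 1L) %% 4L
  block_order <- ((seq_len(4L) - 1L + ord_shift) %% 4L) + 1L
  rows <- lapply(seq_along(block_order), function(k) {
    b <- block_order[k]
    sq <- generate_random_sequence(trials_per_block, iti = ACTIVE_ITIS[b],
                                   seed = seeds[2 * k - 1L])
    ch <- simulate_observer(sq, obs, seed = seeds[2 * k])
    ce <- context_effect(sq, ch)
    ce$subject_id <- subject$subject_id
    ce$group <- subject$group
    ce
  })
  out <- do.call(rbind, rows)
  out[order(out$iti), ]
}

run_erp_session <- function(subject, active, n_events = 100L,
                            noise_sd = 2, artifact_rate = 0.5) {
  pr <- if (active) subject$params$erp_active else subject$params$erp_passive
  p <- erp_gen_params(n1 = pr$n1, p2 = pr$p2, noise_sd = noise_sd,
                      artifact_rate = artifact_rate)
  seeds <- child_seeds(subject$seed + (if (active) 2L else 3L), 4L)
  soas <- if (active) ACTIVE_SOAS else PASSIVE_ISIS
  tt <- if (active) ACTIVE_ITIS else PASSIVE_ISIS
  rows <- lapply(seq_along(soas), function(b) {
    sch <- block_schedule(n_events, soas[b], active = active)
    rec <- generate_eeg(sch, p, seed = seeds[b], block_id = b)
    ar <- erp_block_areas(rec)
    ar$t_s <- tt[b]
    ar$subject_id <- subject$subject_id
    ar$group <- subject$group
    ar
  })
  do.call(rbind, rows)
}

fit_subject_decays <- function(areas, kinds = c(n1 = "erp_n1", p2 = "erp_p2")) {
  rows <- lapply(names(kinds), function(cmp) {
    a <- areas[areas$component == cmp, ]
    ft <- fit_decay(a$t_s, a$area_uv_ms, kinds[[cmp]])
    data.frame(component = cmp, alpha = ft$model$alpha, beta = ft$model$beta,
               tau = ft$model$tau, r_squared = ft$r_squared,
               tau_identifiable = ft$tau_identifiable)
  })
  do.call(rbind, rows)
}

#' Run one experiment on a cohort
#'
#' * `exp1`: decorrelated-sequence choice GLM (4 blocks x 150 trials per
#'   subject); returns per-subject `beta_df`, `beta_global`, `beta_recent`.
#' * `exp2_active`: two-tone blocks at ITIs 1.4/2.9/5.9/8.9 s; per-subject
#'   delta d' per ITI and its decay fit, plus simultaneous EEG at matching
#'   SOAs with N1/P2 area decay fits against the nominal ITIs.
#' * `exp2_passive`: single-tone blocks at ISIs 2/3.5/6.5/9.5 s; N1/P2 area
#'   decay fits against the ISIs.
#' * `exp3`: reading sessions; per-subject repetition benefits in the <2 s
#'   and >2 s lag bins.
#'
#' @param which Experiment name.
#' @param cohort A [simulate_cohort()] result.
#' @param trials_per_block Trials (or events) per block for exp2.
#' @param with_eeg Include the EEG arm of `exp2_active` (default `TRUE`).
#' @return A list with elements `measures` (tidy per-subject data frame) and,
#'   where applicable, `fits` (per-subject decay fits with identifiability
#'   flags).
#' @export
run_experiment <- function(which = c("exp1", "exp2_active", "exp2_passive",
                                     "exp3"),
                           cohort, trials_per_block = 100L, with_eeg = TRUE) {
  which <- match.arg(which)
  if (length(cohort) == 0L) {
    return(list(measures = data.frame(), fits = data.frame()))
  }
  switch(which,
    exp1 = run_exp1(cohort),
    exp2_active = run_exp2_active(cohort, trials_per_block, with_eeg),
    exp2_passive = run_exp2_passive(cohort, trials_per_block),
    exp3 = run_exp3(cohort)
  )
}

run_exp1 <- function(cohort, n_blocks = 4L, trials_per_block = 150L) {
  rows <- lapply(cohort, function(subject) {
    seeds <- child_seeds(subject$seed + 4L, 2L * n_blocks)
    obs <- subject_observer(subject, times = 1.5)
    design <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      sq <- generate_decorrelated_sequence(trials_per_block, iti = 1.5,
                                           seed = seeds[2 * b - 1L])
      ch <- simulate_observer(sq, obs, seed = seeds[2 * b])
      build_design_matrix(sq, ch)
    }))
    fit <- fit_choice_glm(design)
    data.frame(subject_id = subject$subject_id, group = subject$group,
               beta_df = fit$beta_df, beta_global = fit$beta_global,
               beta_recent = fit$beta_recent, n_trials = fit$n_trials,
               ridged = fit$ridged)
  })
  list(measures = do.call(rbind, rows))
}

run_exp2_active <- function(cohort, trials_per_block, with_eeg) {
  beh <- lapply(cohort, function(subject) {
    ce <- run_exp2_active_behavior(subject, trials_per_block)
    ok <- !ce$flagged
    ft <- fit_decay(ce$iti[ok], ce$delta_dprime[ok], "dprime")
    list(measures = ce,
         fit = data.frame(subject_id = subject$subject_id,
                          group = subject$group, measure = "delta_dprime",
                          alpha = ft$model$alpha, beta = ft$model$beta,
                          tau = ft$model$tau, r_squared = ft$r_squared,
                          tau_identifiable = ft$tau_identifiable))
  })
  measures <- do.call(rbind, lapply(beh, `[[`, "measures"))
  fits <- do.call(rbind, lapply(beh, `[[`, "fit"))
  if (with_eeg) {
    erp <- lapply(cohort, function(subject) {
      ar <- run_erp_session(subject, active = TRUE,
                            n_events = trials_per_block)
      fd <- fit_subject_decays(ar)
      fd$subject_id <- subject$subject_id
      fd$group <- subject$group
      fd$measure <- paste0(fd$component, "_active")
      list(areas = ar, fits = fd[setdiff(names(fd), "component")])
    })
    measures <- list(behavior = measures,
                     erp_areas = do.call(rbind, lapply(erp, `[[`, "areas")))
    fits <- rbind(fits, do.call(rbind, lapply(erp, `[[`, "fits")))
  }
  list(measures = measures, fits = fits)
}

run_exp2_passive <- function(cohort, trials_per_block) {
  erp <- lapply(cohort, function(subject) {
    ar <- run_erp_session(subject, active = FALSE,
                          n_events = trials_per_block)
    fd <- fit_subject_decays(ar)
    fd$subject_id <- subject$subject_id
    fd$group <- subject$group
    fd$measure <- paste0(fd$component, "_passive")
    list(areas = ar, fits = fd[setdiff(names(fd), "component")])
  })
  list(measures = do.call(rbind, lapply(erp, `[[`, "areas")),
       fits = do.call(rbind, lapply(erp, `[[`, "fits")))
}

run_exp3 <- function(cohort) {
  rows <- lapply(cohort, function(subject) {
    rd <- subject$params$reading
    p <- reading_gen_params(rt_base_mean = rd$rt_base_mean,
                            benefit0 = rd$benefit0,
                            benefit_floor = rd$benefit_floor,
                            tau_read = rd$tau_read,
                            error_rate = rd$error_rate)
    sess <- generate_reading_session(p, seed = subject$seed + 5L)
    rb <- repetition_benefit(pair_repetitions(sess))
    rb$subject_id <- subject$subject_id
    rb$group <- subject$group
    rb
  })
  list(measures = do.call(rbind, rows))
}

#' Group-level summary of per-subject decay fits
#'
#' Means and SEMs of the fitted parameters per group and measure, restricted
#' to fits whose time constant is identifiable (see [fit_decay()]); the
#' number of excluded subjects is reported.
#'
#' @param fits The `fits` element of a [run_experiment()] result.
#' @return Data frame per (group, measure): `mean_alpha`, `mean_beta`,
#'   `mean_tau`, `sem_tau`, `n`, `n_excluded`.
#' @export
summarize_decay_fits <- function(fits) {
  sp <- split(fits, list(fits$group, fits$measure), drop = TRUE)
  rows <- lapply(sp, function(d) {
    ok <- d$tau_identifiable
    data.frame(group = d$group[1], measure = d$measure[1],
               mean_alpha = mean(d$alpha[ok]), mean_beta = mean(d$beta[ok]),
               mean_tau = mean(d$tau[ok]),
               sem_tau = stats::sd(d$tau[ok]) / sqrt(sum(ok)),
               n = sum(ok), n_excluded = sum(!ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nonparametric group comparison
#'
#' * `mann_whitney`: two-sample rank test between groups (normal
#'   approximation with tie correction); the reported statistic is the
#'   Wilcoxon `W` of the control sample, i.e. the Mann-Whitney U of the
#'   first group.
#' * `wilcoxon`: paired signed-rank test between two named measures within
#'   subjects.
#' * `friedman`: repeated-measures rank test across >= 3 within-subject
#'   conditions.
#'
#' @param values A data frame with `group` and the measure column (for
#'   `mann_whitney`), or a matrix subjects x conditions (for `wilcoxon` with
#'   2 columns, `friedman` with >= 3).
#' @param measure Column name to compare (mann_whitney).
#' @param test Test name.
#' @return A `group_comparison`: test, statistic, p value, group summaries.
#' @export
compare_groups <- function(values, measure = NULL,
                           test = c("mann_whitney", "wilcoxon", "friedman")) {
  test <- match.arg(test)
  if (test == "mann_whitney") {
    stopifnot(is.data.frame(values), "group" %in% names(values),
              measure %in% names(values))
    g <- unique(values$group)
    if (length(g) != 2L) stop_config("mann_whitney needs exactly two groups")
    x <- values[[measure]][values$group == g[1]]
    y <- values[[measure]][values$group == g[2]]
    if (length(x) < 2L || length(y) < 2L) {
      stop_config("need at least 2 subjects per group")
    }
    if (stats::sd(c(x, y)) == 0) {
      stop(errorCondition("measure is constant: comparison undefined",
                          class = c("memdecay_undefined_measure", "error")))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    summaries <- data.frame(
      group = g,
      mean = c(mean(x), mean(y)),
      sem = c(stats::sd(x) / sqrt(length(x)), stats::sd(y) / sqrt(length(y))),
      n = c(length(x), length(y)))
    structure(list(measure = measure, test = test,
                   statistic = unname(wt$statistic), p_value = wt$p.value,
                   summaries = summaries), class = "group_comparison")
  } else if (test == "wilcoxon") {
    stopifnot(is.matrix(values) || is.data.frame(values), ncol(values) == 2L)
    wt <- suppressWarnings(stats::wilcox.test(values[, 1], values[, 2],
                                              paired = TRUE, exact = FALSE))
    structure(list(measure = paste(colnames(values), collapse = " vs "),
                   test = test, statistic = unname(wt$statistic),
                   p_value = wt$p.value, summaries = NULL),
              class = "group_comparison")
  } else {
    m <- as.matrix(values)
    stopifnot(ncol(m) >= 3L)
    ft <- stats::friedman.test(m)
    structure(list(measure = paste(ncol(m), "conditions"), test = test,
                   statistic = unname(ft$statistic), p_value = ft$p.value,
                   summaries = NULL), class = "group_comparison")
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison:%s> %s: statistic = %.3g, p = %.3g\n",
              x$test, x$measure, x$statistic, x$p_value))
  if (!is.null(x$summaries)) {
    print(x$summaries, row.names = FALSE)
  }
  invisible(x)
}
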