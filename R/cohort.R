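#' Fit self-driven and social-induced models for one user
#'
#' Estimates the user's epsilon-machine from the output sequence alone
#' and the epsilon-transducer from the aligned pair, each with its own
#' maximum history length selected by held-out log loss, and summarizes
#' both with [summarize_model()].
#'
#' @param pair The user's [io_pair].
#' @param lmax_grid Candidate history lengths for both models.
#' @param cfg A [cssr_config()] providing `alpha`, `min_count`, and the
#'   scoring floor.
#' @return List of class `user_result`: `user_id`, `machine`,
#'   `transducer` (the fitted models), `machine_summary`,
#'   `transducer_summary`, `troll_count` (number of 1s emitted),
#'   `n_comments` (sequence length), and `error` (NULL on success).
#' @export
fit_user <- function(pair, lmax_grid = 1:6, cfg = cssr_config()) {
  stopifnot(inherits(pair, "io_pair"))
  out <- list(user_id = pair$outputs$user_id,
              troll_count = sum(pair$outputs$symbols),
              n_comments = length(pair$inputs),
              machine = NULL, transducer = NULL,
              machine_summary = NULL, transducer_summary = NULL,
              error = NULL)
  res <- tryCatch({
    sel_m <- select_lmax(pair$outputs, lmax_grid, cfg)
    cfg_m <- cssr_config(alpha = cfg$alpha, lmax = sel_m$lmax,
                         min_count = cfg$min_count,
                         smoothing_floor = cfg$smoothing_floor)
    m <- estimate_machine(pair$outputs, cfg_m)
    sel_t <- select_lmax_transducer(pair, lmax_grid, cfg)
    cfg_t <- cssr_config(alpha = cfg$alpha, lmax = sel_t$lmax,
                         min_count = cfg$min_count,
                         smoothing_floor = cfg$smoothing_floor)
    t <- estimate_transducer(pair, cfg_t)
    list(m = m, t = t,
         sm = summarize_model(m, pair$outputs, sel_m$lmax),
         st = summarize_model(t, pair, sel_t$lmax))
  }, error = function(e) e)
  if (inherits(res, "error")) {
    out$error <- conditionMessage(res)
  } else {
    out$machine <- res$m
    out$transducer <- res$t
    out$machine_summary <- res$sm
    out$transducer_summary <- res$st
  }
  structure(out, class = "user_result")
}

#' Filter user summaries before correlation
#'
#' Reproduces the pre-correlation cleanup of population scatter plots:
#' drops users whose complexity is exactly zero (memoryless models pile
#' up at the origin and would dominate the correlation) and then drops
#' users with any measure further than `sd_mult` standard deviations from
#' the cohort mean.
#'
#' @param df Data frame with columns `C`, `E`, `h`.
#' @param sd_mult Outlier cut in standard deviations (default 3).
#' @return The filtered data frame; a warning is attached if fewer than 3
#'   rows survive.
#' @export
filter_for_correlation <- function(df, sd_mult = 3) {
  keep <- df[df$C > 0, , drop = FALSE]
  if (nrow(keep) > 0) {
    ok <- rep(TRUE, nrow(keep))
    for (col in c("C", "E", "h")) {
      v <- keep[[col]]
      s <- stats::sd(v)
      if (is.na(s) || s == 0) next
      ok <- ok & abs(v - mean(v)) <= sd_mult * s
    }
    keep <- keep[ok, , drop = FALSE]
  }
  if (nrow(keep) < 3) {
    warning("fewer than 3 users survive filtering; correlations skipped")
  }
  keep
}

#' Pearson correlation with significance test
#'
#' @param x,y Numeric vectors of equal length (n >= 3), both with
#'   positive variance.
#' @return List with `r`, `n`, and the two-sided `p` from the t test.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

#' Welch two-sample t test
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @return List with `t`, `df` (Welch-Satterthwaite), and two-sided `p`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    return(list(t = ifelse(mean(a) > mean(b), Inf, -Inf),
                df = length(a) + length(b) - 2, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' One-way fixed-effects ANOVA
#'
#' @param groups List of numeric vectors, one per group.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 1))
  values <- unlist(groups)
  stopifnot(length(values) > length(groups))
  if (stats::sd(values) == 0) {
    return(list(F = 0, df1 = length(groups) - 1,
                df2 = length(values) - length(groups), p = 1))
  }
  labels <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ow <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  list(F = unname(ow$statistic), df1 = unname(ow$parameter[1]),
       df2 = unname(ow$parameter[2]), p = ow$p.value)
}

summary_frame <- function(results, which) {
  rows <- lapply(results, function(r) {
    s <- r[[which]]
    if (is.null(s)) return(NULL)
    data.frame(user_id = r$user_id, n_states = s$n_states, lmax = s$lmax,
               C = s$C, E = s$E, h = s$h,
               troll_count = r$troll_count, n_comments = r$n_comments,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit a whole cohort and build the population report
#'
#' Fits self-driven and social-induced models for every user
#' (per-user failures are tallied, not fatal), then assembles the
#' population-level comparisons: state-count and lmax histograms for both
#' model families, C-h and C-E correlations on the filtered summaries,
#' Welch tests contrasting the two model families (state counts and
#' predictable information) and contrasting user groups defined by the
#' transducer's state count (troll counts; comment counts), and one-way
#' ANOVAs of E, C, h across machine state-count groups.
#'
#' @param cohort A list of user records as produced by
#'   [generate_cohort()] (each with a `pair` element), or a bare list of
#'   [io_pair] objects.
#' @param lmax_grid Candidate history lengths per user and model family.
#' @param cfg A [cssr_config()].
#' @param sd_mult Outlier cut used by [filter_for_correlation()].
#' @return A list of class `cohort_report`.
#' @export
run_cohort <- function(cohort, lmax_grid = 1:3, cfg = cssr_config(),
                       sd_mult = 3) {
  stopifnot(length(cohort) >= 1)
  results <- lapply(cohort, function(u) {
    pair <- if (inherits(u, "io_pair")) u else u$pair
    fit_user(pair, lmax_grid, cfg)
  })
  failures <- sum(vapply(results, function(r) !is.null(r$error), TRUE))
  mach <- summary_frame(results, "machine_summary")
  trans <- summary_frame(results, "transducer_summary")
  hist_states <- list(machine = table(mach$n_states),
                      transducer = table(trans$n_states))
  hist_lmax <- list(machine = table(mach$lmax),
                    transducer = table(trans$lmax))
  correlations <- list()
  for (fam in c("machine", "transducer")) {
    df <- if (fam == "machine") mach else trans
    filt <- suppressWarnings(filter_for_correlation(df, sd_mult))
    correlations[[fam]] <- if (nrow(filt) >= 3 &&
                               stats::sd(filt$C) > 0) {
      list(C_h = if (stats::sd(filt$h) > 0) pearson_r(filt$C, filt$h),
           C_E = if (stats::sd(filt$E) > 0) pearson_r(filt$C, filt$E),
           n_used = nrow(filt))
    } else {
      list(C_h = NULL, C_E = NULL, n_used = nrow(filt))
    }
  }
  tests <- list()
  both <- merge(mach, trans, by = "user_id", suffixes = c("_m", "_t"))
  if (nrow(both) >= 2) {
    tests$states_transducer_vs_machine <-
      welch_t(both$n_states_t, both$n_states_m)
    tests$E_transducer_vs_machine <- welch_t(both$E_t, both$E_m)
  }
  multi <- trans$n_states > 1
  if (sum(multi) >= 2 && sum(!multi) >= 2) {
    tests$troll_count_multi_vs_one <-
      welch_t(trans$troll_count[multi], trans$troll_count[!multi])
    tests$n_comments_one_vs_multi <-
      welch_t(trans$n_comments[!multi], trans$n_comments[multi])
  }
  anovas <- list()
  if (!is.null(mach) && length(unique(mach$n_states)) >= 2) {
    grp <- split(seq_len(nrow(mach)), mach$n_states)
    grp <- grp[vapply(grp, length, 1L) >= 1]
    if (length(grp) >= 2) {
      for (meas in c("E", "C", "h")) {
        anovas[[meas]] <- anova_oneway(lapply(grp, function(i) mach[[meas]][i]))
      }
    }
  }
  structure(list(results = results, machine_summaries = mach,
                 transducer_summaries = trans,
                 hist_states = hist_states, hist_lmax = hist_lmax,
                 correlations = correlations, tests = tests,
                 anovas = anovas, n_failures = failures),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>", nrow(x$machine_summaries), "users fitted,",
      x$n_failures, "failures\n")
  cat("machine state histogram:\n")
  print(x$hist_states$machine)
  cat("transducer state histogram:\n")
  print(x$hist_states$transducer)
  if (!is.null(x$tests$states_transducer_vs_machine)) {
    tt <- x$tests$states_transducer_vs_machine
    cat(sprintf("states transducer vs machine: t = %.3f, df = %.1f, p = %.3g\n",
                tt$t, tt$df, tt$p))
  }
  invisible(x)
}
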