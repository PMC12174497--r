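#' Aggregate first-post-switch outcomes into subject x run-length cells
#'
#' The repetition-interference analyses operate on the trial immediately
#' following each switch, averaged per subject over the `n_sets` switches of
#' each pre-switch run length. Input is a per-trial metrics table that
#' carries the schedule labels (`phase`, `run_length`, `position_in_run`)
#' and a `subject` column; metrics must already be sign-normalized.
#'
#' @param metrics Per-trial metrics table with schedule labels.
#' @param outcomes Character vector of outcome columns to average.
#' @return Tibble: `subject`, `run_length`, one mean column per outcome,
#'   and `n_trials` (trials contributing to the cell).
#' @export
aggregate_post_switch <- function(metrics,
                                  outcomes = c("mcom",
                                               "lf_torque_component",
                                               "grip_torque_component")) {
  if (nrow(metrics) == 0L) {
    stop("aggregate_post_switch: empty metrics table", call. = FALSE)
  }
  need <- c("subject", "phase", "run_length", "position_in_run")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) {
    stop("aggregate_post_switch: missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  outcomes <- intersect(outcomes, names(metrics))
  if ("sign_normalized" %in% names(metrics) &&
      !all(metrics$sign_normalized)) {
    warning("aggregate_post_switch: metrics are not sign-normalized",
            call. = FALSE)
  }
  first_post <- metrics[metrics$phase == "post_switch" &
                          metrics$position_in_run == 1L &
                          !is.na(metrics$run_length), , drop = FALSE]
  cells <- first_post |>
    dplyr::group_by(.data$subject, .data$run_length) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(outcomes),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_trials = dplyr::n(), .groups = "drop")
  incomplete <- cells$subject[!stats::complete.cases(cells)]
  if (length(incomplete)) {
    warning("aggregate_post_switch: cells with missing values for subjects ",
            paste(unique(incomplete), collapse = ", "), call. = FALSE)
  }
  cells
}

#' Mixed-design two-factor ANOVA
#'
#' One between-subjects factor (2 or 3 levels) crossed with one
#' within-subjects factor (2 levels, e.g. pre-switch repetition 1 vs 3).
#' Fitted with [stats::aov()] using an `Error(subject/within)` stratum so
#' the between effect is tested against the between-subject residual and the
#' within effect and interaction against the subject-by-within residual.
#' Partial eta squared is the effect SS over effect SS plus its own error
#' SS.
#'
#' @param cells Long-format tibble with one row per subject x within level:
#'   columns named by `between`, `within`, `subject` and `value`.
#' @param value Name of the outcome column. Default `"value"`.
#' @param between,within Names of the factor columns.
#' @param subject Name of the subject-identifier column.
#' @return An `anova_table`: tibble with `effect`, `ss`, `df`, `ms`, `f`,
#'   `p`, `partial_eta_sq`, plus error rows (`ss`, `df`, `ms` only).
#' @export
mixed_anova <- function(cells, value = "value", between = "between",
                        within = "within", subject = "subject") {
  d <- tibble::tibble(
    y = cells[[value]],
    b = factor(cells[[between]]),
    w = factor(cells[[within]]),
    s = factor(paste(cells[[between]], cells[[subject]], sep = ":")))
  if (any(is.na(d$y))) {
    stop("mixed_anova: missing outcome values", call. = FALSE)
  }
  # drop subjects missing a within level
  n_w <- nlevels(d$w)
  per_subj <- table(d$s[!duplicated(paste(d$s, d$w))])
  keep <- names(per_subj)[per_subj == n_w]
  if (length(keep) < length(per_subj)) {
    warning("mixed_anova: dropping subjects missing a within level: ",
            paste(setdiff(names(per_subj), keep), collapse = ", "),
            call. = FALSE)
    d <- d[d$s %in% keep, , drop = FALSE]
    d$s <- droplevels(d$s)
  }
  grp_n <- table(unique(d[, c("b", "s")])$b)
  if (any(grp_n < 2)) {
    stop("mixed_anova: need >= 2 subjects per between-factor level",
         call. = FALSE)
  }
  fit <- stats::aov(y ~ b * w + Error(s / w), data = d)
  strata <- summary(fit)
  pull <- function(stratum) {
    tab <- strata[[stratum]][[1]]
    data.frame(term = trimws(rownames(tab)), ss = tab[["Sum Sq"]],
               df = tab[["Df"]], stringsAsFactors = FALSE)
  }
  s_between <- pull("Error: s")
  s_within <- pull("Error: s:w")
  err_b <- s_between[s_between$term == "Residuals", ]
  err_w <- s_within[s_within$term == "Residuals", ]
  eff <- rbind(
    cbind(s_between[s_between$term == "b", ],
          err_ss = err_b$ss, err_df = err_b$df),
    cbind(s_within[s_within$term %in% c("w", "b:w"), ],
          err_ss = err_w$ss, err_df = err_w$df))
  eff$ms <- eff$ss / eff$df
  eff$f <- eff$ms / (eff$err_ss / eff$err_df)
  # a degenerate stratum (all values equal): no variance to explain
  zero <- (eff$ss + eff$err_ss) <= 1e-20 * max(1, sum(d$y^2))
  eff$f[zero] <- 0
  eff$p <- stats::pf(eff$f, eff$df, eff$err_df, lower.tail = FALSE)
  eff$partial_eta_sq <- eff$ss / (eff$ss + eff$err_ss)
  eff$partial_eta_sq[zero] <- 0
  label <- c(b = between, w = within, `b:w` = paste(between, within,
                                                    sep = ":"))
  out <- tibble::tibble(
    effect = unname(label[eff$term]), ss = eff$ss, df = eff$df,
    err_df = eff$err_df, ms = eff$ms, f = eff$f, p = eff$p,
    partial_eta_sq = eff$partial_eta_sq)
  errors <- tibble::tibble(
    effect = c("error_between", "error_within"),
    ss = c(err_b$ss, err_w$ss), df = c(err_b$df, err_w$df),
    err_df = NA_real_, ms = c(err_b$ss / err_b$df, err_w$ss / err_w$df),
    f = NA_real_, p = NA_real_, partial_eta_sq = NA_real_)
  structure(dplyr::bind_rows(out, errors), class = c("anova_table",
                                                     "tbl_df", "tbl",
                                                     "data.frame"))
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, algebraically identical to
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (> 0).
#' @export
partial_eta_squared_from_f <- function(f, df1, df2) {
  if (any(df1 <= 0) || any(df2 <= 0)) {
    stop("partial_eta_squared_from_f: degrees of freedom must be positive",
         call. = FALSE)
  }
  if (any(f < 0)) {
    stop("partial_eta_squared_from_f: F must be >= 0", call. = FALSE)
  }
  f * df1 / (f * df1 + df2)
}

#' Bonferroni-corrected pairwise comparisons across within levels
#'
#' Paired t tests of each non-reference within level against the reference
#' level (default the lowest), with Bonferroni scaling of the p values
#' (`p_adj = min(1, m * p)` for `m` comparisons).
#'
#' @param cells Long tibble with `subject`, within-factor and value columns.
#' @param value,within,subject Column names, as in [mixed_anova()].
#' @param reference Reference within level; default the first sorted level.
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble: `contrast`, `mean_diff`, `t`, `df`, `p`, `p_bonferroni`,
#'   `significant`. Empty (with a message) if only one level is present.
#' @export
bonferroni_pairwise <- function(cells, value = "value", within = "within",
                                subject = "subject", reference = NULL,
                                alpha = 0.05) {
  w <- cells[[within]]
  levels_w <- sort(unique(w))
  if (length(levels_w) < 2L) {
    message("bonferroni_pairwise: fewer than two within levels")
    return(tibble::tibble(contrast = character(), mean_diff = numeric(),
                          t = numeric(), df = numeric(), p = numeric(),
                          p_bonferroni = numeric(),
                          significant = logical()))
  }
  if (is.null(reference)) reference <- levels_w[1L]
  others <- setdiff(levels_w, reference)
  m <- length(others)
  res <- lapply(others, function(lv) {
    a <- cells[w == reference, c(subject, value)]
    b <- cells[w == lv, c(subject, value)]
    j <- merge(a, b, by = subject)
    diffs <- j[[paste0(value, ".y")]] - j[[paste0(value, ".x")]]
    tt <- stats::t.test(diffs)
    tibble::tibble(contrast = paste(reference, "vs", lv),
                   mean_diff = mean(diffs),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
  out <- dplyr::bind_rows(res)
  out$p_bonferroni <- pmin(1, m * out$p)
  out$significant <- out$p_bonferroni < alpha
  out
}

#' Repetition x familiarity ANOVA for one outcome
#'
#' Convenience wrapper reproducing the paired analysis frame: a 2 x 2 mixed
#' ANOVA with familiarity (matched vs unmatched cohort) as the between
#' factor and pre-switch repetition (run length 1 vs `rep_level`) as the
#' within factor, computed on subject cell means from
#' [aggregate_post_switch()].
#'
#' @param cells Output of [aggregate_post_switch()] with a `design` column
#'   identifying the cohort of each subject.
#' @param outcome Outcome column name.
#' @param rep_level The higher repetition level contrasted with 1 (3 or 5).
#' @return An `anova_table`.
#' @export
repetition_anova <- function(cells, outcome = "mcom", rep_level = 3) {
  stopifnot(all(c("design", "run_length", "subject") %in% names(cells)))
  d <- cells[cells$run_length %in% c(1, rep_level), , drop = FALSE]
  d$value <- d[[outcome]]
  d$subject_uid <- paste(d$design, d$subject, sep = "/")
  mixed_anova(d, value = "value", between = "design", within = "run_length",
              subject = "subject_uid")
}
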