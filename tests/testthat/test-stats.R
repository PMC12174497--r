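test_that("first-post-switch aggregation yields one mean per subject and run length", {
  cohort <- simulate_cohort(4, schedule_spec("matched"),
                            time_series = FALSE, master_seed = 6L)
  cells <- aggregate_post_switch(truth_metrics(cohort$truth))
  expect_equal(nrow(cells), 4L * 3L)
  expect_true(all(cells$n_trials == 5L))
  expect_setequal(unique(cells$run_length), c(1L, 3L, 5L))
  # cell means equal direct averages of the contributing trials
  tm <- truth_metrics(cohort$truth)
  fp <- tm[tm$phase == "post_switch" & tm$position_in_run == 1L &
             !is.na(tm$run_length) & tm$subject == 2 &
             tm$run_length == 3L, ]
  expect_equal(cells$mcom[cells$subject == 2 & cells$run_length == 3L],
               mean(fp$mcom))
  expect_error(aggregate_post_switch(tm[0, ]), "empty")
})

test_that("mixed ANOVA sums of squares match the definitional textbook computation", {
  set.seed(31)
  d <- expand.grid(s = paste0("s", 1:4), w = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$b <- ifelse(d$s %in% c("s1", "s2"), "g1", "g2")
  d$y <- rnorm(nrow(d), mean = ifelse(d$w == "w2", 1, 0))
  tab <- mixed_anova(d, value = "y", between = "b", within = "w",
                     subject = "s")
  oracle <- bruteforce_mixed_ss(d)
  get <- function(eff, col) tab[[col]][tab$effect == eff]
  expect_equal(get("b", "ss"), oracle$ss_b, tolerance = 1e-10)
  expect_equal(get("w", "ss"), oracle$ss_w, tolerance = 1e-10)
  expect_equal(get("b:w", "ss"), oracle$ss_bw, tolerance = 1e-10)
  expect_equal(get("error_between", "ss"), oracle$ss_err_b,
               tolerance = 1e-10)
  expect_equal(get("error_within", "ss"), oracle$ss_err_w,
               tolerance = 1e-10)
  # F ratios follow from the same decomposition
  expect_equal(get("w", "f"),
               (oracle$ss_w / 1) / (oracle$ss_err_w / 2),
               tolerance = 1e-10)
})

test_that("partial eta squared from F agrees with the SS-ratio definition on fitted tables", {
  set.seed(13)
  d <- expand.grid(s = paste0("s", 1:10), w = c("lo", "hi"),
                   stringsAsFactors = FALSE)
  d$b <- ifelse(d$s %in% paste0("s", 1:5), "m", "u")
  d$y <- rnorm(nrow(d)) + (d$w == "hi") * 0.8
  tab <- mixed_anova(d, value = "y", between = "b", within = "w",
                     subject = "s")
  eff <- tab[!is.na(tab$f), ]
  expect_equal(eff$partial_eta_sq,
               partial_eta_squared_from_f(eff$f, eff$df, eff$err_df),
               tolerance = 1e-12)
})

test_that("degenerate and rescaled inputs behave as the F statistic demands", {
  d <- expand.grid(s = paste0("s", 1:6), w = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$b <- ifelse(d$s %in% paste0("s", 1:3), "g1", "g2")
  d$y <- 5
  tab <- mixed_anova(d, value = "y", between = "b", within = "w",
                     subject = "s")
  expect_equal(tab$f[tab$effect %in% c("b", "w", "b:w")], c(0, 0, 0),
               tolerance = 1e-12)

  set.seed(41)
  d$y <- rnorm(nrow(d), mean = (d$w == "w2") * 2)
  t1 <- mixed_anova(d, value = "y", between = "b", within = "w",
                    subject = "s")
  d2 <- d; d2$y <- d$y * 37.5
  t2 <- mixed_anova(d2, value = "y", between = "b", within = "w",
                    subject = "s")
  expect_equal(t1$f, t2$f, tolerance = 1e-10)
  expect_equal(t1$p, t2$p, tolerance = 1e-10)
  expect_equal(t1$partial_eta_sq, t2$partial_eta_sq, tolerance = 1e-10)
})

test_that("subjects missing a within level are excluded; tiny groups are an error", {
  d <- expand.grid(s = paste0("s", 1:6), w = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$b <- ifelse(d$s %in% paste0("s", 1:3), "g1", "g2")
  set.seed(2); d$y <- rnorm(nrow(d))
  d_miss <- d[!(d$s == "s1" & d$w == "w2"), ]
  expect_warning(tab <- mixed_anova(d_miss, value = "y", between = "b",
                                    within = "w", subject = "s"),
                 "dropping")
  expect_equal(tab$err_df[tab$effect == "w"], 3)  # 5 subjects - 2 groups
  d_tiny <- d[d$s %in% c("s1", "s4", "s5", "s6"), ]
  expect_error(mixed_anova(d_tiny, value = "y", between = "b",
                           within = "w", subject = "s"), ">= 2 subjects")
})

test_that("Bonferroni pairwise contrasts scale and cap the p values", {
  set.seed(77)
  cells <- expand.grid(subject = paste0("s", 1:12),
                       within = c(1, 3, 5), stringsAsFactors = FALSE)
  cells$value <- rnorm(nrow(cells)) + cells$within * 0.05
  res <- bonferroni_pairwise(cells)
  expect_equal(res$contrast, c("1 vs 3", "1 vs 5"))
  expect_equal(res$p_bonferroni, pmin(1, 2 * res$p))
  expect_true(all(res$p_bonferroni <= 1))

  # perfectly balanced subject differences: t = 0, p capped at exactly 1
  flat <- cells
  flat$value <- ifelse(flat$within == 1, 0,
                       rep(c(-1, 1), length.out = nrow(flat)))
  res_flat <- bonferroni_pairwise(flat)
  expect_equal(res_flat$p_bonferroni, c(1, 1))
  expect_false(any(res_flat$significant))

  single <- cells[cells$within == 1, ]
  expect_message(empty <- bonferroni_pairwise(single), "fewer than two")
  expect_equal(nrow(empty), 0L)
})

test_that("a planted repetition effect is detected by both Bonferroni contrasts in most cohorts", {
  hits <- vapply(1:200, function(i) {
    cells <- pooled_cells(10000L + i,
                          subject_sim_params(interference_slope_nmm = 25),
                          n_matched = 10L, n_unmatched = 10L,
                          outcomes = "mcom")
    cells$value <- cells$mcom
    cells$subject_uid <- paste(cells$design, cells$subject, sep = "/")
    pw <- bonferroni_pairwise(cells, value = "value",
                              within = "run_length",
                              subject = "subject_uid")
    all(pw$significant)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
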