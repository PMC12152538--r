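test_that("A/T classification honours strict cutoffs and missing values", {
  thr <- at_thresholds()
  st <- classify_at(
    abr = c(0.081, 0.082, 0.083, NA),
    ptau = c(41.7, 41.8, 41.9, NA), thr)
  expect_equal(st$a_status, c("A+", "A-", "A-", "missing"))
  expect_equal(st$t_status, c("T-", "T-", "T+", "missing"))
  expect_error(classify_at(-0.1, 10), "positive")
  expect_error(classify_at(0.1, -1), "non-negative")

  # group assignment covers the full A/T x cognition grid
  g <- assign_group(c("A+", "A+", "A-", "A-", "A-"),
                    c("T-", "T+", "T-", "T-", "T+"),
                    c("CI", "CU", "CU", "CI", "CU"))
  expect_equal(g, c("A_T_MINUS", "A_T_PLUS", "CONTROL", "OTHER_DEMENTIA",
                    "EXCLUDED_A_MINUS_T_PLUS"))
  expect_error(assign_group("missing", "T-", "CU"), "unresolved")
})

test_that("QC gating and session averaging follow the strict mean rule", {
  # two subjects x two sessions over two regions, one subcortical
  mk <- function(sid, sess, thal_qc, ctx_qc, thal_v, ctx_v) {
    tibble::tibble(subject_id = sid, session_id = paste0(sid, "_", sess),
                   group = "control", age = 70, sex = "female",
                   cognitive_status = "CU", abr = 0.09, ptau181 = 30,
                   icv = 1.5e6, lp_interval_years = 0,
                   vol_thalamus = thal_v, `vol_superior frontal` = ctx_v,
                   qc_thalamus = thal_qc, `qc_superior frontal` = ctx_qc)
  }
  sess <- dplyr::bind_rows(
    mk("S1", 1, 0.80, 0.10, 100, 200),   # kept: subcortical QC = 0.80
    mk("S1", 2, 0.60, 0.99, 300, 400),   # dropped: 0.60 <= 0.65
    mk("S2", 1, 0.65, 0.99, 500, 600),   # dropped: boundary is excluded
    mk("S2", 2, 0.66, 0.99, 700, 800),   # kept
    mk("S3", 1, 0.20, 0.99, 900, 999))   # subject fully dropped
  avg <- qc_filter_and_average(sess)
  expect_equal(avg$subject_id, c("S1", "S2"))
  expect_equal(avg$vol_thalamus, c(100, 700))
  log <- attr(avg, "drop_log")
  expect_equal(log$sessions_dropped, 3)
  expect_equal(log$subjects_dropped, 1)

  # multiple surviving sessions are averaged region-wise
  sess2 <- dplyr::bind_rows(
    mk("S1", 1, 0.9, 0.9, 100, 200),
    mk("S1", 2, 0.8, 0.8, 300, 400))
  avg2 <- qc_filter_and_average(sess2)
  expect_equal(avg2$vol_thalamus, 200)
  expect_equal(avg2$`vol_superior frontal`, 300)
  expect_equal(avg2$qc_thalamus, 0.85)
})

test_that("ICV adjustment sums merged inputs then divides by ICV", {
  tab <- tibble::tibble(
    subject_id = c("S1", "S2"), icv = c(2, 4),
    vol_left = c(10, 20), vol_right = c(30, 40), vol_solo = c(5, 6),
    qc_left = 0.9, qc_right = 0.9, qc_solo = 0.9)
  out <- icv_adjust_and_merge(
    tab, merge_map = list(both = c("left", "right"), solo = "solo"))
  expect_equal(out$vol_both, c((10 + 30) / 2, (20 + 40) / 4))
  expect_equal(out$vol_solo, c(5 / 2, 6 / 4))
  expect_false(any(c("vol_left", "vol_right", "qc_left") %in% names(out)))
  expect_error(icv_adjust_and_merge(
    tab, merge_map = list(a = "left", b = c("left", "right"))),
    "more than once")
  expect_error(icv_adjust_and_merge(
    tab, merge_map = list(a = "nope")), "missing from table")
  tab$icv[1] <- 0
  expect_error(icv_adjust_and_merge(tab), "icv must be positive")
})

test_that("inclusion rules and end-to-end preparation drop the right rows", {
  cfg <- generator_config(
    n_per_group = c("control" = 30, "A+T-" = 10, "A+T+" = 20,
                    "other_dementia" = 15),
    seed = 21L)
  raw <- generate_cohort(cfg)
  # force a few known violations
  raw$age[raw$subject_id == raw$subject_id[1]] <- 49
  raw$lp_interval_years[nrow(raw)] <- 1.5
  inc <- apply_inclusion(raw)
  expect_true(all(inc$age >= 50))
  expect_true(all(abs(inc$lp_interval_years) <= 1))
  log <- attr(inc, "drop_log")
  expect_gte(log$age_excluded, 1)
  expect_gte(log$interval_excluded, 1)

  prepped <- prepare_cohort(raw)
  expect_false("EXCLUDED_A_MINUS_T_PLUS" %in% prepped$at_group)
  expect_setequal(
    setdiff(unique(prepped$at_group), character(0)),
    c("CONTROL", "A_T_MINUS", "A_T_PLUS", "OTHER_DEMENTIA"))
  expect_equal(anyDuplicated(prepped$subject_id), 0)
  # ICV-adjusted volumes are dimensionless fractions well below 1
  expect_true(all(volume_matrix(prepped) < 1))
  expect_true(all(c("age_excluded", "sessions_dropped",
                    "a_minus_t_plus_excluded") %in%
                    names(attr(prepped, "drop_log"))))
})

test_that("demographic summary matches hand-computed pooled statistics", {
  tab <- tibble::tibble(
    at_group = rep(c("CONTROL", "A_T_PLUS"), c(4, 6)),
    age = c(rep(60, 4), rep(70, 6)),
    sex = rep(c("female", "male"), 5))
  dem <- summarize_demographics(tab)
  tot <- dem[dem$group == "Total", ]
  expect_equal(tot$n, 10)
  expect_equal(tot$age_mean, (4 * 60 + 6 * 70) / 10)
  expect_equal(tot$pct_female, 50)
  expect_equal(dem$pct[dem$group == "CONTROL"], 40)
  expect_equal(pooled_mean(c(60, 70), c(4, 6)), 66)
  expect_true(is.na(pooled_mean(numeric(0), numeric(0))))
})
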