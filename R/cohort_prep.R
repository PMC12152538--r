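#' A/T classification thresholds and inclusion rules
#'
#' @param abr_cutoff Abeta42/40 ratio cutoff; values strictly below indicate
#'   amyloid positivity (A+).
#' @param ptau_cutoff p-Tau181 cutoff in pg/mL; values strictly above
#'   indicate tau positivity (T+).
#' @param qc_cutoff Mean subcortical QC must exceed this for a session to be
#'   used.
#' @param age_min Minimum age in years for inclusion.
#' @param lp_window Maximum absolute MRI-to-lumbar-puncture interval (years).
#' @return List of class `morphocov_thresholds`.
#' @export
at_thresholds <- function(abr_cutoff = 0.082, ptau_cutoff = 41.8,
                          qc_cutoff = 0.65, age_min = 50, lp_window = 1) {
  stopifnot(abr_cutoff > 0, abr_cutoff < 1, ptau_cutoff > 0,
            qc_cutoff > 0, age_min > 0, lp_window > 0)
  structure(list(abr_cutoff = abr_cutoff, ptau_cutoff = ptau_cutoff,
                 qc_cutoff = qc_cutoff, age_min = age_min,
                 lp_window = lp_window),
            class = "morphocov_thresholds")
}

#' Classify amyloid and tau status from CSF biomarkers
#'
#' A+ iff `abr < abr_cutoff` (boundary value is A-); T+ iff
#' `ptau > ptau_cutoff` (boundary value is T-). Missing values yield an
#' explicit `"missing"` status.
#'
#' @param abr Abeta42/40 ratio (dimensionless, > 0).
#' @param ptau p-Tau181 concentration (pg/mL, >= 0).
#' @param thresholds [at_thresholds()].
#' @return Data frame with columns `a_status` and `t_status`, each in
#'   `{"A+", "A-", "missing"}` / `{"T+", "T-", "missing"}`.
#' @export
classify_at <- function(abr, ptau, thresholds = at_thresholds()) {
  if (any(!is.na(abr) & abr <= 0)) stop("abr must be positive")
  if (any(!is.na(ptau) & ptau < 0)) stop("ptau must be non-negative")
  a <- ifelse(is.na(abr), "missing",
              ifelse(abr < thresholds$abr_cutoff, "A+", "A-"))
  t <- ifelse(is.na(ptau), "missing",
              ifelse(ptau > thresholds$ptau_cutoff, "T+", "T-"))
  data.frame(a_status = a, t_status = t)
}

#' Assign a CSF biomarker group label
#'
#' A-T- with unimpaired cognition is the control group; A-T- with cognitive
#' impairment is the non-AD ("other dementia") group; A+T- and A+T+ are
#' labelled regardless of cognition; A-T+ is excluded.
#'
#' @param a_status `"A+"`/`"A-"` vector.
#' @param t_status `"T+"`/`"T-"` vector.
#' @param cognitive_status `"CU"` (unimpaired) or `"CI"` (impaired).
#' @return Character vector with levels `CONTROL`, `A_T_MINUS`, `A_T_PLUS`,
#'   `OTHER_DEMENTIA`, `EXCLUDED_A_MINUS_T_PLUS`.
#' @export
assign_group <- function(a_status, t_status, cognitive_status) {
  bad <- !(a_status %in% c("A+", "A-")) | !(t_status %in% c("T+", "T-"))
  if (any(bad)) {
    stop("unresolved A/T status at position(s): ",
         paste(which(bad), collapse = ", "))
  }
  out <- rep(NA_character_, length(a_status))
  out[a_status == "A+" & t_status == "T-"] <- "A_T_MINUS"
  out[a_status == "A+" & t_status == "T+"] <- "A_T_PLUS"
  out[a_status == "A-" & t_status == "T+"] <- "EXCLUDED_A_MINUS_T_PLUS"
  neg <- a_status == "A-" & t_status == "T-"
  out[neg & cognitive_status == "CU"] <- "CONTROL"
  out[neg & cognitive_status == "CI"] <- "OTHER_DEMENTIA"
  if (anyNA(out)) {
    stop("could not assign group at position(s): ",
         paste(which(is.na(out)), collapse = ", "))
  }
  out
}

#' Drop low-QC sessions and average the rest per subject
#'
#' A session is retained when the mean of its subcortical QC scores is
#' strictly above `qc_cutoff`. Surviving sessions of a subject are averaged
#' region-wise (volumes and QC scores); non-numeric covariates are taken
#' from the subject's first surviving session. Subjects with no surviving
#' session are dropped; counts are recorded in the `"drop_log"` attribute.
#'
#' @param sessions Cohort tibble, one row per session.
#' @param thresholds [at_thresholds()].
#' @param subcortical Regions whose QC scores gate a session.
#' @return Cohort tibble, one row per subject, with a `drop_log` attribute
#'   (`sessions_dropped`, `subjects_dropped`).
#' @export
qc_filter_and_average <- function(sessions, thresholds = at_thresholds(),
                                  subcortical = NULL) {
  vcols <- grep("^vol_", names(sessions), value = TRUE)
  qcols <- grep("^qc_", names(sessions), value = TRUE)
  regions <- sub("^vol_", "", vcols)
  if (is.null(subcortical)) subcortical <- subcortical_regions(regions)
  sc_q <- paste0("qc_", intersect(subcortical, regions))
  if (length(sc_q) == 0) stop("no subcortical QC columns found")
  qc_mean <- rowMeans(as.matrix(sessions[, sc_q]))
  keep <- qc_mean > thresholds$qc_cutoff
  n_sessions_dropped <- sum(!keep)
  kept <- sessions[keep, , drop = FALSE]
  all_subjects <- unique(sessions$subject_id)
  n_subjects_dropped <- length(setdiff(all_subjects, kept$subject_id))
  num_cols <- c(vcols, qcols)
  other <- setdiff(names(kept), c(num_cols, "session_id"))
  averaged <- kept |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(setdiff(other, "subject_id")), dplyr::first),
      dplyr::across(dplyr::all_of(num_cols), mean),
      .groups = "drop"
    )
  # keep the original subject order
  averaged <- averaged[order(match(averaged$subject_id, all_subjects)), ]
  attr(averaged, "drop_log") <- list(sessions_dropped = n_sessions_dropped,
                                     subjects_dropped = n_subjects_dropped)
  averaged
}

#' Default merge map: identity over a region set
#'
#' @param regions Character vector of output regions.
#' @return Named list output region -> input regions.
#' @export
identity_merge_map <- function(regions = default_region_names()) {
  setNames(as.list(regions), regions)
}

#' Merge regions and normalise by intracranial volume
#'
#' Each output region's volume is the SUM of its input regions' volumes
#' (so bilateral merging conserves total structure volume), divided by the
#' subject's ICV. The output table carries exactly the merge map's output
#' regions as `vol_<region>` columns (now dimensionless ICV fractions); QC
#' columns for consumed inputs are dropped.
#'
#' @param table Cohort tibble, one row per subject.
#' @param merge_map Named list output region -> character vector of input
#'   regions; every input must exist in `table` and be consumed at most once.
#' @return Cohort tibble with ICV-adjusted merged volumes.
#' @export
icv_adjust_and_merge <- function(table,
                                 merge_map = identity_merge_map(
                                   sub("^vol_", "",
                                       grep("^vol_", names(table),
                                            value = TRUE)))) {
  if (any(table$icv <= 0)) stop("icv must be positive for all rows")
  inputs <- unlist(merge_map, use.names = FALSE)
  if (anyDuplicated(inputs)) {
    stop("merge_map consumes region(s) more than once: ",
         paste(unique(inputs[duplicated(inputs)]), collapse = ", "))
  }
  missing <- setdiff(inputs, sub("^vol_", "",
                                 grep("^vol_", names(table), value = TRUE)))
  if (length(missing) > 0) {
    stop("merge_map region(s) missing from table: ",
         paste(missing, collapse = ", "))
  }
  vols <- volume_matrix(table)
  merged <- sapply(merge_map, function(src) {
    rowSums(vols[, src, drop = FALSE])
  })
  if (is.null(dim(merged))) merged <- matrix(merged, nrow = nrow(table))
  merged <- merged / table$icv
  colnames(merged) <- paste0("vol_", names(merge_map))
  keep <- !grepl("^vol_", names(table)) &
    !(names(table) %in% paste0("qc_", inputs))
  dplyr::bind_cols(table[, keep, drop = FALSE], tibble::as_tibble(merged))
}

#' Apply age and MRI-to-lumbar-puncture inclusion rules
#'
#' Rows with `age < age_min` or `|lp_interval_years| > lp_window` (when that
#' column is present) are removed; removal counts are recorded in the
#' `"drop_log"` attribute.
#'
#' @param table Cohort tibble.
#' @param thresholds [at_thresholds()].
#' @return Filtered tibble with `drop_log` attribute
#'   (`age_excluded`, `interval_excluded`).
#' @export
apply_inclusion <- function(table, thresholds = at_thresholds()) {
  age_ok <- table$age >= thresholds$age_min
  if ("lp_interval_years" %in% names(table)) {
    int_ok <- abs(table$lp_interval_years) <= thresholds$lp_window
  } else {
    int_ok <- rep(TRUE, nrow(table))
  }
  out <- table[age_ok & int_ok, , drop = FALSE]
  attr(out, "drop_log") <- list(age_excluded = sum(!age_ok),
                                interval_excluded = sum(age_ok & !int_ok))
  out
}

#' Prepare a session-level cohort end to end
#'
#' Convenience wrapper: inclusion filters, QC filtering and session
#' averaging, ICV adjustment with merging, and A/T group assignment (with
#' A-T+ rows removed).
#'
#' @param sessions Session-level cohort tibble.
#' @param thresholds [at_thresholds()].
#' @param merge_map Merge map for [icv_adjust_and_merge()].
#' @return Subject-level tibble with ICV-adjusted volumes and an
#'   `at_group` column; excluded A-T+ subjects are dropped (count in the
#'   `drop_log` attribute).
#' @export
prepare_cohort <- function(sessions, thresholds = at_thresholds(),
                           merge_map = NULL) {
  inc <- apply_inclusion(sessions, thresholds)
  avg <- qc_filter_and_average(inc, thresholds)
  if (is.null(merge_map)) {
    merge_map <- identity_merge_map(
      sub("^vol_", "", grep("^vol_", names(avg), value = TRUE)))
  }
  adj <- icv_adjust_and_merge(avg, merge_map)
  st <- classify_at(adj$abr, adj$ptau181, thresholds)
  adj$at_group <- assign_group(st$a_status, st$t_status,
                               adj$cognitive_status)
  excluded <- adj$at_group == "EXCLUDED_A_MINUS_T_PLUS"
  out <- adj[!excluded, , drop = FALSE]
  attr(out, "drop_log") <- c(attr(inc, "drop_log"), attr(avg, "drop_log"),
                             list(a_minus_t_plus_excluded = sum(excluded)))
  out
}

#' Size-weighted pooled mean
#'
#' @param means Group means.
#' @param n Group sizes.
#' @return Weighted mean; NA if total size is zero.
#' @export
pooled_mean <- function(means, n) {
  if (sum(n) == 0) return(NA_real_)
  sum(means * n) / sum(n)
}

#' Per-group and pooled demographic summary
#'
#' @param table Subject-level cohort tibble with `at_group`, `age`, `sex`.
#' @param group_col Name of the group column.
#' @return Tibble with one row per group plus a `Total` row: `n`, `pct`,
#'   `age_mean`, `age_sd`, `n_female`, `pct_female`. The pooled mean age
#'   equals the size-weighted average of the group means.
#' @export
summarize_demographics <- function(table, group_col = "at_group") {
  g <- table[[group_col]]
  groups <- unique(g)
  total_n <- nrow(table)
  per <- lapply(groups, function(gr) {
    sub <- table[g == gr, , drop = FALSE]
    tibble::tibble(
      group = gr, n = nrow(sub), pct = 100 * nrow(sub) / total_n,
      age_mean = if (nrow(sub)) mean(sub$age) else NA_real_,
      age_sd = if (nrow(sub) > 1) sd(sub$age) else NA_real_,
      n_female = sum(sub$sex == "female"),
      pct_female = if (nrow(sub)) 100 * mean(sub$sex == "female") else
        NA_real_
    )
  })
  per <- dplyr::bind_rows(per)
  tot <- tibble::tibble(
    group = "Total", n = total_n, pct = 100,
    age_mean = pooled_mean(per$age_mean, per$n),
    age_sd = if (total_n > 1) sd(table$age) else NA_real_,
    n_female = sum(per$n_female),
    pct_female = 100 * sum(per$n_female) / total_n
  )
  dplyr::bind_rows(per, tot)
}
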