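#' Run the full validity study end-to-end
#'
#' Simulates (or accepts) a paired cohort, processes both sensor branches of
#' every recording, segments repetitions, computes the per-task outcomes,
#' and runs the complete statistical analysis: the 15-row agreement report,
#' between-task comparisons of every outcome family for each sensor, and
#' between-sex comparisons on the smartphone outcomes. Deterministic given
#' the config seed.
#'
#' @param config a [sim_config()], or an existing `pelvic_cohort`.
#' @param seg_params a [segmentation_params()].
#' @param alpha significance level for all gates and tests.
#' @param drift_threshold heading-drift QC threshold, deg.
#' @param mode `"permissive"` (flag anomalies and continue, as the reference
#'   protocol did by excluding flagged recordings) or `"strict"` (any flag is
#'   an error).
#' @return an object of class `pelvic_study`: list with `$outcomes` (long
#'   per-task table, both sources), `$agreement` (the report),
#'   `$task_comparisons` (per source x outcome family), `$sex_comparisons`
#'   (smartphone, per outcome family x task), `$qc` (drift and count flags),
#'   `$config`, `$config_hash`.
#' @export
run_study <- function(config, seg_params = segmentation_params(),
                      alpha = 0.05, drift_threshold = 5,
                      mode = c("permissive", "strict")) {
  mode <- match.arg(mode)
  cohort <- if (inherits(config, "pelvic_cohort")) config else simulate_cohort(config)
  config <- cohort$config
  rows <- list()
  qc <- list()
  for (id in names(cohort$records)) {
    rec <- cohort$records[[id]]
    for (source in c("mocap", "phone")) {
      kin <- if (source == "mocap") process_mocap(rec$markers) else
        process_phone(rec$phone)
      drift_fail <- FALSE
      if (source == "phone") {
        qcd <- qc_heading_drift(kin, pre_window = c(0, config$quiet_duration - 1),
                                threshold_deg = drift_threshold)
        drift_fail <- identical(qcd$status, "fail")
        if (drift_fail && mode == "strict")
          stop(sprintf("%s: heading drift %.1f deg exceeds %.1f deg",
                       id, qcd$drift, drift_threshold))
      }
      marks <- segment_recording(kin, expected_reps = config$reps_per_task,
                                 params = seg_params,
                                 quiet_duration = config$quiet_duration,
                                 mode = mode)
      if (nrow(marks$reps) < 1L) {
        # unusable recording (e.g. squat too shallow for this branch's
        # displacement estimate): flag and exclude, as the protocol excluded
        # unusable recordings, rather than abort the whole study
        if (mode == "strict")
          stop(sprintf("%s (%s): no repetitions detected", id, source))
      } else {
        rep_out <- repetition_outcomes(kin, marks, mode = "permissive")
        rows[[paste(id, source, sep = "_")]] <-
          summarize_task(rep_out, rec$participant, rec$task, source,
                         drift_fail = drift_fail,
                         count_mismatch = isTRUE(marks$count_mismatch))
      }
      qc[[paste(id, source, sep = "_")]] <- data.frame(
        record = id, source = source, drift_fail = drift_fail,
        detected_reps = nrow(marks$reps),
        expected_reps = config$reps_per_task)
    }
  }
  outcomes <- do.call(rbind, rows)
  rownames(outcomes) <- NULL
  qc <- do.call(rbind, qc)
  rownames(qc) <- NULL

  agreement <- build_agreement_report(outcomes, alpha = alpha)

  sexes <- vapply(cohort$records, `[[`, "", "sex")
  sex_of <- sexes[!duplicated(vapply(cohort$records, `[[`, "", "participant"))]
  names(sex_of) <- vapply(cohort$records[!duplicated(
    vapply(cohort$records, `[[`, "", "participant"))], `[[`, "", "participant")

  task_comparisons <- list()
  sex_comparisons <- list()
  for (source in c("mocap", "phone")) {
    for (fam in outcome_families) {
      sub <- outcomes[outcomes$source == source, ]
      if (fam == "transverse") {
        bad <- unique(sub$participant[sub$drift_fail])
        sub <- sub[!sub$participant %in% bad, ]
      }
      long <- data.frame(participant = sub$participant, task = sub$task,
                         value = sub[[fam]])
      key <- paste(source, fam, sep = ".")
      task_comparisons[[key]] <- tryCatch(
        compare_tasks(long, alpha = alpha),
        error = function(e) list(test = "not-computable",
                                 reason = conditionMessage(e)))
    }
  }
  ph <- outcomes[outcomes$source == "phone", ]
  if (length(unique(sex_of)) == 2L) {
    for (fam in outcome_families) {
      for (task in unique(ph$task)) {
        sub <- ph[ph$task == task, ]
        key <- paste(fam, task, sep = ".")
        sex_comparisons[[key]] <- tryCatch(
          compare_groups(sub[[fam]], sex_of[as.character(sub$participant)],
                         alpha = alpha),
          error = function(e) list(test = "not-computable",
                                   reason = conditionMessage(e)))
      }
    }
  }

  study <- list(outcomes = outcomes, agreement = agreement,
                task_comparisons = task_comparisons,
                sex_comparisons = sex_comparisons, qc = qc,
                config = config, config_hash = config_hash(config))
  class(study) <- "pelvic_study"
  study
}

# Stable hash of the configuration (seed included), stamped on every output
# table so a run is traceable to its exact parameters.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(config[order(names(config))]), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.pelvic_study <- function(x, ...) {
  cat(sprintf("<pelvic_study> %d participants, %d outcome rows, config %s\n",
              x$config$n_participants, nrow(x$outcomes),
              substr(x$config_hash, 1, 8)))
  print(x$agreement)
  invisible(x)
}

#' Write all study outputs to a directory
#'
#' CSV tables (per-task outcomes, agreement report, QC log) and a JSON
#' bundle of the comparison tests, each stamped with the config hash.
#'
#' @param study a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "pelvic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(df) { df$config_hash <- study$config_hash; df }
  utils::write.csv(stamp(study$outcomes), file.path(dir, "task_outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(stamp(as.data.frame(study$agreement)),
                   file.path(dir, "agreement_report.csv"), row.names = FALSE)
  utils::write.csv(stamp(study$qc), file.path(dir, "qc_log.csv"),
                   row.names = FALSE)
  comp <- lapply(study$task_comparisons, function(tc) {
    if (is.null(tc)) return(NULL)
    unclass(tc)
  })
  jsonlite::write_json(list(config_hash = study$config_hash,
                            task_comparisons = comp,
                            sex_comparisons = study$sex_comparisons),
                       file.path(dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
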