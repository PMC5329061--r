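# Demographic roster of the 45-subject reference cohort (15 healthy
# controls, 15 amnestic MCI, 15 mild AD) around which the pipeline's
# matched-design checks are calibrated. Groups were matched on age and
# education; a pooled two-tailed t-test on this roster shows no
# significant group differences.

#' Reference cohort demographics
#'
#' The demographic roster (group, age in years, education in years, sex)
#' of the 45-subject AD/MCI/control reference cohort. Used to validate
#' [group_summary()] and [two_sample_t_test()] and to parameterize the
#' synthetic generator's demographic laws.
#'
#' @return Data frame with columns `subject_id`, `group`, `age`,
#'   `education`, `sex` (45 rows).
#' @export
study_demographics <- function() {
  ct <- data.frame(
    subject_id = sprintf("%02d", 1:15), group = "CT",
    age = c(85, 81, 76, 74, 74, 78, 74, 83, 62, 67, 77, 78, 72, 61, 77),
    education = c(11, 8, 17, 11, 4, 11, 15, 15, 11, 11, 8, 11, 11, 21, 15),
    sex = c("F", "F", "F", "F", "F", "F", "M", "M", "F", "F", "F", "F",
            "F", "M", "M")
  )
  mci <- data.frame(
    subject_id = sprintf("%02d", 16:30), group = "MCI",
    age = c(80, 81, 68, 73, 88, 84, 70, 67, 71, 71, 80, 77, 70, 66, 69),
    education = c(8, 4, 15, 15, 8, 11, 20, 4, 11, 20, 14, 8, 15, 15, 11),
    sex = c("F", "F", "F", "M", "M", "F", "M", "M", "F", "F", "F", "F",
            "M", "F", "F")
  )
  ad <- data.frame(
    subject_id = sprintf("%02d", 31:45), group = "AD",
    age = c(74, 73, 77, 68, 68, 71, 74, 84, 75, 86, 73, 80, 61, 72, 81),
    education = c(8, 15, 4, 15, 15, 11, 20, 11, 11, 15, 11, 15, 4, 15, 11),
    sex = c("F", "F", "F", "F", "M", "F", "M", "M", "M", "F", "F", "M",
            "M", "F", "F")
  )
  rbind(ct, mci, ad)
}
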