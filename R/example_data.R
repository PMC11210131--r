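#' Example clinical cohort table
#'
#' A per-patient clinical table for a pediatric B-cell precursor acute
#' lymphoblastic leukemia cohort: 30 newly diagnosed patients (21 male, 9
#' female; molecular abnormalities including t(12;21) in 6, t(9;22) in 3,
#' KMT2A rearrangement in 3; aneuploidy in 9) and 10 relapsed patients (8
#' male; ages at relapse 6, 23, 5, 15, 15, 14, 20, 6, 7 and 6 years). Counts
#' follow the published cohort summary of the study this package models;
#' per-patient rows not individually published are filled in consistently
#' with those marginal counts.
#'
#' @return data.frame with columns `patient`, `group` (newly_diagnosed /
#'   relapsed), `sex` (M/F), `age_at_relapse` (years; NA for newly
#'   diagnosed), `abnormality`, `aneuploidy`.
#' @seealso [summarize_cohort()]
#' @export
example_cohort_table <- function() {
  nd_abn <- c(rep("none", 15), rep("t(12;21)", 6), rep("t(9;22)", 3),
              rep("r(KMT2A)", 3), "t(9;11)", "t(3;9)", "t(5;11)")
  nd <- data.frame(
    patient = sprintf("ND_%02d", 1:30),
    group = "newly_diagnosed",
    sex = c(rep("M", 21), rep("F", 9)),
    age_at_relapse = NA_real_,
    abnormality = nd_abn,
    aneuploidy = c(rep("yes", 9), rep("no", 21)),
    stringsAsFactors = FALSE)
  rl <- data.frame(
    patient = sprintf("RL_%02d", 1:10),
    group = "relapsed",
    sex = c(rep("M", 8), rep("F", 2)),
    age_at_relapse = c(6, 23, 5, 15, 15, 14, 20, 6, 7, 6),
    abnormality = c(rep("none", 5), rep("t(12;21)", 2), "t(9;22)",
                    "r(KMT2A)", "t(8;14)"),
    aneuploidy = c(rep("yes", 3), rep("no", 7)),
    stringsAsFactors = FALSE)
  rbind(nd, rl)
}
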