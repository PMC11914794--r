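#' Convert raw spot counts to SFC per million PBMC
#'
#' @param raw_count Raw spot-forming-cell count(s).
#' @param cells_per_well PBMC plated per well (must be positive). At the
#'   standard plating density of 100,000 cells/well this multiplies by 10.
#' @return SFC per 10^6 PBMC.
#' @export
sfc_per_million <- function(raw_count, cells_per_well) {
  if (any(cells_per_well <= 0)) abort("cells_per_well must be > 0")
  raw_count * (1e6 / cells_per_well)
}

#' Average replicate wells of one condition
#'
#' @param wells Plate wells sharing one `(patient_id, stimulus, cytokine)`
#'   condition (duplicates or triplicates).
#' @return Arithmetic mean of the raw spot counts.
#' @export
summarize_condition <- function(wells) {
  if (nrow(wells) == 0) abort("summarize_condition() needs at least one well")
  key <- unique(wells[c("patient_id", "stimulus", "cytokine")])
  if (nrow(key) > 1) {
    abort("summarize_condition() got wells from more than one condition")
  }
  mean(wells$spot_count)
}

#' Call positivity for one stimulation
#'
#' Subtracts the matched negative-control background from a stimulation's
#' SFC value and calls it positive when the net value strictly exceeds the
#' threshold (net values of exactly the threshold are negative). Negative
#' nets are reported as computed, not clipped.
#'
#' @param stim_sfc Stimulation SFC per 10^6 PBMC.
#' @param background_sfc Matched negative-control SFC per 10^6 PBMC.
#' @param threshold Positivity cutoff in SFC per 10^6 PBMC (default 100).
#' @return One-row tibble with `net_sfc` and `positive`.
#' @export
call_positive <- function(stim_sfc, background_sfc, threshold = 100) {
  if (is.na(background_sfc)) {
    abort("missing negative-control background for positivity call")
  }
  net <- stim_sfc - background_sfc
  tibble(net_sfc = net, positive = net > threshold)
}

#' Analyze an ELISpot/Fluorospot plate table
#'
#' Full screen analysis: replicate wells are averaged per condition,
#' converted to SFC per 10^6 PBMC, background-subtracted against the pooled
#' mean of the negative-control conditions (culture media and DMSO) of the
#' same patient and cytokine, and called positive when the net value
#' strictly exceeds the threshold. PHA positive-control wells are excluded
#' from calling but validated: a patient/cytokine whose PHA net does not
#' exceed the threshold is flagged `QC-warn` on every row (data are kept).
#'
#' @param wells Plate-well tibble (see [read_plate_csv()]).
#' @param threshold Positivity cutoff (default 100 SFC/10^6 PBMC, strict).
#' @param negative_controls Stimulus labels pooled into the background.
#' @param positive_control Stimulus label of the PHA wells.
#' @return A tibble of screen calls, one row per
#'   `(patient_id, stimulus, cytokine)`: `mean_raw_spots`, `sfc_per_million`,
#'   `background_sfc`, `net_sfc`, `positive` (NA for control stimuli),
#'   `qc_flag`.
#' @export
call_screen <- function(wells, threshold = 100,
                        negative_controls = c("DMSO", "media"),
                        positive_control = "PHA") {
  wells <- validate_plate_wells(wells)
  cond <- wells %>%
    group_by(.data$patient_id, .data$stimulus, .data$cytokine) %>%
    summarise(
      mean_raw_spots = mean(.data$spot_count),
      sfc_per_million = mean(sfc_per_million(.data$spot_count, .data$cells_per_well)),
      .groups = "drop"
    )
  bg <- cond %>%
    filter(.data$stimulus %in% negative_controls) %>%
    group_by(.data$patient_id, .data$cytokine) %>%
    summarise(background_sfc = mean(.data$sfc_per_million), .groups = "drop")
  tested <- filter(cond, !.data$stimulus %in% negative_controls)
  if (nrow(tested) > 0) {
    out <- left_join(cond, bg, by = c("patient_id", "cytokine"))
    if (anyNA(out$background_sfc[!out$stimulus %in% negative_controls])) {
      miss <- unique(out$patient_id[is.na(out$background_sfc)])
      abort(paste0("missing negative control (", paste(negative_controls, collapse = "/"),
                   ") for patient(s): ", paste(miss, collapse = ", ")))
    }
  } else {
    out <- left_join(cond, bg, by = c("patient_id", "cytokine"))
  }
  out <- mutate(
    out,
    net_sfc = .data$sfc_per_million - .data$background_sfc,
    positive = dplyr::if_else(
      .data$stimulus %in% c(negative_controls, positive_control),
      NA, .data$net_sfc > threshold
    )
  )
  pha <- out %>%
    filter(.data$stimulus == positive_control) %>%
    mutate(pha_ok = .data$net_sfc > threshold) %>%
    select("patient_id", "cytokine", "pha_ok")
  out <- left_join(out, pha, by = c("patient_id", "cytokine"))
  out$qc_flag <- dplyr::case_when(
    is.na(out$pha_ok) ~ "no-PHA",
    out$pha_ok ~ "ok",
    .default = "QC-warn"
  )
  select(out, -"pha_ok")
}

#' Summarize screen calls per pool
#'
#' Counts positive and negative calls per pool and cytokine, as in a
#' cohort-level response summary table: `percent_positive` is the number of
#' positive responses divided by the number of times the pool was tested.
#'
#' @param calls Screen calls (see [call_screen()]), deduplicated per
#'   `(patient_id, stimulus, cytokine)`.
#' @param pool_labels Stimulus labels that are pools (rows of the summary).
#' @return A tibble per pool and cytokine: `n_tested`, `n_positive`,
#'   `n_negative`, `percent_positive`.
#' @export
summarize_cohort <- function(calls, pool_labels) {
  calls %>%
    filter(.data$stimulus %in% pool_labels, !is.na(.data$positive)) %>%
    group_by(pool = .data$stimulus, .data$cytokine) %>%
    summarise(
      n_tested = n(),
      n_positive = sum(.data$positive),
      n_negative = sum(!.data$positive),
      percent_positive = 100 * .data$n_positive / .data$n_tested,
      .groups = "drop"
    )
}

#' Deconvolute a positive pool response
#'
#' Given a positive pool call and the individual per-variant re-stimulation
#' calls of the same patient and cytokine, lists the variants whose own call
#' is positive. An empty result is a valid outcome: a pool can respond
#' without any single member crossing the threshold on its own.
#'
#' @param pool_call One-row screen call for the pool (`positive` must be
#'   TRUE).
#' @param variant_calls Screen calls for the individual variant stimuli of
#'   the same patient and cytokine.
#' @return The positive rows of `variant_calls`.
#' @export
deconvolute <- function(pool_call, variant_calls) {
  if (nrow(pool_call) != 1 || !isTRUE(pool_call$positive)) {
    abort("deconvolute() expects a single positive pool call")
  }
  same <- variant_calls$patient_id == pool_call$patient_id &
    variant_calls$cytokine == pool_call$cytokine
  if (!all(same)) {
    abort("variant calls must share the pool call's patient and cytokine")
  }
  filter(variant_calls, .data$positive)
}
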