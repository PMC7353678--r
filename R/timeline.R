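#' Titration adjustment for the first fill
#'
#' The first fill of the titrated antifibrotic (pirfenidone role) receives an
#' extra 7 days' supply, because patients following the recommended titration
#' schedule stretch a standard fill over the first five weeks — unless the
#' fill is already the titration pack (207 pills for 30 days), which is
#' dispensed exactly as labelled. Fills of the other drug are never adjusted.
#'
#' @param days_supply,quantity,drug Vectors describing first fills.
#' @param titration_drug Name of the drug the rule applies to.
#' @return Adjusted days' supply (integer vector).
#' @export
#' @examples
#' adjust_titration(30, 90, "pirfenidone")   # 37
#' adjust_titration(30, 207, "pirfenidone")  # 30
#' adjust_titration(30, 60, "nintedanib")    # 30
adjust_titration <- function(days_supply, quantity, drug,
                             titration_drug = "pirfenidone") {
  as.integer(ifelse(drug == titration_drug &
                      !(quantity == 207 & days_supply == 30),
                    days_supply + 7L, days_supply))
}

#' Build a medication coverage timeline from fills
#'
#' Fills are sorted by service date; same-day fills have their supplies
#' summed. A fill starting on or before the current coverage end has its full
#' supply appended starting the day after coverage ends (overlap appending —
#' no supply is lost to early refills); a fill starting later opens a new
#' interval at its own date. A fill on day `d` with supply `s` covers days
#' `[d, d + s - 1]` inclusive.
#'
#' @param dates Integer day offsets of fills (any order).
#' @param days_supply Adjusted days' supply per fill (>= 1).
#' @return A tibble of disjoint, sorted covered intervals with columns
#'   `start` and `end` (inclusive), class `coverage_timeline`.
#' @export
#' @examples
#' build_timeline(c(0, 20), c(30, 30))  # one interval [0, 59]
build_timeline <- function(dates, days_supply) {
  if (length(dates) == 0L) {
    out <- tibble(start = integer(), end = integer())
    class(out) <- c("coverage_timeline", class(out))
    return(out)
  }
  if (any(days_supply < 1)) abort("days_supply must be >= 1")
  o <- order(dates)
  dates <- as.integer(dates[o])
  supply <- as.integer(days_supply[o])
  agg <- rowsum(supply, dates)
  s <- as.integer(rownames(agg))
  d <- as.integer(agg[, 1])
  cum <- cumsum(d)
  e <- cum + cummax(s - c(0L, cum[-length(cum)])) - 1L
  prev_e <- c(-1L, e[-length(e)])
  new_int <- s > prev_e + 1L
  grp <- cumsum(new_int)
  out <- tibble(start = s, end = e, grp = grp) |>
    group_by(.data$grp) |>
    summarise(start = first(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("start", "end")
  class(out) <- c("coverage_timeline", class(out))
  out
}

#' Proportion of days covered over a follow-up window
#'
#' Covered days within the inclusive window `[window_start, window_end]`
#' divided by the window length in days (both endpoints counted), truncated
#' at 1.0: supply appended beyond the window never pushes PDC above 1.
#'
#' @param timeline A [build_timeline()] result.
#' @param window_start,window_end Integer day offsets, `window_end >=
#'   window_start`.
#' @return PDC in `[0, 1]`.
#' @export
compute_pdc <- function(timeline, window_start, window_end) {
  if (window_end < window_start) {
    abort("zero-length follow-up window: window_end < window_start")
  }
  covered <- sum(pmax(0L, pmin(timeline$end, window_end) -
                        pmax(timeline$start, window_start) + 1L))
  min(covered / (window_end - window_start + 1), 1.0)
}

#' Adherence classification from PDC
#'
#' @param pdc PDC values in `[0, 1]`.
#' @param threshold Adherence threshold (default 0.8).
#' @param rule `"gt"` (strictly greater, the default) or `"ge"`.
#' @return Logical vector.
#' @export
classify_adherent <- function(pdc, threshold = 0.8, rule = c("gt", "ge")) {
  rule <- match.arg(rule)
  if (rule == "gt") pdc > threshold else pdc >= threshold
}

#' Detect treatment discontinuation from a coverage timeline
#'
#' Discontinuation is a gap of at least `gap_days` uncovered days, either
#' strictly between two covered intervals or running from the end of coverage
#' to the follow-up end with at least `gap_days` uncovered days elapsed. The
#' discontinuation date is the last covered day before the first qualifying
#' gap. A lung transplant before the gap's `gap_days`-th uncovered day (i.e.
#' `transplant_date < discontinuation_date + gap_days`) cancels the
#' discontinuation.
#'
#' @param timeline A [build_timeline()] result.
#' @param follow_up_end Integer day offset of the end of follow-up.
#' @param transplant_date Integer day offset of a lung transplant, or `NULL`.
#' @param gap_days Minimum qualifying gap (default 60).
#' @return The discontinuation day offset, or `NA_integer_` if none.
#' @export
detect_discontinuation <- function(timeline, follow_up_end,
                                   transplant_date = NULL, gap_days = 60L) {
  if (nrow(timeline) == 0L) return(NA_integer_)
  cand <- NA_integer_
  if (nrow(timeline) > 1L) {
    ## cap each gap at the follow-up horizon: only uncovered days observed
    ## during follow-up can complete the qualifying run
    gap_start <- timeline$end[-nrow(timeline)] + 1L
    gap_end <- pmin(timeline$start[-1L] - 1L, follow_up_end)
    hit <- which(gap_end - gap_start + 1L >= gap_days)
    if (length(hit) > 0L) cand <- timeline$end[hit[1L]]
  }
  if (is.na(cand)) {
    last_end <- timeline$end[nrow(timeline)]
    if (follow_up_end - last_end >= gap_days) cand <- last_end
  }
  if (!is.na(cand) && !is.null(transplant_date) && !is.na(transplant_date) &&
      transplant_date < cand + gap_days) {
    return(NA_integer_)
  }
  as.integer(cand)
}

#' Detect a switch to the alternate antifibrotic
#'
#' @param other_drug_dates Integer day offsets of post-index fills of the
#'   non-index antifibrotic.
#' @return The earliest such date, or `NA_integer_`.
#' @export
detect_switch <- function(other_drug_dates) {
  if (length(other_drug_dates) == 0L || all(is.na(other_drug_dates))) {
    return(NA_integer_)
  }
  as.integer(min(other_drug_dates, na.rm = TRUE))
}

#' Assemble a treatment episode for one patient
#'
#' Combines the coverage timeline, switch/transplant dates and follow-up end
#' into the persistence record: discontinuation, the persistence period (time
#' from index to the earliest of discontinuation, transplant, switch, or end
#' of follow-up; on ties the priority is transplant, then switch, then
#' discontinuation), PDC and the adherence flag, and re-initiation (the first
#' index-drug fill after the qualifying gap completes, i.e. strictly after
#' `discontinuation + gap_days`; the earliest possible `days_to_reinitiation`
#' is therefore `gap_days + 1`).
#'
#' All day arguments are integer offsets with the index date at 0.
#'
#' @param timeline A [build_timeline()] result for the index drug.
#' @param follow_up_end Follow-up end day offset (>= 0).
#' @param switch_date,transplant_date Event day offsets or `NA`/`NULL`.
#' @param index_drug_fill_dates Day offsets of all index-drug fills (used for
#'   re-initiation detection).
#' @param gap_days,pdc_threshold,adherence_rule Algorithm settings.
#' @return A one-row tibble: `pdc`, `adherent`, `discontinuation_day`,
#'   `switch_day`, `transplant_day`, `persistence_end`, `persistence_days`,
#'   `persistence_reason`, `reinitiation_day`, `days_to_reinitiation`.
#' @export
build_episode <- function(timeline, follow_up_end,
                          switch_date = NA_integer_,
                          transplant_date = NA_integer_,
                          index_drug_fill_dates = integer(),
                          gap_days = 60L, pdc_threshold = 0.8,
                          adherence_rule = c("gt", "ge")) {
  adherence_rule <- match.arg(adherence_rule)
  switch_date <- switch_date %||% NA_integer_
  transplant_date <- transplant_date %||% NA_integer_
  events <- c(switch_date, transplant_date)
  if (any(!is.na(events) & events < 0) || follow_up_end < 0 ||
      (length(index_drug_fill_dates) && any(index_drug_fill_dates < 0))) {
    abort("data error: event before index date")
  }
  disc <- detect_discontinuation(timeline, follow_up_end,
                                 transplant_date, gap_days)
  pdc <- compute_pdc(timeline, 0L, follow_up_end)
  reinit <- NA_integer_
  if (!is.na(disc)) {
    later <- index_drug_fill_dates[index_drug_fill_dates > disc + gap_days]
    if (length(later) > 0L) reinit <- as.integer(min(later))
  }
  cand <- c(transplant = transplant_date, switched = switch_date,
            discontinued = disc, censored = as.integer(follow_up_end))
  pe <- min(cand, na.rm = TRUE)
  reason <- names(cand)[which(!is.na(cand) & cand == pe)[1L]]
  tibble(
    pdc = pdc,
    adherent = classify_adherent(pdc, pdc_threshold, adherence_rule),
    discontinuation_day = disc,
    switch_day = as.integer(switch_date),
    transplant_day = as.integer(transplant_date),
    persistence_end = as.integer(pe),
    persistence_days = as.integer(pe) + 1L,
    persistence_reason = reason,
    reinitiation_day = reinit,
    days_to_reinitiation = reinit - disc
  )
}
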