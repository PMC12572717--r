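#' Gap-adjust a dispensing history into coverage intervals
#'
#' Converts a patient's sorted dispensing fills into maximal non-overlapping
#' coverage intervals, granting carry-over for early refills: a fill dispensed
#' before the previous supply runs out starts to count only when that supply
#' is exhausted, so no supply is lost and no day is double counted. All agents
#' are pooled into a single supply stream (switching between agents within the
#' class keeps the carry-over credit).
#'
#' @param fill_day integer vector of dispense days as 0-based offsets from the
#'   patient's index date, sorted ascending.
#' @param days_supplied integer vector of positive days supplied, same length.
#' @return A data.frame with columns `start_day`, `end_day` describing
#'   non-overlapping, sorted, half-open coverage intervals
#'   `[start_day, end_day)`. Intervals may extend past any follow-up horizon;
#'   windowing truncates later. Total covered days always equals
#'   `sum(days_supplied)` (carry-over conserves supply).
#' @examples
#' gap_adjust(c(0, 20), c(30, 30))  # early refill pushed to day 30 -> [0, 60)
#' @export
gap_adjust <- function(fill_day, days_supplied) {
  if (length(fill_day) == 0L) stop("empty dispensing history")
  if (length(fill_day) != length(days_supplied))
    stop("fill_day and days_supplied must have the same length")
  if (anyNA(fill_day) || anyNA(days_supplied))
    stop("missing values in dispensing history")
  if (is.unsorted(fill_day)) stop("fills must be sorted ascending by dispense day")
  if (any(days_supplied < 1)) stop("days_supplied must be >= 1")

  n <- length(fill_day)
  start <- numeric(n)
  end <- numeric(n)
  prev_end <- -Inf
  for (i in seq_len(n)) {
    start[i] <- max(fill_day[i], prev_end)
    end[i] <- start[i] + days_supplied[i]
    prev_end <- end[i]
  }
  # merge abutting/contiguous intervals into maximal runs
  new_run <- c(TRUE, start[-1L] > end[-n])
  run_id <- cumsum(new_run)
  data.frame(
    start_day = as.integer(start[new_run]),
    end_day = as.integer(tapply(end, run_id, max))
  )
}

#' Covered and hospital days of one 90-day window
#'
#' Intersects gap-adjusted coverage intervals and hospital stays with window
#' `k` (days `[90(k-1), 90k)` from the index date). Hospital days are credited
#' because in-hospital supply is assumed; by default (`mode = "union"`) a
#' hospital day that is already drug-covered is not counted twice, so
#' `covered_days + hospital_days <= 90` always holds. `mode = "sum"` counts
#' every in-window stay day regardless of drug coverage (the cap in
#' [compute_pdc()] then still bounds PDC at 1).
#'
#' @param intervals data.frame from [gap_adjust()] (`start_day`, `end_day`).
#' @param stays data.frame with `admit_day`, `discharge_day` (0-based offsets,
#'   inclusive of both endpoints). Days before the index date are clipped.
#'   May be `NULL` or empty.
#' @param k window index (>= 1).
#' @param mode `"union"` (default) or `"sum"`; see Details.
#' @return Integer vector `c(covered_days, hospital_days)`, each in 0..90.
#' @export
window_coverage <- function(intervals, stays = NULL, k, mode = c("union", "sum")) {
  mode <- match.arg(mode)
  stopifnot(length(k) == 1L, k >= 1)
  w0 <- 90 * (k - 1)
  w1 <- 90 * k
  covered <- 0L
  cov_days <- logical(90L)
  if (!is.null(intervals) && nrow(intervals)) {
    lo <- pmax(intervals$start_day, w0)
    hi <- pmin(intervals$end_day, w1)
    keep <- hi > lo
    covered <- as.integer(sum(hi[keep] - lo[keep]))
    for (i in which(keep)) cov_days[(lo[i] - w0 + 1L):(hi[i] - w0)] <- TRUE
  }
  hosp <- 0L
  if (!is.null(stays) && nrow(stays)) {
    hosp_days <- logical(90L)
    lo <- pmax(stays$admit_day, 0)            # clip pre-index days
    hi <- pmin(stays$discharge_day + 1L, w1)  # inclusive discharge -> half-open
    lo <- pmax(lo, w0)
    keep <- hi > lo
    for (i in which(keep)) hosp_days[(lo[i] - w0 + 1L):(hi[i] - w0)] <- TRUE
    hosp <- if (mode == "union") sum(hosp_days & !cov_days) else sum(hosp_days)
  }
  c(covered_days = covered, hospital_days = as.integer(hosp))
}

#' Proportion of days covered for a 90-day window
#'
#' `pdc = min(covered_days + hospital_days, 90) / 90`. The denominator is
#' always 90; the cap keeps PDC in `[0, 1]` when hospital credit is summed
#' rather than unioned with drug coverage.
#'
#' @param covered_days,hospital_days integers in 0..90 (vectorized).
#' @return Numeric PDC in `[0, 1]`.
#' @export
compute_pdc <- function(covered_days, hospital_days) {
  if (any(covered_days < 0) || any(hospital_days < 0))
    stop("covered_days and hospital_days must be non-negative")
  if (any(covered_days > 90) || any(hospital_days > 90))
    stop("covered_days and hospital_days cannot exceed 90")
  pmin(covered_days + hospital_days, 90) / 90
}

#' Map PDC to the 10-level ordinal adherence state
#'
#' Percentage bins are left-closed, right-open (`[0,10), [10,20), ...`) with
#' the top bin `[90,100]` closed, so PDC 0-9% is state 1, ..., 80-89% is
#' state 9 and 90-100% is state 10. A small tolerance absorbs floating-point
#' error from `days/90` ratios so that integer day counts always land in the
#' intended bin.
#'
#' @param pdc numeric vector in `[0, 1]`.
#' @return Integer states in 1..10, non-decreasing in `pdc`.
#' @export
map_pdc_to_state <- function(pdc) {
  eps <- 1e-9
  if (any(pdc < -eps) || any(pdc > 1 + eps)) stop("pdc must lie in [0, 1]")
  pct <- 100 * pmin(pmax(pdc, 0), 1)
  ifelse(pct >= 90 - eps, 10L, pmin(as.integer(floor((pct + eps) / 10)) + 1L, 10L))
}

#' Windowed adherence states for a whole cohort
#'
#' Runs the PDC engine per patient: gap-adjusts fills (all agents pooled),
#' intersects coverage and hospital stays with consecutive 90-day windows,
#' computes PDC and the ordinal state for windows `1..n_windows`.
#'
#' Eligibility mirrors a new-user claims cohort: at least `min_fills`
#' dispensing records and at least `min_days_supplied` total days supplied.
#' Patients missing a baseline row are dropped with a message. The index date
#' defaults to the first dispense date (`index = "first_fill"`);
#' `index = "baseline"` uses `baseline$index_date` instead, and fills before
#' it are ignored.
#'
#' @param dispensing data.frame with `patient_id`, `dispense_date` (Date or
#'   ISO-8601 string), `drug_code`, `days_supplied`.
#' @param hospital data.frame with `patient_id`, `admit_date`,
#'   `discharge_date`, or `NULL`.
#' @param baseline data.frame with `patient_id`, `index_date`, `age`,
#'   `chads_vasc`.
#' @param n_windows number of 90-day windows (default 20 = 5 years).
#' @param hospital_credit `"union"` or `"sum"`, see [window_coverage()].
#' @param min_fills,min_days_supplied eligibility thresholds (defaults 2 and
#'   60: at least two fills covering two months of supply).
#' @param index `"first_fill"` (default) or `"baseline"`.
#' @return data.frame with one row per eligible patient and window:
#'   `patient_id`, `window_index`, `covered_days`, `hospital_days`, `pdc`,
#'   `state`.
#' @export
build_cohort_windows <- function(dispensing, hospital = NULL, baseline,
                                 n_windows = 20L,
                                 hospital_credit = c("union", "sum"),
                                 min_fills = 2L, min_days_supplied = 60L,
                                 index = c("first_fill", "baseline")) {
  hospital_credit <- match.arg(hospital_credit)
  index <- match.arg(index)
  need <- c("patient_id", "dispense_date", "drug_code", "days_supplied")
  if (!all(need %in% names(dispensing)))
    stop("dispensing is missing columns: ",
         paste(setdiff(need, names(dispensing)), collapse = ", "))
  if (!all(c("patient_id", "index_date") %in% names(baseline)))
    stop("baseline must contain patient_id and index_date")
  dispensing$dispense_date <- as.Date(dispensing$dispense_date)
  baseline$index_date <- as.Date(baseline$index_date)
  if (!is.null(hospital) && nrow(hospital)) {
    hospital$admit_date <- as.Date(hospital$admit_date)
    hospital$discharge_date <- as.Date(hospital$discharge_date)
    if (any(hospital$discharge_date < hospital$admit_date))
      stop("hospital stays must have discharge_date >= admit_date")
  }

  ids <- unique(dispensing$patient_id)
  missing_base <- setdiff(ids, baseline$patient_id)
  if (length(missing_base)) {
    message(length(missing_base), " patient(s) without a baseline row dropped")
    ids <- setdiff(ids, missing_base)
  }

  disp_split <- split(dispensing, dispensing$patient_id)
  hosp_split <- if (!is.null(hospital) && nrow(hospital))
    split(hospital, hospital$patient_id) else list()
  base_idx <- setNames(as.integer(baseline$index_date), baseline$patient_id)

  out <- vector("list", length(ids))
  n_excl <- 0L
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    fills <- disp_split[[as.character(id)]]
    fills <- fills[order(fills$dispense_date), , drop = FALSE]
    idx0 <- if (index == "first_fill") as.integer(min(fills$dispense_date))
            else base_idx[[as.character(id)]]
    day <- as.integer(fills$dispense_date) - idx0
    keep <- day >= 0
    fills <- fills[keep, , drop = FALSE]
    day <- day[keep]
    if (nrow(fills) < min_fills || sum(fills$days_supplied) < min_days_supplied) {
      n_excl <- n_excl + 1L
      next
    }
    intervals <- gap_adjust(day, fills$days_supplied)
    st <- hosp_split[[as.character(id)]]
    stays <- if (is.null(st)) NULL else
      data.frame(admit_day = as.integer(st$admit_date) - idx0,
                 discharge_day = as.integer(st$discharge_date) - idx0)
    cov <- matrix(0L, n_windows, 2L)
    for (k in seq_len(n_windows))
      cov[k, ] <- window_coverage(intervals, stays, k, mode = hospital_credit)
    pdc <- compute_pdc(cov[, 1L], cov[, 2L])
    out[[i]] <- data.frame(
      patient_id = id,
      window_index = seq_len(n_windows),
      covered_days = cov[, 1L],
      hospital_days = cov[, 2L],
      pdc = pdc,
      state = map_pdc_to_state(pdc)
    )
  }
  if (n_excl) message(n_excl, " patient(s) excluded by the eligibility rule ",
                      "(>= ", min_fills, " fills, >= ", min_days_supplied,
                      " days supplied)")
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(patient_id = character(), window_index = integer(),
                      covered_days = integer(), hospital_days = integer(),
                      pdc = numeric(), state = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
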