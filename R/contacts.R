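#' Extract between-group contacts
#'
#' A (pair, second) counts as a contact iff the merged distance is strictly
#' below `threshold_cm` (default 150 cm, the distancing regulation) and the
#' two participants belong to different groups. All qualifying seconds of a
#' pair are summed into one dyad record; a contact need not be contiguous in
#' time. Pairs with fewer than `min_contact_seconds` qualifying seconds are
#' dropped (default 1, i.e. no minimum-duration filter).
#'
#' @param pairsec symmetrized pair-second table from [symmetrize()].
#' @param groups participant-to-group partition from [assign_groups()].
#' @param threshold_cm contact distance threshold, strict `<` (default 150).
#' @param min_contact_seconds minimum summed seconds to keep a dyad
#'   (default 1).
#' @return data frame `participant_a`, `participant_b`, `contact_seconds`,
#'   `first_s`, `last_s`; one row per contact dyad.
#' @export
extract_contacts <- function(pairsec, groups, threshold_cm = 150,
                             min_contact_seconds = 1) {
  empty <- data.frame(participant_a = character(), participant_b = character(),
                      contact_seconds = integer(), first_s = integer(),
                      last_s = integer(), stringsAsFactors = FALSE)
  if (nrow(pairsec) == 0) return(empty)
  gmap <- stats::setNames(groups$group_id, groups$participant_id)
  sel <- pairsec$distance_cm < threshold_cm &
    gmap[pairsec$participant_a] != gmap[pairsec$participant_b]
  sel[is.na(sel)] <- FALSE
  ps <- pairsec[sel, , drop = FALSE]
  if (nrow(ps) == 0) return(empty)
  key <- paste(ps$participant_a, ps$participant_b, sep = "\r")
  secs <- tapply(ps$timestamp_s, key, function(z) {
    c(length(unique(z)), min(z), max(z))
  })
  parts <- strsplit(names(secs), "\r", fixed = TRUE)
  m <- do.call(rbind, secs)
  res <- data.frame(participant_a = vapply(parts, `[`, "", 1L),
                    participant_b = vapply(parts, `[`, "", 2L),
                    contact_seconds = as.integer(m[, 1]),
                    first_s = as.integer(m[, 2]),
                    last_s = as.integer(m[, 3]),
                    stringsAsFactors = FALSE)
  res <- res[res$contact_seconds >= min_contact_seconds, , drop = FALSE]
  res <- res[order(res$participant_a, res$participant_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-participant contact degree and durations
#'
#' Degree is the number of distinct contact partners (unique contacts);
#' participants with no contacts get degree 0.
#'
#' @param contacts dyad table from [extract_contacts()].
#' @param participants character vector of all participants under study.
#' @return data frame `participant_id`, `n_unique_contacts`, plus a list
#'   column `durations` of per-dyad contact durations (seconds).
#' @export
participant_degree <- function(contacts, participants) {
  participants <- unique(participants)
  durs <- lapply(stats::setNames(participants, participants),
                 function(p) {
                   sel <- contacts$participant_a == p |
                     contacts$participant_b == p
                   contacts$contact_seconds[sel]
                 })
  res <- data.frame(participant_id = participants,
                    n_unique_contacts = vapply(durs, length, 1L),
                    stringsAsFactors = FALSE)
  res$durations <- unname(durs)
  rownames(res) <- NULL
  res
}

#' Restrict the analysis to a time window
#'
#' Selects participants whose session intersects the half-open window
#' `[t0, t1)` and recomputes contact durations on the qualifying seconds that
#' fall inside the window; dyads whose members are not both selected, or with
#' no in-window seconds, are dropped.
#'
#' @param sessions sessions from [sessionize()].
#' @param pairsec symmetrized pair-second table (used to recompute in-window
#'   durations).
#' @param groups participant-to-group partition.
#' @param t0,t1 window bounds in seconds, `t0 < t1`, half-open `[t0, t1)`.
#' @param threshold_cm contact distance threshold (default 150).
#' @param min_contact_seconds minimum summed seconds per dyad (default 1).
#' @return list with `participants` (selected ids) and `contacts` (restricted
#'   dyad table).
#' @export
select_window <- function(sessions, pairsec, groups, t0, t1,
                          threshold_cm = 150, min_contact_seconds = 1) {
  stopifnot(t0 < t1)
  sel <- sessions$start_s < t1 & sessions$end_s >= t0
  participants <- sessions$participant_id[sel]
  ps <- pairsec[pairsec$timestamp_s >= t0 & pairsec$timestamp_s < t1 &
                  pairsec$participant_a %in% participants &
                  pairsec$participant_b %in% participants, , drop = FALSE]
  contacts <- extract_contacts(ps, groups, threshold_cm, min_contact_seconds)
  list(participants = participants, contacts = contacts)
}

#' Hourly crowdedness summary
#'
#' For each one-hour window `[h, h + 3600)` reports the number of
#' participants present and the median number of unique contacts among them,
#' the pairs consumed by the crowdedness regression.
#'
#' @param sessions sessions from [sessionize()].
#' @param pairsec symmetrized pair-second table.
#' @param groups participant-to-group partition.
#' @param hours integer vector of window start seconds, each a multiple of
#'   3600.
#' @param threshold_cm contact distance threshold (default 150).
#' @return data frame `hour_start_s`, `n_participants`, `median_degree`
#'   (`NA` for empty hours).
#' @export
hourly_summary <- function(sessions, pairsec, groups, hours,
                           threshold_cm = 150) {
  stopifnot(all(hours %% 3600 == 0))
  rows <- lapply(hours, function(h) {
    w <- select_window(sessions, pairsec, groups, h, h + 3600, threshold_cm)
    deg <- participant_degree(w$contacts, w$participants)
    data.frame(hour_start_s = h,
               n_participants = length(w$participants),
               median_degree = if (length(w$participants) == 0) NA_real_
                               else stats::median(deg$n_unique_contacts))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Descriptive summary of a sample
#'
#' Range, mean, standard deviation, median and interquartile range — the
#' layout used for per-condition degree and duration descriptives.
#'
#' @param x numeric vector.
#' @return one-row data frame `n`, `min`, `max`, `mean`, `sd`, `median`,
#'   `q25`, `q75`.
#' @export
describe_sample <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0) {
    return(data.frame(n = 0L, min = NA_real_, max = NA_real_, mean = NA_real_,
                      sd = NA_real_, median = NA_real_, q25 = NA_real_,
                      q75 = NA_real_))
  }
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  data.frame(n = length(x), min = min(x), max = max(x), mean = mean(x),
             sd = stats::sd(x), median = stats::median(x),
             q25 = q[1], q75 = q[2])
}
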