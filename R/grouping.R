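#' Parameters of the household/group detection rule
#'
#' Two participants are considered members of the same shopping group
#' (household) if they meet at least `min_criteria` of three pairwise
#' criteria: (1) at least `min_close_seconds` seconds of records at distance
#' at most `close_dist_cm`; (2) being closer than `prox_dist_cm` for at least
#' a fraction `min_prox_fraction` of the shorter of their two visit
#' durations; (3) exiting within `max_coexit_lag_s` seconds of each other.
#'
#' @param close_dist_cm close-contact distance, cm (default 80).
#' @param min_close_seconds minimum close-contact seconds (default 10).
#' @param prox_dist_cm proximity distance, cm (default 150, strict `<`).
#' @param min_prox_fraction minimum fraction of the visit spent in proximity
#'   (default 0.25).
#' @param max_coexit_lag_s maximum exit-time difference, seconds (default 60).
#' @param min_criteria how many of the three criteria must hold (default 2).
#' @return an object of class `group_params`.
#' @export
group_params <- function(close_dist_cm = 80, min_close_seconds = 10,
                         prox_dist_cm = 150, min_prox_fraction = 0.25,
                         max_coexit_lag_s = 60, min_criteria = 2) {
  stopifnot(close_dist_cm > 0, min_close_seconds > 0, prox_dist_cm > 0,
            min_prox_fraction > 0, min_prox_fraction <= 1,
            max_coexit_lag_s > 0, min_criteria %in% 1:3)
  structure(list(close_dist_cm = close_dist_cm,
                 min_close_seconds = min_close_seconds,
                 prox_dist_cm = prox_dist_cm,
                 min_prox_fraction = min_prox_fraction,
                 max_coexit_lag_s = max_coexit_lag_s,
                 min_criteria = min_criteria),
            class = "group_params")
}

#' Evaluate the three group criteria for every observed pair
#'
#' Criterion 1 counts seconds at distance `<= close_dist_cm` (inclusive
#' "within"). Criterion 2 counts seconds at distance `< prox_dist_cm` (the
#' same strict convention as the contact definition) against the shorter of
#' the two visit durations, so a short-visit household member still
#' qualifies. Criterion 3 compares session end times. Pairs whose sessions do
#' not overlap in time are skipped: they cannot be a shopping group.
#'
#' @param pairsec symmetrized pair-second table from [symmetrize()].
#' @param sessions sessions from [sessionize()].
#' @param params a [group_params()] object.
#' @return data frame with one row per evaluated pair: `participant_a`,
#'   `participant_b`, logical `c_close`, `c_prox`, `c_coexit`, and `n_met`.
#' @export
evaluate_pair_criteria <- function(pairsec, sessions, params = group_params()) {
  stopifnot(inherits(params, "group_params"))
  empty <- data.frame(participant_a = character(), participant_b = character(),
                      c_close = logical(), c_prox = logical(),
                      c_coexit = logical(), n_met = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(sessions) < 2) return(empty)
  dur <- stats::setNames(sessions$end_s - sessions$start_s + 1L,
                         sessions$participant_id)
  end <- stats::setNames(sessions$end_s, sessions$participant_id)
  start <- stats::setNames(sessions$start_s, sessions$participant_id)

  # all co-present (session-overlapping) pairs, including pairs that never
  # came within recording range
  ids <- sessions$participant_id[order(sessions$participant_id)]
  cmb <- utils::combn(ids, 2)
  a <- cmb[1, ]; b <- cmb[2, ]
  overlap <- pmin(end[a], end[b]) >= pmax(start[a], start[b])
  a <- a[overlap]; b <- b[overlap]
  if (length(a) == 0) return(empty)

  key <- paste(pairsec$participant_a, pairsec$participant_b, sep = "\r")
  close_tab <- tapply(pairsec$distance_cm <= params$close_dist_cm, key, sum)
  prox_tab <- tapply(pairsec$distance_cm < params$prox_dist_cm, key, sum)
  pk <- paste(a, b, sep = "\r")
  n_close <- close_tab[pk]; n_close[is.na(n_close)] <- 0L
  n_prox <- prox_tab[pk]; n_prox[is.na(n_prox)] <- 0L
  n_close <- as.integer(n_close); n_prox <- as.integer(n_prox)

  ref_dur <- pmin(dur[a], dur[b])
  c_close <- n_close >= params$min_close_seconds
  c_prox <- n_prox >= params$min_prox_fraction * ref_dur
  c_coexit <- abs(end[a] - end[b]) <= params$max_coexit_lag_s
  res <- data.frame(participant_a = a, participant_b = b,
                    c_close = unname(c_close), c_prox = unname(c_prox),
                    c_coexit = unname(c_coexit),
                    n_met = unname(as.integer(c_close) + as.integer(c_prox) +
                                     as.integer(c_coexit)),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# connected components over an edge list, by union-find
components_from_edges <- function(ids, edge_a, edge_b) {
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- match(edge_a, ids)
  ib <- match(edge_b, ids)
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(ids), find, 1L)
  match(roots, unique(roots))
}

#' Assign participants to groups
#'
#' Builds a graph with an edge for every pair meeting at least `min_criteria`
#' of the three criteria and takes connected components as groups (transitive
#' closure: a three-person household where only adjacent pairs qualify is one
#' group). Participants in no qualifying pair form singleton groups.
#'
#' @param criteria output of [evaluate_pair_criteria()].
#' @param participants character vector of all participant ids.
#' @param min_criteria minimum criteria met to link a pair (default 2).
#' @return data frame `participant_id`, `group_id` — a partition of
#'   `participants`.
#' @export
assign_groups <- function(criteria, participants, min_criteria = 2) {
  participants <- unique(participants)
  if (length(participants) == 0) {
    return(data.frame(participant_id = character(), group_id = character(),
                      stringsAsFactors = FALSE))
  }
  qual <- criteria[criteria$n_met >= min_criteria, , drop = FALSE]
  comp <- components_from_edges(participants, qual$participant_a,
                                qual$participant_b)
  data.frame(participant_id = participants,
             group_id = paste0("G", comp),
             stringsAsFactors = FALSE)
}

#' Detect groups in one step
#'
#' Convenience wrapper chaining [evaluate_pair_criteria()] and
#' [assign_groups()] over all participants with a session.
#'
#' @inheritParams evaluate_pair_criteria
#' @return list with elements `criteria` (the pairwise audit table) and
#'   `groups` (the participant-to-group partition).
#' @export
detect_groups <- function(pairsec, sessions, params = group_params()) {
  criteria <- evaluate_pair_criteria(pairsec, sessions, params)
  groups <- assign_groups(criteria, sessions$participant_id,
                          params$min_criteria)
  list(criteria = criteria, groups = groups)
}
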