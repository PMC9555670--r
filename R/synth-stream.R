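#' Configuration for the synthetic tag-stream generator
#'
#' Describes a stream of supermarket visits instrumented with wearable
#' distance tags: customers arrive in parties (households) of random size,
#' wear a reusable physical tag for the visit, stay close to their own party
#' throughout, exit near-simultaneously with it, and have short background
#' encounters with other customers. Distances are recorded at 1 Hz below a
#' finite recording horizon, as real ultra-wideband tags only report nearby
#' peers.
#'
#' @param duration_s length of the simulated stream, seconds (default 3600).
#' @param arrival_rate customer arrivals per minute (default 2).
#' @param visit_meanlog,visit_sdlog log-normal visit-duration parameters on
#'   the log-seconds scale (defaults give mean about 10 minutes).
#' @param group_size_probs probabilities of party sizes 1, 2, 3, ...
#'   (must sum to 1; default `c(0.7, 0.25, 0.05)` - most customers shop
#'   alone).
#' @param group_proximity_cm typical within-party distance, cm (default 60).
#' @param group_noise_sd_cm per-second jitter of within-party distances
#'   (default 10, the nominal ranging accuracy scale).
#' @param max_coexit_lag_s party members exit within this many seconds of
#'   each other (default 10).
#' @param encounter_rate background encounters per co-present cross-party
#'   pair per minute (default 0.05).
#' @param encounter_meanlog,encounter_sdlog log-normal encounter-duration
#'   parameters (defaults give mean about 8 seconds).
#' @param encounter_dist_range integer range of encounter distances, cm
#'   (default `c(60, 149)`).
#' @param extra_bout_rate Poisson mean of additional encounter bouts for a
#'   pair that meets at all (default 0.3).
#' @param ambient_rate per-second probability that a co-present cross-party
#'   pair logs a mid-range distance record (default 0.02). Customers milling
#'   around a store constantly pass within the recording horizon without
#'   coming into contact range; these records anchor the observed wearing
#'   sessions to the full visit.
#' @param ambient_dist_range integer range of ambient distances, cm
#'   (default `c(150, 400)`, i.e. outside contact range but inside the
#'   horizon).
#' @param n_tags physical tag pool size (default 200).
#' @param recharge_gap_s minimum idle gap between two uses of one tag
#'   (default 300).
#' @param horizon_cm recording horizon: pair-seconds farther apart than this
#'   produce no record (default 500).
#' @param condition_label text label for the condition (default "control").
#' @param contact_logodds_shift planted condition effect: shift, on the
#'   log-odds scale, of the probability that a co-present cross-party pair
#'   has any encounter (default 0; negative means fewer contacts).
#' @param seed integer seed; one generator drives every draw.
#' @return an object of class `stream_config`.
#' @export
stream_config <- function(duration_s = 3600, arrival_rate = 2,
                          visit_meanlog = 6.29, visit_sdlog = 0.47,
                          group_size_probs = c(0.7, 0.25, 0.05),
                          group_proximity_cm = 60, group_noise_sd_cm = 10,
                          max_coexit_lag_s = 10,
                          encounter_rate = 0.05,
                          encounter_meanlog = 2, encounter_sdlog = 0.5,
                          encounter_dist_range = c(60, 149),
                          extra_bout_rate = 0.3,
                          ambient_rate = 0.02,
                          ambient_dist_range = c(150, 400),
                          n_tags = 200, recharge_gap_s = 300,
                          horizon_cm = 500,
                          condition_label = "control",
                          contact_logodds_shift = 0, seed = 1) {
  stopifnot(duration_s > 0, arrival_rate >= 0, visit_sdlog > 0,
            all(group_size_probs >= 0),
            abs(sum(group_size_probs) - 1) < 1e-8,
            group_proximity_cm > 0, group_noise_sd_cm >= 0,
            max_coexit_lag_s >= 0, encounter_rate >= 0,
            encounter_sdlog > 0, length(encounter_dist_range) == 2,
            encounter_dist_range[1] <= encounter_dist_range[2],
            extra_bout_rate >= 0, ambient_rate >= 0, ambient_rate <= 1,
            length(ambient_dist_range) == 2,
            ambient_dist_range[1] <= ambient_dist_range[2],
            n_tags >= 1, recharge_gap_s >= 0, horizon_cm > 0)
  structure(as.list(environment()), class = "stream_config")
}

# per-second distance trace rows for one pair over [from, to]
trace_rows <- function(p1, p2, from, to, dist) {
  if (to < from) return(NULL)
  tt <- from:to
  data.frame(t = tt, a = pmin(p1, p2), b = pmax(p1, p2),
             d = as.integer(dist), stringsAsFactors = FALSE)
}

#' Simulate a raw tag-log stream with known ground truth
#'
#' Generates the full observable stream a study day would produce: party
#' arrivals (Poisson), log-normal visit durations, physical tags assigned
#' from a finite pool with a recharge gap between uses, sustained
#' within-party proximity traces with near-simultaneous exits, and sparse
#' background encounters between co-present customers whose propensity can
#' be shifted by a planted condition effect. Every emitted record is a
#' reciprocal pair of reports (both tags report the same integer distance).
#'
#' @param config a [stream_config()].
#' @return list with
#'   * `records`: raw-log data frame (`timestamp_s`, `reporter_tag`,
#'     `opposing_tag`, `distance_cm`) sorted by time stamp;
#'   * `truth`: list with `sessions` (true participant intervals:
#'     `participant`, `tag_id`, `start_s`, `end_s`, `group`, `emitted`),
#'     `group_map`, `true_contacts` (cross-party pairs with seconds below
#'     150 cm) and `n_dropped_no_tag` (customers turned away because no tag
#'     was free).
#' @export
simulate_tag_stream <- function(config) {
  stopifnot(inherits(config, "stream_config"))
  set.seed(config$seed)
  cfg <- config

  empty_records <- data.frame(timestamp_s = integer(),
                              reporter_tag = character(),
                              opposing_tag = character(),
                              distance_cm = integer(),
                              stringsAsFactors = FALSE)
  sizes <- seq_along(cfg$group_size_probs)
  mean_size <- sum(sizes * cfg$group_size_probs)
  party_rate_s <- cfg$arrival_rate / 60 / mean_size
  n_parties <- if (party_rate_s > 0) {
    stats::rpois(1, party_rate_s * cfg$duration_s)
  } else 0L

  sessions <- NULL
  n_dropped <- 0L
  if (n_parties > 0) {
    arrivals <- sort(round(stats::runif(n_parties, 0, cfg$duration_s)))
    tag_free_at <- rep(-Inf, cfg$n_tags)
    rows <- list()
    pid <- 0L
    for (g in seq_len(n_parties)) {
      size <- sample(sizes, 1, prob = cfg$group_size_probs)
      t0 <- arrivals[g]
      stay <- max(30, round(stats::rlnorm(1, cfg$visit_meanlog,
                                          cfg$visit_sdlog)))
      base_end <- t0 + stay
      for (m in seq_len(size)) {
        end_m <- base_end + round(stats::runif(1, 0, cfg$max_coexit_lag_s))
        free <- which(tag_free_at + cfg$recharge_gap_s <= t0)
        if (length(free) == 0) { n_dropped <- n_dropped + 1L; next }
        tag <- free[1]
        tag_free_at[tag] <- end_m
        pid <- pid + 1L
        rows[[pid]] <- data.frame(
          participant = sprintf("P%04d", pid),
          tag_id = sprintf("T%03d", tag),
          start_s = t0, end_s = end_m,
          group = sprintf("party%03d", g),
          stringsAsFactors = FALSE)
      }
    }
    sessions <- do.call(rbind, rows)
  }
  if (is.null(sessions) || nrow(sessions) == 0) {
    return(list(records = empty_records,
                truth = list(sessions = data.frame(),
                             group_map = data.frame(),
                             true_contacts = data.frame(),
                             n_dropped_no_tag = n_dropped)))
  }

  traces <- list()
  ti <- 0L
  # sustained within-party proximity
  parties <- split(sessions, sessions$group)
  for (p in parties) {
    if (nrow(p) < 2) next
    for (i in seq_len(nrow(p) - 1)) {
      for (j in (i + 1):nrow(p)) {
        from <- max(p$start_s[i], p$start_s[j])
        to <- min(p$end_s[i], p$end_s[j])
        if (to < from) next
        d <- pmax(10L, pmin(as.integer(cfg$horizon_cm), as.integer(round(
          stats::rnorm(to - from + 1, cfg$group_proximity_cm,
                       cfg$group_noise_sd_cm)))))
        ti <- ti + 1L
        traces[[ti]] <- trace_rows(p$participant[i], p$participant[j],
                                   from, to, d)
      }
    }
  }
  # background encounters and ambient mid-range traffic between co-present
  # cross-party pairs
  n <- nrow(sessions)
  if (n >= 2 && (cfg$encounter_rate > 0 || cfg$ambient_rate > 0)) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (sessions$group[i] == sessions$group[j]) next
        from <- max(sessions$start_s[i], sessions$start_s[j])
        to <- min(sessions$end_s[i], sessions$end_s[j])
        if (to < from) next
        if (cfg$ambient_rate > 0) {
          ov <- to - from + 1L
          n_amb <- stats::rbinom(1, ov, cfg$ambient_rate)
          if (n_amb > 0) {
            tt <- sort(sample.int(ov, n_amb)) + from - 1L
            d <- as.integer(round(stats::runif(n_amb,
                                               cfg$ambient_dist_range[1],
                                               cfg$ambient_dist_range[2])))
            ti <- ti + 1L
            traces[[ti]] <- data.frame(t = tt,
                                       a = pmin(sessions$participant[i],
                                                sessions$participant[j]),
                                       b = pmax(sessions$participant[i],
                                                sessions$participant[j]),
                                       d = d, stringsAsFactors = FALSE)
          }
        }
        if (cfg$encounter_rate <= 0) next
        ov_min <- (to - from + 1) / 60
        p0 <- -expm1(-cfg$encounter_rate * ov_min)
        p0 <- min(max(p0, 1e-12), 1 - 1e-12)
        p_meet <- stats::plogis(stats::qlogis(p0) +
                                  cfg$contact_logodds_shift)
        if (stats::runif(1) >= p_meet) next
        n_bouts <- 1L + stats::rpois(1, cfg$extra_bout_rate)
        for (b in seq_len(n_bouts)) {
          dur <- max(1, round(stats::rlnorm(1, cfg$encounter_meanlog,
                                            cfg$encounter_sdlog)))
          dur <- min(dur, to - from + 1)
          b0 <- from + floor(stats::runif(1, 0, to - from + 1 - dur + 1))
          d <- as.integer(round(stats::runif(dur,
                                             cfg$encounter_dist_range[1],
                                             cfg$encounter_dist_range[2])))
          ti <- ti + 1L
          traces[[ti]] <- trace_rows(sessions$participant[i],
                                     sessions$participant[j],
                                     b0, b0 + dur - 1L, d)
        }
      }
    }
  }

  if (ti == 0L) {
    pairsec <- data.frame(t = integer(), a = character(), b = character(),
                          d = integer(), stringsAsFactors = FALSE)
  } else {
    tr <- do.call(rbind, traces)
    # one distance per (pair, second): overlapping bouts merged by minimum
    key <- paste(tr$a, tr$b, tr$t, sep = "\r")
    keep <- !duplicated(key)
    dmin <- tapply(tr$d, key, min)
    pairsec <- tr[keep, , drop = FALSE]
    pairsec$d <- as.integer(dmin[paste(pairsec$a, pairsec$b, pairsec$t,
                                       sep = "\r")])
  }
  pairsec <- pairsec[pairsec$d <= cfg$horizon_cm, , drop = FALSE]

  tag_of <- stats::setNames(sessions$tag_id, sessions$participant)
  if (nrow(pairsec) > 0) {
    records <- data.frame(
      timestamp_s = as.integer(c(pairsec$t, pairsec$t)),
      reporter_tag = c(tag_of[pairsec$a], tag_of[pairsec$b]),
      opposing_tag = c(tag_of[pairsec$b], tag_of[pairsec$a]),
      distance_cm = as.integer(c(pairsec$d, pairsec$d)),
      stringsAsFactors = FALSE)
    records <- records[order(records$timestamp_s, records$reporter_tag,
                             records$opposing_tag), , drop = FALSE]
    rownames(records) <- NULL
  } else {
    records <- empty_records
  }

  emitted <- sessions$participant %in% c(pairsec$a, pairsec$b)
  sessions$emitted <- emitted

  # true cross-party contacts (< 150 cm), from the emitted traces
  cross <- pairsec[pairsec$d < 150, , drop = FALSE]
  grp <- stats::setNames(sessions$group, sessions$participant)
  cross <- cross[grp[cross$a] != grp[cross$b], , drop = FALSE]
  if (nrow(cross) > 0) {
    key <- paste(cross$a, cross$b, sep = "\r")
    cs <- tapply(cross$t, key, function(z) length(unique(z)))
    parts <- strsplit(names(cs), "\r", fixed = TRUE)
    true_contacts <- data.frame(
      participant_a = vapply(parts, `[`, "", 1L),
      participant_b = vapply(parts, `[`, "", 2L),
      contact_seconds = as.integer(cs),
      stringsAsFactors = FALSE)
    rownames(true_contacts) <- NULL
  } else {
    true_contacts <- data.frame(participant_a = character(),
                                participant_b = character(),
                                contact_seconds = integer(),
                                stringsAsFactors = FALSE)
  }

  list(records = records,
       truth = list(sessions = sessions,
                    group_map = data.frame(
                      participant_id = sessions$participant,
                      group_id = sessions$group,
                      stringsAsFactors = FALSE),
                    true_contacts = true_contacts,
                    n_dropped_no_tag = n_dropped))
}

#' Write a raw tag log to CSV
#'
#' Schema `timestamp_s,reporter_tag,opposing_tag,distance_cm`; round-trips
#' losslessly through [parse_raw_log()].
#'
#' @param records raw-log data frame, sorted by time stamp.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_raw_log <- function(records, path) {
  stopifnot(!is.unsorted(records$timestamp_s))
  utils::write.csv(records[, c("timestamp_s", "reporter_tag",
                               "opposing_tag", "distance_cm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize simulation ground truth as JSON
#'
#' @param truth the `truth` element of [simulate_tag_stream()].
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Match pipeline participants to ground-truth participants
#'
#' A pipeline participant id names an observed wearing session of a tag;
#' the matching ground-truth participant is the one whose true session on
#' the same tag contains the observed interval.
#'
#' @param truth_sessions `truth$sessions` from [simulate_tag_stream()].
#' @param sessions observed sessions from [sessionize()].
#' @return named character vector: ground-truth participant by pipeline
#'   participant id (`NA` where no true session contains the observation).
#' @export
match_participants <- function(truth_sessions, sessions) {
  out <- rep(NA_character_, nrow(sessions))
  for (r in seq_len(nrow(sessions))) {
    cand <- truth_sessions$tag_id == sessions$tag_id[r] &
      truth_sessions$start_s <= sessions$start_s[r] &
      truth_sessions$end_s >= sessions$end_s[r]
    hit <- which(cand)
    if (length(hit) == 1) out[r] <- truth_sessions$participant[hit]
  }
  stats::setNames(out, sessions$participant_id)
}
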