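#' Parse a raw tag log
#'
#' Reads a CSV of 1 Hz distance assessments between wearable tags. Each row
#' holds a time stamp (integer seconds), the reporting tag id, the opposing
#' tag id, and the measured distance in centimetres. Rows where a tag reports
#' itself are dropped (with a message giving the count); negative distances or
#' malformed rows are an error naming the offending line.
#'
#' @param path path to a CSV file with header
#'   `timestamp_s,reporter_tag,opposing_tag,distance_cm`.
#' @return A data frame of records sorted by time stamp, with columns
#'   `timestamp_s` (integer), `reporter_tag`, `opposing_tag` (character) and
#'   `distance_cm` (integer). The number of dropped self-reports is attached
#'   as attribute `"n_self_reports"`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("timestamp_s,reporter_tag,opposing_tag,distance_cm",
#'              "100,T1,T2,132"), f)
#' parse_raw_log(f)
parse_raw_log <- function(path) {
  if (!file.exists(path)) stop("raw log not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  expected <- c("timestamp_s", "reporter_tag", "opposing_tag", "distance_cm")
  if (!identical(names(df), expected)) {
    stop("raw log header must be '", paste(expected, collapse = ","),
         "', got '", paste(names(df), collapse = ","), "'")
  }
  df$timestamp_s <- suppressWarnings(as.numeric(df$timestamp_s))
  df$distance_cm <- suppressWarnings(as.numeric(df$distance_cm))
  bad <- which(!is.finite(df$timestamp_s) | !is.finite(df$distance_cm) |
                 is.na(df$reporter_tag) | df$reporter_tag == "" |
                 is.na(df$opposing_tag) | df$opposing_tag == "")
  if (length(bad)) {
    stop("malformed raw-log row at line ", bad[1] + 1L)
  }
  neg <- which(df$distance_cm < 0)
  if (length(neg)) {
    stop("negative distance at line ", neg[1] + 1L)
  }
  self <- df$reporter_tag == df$opposing_tag
  n_self <- sum(self)
  if (n_self > 0) {
    message("parse_raw_log: dropped ", n_self, " self-report record(s)")
    df <- df[!self, , drop = FALSE]
  }
  # sub-second input is floored to the 1 Hz grid
  df$timestamp_s <- as.integer(floor(df$timestamp_s))
  df$distance_cm <- as.integer(df$distance_cm)
  df <- df[order(df$timestamp_s), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_self_reports") <- n_self
  df
}

#' Split tag activity into wearing sessions
#'
#' Physical tags are handed out to several customers over a day. For each tag,
#' the seconds at which it appears in the log (as reporter or as opposing tag)
#' are split wherever two consecutive appearances are more than
#' `gap_threshold_s` apart; each maximal run becomes one visit session and is
#' assigned a unique participant id `"<tag>#<ordinal>"`.
#'
#' Sessions are closed intervals `[start_s, end_s]` on the 1 Hz grid, so a
#' visit lasts `end_s - start_s + 1` seconds. A tag worn but never within
#' recording range of another tag produces no records and hence no session.
#'
#' @param records data frame from [parse_raw_log()].
#' @param gap_threshold_s minimum idle gap (seconds) separating two uses of
#'   one tag; default 120.
#' @return data frame with columns `participant_id`, `tag_id`, `start_s`,
#'   `end_s`, ordered by tag then start time.
#' @export
sessionize <- function(records, gap_threshold_s = 120) {
  stopifnot(gap_threshold_s > 0)
  if (nrow(records) == 0) {
    return(data.frame(participant_id = character(), tag_id = character(),
                      start_s = integer(), end_s = integer(),
                      stringsAsFactors = FALSE))
  }
  tags <- c(records$reporter_tag, records$opposing_tag)
  times <- c(records$timestamp_s, records$timestamp_s)
  out <- lapply(split(times, tags), function(tt) {
    tt <- sort(unique(tt))
    brk <- which(diff(tt) > gap_threshold_s)
    starts <- tt[c(1L, brk + 1L)]
    ends <- tt[c(brk, length(tt))]
    data.frame(start_s = starts, end_s = ends)
  })
  tag_ids <- rep(names(out), vapply(out, nrow, 1L))
  out <- do.call(rbind, out)
  ord <- unlist(lapply(split(seq_along(tag_ids), tag_ids),
                       seq_along), use.names = FALSE)
  # split() orders by tag name; rebuild ordinals in start order per tag
  res <- data.frame(
    participant_id = paste0(tag_ids, "#", ave(out$start_s, tag_ids,
                                              FUN = function(z) rank(z))),
    tag_id = tag_ids,
    start_s = as.integer(out$start_s),
    end_s = as.integer(out$end_s),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$tag_id, res$start_s), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate records with participant ids
#'
#' Maps the reporter and opposing tag of every record to the unique visit
#' session enclosing its time stamp. Records whose time stamp falls inside no
#' session for either tag (e.g. in the idle gap between two uses) are dropped
#' and counted.
#'
#' @param records data frame from [parse_raw_log()].
#' @param sessions data frame from [sessionize()].
#' @return `records` with added character columns `reporter_participant` and
#'   `opposing_participant`; dropped-record count attached as attribute
#'   `"n_dropped"`.
#' @export
assign_participants <- function(records, sessions) {
  if (nrow(records) == 0) {
    records$reporter_participant <- character(0)
    records$opposing_participant <- character(0)
    attr(records, "n_dropped") <- 0L
    return(records)
  }
  by_tag <- split(sessions, sessions$tag_id)
  for (s in by_tag) {
    if (nrow(s) > 1) {
      s <- s[order(s$start_s), ]
      if (any(s$start_s[-1] <= s$end_s[-nrow(s)])) {
        stop("overlapping sessions for tag ", s$tag_id[1])
      }
    }
  }
  lookup <- function(tag, ts) {
    s <- by_tag[[tag]]
    if (is.null(s)) return(rep(NA_character_, length(ts)))
    idx <- findInterval(ts, s$start_s)
    ok <- idx >= 1L & ts <= s$end_s[pmax(idx, 1L)]
    out <- rep(NA_character_, length(ts))
    out[ok] <- s$participant_id[idx[ok]]
    out
  }
  map_side <- function(tags, ts) {
    out <- rep(NA_character_, length(tags))
    for (tag in unique(tags)) {
      sel <- tags == tag
      out[sel] <- lookup(tag, ts[sel])
    }
    out
  }
  rp <- map_side(records$reporter_tag, records$timestamp_s)
  op <- map_side(records$opposing_tag, records$timestamp_s)
  keep <- !is.na(rp) & !is.na(op)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("assign_participants: dropped ", n_dropped,
            " record(s) outside any session")
  }
  records <- records[keep, , drop = FALSE]
  records$reporter_participant <- rp[keep]
  records$opposing_participant <- op[keep]
  rownames(records) <- NULL
  attr(records, "n_dropped") <- n_dropped
  records
}

#' Merge reciprocal reports into one distance per pair-second
#'
#' Both tags of a pair may report the same second; the two reports are merged
#' by taking the minimum distance. The minimum is the conservative choice for
#' a distancing analysis: it biases toward declaring contact, never away from
#' it.
#'
#' @param annotated records from [assign_participants()].
#' @return data frame with one row per (unordered participant pair, second):
#'   columns `participant_a`, `participant_b` (with `a < b` in string order),
#'   `timestamp_s`, `distance_cm`.
#' @export
symmetrize <- function(annotated) {
  if (nrow(annotated) == 0) {
    return(data.frame(participant_a = character(), participant_b = character(),
                      timestamp_s = integer(), distance_cm = integer(),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(annotated$reporter_participant, annotated$opposing_participant)
  b <- pmax(annotated$reporter_participant, annotated$opposing_participant)
  key <- paste(a, b, annotated$timestamp_s, sep = "\r")
  d <- tapply(annotated$distance_cm, key, min)
  parts <- strsplit(names(d), "\r", fixed = TRUE)
  res <- data.frame(
    participant_a = vapply(parts, `[`, "", 1L),
    participant_b = vapply(parts, `[`, "", 2L),
    timestamp_s = as.integer(vapply(parts, `[`, "", 3L)),
    distance_cm = as.integer(d),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$participant_a, res$participant_b, res$timestamp_s), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
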