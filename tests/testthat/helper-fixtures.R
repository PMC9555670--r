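# shared builders and independent oracles for the test suite

# pair-second table in the symmetrize() output format
make_pairsec <- function(a, b, t, d) {
  data.frame(participant_a = pmin(a, b), participant_b = pmax(a, b),
             timestamp_s = as.integer(t), distance_cm = as.integer(d),
             stringsAsFactors = FALSE)
}

make_sessions <- function(participant_id, tag_id, start_s, end_s) {
  data.frame(participant_id = participant_id, tag_id = tag_id,
             start_s = as.integer(start_s), end_s = as.integer(end_s),
             stringsAsFactors = FALSE)
}

empty_contacts <- function() {
  data.frame(participant_a = character(), participant_b = character(),
             contact_seconds = integer(), first_s = integer(),
             last_s = integer(), stringsAsFactors = FALSE)
}

singleton_groups <- function(ids) {
  data.frame(participant_id = ids, group_id = paste0("S", seq_along(ids)),
             stringsAsFactors = FALSE)
}

# brute-force contact extraction: explicit loop over every (pair, second)
# row; the independent oracle for extract_contacts()
brute_force_contacts <- function(pairsec, groups, threshold_cm = 150) {
  gmap <- setNames(groups$group_id, groups$participant_id)
  acc <- list()
  for (r in seq_len(nrow(pairsec))) {
    a <- pairsec$participant_a[r]; b <- pairsec$participant_b[r]
    if (pairsec$distance_cm[r] >= threshold_cm) next
    if (gmap[[a]] == gmap[[b]]) next
    key <- paste(a, b)
    if (is.null(acc[[key]])) acc[[key]] <- integer(0)
    acc[[key]] <- c(acc[[key]], pairsec$timestamp_s[r])
  }
  if (length(acc) == 0) return(empty_contacts())
  rows <- lapply(names(acc), function(k) {
    ab <- strsplit(k, " ")[[1]]
    tt <- unique(acc[[k]])
    data.frame(participant_a = ab[1], participant_b = ab[2],
               contact_seconds = length(tt), first_s = min(tt),
               last_s = max(tt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_a, out$participant_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random symmetrized pair-second instance with a random group partition
random_contact_instance <- function(n_participants, n_seconds, n_rows,
                                    n_groups = max(2, n_participants %/% 3)) {
  ids <- sprintf("p%02d", seq_len(n_participants))
  a <- sample(ids, n_rows, replace = TRUE)
  b <- sample(ids, n_rows, replace = TRUE)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  t <- sample.int(n_seconds, length(a), replace = TRUE)
  d <- sample.int(400, length(a), replace = TRUE)
  ps <- make_pairsec(a, b, t, d)
  key <- paste(ps$participant_a, ps$participant_b, ps$timestamp_s)
  ps <- ps[!duplicated(key), , drop = FALSE]
  groups <- data.frame(participant_id = ids,
                       group_id = paste0("G", sample.int(n_groups,
                                                         n_participants,
                                                         replace = TRUE)),
                       stringsAsFactors = FALSE)
  list(pairsec = ps, groups = groups, participants = ids)
}

# aggregate pipeline contacts onto ground-truth participant ids so that
# split observed sessions of one true participant are re-identified
contacts_on_truth_ids <- function(contacts, mapping) {
  if (nrow(contacts) == 0) return(empty_contacts()[, 1:3])
  a <- unname(mapping[contacts$participant_a])
  b <- unname(mapping[contacts$participant_b])
  df <- data.frame(participant_a = pmin(a, b), participant_b = pmax(a, b),
                   contact_seconds = contacts$contact_seconds,
                   stringsAsFactors = FALSE)
  agg <- aggregate(contact_seconds ~ participant_a + participant_b, df, sum)
  agg <- agg[order(agg$participant_a, agg$participant_b), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# run the full pre-processing chain on an in-memory record table
run_pipeline_records <- function(records, gap_threshold_s = 120,
                                 params = group_params(),
                                 threshold_cm = 150) {
  sessions <- sessionize(records, gap_threshold_s)
  annotated <- assign_participants(records, sessions)
  pairsec <- symmetrize(annotated)
  det <- detect_groups(pairsec, sessions, params)
  contacts <- extract_contacts(pairsec, det$groups, threshold_cm)
  list(sessions = sessions, pairsec = pairsec, groups = det$groups,
       contacts = contacts)
}
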