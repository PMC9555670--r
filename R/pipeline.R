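#' Pipeline configuration
#'
#' One structured configuration drives the whole pipeline: per-condition
#' raw-log paths (or synthetic-stream settings), the pre-processing
#' constants, the contact threshold, analysis windows and the MCMC
#' settings. Every analysis constant is a named default here, never
#' hard-coded downstream.
#'
#' @param conditions named list; each element a list with fields `raw_log`
#'   (CSV path; filled in by [pipeline_simulate()] for synthetic runs),
#'   optional `window` (`c(t0, t1)` seconds, half-open), optional `stream`
#'   (argument list for [stream_config()]), optional `ratings` (numeric
#'   vector of experience ratings).
#' @param output_dir directory for all written artifacts.
#' @param gap_threshold_s sessionization gap, seconds (default 120).
#' @param group arguments for [group_params()] (list; defaults apply).
#' @param threshold_cm contact distance threshold, cm (default 150,
#'   strict `<`).
#' @param min_contact_seconds minimum summed contact seconds per dyad
#'   (default 1).
#' @param b2 arguments for [b2_spec()] (list; defaults apply).
#' @param seed master seed (default 1).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(conditions, output_dir = tempdir(),
                            gap_threshold_s = 120, group = list(),
                            threshold_cm = 150, min_contact_seconds = 1,
                            b2 = list(), seed = 1) {
  stopifnot(is.list(conditions), length(conditions) >= 1,
            !is.null(names(conditions)))
  structure(list(conditions = conditions, output_dir = output_dir,
                 gap_threshold_s = gap_threshold_s, group = group,
                 threshold_cm = threshold_cm,
                 min_contact_seconds = min_contact_seconds,
                 b2 = b2, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring the [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$conditions)) stop("config is missing the 'conditions' field")
  do.call(pipeline_config, y)
}

log_stage <- function(...) message("[proxnet] ", ...)

#' Simulate raw logs for every configured condition
#'
#' Each condition with a `stream` block gets a synthetic raw log and a
#' ground-truth JSON written under the output directory; the condition's
#' `raw_log` path is filled in. Per-condition seeds are derived from the
#' master seed so the run is reproducible as a whole.
#'
#' @param config a [pipeline_config()].
#' @return the config with `raw_log` paths set, plus the simulation truths
#'   attached as attribute `"truths"`.
#' @export
pipeline_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cond_seeds <- sample.int(.Machine$integer.max - 1L,
                           length(config$conditions))
  truths <- list()
  for (i in seq_along(config$conditions)) {
    nm <- names(config$conditions)[i]
    cond <- config$conditions[[i]]
    if (is.null(cond$stream)) next
    args <- cond$stream
    args$condition_label <- nm
    if (is.null(args$seed)) args$seed <- cond_seeds[i]
    cfg <- do.call(stream_config, args)
    sim <- simulate_tag_stream(cfg)
    raw_path <- file.path(config$output_dir, paste0(nm, "_raw.csv"))
    write_raw_log(sim$records, raw_path)
    write_ground_truth(sim$truth,
                       file.path(config$output_dir, paste0(nm, "_truth.json")))
    config$conditions[[i]]$raw_log <- raw_path
    truths[[nm]] <- sim$truth
    log_stage("simulate[", nm, "]: ", nrow(sim$records), " records, ",
              nrow(sim$truth$sessions), " participants, ",
              sim$truth$n_dropped_no_tag, " dropped (no free tag)")
  }
  attr(config, "truths") <- truths
  config
}

#' Pre-process one condition's raw log
#'
#' Chains the pre-processing stages in order: parse, sessionize, assign
#' participants, merge reciprocal reports, detect and exclude groups,
#' extract between-group contacts. Every filter logs how many records or
#' pairs it dropped, and all intermediate tables are written as CSVs.
#'
#' @param config a [pipeline_config()].
#' @param condition condition name; default all conditions.
#' @return for one condition, a list `sessions`, `pairsec`, `groups`,
#'   `criteria`, `contacts`; for several, a named list of those.
#' @export
pipeline_preprocess <- function(config, condition = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(condition)) {
    res <- lapply(names(config$conditions),
                  function(nm) pipeline_preprocess(config, nm))
    names(res) <- names(config$conditions)
    return(res)
  }
  cond <- config$conditions[[condition]]
  if (is.null(cond)) stop("unknown condition: ", condition)
  if (is.null(cond$raw_log)) {
    stop("condition '", condition, "' has no raw_log; run pipeline_simulate")
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  records <- parse_raw_log(cond$raw_log)
  log_stage("preprocess[", condition, "]: ", nrow(records), " records (",
            attr(records, "n_self_reports"), " self-reports dropped)")
  sessions <- sessionize(records, config$gap_threshold_s)
  log_stage("preprocess[", condition, "]: ", nrow(sessions),
            " sessions over ", length(unique(sessions$tag_id)), " tags")
  annotated <- assign_participants(records, sessions)
  pairsec <- symmetrize(annotated)
  params <- do.call(group_params, config$group)
  det <- detect_groups(pairsec, sessions, params)
  n_grouped <- sum(table(det$groups$group_id) > 1)
  log_stage("preprocess[", condition, "]: ",
            sum(duplicated(det$groups$group_id)),
            " participants folded into ", n_grouped, " multi-member groups")
  contacts <- extract_contacts(pairsec, det$groups, config$threshold_cm,
                               config$min_contact_seconds)
  log_stage("preprocess[", condition, "]: ", nrow(contacts),
            " contact dyads")
  pre <- paste0(condition, "_")
  utils::write.csv(sessions,
                   file.path(config$output_dir, paste0(pre, "sessions.csv")),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(det$groups,
                   file.path(config$output_dir, paste0(pre, "groups.csv")),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(det$criteria,
                   file.path(config$output_dir, paste0(pre, "criteria.csv")),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(contacts,
                   file.path(config$output_dir, paste0(pre, "contacts.csv")),
                   row.names = FALSE, quote = FALSE)
  list(sessions = sessions, pairsec = pairsec, groups = det$groups,
       criteria = det$criteria, contacts = contacts)
}

condition_slice <- function(config, condition, pp) {
  cond <- config$conditions[[condition]]
  if (!is.null(cond$window)) {
    w <- select_window(pp$sessions, pp$pairsec, pp$groups,
                       cond$window[1], cond$window[2],
                       config$threshold_cm, config$min_contact_seconds)
    list(participants = w$participants, contacts = w$contacts)
  } else {
    list(participants = pp$sessions$participant_id, contacts = pp$contacts)
  }
}

#' Compare two conditions
#'
#' Builds the two condition networks (restricted to each condition's
#' analysis window when configured), stacks them with a condition dummy,
#' fits the b2 model, and assembles a report: per-condition descriptives of
#' degrees and per-dyad contact durations (range, mean, SD, median, IQR),
#' the odds ratio with its 95% credible interval, a Mann-Whitney test on
#' the per-dyad contact durations, a Welch t test on experience ratings
#' when both conditions carry them, and an echo of every parameter and
#' seed. The report is also written as JSON.
#'
#' @param config a [pipeline_config()].
#' @param condition_a,condition_b condition names; the dummy is 0 for
#'   `condition_a` actors and 1 for `condition_b` actors, so an odds ratio
#'   below 1 means fewer contacts under `condition_b`.
#' @param preprocessed optional output of `pipeline_preprocess(config)`,
#'   to avoid recomputation.
#' @return the report as a list (class `proxnet_report`), with the fitted
#'   `b2_fit` attached as attribute `"fit"`.
#' @export
pipeline_compare <- function(config, condition_a, condition_b,
                             preprocessed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  for (nm in c(condition_a, condition_b)) {
    if (is.null(config$conditions[[nm]])) stop("unknown condition: ", nm)
  }
  if (is.null(preprocessed)) {
    preprocessed <- list()
    preprocessed[[condition_a]] <- pipeline_preprocess(config, condition_a)
    preprocessed[[condition_b]] <- pipeline_preprocess(config, condition_b)
  }
  sl_a <- condition_slice(config, condition_a, preprocessed[[condition_a]])
  sl_b <- condition_slice(config, condition_b, preprocessed[[condition_b]])
  # participant ids are unique per condition only; prefix to keep the
  # stacked actor set disjoint
  relabel <- function(sl, prefix) {
    sl$participants <- paste0(prefix, sl$participants)
    if (nrow(sl$contacts) > 0) {
      sl$contacts$participant_a <- paste0(prefix, sl$contacts$participant_a)
      sl$contacts$participant_b <- paste0(prefix, sl$contacts$participant_b)
    }
    sl
  }
  sl_a <- relabel(sl_a, paste0(condition_a, ":"))
  sl_b <- relabel(sl_b, paste0(condition_b, ":"))
  net_a <- build_network(sl_a$participants, sl_a$contacts)
  net_b <- build_network(sl_b$participants, sl_b$contacts)
  net <- combine_networks(net_a, net_b, dummy_name = "condition")
  spec <- do.call(b2_spec, c(config$b2,
                             if (is.null(config$b2$seed)) {
                               list(seed = config$seed)
                             }))
  fit <- fit_b2(net, spec)
  or <- summarize_or(fit, "condition")

  deg_a <- participant_degree(sl_a$contacts, sl_a$participants)
  deg_b <- participant_degree(sl_b$contacts, sl_b$participants)
  descr <- function(sl, deg) {
    list(n_participants = length(sl$participants),
         n_contact_dyads = nrow(sl$contacts),
         degrees = describe_sample(deg$n_unique_contacts),
         durations = describe_sample(sl$contacts$contact_seconds))
  }
  dur_a <- sl_a$contacts$contact_seconds
  dur_b <- sl_b$contacts$contact_seconds
  mwu <- if (length(dur_a) > 0 && length(dur_b) > 0) {
    res <- mann_whitney_u(dur_a, dur_b)
    list(U = unname(res$statistic), p_value = res$p.value,
         method = res$method, n1 = res$n1, n2 = res$n2)
  }
  r_a <- config$conditions[[condition_a]]$ratings
  r_b <- config$conditions[[condition_b]]$ratings
  welch <- if (length(r_a) >= 2 && length(r_b) >= 2) {
    res <- welch_t(r_a, r_b)
    list(t = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value)
  }
  report <- list(
    comparison = list(condition_a = condition_a, condition_b = condition_b),
    descriptives = stats::setNames(list(descr(sl_a, deg_a),
                                        descr(sl_b, deg_b)),
                                   c(condition_a, condition_b)),
    b2 = list(or_point = or$or_point, ci_low = or$ci_low,
              ci_high = or$ci_high, formatted = or$formatted),
    mann_whitney_durations = mwu,
    welch_ratings = welch,
    parameters = list(gap_threshold_s = config$gap_threshold_s,
                      threshold_cm = config$threshold_cm,
                      min_contact_seconds = config$min_contact_seconds,
                      group = unclass(do.call(group_params, config$group)),
                      b2 = unclass(spec)),
    seed = config$seed)
  class(report) <- "proxnet_report"
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    unclass(report),
    file.path(config$output_dir,
              paste0("compare_", condition_a, "_vs_", condition_b, ".json")),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null")
  attr(report, "fit") <- fit
  report
}

#' @export
print.proxnet_report <- function(x, ...) {
  cat("Condition comparison:", x$comparison$condition_a, "vs",
      x$comparison$condition_b, "\n")
  for (nm in names(x$descriptives)) {
    d <- x$descriptives[[nm]]
    cat(sprintf("  %s: %d participants, %d contact dyads, median degree %s\n",
                nm, d$n_participants, d$n_contact_dyads,
                format(d$degrees$median)))
  }
  cat(" ", x$b2$formatted, "\n")
  if (!is.null(x$mann_whitney_durations)) {
    cat(sprintf("  durations: U = %g, p = %.4g\n",
                x$mann_whitney_durations$U, x$mann_whitney_durations$p_value))
  }
  if (!is.null(x$welch_ratings)) {
    cat(sprintf("  ratings: t(%.2f) = %.3f, p = %.4g\n",
                x$welch_ratings$df, x$welch_ratings$t,
                x$welch_ratings$p_value))
  }
  invisible(x)
}
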