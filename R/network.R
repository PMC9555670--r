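#' Construct a contact network
#'
#' An undirected, unweighted contact network: actors are participants, an
#' edge links two actors iff they had at least one between-group contact.
#' Contact durations are kept as optional edge weights but play no role in
#' the dyadic model ("a contact is binary"). The `dyad_mask` marks which
#' dyads are eligible, i.e. enter the likelihood; for a single-condition
#' network all off-diagonal dyads are eligible.
#'
#' @param participants ordered character vector of actor ids.
#' @param contacts dyad table from [extract_contacts()] (may be empty).
#' @param covariates optional numeric matrix or data frame, one row per
#'   actor, actor-level covariates (e.g. a condition dummy).
#' @return object of class `contact_network` with fields `actors`,
#'   `adjacency` (symmetric 0/1 matrix, zero diagonal), `weights` (duration
#'   seconds where edges exist, else 0), `covariates` (n-by-k matrix) and
#'   `dyad_mask` (symmetric logical matrix of eligible dyads).
#' @export
build_network <- function(participants, contacts, covariates = NULL) {
  actors <- unique(as.character(participants))
  n <- length(actors)
  unknown <- setdiff(unique(c(contacts$participant_a, contacts$participant_b)),
                     actors)
  if (length(unknown)) {
    stop("contacts reference unknown participant(s): ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  adj <- matrix(0L, n, n, dimnames = list(actors, actors))
  w <- matrix(0L, n, n, dimnames = list(actors, actors))
  if (nrow(contacts) > 0) {
    ia <- match(contacts$participant_a, actors)
    ib <- match(contacts$participant_b, actors)
    adj[cbind(ia, ib)] <- 1L
    adj[cbind(ib, ia)] <- 1L
    w[cbind(ia, ib)] <- contacts$contact_seconds
    w[cbind(ib, ia)] <- contacts$contact_seconds
  }
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0,
                         dimnames = list(actors, NULL))
  } else {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    rownames(covariates) <- actors
  }
  mask <- matrix(TRUE, n, n, dimnames = list(actors, actors))
  diag(mask) <- FALSE
  structure(list(actors = actors, adjacency = adj, weights = w,
                 covariates = covariates, dyad_mask = mask),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  n <- length(x$actors)
  n_edges <- sum(x$adjacency[upper.tri(x$adjacency)])
  n_elig <- sum(x$dyad_mask[upper.tri(x$dyad_mask)])
  cat("Contact network: ", n, " actors, ", n_edges, " edges, ",
      n_elig, " eligible dyads", sep = "")
  if (ncol(x$covariates) > 0) {
    cat(", covariates: ", paste(colnames(x$covariates), collapse = ", "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Stack two condition networks for comparison
#'
#' Combines the networks of two conditions (e.g. two study days) into one
#' block network. Participants of different days were never co-present, so
#' cross-network dyads are structurally excluded via `dyad_mask` rather than
#' coded as observed zeros — treating them as non-contacts would bias the
#' density estimate. A new actor-level dummy covariate is 0 for `net_a`
#' actors and 1 for `net_b` actors; existing covariates shared by name are
#' carried over.
#'
#' @param net_a,net_b `contact_network` objects with disjoint actor sets.
#' @param dummy_name name for the condition dummy covariate.
#' @return a `contact_network` over the union of actors (`net_a` first).
#' @export
combine_networks <- function(net_a, net_b, dummy_name = "condition") {
  stopifnot(inherits(net_a, "contact_network"),
            inherits(net_b, "contact_network"))
  if (length(intersect(net_a$actors, net_b$actors)) > 0) {
    stop("actor id collision between the two networks")
  }
  na <- length(net_a$actors); nb <- length(net_b$actors)
  n <- na + nb
  actors <- c(net_a$actors, net_b$actors)
  adj <- matrix(0L, n, n, dimnames = list(actors, actors))
  w <- matrix(0L, n, n, dimnames = list(actors, actors))
  mask <- matrix(FALSE, n, n, dimnames = list(actors, actors))
  ia <- seq_len(na); ib <- na + seq_len(nb)
  adj[ia, ia] <- net_a$adjacency; adj[ib, ib] <- net_b$adjacency
  w[ia, ia] <- net_a$weights; w[ib, ib] <- net_b$weights
  mask[ia, ia] <- net_a$dyad_mask; mask[ib, ib] <- net_b$dyad_mask
  shared <- intersect(colnames(net_a$covariates), colnames(net_b$covariates))
  cov <- cbind(matrix(c(rep(0, na), rep(1, nb)), ncol = 1,
                      dimnames = list(actors, dummy_name)))
  for (nm in shared) {
    cov <- cbind(cov, stats::setNames(
      c(net_a$covariates[, nm], net_b$covariates[, nm]), NULL))
    colnames(cov)[ncol(cov)] <- nm
  }
  structure(list(actors = actors, adjacency = adj, weights = w,
                 covariates = cov, dyad_mask = mask),
            class = "contact_network")
}

#' Write / read a contact network as edge and node CSVs
#'
#' The edge file has header `actor_a,actor_b,weight` (one row per edge,
#' weight in integer seconds); the node file has `actor` followed by one
#' column per covariate. The round trip is lossless for single-condition
#' networks (an all-eligible `dyad_mask` is implied).
#'
#' @param network a `contact_network`.
#' @param edge_path,node_path output CSV paths.
#' @return (write) invisibly the paths; (read) a `contact_network`.
#' @export
write_edge_list <- function(network, edge_path, node_path) {
  ut <- upper.tri(network$adjacency)
  idx <- which(network$adjacency == 1L & ut, arr.ind = TRUE)
  edges <- data.frame(actor_a = network$actors[idx[, 1]],
                      actor_b = network$actors[idx[, 2]],
                      weight = network$weights[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$actor_a, edges$actor_b), , drop = FALSE]
  utils::write.csv(edges, edge_path, row.names = FALSE, quote = FALSE)
  nodes <- data.frame(actor = network$actors, stringsAsFactors = FALSE)
  if (ncol(network$covariates) > 0) {
    nodes <- cbind(nodes, as.data.frame(network$covariates,
                                        row.names = NULL))
  }
  utils::write.csv(nodes, node_path, row.names = FALSE, quote = FALSE)
  invisible(c(edge_path, node_path))
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(edge_path, node_path) {
  edges <- utils::read.csv(edge_path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "integer"))
  nodes <- utils::read.csv(node_path, stringsAsFactors = FALSE,
                           colClasses = c(actor = "character"))
  dangling <- setdiff(unique(c(edges$actor_a, edges$actor_b)), nodes$actor)
  if (length(dangling)) {
    stop("edge list references unknown actor(s): ",
         paste(utils::head(dangling, 3), collapse = ", "))
  }
  cov <- NULL
  if (ncol(nodes) > 1) {
    cov <- as.matrix(nodes[, -1, drop = FALSE])
  }
  contacts <- data.frame(participant_a = pmin(edges$actor_a, edges$actor_b),
                         participant_b = pmax(edges$actor_a, edges$actor_b),
                         contact_seconds = edges$weight,
                         first_s = rep(NA_integer_, nrow(edges)),
                         last_s = rep(NA_integer_, nrow(edges)),
                         stringsAsFactors = FALSE)
  build_network(nodes$actor, contacts, cov)
}
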