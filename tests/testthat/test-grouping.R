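test_that("pair criteria follow the 10-contacts / 25% / 60-s rules", {
  # A: visit [0, 99] (100 s), B: visit [0, 129]; 12 s at 70 cm;
  # exits 30 s apart -> close TRUE (12 >= 10), prox FALSE (12/100 < 0.25),
  # coexit TRUE
  sessions <- make_sessions(c("A#1", "B#1"), c("A", "B"), c(0, 0), c(99, 129))
  ps <- make_pairsec(rep("A#1", 12), rep("B#1", 12), 0:11, rep(70, 12))
  cr <- evaluate_pair_criteria(ps, sessions, group_params())
  expect_equal(nrow(cr), 1)
  expect_true(cr$c_close)
  expect_false(cr$c_prox)
  expect_true(cr$c_coexit)
  expect_equal(cr$n_met, 2L)

  # 9 s at 70 cm only: "at least 10" is strict, so c_close is FALSE
  ps9 <- make_pairsec(rep("A#1", 9), rep("B#1", 9), 0:8, rep(70, 9))
  cr9 <- evaluate_pair_criteria(ps9, sessions, group_params())
  expect_false(cr9$c_close)

  # no proximity records, exits 500 s apart: all criteria false
  s2 <- make_sessions(c("A#1", "B#1"), c("A", "B"), c(0, 0), c(100, 600))
  cr0 <- evaluate_pair_criteria(make_pairsec(character(), character(),
                                             integer(), integer()),
                                s2, group_params())
  expect_equal(cr0$n_met, 0L)
  expect_false(any(cr0$c_close, cr0$c_prox, cr0$c_coexit))
})

test_that("proximity fraction uses the shorter visit as denominator", {
  # B visits only 40 s; 12 proximate seconds = 30% of B's visit
  sessions <- make_sessions(c("A#1", "B#1"), c("A", "B"), c(0, 0), c(199, 39))
  ps <- make_pairsec(rep("A#1", 12), rep("B#1", 12), 0:11, rep(120, 12))
  cr <- evaluate_pair_criteria(ps, sessions, group_params())
  expect_true(cr$c_prox)    # 12 >= 0.25 * 40
  expect_false(cr$c_close)  # 120 cm is outside the 80 cm close range
})

test_that("criterion boundaries: 80 cm inclusive, 150 cm strict", {
  sessions <- make_sessions(c("A#1", "B#1"), c("A", "B"), c(0, 0), c(39, 39))
  at80 <- make_pairsec(rep("A#1", 10), rep("B#1", 10), 0:9, rep(80, 10))
  expect_true(evaluate_pair_criteria(at80, sessions, group_params())$c_close)
  at150 <- make_pairsec(rep("A#1", 10), rep("B#1", 10), 0:9, rep(150, 10))
  expect_false(evaluate_pair_criteria(at150, sessions, group_params())$c_prox)
  at149 <- make_pairsec(rep("A#1", 10), rep("B#1", 10), 0:9, rep(149, 10))
  expect_true(evaluate_pair_criteria(at149, sessions, group_params())$c_prox)
})

test_that("non-overlapping sessions are never evaluated as a pair", {
  sessions <- make_sessions(c("A#1", "B#1"), c("A", "B"),
                            c(0, 200), c(100, 300))
  cr <- evaluate_pair_criteria(make_pairsec(character(), character(),
                                            integer(), integer()),
                               sessions, group_params())
  expect_equal(nrow(cr), 0)
})

test_that("group assignment takes connected components", {
  crit <- data.frame(participant_a = c("A", "B"), participant_b = c("B", "C"),
                     c_close = TRUE, c_prox = TRUE, c_coexit = FALSE,
                     n_met = 2L, stringsAsFactors = FALSE)
  g <- assign_groups(crit, c("A", "B", "C", "D"))
  expect_equal(g$group_id[g$participant_id == "A"],
               g$group_id[g$participant_id == "C"])
  expect_false(g$group_id[g$participant_id == "D"] %in%
                 g$group_id[g$participant_id != "D"])

  # no qualifying pairs: everyone a singleton
  g0 <- assign_groups(crit[0, ], c("A", "B", "C"))
  expect_equal(length(unique(g0$group_id)), 3)

  # one qualifying pair among 5 participants: {A,B} plus 3 singletons
  crit1 <- crit[1, ]
  g1 <- assign_groups(crit1, c("A", "B", "C", "D", "E"))
  expect_equal(length(unique(g1$group_id)), 4)
  expect_equal(g1$group_id[g1$participant_id == "A"],
               g1$group_id[g1$participant_id == "B"])
})

test_that("group assignment is a partition and agrees with igraph", {
  set.seed(99)
  ids <- sprintf("p%02d", 1:15)
  for (rep in 1:5) {
    n_edges <- sample(0:12, 1)
    ab <- t(replicate(max(n_edges, 1), sample(ids, 2)))
    crit <- data.frame(participant_a = pmin(ab[, 1], ab[, 2]),
                       participant_b = pmax(ab[, 1], ab[, 2]),
                       c_close = TRUE, c_prox = TRUE, c_coexit = FALSE,
                       n_met = 2L, stringsAsFactors = FALSE)
    if (n_edges == 0) crit <- crit[0, ]
    g <- assign_groups(crit, ids)
    expect_setequal(g$participant_id, ids)
    expect_false(any(duplicated(g$participant_id)))
    gr <- igraph::graph_from_data_frame(crit[, 1:2], directed = FALSE,
                                        vertices = ids)
    memb <- igraph::components(gr)$membership[g$participant_id]
    # same partition up to label names
    expect_equal(length(unique(g$group_id)), length(unique(memb)))
    expect_true(all(tapply(memb, g$group_id,
                           function(z) length(unique(z))) == 1))
  }
})

test_that("lowering min_criteria never splits an existing group", {
  set.seed(5)
  ids <- sprintf("p%02d", 1:12)
  ab <- t(replicate(15, sample(ids, 2)))
  crit <- data.frame(participant_a = pmin(ab[, 1], ab[, 2]),
                     participant_b = pmax(ab[, 1], ab[, 2]),
                     stringsAsFactors = FALSE)
  crit$c_close <- sample(c(TRUE, FALSE), 15, TRUE)
  crit$c_prox <- sample(c(TRUE, FALSE), 15, TRUE)
  crit$c_coexit <- sample(c(TRUE, FALSE), 15, TRUE)
  crit$n_met <- with(crit, c_close + c_prox + c_coexit)
  for (m in 3:2) {
    g_hi <- assign_groups(crit, ids, min_criteria = m)
    g_lo <- assign_groups(crit, ids, min_criteria = m - 1)
    hi <- setNames(g_hi$group_id, g_hi$participant_id)
    lo <- setNames(g_lo$group_id, g_lo$participant_id)
    # any pair grouped at the stricter level stays grouped at the looser one
    for (i in seq_along(ids)) {
      same_hi <- names(hi)[hi == hi[ids[i]]]
      expect_true(all(lo[same_hi] == lo[ids[i]]))
    }
  }
})
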