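two_group_map <- function() {
  data.frame(participant_id = c("A", "B", "C", "D"),
             group_id = c("G1", "G2", "G3", "G4"),
             stringsAsFactors = FALSE)
}

test_that("contact seconds use the strict 150 cm threshold", {
  ps <- make_pairsec(rep("A", 3), rep("B", 3), 1:3, c(140, 160, 149))
  ct <- extract_contacts(ps, two_group_map())
  expect_equal(nrow(ct), 1)
  expect_equal(ct$contact_seconds, 2L)
  expect_equal(c(ct$first_s, ct$last_s), c(1L, 3L))

  at150 <- make_pairsec("A", "B", 1, 150)
  expect_equal(nrow(extract_contacts(at150, two_group_map())), 0)
})

test_that("within-group pairs are excluded from contacts", {
  g <- data.frame(participant_id = c("A", "B"), group_id = c("G1", "G1"),
                  stringsAsFactors = FALSE)
  ps <- make_pairsec(rep("A", 100), rep("B", 100), 1:100, rep(30, 100))
  expect_equal(nrow(extract_contacts(ps, g)), 0)
})

test_that("durations sum non-contiguous qualifying seconds", {
  ps <- make_pairsec(rep("A", 5), rep("B", 5),
                     c(1, 2, 50, 51, 52), rep(100, 5))
  ct <- extract_contacts(ps, two_group_map())
  expect_equal(ct$contact_seconds, 5L)
  expect_equal(c(ct$first_s, ct$last_s), c(1L, 52L))
})

test_that("min_contact_seconds filters short dyads", {
  ps <- rbind(make_pairsec("A", "B", 1, 100),
              make_pairsec(rep("A", 3), rep("C", 3), 1:3, rep(100, 3)))
  ct <- extract_contacts(ps, two_group_map(), min_contact_seconds = 2)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$participant_b, "C")
})

test_that("participant degree counts distinct partners, zeros included", {
  ct <- rbind(make_pairsec("A", "B", 1, 1), make_pairsec("A", "C", 1, 1))
  contacts <- data.frame(participant_a = c("A", "A"),
                         participant_b = c("B", "C"),
                         contact_seconds = c(5L, 7L),
                         first_s = 1L, last_s = 9L,
                         stringsAsFactors = FALSE)
  deg <- participant_degree(contacts, c("A", "B", "C", "D"))
  expect_equal(setNames(deg$n_unique_contacts, deg$participant_id),
               c(A = 2L, B = 1L, C = 1L, D = 0L))
  expect_equal(sort(deg$durations[[1]]), c(5L, 7L))
  expect_equal(deg$n_unique_contacts,
               vapply(deg$durations, length, 1L))

  deg0 <- participant_degree(empty_contacts(), c("A", "B"))
  expect_true(all(deg0$n_unique_contacts == 0))
})

test_that("degree sum equals twice the dyad count (handshake lemma)", {
  set.seed(31)
  for (rep in 1:5) {
    inst <- random_contact_instance(12, 100, 300)
    ct <- extract_contacts(inst$pairsec, inst$groups)
    deg <- participant_degree(ct, inst$participants)
    expect_equal(sum(deg$n_unique_contacts), 2 * nrow(ct))
  }
})

test_that("extract_contacts matches the brute-force per-second oracle", {
  set.seed(17)
  for (rep in 1:8) {
    inst <- random_contact_instance(sample(5:15, 1), sample(50:200, 1),
                                    sample(100:500, 1))
    expect_equal(extract_contacts(inst$pairsec, inst$groups),
                 brute_force_contacts(inst$pairsec, inst$groups))
  }
})

test_that("select_window intersects sessions and truncates durations", {
  sessions <- make_sessions(c("A", "B", "C"), c("tA", "tB", "tC"),
                            c(0, 0, 0), c(200, 200, 100))
  ps <- make_pairsec(rep("A", 11), rep("B", 11), 95:105, rep(100, 11))
  g <- two_group_map()

  # window covering everything: identity
  w_all <- select_window(sessions, ps, g, 0, 1000)
  expect_setequal(w_all$participants, c("A", "B", "C"))
  expect_equal(w_all$contacts$contact_seconds, 11L)

  # half-open window [100, 200): seconds 100..105 remain
  w <- select_window(sessions, ps, g, 100, 200)
  expect_equal(w$contacts$contact_seconds, 6L)

  # session [0, 100] vs window [200, 300): excluded
  s1 <- make_sessions("A", "tA", 0, 100)
  expect_length(select_window(s1, ps[0, ], g, 200, 300)$participants, 0)
})

test_that("narrowing the window never increases durations or degrees", {
  set.seed(23)
  inst <- random_contact_instance(10, 200, 400)
  sessions <- make_sessions(inst$participants, inst$participants,
                            rep(0, 10), rep(200, 10))
  wide <- select_window(sessions, inst$pairsec, inst$groups, 0, 200)
  narrow <- select_window(sessions, inst$pairsec, inst$groups, 50, 150)
  wd <- setNames(wide$contacts$contact_seconds,
                 paste(wide$contacts$participant_a,
                       wide$contacts$participant_b))
  nd <- setNames(narrow$contacts$contact_seconds,
                 paste(narrow$contacts$participant_a,
                       narrow$contacts$participant_b))
  expect_true(all(names(nd) %in% names(wd)))
  expect_true(all(nd <= wd[names(nd)]))
})

test_that("hourly summary reports participant count and median degree", {
  sessions <- make_sessions(c("A", "B", "C"), c("tA", "tB", "tC"),
                            c(0, 0, 0), c(3000, 3000, 3000))
  # one contact dyad A-B inside hour 0; C present with no contacts
  ps <- make_pairsec(rep("A", 5), rep("B", 5), 10:14, rep(100, 5))
  hs <- hourly_summary(sessions, ps, two_group_map(), c(0, 3600))
  expect_equal(hs$n_participants, c(3L, 0L))
  expect_equal(hs$median_degree[1], 1)   # degrees 1, 1, 0
  expect_true(is.na(hs$median_degree[2]))
  expect_error(hourly_summary(sessions, ps, two_group_map(), 100),
               "3600")
})

test_that("describe_sample reports range, mean, sd, median and IQR", {
  d <- describe_sample(c(2, 4, 6, 8, 20))
  expect_equal(d$n, 5L)
  expect_equal(c(d$min, d$max), c(2, 20))
  expect_equal(d$mean, 8)
  expect_equal(d$sd, sd(c(2, 4, 6, 8, 20)))
  expect_equal(d$median, 6)
  expect_equal(c(d$q25, d$q75), unname(quantile(c(2, 4, 6, 8, 20),
                                                c(0.25, 0.75))))
  expect_equal(describe_sample(numeric(0))$n, 0L)
})
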