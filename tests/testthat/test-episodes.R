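bal_day <- as.Date("2021-03-10")
epi <- list(episode_id = "E1", bal_day = bal_day)

daily <- function(scores, from = bal_day - 2) {
  data.frame(date = seq(from, by = 1, length.out = length(scores)),
             nat = as.integer(scores))
}

test_that("alignment covers the full window when the stay allows", {
  t <- align_trajectory(daily(c(2, 2, 2, 1, 1, 0, 0, 0, -2, -2)), epi)
  expect_identical(as.integer(names(t$scores)), -2:7)
  expect_identical(unname(t$scores[1]), 2L)
  expect_true(is.na(t$end_day))
})

test_that("death or discharge truncates the trajectory", {
  t <- align_trajectory(daily(c(2, 2, 2, 1, 1, 0)), epi,
                        end_of_stay = bal_day + 3)
  expect_identical(as.integer(names(t$scores)), -2:3)
  expect_identical(t$end_day, 3L)
  expect_error(align_trajectory(daily(2), epi, end_of_stay = bal_day - 1),
               "end_of_stay precedes")
})

test_that("admission on the BAL day removes pre-BAL days", {
  t <- align_trajectory(daily(c(2, 1, 1), from = bal_day), epi,
                        admission_day = bal_day)
  expect_identical(min(as.integer(names(t$scores))), 0L)
  expect_error(align_trajectory(daily(2), epi, admission_day = bal_day + 1),
               "admission after")
})

test_that("in-window days without administration rows score -2", {
  t <- align_trajectory(daily(c(2, 1), from = bal_day), epi)
  expect_identical(unname(t$scores[as.character(5)]), -2L)
})

test_that("average NAT covers post-BAL days 1..7 truncated at end of stay", {
  t <- make_traj(c(2, 1, 1, 0, 0, 0, 0))
  expect_equal(average_nat(t), 4 / 7)
  t3 <- align_trajectory(daily(c(2, 2, 2, 1, 1)), epi,
                         end_of_stay = bal_day + 2)
  expect_equal(average_nat(t3), (1 + 1) / 2)
  expect_equal(average_nat(make_traj(rep(-2, 7), day0 = -2L,
                                     pre = c(-2L, -2L))), -2)
  # day 0 and pre-BAL days never contribute
  hi <- make_traj(c(0, 0, 0, 0, 0, 0, 0), day0 = 4L, pre = c(4L, 4L))
  expect_equal(average_nat(hi), 0)
  day0_only <- align_trajectory(daily(2, from = bal_day), epi,
                                end_of_stay = bal_day)
  expect_warning(res <- average_nat(day0_only), "no post-BAL days")
  expect_true(is.na(res))
})

test_that("average NAT lies within the range of included scores", {
  set.seed(5)
  for (i in 1:50) {
    post <- sample(-2:4, 7, replace = TRUE)
    t <- make_traj(post)
    a <- average_nat(t)
    expect_gte(a, min(post)); expect_lte(a, max(post))
    # invariant to pre-BAL/day-0 content
    t2 <- make_traj(post, day0 = 4L, pre = c(-2L, 4L))
    expect_identical(a, average_nat(t2))
  }
})

test_that("per-day summaries match a sort-based quantile oracle", {
  set.seed(9)
  trajs <- lapply(1:10, function(i) {
    make_traj(sample(-2:4, 7, replace = TRUE),
              day0 = sample(0:3, 1), id = paste0("E", i))
  })
  s <- summarize_by_day(trajs)
  for (d in c(-2, 0, 3, 7)) {
    vals <- vapply(trajs, function(t) t$scores[[as.character(d)]], integer(1))
    row <- s[s$rel_day == d, ]
    expect_equal(row$median, oracle_quantile(vals, 0.5))
    expect_equal(row$q1, oracle_quantile(vals, 0.25))
    expect_equal(row$q3, oracle_quantile(vals, 0.75))
    expect_identical(row$n, length(vals))
    expect_lte(row$q1, row$median); expect_lte(row$median, row$q3)
  }
  # single trajectory: median == quartiles == its score
  one <- summarize_by_day(trajs[1])
  expect_true(all(one$q1 == one$median & one$median == one$q3))
  # day-0 median over {1,2,3} is 2
  three <- lapply(1:3, function(i) make_traj(rep(0L, 7), day0 = i))
  expect_equal(summarize_by_day(three)[summarize_by_day(three)$rel_day == 0,
                                       "median"], 2)
  # grouping splits episodes
  g <- summarize_by_day(trajs, rep(c("a", "b"), 5))
  expect_setequal(unique(g$group), c("a", "b"))
})

test_that("de-escalation compares the post-BAL running minimum to day 0", {
  expect_true(deescalated_by(make_traj(c(1, 1, 1, 1, 1, 1, 1)), 1))
  t <- make_traj(c(2, 2, 2, 1, 1, 1, 1))
  expect_false(deescalated_by(t, 1))
  expect_true(deescalated_by(t, 4))
  flat0 <- make_traj(rep(0L, 7), day0 = 0L, pre = c(0L, 0L))
  for (k in 1:7) expect_false(deescalated_by(flat0, k))
  # a transient drop still counts as de-escalation thereafter
  vee <- make_traj(c(1, 2, 2, 2, 2, 2, 2))
  expect_true(deescalated_by(vee, 4))
})

test_that("de-escalation is monotone in k", {
  set.seed(13)
  for (i in 1:50) {
    t <- make_traj(sample(-2:3, 7, replace = TRUE), day0 = sample(0:3, 1))
    hits <- vapply(1:7, function(k) deescalated_by(t, k), logical(1))
    expect_true(all(diff(hits) >= 0))
  }
})

test_that("cessation requires sustained -2 through day k", {
  expect_true(cessation_by(make_traj(c(1, 0, -2, -2, -2, -2, -2)), 5))
  expect_false(cessation_by(make_traj(c(1, 0, -2, 0, 0, 0, 0)), 5))
  all_off <- make_traj(rep(-2L, 7), day0 = -2L)
  for (k in 1:7) expect_true(cessation_by(all_off, k))
})

test_that("cessation implies de-escalation when day 0 had antibiotics", {
  set.seed(17)
  for (i in 1:50) {
    t <- make_traj(sample(c(-2L, -2L, 0L, 1L), 7, replace = TRUE),
                   day0 = sample(0:2, 1))
    for (k in c(3, 5, 7)) {
      if (cessation_by(t, k)) expect_true(deescalated_by(t, k))
    }
  }
})

test_that("eligibility is enforced before de-escalation calls", {
  short <- make_traj(c(1, 1))
  short$scores <- short$scores[as.character(-2:2)]
  expect_error(deescalated_by(short, 4), "does not cover")
  expect_error(cessation_by(short, 5), "does not cover")
})

test_that("the cumulative timeline counts and percentages are exact", {
  trajs <- c(rep(list(make_traj(c(1, 1, 1, 1, 1, 1, 1))), 2),
             rep(list(make_traj(c(2, 2, 2, 1, 1, 1, 1))), 1),
             rep(list(make_traj(rep(2L, 7))), 1))
  tl <- deescalation_timeline(trajs, days = c(1, 4))
  expect_identical(tl$n_deescalated, c(2L, 3L))
  expect_identical(tl$percent, c(50, 75))
  expect_true(all(diff(tl$n_deescalated) >= 0))
  # degenerate mixes
  flat <- rep(list(make_traj(rep(2L, 7))), 5)
  expect_true(all(deescalation_timeline(flat, 1:4)$percent == 0))
  drop1 <- rep(list(make_traj(rep(1L, 7))), 5)
  expect_true(all(deescalation_timeline(drop1, 1:4)$percent == 100))
  expect_error(deescalation_timeline(list()), "no trajectories")
})

test_that("episode tables are validated on read", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(episode_id = "E1", patient_id = "P1",
                   bal_day = "2021-01-01", etiology = "bacterial",
                   resistant = TRUE, setting = "VAP", cured_day7 = NA,
                   extra_pulmonary_infection = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  expect_silent(read_episodes(path))
  df_bad <- df; df_bad$etiology <- "fungal"
  utils::write.csv(df_bad, path, row.names = FALSE)
  expect_error(read_episodes(path), "unknown etiology")
  df_bad <- df; df_bad$etiology <- "viral"  # resistant flag now invalid
  utils::write.csv(df_bad, path, row.names = FALSE)
  expect_error(read_episodes(path), "resistant flag")
})
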