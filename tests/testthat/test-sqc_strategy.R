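test_that("select_strategy reproduces the published worked examples", {
  s <- select_strategy(c(level1 = 5.94, level2 = 5.97))
  expect_equal(s$rules, c("1_3s", "2_2s", "R_4s"))
  expect_equal(s$n_controls, 2L)
  expect_equal(s$run_size, 450L)

  s <- select_strategy(c(level1 = 7.14, level2 = 7.46))
  expect_equal(s$rules, "1_3s")
  expect_equal(s$run_size, 1000L)

  s <- select_strategy(c(level1 = 4.77, level2 = 4.98))
  expect_equal(s$rules, c("1_3s", "2_2s", "R_4s", "4_1s"))
  expect_equal(s$n_controls, 4L)
  expect_equal(s$run_size, 200L)

  expect_error(select_strategy(numeric(0)), "at least one")
})

test_that("sub-three-sigma band flags maximum QC and doubles events", {
  s <- select_strategy(c(2.4, 3.6))
  expect_equal(s$run_size, 23L)
  expect_true(s$max_qc)
  expect_equal(s$events, 2L)
  expect_setequal(s$rules, c("1_3s", "2_2s", "R_4s", "4_1s", "8_x"))
})

test_that("policy overrides replace band rows and unknown bands error", {
  pol <- westgard_policy(list("4>sigma>=3" = list(run_size = 60L)))
  expect_equal(select_strategy(3.5, policy_table = pol)$run_size, 60L)
  expect_error(westgard_policy(list(nonsense = list(run_size = 1))),
               "unknown sigma band")
})

test_that("lower sigma never shrinks the rule set nor grows the run size", {
  sig <- seq(8, 1, by = -0.25)
  strategies <- lapply(sig, select_strategy)
  nrules <- vapply(strategies, \(s) length(s$rules), integer(1))
  runs <- vapply(strategies, \(s) s$run_size, integer(1))
  expect_true(all(diff(nrules) >= 0))
  expect_true(all(diff(runs) <= 0))
})

qc_series_from_z <- function(z_by_run) {
  # z_by_run: list of per-run z vectors (level order); mean 0, sd 1 limits
  obs <- dplyr::bind_rows(lapply(seq_along(z_by_run), function(r) {
    tibble::tibble(run = r,
                   level = paste0("level", seq_along(z_by_run[[r]])),
                   value = z_by_run[[r]])
  }))
  lv <- unique(obs$level)
  qc_run_series(obs, tibble::tibble(level = lv, mean = 0, sd = 1))
}

test_that("rule engine fires the classic Westgard patterns", {
  # 1_3s on a single excursion
  ev <- evaluate_rules(qc_series_from_z(list(c(3.2, 0.1))), "1_3s")
  expect_equal(ev$decision, "reject")
  expect_equal(ev$violated_rules[[1]], "1_3s")

  # 2_2s across two consecutive observations
  ev <- evaluate_rules(qc_series_from_z(list(c(2.1, 2.3))),
                       c("1_3s", "2_2s", "R_4s"))
  expect_equal(ev$decision, "reject")
  expect_equal(ev$violated_rules[[1]], "2_2s")

  # 2_2s also spans runs (one material per run)
  ev <- evaluate_rules(qc_series_from_z(list(2.5, 2.2)), c("1_3s", "2_2s"))
  expect_equal(ev$decision, c("accept", "reject"))

  # R_4s within a run; the same pattern under 1_3s alone passes
  z <- list(c(2.1, -2.2))
  ev <- evaluate_rules(qc_series_from_z(z), c("1_3s", "2_2s", "R_4s"))
  expect_equal(ev$violated_rules[[1]], "R_4s")
  ev <- evaluate_rules(qc_series_from_z(z), "1_3s")
  expect_equal(ev$decision, "accept")

  # 4_1s: four consecutive beyond the same 1 SD limit
  ev <- evaluate_rules(qc_series_from_z(list(c(1.2, 1.4), c(1.1, 1.7))),
                       c("1_3s", "4_1s"))
  expect_equal(ev$decision, c("accept", "reject"))
  expect_equal(ev$violated_rules[[2]], "4_1s")

  # 8_x: eight consecutive on one side of the mean
  ev <- evaluate_rules(
    qc_series_from_z(list(c(-0.2, -0.5), c(-0.1, -0.9),
                          c(-0.4, -0.3), c(-0.6, -0.2))),
    c("1_3s", "8_x"))
  expect_equal(ev$decision, c("accept", "accept", "accept", "reject"))

  expect_error(evaluate_rules(qc_series_from_z(list(c(0, 0))), "9_z"),
               "9_z")
})

test_that("in-control data is accepted everywhere", {
  set.seed(5)
  # magnitudes below 2 with strictly alternating signs: no rule can fire
  z <- replicate(50, pmin(abs(rnorm(2, 0, 0.5)), 1.9) + 0.01,
                 simplify = FALSE)
  z <- lapply(z, \(v) v * c(1, -1))
  ev <- evaluate_rules(qc_series_from_z(z),
                       c("1_3s", "2_2s", "R_4s", "4_1s", "8_x"))
  expect_true(all(ev$decision == "accept"))
  expect_true(all(lengths(ev$violated_rules) == 0))
})

test_that("schedule_qc brackets the day's workload", {
  expect_equal(schedule_qc(450, 900), 2L)
  expect_equal(schedule_qc(1000, 100), 1L)
  expect_equal(schedule_qc(200, 201), 2L)
})
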