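test_that("the related-samples test reproduces the worked assessment", {
  res <- related_samples_test(vox_fixture("table2"))
  expect_equal(unname(res$statistic), 153 / 19)
  expect_equal(unname(res$parameter), 3)
  expect_equal(res$p.value, pchisq(153 / 19, 3, lower.tail = FALSE))
  expect_lt(res$p.value, 0.05)
  expect_equal(res$n_informative_rows, 6)
  expect_false(res$degenerate)
})

test_that("uninformative rows and balanced designs behave as the algebra dictates", {
  # equal column totals from non-constant rows: statistic exactly 0
  bal <- rbind(c(1, 0, 1, 0), c(0, 1, 0, 1), c(1, 1, 0, 0), c(0, 0, 1, 1))
  res <- related_samples_test(bal)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)

  # all-0 / all-1 rows leave the statistic unchanged
  m <- table2_matrix()
  base <- related_samples_test(m)
  with_ones <- related_samples_test(rbind(m, 1))
  with_zeros <- related_samples_test(rbind(m, 0, 1, 0))
  expect_equal(with_ones$statistic, base$statistic)
  expect_equal(with_zeros$statistic, base$statistic)
  expect_equal(with_zeros$n_informative_rows, base$n_informative_rows)

  # every row constant: the statistic is undefined
  degen <- related_samples_test(rbind(c(1, 1, 1, 1), c(0, 0, 0, 0)))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$statistic))
  expect_equal(degen$p.value, 1)

  expect_error(related_samples_test(matrix(2, 3, 4)), "binary")
  expect_error(related_samples_test(matrix(1, 1, 4)), "at least 2")
})

test_that("the statistic matches exhaustive evaluation on all small designs", {
  for (rows in 2:3) {
    cells <- rows * 4
    for (code in 0:(2^cells - 1)) {
      m <- matrix(as.integer(intToBits(code)[1:cells]), nrow = rows,
                  byrow = TRUE)
      expected <- oracle_cochran_variance_form(m)
      got <- related_samples_test(m)
      if (is.na(expected)) {
        expect_true(got$degenerate)
      } else {
        expect_equal(unname(got$statistic), expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("the statistic agrees with the rank-test oracle on random designs", {
  set.seed(57)
  for (rep in 1:25) {
    m <- matrix(rbinom(4 * sample(5:15, 1), 1, runif(1, 0.2, 0.8)), ncol = 4)
    got <- related_samples_test(m)
    if (got$degenerate) next
    fr <- suppressWarnings(friedman.test(m))
    expect_equal(unname(got$statistic), unname(fr$statistic),
                 tolerance = 1e-10)
    expect_equal(got$p.value, fr$p.value, tolerance = 1e-10)
  }
})

test_that("permutation and asymptotic p-values agree on a moderate design", {
  set.seed(61)
  m <- matrix(rbinom(30 * 4, 1, 0.5), ncol = 4)
  asym <- related_samples_test(m)
  perm <- related_samples_test(m, p_method = "permutation",
                               n_perm = 4000, seed = 8)
  expect_lt(abs(perm$p.value - asym$p.value), 0.02)
})

test_that("the designed imbalance is detected with high power", {
  p <- c(0.8, 0.3, 0.8, 0.2)
  hits <- 0L
  for (i in 1:100) {
    ds <- generate_synthetic(synthetic_spec(1000, p, seed = 10000 + i))
    if (related_samples_test(vox_matrix(ds))$p.value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("printed longitudinal Q values are consistent with Q = A(C - R)", {
  t3 <- vox_fixture("table3")
  q_recomputed <- mapply(first_moment, t3$A, t3$R,
                         MoreArgs = list(property_radius = 12))
  # times 1, 4 and 5 are exact at printed precision; times 2 and 3 carry
  # the published tables' internal rounding and are interval-checked
  expect_equal(round(q_recomputed[c(1, 5)], 2), t3$Q[c(1, 5)])
  fig4_q <- describe_profile(vox_fixture("fig4"), radar_config(12))$Q
  expect_equal(round(fig4_q, 2), t3$Q[4])
  expect_lt(max(abs(q_recomputed[2:3] - t3$Q[2:3])), 0.5)
})

test_that("all printed descriptor rows admit a consistent C = 12", {
  rows <- rbind(vox_fixture("table3")[, c("A", "R", "Q")],
                vox_fixture("table4")[, c("A", "R", "Q")])
  # half-ulp intervals around the printed (rounded) A and R values
  a_tol <- ifelse(rows$A == round(rows$A), 0.5, 0.005)
  r_tol <- 0.005
  q_lo <- (rows$A - a_tol) * (12 - rows$R - r_tol)
  q_hi <- (rows$A + a_tol) * (12 - rows$R + r_tol)
  expect_true(all(rows$Q >= q_lo - 0.005 & rows$Q <= q_hi + 0.005))
})

test_that("longitudinal series validate ages and track growth", {
  cfg <- radar_config(12)
  one <- longitudinal_series("3:4", list(axis_values(1, 1, 2, 0)), cfg)
  expect_equal(nrow(one$table), 1)
  expect_equal(one$table$age, "3:4")

  expect_error(longitudinal_series(c("4:0", "4:0"),
                                   list(axis_values(1, 1, 1, 1),
                                        axis_values(2, 2, 2, 2)), cfg),
               "strictly increasing")

  # monotone growth toward balance: A nondecreasing and, with R
  # nonincreasing, Q nondecreasing
  start <- c(tact = 6, mand = 2, echoic = 5, sequelic = 1)
  end <- c(tact = 10, mand = 10, echoic = 10, sequelic = 10)
  vals <- lapply(seq(0, 1, length.out = 5), function(w) {
    v <- (1 - w) * start + w * end
    axis_values(v[["tact"]], v[["mand"]], v[["echoic"]], v[["sequelic"]])
  })
  ser <- longitudinal_series(c("3:4", "3:10", "4:4", "4:10", "5:4"),
                             vals, cfg)
  expect_true(all(diff(ser$table$A) >= 0))
  expect_true(all(diff(ser$table$R) <= 1e-9))
  expect_true(all(diff(ser$table$Q) >= 0))
})

test_that("profile comparisons reproduce the cross-speaker contrasts", {
  t4 <- vox_fixture("table4")
  child <- function(i) {
    shape_descriptors(area = t4$A[i],
                      centroid = c(x = t4$centroid_x[i], y = t4$centroid_y[i]),
                      r = t4$R[i], q = t4$Q[i], property_radius = 12)
  }
  cd <- compare_profiles(child(3), child(4))  # C vs D
  expect_equal(cd$delta_A, -271)
  expect_equal(cd$delta_Q, -3131.86)
  expect_equal(cd$centroid_separation,
               sqrt((-1 / 3 - 0.5)^2 + (-2 / 3)^2))

  self <- compare_profiles(child(1), child(1))
  expect_equal(self$delta_A, 0)
  expect_equal(self$delta_Q, 0)
  expect_equal(self$centroid_separation, 0)

  ab <- compare_profiles(child(1), child(2))
  ba <- compare_profiles(child(2), child(1))
  expect_equal(ab$delta_A, -ba$delta_A)
  expect_equal(ab$delta_R, -ba$delta_R)
  expect_equal(ab$delta_Q, -ba$delta_Q)

  other_c <- shape_descriptors(area = 1, centroid = c(x = 0, y = 0),
                               q = 12, property_radius = 10)
  expect_error(compare_profiles(child(1), other_c), "property radius")
})

test_that("equal mand control can sit inside vastly different repertoires", {
  # synthetic stand-ins for the two-speaker contrast: same mand value,
  # different remaining axes
  cfg <- radar_config(12)
  small <- describe_profile(axis_values(tact = 2, mand = 6, echoic = 1,
                                        sequelic = 1), cfg)
  large <- describe_profile(axis_values(tact = 8, mand = 6, echoic = 9,
                                        sequelic = 4), cfg)
  cmp <- compare_profiles(small, large)
  expect_equal(unname(cmp$axis_deltas[["mand"]]), 0)
  expect_true(cmp$delta_A != 0)
})
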