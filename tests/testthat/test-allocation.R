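test_that("lines_per_location implements the ceiling rule", {
  expect_identical(lines_per_location(8, 2, 4), 4L)
  expect_identical(lines_per_location(8, 4, 4), 8L)
  expect_identical(lines_per_location(10, 3, 4), 8L)
  expect_error(lines_per_location(8, 5, 4), "r > I")
})

test_that("M1 phenotypes a random subset of lines in every environment", {
  d <- allocate_m1(line_names(8), env_names(4), 0.5, seed = 7)
  rs <- rowSums(d$mask)
  expect_true(all(rs %in% c(0L, 4L)))
  expect_identical(sum(d$mask), 16L)
  expect_identical(sum(rs == 4L), 4L)
  # full-fraction limit and determinism
  expect_true(all(allocate_m1(line_names(8), env_names(4), 1, seed = 1)$mask == 1L))
  expect_identical(allocate_m1(line_names(8), env_names(4), 0.5, seed = 3)$mask,
                   allocate_m1(line_names(8), env_names(4), 0.5, seed = 3)$mask)
  expect_error(allocate_m1(line_names(8), env_names(4), 0.01), "zero training")
})

test_that("M2 shares a core and rotates one testing slice into each environment", {
  d <- allocate_m2(line_names(8), env_names(4), 0.5, seed = 7)
  expect_true(all(rowSums(d$mask) %in% c(4L, 1L)))
  expect_true(all(colSums(d$mask) == 5L))
  expect_gte(min(rowSums(d$mask)), 1L)
  d2 <- allocate_m2(line_names(12), env_names(3), 0.5, seed = 9)
  expect_true(all(colSums(d2$mask) == 8L))
  # near-equal split with remainder: 5 testing lines over 3 environments
  d3 <- allocate_m2(line_names(10), env_names(3), 0.5, seed = 2)
  expect_equal(unname(sort(colSums(d3$mask) - 5, decreasing = TRUE)), c(2, 2, 1))
  expect_error(allocate_m2(line_names(8), env_names(6), 0.7), "cannot split")
})

test_that("M3 keeps column sums exactly k and row sums within 1 of r", {
  for (s in 1:200) {
    d <- allocate_m3(line_names(8), env_names(4), r = 2, seed = s)
    expect_true(all(colSums(d$mask) == 4L))
    expect_true(all(rowSums(d$mask) >= 1L & rowSums(d$mask) <= 3L))
  }
  # r = 1 with J = I * k: rows partition the lines, one environment each
  d <- allocate_m3(line_names(8), env_names(4), r = 1, seed = 5)
  expect_true(all(rowSums(d$mask) == 1L))
  expect_true(all(colSums(d$mask) == 2L))
  expect_error(allocate_m3(line_names(8), env_names(4), r = 4), "r < I")
})

test_that("M4 finds an exact balanced design when one exists", {
  # 7 lines in 7 environments of size 3: the classical lambda = 1 design
  d <- allocate_m4(line_names(7), env_names(7), r = 3, seed = 1, n_restarts = 40)
  cc <- concurrence(d)
  expect_true(all(colSums(d$mask) == 3L))
  expect_true(all(rowSums(d$mask) == 3L))
  off <- cc$lambda_matrix[upper.tri(cc$lambda_matrix)]
  expect_true(all(off == 1L))
  expect_identical(cc$balance_score, 0)
})

test_that("M4 is at least as concurrence-balanced as M3 and descends monotonically", {
  b3 <- b4 <- numeric(60)
  for (s in seq_along(b3)) {
    b3[s] <- concurrence(allocate_m3(line_names(8), env_names(4), 2, seed = s))$balance_score
    d4 <- allocate_m4(line_names(8), env_names(4), 2, seed = s, n_restarts = 5)
    b4[s] <- d4$balance_score
    expect_true(all(diff(d4$score_trace) <= 1e-12))
    expect_true(all(colSums(d4$mask) == 4L))
    expect_true(all(rowSums(d4$mask) >= 1L & rowSums(d4$mask) <= 3L))
  }
  expect_lte(mean(b4), mean(b3))
})

test_that("concurrence matches brute-force counting and its invariants", {
  d <- allocate_m3(line_names(10), env_names(5), r = 2, seed = 3)
  cc <- concurrence(d)
  expect_identical(unname(cc$lambda_matrix), naive_concurrence(d$mask))
  expect_equal(as.numeric(cc$replications), unname(rowSums(d$mask)))
  # M1: every training pair concurs in all I environments
  d1 <- allocate_m1(line_names(8), env_names(4), 0.5, seed = 2)
  lam1 <- concurrence(d1)$lambda_matrix
  tr <- rowSums(d1$mask) > 0
  expect_true(all(lam1[tr, tr] == 4L))
  expect_true(all(lam1[!tr, ] == 0L))
  # single environment: concurrences are 0/1
  ds <- allocate_m1(line_names(6), "E1", 0.5, seed = 1)
  expect_true(all(concurrence(ds)$lambda_matrix %in% c(0L, 1L)))
  # zero balance score iff all off-diagonal concurrences equal
  expect_identical(concurrence(d1)$balance_score == 0, FALSE)
  dfull <- allocate_m1(line_names(4), env_names(2), 1, seed = 1)
  expect_identical(concurrence(dfull)$balance_score, 0)
})

test_that("training_fraction is the plot fraction of the mask", {
  expect_identical(training_fraction(allocate_m1(line_names(4), env_names(2), 1, seed = 1)), 1)
  expect_identical(training_fraction(allocate_m1(line_names(8), env_names(4), 0.5, seed = 1)), 0.5)
  expect_identical(training_fraction(allocate_m3(line_names(8), env_names(4), 2, seed = 1)), 0.5)
})

test_that("the fraction-to-replication mapping keeps realized fractions within 1/I", {
  for (m in c("M1", "M2", "M3", "M4")) for (f in c(0.25, 0.5, 0.75)) {
    d <- allocate_lines(line_names(16), env_names(4), m,
                        train_fraction = f, seed = 11)
    expect_lte(abs(training_fraction(d) - f), 1 / 4 + 1e-9)
    expect_true(all(colSums(d$mask) >= 1L))
    expect_true(all(d$mask %in% c(0L, 1L)))
  }
})

test_that("designs survive the CSV + JSON round trip", {
  d <- allocate_m4(line_names(8), env_names(4), 2, seed = 6)
  f <- tempfile(fileext = ".csv")
  write_design(d, f)
  d2 <- read_design(f)
  expect_identical(d2$mask, d$mask)
  expect_identical(d2$method, d$method)
  unlink(c(f, paste0(f, ".json")))
})
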