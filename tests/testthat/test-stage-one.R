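test_that("balanced complete blocks without block variance give plot means as BLUEs", {
  g <- setNames(rnorm(15), line_names(15))
  plots <- sim_plot_data(g, reps = 3, blocks_per_rep = 1, sigma_block = 0,
                         sigma_e = 0.4, rep_shift_sd = 0.5, seed = 8)
  blues <- suppressWarnings(fit_stage_one(plots, "trait1"))
  mns <- tapply(plots$trait1, plots$line_id, mean)
  expect_lt(max(abs(blues$value - mns[blues$line_id])), 1e-6)
  expect_true(all(blues$se > 0))
  expect_equal(blues$weight, 1 / blues$se^2)
})

test_that("with block variance fixed at zero BLUEs equal OLS adjusted means", {
  g <- setNames(rnorm(20), line_names(20))
  plots <- sim_plot_data(g, reps = 2, blocks_per_rep = 5, sigma_block = 1,
                         sigma_e = 0.5, seed = 12)
  blues <- suppressWarnings(
    fit_stage_one(plots, "trait1", fix_vc = c(block = 0, resid = 0.25)))
  # direct normal-equations oracle
  line <- factor(plots$line_id); rep_ <- factor(plots$rep)
  fit <- lm(plots$trait1 ~ 0 + line + rep_)
  ols <- coef(fit)[seq_len(nlevels(line))] + mean(c(0, coef(fit)[-seq_len(nlevels(line))]))
  expect_lt(max(abs(blues$value - unname(ols))), 1e-6)
})

test_that("REML recovers the block and residual variances on average", {
  set.seed(202)
  est <- replicate(30, {
    g <- setNames(rnorm(40, sd = 1), line_names(40))
    plots <- sim_plot_data(g, reps = 2, blocks_per_rep = 8, sigma_block = 2,
                           sigma_e = 1, seed = sample.int(1e6, 1))
    sparseMET:::estimate_block_vc(plots$trait1, factor(plots$line_id),
                                  factor(plots$rep),
                                  interaction(plots$rep, plots$block, drop = TRUE))
  })
  expect_lt(abs(mean(est["block", ]) - 4) / 4, 0.25)
  expect_lt(abs(mean(est["resid", ]) - 1), 0.25)
})

test_that("duplicating every plot leaves BLUEs in place and shrinks SEs by about sqrt(2)", {
  g <- setNames(rnorm(12), line_names(12))
  plots <- sim_plot_data(g, reps = 2, blocks_per_rep = 1, sigma_block = 0,
                         sigma_e = 0.5, seed = 3)
  dup <- plots
  dup$rep <- paste0(dup$rep, "dup")
  both <- rbind(plots, dup)
  # hold the variance components fixed so doubling the data acts purely
  # through the information content
  vc <- c(block = 1e-8, resid = 0.25)
  b1 <- suppressWarnings(fit_stage_one(plots, "trait1", fix_vc = vc))
  b2 <- suppressWarnings(fit_stage_one(both, "trait1", fix_vc = vc))
  expect_lt(max(abs(b1$value - b2$value)), 1e-6)
  expect_equal(b2$se / b1$se, rep(1 / sqrt(2), nrow(b1)), tolerance = 0.01)
})

test_that("BLUEs are translation equivariant", {
  g <- setNames(rnorm(10), line_names(10))
  plots <- sim_plot_data(g, reps = 2, blocks_per_rep = 3, sigma_block = 1,
                         sigma_e = 0.5, seed = 5)
  b1 <- fit_stage_one(plots, "trait1")
  plots2 <- plots
  plots2$trait1 <- plots2$trait1 + 7.5
  b2 <- fit_stage_one(plots2, "trait1")
  expect_equal(b2$value, b1$value + 7.5, tolerance = 1e-6)
  expect_equal(b2$se, b1$se, tolerance = 1e-6)
})

test_that("confounded genotype and replicate effects are reported", {
  plots <- data.frame(line_id = c("L1", "L2"), env_id = "E1",
                      rep = c("R1", "R2"), block = c("B1", "B1"),
                      trait1 = c(1, 2))
  expect_error(fit_stage_one(plots, "trait1"), "confounded")
})

test_that("merge_blues produces the full line x environment table", {
  tabs <- lapply(env_names(3), function(e)
    data.frame(line_id = line_names(484), env_id = e, trait = "yield",
               value = rnorm(484)))
  merged <- merge_blues(tabs)
  expect_identical(nrow(merged), 1452L)
  # single table passthrough
  expect_identical(merge_blues(tabs[[1]]), tabs[[1]])
  # conflicting duplicates rejected
  expect_error(merge_blues(c(tabs, tabs[1])), "duplicate")
})
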