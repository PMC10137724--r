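test_that("with fixed variances and no interaction the posterior mean matches the MME solve", {
  panel <- fixture_panel(J = 60, p = 300, seed = 11)
  sim <- sim_phenotypes(panel$M, I = 3, nT = 1, h2 = 0.5, prop_ge = 0,
                        rg = 0, seed = 12)
  d <- allocate_m3(rownames(panel$G), env_names(3), r = 2, seed = 5)
  s2g <- 0.5; s2e <- 0.5
  fit <- sparse_gblup(sim$pheno, panel$G, design = d, include_ge = FALSE,
                      niter = 3000, burnin = 800, thin = 2, seed = 7,
                      fix = list(Sigma_T = matrix(s2g), R = matrix(s2e)))
  oracle <- mme_gblup(training_cells(sim$pheno, d), panel$G, s2g, s2e)
  g_hat <- coef(fit)[, 1]
  mcse <- apply(fit$draws$g[, , 1], 2, sparseMET:::mcse_batch)
  z <- abs(g_hat - oracle$g) / mcse
  expect_gt(cor(g_hat, oracle$g), 0.995)
  expect_gte(mean(z <= 3), 0.95)
})

test_that("noiseless phenotypes are recovered almost exactly", {
  panel <- fixture_panel(J = 50, p = 300, seed = 13)
  sim <- sim_phenotypes(panel$M, I = 2, nT = 1, h2 = 1, prop_ge = 0,
                        rg = 0, seed = 14)
  fit <- sparse_gblup(sim$pheno, panel$G, niter = 1500, burnin = 400,
                      thin = 2, seed = 15)
  y <- sim$pheno$value
  pred <- predict(fit, newdata = sim$pheno)
  expect_lt(sqrt(mean((y - pred)^2)), 0.05 * sd(y))
})

test_that("chains are reproducible under a seed and predictions ignore masked values", {
  panel <- fixture_panel(J = 30, p = 150, seed = 16)
  sim <- sim_phenotypes(panel$M, I = 2, nT = 2, h2 = 0.5, prop_ge = 0.2,
                        rg = 0.6, seed = 17)
  d <- allocate_m3(rownames(panel$G), env_names(2), r = 1, seed = 6)
  ctrl <- list(niter = 500, burnin = 100, thin = 2)
  f1 <- sparse_gblup(sim$pheno, panel$G, design = d, niter = ctrl$niter,
                     burnin = ctrl$burnin, thin = ctrl$thin, seed = 21)
  f2 <- sparse_gblup(sim$pheno, panel$G, design = d, niter = ctrl$niter,
                     burnin = ctrl$burnin, thin = ctrl$thin, seed = 21)
  expect_identical(f1$g_mean, f2$g_mean)
  expect_identical(f1$yhat, f2$yhat)
  f3 <- sparse_gblup(sim$pheno, panel$G, design = d, niter = ctrl$niter,
                     burnin = ctrl$burnin, thin = ctrl$thin, seed = 22)
  expect_false(identical(f1$g_mean, f3$g_mean))
  # leakage: corrupting testing-cell phenotypes changes nothing
  corrupted <- sim$pheno
  tst <- testing_cells(corrupted, d)
  corrupted$value[rownames(corrupted) %in% rownames(tst)] <-
    corrupted$value[rownames(corrupted) %in% rownames(tst)] + 1000
  f4 <- sparse_gblup(corrupted, panel$G, design = d, niter = ctrl$niter,
                     burnin = ctrl$burnin, thin = ctrl$thin, seed = 21)
  expect_identical(f1$yhat, f4$yhat)
  expect_identical(f1$g_mean, f4$g_mean)
})

test_that("line relabelling permutes the estimated effects", {
  panel <- fixture_panel(J = 40, p = 200, seed = 18)
  sim <- sim_phenotypes(panel$M, I = 2, nT = 1, h2 = 0.6, prop_ge = 0.1,
                        rg = 0, seed = 19)
  fit <- sparse_gblup(sim$pheno, panel$G, niter = 2500, burnin = 600,
                      thin = 2, seed = 31)
  set.seed(32)
  perm <- sample(nrow(panel$G))
  Gp <- panel$G[perm, perm]
  fitp <- sparse_gblup(sim$pheno, Gp, niter = 2500, burnin = 600,
                       thin = 2, seed = 31)
  g1 <- coef(fit); g2 <- coef(fitp)[rownames(coef(fit)), , drop = FALSE]
  expect_gt(cor(g1[, 1], g2[, 1]), 0.99)
  expect_lt(mean(abs(g1 - g2)), 0.03)
})

test_that("posterior covariance draws are symmetric positive definite", {
  panel <- fixture_panel(J = 30, p = 150, seed = 16)
  sim <- sim_phenotypes(panel$M, I = 2, nT = 2, h2 = 0.5, prop_ge = 0.2,
                        rg = 0.6, seed = 23)
  fit <- sparse_gblup(sim$pheno, panel$G, niter = 400, burnin = 100,
                      thin = 2, seed = 24)
  for (nm in c("Sigma_T", "Sigma_T2", "R")) {
    dr <- fit$draws[[nm]]
    for (k in seq_len(dim(dr)[1])) {
      S <- dr[k, , ]
      expect_lt(max(abs(S - t(S))), 1e-10)
      expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  }
})

test_that("an unrelated never-observed line is predicted at the environment mean", {
  panel <- fixture_panel(J = 30, p = 150, seed = 16)
  G <- panel$G
  G["L1", -1] <- 0; G[-1, "L1"] <- 0; G["L1", "L1"] <- 1
  sim <- sim_phenotypes(NULL, G = G, I = 2, nT = 1, h2 = 0.5, prop_ge = 0.1,
                        rg = 0, seed = 25)
  mask <- matrix(1L, 30, 2); mask[1, ] <- 0L
  d <- sparseMET:::new_allocation_design(mask, rownames(G), env_names(2),
                                         "M1", 29 / 30, 1L)
  # fixed variances keep the augmented chain well mixed, so the posterior
  # mean of the uninformed effect is zero up to Monte Carlo error
  fit <- sparse_gblup(sim$pheno, G, design = d, niter = 3000, burnin = 800,
                      thin = 2, seed = 26,
                      fix = list(Sigma_T = matrix(0.5), Sigma_T2 = matrix(0.1),
                                 R = matrix(0.4)))
  pred <- predict(fit, newdata = data.frame(line_id = "L1", env_id = "E1",
                                            trait = "trait1"))
  mcse_g1 <- sparseMET:::mcse_batch(fit$draws$g[, 1, 1])
  expect_lt(abs(coef(fit)["L1", 1]), 4 * mcse_g1)
  expect_lt(abs(pred - fit$b_mean[1, 1]), 0.3)
})

test_that("prediction validates cell identifiers and agrees with internal fitted values", {
  panel <- fixture_panel(J = 30, p = 150, seed = 16)
  sim <- sim_phenotypes(panel$M, I = 2, nT = 1, h2 = 0.5, prop_ge = 0.1,
                        rg = 0, seed = 27)
  fit <- sparse_gblup(sim$pheno, panel$G, niter = 400, burnin = 100,
                      thin = 2, seed = 28)
  expect_error(predict(fit, data.frame(line_id = "nope", env_id = "E1")), "unknown line")
  expect_error(predict(fit, data.frame(line_id = "L1", env_id = "nope")), "unknown environment")
  full <- predict(fit)
  one <- predict(fit, newdata = data.frame(line_id = "L3", env_id = "E2",
                                           trait = "trait1"))
  expect_identical(unname(one), unname(full["E2:L3", "trait1"]))
  r <- residuals(fit)
  expect_equal(r[fit$observed], (fit$y - fit$yhat)[fit$observed])
  expect_gt(cor(as.vector(fitted(fit))[fit$observed], fit$y[fit$observed]), 0.5)
})

test_that("uniform explicit weights reproduce the unweighted chain", {
  panel <- fixture_panel(J = 25, p = 120, seed = 29)
  sim <- sim_phenotypes(panel$M, I = 2, nT = 1, h2 = 0.5, prop_ge = 0.1,
                        rg = 0, seed = 30)
  ph <- sim$pheno
  ph$weight <- 2.5
  f_w <- sparse_gblup(ph, panel$G, niter = 300, burnin = 100, thin = 2, seed = 33)
  f_n <- sparse_gblup(sim$pheno, panel$G, niter = 300, burnin = 100, thin = 2, seed = 33)
  expect_identical(f_w$g_mean, f_n$g_mean)
  # non-uniform weights change the fit but stay reproducible
  ph$weight <- with_seed(34, runif(nrow(ph), 0.5, 2))
  f_h1 <- sparse_gblup(ph, panel$G, niter = 300, burnin = 100, thin = 2, seed = 33)
  f_h2 <- sparse_gblup(ph, panel$G, niter = 300, burnin = 100, thin = 2, seed = 33)
  expect_identical(f_h1$g_mean, f_h2$g_mean)
  expect_false(identical(f_h1$g_mean, f_n$g_mean))
})

test_that("model summaries expose the variance partition and MC errors", {
  panel <- fixture_panel(J = 30, p = 150, seed = 16)
  sim <- sim_phenotypes(panel$M, I = 2, nT = 2, h2 = 0.5, prop_ge = 0.2,
                        rg = 0.6, seed = 35)
  fit <- sparse_gblup(sim$pheno, panel$G, niter = 400, burnin = 100,
                      thin = 2, seed = 36)
  s <- summary(fit)
  expect_equal(colSums(s$variance_partition), c(trait1 = 1, trait2 = 1))
  expect_true(all(s$mcse > 0))
  expect_equal(dim(s$trait_correlation), c(2L, 2L))
  expect_output(print(fit), "Bayesian GBLUP")
  expect_output(print(s), "Variance partition")
  sims <- simulate(fit, nsim = 2, seed = 37)
  expect_length(sims, 2)
  expect_identical(dim(sims[[1]]), dim(fit$yhat))
})
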