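test_that("soft and block thresholding satisfy their closed forms", {
  expect_equal(soft_threshold(0.5, 1), 0)
  expect_equal(soft_threshold(-2, 0.5), -1.5)
  expect_equal(soft_threshold(3, 0), 3)
  X <- matrix(c(0.6, 0.8, 0, 0), 2)   # Frobenius norm 1
  expect_equal(block_soft_threshold(X, 2), matrix(0, 2, 2))
  X2 <- X * 2                          # norm 2, t = 1 -> X2 / 2
  expect_equal(block_soft_threshold(X2, 1), X2 / 2)
  expect_equal(block_soft_threshold(X2, 0), X2)
})

test_that("large lambda1 empties every graph and collapses to one phase", {
  sc <- make_scenario(p = 4, M = 3, n_phases = 2, edges_per_phase = 3,
                      n_per_period = 60, seed = 8)
  pan <- sample_scenario_panel(sc)
  lmax <- lambda1_max(pan)
  f <- fit_joint(pan, fit_config(lambda1 = lmax * 1.05, lambda2 = 0.01))
  for (m in 1:3) {
    Th <- f$estimates[[m]]$Theta
    expect_equal(sum(Th[upper.tri(Th)] != 0), 0)
  }
  expect_length(f$phases, 1)
  expect_length(f$change_points, 0)
})

test_that("lambda2 = 0 reproduces independent per-period fits", {
  sc <- make_scenario(p = 3, M = 2, n_phases = 2, edges_per_phase = 2,
                      n_per_period = 50, seed = 6)
  pan <- sample_scenario_panel(sc)
  cfg <- fit_config(lambda1 = 0.05, lambda2 = 0, standardize = FALSE,
                    tol = 1e-7)
  joint <- fit_joint(pan, cfg)
  sep_obj <- 0
  for (m in 1:2) {
    sub <- panel_data(pan$matrices[m], pan$periods[m],
                      pan$keywords$keywords)
    fm <- fit_joint(sub, cfg)
    sep_obj <- sep_obj + fm$objective
  }
  expect_equal(joint$objective, sep_obj, tolerance = 1e-4)
})

test_that("fit_joint objective matches a generic convex-solver oracle", {
  sc <- make_scenario(p = 3, M = 2, n_phases = 2, edges_per_phase = 2,
                      n_per_period = 50, seed = 12)
  pan <- sample_scenario_panel(sc)
  lambda1 <- 0.08
  lambda2 <- 0.15
  cfg <- fit_config(lambda1 = lambda1, lambda2 = lambda2,
                    standardize = FALSE, tol = 1e-8, max_iter = 5000)
  f <- fit_joint(pan, cfg)
  orc <- oracle_joint_fit(pan, lambda1, lambda2, cap = 3)
  obj_oracle <- joint_objective(pan, orc$estimates, lambda1, lambda2)
  expect_equal(f$objective, obj_oracle, tolerance = 1e-4)
  # and never worse than the zero-parameter point
  zero <- lapply(1:2, function(m) tgm_params(matrix(0, 3, 3), numeric(3)))
  expect_lte(f$objective, joint_objective(pan, zero, lambda1, lambda2))
})

test_that("large lambda2 collapses to the pooled-loss minimizer", {
  sc <- make_scenario(p = 3, M = 3, n_phases = 3, edges_per_phase = 2,
                      n_per_period = 40, seed = 13)
  pan <- sample_scenario_panel(sc)
  f <- fit_joint(pan, fit_config(lambda1 = 0, lambda2 = 50,
                                 standardize = FALSE, tol = 1e-8,
                                 max_iter = 5000))
  expect_length(f$phases, 1)
  # independent oracle: smooth minimization of sum_m J_m with the
  # off-diagonals tied across periods (diagonal and eta free per period)
  p <- 3; M <- 3
  ut <- which(upper.tri(matrix(0, p, p)))
  unpack <- function(x) lapply(seq_len(M), function(m) {
    Th <- matrix(0, p, p)
    Th[ut] <- x[seq_along(ut)]
    Th <- Th + t(Th)
    diag(Th) <- x[length(ut) + (m - 1) * 2 * p + seq_len(p)]
    eta <- x[length(ut) + (m - 1) * 2 * p + p + seq_len(p)]
    tgm_params(Th, eta)
  })
  fn <- function(x) {
    ps <- unpack(x)
    sum(vapply(seq_len(M), function(m)
      sm_loss(pan$matrices[[m]], ps[[m]], h_weight(3)), 0))
  }
  gr <- function(x) {
    ps <- unpack(x)
    g <- numeric(length(x))
    for (m in seq_len(M)) {
      sg <- sm_loss_grad(pan$matrices[[m]], ps[[m]], h_weight(3))
      g[seq_along(ut)] <- g[seq_along(ut)] + sg$grad_Theta[ut]
      g[length(ut) + (m - 1) * 2 * p + seq_len(p)] <- diag(sg$grad_Theta)
      g[length(ut) + (m - 1) * 2 * p + p + seq_len(p)] <- sg$grad_eta
    }
    g
  }
  opt <- stats::optim(numeric(length(ut) + 2 * p * M), fn, gr,
                      method = "L-BFGS-B", control = list(factr = 10))
  od <- function(e) { Th <- e$Theta; diag(Th) <- 0; Th }
  oracle <- unpack(opt$par)
  expect_equal(od(f$estimates[[1]]), od(oracle[[1]]), tolerance = 1e-4,
               ignore_attr = TRUE)
  # fused objective value matches the constrained optimum
  expect_equal(sum(f$.losses), opt$value, tolerance = 1e-4)
})

test_that("edge count is monotone non-increasing in lambda1", {
  sc <- make_scenario(p = 5, M = 2, n_phases = 1, edges_per_phase = 4,
                      n_per_period = 80, seed = 14)
  pan <- sample_scenario_panel(sc)
  lmax <- lambda1_max(pan)
  grid <- lmax * c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8)
  edges <- sapply(grid, function(l1) {
    f <- fit_joint(pan, fit_config(lambda1 = l1, lambda2 = 0.01))
    sum(sapply(f$estimates, function(e) sum(e$Theta[upper.tri(e$Theta)] != 0)))
  })
  expect_true(all(diff(edges) <= 0))
})

test_that("extract_phases merges equal matrices and finds boundaries", {
  p1 <- tgm_params(diag(3), numeric(3))
  expect_equal(extract_phases(list(p1))$phases, list(1L))
  expect_length(extract_phases(list(p1))$change_points, 0)
  same <- replicate(4, p1, simplify = FALSE)
  expect_equal(extract_phases(same)$phases, list(1:4))
  Th2 <- diag(3); Th2[1, 2] <- Th2[2, 1] <- 0.5
  p2 <- tgm_params(Th2, numeric(3))
  ph <- extract_phases(list(p1, p1, p2, p2, p2))
  expect_equal(ph$phases, list(1:2, 3:5))
  expect_equal(ph$change_points, 2L)
})

test_that("the AIC df counts each phase's edges once plus p per phase", {
  Th <- diag(10)
  Th[1, 2] <- Th[2, 1] <- 0.3
  Th[3, 4] <- Th[4, 3] <- -0.2
  fake <- list(estimates = replicate(3, tgm_params(Th, numeric(10)),
                                     simplify = FALSE),
               phases = list(1:3))
  # one phase, k = 2 shared edges, p = 10 -> df = 12 (penalty 2 * (k + p))
  expect_equal(fusedtgm:::.aic_df(fake), 12)
  fake2 <- list(estimates = fake$estimates, phases = list(1L, 2:3))
  expect_equal(fusedtgm:::.aic_df(fake2), 24)
})

test_that("aic_select returns a single grid point unchanged", {
  sc <- make_scenario(p = 3, M = 2, n_phases = 1, edges_per_phase = 1,
                      n_per_period = 40, seed = 15)
  pan <- sample_scenario_panel(sc)
  sel <- aic_select(pan, lambda1_grid = 0.1, lambda2_grid = 0.2)
  expect_equal(sel$lambda1, 0.1)
  expect_equal(sel$lambda2, 0.2)
  expect_s3_class(sel$fit, "tgm_fit")
  expect_equal(nrow(sel$table), 1)
})

test_that("selection on empty true graphs is at least 90% sparse", {
  sc <- make_scenario(p = 8, M = 6, n_phases = 1, edges_per_phase = 0,
                      n_per_period = 200, seed = 5)
  pan <- sample_scenario_panel(sc)
  sel <- aic_select(pan)
  Th <- sel$fit$estimates[[1]]$Theta
  sparsity <- 1 - sum(Th[upper.tri(Th)] != 0) / choose(8, 2)
  expect_gte(sparsity, 0.9)
})

test_that("periods with fewer than two observations are rejected", {
  pan <- panel_data(list(matrix(c(1, 2, 3), 1, 3)), "2015 Q1",
                    c("a", "b", "c"))
  expect_error(fit_joint(pan), "at least 2")
})
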