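# Reaction-norm REML, BLUP solving, scale correction, variance profiles
# and accuracies.

small_sire_sim <- function(seed = 4, n_sires = 12, progeny = 5) {
  cfg <- sim_config(n_sires = n_sires, progeny_per_sire = progeny,
                    n_cg = 6, sigma2_c = 0,
                    K = matrix(c(6, 0.5, 0.5, 1.2), 2, 2),
                    E = matrix(c(8, 0.3, 0.3, 0.9), 2, 2))
  simulate_population(cfg, seed = seed)
}

test_that("the MME restricted likelihood equals the dense formula", {
  sim <- small_sire_sim()
  em <- true_ecmap(sim)
  spec <- rn_model(response = "pw_weight", fixed = "mean", genetic = "sire",
                   relationship = "identity")
  vc <- rn_varcomp(K = matrix(c(1.5, 0.1, 0.1, 0.3), 2, 2),
                   E = matrix(c(9, 0.2, 0.2, 1.1), 2, 2))
  ll_pkg <- reml_loglik(sim$dataset, em, spec, vc)

  phen <- sim$dataset$phenotypes
  x <- ec_for_records(em, phen$cg_key)
  sires <- sort(unique(phen$sire))
  Zs <- outer(phen$sire, sires, "==") * 1
  Z <- cbind(Zs, Zs * x)
  Rdiag <- vc$E[1, 1] + 2 * x * vc$E[1, 2] + x^2 * vc$E[2, 2]
  ll_dense <- dense_reml_loglik(phen$pw_weight, matrix(1, nrow(phen), 1),
                                list(Z),
                                list(kronecker(vc$K, diag(length(sires)))),
                                Rdiag)
  expect_equal(ll_pkg, ll_dense, tolerance = 1e-8)
})

test_that("the likelihood also matches densely for a full animal model", {
  # animal model with pedigree relationships, dam permanent environment,
  # maternal genetic effect and random genetic groups
  cfg <- sim_config(n_sires = 5, progeny_per_sire = 6, n_cg = 4,
                    sigma2_c = 1.5)
  sim <- simulate_population(cfg, seed = 9)
  ped <- sim$dataset$pedigree
  founders <- is.na(ped$sire) & is.na(ped$dam)
  ped$genetic_group[founders] <- rep(c("G1", "G2"),
                                     length.out = sum(founders))
  ds <- rn_dataset(ped, sim$dataset$phenotypes)
  em <- true_ecmap(sim)
  spec <- rn_model(response = "pw_weight", fixed = "mean",
                   genetic = "animal", relationship = "A", dam_pe = TRUE,
                   maternal = TRUE, genetic_groups = TRUE)
  vc <- rn_varcomp(K = matrix(c(5, 0.4, 0.4, 0.9), 2, 2),
                   E = matrix(c(7, 0.1, 0.1, 0.8), 2, 2), sigma2_c = 1.2,
                   sigma2_m = 0.8, sigma2_g = 2.5)
  ll_pkg <- reml_loglik(ds, em, spec, vc)

  phen <- ds$phenotypes
  x <- ec_for_records(em, phen$cg_key)
  A <- build_A(ped)
  ids <- rownames(A)
  Za <- outer(phen$animal, ids, "==") * 1
  Zrr <- cbind(Za, Za * x)
  dams <- sort(unique(phen$dam))
  Zc <- outer(phen$dam, dams, "==") * 1
  Zm <- outer(phen$dam, ids, "==") * 1
  qm <- build_Q(ped)
  Zq <- qm$Q[match(phen$animal, qm$ids), , drop = FALSE]
  Rdiag <- vc$E[1, 1] + 2 * x * vc$E[1, 2] + x^2 * vc$E[2, 2]
  ll_dense <- dense_reml_loglik(
    phen$pw_weight, matrix(1, nrow(phen), 1),
    list(Zrr, Zc, Zm, Zq),
    list(kronecker(vc$K, A), vc$sigma2_c * diag(length(dams)),
         vc$sigma2_m * A, vc$sigma2_g * diag(length(qm$groups))),
    Rdiag)
  expect_equal(ll_pkg, ll_dense, tolerance = 1e-8)

  # and the fit with all terms runs end to end on this small instance
  fit <- fit_reaction_norm(ds, em, spec, start = vc)
  expect_true(is.finite(fit$varcomp$loglik))
  expect_gt(fit$varcomp$loglik, ll_pkg - 1e-6)
})

test_that("BLUP solutions match a dense solve of the same equations", {
  ped <- data.frame(animal = c("S1", "S2", "D1", "D2", "P1", "P2", "P3",
                               "P4", "P5"),
                    sire = c(NA, NA, NA, NA, "S1", "S1", "S2", "S2", "S1"),
                    dam = c(NA, NA, NA, NA, "D1", "D1", "D2", "D2", "D2"))
  phen <- toy_phenotypes(5, cg = rep(c("C1", "C2"), length.out = 5),
                         animal = c("P1", "P2", "P3", "P4", "P5"),
                         sire = c("S1", "S1", "S2", "S2", "S1"),
                         dam = c("D1", "D1", "D2", "D2", "D2"))
  phen$pw_weight <- c(38, 42, 41, 39, 44)
  ds <- rn_dataset(ped, phen)
  em <- rn_ecmap(c("C1", "C2"), c(-20, 20), ec_sd = 20)
  spec <- rn_model(response = "pw_weight", fixed = "mean",
                   genetic = "animal", relationship = "A")
  vc <- rn_varcomp(K = matrix(c(4, 0.3, 0.3, 0.8), 2, 2),
                   E = matrix(c(6, 0, 0, 0.5), 2, 2))
  blup <- solve_blup(ds, em, spec, vc, pev = TRUE)

  # dense MME assembled from scratch
  x <- ec_for_records(em, phen$cg_key)
  A <- build_A(ped)
  ids <- rownames(A)
  Za <- outer(phen$animal, ids, "==") * 1
  W <- cbind(1, Za, Za * x)
  Rinv <- diag(1 / (vc$E[1, 1] + 2 * x * vc$E[1, 2] + x^2 * vc$E[2, 2]))
  Ginv <- solve(kronecker(vc$K, A))
  C <- t(W) %*% Rinv %*% W
  idx <- 1 + seq_len(2 * length(ids))
  C[idx, idx] <- C[idx, idx] + Ginv
  sol <- solve(C, t(W) %*% Rinv %*% phen$pw_weight)
  a0_dense <- sol[1 + seq_along(ids)]
  a1_dense <- sol[1 + length(ids) + seq_along(ids)]
  m <- match(blup$ebv$animal_id, ids)
  expect_equal(blup$ebv$a0, a0_dense[m], tolerance = 1e-8)
  expect_equal(blup$ebv$a1, a1_dense[m], tolerance = 1e-8)
  # PEV equals the diagonal of the inverse coefficient matrix
  Cinv <- solve(C)
  expect_equal(blup$ebv$pev_a0, diag(Cinv)[1 + m], tolerance = 1e-8)
  expect_equal(blup$ebv$pev_a1, diag(Cinv)[1 + length(ids) + m],
               tolerance = 1e-8)
})

test_that("REML estimates agree with a dense direct maximizer", {
  sim <- small_sire_sim(seed = 63, n_sires = 12, progeny = 5) # 60 records
  em <- true_ecmap(sim)
  spec <- rn_model(response = "pw_weight", fixed = "mean", genetic = "sire",
                   relationship = "identity")
  fit <- fit_reaction_norm(sim$dataset, em, spec,
                           control = list(reltol = 1e-12))
  # independent dense maximizer over the same parameterisation
  phen <- sim$dataset$phenotypes
  x <- ec_for_records(em, phen$cg_key)
  nll_dense <- dense_sire_rr_nll(phen, x)
  vy <- var(phen$pw_weight)
  par0 <- c(log(sqrt(0.08 * vy)), 0, log(sqrt(0.15 * 0.08 * vy)),
            log(sqrt(0.55 * vy)), 0, log(sqrt(0.05 * vy)))
  od <- polish_optim(par0, nll_dense)
  Ld <- matrix(c(exp(od$par[1]), od$par[2], 0, exp(od$par[3])), 2, 2)
  Kd <- Ld %*% t(Ld)
  Le <- matrix(c(exp(od$par[4]), od$par[5], 0, exp(od$par[6])), 2, 2)
  Ed <- Le %*% t(Le)
  # likelihoods at the two optima agree tightly
  expect_equal(fit$varcomp$loglik, -od$value, tolerance = 1e-6)
  scale_ <- max(abs(Kd))
  expect_lt(max(abs(fit$varcomp$K - Kd)) / scale_, 1e-3)
  expect_lt(max(abs(fit$varcomp$E - Ed)) / max(abs(Ed)), 1e-3)
})

test_that("an animal with no records and no informative relatives is null", {
  ped <- data.frame(animal = c("S1", "S2", "D1", "D2", "LONER",
                               sprintf("P%02d", 1:8)),
                    sire = c(NA, NA, NA, NA, NA, rep(c("S1", "S2"), 4)),
                    dam = c(NA, NA, NA, NA, NA, rep(c("D1", "D2"), each = 4)),
                    stringsAsFactors = FALSE)
  phen <- toy_phenotypes(8, cg = rep(c("C1", "C2"), 4),
                         animal = sprintf("P%02d", 1:8),
                         sire = rep(c("S1", "S2"), 4),
                         dam = rep(c("D1", "D2"), each = 4))
  set.seed(2)
  phen$pw_weight <- 40 + rnorm(8, 0, 3)
  ds <- rn_dataset(ped, phen)
  em <- rn_ecmap(c("C1", "C2"), c(-20, 20), ec_sd = 20)
  spec <- rn_model(response = "pw_weight", fixed = "mean",
                   genetic = "animal", relationship = "A")
  vc <- rn_varcomp(K = matrix(c(4, 0, 0, 0.8), 2, 2),
                   E = matrix(c(6, 0, 0, 0.5), 2, 2))
  blup <- solve_blup(ds, em, spec, vc, pev = TRUE, pev_ids = "LONER")
  row <- blup$ebv[blup$ebv$animal_id == "LONER", ]
  expect_equal(row$a0, 0, tolerance = 1e-10)
  expect_equal(row$a1, 0, tolerance = 1e-10)
  expect_equal(row$pev_a0, vc$K[1, 1], tolerance = 1e-8)
  expect_equal(row$pev_a1, vc$K[2, 2], tolerance = 1e-8)
  expect_equal(row$acc_a0, 0)
})

test_that("doubling the records preserves EBV ranking and shrinks PEV", {
  sim <- small_sire_sim(seed = 8, n_sires = 10, progeny = 8)
  em <- true_ecmap(sim)
  spec <- rn_model(response = "pw_weight", fixed = "mean", genetic = "sire",
                   relationship = "identity")
  vc <- rn_varcomp(K = matrix(c(1.5, 0.12, 0.12, 0.3), 2, 2),
                   E = matrix(c(8, 0.3, 0.3, 0.9), 2, 2))
  b1 <- solve_blup(sim$dataset, em, spec, vc, pev = TRUE)

  ph2 <- sim$dataset$phenotypes
  ph2$animal <- paste0(ph2$animal, "_rep")
  ph2$dam <- paste0(ph2$dam, "_rep")
  dup <- sim$dataset
  dup$phenotypes <- rbind(sim$dataset$phenotypes, ph2)
  dup <- suppressWarnings(rn_dataset(dup$pedigree, dup$phenotypes))
  b2 <- solve_blup(dup, em, spec, vc, pev = TRUE)

  m <- match(b1$ebv$animal_id, b2$ebv$animal_id)
  expect_gt(cor(b1$ebv$a0, b2$ebv$a0[m]), 0.99)
  expect_gt(cor(b1$ebv$a1, b2$ebv$a1[m]), 0.99)
  expect_true(all(b2$ebv$pev_a0[m] < b1$ebv$pev_a0))
  expect_true(all(b2$ebv$pev_a1[m] < b1$ebv$pev_a1))
})

test_that("scale correction removes the genetic regression on the intercept", {
  # zero covariance: slopes unchanged
  vc0 <- rn_varcomp(K = diag(c(4, 0.8)), E = diag(c(6, 0.5)))
  tab <- data.frame(a0 = c(1, -2), a1 = c(0.3, 0.1))
  expect_equal(scale_correct(tab, vc0)$a1_star, tab$a1)

  # published component arithmetic: regression coefficient 0.2673
  K <- matrix(c(11.35, 0.64 * sqrt(11.35 * 1.98),
                0.64 * sqrt(11.35 * 1.98), 1.98), 2, 2)
  vc <- rn_varcomp(K = K, E = diag(c(10, 1)))
  expect_equal(K[1, 2] / K[1, 1], 0.26731, tolerance = 1e-4)
  got <- scale_correct(data.frame(a0 = 2, a1 = 0.5), vc)$a1_star
  expect_equal(got, 0.5 - 0.26731 * 2, tolerance = 1e-4)
  expect_equal(got, -0.03463, tolerance = 1e-3)

  # over true breeding values drawn from K, cov(a1*, a0) is zero
  set.seed(42)
  tbv <- robustnorm:::rmvn(20000, K)
  df <- scale_correct(data.frame(a0 = tbv[, 1], a1 = tbv[, 2]), vc)
  expect_lt(abs(cov(df$a1_star, df$a0)), 3 * sqrt(11.35 * 1.98) / sqrt(20000) * 2)

  vc_bad <- vc
  vc_bad$K <- matrix(c(0, 0, 0, 1), 2, 2)
  expect_error(scale_correct(tab, vc_bad), "positive")
})

test_that("variance profile matches the closed forms", {
  K <- matrix(c(8.06, 0.60 * sqrt(8.06 * 1.00),
                0.60 * sqrt(8.06 * 1.00), 1.00), 2, 2)
  vc <- rn_varcomp(K = K, E = matrix(c(12, 0.4, 0.4, 1.5), 2, 2),
                   sigma2_c = 1.28, sigma2_m = 0.95,
                   ec_range_std = c(-2, 2))
  pr <- variance_profile(vc, c(-1, 0, 1))
  expect_equal(pr$genetic_variance[pr$x == 0], K[1, 1])
  expect_equal(pr$genetic_variance[pr$x == 1], K[1, 1] + 2 * K[1, 2] + K[2, 2])
  # difference between +1 and -1 SD is four times the covariance
  expect_equal(pr$genetic_variance[pr$x == 1] - pr$genetic_variance[pr$x == -1],
               4 * 0.60 * sqrt(8.06 * 1.00), tolerance = 1e-10)
  expect_equal(pr$genetic_variance[pr$x == 1] - pr$genetic_variance[pr$x == -1],
               6.814, tolerance = 1e-3)
  # profile equals the explicit matrix product at the endpoints
  L <- cbind(1, c(-1, 0, 1))
  expect_equal(pr$genetic_variance, diag(L %*% K %*% t(L)))
  # heritability denominator includes c, m and the residual at the EC
  rv <- 12 + 2 * 1 * 0.4 + 1.5
  expect_equal(pr$heritability[pr$x == 1],
               (K[1, 1] + 2 * K[1, 2] + K[2, 2]) /
                 (K[1, 1] + 2 * K[1, 2] + K[2, 2] + rv + 1.28 + 0.95))
  expect_error(variance_profile(vc, 3), "outside")
})

test_that("continuous and single-class residual models agree when matched", {
  sim <- small_sire_sim(seed = 17, n_sires = 8, progeny = 6)
  em <- true_ecmap(sim)
  spec_cont <- rn_model(response = "pw_weight", fixed = "mean",
                        genetic = "sire", relationship = "identity",
                        residual = rn_residual("continuous"))
  spec_cls <- rn_model(response = "pw_weight", fixed = "mean",
                       genetic = "sire", relationship = "identity",
                       residual = rn_residual("classes",
                                              breaks = c(-100, 100)))
  K <- matrix(c(1.5, 0.1, 0.1, 0.3), 2, 2)
  vc_cont <- rn_varcomp(K = K, E = matrix(c(9, 0, 0, 0), 2, 2))
  vc_cls <- rn_varcomp(K = K, sigma2_e = 9, breaks = c(-100, 100))
  expect_equal(reml_loglik(sim$dataset, em, spec_cont, vc_cont),
               reml_loglik(sim$dataset, em, spec_cls, vc_cls),
               tolerance = 1e-10)
  b1 <- solve_blup(sim$dataset, em, spec_cont, vc_cont)
  b2 <- solve_blup(sim$dataset, em, spec_cls, vc_cls)
  expect_equal(b1$ebv$a0, b2$ebv$a0, tolerance = 1e-10)
  expect_equal(b1$ebv$a1, b2$ebv$a1, tolerance = 1e-10)
})

test_that("class residual model fits and respects breakpoints", {
  sim <- small_sire_sim(seed = 23, n_sires = 10, progeny = 8)
  em <- true_ecmap(sim)
  spec <- rn_model(response = "pw_weight", fixed = "mean", genetic = "sire",
                   relationship = "identity",
                   residual = rn_residual("classes", breaks = c(-80, 0, 80)))
  fit <- fit_reaction_norm(sim$dataset, em, spec)
  expect_length(fit$varcomp$sigma2_e, 2)
  expect_true(all(fit$varcomp$sigma2_e > 0))
  expect_error(rn_residual("classes", breaks = c(10, -10)), "increasing")
})

test_that("accuracy follows r = sqrt(1 - PEV / sigma2)", {
  expect_equal(accuracy_from_pev(0, 2), 1)
  expect_equal(accuracy_from_pev(2, 2), 0)
  expect_equal(accuracy_from_pev(1, 2), 0.7071, tolerance = 1e-4)
  expect_error(accuracy_from_pev(1, 0), "positive")
  expect_error(accuracy_from_pev(-1, 2), "non-negative")
  expect_warning(r <- accuracy_from_pev(2.0000001, 2), "clipped")
  expect_equal(r, 0)
  expect_error(accuracy_from_pev(3, 2), "exceeds")
})

test_that("REML recovers a null slope variance as null", {
  # with sigma2_a1 = 0 in the generator, the fitted slope variance is tiny
  cfg <- sim_config(n_sires = 40, progeny_per_sire = 25, sigma2_c = 0,
                    K = matrix(c(6, 0, 0, 1e-8), 2, 2),
                    E = matrix(c(8, 0, 0, 0.6), 2, 2))
  sim <- simulate_population(cfg, seed = 77)
  em <- true_ecmap(sim)
  spec <- rn_model(response = "pw_weight", fixed = "mean", genetic = "sire",
                   relationship = "identity")
  fit <- fit_reaction_norm(sim$dataset, em, spec)
  # sire-scale slope variance (truth 0); compare with the intercept variance
  expect_lt(fit$varcomp$K[2, 2], 0.05 * fit$varcomp$K[1, 1])
})

test_that("standard errors are returned when requested", {
  cfg <- sim_config(n_sires = 60, progeny_per_sire = 25, sigma2_c = 0,
                    K = matrix(c(6, 0.5, 0.5, 1.2), 2, 2),
                    E = matrix(c(8, 0.3, 0.3, 0.9), 2, 2))
  sim <- simulate_population(cfg, seed = 3)
  em <- true_ecmap(sim)
  spec <- rn_model(response = "pw_weight", fixed = "mean", genetic = "sire",
                   relationship = "identity")
  fit <- fit_reaction_norm(sim$dataset, em, spec, se = TRUE)
  expect_false(is.null(fit$varcomp$se))
  expect_true(all(c("K_11", "K_22", "E_11") %in% names(fit$varcomp$se)))
  expect_true(all(is.na(fit$varcomp$se) | fit$varcomp$se > 0))
})
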