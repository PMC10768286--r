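# Synthetic populations with the variance structure the reaction-norm
# analysis assumes, and the self-contained cross-validation simulation
# experiment (337 unrelated sires with 43 progeny each).

#' Configuration for the synthetic-population generator
#'
#' Defaults describe a half-sib design on the standardized EC scale:
#' contemporary groups with equally spaced EC values spanning about
#' +/- sqrt(3) SD (so the progeny EC variance is ~1, matching an EC
#' standardized to unit variance), an EC standard deviation of 38 g/day for
#' unit conversions, and phenotypes built forward from the linear
#' reaction-norm model `y = mu + fixed + a0 + a1 x + c + e(x)` with
#' continuous residual covariance E.
#'
#' @param n_sires Number of sires.
#' @param progeny_per_sire Progeny per sire.
#' @param K 2x2 genetic intercept/slope covariance (kg^2, slope per SD EC).
#' @param E 2x2 residual intercept/slope covariance.
#' @param sigma2_c Permanent environmental dam variance (kg^2).
#' @param n_cg Number of contemporary groups.
#' @param ec_span_sd Half-width of the equally spaced EC grid (SD units).
#' @param ec_sd_gday EC standard deviation in g/day.
#' @param progeny_per_dam Progeny per dam (1 = each progeny its own dam).
#' @param cg_growth_effect If `TRUE`, the contemporary group's growth-rate
#'   deviation (its EC, in g/day) is added to the phenotype over the
#'   individual growth period, so the EC is recoverable from growth rates.
#' @param sex_effect_kg Additive fixed effect of male sex (kg).
#' @param mu Overall mean post-weaning weight (kg).
#' @param base_pwgr Mean post-weaning growth rate (g/day) used to construct
#'   weaning weights.
#' @param sires_related If `TRUE`, sires are paternal half-sib groups (five
#'   sons per grandsire) instead of unrelated founders.
#' @param n_markers Number of unlinked biallelic markers to gene-drop
#'   (0 = no genotypes).
#' @param birth_years Optional vector of years assigned to contemporary
#'   groups (cyclically); default single year 2010.
#' @return List of class `rn_sim_config`.
#' @export
sim_config <- function(n_sires = 100, progeny_per_sire = 30,
                       K = matrix(c(7.88, 0.04 * sqrt(7.88 * 0.64),
                                    0.04 * sqrt(7.88 * 0.64), 0.64), 2, 2),
                       E = matrix(c(10, 0.35, 0.35, 0.8), 2, 2),
                       sigma2_c = 2.13, n_cg = 50, ec_span_sd = sqrt(3),
                       ec_sd_gday = 38, progeny_per_dam = 1,
                       cg_growth_effect = FALSE, sex_effect_kg = 0, mu = 40,
                       base_pwgr = 84, sires_related = FALSE, n_markers = 0,
                       birth_years = NULL) {
  if (!is_square_psd(K) || !is_square_psd(E))
    stop("K and E must be symmetric positive semi-definite")
  if (n_sires < 1 || progeny_per_sire < 1 || n_cg < 2 || progeny_per_dam < 1)
    stop("counts must be positive (and n_cg >= 2)")
  if (sigma2_c < 0) stop("sigma2_c must be non-negative")
  structure(as.list(environment()), class = "rn_sim_config")
}

#' Configuration of the cross-validation simulation experiment
#'
#' 337 unrelated sires with 43 progeny each, spread across an EC, with the
#' genetic covariance and dam variance of the full-data reaction-norm fit
#' (intercept variance 7.88 kg^2, slope variance 0.64 kg^2 per SD EC,
#' intercept-slope correlation 0.04, dam variance 2.13 kg^2).
#'
#' @param ... Overrides passed to [sim_config()].
#' @return An `rn_sim_config`.
#' @export
cv_experiment_config <- function(...) {
  args <- list(n_sires = 337, progeny_per_sire = 43)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

#' Simulate a half-sib population along an environmental gradient
#'
#' Builds a pedigree of founder sires and dams (one litter per dam) with
#' progeny assigned to contemporary groups of known EC, true breeding
#' values for intercept and slope drawn from K (progeny by parent average
#' plus Mendelian sampling), dam permanent-environment effects, and
#' phenotypes from the forward reaction-norm model with residual variance
#' increasing along the EC. Optionally gene-drops unlinked markers so the
#' genomic relationships approximate the pedigree ones.
#'
#' @param config An [sim_config()].
#' @param seed Integer seed (all randomness flows from it).
#' @param sire_tbv Optional matrix (n_sires x 2) of true sire breeding
#'   values, overriding the draw from K (used for paired datasets).
#' @param sire_ids Optional sire id labels.
#' @return List of class `rn_sim`: `dataset` (an `rn_dataset`), `truth`
#'   (per-animal true values, per-dam effects, per-CG ECs, per-record
#'   components) and `config`.
#' @export
simulate_population <- function(config = sim_config(), seed = NULL,
                                sire_tbv = NULL, sire_ids = NULL) {
  stopifnot(inherits(config, "rn_sim_config"))
  cf <- config
  with_seed(seed, {
    ns <- cf$n_sires
    npr <- ns * cf$progeny_per_sire
    nd <- ceiling(npr / cf$progeny_per_dam)
    sid <- sire_ids %||% sprintf("S%04d", seq_len(ns))
    did <- sprintf("D%05d", seq_len(nd))
    pid <- sprintf("P%06d", seq_len(npr))

    # pedigree
    if (cf$sires_related) {
      ngs <- ceiling(ns / 5)
      gsid <- sprintf("GS%03d", seq_len(ngs))
      sire_of_sire <- gsid[rep(seq_len(ngs), each = 5)[seq_len(ns)]]
      ped <- data.frame(
        animal = c(gsid, sid, did, pid),
        sire = c(rep(NA, ngs), sire_of_sire, rep(NA, nd),
                 rep(sid, each = cf$progeny_per_sire)),
        dam = c(rep(NA, ngs + ns + nd), did[ceiling(seq_len(npr) / cf$progeny_per_dam)]),
        stringsAsFactors = FALSE)
    } else {
      ped <- data.frame(
        animal = c(sid, did, pid),
        sire = c(rep(NA, ns + nd), rep(sid, each = cf$progeny_per_sire)),
        dam = c(rep(NA, ns + nd), did[ceiling(seq_len(npr) / cf$progeny_per_dam)]),
        stringsAsFactors = FALSE)
    }
    ped$genetic_group <- ifelse(is.na(ped$sire) & is.na(ped$dam), "G1", NA)

    # dams are mated within sire families (the dam index follows the
    # progeny blocks), so a dam's litter shares one sire
    prog_sire <- rep(sid, each = cf$progeny_per_sire)
    prog_dam <- did[ceiling(seq_len(npr) / cf$progeny_per_dam)]

    # true breeding values
    if (cf$sires_related) {
      gs_tbv <- rmvn(ngs, cf$K)
      s_tbv <- sire_tbv %||%
        (0.5 * gs_tbv[rep(seq_len(ngs), each = 5)[seq_len(ns)], , drop = FALSE] +
           rmvn(ns, 0.75 * cf$K))
    } else {
      s_tbv <- sire_tbv %||% rmvn(ns, cf$K)
    }
    d_tbv <- rmvn(nd, cf$K)
    p_tbv <- 0.5 * s_tbv[match(prog_sire, sid), , drop = FALSE] +
      0.5 * d_tbv[match(prog_dam, did), , drop = FALSE] +
      rmvn(npr, 0.5 * cf$K)

    # contemporary groups with equally spaced EC values
    cgk <- sprintf("CG%03d", seq_len(cf$n_cg))
    ec_std <- seq(-cf$ec_span_sd, cf$ec_span_sd, length.out = cf$n_cg)
    years <- if (is.null(cf$birth_years)) rep(2010L, cf$n_cg)
             else rep(as.integer(cf$birth_years), length.out = cf$n_cg)
    cg_of <- sample.int(cf$n_cg, npr, replace = TRUE)
    x <- ec_std[cg_of]

    c_dam <- if (cf$sigma2_c > 0) rnorm(nd, 0, sqrt(cf$sigma2_c)) else numeric(nd)
    eta <- rmvn(npr, cf$E)
    e <- eta[, 1] + x * eta[, 2]
    sex <- sample(c("M", "F"), npr, replace = TRUE)
    weaning_age <- pmin(pmax(round(rnorm(npr, 94, 9.8)), 50), 120)
    growth_days <- pmin(pmax(round(rnorm(npr, 168, 20)), 45), 250)
    fixed <- cf$sex_effect_kg * (sex == "M")
    if (cf$cg_growth_effect)
      fixed <- fixed + ec_std[cg_of] * cf$ec_sd_gday * growth_days / 1000
    cc <- c_dam[match(prog_dam, did)]
    y <- cf$mu + fixed + p_tbv[, 1] + p_tbv[, 2] * x + cc + e
    weaning_weight <- pmax(cf$mu - cf$base_pwgr * 168 / 1000 +
                             rnorm(npr, 0, 2), 5)

    phen <- data.frame(
      animal = pid, sire = prog_sire, dam = prog_dam, sex = sex,
      birth_type = sample(1:2, npr, replace = TRUE),
      rear_type = sample(1:2, npr, replace = TRUE),
      weaning_age = weaning_age, pw_age = weaning_age + growth_days,
      weaning_weight = weaning_weight, pw_weight = y,
      cg_key = cgk[cg_of], birth_year = years[cg_of],
      stringsAsFactors = FALSE)

    geno <- if (cf$n_markers > 0)
      gene_drop(ped, cf$n_markers) else NULL

    dataset <- suppressWarnings(rn_dataset(ped, phen, geno))
    truth <- list(
      sires = data.frame(sire_id = sid, a0 = s_tbv[, 1], a1 = s_tbv[, 2],
                         stringsAsFactors = FALSE),
      animals = data.frame(animal_id = pid, a0 = p_tbv[, 1], a1 = p_tbv[, 2],
                           stringsAsFactors = FALSE),
      dams = data.frame(dam_id = did, c = c_dam, stringsAsFactors = FALSE),
      cg = data.frame(cg_key = cgk, ec_std = ec_std,
                      ec_gday = ec_std * cf$ec_sd_gday, birth_year = years,
                      stringsAsFactors = FALSE),
      records = data.frame(animal = pid, cg_key = cgk[cg_of], x = x,
                           mu = cf$mu, fixed = fixed, a0 = p_tbv[, 1],
                           a1 = p_tbv[, 2], c = cc, e = e,
                           stringsAsFactors = FALSE))
    structure(list(dataset = dataset, truth = truth, config = cf),
              class = "rn_sim")
  })
}

# gene-drop unlinked biallelic markers down a pedigree
gene_drop <- function(ped, n_markers) {
  prep <- ped_prepare(ped)
  n <- length(prep$ids)
  p <- runif(n_markers, 0.1, 0.9)
  H1 <- matrix(0L, n, n_markers)
  H2 <- matrix(0L, n, n_markers)
  for (i in prep$order) {
    s <- prep$sire_idx[i]; d <- prep$dam_idx[i]
    H1[i, ] <- if (s == 0L) rbinom(n_markers, 1L, p)
               else ifelse(runif(n_markers) < 0.5, H1[s, ], H2[s, ])
    H2[i, ] <- if (d == 0L) rbinom(n_markers, 1L, p)
               else ifelse(runif(n_markers) < 0.5, H1[d, ], H2[d, ])
  }
  codes <- H1 + H2
  rownames(codes) <- prep$ids
  codes
}

#' ECMap holding the true simulated contemporary-group values
#'
#' @param sim An `rn_sim` from [simulate_population()].
#' @return An `rn_ecmap` with the generator's EC values (standardization by
#'   the configured EC standard deviation).
#' @export
true_ecmap <- function(sim) {
  stopifnot(inherits(sim, "rn_sim"))
  rn_ecmap(sim$truth$cg$cg_key, sim$truth$cg$ec_gday,
           ec_sd = sim$config$ec_sd_gday,
           ec_mean = sim$config$base_pwgr)
}

#' Subset the phenotype records of a dataset
#'
#' @param dataset An `rn_dataset`.
#' @param keep Logical or integer index into the phenotype rows.
#' @return The dataset with phenotypes restricted to `keep`.
#' @export
subset_records <- function(dataset, keep) {
  dataset$phenotypes <- dataset$phenotypes[keep, , drop = FALSE]
  if (!nrow(dataset$phenotypes)) stop("no records left after subsetting")
  dataset
}

#' Run the cross-validation simulation experiment
#'
#' For each run: simulate the configured population, assign threefold
#' cross-validation folds by the triplet design, fit the sire-model
#' reaction norm (identity sire covariance, continuous residual) on two
#' folds, pre-correct phenotypes, estimate each sire's realized regression
#' on the third fold, and correlate training EBV with realized performance.
#' Correlations are averaged over runs and folds.
#'
#' @param n_runs Number of simulation replicates (default 20).
#' @param config An [sim_config()]; defaults to [cv_experiment_config()].
#' @param seed Integer seed for the whole experiment.
#' @param min_progeny,min_range_gday Cross-validation eligibility rules.
#' @return List of class `rn_sim_summary`: `summary` (per component the
#'   mean correlation over runs x folds and its SE over runs), `per_fold`
#'   (all individual correlations), `n_failed`.
#' @export
run_cv_experiment <- function(n_runs = 20, config = cv_experiment_config(),
                              seed = 1, min_progeny = 25,
                              min_range_gday = 60) {
  # a few spare seeds are pre-drawn so that an occasional failed replicate
  # (REML non-convergence on an unlucky population) can be replaced
  # deterministically and the summary still aggregates n_runs replicates
  max_failed <- max(1L, ceiling(0.1 * n_runs))
  run_seeds <- with_seed(seed, sample.int(2147483600, n_runs + max_failed))
  rows <- list()
  n_failed <- 0L
  start <- NULL
  r <- 0L
  for (sd_i in run_seeds) {
    if (r >= n_runs) break
    res <- tryCatch(
      one_cv_run(config, sd_i, min_progeny, min_range_gday, start = start),
      error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      if (n_failed > max_failed)
        stop("more than 10% of simulation runs failed; last error: ",
             conditionMessage(res))
      next
    }
    start <- res$varcomp
    res <- res$cors
    r <- r + 1L
    res$run <- r
    rows[[length(rows) + 1L]] <- res
  }
  per_fold <- do.call(rbind, rows)
  agg <- aggregate(correlation ~ component, data = per_fold, FUN = mean)
  run_means <- aggregate(correlation ~ component + run, data = per_fold,
                         FUN = mean)
  se <- aggregate(correlation ~ component, data = run_means,
                  FUN = function(v) sd(v) / sqrt(length(v)))
  agg$se <- se$correlation[match(agg$component, se$component)]
  structure(list(summary = agg, per_fold = per_fold, n_failed = n_failed,
                 n_runs = r),
            class = "rn_sim_summary")
}

#' @exportS3Method base::print
print.rn_sim_summary <- function(x, ...) {
  cat("<rn_sim_summary> ", x$n_runs, " runs (", x$n_failed, " failed)\n",
      sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

one_cv_run <- function(config, run_seed, min_progeny, min_range_gday,
                       start = NULL) {
  sim <- simulate_population(config, seed = run_seed)
  ecmap <- true_ecmap(sim)
  ds <- sim$dataset
  folds <- assign_cv_folds(ds, ecmap, seed = run_seed + 1L,
                           min_progeny = min_progeny,
                           min_range_gday = min_range_gday)
  fold <- folds$assignment$fold

  # pre-correction: the simulation's only fixed effect is the overall mean,
  # estimated by GLS in a plain sire model
  spec_pre <- rn_model(response = "pw_weight", fixed = "mean",
                       genetic = "sire", reaction_norm = FALSE,
                       relationship = "identity",
                       residual = rn_residual("iid"))
  pre_fit <- fit_reaction_norm(ds, NULL, spec_pre)
  ds_star <- precorrect_phenotypes(ds, solve_blup(ds, NULL, spec_pre,
                                                  pre_fit$varcomp))

  spec_rn <- rn_model(response = "pw_weight", fixed = "mean",
                      genetic = "sire", reaction_norm = TRUE,
                      relationship = "identity",
                      residual = rn_residual("continuous"))
  out <- list()
  for (f in seq_len(folds$n_folds)) {
    train <- subset_records(ds, is.na(fold) | fold != f)
    fit <- fit_reaction_norm(train, ecmap, spec_rn, start = start)
    start <- fit$varcomp
    blup <- scale_correct(solve_blup(train, ecmap, spec_rn, fit$varcomp),
                          fit$varcomp)
    test <- subset_records(ds_star, !is.na(fold) & fold == f &
                             ds_star$phenotypes$sire %in% folds$eligible_sires)
    realized <- fit_realized_regression(test, ecmap, start = fit$varcomp)
    cors <- correlate_validation(blup, realized, design = "cv")
    cors$fold <- f
    out[[f]] <- cors
  }
  list(cors = do.call(rbind, out), varcomp = start)
}

#' Simulate two datasets linked by common sires
#'
#' Shared sires' true (intercept, slope) values in dataset B are correlated
#' `rho` with their dataset-A values (jointly MVN with marginal covariance K
#' and cross-covariance `rho K`), emulating progeny recorded in two
#' populations with a between-dataset genetic correlation `rho`.
#'
#' @param config_a,config_b [sim_config()]s for the two datasets.
#' @param shared_sires Number of sires with progeny in both datasets.
#' @param rho Between-dataset genetic correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @return List of class `rn_paired_sim`: `a`, `b` (each an `rn_sim`),
#'   `shared_sires` (ids common to both), `rho`.
#' @export
simulate_paired_datasets <- function(config_a, config_b = config_a,
                                     shared_sires, rho, seed = NULL) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (shared_sires > min(config_a$n_sires, config_b$n_sires))
    stop("shared_sires exceeds the number of sires")
  if (!isTRUE(all.equal(config_a$K, config_b$K)))
    stop("paired datasets assume a common genetic covariance K")
  with_seed(seed, {
    K <- config_a$K
    shared_a <- rmvn(shared_sires, K)
    shared_b <- rho * shared_a + sqrt(1 - rho^2) * rmvn(shared_sires, K)
    sid_shared <- sprintf("CS%04d", seq_len(shared_sires))
    make_tbv <- function(cf, shared, prefix) {
      extra <- cf$n_sires - shared_sires
      list(tbv = rbind(shared, rmvn(extra, K)),
           ids = c(sid_shared, if (extra > 0)
             sprintf("%s%04d", prefix, seq_len(extra))))
    }
    ta <- make_tbv(config_a, shared_a, "AS")
    tb <- make_tbv(config_b, shared_b, "BS")
    s1 <- sample.int(2147483600, 2)
    a <- simulate_population(config_a, seed = s1[1], sire_tbv = ta$tbv,
                             sire_ids = ta$ids)
    b <- simulate_population(config_b, seed = s1[2], sire_tbv = tb$tbv,
                             sire_ids = tb$ids)
    structure(list(a = a, b = b, shared_sires = sid_shared, rho = rho),
              class = "rn_paired_sim")
  })
}
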