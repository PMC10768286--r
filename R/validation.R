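# Validation designs: threefold cross-validation with triplet fold
# assignment, forward prediction, and between-dataset sire comparison,
# with phenotype pre-correction and realized sire regressions.

#' Assign cross-validation folds by the within-sire triplet design
#'
#' Within each sire, progeny are ordered by EC; each consecutive triplet is
#' randomly permuted over the folds (leftover one or two progeny get a
#' random partial permutation), which spreads every sire's environmental
#' range across all folds. Sires need `min_progeny` progeny in total, an
#' overall EC range of `min_range_gday`, and that range within every fold;
#' progeny of ineligible sires are left unassigned (training-only).
#'
#' @param dataset A filtered `rn_dataset`.
#' @param ecmap An `rn_ecmap`.
#' @param seed Integer seed controlling the (only) randomness.
#' @param min_progeny Minimum progeny per eligible sire (default 25).
#' @param min_range_gday Minimum EC range in g/day overall and per fold
#'   (default 60).
#' @param n_folds Number of folds (default 3).
#' @return List of class `rn_folds`: `assignment` (data.frame `animal_id`,
#'   `sire_id`, `fold`; `NA` fold = training only), `eligible_sires`,
#'   `n_folds`.
#' @export
assign_cv_folds <- function(dataset, ecmap, seed = NULL, min_progeny = 25,
                            min_range_gday = 60, n_folds = 3) {
  stopifnot(inherits(dataset, "rn_dataset"))
  df <- dataset$phenotypes
  x_gday <- ec_for_records(ecmap, df$cg_key, "centred")
  with_seed(seed, {
    fold <- rep(NA_integer_, nrow(df))
    sires <- unique(df$sire)
    eligible <- character(0)
    for (s in sires) {
      idx <- which(df$sire == s)
      if (length(idx) < min_progeny) next
      if (diff(range(x_gday[idx])) < min_range_gday) next
      ord <- idx[order(x_gday[idx])]
      f <- integer(length(ord))
      i <- 1L
      while (i <= length(ord)) {
        k <- min(n_folds, length(ord) - i + 1L)
        f[i:(i + k - 1L)] <- sample(n_folds, k)
        i <- i + k
      }
      ranges <- vapply(seq_len(n_folds), function(j) {
        v <- x_gday[ord[f == j]]
        if (length(v) < 2) 0 else diff(range(v))
      }, numeric(1))
      if (all(ranges >= min_range_gday)) {
        fold[ord] <- f
        eligible <- c(eligible, s)
      }
    }
    if (!length(eligible))
      stop("no sires meet the cross-validation eligibility rules")
    structure(list(assignment = data.frame(animal_id = df$animal,
                                           sire_id = df$sire, fold = fold,
                                           stringsAsFactors = FALSE),
                   eligible_sires = sort(eligible), n_folds = n_folds),
              class = "rn_folds")
  })
}

#' Pre-correct phenotypes for fixed, dam-PE and genetic-group effects
#'
#' `y* = y - Xb - Z c - Q g`, retaining the additive genetic and residual
#' signal. Solutions come from a full-data animal-model fit (an `rn_blup`),
#' so information from all validation-years records enters the corrections.
#'
#' @param dataset The `rn_dataset` whose phenotypes are corrected (must be
#'   the data the `blup` was solved on).
#' @param blup An `rn_blup` from [solve_blup()] on an animal model with the
#'   effects to be removed.
#' @return The dataset with a `y_star` column added to its phenotypes.
#' @export
precorrect_phenotypes <- function(dataset, blup) {
  stopifnot(inherits(dataset, "rn_dataset"), inherits(blup, "rn_blup"))
  df <- dataset$phenotypes
  if (!identical(as.character(df$animal), as.character(blup$records)))
    stop("blup was solved on different records than the dataset")
  out <- dataset
  out$phenotypes$y_star <- df[[blup$spec$response]] - blup$correction
  out
}

#' Realized progeny performance: sire random regression on the EC
#'
#' Regresses pre-corrected phenotypes of each sire's (test-set) progeny
#' across the EC with a random intercept and slope per sire, identity sire
#' covariance (relationships between sires ignored) and the continuous
#' residual model. Variance components are re-estimated by REML within the
#' test set; the BLUP coefficients `p0` (overall progeny performance) and
#' `p1` (realized robustness) are returned per sire.
#'
#' @param dataset An `rn_dataset` whose phenotypes carry `y_star` (see
#'   [precorrect_phenotypes()]); typically already restricted to one test
#'   fold.
#' @param ecmap An `rn_ecmap`.
#' @param sires Optional sire ids to include (default: all in the data).
#' @param start Optional starting variance components for the REML fit.
#' @param varcomp Optional variance components; when supplied the REML step
#'   is skipped and BLUP is solved directly at these values.
#' @param fixed Fixed effects of the sire regression (default `"mean"`:
#'   phenotypes are already pre-corrected).
#' @return List of class `rn_realized`: `regression` (data.frame `sire_id`,
#'   `p0`, `p1`), `varcomp`.
#' @export
fit_realized_regression <- function(dataset, ecmap, sires = NULL, start = NULL,
                                    varcomp = NULL, fixed = "mean") {
  stopifnot(inherits(dataset, "rn_dataset"))
  df <- dataset$phenotypes
  if (is.null(df$y_star)) stop("phenotypes lack y_star; pre-correct first")
  if (!is.null(sires)) {
    out <- dataset
    out$phenotypes <- df[df$sire %in% sires, , drop = FALSE]
    dataset <- out
    df <- dataset$phenotypes
  }
  if (!nrow(df)) stop("no test records")
  x <- ec_for_records(ecmap, df$cg_key)
  flat <- tapply(x, df$sire, function(v) diff(range(v)) == 0)
  if (any(flat))
    warning("sire(s) with all progeny at one EC; their slope is shrunk to 0: ",
            paste(head(names(flat)[flat], 5), collapse = ", "))
  spec <- rn_model(response = "y_star", fixed = fixed, genetic = "sire",
                   reaction_norm = TRUE, relationship = "identity",
                   residual = rn_residual("continuous"))
  vc <- varcomp %||% fit_reaction_norm(dataset, ecmap, spec, start = start)$varcomp
  blup <- solve_blup(dataset, ecmap, spec, vc)
  structure(list(regression = data.frame(sire_id = blup$ebv$animal_id,
                                         p0 = blup$ebv$a0, p1 = blup$ebv$a1,
                                         stringsAsFactors = FALSE),
                 varcomp = vc),
            class = "rn_realized")
}

#' Correlate training EBV with realized progeny performance
#'
#' Pearson correlations between sire EBV (intercept, slope, scale-corrected
#' slope) and the realized regression coefficients of their test progeny.
#'
#' @param ebv Data.frame with `animal_id`, `a0`, `a1` and optionally
#'   `a1_star` (e.g. the `ebv` element of an `rn_blup`), or an `rn_blup`.
#' @param realized An `rn_realized` or data.frame with `sire_id`, `p0`,
#'   `p1`.
#' @param design Label stored with the result (`"cv"`, `"forward"`,
#'   `"between-datasets"`).
#' @return Data.frame of class `rn_validation` with columns `component`
#'   (`a0_p0`, `a1_p1`, `a1_star_p1`), `correlation`, `n_sires`, `design`.
#' @export
correlate_validation <- function(ebv, realized, design = "cv") {
  if (inherits(ebv, "rn_blup")) ebv <- ebv$ebv
  if (inherits(realized, "rn_realized")) realized <- realized$regression
  m <- merge(ebv, realized, by.x = "animal_id", by.y = "sire_id")
  if (nrow(m) < 3) stop("fewer than 3 sires in common")
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }
  comps <- c(a0_p0 = safe_cor(m$a0, m$p0), a1_p1 = safe_cor(m$a1, m$p1))
  if (!is.null(m$a1_star))
    comps <- c(comps, a1_star_p1 = safe_cor(m$a1_star, m$p1))
  out <- data.frame(component = names(comps), correlation = unname(comps),
                    n_sires = nrow(m), design = design,
                    stringsAsFactors = FALSE)
  class(out) <- c("rn_validation", "data.frame")
  out
}

#' Average validation correlations across folds
#'
#' Arithmetic mean of per-fold Pearson correlations per component.
#'
#' @param results List of `rn_validation` data.frames (one per fold).
#' @return Data.frame `component`, `correlation` (mean), `n_folds`.
#' @export
average_folds <- function(results) {
  all <- do.call(rbind, results)
  agg <- aggregate(correlation ~ component, data = all, FUN = mean)
  agg$n_folds <- length(results)
  agg
}

#' Split a dataset for forward prediction by birth year
#'
#' @param dataset A filtered `rn_dataset` with `birth_year`.
#' @param train_years Years forming the training partition.
#' @param test_year Single test year.
#' @param ecmap An `rn_ecmap` (for the test-sire eligibility rules).
#' @param min_progeny,min_range_gday Test-sire eligibility: at least this
#'   many progeny spanning at least this EC range (g/day) within the test
#'   year.
#' @return List: `train` and `test` (`rn_dataset`s) and `eligible_sires`.
#' @export
forward_split <- function(dataset, train_years, test_year, ecmap,
                          min_progeny = 25, min_range_gday = 60) {
  stopifnot(inherits(dataset, "rn_dataset"), length(test_year) == 1)
  df <- dataset$phenotypes
  if (all(is.na(df$birth_year))) stop("birth_year is missing")
  tr <- df$birth_year %in% train_years
  te <- df$birth_year %in% test_year
  if (!any(tr) || !any(te)) stop("empty train or test partition")
  test_df <- df[te, , drop = FALSE]
  x_gday <- ec_for_records(ecmap, test_df$cg_key, "centred")
  prog <- table(test_df$sire)
  rng <- tapply(x_gday, test_df$sire, function(v) diff(range(v)))
  eligible <- names(prog)[prog >= min_progeny &
                            rng[names(prog)] >= min_range_gday]
  if (!length(eligible)) stop("no eligible test sires")
  train <- test <- dataset
  train$phenotypes <- df[tr, , drop = FALSE]
  test$phenotypes <- test_df
  list(train = train, test = test, eligible_sires = sort(eligible))
}

#' Expected between-dataset EBV correlation from accuracies
#'
#' Per component, the mean EBV accuracy within each dataset is obtained by
#' Fisher-Z averaging over the common sires; the expected correlation of the
#' two sets of EBV (under a between-dataset genetic correlation of 1) is the
#' product of the two mean accuracies. The `a1` expectation serves as the
#' approximation for the scale-corrected slope.
#'
#' @param ebv1,ebv2 Data.frames (or `rn_blup`s) with `animal_id`, `acc_a0`,
#'   `acc_a1` for the two datasets.
#' @return Data.frame `component`, `rbar_1`, `rbar_2`, `expected`.
#' @export
expected_correlation <- function(ebv1, ebv2) {
  if (inherits(ebv1, "rn_blup")) ebv1 <- ebv1$ebv
  if (inherits(ebv2, "rn_blup")) ebv2 <- ebv2$ebv
  common <- intersect(ebv1$animal_id, ebv2$animal_id)
  if (length(common) < 1) stop("no common sires")
  e1 <- ebv1[match(common, ebv1$animal_id), ]
  e2 <- ebv2[match(common, ebv2$animal_id), ]
  comp <- c(a0 = "acc_a0", a1 = "acc_a1")
  out <- do.call(rbind, lapply(names(comp), function(nm) {
    r1 <- fisher_z_mean(e1[[comp[nm]]])
    r2 <- fisher_z_mean(e2[[comp[nm]]])
    data.frame(component = nm, rbar_1 = r1, rbar_2 = r2,
               expected = r1 * r2, stringsAsFactors = FALSE)
  }))
  out
}

#' Compare sire EBV between two independently fitted datasets
#'
#' Pearson correlations of intercept, slope and scale-corrected slope EBV
#' over common sires (optionally within subsets, e.g. sires with many
#' progeny in both datasets), paired with the accuracy-based expected
#' correlations.
#'
#' @param blup1,blup2 `rn_blup`s (with PEV/accuracies for the expected
#'   correlations) from the two datasets; `a1_star` added via
#'   [scale_correct()].
#' @param subsets Named list of sire-id vectors defining subsets (`NULL`
#'   entry = all common sires). Default: all common sires.
#' @return List of class `rn_between`: `correlations` (per subset an
#'   `rn_validation`-style data.frame; subsets with fewer than 3 common
#'   sires are reported as missing), `expected` (per subset).
#' @export
compare_between_datasets <- function(blup1, blup2, subsets = list(all = NULL)) {
  e1 <- if (inherits(blup1, "rn_blup")) blup1$ebv else blup1
  e2 <- if (inherits(blup2, "rn_blup")) blup2$ebv else blup2
  common <- intersect(e1$animal_id, e2$animal_id)
  res <- list(); exp_res <- list()
  for (nm in names(subsets)) {
    ids <- if (is.null(subsets[[nm]])) common else intersect(subsets[[nm]], common)
    if (length(ids) < 3) {
      res[[nm]] <- NULL
      exp_res[[nm]] <- NULL
      next
    }
    a <- e1[match(ids, e1$animal_id), ]
    b <- e2[match(ids, e2$animal_id), ]
    safe_cor <- function(u, v) if (sd(u) == 0 || sd(v) == 0) NA_real_ else cor(u, v)
    comps <- c(a0 = safe_cor(a$a0, b$a0), a1 = safe_cor(a$a1, b$a1))
    if (!is.null(a$a1_star) && !is.null(b$a1_star))
      comps <- c(comps, a1_star = safe_cor(a$a1_star, b$a1_star))
    res[[nm]] <- data.frame(component = names(comps),
                            correlation = unname(comps),
                            n_sires = length(ids), design = "between-datasets",
                            stringsAsFactors = FALSE)
    if (!is.null(a$acc_a0))
      exp_res[[nm]] <- expected_correlation(a, b)
  }
  if (!length(res)) stop("fewer than 3 common sires in every subset")
  structure(list(correlations = res, expected = exp_res,
                 n_common = length(common)),
            class = "rn_between")
}
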