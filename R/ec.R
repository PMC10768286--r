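# Environmental covariable (EC): the BLUE of contemporary-group
# post-weaning growth rate, centred and standardized.

#' Construct an ECMap from known contemporary-group values
#'
#' Used by the simulator and for externally supplied ECs. Values are given
#' as mean-centred g/day; standardization divides by `ec_sd` (default: the
#' SD of the supplied values).
#'
#' @param cg_key Contemporary-group keys.
#' @param centred_gday Mean-centred EC values in g/day.
#' @param ec_sd EC standard deviation in g/day used for standardization.
#' @param ec_mean Mean growth rate in g/day (kept for reporting; default 0).
#' @return Data.frame of class `rn_ecmap` with columns `cg_key`, `blue`,
#'   `centred`, `standardized` and attributes `ec_mean`, `ec_sd`.
#' @export
rn_ecmap <- function(cg_key, centred_gday, ec_sd = NULL, ec_mean = 0) {
  stopifnot(length(cg_key) == length(centred_gday))
  if (anyDuplicated(cg_key)) stop("duplicate contemporary-group keys")
  centred_gday <- centred_gday - mean(centred_gday)
  ec_sd <- ec_sd %||% sd(centred_gday)
  if (!is.finite(ec_sd) || ec_sd <= 0) stop("ec_sd must be positive")
  out <- data.frame(cg_key = as.character(cg_key), blue = ec_mean + centred_gday,
                    centred = centred_gday, standardized = centred_gday / ec_sd,
                    stringsAsFactors = FALSE)
  attr(out, "ec_mean") <- ec_mean
  attr(out, "ec_sd") <- ec_sd
  class(out) <- c("rn_ecmap", "data.frame")
  out
}

#' Derive the environmental covariable from contemporary-group growth
#'
#' Fits a mixed model to post-weaning growth rate with fixed sex,
#' birth-by-rear type, post-weaning age (linear and quadratic) and
#' contemporary group, plus random additive genetic effects (pedigree
#' relationship), optional random genetic-group effects and an optional
#' permanent environmental dam effect. The BLUEs of the contemporary-group
#' effects form the EC, which is mean-centred and standardized to unit
#' variance across contemporary groups.
#'
#' @param dataset A filtered `rn_dataset`.
#' @param relationship `"A"`, `"identity"`, or an `rn_relinv`.
#' @param use_dam_pe Fit the permanent environmental dam effect.
#' @param genetic_groups Fit random genetic-group effects (requires
#'   `genetic_group` labels in the pedigree).
#' @param var_ratios Optional known variance components
#'   (`list(sigma2_a=, sigma2_e=, sigma2_c=, sigma2_g=)`) to skip REML.
#' @param size_weighted Standardize using the record-weighted EC variance
#'   instead of the unweighted variance across contemporary groups.
#' @return An `rn_ecmap`; contemporary groups whose records all share one
#'   sire are flagged in a `confounded` column with a warning.
#' @export
derive_ec <- function(dataset, relationship = "A", use_dam_pe = FALSE,
                      genetic_groups = FALSE, var_ratios = NULL,
                      size_weighted = FALSE) {
  stopifnot(inherits(dataset, "rn_dataset"))
  df <- dataset$phenotypes
  if (length(unique(df$cg_key)) < 2)
    stop("at least two contemporary groups are required to derive an EC")
  spec <- rn_model(response = "pwgr",
                   fixed = c("sex", "birth_rear", "age", "cg"),
                   genetic = "animal", reaction_norm = FALSE,
                   relationship = relationship, dam_pe = use_dam_pe,
                   genetic_groups = genetic_groups,
                   residual = rn_residual("iid"))
  vc <- if (!is.null(var_ratios)) {
    do.call(rn_varcomp, var_ratios[intersect(names(var_ratios),
      c("sigma2_a", "sigma2_e", "sigma2_c", "sigma2_g"))])
  } else {
    fit_reaction_norm(dataset, NULL, spec)$varcomp
  }
  blup <- solve_blup(dataset, NULL, spec, vc)

  cg_levels <- levels(factor(df$cg_key))
  coef <- blup$fixed
  icpt <- unname(coef["(Intercept)"])
  blue <- setNames(rep(icpt, length(cg_levels)), cg_levels)
  cg_cols <- grep("^cg", names(coef))
  if (length(cg_cols)) {
    lv <- sub("^cg", "", names(coef)[cg_cols])
    blue[lv] <- blue[lv] + coef[cg_cols]
  }
  centred <- blue - mean(blue)
  sizes <- as.numeric(table(factor(df$cg_key, levels = cg_levels)))
  ec_sd <- if (size_weighted) {
    mu_w <- sum(sizes * blue) / sum(sizes)
    sqrt(sum(sizes * (blue - mu_w)^2) / sum(sizes))
  } else sd(centred)
  out <- rn_ecmap(cg_levels, as.numeric(centred), ec_sd = ec_sd,
                  ec_mean = mean(blue))
  one_sire <- tapply(df$sire, factor(df$cg_key, levels = cg_levels),
                     function(s) length(unique(s)) == 1)
  out$confounded <- as.logical(one_sire[out$cg_key])
  if (any(out$confounded))
    warning("contemporary group(s) with a single sire retained but flagged: ",
            paste(head(out$cg_key[out$confounded], 5), collapse = ", "))
  out
}

#' EC values for a vector of contemporary-group keys
#'
#' @param ecmap An `rn_ecmap`.
#' @param cg_keys Contemporary-group keys.
#' @param scale `"standardized"` (unitless) or `"centred"` (g/day).
#' @return Numeric vector of EC values.
#' @export
ec_for_records <- function(ecmap, cg_keys, scale = c("standardized", "centred")) {
  scale <- match.arg(scale)
  m <- match(as.character(cg_keys), ecmap$cg_key)
  if (anyNA(m)) stop("unknown contemporary group(s): ",
                     paste(head(unique(cg_keys[is.na(m)]), 5), collapse = ", "))
  ecmap[[scale]][m]
}

#' Trim a dataset to contemporary groups near the mean EC
#'
#' Removes all records in contemporary groups whose mean-centred EC is more
#' than `limit_g_per_day` from zero, because sparse data at the extremes of
#' an EC yield unreliable reaction-norm estimates.
#'
#' @param dataset An `rn_dataset`.
#' @param ecmap An `rn_ecmap`.
#' @param limit_g_per_day Positive trimming limit in g/day (e.g. 75 or 120).
#' @return The trimmed `rn_dataset`.
#' @export
trim_by_ec <- function(dataset, ecmap, limit_g_per_day) {
  if (!is.numeric(limit_g_per_day) || length(limit_g_per_day) != 1 ||
      is.na(limit_g_per_day) || limit_g_per_day <= 0)
    stop("limit must be a positive number of g/day")
  keep_cg <- ecmap$cg_key[abs(ecmap$centred) <= limit_g_per_day]
  out <- dataset
  out$phenotypes <- dataset$phenotypes[dataset$phenotypes$cg_key %in% keep_cg, ,
                                       drop = FALSE]
  if (!nrow(out$phenotypes)) stop("no records remain after EC trimming")
  out
}
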