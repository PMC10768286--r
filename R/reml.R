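# Linear reaction-norm mixed models: model specification, design
# construction, restricted likelihood, REML fitting and BLUP solving.
#
# The restricted log-likelihood is evaluated through Henderson's mixed-model
# equations: with C the full MME coefficient matrix,
#   -2 logL = (n - p) log 2pi + log|R| + log|G| + log|C| + y' P y,
# which equals the dense form log|V| + log|X' V^-1 X| + y' P y. Variance
# matrices are kept positive definite by log-Cholesky parameterisation, so
# no projection onto the PSD cone is ever needed during optimisation.

#' Residual-variance model along the EC
#'
#' @param type `"continuous"` (intercept and slope residual coefficients,
#'   2x2 covariance E, per-record variance `[1, x] E [1, x]'`),
#'   `"classes"` (separate variances in discrete EC intervals) or `"iid"`.
#' @param breaks For `"classes"`: strictly increasing class boundaries on
#'   the mean-centred EC scale in g/day, spanning the data range.
#' @return List of class `rn_residual`.
#' @export
rn_residual <- function(type = c("continuous", "classes", "iid"), breaks = NULL) {
  type <- match.arg(type)
  if (type == "classes") {
    if (is.null(breaks) || length(breaks) < 2 || any(diff(breaks) <= 0))
      stop("class residual model needs strictly increasing breaks")
  }
  structure(list(type = type, breaks = breaks), class = "rn_residual")
}

#' Specify a (reaction-norm) mixed model
#'
#' @param response Phenotype column to analyse (default `"pw_weight"`).
#' @param fixed Character vector of fixed-effect terms among `"mean"`,
#'   `"sex"`, `"birth_rear"`, `"age"`, `"dam_age"`, `"cg"`. `NULL` selects
#'   `sex`, `birth_rear`, `age` and `cg` where the data support them
#'   (factors with a single level are dropped).
#' @param genetic `"animal"` or `"sire"` model.
#' @param reaction_norm If `TRUE`, fit genetic intercept and slope on the
#'   EC; if `FALSE`, a plain single-coefficient genetic effect.
#' @param relationship `"A"` (pedigree), `"identity"`, or an `rn_relinv`
#'   object (e.g. a blended single-step matrix via [as_relinv()]).
#' @param dam_pe Fit a permanent environmental dam effect (identity
#'   covariance; relationships between dams ignored).
#' @param genetic_groups Fit random genetic-group effects with common
#'   variance through the group-proportion matrix Q.
#' @param maternal Fit an additive maternal genetic effect (pedigree
#'   covariance, zero covariance with all other terms).
#' @param residual An [rn_residual()] specification.
#' @param generations Ancestral pedigree depth used for A (default `Inf`).
#' @return List of class `rn_model`.
#' @export
rn_model <- function(response = "pw_weight", fixed = NULL,
                     genetic = c("animal", "sire"), reaction_norm = TRUE,
                     relationship = if (genetic[1] == "sire") "identity" else "A",
                     dam_pe = FALSE, genetic_groups = FALSE, maternal = FALSE,
                     residual = rn_residual(if (reaction_norm) "continuous" else "iid"),
                     generations = Inf) {
  genetic <- match.arg(genetic)
  structure(list(response = response, fixed = fixed, genetic = genetic,
                 reaction_norm = reaction_norm, relationship = relationship,
                 dam_pe = dam_pe, genetic_groups = genetic_groups,
                 maternal = maternal, residual = residual,
                 generations = generations),
            class = "rn_model")
}

build_fixed <- function(df, terms) {
  n <- nrow(df)
  if (is.null(terms)) terms <- c("sex", "birth_rear", "age", "cg")
  dat <- list()
  for (t in terms) {
    switch(t,
      mean = NULL,
      sex = {
        f <- factor(df$sex)
        if (nlevels(f) > 1) dat$sex <- f
      },
      birth_rear = {
        f <- interaction(df$birth_type, df$rear_type, drop = TRUE)
        if (nlevels(f) > 1) dat$birth_rear <- f
      },
      cg = {
        f <- factor(df$cg_key)
        if (nlevels(f) > 1) dat$cg <- f
      },
      age = {
        if (sd(df$pw_age) > 0) {
          z <- (df$pw_age - mean(df$pw_age)) / sd(df$pw_age)
          dat$age <- z
          dat$age2 <- z^2
        }
      },
      dam_age = {
        if (!is.null(df$dam_age) && sd(df$dam_age) > 0) {
          z <- (df$dam_age - mean(df$dam_age)) / sd(df$dam_age)
          dat$dam_age <- z
          dat$dam_age2 <- z^2
        }
      },
      stop("unknown fixed term: ", t))
  }
  X <- if (length(dat)) model.matrix(~ ., data = as.data.frame(dat))
       else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X
}

incidence <- function(keys, ids) {
  j <- match(keys, ids)
  if (anyNA(j)) stop("levels without a covariance entry: ",
                     paste(head(unique(keys[is.na(j)]), 5), collapse = ", "))
  sparseMatrix(i = seq_along(keys), j = j, x = 1,
               dims = c(length(keys), length(ids)))
}

# Assemble response, EC values, fixed design, random terms and residual
# structure for a model specification.
build_design <- function(dataset, ecmap, spec) {
  stopifnot(inherits(dataset, "rn_dataset"), inherits(spec, "rn_model"))
  df <- dataset$phenotypes
  y <- df[[spec$response]]
  if (is.null(y) || !is.numeric(y) || anyNA(y))
    stop("response '", spec$response, "' missing or non-numeric")
  n <- nrow(df)

  if (!is.null(ecmap)) {
    m <- match(df$cg_key, ecmap$cg_key)
    if (anyNA(m))
      stop("records in contemporary groups without an EC value: ",
           paste(head(unique(df$cg_key[is.na(m)]), 5), collapse = ", "))
    x <- ecmap$standardized[m]
    x_gday <- ecmap$centred[m]
    ec_sd <- attr(ecmap, "ec_sd")
  } else {
    if (spec$reaction_norm) stop("an ECMap is required for a reaction-norm model")
    x <- rep(0, n)
    x_gday <- x
    ec_sd <- NA_real_
  }

  X <- build_fixed(df, spec$fixed)
  p <- ncol(X)

  ped <- dataset$pedigree
  need_ped <- identical(spec$relationship, "A") || spec$maternal ||
    spec$genetic_groups
  if (need_ped && is.finite(spec$generations))
    ped <- truncate_pedigree(ped, unique(df$animal), spec$generations)
  a_relinv <- NULL
  get_a_relinv <- function() {
    if (is.null(a_relinv)) a_relinv <<- build_Ainv(ped)
    a_relinv
  }

  key <- if (spec$genetic == "animal") df$animal else df$sire
  rl <- if (inherits(spec$relationship, "rn_relinv")) spec$relationship
        else if (identical(spec$relationship, "identity"))
          identity_relinv(sort(unique(key)))
        else if (identical(spec$relationship, "A")) get_a_relinv()
        else stop("relationship must be 'A', 'identity' or an rn_relinv object")

  terms <- list()
  Z1 <- incidence(key, rl$ids)
  if (spec$reaction_norm) {
    Zg <- cbind(Z1, Diagonal(x = x) %*% Z1)
    terms$genetic <- list(name = "genetic", type = "rr", Z = Zg,
                          q = length(rl$ids), ids = rl$ids, relinv = rl,
                          vc_name = "K")
  } else {
    terms$genetic <- list(name = "genetic", type = "rel1", Z = Z1,
                          q = length(rl$ids), ids = rl$ids, relinv = rl,
                          vc_name = "sigma2_a")
  }
  if (spec$dam_pe) {
    dams <- sort(unique(df$dam))
    terms$dam_pe <- list(name = "dam_pe", type = "iid",
                         Z = incidence(df$dam, dams), q = length(dams),
                         ids = dams, vc_name = "sigma2_c")
  }
  if (spec$genetic_groups) {
    qm <- build_Q(ped)
    Zq <- Matrix(qm$Q[match(df$animal, qm$ids), , drop = FALSE], sparse = TRUE)
    if (anyNA(match(df$animal, qm$ids)))
      stop("phenotyped animals missing from the genetic-group pedigree")
    terms$groups <- list(name = "groups", type = "iid", Z = Zq,
                         q = length(qm$groups), ids = qm$groups,
                         vc_name = "sigma2_g")
  }
  if (spec$maternal) {
    rlm <- get_a_relinv()
    terms$maternal <- list(name = "maternal", type = "rel1",
                           Z = incidence(df$dam, rlm$ids), q = length(rlm$ids),
                           ids = rlm$ids, relinv = rlm, vc_name = "sigma2_m")
  }

  res <- spec$residual
  if (res$type == "continuous") {
    residual <- list(type = "continuous", rbasis = cbind(1, 2 * x, x^2))
  } else if (res$type == "classes") {
    cls <- findInterval(x_gday, res$breaks, rightmost.closed = TRUE)
    if (any(cls < 1 | cls > length(res$breaks) - 1))
      stop("records outside the residual class breakpoints")
    residual <- list(type = "classes", cls = cls,
                     nclass = length(res$breaks) - 1, breaks = res$breaks)
  } else {
    residual <- list(type = "classes", cls = rep(1L, n), nclass = 1L,
                     breaks = NULL)
  }

  W <- cbind(Matrix(X, sparse = TRUE), do.call(cbind, lapply(terms, `[[`, "Z")))
  q_each <- vapply(terms, function(t)
    if (t$type == "rr") 2L * t$q else t$q, integer(1))
  offsets <- p + c(0L, cumsum(q_each))[seq_along(terms)]
  names(offsets) <- names(terms)

  list(df = df, y = y, n = n, x = x, x_gday = x_gday, ec_sd = ec_sd,
       X = X, p = p, W = W, terms = terms, offsets = offsets,
       residual = residual, spec = spec)
}

resid_var <- function(des, vc) {
  if (des$residual$type == "continuous") {
    E <- vc$E
    if (is.null(E)) stop("continuous residual model needs E")
    drop(des$residual$rbasis %*% c(E[1, 1], E[1, 2], E[2, 2]))
  } else {
    s <- vc$sigma2_e
    if (is.null(s) || length(s) != des$residual$nclass)
      stop("class residual model needs ", des$residual$nclass, " variances")
    s[des$residual$cls]
  }
}

# --- parameter packing ------------------------------------------------------

par_blocks <- function(des) {
  blocks <- list()
  add <- function(name, kind, k) blocks[[name]] <<- list(kind = kind, k = k)
  for (t in des$terms) {
    if (t$type == "rr") add(t$vc_name, "cov2", 3L)
    else add(t$vc_name, "logvar", 1L)
  }
  if (des$residual$type == "continuous") add("E", "cov2", 3L)
  else add("sigma2_e", "logvar_vec", des$residual$nclass)
  blocks
}

vc_to_par <- function(vc, des) {
  out <- numeric(0)
  for (nm in names(par_blocks(des))) {
    b <- par_blocks(des)[[nm]]
    v <- vc[[nm]]
    if (is.null(v)) stop("variance components lack '", nm, "'")
    out <- c(out, switch(b$kind,
      cov2 = pack_cov2(v),
      logvar = log(v),
      logvar_vec = log(v)))
  }
  out
}

par_to_vc <- function(par, des) {
  blocks <- par_blocks(des)
  vc <- list()
  i <- 0L
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    pp <- par[i + seq_len(b$k)]
    i <- i + b$k
    vc[[nm]] <- switch(b$kind,
      cov2 = unpack_cov2(pp),
      logvar = exp(pp),
      logvar_vec = exp(pp))
  }
  if (!is.null(vc$K))
    vc$r_a0a1 <- vc$K[1, 2] / sqrt(vc$K[1, 1] * vc$K[2, 2])
  vc
}

default_start <- function(des) {
  vy <- var(des$y)
  vc <- list()
  gshare <- if (des$spec$genetic == "sire") 0.08 else 0.3
  for (t in des$terms) {
    if (t$type == "rr") vc$K <- diag(c(gshare * vy, 0.15 * gshare * vy))
    else vc[[t$vc_name]] <- 0.05 * vy
  }
  if (!is.null(vc$sigma2_a)) vc$sigma2_a <- gshare * vy
  if (des$residual$type == "continuous")
    vc$E <- diag(c(0.55 * vy, 0.05 * vy))
  else vc$sigma2_e <- rep(0.55 * vy, des$residual$nclass)
  vc
}

# --- restricted likelihood --------------------------------------------------

# Restricted log-likelihood at given components; returns -Inf-like `big`
# on infeasible values. `cache` (an environment) carries the symbolic
# Cholesky factorisation between calls.
eval_restricted <- function(des, vc, cache = new.env(parent = emptyenv())) {
  big <- 1e10
  W <- des$W
  y <- des$y
  rv <- tryCatch(resid_var(des, vc), error = function(e) NULL)
  if (is.null(rv) || any(!is.finite(rv)) || any(rv <= 1e-10)) return(-big)
  dinv <- 1 / rv
  Ginvs <- vector("list", length(des$terms))
  ldG <- 0
  for (k in seq_along(des$terms)) {
    t <- des$terms[[k]]
    if (t$type == "rr") {
      Kc <- tryCatch(chol(vc$K), error = function(e) NULL)
      if (is.null(Kc) || any(diag(Kc) < 1e-8)) return(-big)
      Ginvs[[k]] <- kronecker(chol2inv(Kc), t$relinv$inv)
      ldG <- ldG + t$q * 2 * sum(log(diag(Kc))) + 2 * t$relinv$logdet
    } else if (t$type == "rel1") {
      s2 <- vc[[t$vc_name]]
      if (s2 <= 1e-12) return(-big)
      Ginvs[[k]] <- t$relinv$inv / s2
      ldG <- ldG + t$q * log(s2) + t$relinv$logdet
    } else {
      s2 <- vc[[t$vc_name]]
      if (s2 <= 1e-12) return(-big)
      Ginvs[[k]] <- Diagonal(t$q) / s2
      ldG <- ldG + t$q * log(s2)
    }
  }
  Ws <- Diagonal(x = sqrt(dinv)) %*% W
  C <- forceSymmetric(crossprod(Ws) +
                        bdiag(c(list(Matrix(0, des$p, des$p)), Ginvs)))
  ch <- if (is.null(cache$ch)) {
    tryCatch(Cholesky(C, LDL = FALSE, perm = TRUE), error = function(e) NULL)
  } else {
    tryCatch(update(cache$ch, C), error = function(e)
      tryCatch(Cholesky(C, LDL = FALSE, perm = TRUE), error = function(e) NULL))
  }
  if (is.null(ch)) return(-big)
  cache$ch <- ch
  rhs <- crossprod(W, dinv * y)
  sol <- solve(ch, rhs)
  yPy <- sum(dinv * y^2) - sum(rhs * sol)
  ldC <- 2 * as.numeric(determinant(ch, sqrt = TRUE)$modulus)
  ll <- -0.5 * ((des$n - des$p) * log(2 * pi) + sum(log(rv)) + ldG + ldC + yPy)
  if (!is.finite(ll)) return(-big)
  ll
}

make_nll <- function(des) {
  cache <- new.env(parent = emptyenv())
  function(par) {
    vc <- tryCatch(par_to_vc(par, des), error = function(e) NULL)
    if (is.null(vc)) return(1e10)
    -eval_restricted(des, vc, cache)
  }
}

#' Restricted log-likelihood of a reaction-norm model
#'
#' Evaluates the REML log-likelihood (including its constant) at given
#' variance components. Mainly useful for diagnostics and model comparison.
#'
#' @inheritParams fit_reaction_norm
#' @param varcomp Variance components (list or `rn_varcomp`).
#' @return The restricted log-likelihood.
#' @export
reml_loglik <- function(dataset, ecmap, spec, varcomp) {
  des <- build_design(dataset, ecmap, spec)
  eval_restricted(des, varcomp)
}

new_varcomp <- function(vc, des, loglik = NA_real_, se = NULL) {
  structure(list(
    K = vc$K, r_a0a1 = vc$r_a0a1, sigma2_a = vc$sigma2_a,
    E = vc$E, sigma2_e = vc$sigma2_e,
    residual_type = des$residual$type, breaks = des$residual$breaks,
    sigma2_c = vc$sigma2_c, sigma2_g = vc$sigma2_g, sigma2_m = vc$sigma2_m,
    loglik = loglik, se = se,
    ec_range_std = if (all(is.finite(des$x))) range(des$x) else c(-Inf, Inf),
    ec_sd = des$ec_sd), class = "rn_varcomp")
}

#' Construct a variance-component object directly
#'
#' Builds the container returned by [fit_reaction_norm()] from known values,
#' e.g. published estimates, for use with [solve_blup()],
#' [variance_profile()] or [scale_correct()].
#'
#' @param K 2x2 genetic (co)variance of intercept and slope (kg^2; slope per
#'   SD of EC). Alternatively `sigma2_a` for a single-coefficient model.
#' @param E 2x2 residual intercept/slope covariance (continuous model), or
#'   `sigma2_e` a vector of per-class residual variances with `breaks`.
#' @param sigma2_a,sigma2_e,breaks,sigma2_c,sigma2_g,sigma2_m Remaining
#'   components; `NULL` when absent from the model.
#' @param ec_range_std EC range (standardized units) over which the model is
#'   considered fitted.
#' @param ec_sd EC standard deviation in g/day (for unit conversions).
#' @return An object of class `rn_varcomp`.
#' @export
rn_varcomp <- function(K = NULL, E = NULL, sigma2_a = NULL, sigma2_e = NULL,
                       breaks = NULL, sigma2_c = NULL, sigma2_g = NULL,
                       sigma2_m = NULL, ec_range_std = c(-2, 2), ec_sd = NA) {
  if (!is.null(K) && !is_square_psd(K)) stop("K must be symmetric PSD")
  if (!is.null(E) && !is_square_psd(E)) stop("E must be symmetric PSD")
  structure(list(K = K,
                 r_a0a1 = if (!is.null(K)) K[1, 2] / sqrt(K[1, 1] * K[2, 2]),
                 sigma2_a = sigma2_a, E = E, sigma2_e = sigma2_e,
                 residual_type = if (!is.null(E)) "continuous" else "classes",
                 breaks = breaks, sigma2_c = sigma2_c, sigma2_g = sigma2_g,
                 sigma2_m = sigma2_m, loglik = NA_real_, se = NULL,
                 ec_range_std = ec_range_std, ec_sd = ec_sd),
            class = "rn_varcomp")
}

#' @exportS3Method base::print
print.rn_varcomp <- function(x, ...) {
  cat("<rn_varcomp>\n")
  if (!is.null(x$K)) {
    cat(sprintf("  K: s2_a0 = %.4g, s2_a1 = %.4g, r_a0a1 = %.3f\n",
                x$K[1, 1], x$K[2, 2], x$r_a0a1))
  } else cat(sprintf("  s2_a = %.4g\n", x$sigma2_a))
  if (!is.null(x$E))
    cat(sprintf("  E: s2_e1 = %.4g, s2_e2 = %.4g, cov = %.4g\n",
                x$E[1, 1], x$E[2, 2], x$E[1, 2]))
  if (!is.null(x$sigma2_e))
    cat("  residual classes:", paste(signif(x$sigma2_e, 4), collapse = ", "), "\n")
  for (nm in c("sigma2_c", "sigma2_g", "sigma2_m"))
    if (!is.null(x[[nm]])) cat(sprintf("  %s = %.4g\n", nm, x[[nm]]))
  if (is.finite(x$loglik)) cat(sprintf("  logL(REML) = %.4f\n", x$loglik))
  invisible(x)
}

#' Fit a linear reaction-norm mixed model by REML
#'
#' Maximises the restricted likelihood over the genetic intercept/slope
#' covariance K, the residual model (continuous intercept/slope covariance E
#' or per-class variances), and any additional variance components in the
#' model (dam permanent environment, genetic groups, maternal genetic).
#' Covariance matrices are parameterised by their log-Cholesky factors, so
#' all iterates are positive definite; the optimiser is Nelder-Mead with a
#' restart on non-convergence.
#'
#' @param dataset An `rn_dataset` (filtered).
#' @param ecmap An `rn_ecmap` giving each contemporary group's EC.
#' @param spec An [rn_model()] specification.
#' @param start Optional starting variance components (list or
#'   `rn_varcomp`).
#' @param se Compute asymptotic standard errors from the numerically
#'   differentiated observed information (default `FALSE`).
#' @param control List: `maxit` (default `600 * n_par`), `reltol`
#'   (default 1e-10 on the likelihood).
#' @return List of class `rn_fit` with elements `varcomp` (`rn_varcomp`
#'   including the REML log-likelihood), `opt` (optimiser diagnostics) and
#'   `spec`.
#' @export
fit_reaction_norm <- function(dataset, ecmap, spec, start = NULL, se = FALSE,
                              control = list()) {
  des <- build_design(dataset, ecmap, spec)
  nll <- make_nll(des)
  par0 <- if (!is.null(start)) vc_to_par(start, des)
          else vc_to_par(default_start(des), des)
  maxit <- control$maxit %||% (600L * length(par0))
  reltol <- control$reltol %||% 1e-10
  lltol <- control$lltol %||% 1e-6
  opt <- optim(par0, nll, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
  for (k in 1:3) {
    if (opt$convergence == 0) break
    nxt <- optim(opt$par, nll, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
    improved <- opt$value - nxt$value
    opt <- nxt
    if (improved < lltol) {
      # the restart no longer moves the restricted likelihood
      opt$convergence <- 0
      break
    }
  }
  if (opt$convergence != 0)
    stop("REML did not converge within ", 4 * maxit,
         " evaluations (last -logL = ", signif(opt$value, 8), ")")
  if (opt$value >= 1e10)
    stop("REML failed: likelihood not evaluable at the optimum")
  vc <- par_to_vc(opt$par, des)
  se_out <- if (se) varcomp_se(des, vc) else NULL
  varcomp <- new_varcomp(vc, des, loglik = -opt$value, se = se_out)
  structure(list(varcomp = varcomp, opt = opt[c("counts", "convergence", "value")],
                 spec = spec, n = des$n, p = des$p),
            class = "rn_fit")
}

#' @exportS3Method base::print
print.rn_fit <- function(x, ...) {
  cat("<rn_fit> n =", x$n, " fixed df =", x$p,
      " evals =", x$opt$counts[1], "\n")
  print(x$varcomp)
  invisible(x)
}

# Standard errors by central-difference observed information on the natural
# (covariance) scale.
varcomp_se <- function(des, vc) {
  flat <- flatten_vc(vc, des)
  cache <- new.env(parent = emptyenv())
  f <- function(v) -eval_restricted(des, unflatten_vc(v, vc, des), cache)
  k <- length(flat$values)
  H <- matrix(NA_real_, k, k)
  h <- pmax(1e-5, 1e-3 * abs(flat$values))
  for (i in seq_len(k)) {
    for (j in i:k) {
      vpp <- vpm <- vmp <- vmm <- flat$values
      vpp[i] <- vpp[i] + h[i]; vpp[j] <- vpp[j] + h[j]
      vpm[i] <- vpm[i] + h[i]; vpm[j] <- vpm[j] - h[j]
      vmp[i] <- vmp[i] - h[i]; vmp[j] <- vmp[j] + h[j]
      vmm[i] <- vmm[i] - h[i]; vmm[j] <- vmm[j] - h[j]
      H[i, j] <- H[j, i] <-
        (f(vpp) - f(vpm) - f(vmp) + f(vmm)) / (4 * h[i] * h[j])
    }
  }
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  d <- diag(cov)
  d[d < 0] <- NA_real_
  setNames(sqrt(d), flat$names)
}

flatten_vc <- function(vc, des) {
  vals <- numeric(0); nms <- character(0)
  blocks <- par_blocks(des)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (b$kind == "cov2") {
      S <- vc[[nm]]
      vals <- c(vals, S[1, 1], S[1, 2], S[2, 2])
      nms <- c(nms, paste0(nm, c("_11", "_12", "_22")))
    } else {
      vals <- c(vals, vc[[nm]])
      nms <- c(nms, if (b$k > 1) paste0(nm, "_", seq_len(b$k)) else nm)
    }
  }
  list(values = vals, names = nms)
}

unflatten_vc <- function(v, template, des) {
  blocks <- par_blocks(des)
  vc <- template
  i <- 0L
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (b$kind == "cov2") {
      vc[[nm]] <- matrix(c(v[i + 1], v[i + 2], v[i + 2], v[i + 3]), 2, 2)
      i <- i + 3L
    } else {
      vc[[nm]] <- v[i + seq_len(b$k)]
      i <- i + b$k
    }
  }
  vc
}

#' Solve the mixed-model equations at given variance components
#'
#' Returns BLUE fixed effects and BLUP random effects, with optional
#' prediction error variances (diagonal of the inverse MME coefficient
#' matrix, in trait units squared since the equations carry `R^-1`
#' explicitly) and accuracies `r = sqrt(1 - PEV / sigma2)`.
#'
#' @inheritParams fit_reaction_norm
#' @param varcomp Variance components (`rn_varcomp` or the `varcomp` element
#'   of an `rn_fit`).
#' @param pev Compute PEV/accuracy for the genetic effects.
#' @param pev_ids Restrict PEV computation to these animal/sire ids
#'   (defaults to all levels of the genetic term; the MME solve is dense in
#'   the number of requested columns, so restrict on large problems).
#' @return List of class `rn_blup`: `ebv` (data.frame with `animal_id`,
#'   `a0`, `a1` or `a`, and PEV/accuracy columns when requested), `fixed`,
#'   `random` (per-term solution vectors), `correction` (per-record
#'   `Xb + dam-PE + genetic-group` adjustment used for phenotype
#'   pre-correction), `records` (record animal ids) and `varcomp`.
#' @export
solve_blup <- function(dataset, ecmap, spec, varcomp, pev = FALSE,
                       pev_ids = NULL) {
  des <- build_design(dataset, ecmap, spec)
  vc <- varcomp
  rv <- resid_var(des, vc)
  if (any(rv <= 0))
    stop("residual variance non-positive at some EC level; ",
         "consider the class residual model")
  dinv <- 1 / rv
  Ginvs <- vector("list", length(des$terms))
  for (k in seq_along(des$terms)) {
    t <- des$terms[[k]]
    Ginvs[[k]] <- if (t$type == "rr") kronecker(solve(vc$K), t$relinv$inv)
      else if (t$type == "rel1") t$relinv$inv / vc[[t$vc_name]]
      else Diagonal(t$q) / vc[[t$vc_name]]
  }
  W <- des$W
  p <- des$p
  C <- forceSymmetric(crossprod(Diagonal(x = sqrt(dinv)) %*% W) +
                        bdiag(c(list(Matrix(0, p, p)), Ginvs)))
  ch <- tryCatch(Cholesky(C, LDL = FALSE, perm = TRUE), error = function(e)
    stop("singular mixed-model equations; check for confounded effects"))
  rhs <- crossprod(W, dinv * des$y)
  sol <- as.numeric(solve(ch, rhs))

  fixed <- setNames(sol[seq_len(p)], colnames(des$X))
  random <- list()
  for (nm in names(des$terms)) {
    t <- des$terms[[nm]]
    off <- des$offsets[[nm]]
    k <- if (t$type == "rr") 2L * t$q else t$q
    random[[nm]] <- setNames(sol[off + seq_len(k)],
                             if (t$type == "rr") c(paste0(t$ids, ".a0"),
                                                   paste0(t$ids, ".a1"))
                             else t$ids)
  }

  gt <- des$terms$genetic
  goff <- des$offsets[["genetic"]]
  if (gt$type == "rr") {
    ebv <- data.frame(animal_id = gt$ids,
                      a0 = sol[goff + seq_len(gt$q)],
                      a1 = sol[goff + gt$q + seq_len(gt$q)],
                      stringsAsFactors = FALSE)
  } else {
    ebv <- data.frame(animal_id = gt$ids, a = sol[goff + seq_len(gt$q)],
                      stringsAsFactors = FALSE)
  }

  if (pev) {
    ids <- pev_ids %||% gt$ids
    ridx <- match(ids, gt$ids)
    if (anyNA(ridx)) stop("pev_ids not in the genetic term")
    nc <- nrow(C)
    pev_block <- function(rows) {
      out <- numeric(length(rows))
      chunk <- 200L
      for (s in seq(1L, length(rows), by = chunk)) {
        sel <- s:min(s + chunk - 1L, length(rows))
        B <- sparseMatrix(i = rows[sel], j = seq_along(sel), x = 1,
                          dims = c(nc, length(sel)))
        S <- solve(ch, B)
        out[sel] <- S[cbind(rows[sel], seq_along(sel))]
      }
      out
    }
    if (gt$type == "rr") {
      pev0 <- pev_block(goff + ridx)
      pev1 <- pev_block(goff + gt$q + ridx)
      m <- match(ids, ebv$animal_id)
      ebv$pev_a0 <- NA_real_; ebv$pev_a1 <- NA_real_
      ebv$acc_a0 <- NA_real_; ebv$acc_a1 <- NA_real_
      ebv$pev_a0[m] <- pev0
      ebv$pev_a1[m] <- pev1
      ebv$acc_a0[m] <- accuracy_from_pev(pev0, vc$K[1, 1])
      ebv$acc_a1[m] <- accuracy_from_pev(pev1, vc$K[2, 2])
    } else {
      pv <- pev_block(goff + ridx)
      m <- match(ids, ebv$animal_id)
      ebv$pev_a <- NA_real_; ebv$acc_a <- NA_real_
      ebv$pev_a[m] <- pv
      ebv$acc_a[m] <- accuracy_from_pev(pv, vc$sigma2_a)
    }
  }

  correction <- as.numeric(des$X %*% fixed)
  for (nm in intersect(c("dam_pe", "groups"), names(des$terms)))
    correction <- correction +
      as.numeric(des$terms[[nm]]$Z %*% random[[nm]])

  structure(list(ebv = ebv, fixed = fixed, random = random,
                 correction = correction, records = des$df$animal,
                 varcomp = vc, spec = spec),
            class = "rn_blup")
}

#' @exportS3Method base::print
print.rn_blup <- function(x, ...) {
  cat("<rn_blup> ", nrow(x$ebv), " genetic levels, ",
      length(x$fixed), " fixed effects\n", sep = "")
  print(head(x$ebv))
  invisible(x)
}
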