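# Independent oracles and small fixture builders shared across tests.
# Everything here deliberately avoids the package's own computational
# paths (tabular loop, sparse MME) so that agreement is informative.

# --- toy phenotype/pedigree builders ---------------------------------------

toy_phenotypes <- function(n, cg = "CG1", sire = "S1", dam = NULL,
                           weaning_age = 95, pw_age = 260,
                           weaning_weight = 25, pw_weight = 40,
                           animal = NULL, birth_year = 2010) {
  data.frame(
    animal = animal %||% sprintf("A%03d", seq_len(n)),
    sire = rep(sire, length.out = n),
    dam = dam %||% sprintf("DD%03d", seq_len(n)),
    sex = rep(c("M", "F"), length.out = n),
    birth_type = 1L, rear_type = 1L,
    weaning_age = rep(weaning_age, length.out = n),
    pw_age = rep(pw_age, length.out = n),
    weaning_weight = rep(weaning_weight, length.out = n),
    pw_weight = rep(pw_weight, length.out = n),
    cg_key = rep(cg, length.out = n),
    birth_year = rep(birth_year, length.out = n),
    stringsAsFactors = FALSE)
}

toy_pedigree_for <- function(phen) {
  founders <- unique(c(phen$sire, phen$dam))
  founders <- founders[!is.na(founders)]
  data.frame(
    animal = c(founders, phen$animal),
    sire = c(rep(NA, length(founders)), phen$sire),
    dam = c(rep(NA, length(founders)), phen$dam),
    stringsAsFactors = FALSE)
}

# --- relationship-matrix oracles -------------------------------------------

# recursive-with-memo evaluation of the additive relationship coefficients
a_coeff_oracle <- function(pedigree) {
  ids <- as.character(pedigree$animal)
  sire <- as.character(pedigree$sire)
  dam <- as.character(pedigree$dam)
  sire[sire %in% c("", "0")] <- NA
  dam[dam %in% c("", "0")] <- NA
  pos <- seq_along(ids)
  names(pos) <- ids
  memo <- new.env(parent = emptyenv())
  aval <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (pos[i] < pos[j]) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    v <- if (i == j) {
      1 + 0.5 * aval(sire[pos[i]], dam[pos[i]])
    } else {
      0.5 * (aval(sire[pos[i]], j) + aval(dam[pos[i]], j))
    }
    memo[[key]] <- v
    v
  }
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(i)) A[i, j] <- A[j, i] <-
      aval(ids[i], ids[j])
  A
}

# random acyclic pedigree generator (parents always listed earlier)
random_pedigree <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("R%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > 2 && runif(1) < 0.7) {
      sire[i] <- ids[sample(i - 1, 1)]
      cand <- setdiff(seq_len(i - 1), match(sire[i], ids))
      if (length(cand)) dam[i] <- ids[sample(cand, 1)][1]
    }
  }
  data.frame(animal = ids, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# --- dense REML oracle ------------------------------------------------------

# Restricted log-likelihood from the dense variance matrix:
# -0.5 [ (n - p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ].
# Design pieces are rebuilt densely from the raw tables, independent of the
# package's sparse MME machinery.
dense_reml_loglik <- function(y, X, Zlist, Glist, Rdiag) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(Rdiag, n)
  for (k in seq_along(Zlist))
    V <- V + Zlist[[k]] %*% Glist[[k]] %*% t(Zlist[[k]])
  cV <- chol(V)
  Vi <- chol2inv(cV)
  XtVi <- t(X) %*% Vi
  XtViX <- XtVi %*% X
  cX <- chol(XtViX)
  P <- Vi - t(XtVi) %*% chol2inv(cX) %*% XtVi
  -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(cV))) +
            2 * sum(log(diag(cX))) + drop(t(y) %*% P %*% y))
}

# dense oracle for a sire random-regression model with continuous residual
# (mean-only fixed effect), parameterised like the package (log-Cholesky)
dense_sire_rr_nll <- function(phen, x_by_record) {
  sires <- sort(unique(phen$sire))
  n <- nrow(phen)
  Zs <- outer(phen$sire, sires, "==") * 1
  Z <- cbind(Zs, Zs * x_by_record)
  X <- matrix(1, n, 1)
  y <- phen$pw_weight
  function(par) {
    L <- matrix(c(exp(par[1]), par[2], 0, exp(par[3])), 2, 2)
    K <- L %*% t(L)
    Le <- matrix(c(exp(par[4]), par[5], 0, exp(par[6])), 2, 2)
    E <- Le %*% t(Le)
    Rdiag <- E[1, 1] + 2 * x_by_record * E[1, 2] + x_by_record^2 * E[2, 2]
    if (any(Rdiag <= 0)) return(1e10)
    G <- kronecker(K, diag(length(sires)))
    ll <- tryCatch(dense_reml_loglik(y, X, list(Z), list(G), Rdiag),
                   error = function(e) -1e10)
    -ll
  }
}

# polish an optimum to high precision (shared treatment for both the
# package fit and the oracle when comparing maximizers)
polish_optim <- function(par, fn) {
  for (i in 1:3) {
    o <- optim(par, fn, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    par <- o$par
  }
  o <- optim(par, fn, method = "BFGS",
             control = list(maxit = 200, reltol = 1e-14))
  o
}

# map a fitted sire-model rn_varcomp to an animal-scale starting point for
# the full animal-model REML (sire variance is a quarter of the additive
# variance; the sire-model residual absorbs three quarters of the genetic
# variance plus the dam terms)
animal_start_from_sire <- function(vc_sire, sigma2_c_guess = 2) {
  K <- 4 * vc_sire$K
  E <- vc_sire$E - 0.75 * K
  E[1, 1] <- E[1, 1] - sigma2_c_guess
  # keep the start safely positive definite
  ev <- eigen(E, symmetric = TRUE)
  ev$values <- pmax(ev$values, 0.05 * max(ev$values))
  E <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
  list(K = K, E = E, sigma2_c = sigma2_c_guess)
}
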