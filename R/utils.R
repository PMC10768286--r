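`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the previous RNG state so
#' that seeded operations do not disturb the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream unchanged.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ids: map "", "0", NA to unknown (NA)
normalize_id <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
  x
}

# multivariate normal draws via Cholesky, n x k
rmvn <- function(n, Sigma) {
  k <- ncol(Sigma)
  R <- chol(Sigma)
  matrix(rnorm(n * k), n, k) %*% R
}

# log-Cholesky packing of a 2x2 PD covariance matrix
pack_cov2 <- function(S) {
  L <- tryCatch(t(chol(S)), error = function(e) {
    # boundary covariances (e.g. correlation +/-1 from a previous fit used
    # as a warm start) are nudged into the interior before packing
    t(chol(S + diag(2) * 1e-6 * max(diag(S))))
  })
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

unpack_cov2 <- function(p) {
  L <- matrix(c(exp(p[1]), p[2], 0, exp(p[3])), 2, 2)
  L %*% t(L)
}

is_square_psd <- function(S, tol = 1e-8) {
  is.matrix(S) && nrow(S) == ncol(S) &&
    isTRUE(all.equal(S, t(S), tolerance = 1e-6)) &&
    min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > -tol * max(1, max(abs(S)))
}

#' Average correlations on the Fisher-Z scale
#'
#' Correlations (and accuracies) are averaged as `tanh(mean(atanh(r)))`.
#' Values at or above the clip point are clipped with a warning because
#' `atanh(1)` is infinite.
#'
#' @param r Numeric vector of correlations/accuracies in `[-1, 1]`.
#' @param clip Clip point for `|r|` (default 0.9999).
#' @return The Fisher-Z averaged value.
#' @export
#' @examples
#' fisher_z_mean(c(0.5, 0.9)) # 0.7658
fisher_z_mean <- function(r, clip = 0.9999) {
  r <- r[!is.na(r)]
  if (!length(r)) return(NA_real_)
  if (any(abs(r) > 1)) stop("correlations must lie in [-1, 1]")
  if (any(abs(r) >= clip)) {
    warning("accuracies at 1 clipped to ", clip, " before Fisher-Z averaging")
    r <- pmin(pmax(r, -clip), clip)
  }
  tanh(mean(atanh(r)))
}
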