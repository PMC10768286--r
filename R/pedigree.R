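# Pedigree utilities: validation, topological ordering, inbreeding,
# numerator relationship matrix (A) and its sparse inverse, genetic-group
# proportion matrix (Q).

# Internal normalized representation of a pedigree data.frame.
# Returns list(ids, sire_idx, dam_idx, group, order, rank) where parent
# indices are 0 when unknown and `order` lists indices parents-first.
ped_prepare <- function(pedigree) {
  if (!is.data.frame(pedigree) || !all(c("animal", "sire", "dam") %in% names(pedigree)))
    stop("pedigree must be a data.frame with columns animal, sire, dam")
  ids <- normalize_id(pedigree$animal)
  if (anyNA(ids)) stop("pedigree contains missing animal ids")
  if (anyDuplicated(ids))
    stop("duplicate animal ids in pedigree: ",
         paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  sire <- normalize_id(pedigree$sire)
  dam <- normalize_id(pedigree$dam)
  grp <- if ("genetic_group" %in% names(pedigree)) as.character(pedigree$genetic_group)
         else rep(NA_character_, length(ids))

  # parents referenced but not listed become founders
  extra <- setdiff(stats::na.omit(unique(c(sire, dam))), ids)
  if (length(extra)) {
    ids <- c(ids, extra)
    sire <- c(sire, rep(NA_character_, length(extra)))
    dam <- c(dam, rep(NA_character_, length(extra)))
    grp <- c(grp, rep(NA_character_, length(extra)))
  }
  n <- length(ids)
  si <- match(sire, ids, nomatch = 0L)
  di <- match(dam, ids, nomatch = 0L)
  self <- which(si == seq_len(n) | di == seq_len(n))
  if (length(self))
    stop("animal is its own parent: ", paste(ids[head(self, 5)], collapse = ", "))

  # Kahn-style topological sort (parents before offspring)
  placed <- logical(n)
  ord <- integer(n)
  filled <- 0L
  repeat {
    ok_s <- si == 0L
    ok_s[!ok_s] <- placed[si[!ok_s]]
    ok_d <- di == 0L
    ok_d[!ok_d] <- placed[di[!ok_d]]
    ready <- which(!placed & ok_s & ok_d)
    if (!length(ready)) break
    ord[filled + seq_along(ready)] <- ready
    filled <- filled + length(ready)
    placed[ready] <- TRUE
  }
  if (filled < n)
    stop("pedigree contains a cycle involving: ",
         paste(ids[head(which(!placed), 10)], collapse = ", "))
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  list(ids = ids, sire_idx = si, dam_idx = di, group = grp, order = ord, rank = rank)
}

# Inbreeding coefficients by the Meuwissen & Luo recursion.
# Returns list(F = coefficients, D = Mendelian-sampling variance scalars).
ped_inbreeding <- function(prep) {
  n <- length(prep$ids)
  si <- prep$sire_idx
  di <- prep$dam_idx
  Fv <- rep(NA_real_, n)
  Dv <- rep(NA_real_, n)
  Fe <- function(j) if (j == 0L) -1 else Fv[j]
  L <- numeric(n)
  for (i in prep$order) {
    s <- si[i]; d <- di[i]
    Dv[i] <- 0.5 - 0.25 * (Fe(s) + Fe(d))
    if (s == 0L || d == 0L) {
      Fv[i] <- 0
      next
    }
    # collect ancestors of i (including i), then sweep youngest-first
    anc <- i
    seen <- c(i)
    k <- 1L
    while (k <= length(anc)) {
      j <- anc[k]
      for (p in c(si[j], di[j])) {
        if (p != 0L && !(p %in% seen)) {
          anc <- c(anc, p)
          seen <- c(seen, p)
        }
      }
      k <- k + 1L
    }
    anc <- anc[order(prep$rank[anc], decreasing = TRUE)]
    L[anc] <- 0
    L[i] <- 1
    aii <- 0
    for (j in anc) {
      if (si[j] != 0L) L[si[j]] <- L[si[j]] + 0.5 * L[j]
      if (di[j] != 0L) L[di[j]] <- L[di[j]] + 0.5 * L[j]
      aii <- aii + L[j]^2 * Dv[j]
    }
    Fv[i] <- aii - 1
  }
  list(F = Fv, D = Dv)
}

#' Inbreeding coefficients from a pedigree
#'
#' @param pedigree A data.frame with columns `animal`, `sire`, `dam`
#'   (unknown parents as `NA`, `""` or `"0"`).
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(pedigree) {
  prep <- ped_prepare(pedigree)
  setNames(ped_inbreeding(prep)$F, prep$ids)
}

#' Truncate a pedigree to a number of ancestral generations
#'
#' Keeps `keep_ids` plus up to `generations` levels of known ancestors;
#' parents outside the retained set are recoded as unknown.
#'
#' @param pedigree Pedigree data.frame (`animal`, `sire`, `dam`, optional
#'   `genetic_group`).
#' @param keep_ids Animals whose ancestry is retained (typically the
#'   phenotyped animals).
#' @param generations Number of ancestral generations to keep.
#' @return A pedigree data.frame restricted to the retained animals.
#' @export
truncate_pedigree <- function(pedigree, keep_ids, generations) {
  stopifnot(generations >= 0)
  ped <- data.frame(animal = normalize_id(pedigree$animal),
                    sire = normalize_id(pedigree$sire),
                    dam = normalize_id(pedigree$dam),
                    stringsAsFactors = FALSE)
  if ("genetic_group" %in% names(pedigree))
    ped$genetic_group <- as.character(pedigree$genetic_group)
  keep_ids <- unique(normalize_id(keep_ids))
  missing <- setdiff(keep_ids, ped$animal)
  if (length(missing))
    stop("keep_ids absent from pedigree: ", paste(head(missing, 5), collapse = ", "))
  sel <- keep_ids
  cur <- keep_ids
  g <- 0
  while (g < generations && length(cur)) {
    rows <- ped[ped$animal %in% cur, , drop = FALSE]
    par <- stats::na.omit(unique(c(rows$sire, rows$dam)))
    cur <- setdiff(par, sel)
    sel <- union(sel, cur)
    g <- g + 1
  }
  out <- ped[ped$animal %in% sel, , drop = FALSE]
  out$sire[!(out$sire %in% out$animal)] <- NA_character_
  out$dam[!(out$dam %in% out$animal)] <- NA_character_
  rownames(out) <- NULL
  out
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A from a pedigree by
#' the tabular method. Optionally the pedigree is first truncated to a fixed
#' number of ancestral generations above a set of (phenotyped) animals.
#'
#' @param pedigree Pedigree data.frame (`animal`, `sire`, `dam`).
#' @param generations Ancestral depth to retain (default `Inf` = full
#'   pedigree). Requires `phenotyped` when finite.
#' @param phenotyped Ids anchoring the truncation.
#' @return A dense symmetric matrix with animal ids as dimnames.
#' @export
#' @examples
#' ped <- data.frame(animal = c("S", "D", "O"), sire = c(NA, NA, "S"),
#'                   dam = c(NA, NA, "D"))
#' build_A(ped)["S", "O"] # 0.5
build_A <- function(pedigree, generations = Inf, phenotyped = NULL) {
  if (is.finite(generations)) {
    if (is.null(phenotyped))
      stop("phenotyped ids are required when truncating the pedigree")
    pedigree <- truncate_pedigree(pedigree, phenotyped, generations)
  }
  prep <- ped_prepare(pedigree)
  n <- length(prep$ids)
  if (n > 8000)
    stop("pedigree too large for the dense tabular method; use build_Ainv()")
  A <- matrix(0, n, n, dimnames = list(prep$ids, prep$ids))
  done <- integer(0)
  for (i in prep$order) {
    s <- prep$sire_idx[i]; d <- prep$dam_idx[i]
    if (length(done)) {
      as_ <- if (s != 0L) A[done, s] else numeric(length(done))
      ad_ <- if (d != 0L) A[done, d] else numeric(length(done))
      v <- 0.5 * (as_ + ad_)
      A[done, i] <- v
      A[i, done] <- v
    }
    A[i, i] <- 1 + if (s != 0L && d != 0L) 0.5 * A[s, d] else 0
    done <- c(done, i)
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding from the Meuwissen & Luo recursion.
#'
#' @param pedigree Pedigree data.frame.
#' @return An object of class `rn_relinv`: list with `ids`, `inv` (sparse
#'   symmetric inverse), and `logdet` (log-determinant of A itself).
#' @export
build_Ainv <- function(pedigree) {
  prep <- ped_prepare(pedigree)
  n <- length(prep$ids)
  D <- ped_inbreeding(prep)$D
  si <- prep$sire_idx
  di <- prep$dam_idx
  b <- 1 / D
  ii <- list(); jj <- list(); xx <- list()
  add <- function(i, j, v) {
    ii[[length(ii) + 1L]] <<- i
    jj[[length(jj) + 1L]] <<- j
    xx[[length(xx) + 1L]] <<- v
  }
  idx <- seq_len(n)
  add(idx, idx, b)
  hs <- si != 0L
  hd <- di != 0L
  if (any(hs)) {
    add(si[hs], idx[hs], -b[hs] / 2); add(idx[hs], si[hs], -b[hs] / 2)
    add(si[hs], si[hs], b[hs] / 4)
  }
  if (any(hd)) {
    add(di[hd], idx[hd], -b[hd] / 2); add(idx[hd], di[hd], -b[hd] / 2)
    add(di[hd], di[hd], b[hd] / 4)
  }
  both <- hs & hd
  if (any(both)) {
    add(si[both], di[both], b[both] / 4)
    add(di[both], si[both], b[both] / 4)
  }
  inv <- sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                      dims = c(n, n), dimnames = list(prep$ids, prep$ids))
  structure(list(ids = prep$ids, inv = inv, logdet = sum(log(D))),
            class = "rn_relinv")
}

#' Wrap a dense relationship matrix for model fitting
#'
#' @param mat Symmetric positive-definite relationship matrix with ids as
#'   dimnames (e.g. from [build_A()] or [blend_H()]).
#' @return An `rn_relinv` object (ids, sparse inverse, log-determinant).
#' @export
as_relinv <- function(mat) {
  ids <- rownames(mat)
  if (is.null(ids)) stop("relationship matrix must carry ids as dimnames")
  R <- tryCatch(chol(mat), error = function(e)
    stop("relationship matrix is not positive definite: ", conditionMessage(e)))
  inv <- chol2inv(R)
  dimnames(inv) <- dimnames(mat)
  structure(list(ids = ids, inv = Matrix(inv, sparse = TRUE),
                 logdet = 2 * sum(log(diag(R)))),
            class = "rn_relinv")
}

identity_relinv <- function(ids) {
  structure(list(ids = ids,
                 inv = Diagonal(length(ids)),
                 logdet = 0),
            class = "rn_relinv")
}

#' Genetic-group proportion matrix Q
#'
#' Proportions of each animal's genome tracing to founder genetic groups,
#' computed by the usual recursion: an animal's row is the average of its
#' parents' rows; an unknown-parent slot contributes the animal's own group
#' label. Founders are unit vectors on their group.
#'
#' @param pedigree Pedigree data.frame; group labels taken from its
#'   `genetic_group` column unless `founder_groups` is given.
#' @param founder_groups Optional named character vector (animal -> group)
#'   overriding/augmenting the pedigree labels.
#' @return List of class `rn_qmatrix` with `ids`, `groups`, and the
#'   animals-by-groups proportion matrix `Q` (rows sum to 1).
#' @export
build_Q <- function(pedigree, founder_groups = NULL) {
  prep <- ped_prepare(pedigree)
  n <- length(prep$ids)
  lab <- prep$group
  if (!is.null(founder_groups)) {
    m <- match(names(founder_groups), prep$ids)
    if (anyNA(m)) stop("founder_groups contains unknown animal ids")
    lab[m] <- as.character(founder_groups)
  }
  needs <- prep$sire_idx == 0L | prep$dam_idx == 0L
  if (any(needs & is.na(lab)))
    stop("genetic-group label missing for founders: ",
         paste(head(prep$ids[needs & is.na(lab)], 5), collapse = ", "))
  groups <- sort(unique(lab[needs & !is.na(lab)]))
  G <- length(groups)
  Q <- matrix(0, n, G, dimnames = list(prep$ids, groups))
  for (i in prep$order) {
    s <- prep$sire_idx[i]; d <- prep$dam_idx[i]
    row <- numeric(G)
    if (s != 0L) row <- row + 0.5 * Q[s, ] else row[match(lab[i], groups)] <-
        row[match(lab[i], groups)] + 0.5
    if (d != 0L) row <- row + 0.5 * Q[d, ] else row[match(lab[i], groups)] <-
        row[match(lab[i], groups)] + 0.5
    Q[i, ] <- row
  }
  structure(list(ids = prep$ids, groups = groups, Q = Q), class = "rn_qmatrix")
}
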