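# Reading, validation and record-eligibility filtering of pedigree,
# phenotype and genotype inputs.

#' Filtering thresholds for record eligibility
#'
#' @param min_growth_days Minimum days between weaning and post-weaning
#'   weights (default 40).
#' @param min_cg_size Minimum animals per contemporary group (default 15).
#' @param min_cg_sires Minimum distinct sires per contemporary group
#'   (default 3).
#' @param outlier_sd Post-weaning growth-rate records farther than this many
#'   standard deviations from the mean are dropped (default 4; applied as a
#'   single global screen).
#' @return A list of class `rn_filter_config`.
#' @export
filter_config <- function(min_growth_days = 40, min_cg_size = 15,
                          min_cg_sires = 3, outlier_sd = 4) {
  vals <- c(min_growth_days, min_cg_size, min_cg_sires, outlier_sd)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all filter thresholds must be strictly positive")
  structure(list(min_growth_days = min_growth_days, min_cg_size = min_cg_size,
                 min_cg_sires = min_cg_sires, outlier_sd = outlier_sd),
            class = "rn_filter_config")
}

required_phenotype_cols <- c("animal", "sire", "dam", "sex", "birth_type",
                             "rear_type", "weaning_age", "pw_age",
                             "weaning_weight", "pw_weight", "cg_key")

#' Assemble a dataset from pedigree and phenotype tables
#'
#' Joins in-memory tables into the container consumed by all downstream
#' stages and computes the post-weaning growth rate
#' `pwgr = 1000 * (pw_weight - weaning_weight) / (pw_age - weaning_age)`
#' in g/day. Phenotyped animals absent from the pedigree are appended as
#' founders with a warning.
#'
#' @param pedigree Pedigree data.frame (`animal`, `sire`, `dam`, optional
#'   `genetic_group`).
#' @param phenotypes Phenotype data.frame with columns
#'   `animal, sire, dam, sex, birth_type, rear_type, weaning_age, pw_age,
#'   weaning_weight, pw_weight, cg_key` and optionally `birth_year`.
#' @param genotypes Optional 0/1/2 genotype matrix (animal ids as rownames).
#' @return An object of class `rn_dataset` (list with `pedigree`,
#'   `phenotypes`, `genotypes`).
#' @export
rn_dataset <- function(pedigree, phenotypes, genotypes = NULL) {
  ph <- as.data.frame(phenotypes, stringsAsFactors = FALSE)
  if (!nrow(ph)) stop("no records in phenotype table")
  missing_cols <- setdiff(required_phenotype_cols, names(ph))
  if (length(missing_cols))
    stop("phenotype table lacks columns: ", paste(missing_cols, collapse = ", "))
  ph$animal <- normalize_id(ph$animal)
  ph$sire <- normalize_id(ph$sire)
  ph$dam <- normalize_id(ph$dam)
  if (anyNA(ph$animal)) stop("phenotype records with missing animal id")
  if (anyDuplicated(ph$animal))
    stop("duplicate animal ids in phenotypes: ",
         paste(head(unique(ph$animal[duplicated(ph$animal)]), 5), collapse = ", "))
  for (col in c("weaning_age", "pw_age", "weaning_weight", "pw_weight")) {
    v <- suppressWarnings(as.numeric(ph[[col]]))
    bad <- which(is.na(v) & !is.na(ph[[col]]))
    if (length(bad))
      stop("non-numeric ", col, " in phenotype row(s) ",
           paste(head(bad, 5), collapse = ", "))
    ph[[col]] <- v
  }
  if (any(is.na(ph$cg_key) | ph$cg_key == ""))
    stop("phenotype records with empty cg_key")
  bad_w <- which(ph$weaning_weight <= 0 | ph$pw_weight <= 0)
  if (length(bad_w))
    stop("non-positive weight in phenotype row(s) ",
         paste(head(bad_w, 5), collapse = ", "))
  bad_a <- which(!(ph$pw_age > ph$weaning_age))
  if (length(bad_a))
    stop("pw_age must exceed weaning_age; offending row(s) ",
         paste(head(bad_a, 5), collapse = ", "))
  ph$cg_key <- as.character(ph$cg_key)
  if (!"birth_year" %in% names(ph)) ph$birth_year <- NA_integer_
  ph$pwgr <- 1000 * (ph$pw_weight - ph$weaning_weight) / (ph$pw_age - ph$weaning_age)

  ped <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  ped <- ped[, intersect(c("animal", "sire", "dam", "genetic_group"),
                         names(ped)), drop = FALSE]
  ped$animal <- normalize_id(ped$animal)
  ped$sire <- normalize_id(ped$sire)
  ped$dam <- normalize_id(ped$dam)
  absent <- setdiff(ph$animal, ped$animal)
  if (length(absent)) {
    warning(length(absent), " phenotyped animal(s) absent from pedigree; ",
            "appended with unknown parents")
    add <- data.frame(animal = absent, sire = NA_character_, dam = NA_character_,
                      stringsAsFactors = FALSE)
    if ("genetic_group" %in% names(ped)) add$genetic_group <- NA_character_
    ped <- rbind(ped[, names(add), drop = FALSE], add)
  }
  parents <- stats::na.omit(unique(c(ped$sire, ped$dam, ph$sire, ph$dam)))
  orphan <- setdiff(parents, ped$animal)
  if (length(orphan)) {
    add <- data.frame(animal = orphan, sire = NA_character_,
                      dam = NA_character_, stringsAsFactors = FALSE)
    if ("genetic_group" %in% names(ped)) add$genetic_group <- NA_character_
    ped <- rbind(ped, add[, names(ped), drop = FALSE])
  }
  ped_prepare(ped) # validates (cycles, duplicates)
  if (!is.null(genotypes)) {
    if (is.null(rownames(genotypes)))
      stop("genotype matrix must have animal ids as rownames")
  }
  structure(list(pedigree = ped, phenotypes = ph, genotypes = genotypes),
            class = "rn_dataset")
}

#' @exportS3Method base::print
print.rn_dataset <- function(x, ...) {
  cat("<rn_dataset> ", nrow(x$phenotypes), " records, ",
      length(unique(x$phenotypes$cg_key)), " contemporary groups, ",
      nrow(x$pedigree), " animals in pedigree",
      if (!is.null(x$genotypes)) paste0(", ", nrow(x$genotypes), " genotyped"),
      "\n", sep = "")
  invisible(x)
}

read_genotype_file <- function(path) {
  first <- strsplit(readLines(path, n = 1), "[ \t]+")[[1]]
  has_header <- length(first) > 1 &&
    all(is.na(suppressWarnings(as.numeric(first[-1]))))
  tab <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  codes <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(codes) <- "double"
  rownames(codes) <- ids
  codes
}

#' Load a dataset from delimited text files
#'
#' @param pedigree_path CSV with columns `animal,sire,dam[,genetic_group]`.
#' @param phenotype_path CSV with the phenotype columns (see
#'   [rn_dataset()]).
#' @param genotype_path Optional whitespace-delimited genotype file: first
#'   column animal id, remaining columns 0/1/2 codes, optional marker-id
#'   header row.
#' @param config Filter configuration (kept with the dataset; filtering
#'   itself is done by [filter_records()]).
#' @return An `rn_dataset`.
#' @export
load_dataset <- function(pedigree_path, phenotype_path, genotype_path = NULL,
                         config = filter_config()) {
  for (p in c(pedigree_path, phenotype_path, genotype_path))
    if (!file.exists(p)) stop("file not found: ", p)
  ped <- read.csv(pedigree_path, stringsAsFactors = FALSE)
  ph <- read.csv(phenotype_path, stringsAsFactors = FALSE)
  if (!nrow(ph)) stop("no records in ", phenotype_path)
  geno <- if (!is.null(genotype_path)) read_genotype_file(genotype_path)
  ds <- rn_dataset(ped, ph, geno)
  attr(ds, "filter_config") <- config
  ds
}

#' Apply record- and contemporary-group-level eligibility filters
#'
#' Record-level rules (known sire, dam, birth- and rear-type; at least
#' `min_growth_days` between weaning and post-weaning weights) are applied
#' first, then a single global screen removing growth-rate records beyond
#' `outlier_sd` standard deviations of the mean, then contemporary-group
#' rules (at least `min_cg_size` animals from at least `min_cg_sires`
#' sires), iterated to a fixed point.
#'
#' @param dataset An `rn_dataset`.
#' @param config An `rn_filter_config`.
#' @return List with elements `dataset` (filtered) and `report`
#'   (`rn_filter_report`: per-rule removal counts).
#' @export
filter_records <- function(dataset, config = filter_config()) {
  stopifnot(inherits(dataset, "rn_dataset"))
  ph <- dataset$phenotypes
  n_input <- nrow(ph)
  counts <- c(missing_parent = 0L, missing_type = 0L, growth_window = 0L,
              pwgr_outlier = 0L, cg_size = 0L, cg_sires = 0L)

  drop <- is.na(ph$sire) | is.na(ph$dam)
  counts["missing_parent"] <- sum(drop)
  ph <- ph[!drop, , drop = FALSE]

  drop <- is.na(ph$birth_type) | is.na(ph$rear_type)
  counts["missing_type"] <- sum(drop)
  ph <- ph[!drop, , drop = FALSE]

  drop <- (ph$pw_age - ph$weaning_age) < config$min_growth_days
  counts["growth_window"] <- sum(drop)
  ph <- ph[!drop, , drop = FALSE]

  if (nrow(ph)) {
    m <- mean(ph$pwgr); s <- sd(ph$pwgr)
    if (is.finite(s) && s > 0) {
      drop <- abs(ph$pwgr - m) > config$outlier_sd * s
      counts["pwgr_outlier"] <- sum(drop)
      ph <- ph[!drop, , drop = FALSE]
    }
  }

  repeat {
    if (!nrow(ph)) break
    size <- table(ph$cg_key)
    small <- names(size)[size < config$min_cg_size]
    drop <- ph$cg_key %in% small
    counts["cg_size"] <- counts["cg_size"] + sum(drop)
    ph <- ph[!drop, , drop = FALSE]
    if (!nrow(ph)) break
    nsires <- tapply(ph$sire, ph$cg_key, function(s) length(unique(s)))
    few <- names(nsires)[nsires < config$min_cg_sires]
    drop2 <- ph$cg_key %in% few
    counts["cg_sires"] <- counts["cg_sires"] + sum(drop2)
    ph <- ph[!drop2, , drop = FALSE]
    if (!any(drop) && !any(drop2)) break
  }
  if (!nrow(ph)) stop("empty after filtering")

  out <- dataset
  out$phenotypes <- ph
  report <- structure(list(counts = counts, n_input = n_input,
                           n_output = nrow(ph), outlier_scope = "global"),
                      class = "rn_filter_report")
  list(dataset = out, report = report)
}

#' @exportS3Method base::print
print.rn_filter_report <- function(x, ...) {
  cat("<rn_filter_report> ", x$n_input, " -> ", x$n_output, " records\n", sep = "")
  for (nm in names(x$counts))
    cat(sprintf("  %-14s %d\n", nm, x$counts[[nm]]))
  cat("  (growth-rate outlier screen applied globally)\n")
  invisible(x)
}
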