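#' Construct a genotype dataset
#'
#' Bundles an n x p minor-allele dosage matrix with per-marker map
#' information and per-sample identifiers. Dosages count copies of the
#' in-sample minor allele (0, 1, 2); `NA` entries are allowed before
#' imputation and are tracked in a logical missingness mask.
#'
#' @param dosages numeric matrix, individuals in rows, markers in columns.
#' @param map data.frame with columns `chrom`, `id`, `cM`, `bp` (one row
#'   per marker, ids unique, bp 1-based and non-decreasing within a
#'   chromosome).
#' @param samples data.frame with columns `fid`, `iid`, `sex` (one row per
#'   individual). Generated when omitted.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(dosages, map, samples = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); p <- ncol(dosages)
  if (n < 1L || p < 1L) stop("need at least one individual and one marker")
  if (nrow(map) != p) stop("map must have one row per marker")
  map <- as.data.frame(map)
  need <- c("chrom", "id", "cM", "bp")
  if (!all(need %in% names(map))) {
    stop("map must have columns: ", paste(need, collapse = ", "))
  }
  map$id <- as.character(map$id)
  if (anyDuplicated(map$id)) stop("marker ids must be unique")
  for (ch in unique(map$chrom)) {
    bp <- map$bp[map$chrom == ch]
    if (is.unsorted(bp)) {
      stop("bp positions must be non-decreasing within chromosome ", ch)
    }
  }
  obs <- dosages[!is.na(dosages)]
  # raw calls are 0/1/2; fractional values in [0,2] arise after mean imputation
  if (length(obs) && (min(obs) < 0 || max(obs) > 2)) {
    stop("non-missing dosages must lie in [0, 2]")
  }
  if (is.null(samples)) {
    samples <- data.frame(fid = paste0("F", seq_len(n)),
                          iid = paste0("I", seq_len(n)),
                          sex = rep(0L, n), stringsAsFactors = FALSE)
  }
  if (nrow(samples) != n) stop("samples must have one row per individual")
  colnames(dosages) <- map$id
  structure(list(dosages = dosages, map = map, samples = samples,
                 missing = is.na(dosages)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals x %d markers (%d missing calls)\n",
              nrow(x$dosages), ncol(x$dosages), sum(x$missing)))
  invisible(x)
}

#' Keep a subset of markers
#'
#' @param g a [genotype_dataset()].
#' @param idx marker indices or ids to retain.
#' @return A `genotype_dataset` restricted to the requested markers.
#' @export
subset_markers <- function(g, idx) {
  if (is.character(idx)) idx <- match(idx, g$map$id)
  if (anyNA(idx)) stop("unknown marker id")
  # direct construction: derived subsets may legitimately reorder markers,
  # which the position-sortedness check on freshly read data would reject
  map <- g$map[idx, , drop = FALSE]
  rownames(map) <- NULL
  structure(list(dosages = g$dosages[, idx, drop = FALSE], map = map,
                 samples = g$samples,
                 missing = g$missing[, idx, drop = FALSE]),
            class = "genotype_dataset")
}

#' Construct a phenotype vector
#'
#' @param values numeric vector; for `family = "logistic"` values must be
#'   0/1 (control/case).
#' @param family `"linear"` (continuous, normal error) or `"logistic"`.
#' @return Numeric vector with a `family` attribute, class
#'   `phenotype_vector`.
#' @export
phenotype_vector <- function(values, family = c("logistic", "linear")) {
  family <- match.arg(family)
  values <- as.numeric(values)
  if (anyNA(values)) stop("phenotype values must be non-missing")
  if (family == "logistic" && !all(values %in% c(0, 1))) {
    stop("logistic phenotype values must be 0/1")
  }
  structure(values, family = family, class = "phenotype_vector")
}

pheno_family <- function(y) {
  fam <- attr(y, "family")
  if (is.null(fam)) if (all(y %in% c(0, 1))) "logistic" else "linear" else fam
}

#' Build an unpenalized covariate matrix
#'
#' Prepends an all-ones intercept column, drops constant non-intercept
#' columns, and errors on rank deficiency.
#'
#' @param n number of individuals (used when `x` is `NULL`).
#' @param x optional numeric matrix or data.frame of covariates (no
#'   intercept column).
#' @return Numeric matrix whose first column is the intercept.
#' @export
covariate_matrix <- function(n, x = NULL) {
  if (is.null(x)) {
    out <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
    return(out)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) != n) stop("covariate rows must match sample count")
  keep <- apply(x, 2, function(v) var(v) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  out <- cbind(intercept = 1, x)
  qr_out <- qr(out)
  if (qr_out$rank < ncol(out)) {
    bad <- colnames(out)[-qr_out$pivot[seq_len(qr_out$rank)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  out
}

split_fields <- function(lines) {
  strsplit(trimws(lines), "[ \t]+")
}

#' Read PLINK transposed-text genotype and phenotype files
#'
#' Parses a TPED/TFAM pair. Each TPED row is one marker (chromosome, id,
#' genetic position in cM, bp position, then two allele calls per
#' individual); each TFAM row is one individual with the phenotype in the
#' sixth column. Alleles are recoded to minor-allele dosages, the minor
#' allele being the less frequent allele in-sample (ties broken toward the
#' alphabetically later allele). The `0` allele code marks a missing call;
#' half-missing genotypes are treated as fully missing. Case/control
#' phenotypes coded 2/1 are recoded to 1/0, and individuals with a missing
#' phenotype (`-9`, or also `0` for case/control) are dropped with a
#' warning.
#'
#' @param tped_path,tfam_path file paths.
#' @return List with elements `genotypes` (a [genotype_dataset()]) and
#'   `phenotype` (a [phenotype_vector()]).
#' @export
read_tped_tfam <- function(tped_path, tfam_path) {
  if (!file.exists(tped_path)) stop("TPED file not found: ", tped_path)
  if (!file.exists(tfam_path)) stop("TFAM file not found: ", tfam_path)

  fam <- split_fields(readLines(tfam_path))
  fam <- fam[lengths(fam) > 0]
  if (any(lengths(fam) != 6L)) stop("malformed TFAM: expected 6 fields per row")
  fam <- do.call(rbind, fam)
  samples <- data.frame(fid = fam[, 1], iid = fam[, 2],
                        sex = suppressWarnings(as.integer(fam[, 5])),
                        stringsAsFactors = FALSE)
  pheno_raw <- suppressWarnings(as.numeric(fam[, 6]))
  n <- nrow(samples)

  rows <- split_fields(readLines(tped_path))
  rows <- rows[lengths(rows) > 0]
  p <- length(rows)
  if (p < 1L) stop("malformed TPED: no marker rows")
  dos <- matrix(NA_real_, n, p)
  map <- data.frame(chrom = character(p), id = character(p),
                    cM = numeric(p), bp = integer(p),
                    stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    f <- rows[[j]]
    if (length(f) != 4L + 2L * n) {
      stop("malformed TPED: row ", j, " has ", length(f) - 4L,
           " allele fields, expected ", 2L * n)
    }
    map$chrom[j] <- f[1]; map$id[j] <- f[2]
    map$cM[j] <- as.numeric(f[3]); map$bp[j] <- as.integer(f[4])
    a1 <- f[seq(5L, length(f), by = 2L)]
    a2 <- f[seq(6L, length(f), by = 2L)]
    miss <- a1 == "0" | a2 == "0"
    alleles <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(alleles) > 2L) {
      stop("marker ", map$id[j], " is not biallelic (alleles: ",
           paste(alleles, collapse = ","), ")")
    }
    if (length(alleles) == 0L) next  # fully missing marker
    if (length(alleles) == 1L) {
      dos[!miss, j] <- 0
      next
    }
    cnt1 <- sum(a1[!miss] == alleles[1]) + sum(a2[!miss] == alleles[1])
    tot <- 2L * sum(!miss)
    # minor = less frequent allele; tie -> alphabetically later allele
    minor <- if (cnt1 < tot - cnt1) alleles[1] else alleles[2]
    dos[!miss, j] <- (a1[!miss] == minor) + (a2[!miss] == minor)
  }
  g <- genotype_dataset(dos, map, samples)

  missing_ph <- is.na(pheno_raw) | pheno_raw == -9
  is_cc <- all(pheno_raw[!missing_ph] %in% c(0, 1, 2))
  if (is_cc) missing_ph <- missing_ph | pheno_raw == 0
  if (any(missing_ph)) {
    warning("dropping ", sum(missing_ph), " individual(s) with missing phenotype")
    keep <- !missing_ph
    g <- genotype_dataset(g$dosages[keep, , drop = FALSE], g$map,
                          g$samples[keep, , drop = FALSE])
    pheno_raw <- pheno_raw[keep]
  }
  y <- if (is_cc) phenotype_vector(pheno_raw - 1, "logistic")
       else phenotype_vector(pheno_raw, "linear")
  list(genotypes = g, phenotype = y)
}

#' Write PLINK transposed-text files
#'
#' Inverse of [read_tped_tfam()]: dosages are expanded to allele pairs
#' using `A` for the minor and `G` for the major allele, and missing
#' entries become `0 0`. Logistic phenotypes are written as 1/2
#' (control/case).
#'
#' @param g a [genotype_dataset()].
#' @param y a [phenotype_vector()].
#' @param tped_path,tfam_path output file paths.
#' @return Invisibly, the TPED path.
#' @export
write_tped_tfam <- function(g, y, tped_path, tfam_path) {
  n <- nrow(g$dosages)
  code <- c("G G", "A G", "A A")  # dosage 0,1,2 of minor allele A
  lines <- character(ncol(g$dosages))
  for (j in seq_along(lines)) {
    d <- g$dosages[, j]
    al <- ifelse(is.na(d), "0 0", code[d + 1])
    lines[j] <- paste(g$map$chrom[j], g$map$id[j], format(g$map$cM[j], trim = TRUE),
                      g$map$bp[j], paste(al, collapse = " "))
  }
  writeLines(lines, tped_path)
  ph <- if (pheno_family(y) == "logistic") as.numeric(y) + 1 else as.numeric(y)
  fam <- paste(g$samples$fid, g$samples$iid, 0, 0, g$samples$sex, ph)
  writeLines(fam, tfam_path)
  invisible(tped_path)
}

#' Read an unpenalized covariate table
#'
#' Whitespace-delimited text with a header; the first two columns must be
#' `FID` and `IID` and are matched against the dataset's samples.
#'
#' @param path file path.
#' @param g a [genotype_dataset()] giving the sample order.
#' @return Covariate matrix from [covariate_matrix()] (intercept included).
#' @export
read_covariates <- function(path, g) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  key <- paste(tab[[1]], tab[[2]])
  want <- paste(g$samples$fid, g$samples$iid)
  idx <- match(want, key)
  if (anyNA(idx)) stop("covariate file is missing ", sum(is.na(idx)), " individual(s)")
  covariate_matrix(nrow(g$dosages), as.matrix(tab[idx, -(1:2), drop = FALSE]))
}

#' Mean-impute sporadic missing genotypes
#'
#' Replaces each missing call by the marker's mean dosage over non-missing
#' individuals; observed entries are untouched and the missingness mask is
#' cleared.
#'
#' @param g a [genotype_dataset()].
#' @return The imputed `genotype_dataset` (dosages may be fractional).
#' @export
impute_missing_mean <- function(g) {
  if (!any(g$missing)) return(g)
  n_obs <- colSums(!g$missing)
  if (any(n_obs == 0L)) {
    stop("marker(s) with all calls missing: ",
         paste(g$map$id[n_obs == 0L], collapse = ", "))
  }
  dos <- g$dosages
  means <- unname(colMeans(dos, na.rm = TRUE))
  bad <- which(g$missing, arr.ind = TRUE)
  dos[bad] <- means[bad[, 2]]
  out <- g
  out$dosages <- dos
  out$missing <- matrix(FALSE, nrow(dos), ncol(dos))
  out
}
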