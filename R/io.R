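#' @useDynLib introscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats integrate rbeta rbinom rgamma runif rmultinom sd
#'   var cor median quantile setNames wilcox.test kruskal.test
#'   cor.test dbeta optimize
#' @importFrom graphics barplot
#' @importFrom utils read.delim write.table head tail
"_PACKAGE"

# Sentinel used for missing values in all text formats (STRUCTURE convention).
MISSING_CODE <- -9L

#' Default population vocabulary
#'
#' The five population labels used throughout: old landraces (OL), recent
#' landraces (RL), northern-Italy landraces (NI), flint modern maize (FMM)
#' and dent modern maize (DMM).  The vocabulary is configurable in
#' [sample_table()]; these are the defaults.
#'
#' @export
DEFAULT_POPULATIONS <- c("OL", "RL", "NI", "FMM", "DMM")

#' Construct a sample table
#'
#' A sample table maps individuals to accessions and accessions to
#' populations.  Control accessions (e.g. a modern hybrid grown alongside
#' the landraces) are excluded from all statistics except admixture
#' display.
#'
#' @param individual character vector of unique individual ids.
#' @param accession character vector, same length, accession of each
#'   individual.  Every accession must belong to exactly one population.
#' @param population character vector, same length, population label of
#'   each individual.
#' @param control logical vector, same length; `TRUE` marks individuals of
#'   control accessions.
#' @param populations allowed population vocabulary.
#' @return A `sample_table` object (a data frame with columns
#'   `individual`, `accession`, `population`, `control`).
#' @export
sample_table <- function(individual, accession, population,
                         control = rep(FALSE, length(individual)),
                         populations = DEFAULT_POPULATIONS) {
  individual <- as.character(individual)
  accession <- as.character(accession)
  population <- as.character(population)
  control <- as.logical(control)
  n <- length(individual)
  stopifnot(length(accession) == n, length(population) == n,
            length(control) == n)
  dup <- individual[duplicated(individual)]
  if (length(dup) > 0L)
    stop("duplicate individual id(s): ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(population), populations)
  if (length(bad) > 0L)
    stop("unknown population label(s): ", paste(bad, collapse = ", "))
  span <- tapply(population, accession, function(p) length(unique(p)))
  if (any(span > 1L))
    stop("accession(s) assigned to more than one population: ",
         paste(names(span)[span > 1L], collapse = ", "))
  out <- data.frame(individual = individual, accession = accession,
                    population = population, control = control,
                    stringsAsFactors = FALSE)
  attr(out, "populations") <- populations
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Read a sample metadata table
#'
#' Expects a tab-separated file with header columns `individual`,
#' `accession`, `population`, `control` (control may be 0/1 or
#' TRUE/FALSE).
#'
#' @param path path to the TSV file.
#' @param populations allowed population vocabulary.
#' @return A [sample_table()].
#' @export
read_samples <- function(path, populations = DEFAULT_POPULATIONS) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("individual", "accession", "population", "control")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  sample_table(df$individual, df$accession, df$population,
               as.logical(df$control) | df$control %in% c(1, "1"),
               populations = populations)
}

#' Write a sample table
#' @param samples a [sample_table()].
#' @param path output path.
#' @export
write_samples <- function(samples, path) {
  df <- as.data.frame(samples)
  df$control <- as.integer(df$control)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a dominant (band presence/absence) matrix
#'
#' @param x integer matrix, individuals x loci, values 1 (band present),
#'   0 (absent) or -9 (missing).  Row names are individual ids, column
#'   names locus ids.
#' @return A `dominant_matrix` object.
#' @export
dominant_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  ok <- x %in% c(0L, 1L, MISSING_CODE)
  if (!all(ok)) {
    idx <- which(!matrix(ok, nrow(x)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid dominant value %s at (row %d [%s], col %d [%s])",
                 x[idx[1L], idx[2L]], idx[1L],
                 rownames(x)[idx[1L]] %||% "?", idx[2L],
                 colnames(x)[idx[2L]] %||% "?"))
  }
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("L%03d", seq_len(ncol(x)))
  class(x) <- c("dominant_matrix", class(x))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a dominant marker matrix
#'
#' TSV with one row per individual (first column the individual id,
#' header row of locus ids) and cells in {0, 1, -9}.  Rows are realigned
#' to the order of `samples`; only clearly scored loci should be present.
#'
#' @param path path to TSV.
#' @param samples a [sample_table()]; the row set must match exactly.
#' @return A [dominant_matrix()] aligned to `samples`.
#' @export
read_dominant_matrix <- function(path, samples) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  extra <- setdiff(ids, samples$individual)
  if (length(extra) > 0L)
    stop("individual(s) not in sample table: ",
         paste(extra, collapse = ", "))
  absent <- setdiff(samples$individual, ids)
  if (length(absent) > 0L)
    stop("individual(s) missing from matrix: ",
         paste(absent, collapse = ", "))
  dominant_matrix(m[samples$individual, , drop = FALSE])
}

#' Write a dominant matrix
#' @param x a [dominant_matrix()].
#' @param path output path.
#' @export
write_dominant_matrix <- function(x, path) {
  df <- data.frame(individual = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a codominant genotype matrix
#'
#' Genotypes are unordered pairs of non-negative integer allele codes;
#' internally the smaller code is stored first.  Missing genotypes have
#' both alleles -9 (a half-missing cell is rejected).
#'
#' @param a1,a2 integer matrices (individuals x loci) of allele codes.
#' @return A `codominant_matrix` object: a list with sorted `a1`, `a2`.
#' @export
codominant_matrix <- function(a1, a2) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  stopifnot(identical(dim(a1), dim(a2)))
  m1 <- a1 == MISSING_CODE
  m2 <- a2 == MISSING_CODE
  if (any(m1 != m2))
    stop("half-missing genotype: both alleles of a cell must be missing or observed")
  if (any(a1[!m1] < 0L) || any(a2[!m2] < 0L))
    stop("allele codes must be non-negative (missing = -9)")
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  lo[m1] <- MISSING_CODE; hi[m1] <- MISSING_CODE
  if (is.null(colnames(lo)))
    colnames(lo) <- colnames(hi) <- sprintf("S%02d", seq_len(ncol(lo)))
  out <- list(a1 = lo, a2 = hi)
  class(out) <- "codominant_matrix"
  out
}

#' @export
dim.codominant_matrix <- function(x) dim(x$a1)

#' Read a codominant genotype matrix
#'
#' Two dialects are supported.  `two-row-structure`: each individual has
#' two consecutive lines (one per haploid complement), first column the
#' individual id, then one allele code per locus, -9 for missing.
#' `one-row-paired`: one line per individual with cells `a/b` (or `-9`).
#' A header row of locus ids is required in both dialects.
#'
#' @param path path to the text file.
#' @param samples a [sample_table()].
#' @param dialect `"two-row-structure"` or `"one-row-paired"`.
#' @return A [codominant_matrix()] aligned to `samples`.
#' @export
read_codominant_matrix <- function(path, samples,
                                   dialect = c("two-row-structure",
                                               "one-row-paired")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  body <- lines[-1L]
  if (dialect == "two-row-structure") {
    toks <- strsplit(trimws(body), "[ \t]+")
    ids <- vapply(toks, `[[`, "", 1L)
    runs <- rle(ids)
    if (any(runs$lengths != 2L))
      stop("odd number of rows for individual(s): ",
           paste(runs$values[runs$lengths != 2L], collapse = ", "))
    vals <- lapply(toks, function(t) as.integer(t[-1L]))
    nl <- lengths(vals)
    if (length(unique(nl)) != 1L || nl[1L] != length(header))
      stop("row length does not match header locus count")
    a1 <- do.call(rbind, vals[seq(1L, length(vals), by = 2L)])
    a2 <- do.call(rbind, vals[seq(2L, length(vals), by = 2L)])
    uid <- runs$values
  } else {
    toks <- strsplit(trimws(body), "[ \t]+")
    uid <- vapply(toks, `[[`, "", 1L)
    cells <- lapply(toks, `[`, -1L)
    if (any(lengths(cells) != length(header)))
      stop("row length does not match header locus count")
    parse_cell <- function(s) {
      if (s == "-9" || s == "-9/-9") return(c(MISSING_CODE, MISSING_CODE))
      parts <- strsplit(s, "/", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) stop("malformed genotype cell: ", s)
      as.integer(parts)
    }
    mat <- lapply(cells, function(cc) vapply(cc, parse_cell, integer(2L)))
    a1 <- do.call(rbind, lapply(mat, function(m) m[1L, ]))
    a2 <- do.call(rbind, lapply(mat, function(m) m[2L, ]))
  }
  rownames(a1) <- rownames(a2) <- uid
  colnames(a1) <- colnames(a2) <- header
  extra <- setdiff(uid, samples$individual)
  if (length(extra) > 0L)
    stop("individual(s) not in sample table: ", paste(extra, collapse = ", "))
  absent <- setdiff(samples$individual, uid)
  if (length(absent) > 0L)
    stop("individual(s) missing from matrix: ", paste(absent, collapse = ", "))
  codominant_matrix(a1[samples$individual, , drop = FALSE],
                    a2[samples$individual, , drop = FALSE])
}

#' Write a codominant matrix
#' @param x a [codominant_matrix()].
#' @param path output path.
#' @param dialect output dialect, see [read_codominant_matrix()].
#' @export
write_codominant_matrix <- function(x, path,
                                    dialect = c("two-row-structure",
                                                "one-row-paired")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(x$a1), collapse = "\t"), con)
  ids <- rownames(x$a1)
  if (dialect == "two-row-structure") {
    for (i in seq_along(ids)) {
      writeLines(paste(c(ids[i], x$a1[i, ]), collapse = "\t"), con)
      writeLines(paste(c(ids[i], x$a2[i, ]), collapse = "\t"), con)
    }
  } else {
    for (i in seq_along(ids)) {
      cells <- ifelse(x$a1[i, ] == MISSING_CODE, "-9",
                      paste0(x$a1[i, ], "/", x$a2[i, ]))
      writeLines(paste(c(ids[i], cells), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Bundle marker matrices with sample metadata
#'
#' @param samples a [sample_table()].
#' @param codominant optional [codominant_matrix()] (row order must match
#'   `samples`).
#' @param dominant optional [dominant_matrix()] (row order must match).
#' @return A `genotype_dataset` object.
#' @export
genotype_dataset <- function(samples, codominant = NULL, dominant = NULL) {
  stopifnot(inherits(samples, "sample_table"))
  if (is.null(codominant) && is.null(dominant))
    stop("at least one marker matrix is required")
  if (!is.null(codominant)) {
    stopifnot(inherits(codominant, "codominant_matrix"))
    if (!identical(rownames(codominant$a1), samples$individual))
      stop("codominant matrix rows do not match sample table order")
  }
  if (!is.null(dominant)) {
    stopifnot(inherits(dominant, "dominant_matrix"))
    if (!identical(rownames(dominant), samples$individual))
      stop("dominant matrix rows do not match sample table order")
  }
  structure(list(samples = samples, codominant = codominant,
                 dominant = dominant),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "individuals,",
      length(unique(x$samples$accession)), "accessions,",
      length(unique(x$samples$population)), "populations\n")
  if (!is.null(x$codominant))
    cat("  codominant loci:", ncol(x$codominant$a1), "\n")
  if (!is.null(x$dominant))
    cat("  dominant loci:  ", ncol(x$dominant), "\n")
  invisible(x)
}

#' Drop control accessions from a dataset
#'
#' Control accessions take part only in admixture display; every other
#' statistic excludes them.
#' @param dataset a [genotype_dataset()].
#' @return The dataset restricted to non-control individuals.
#' @export
drop_controls <- function(dataset) {
  keep <- !dataset$samples$control
  subset_dataset(dataset, keep)
}

subset_dataset <- function(dataset, keep) {
  s <- dataset$samples[keep, , drop = FALSE]
  attr(s, "populations") <- attr(dataset$samples, "populations")
  class(s) <- class(dataset$samples)
  cod <- dataset$codominant
  if (!is.null(cod))
    cod <- codominant_matrix(cod$a1[keep, , drop = FALSE],
                             cod$a2[keep, , drop = FALSE])
  dom <- dataset$dominant
  if (!is.null(dom))
    dom <- dominant_matrix(unclass(dom)[keep, , drop = FALSE])
  genotype_dataset(s, cod, dom)
}

# Restrict a dataset to a set of locus ids (either marker system).
subset_loci <- function(dataset, loci) {
  cod <- dataset$codominant
  if (!is.null(cod)) {
    keep <- colnames(cod$a1) %in% loci
    cod <- if (any(keep))
      codominant_matrix(cod$a1[, keep, drop = FALSE],
                        cod$a2[, keep, drop = FALSE]) else NULL
  }
  dom <- dataset$dominant
  if (!is.null(dom)) {
    keep <- colnames(dom) %in% loci
    dom <- if (any(keep))
      dominant_matrix(unclass(dom)[, keep, drop = FALSE]) else NULL
  }
  genotype_dataset(dataset$samples, cod, dom)
}
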