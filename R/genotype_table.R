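#' Georeferenced genotype tables
#'
#' A `genotype_table` holds a set of georeferenced diploid individuals typed
#' at a shared panel of codominant loci (e.g. microsatellites). Alleles are
#' opaque positive integer labels (typically fragment sizes); no binning or
#' size-calling is performed. A genotype at a locus is either a complete
#' ordered pair of alleles or missing -- half-missing genotypes are rejected
#' because they bias gene counts.
#'
#' @param samples data.frame with columns `sample_id` (unique character),
#'   `lon`, `lat` (WGS84 decimal degrees), `status` (`"in_situ"` or
#'   `"ex_situ"`), and optionally `admin1` (first-level administrative unit).
#' @param loci character vector of locus names.
#' @param a1,a2 integer matrices (`nrow(samples)` x `length(loci)`) holding
#'   the two allele labels per individual per locus; `NA` in both marks a
#'   missing genotype.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(samples, loci, a1, a2) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "lon", "lat", "status") %in% names(samples)))
  loci <- as.character(loci)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (nrow(a1) != nrow(samples) || nrow(a2) != nrow(samples) ||
      ncol(a1) != length(loci) || ncol(a2) != length(loci))
    stop("allele matrices must be n_samples x n_loci")
  colnames(a1) <- colnames(a2) <- loci
  obj <- structure(list(samples = samples, loci = loci, a1 = a1, a2 = a2),
                   class = "genotype_table")
  validate_genotype_table(obj)
  obj
}

validate_genotype_table <- function(x) {
  s <- x$samples
  if (anyDuplicated(s$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", "))
  if (any(s$lon < -180 | s$lon > 180, na.rm = TRUE) ||
      any(s$lat < -90 | s$lat > 90, na.rm = TRUE))
    stop("coordinates outside WGS84 bounds")
  if (!all(s$status %in% c("in_situ", "ex_situ")))
    stop("status must be 'in_situ' or 'ex_situ'")
  half <- which(is.na(x$a1) != is.na(x$a2), arr.ind = TRUE)
  if (nrow(half) > 0)
    stop("half-missing genotype for sample '", s$sample_id[half[1, 1]],
         "' at locus '", x$loci[half[1, 2]], "'")
  if (any(x$a1 <= 0, na.rm = TRUE) || any(x$a2 <= 0, na.rm = TRUE))
    stop("allele labels must be positive integers")
  invisible(x)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$samples), "samples,",
      length(x$loci), "loci\n")
  cat("  loci:", paste(x$loci, collapse = ", "), "\n")
  cat("  status:", sum(x$samples$status == "in_situ"), "in situ,",
      sum(x$samples$status == "ex_situ"), "ex situ\n")
  miss <- mean(is.na(x$a1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / loci in a genotype table
#' @param x a `genotype_table`.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_loci <- function(x) length(x$loci)

#' Subset a genotype table by sample
#' @param x a `genotype_table`.
#' @param i sample index (integer/logical) or sample_id (character).
#' @param ... ignored.
#' @export
`[.genotype_table` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  genotype_table(x$samples[i, , drop = FALSE], x$loci,
                 x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE])
}

#' Total number of observed allele copies
#'
#' Counts the georeferenced allele copies in a table: two per non-missing
#' genotype. A complete table of n samples at L diploid loci therefore
#' contains `2 * n * L` copies.
#'
#' @param x a `genotype_table`.
#' @return integer count of allele copies.
#' @export
allele_copy_count <- function(x) 2L * sum(!is.na(x$a1))

#' Read a georeferenced genotype table
#'
#' Two CSV dialects are supported. The `genalex_csv` dialect is wide: columns
#' `sample_id, lon, lat, status[, admin1]` followed by one `"a/b"` pair field
#' per locus (locus names from the header); `"0/0"` or an empty field marks a
#' missing genotype (GenAlEx convention). The `long_csv` dialect has one row
#' per sample x locus: `sample,lon,lat,status,locus,allele1,allele2`, with 0
#' or empty alleles marking missing genotypes.
#'
#' A genotype with exactly one missing allele is a scoring error and raises a
#' hard error naming the sample and locus; duplicated sample ids are also
#' errors.
#'
#' @param path CSV file path.
#' @param dialect `"genalex_csv"` (default) or `"long_csv"`.
#' @return a [genotype_table].
#' @export
read_genotype_table <- function(path, dialect = c("genalex_csv", "long_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (dialect == "genalex_csv") parse_genalex(raw) else parse_long(raw)
}

parse_pair <- function(field, sample_id, locus) {
  field <- trimws(field)
  if (is.na(field) || field == "" || field == "0/0") return(c(NA_integer_, NA_integer_))
  parts <- strsplit(field, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("malformed genotype '", field, "' for sample '", sample_id,
         "' at locus '", locus, "'")
  al <- suppressWarnings(as.integer(parts))
  if (any(is.na(al)))
    stop("non-integer allele '", field, "' for sample '", sample_id,
         "' at locus '", locus, "'")
  al[al == 0L] <- NA_integer_
  if (xor(is.na(al[1]), is.na(al[2])))
    stop("half-missing genotype for sample '", sample_id,
         "' at locus '", locus, "'")
  al
}

parse_genalex <- function(raw) {
  meta_cols <- intersect(c("sample_id", "lon", "lat", "status", "admin1"),
                         names(raw))
  need <- c("sample_id", "lon", "lat", "status")
  if (!all(need %in% meta_cols))
    stop("genalex_csv header must contain: ", paste(need, collapse = ", "))
  loci <- setdiff(names(raw), meta_cols)
  if (length(loci) == 0) stop("no locus columns found")
  n <- nrow(raw)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  for (j in seq_along(loci)) {
    for (i in seq_len(n)) {
      al <- parse_pair(raw[[loci[j]]][i], raw$sample_id[i], loci[j])
      a1[i, j] <- al[1]; a2[i, j] <- al[2]
    }
  }
  samples <- data.frame(sample_id = raw$sample_id,
                        lon = as.numeric(raw$lon),
                        lat = as.numeric(raw$lat),
                        status = raw$status,
                        stringsAsFactors = FALSE)
  if ("admin1" %in% meta_cols) samples$admin1 <- raw$admin1
  genotype_table(samples, loci, a1, a2)
}

parse_long <- function(raw) {
  need <- c("sample", "lon", "lat", "status", "locus", "allele1", "allele2")
  if (!all(need %in% names(raw)))
    stop("long_csv header must contain: ", paste(need, collapse = ", "))
  ids <- unique(raw$sample)
  loci <- unique(raw$locus)
  n <- length(ids)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  ii <- match(raw$sample, ids)
  jj <- match(raw$locus, loci)
  if (anyDuplicated(cbind(ii, jj)))
    stop("duplicate sample x locus rows in long_csv")
  to_int <- function(v) {
    v <- suppressWarnings(as.integer(v))
    v[!is.na(v) & v == 0L] <- NA_integer_
    v
  }
  v1 <- to_int(raw$allele1); v2 <- to_int(raw$allele2)
  bad <- which(xor(is.na(v1), is.na(v2)))
  if (length(bad) > 0)
    stop("half-missing genotype for sample '", raw$sample[bad[1]],
         "' at locus '", raw$locus[bad[1]], "'")
  a1[cbind(ii, jj)] <- v1
  a2[cbind(ii, jj)] <- v2
  first <- match(ids, raw$sample)
  samples <- data.frame(sample_id = ids,
                        lon = as.numeric(raw$lon[first]),
                        lat = as.numeric(raw$lat[first]),
                        status = raw$status[first],
                        stringsAsFactors = FALSE)
  if ("admin1" %in% names(raw)) samples$admin1 <- raw$admin1[first]
  genotype_table(samples, loci, a1, a2)
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotype_table()]; missing genotypes are written as
#' `"0/0"` (wide dialect) or `0,0` (long dialect) so that a round trip
#' reproduces the table.
#'
#' @param x a [genotype_table].
#' @param path output CSV path.
#' @param dialect `"genalex_csv"` or `"long_csv"`.
#' @export
write_genotype_table <- function(x, path,
                                 dialect = c("genalex_csv", "long_csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "genalex_csv") {
    out <- x$samples[intersect(c("sample_id", "lon", "lat", "status", "admin1"),
                               names(x$samples))]
    for (j in seq_along(x$loci)) {
      f <- ifelse(is.na(x$a1[, j]), "0/0", paste0(x$a1[, j], "/", x$a2[, j]))
      out[[x$loci[j]]] <- f
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    n <- n_samples(x); L <- n_loci(x)
    out <- data.frame(
      sample = rep(x$samples$sample_id, times = L),
      lon = rep(x$samples$lon, times = L),
      lat = rep(x$samples$lat, times = L),
      status = rep(x$samples$status, times = L),
      locus = rep(x$loci, each = n),
      allele1 = ifelse(is.na(as.vector(x$a1)), 0L, as.vector(x$a1)),
      allele2 = ifelse(is.na(as.vector(x$a2)), 0L, as.vector(x$a2)),
      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
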