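#' @useDynLib ecoimmune, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd var median quantile rnorm runif rbinom rgamma
#'   setNames complete.cases cov cov2cor prcomp cmdscale hclust as.dist
#'   cophenetic optim nlminb pchisq pnorm qgamma uniroot dist qchisq rbeta
#' @importFrom utils read.csv write.csv head
NULL

# Column sets for the tabular schemas mirrored from the study's
# supplementary files. Canonical CSV is UTF-8 with '.' decimal; blank
# cells are missing values (never 0 or -1).
.infection_cols <- c("noro", "minute", "parvo", "sendai", "corona", "mhv",
                     "m_pulmonis")
.immune_cols <- c("cd4", "cd8", "cd19", "nk", "neutrophil", "dc",
                  "macrophage", "igg", "ige", "iga")

.schema_cols <- function(schema) {
  switch(schema,
    s1_infection = c("mouse_id", "site", .infection_cols,
                     "mite_count_class", "worm_count"),
    s3_pcs       = c("mouse_id", "site", "pc1", "pc2", "pc3"),
    s6_physical  = c("mouse_id", "site", "day_length", "sex", "body_length",
                     "body_mass", "abdominal_fat", "lens_mass", "age",
                     "haemoglobin", "leptin"),
    canonical    = c("mouse_id", "site", "sex", "day_length", "body_mass",
                     "body_length", "abdominal_fat", "lens_mass", "age",
                     "leptin", "haemoglobin", .infection_cols,
                     "mite_count_class", "worm_count", .immune_cols),
    stop("unknown schema '", schema, "'", call. = FALSE)
  )
}

# Normalise unicode minus / plus-minus sometimes carried over from
# supplementary legends, then coerce to numeric.
.to_num <- function(x) {
  if (is.numeric(x)) return(x)
  x <- gsub("−", "-", x)
  x <- gsub("±.*$", "", x)
  x[x %in% c("", "NA", "ND", "nd")] <- NA
  as.numeric(x)
}

.decode_sex <- function(x) {
  if (is.numeric(x)) {
    out <- rep(NA_character_, length(x))
    out[x == 1] <- "female"
    out[x == 2] <- "male"
    bad <- !is.na(x) & !(x %in% c(1, 2))
    if (any(bad)) stop("invalid sex code: ", x[which(bad)[1]], call. = FALSE)
    return(out)
  }
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("", "na")] <- NA
  x[x %in% c("f", "1")] <- "female"
  x[x %in% c("m", "2")] <- "male"
  bad <- !is.na(x) & !(x %in% c("female", "male"))
  if (any(bad)) stop("invalid sex value: ", x[which(bad)[1]], call. = FALSE)
  x
}

#' Read a cohort table in one of the canonical schemas
#'
#' Reads a per-mouse CSV mirroring the study's supplementary layouts:
#' `s1_infection` (serological scores 0-4 for seven microbes plus
#' macroparasite counts), `s3_pcs` (three immune principal-component scores
#' per mouse), `s6_physical` (morphometrics, day length, lens mass, age) or
#' `canonical` (every field). Numeric site codes are mapped to the twelve
#' two-letter designations; blank cells become `NA`.
#'
#' @param path CSV file path (an `.xlsx` path is converted first if the
#'   readxl package is installed).
#' @param schema one of `"s1_infection"`, `"s3_pcs"`, `"s6_physical"`,
#'   `"canonical"`.
#' @return A data frame with one row per mouse, `mouse_id` as character,
#'   `site` as a two-letter code, `sex` in `{female, male}` where present.
#' @export
read_cohort <- function(path, schema = "canonical") {
  cols <- .schema_cols(schema)
  df <- .read_table(path)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop("file does not match schema '", schema, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[cols]
  df$mouse_id <- as.character(df$mouse_id)
  df$site <- map_site_code(df$site)
  num_cols <- setdiff(cols, c("mouse_id", "site", "sex"))
  for (cc in num_cols) df[[cc]] <- .to_num(df[[cc]])
  if ("sex" %in% cols) df$sex <- .decode_sex(df$sex)
  validate_cohort(df, schema)
  df
}

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package; convert to CSV first",
           call. = FALSE)
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = c("", "NA", "ND"))
  }
}

#' Validate a cohort data frame against schema invariants
#'
#' @param df cohort data frame as returned by [read_cohort()].
#' @param schema schema name (used to pick which invariants apply).
#' @return `df`, invisibly; errors name the offending cell.
#' @export
validate_cohort <- function(df, schema = "canonical") {
  chk_pos <- function(col) {
    if (!col %in% names(df)) return(invisible(NULL))
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad) > 0) {
      stop("validation error: non-positive ", col, " for mouse_id ",
           df$mouse_id[bad[1]], call. = FALSE)
    }
  }
  chk_pos("body_mass"); chk_pos("body_length"); chk_pos("lens_mass")
  for (cc in intersect(.infection_cols, names(df))) {
    bad <- which(!is.na(df[[cc]]) & !(df[[cc]] %in% 0:4))
    if (length(bad) > 0) {
      stop("validation error: infection score ", cc, " outside 0-4 for ",
           "mouse_id ", df$mouse_id[bad[1]], call. = FALSE)
    }
  }
  invisible(df)
}

#' Write a cohort table
#'
#' Missing values are written as empty cells, so `read_cohort()` /
#' `write_cohort()` round-trip field-for-field.
#'
#' @param df cohort data frame.
#' @param path output CSV path.
#' @export
write_cohort <- function(df, path) {
  out <- df
  if ("sex" %in% names(out)) out$sex <- as.character(out$sex)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

## ---- genotypes --------------------------------------------------------

#' Construct a genotype matrix object
#'
#' Biallelic diploid genotypes as alt-allele dosage (0, 1, 2 or `NA`),
#' loci in rows and individuals in columns, with per-individual site labels.
#'
#' @param dosage integer matrix, loci x individuals, values in
#'   `{0, 1, 2, NA}`.
#' @param locus_ids,chromosome,position per-locus annotation vectors.
#' @param sites character vector of site labels, one per individual.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, locus_ids = rownames(dosage),
                            chromosome = rep(NA_character_, nrow(dosage)),
                            position = rep(NA_integer_, nrow(dosage)),
                            sites = rep(NA_character_, ncol(dosage))) {
  dosage <- as.matrix(dosage)
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) stop("dosage values must be 0, 1, 2 or missing", call. = FALSE)
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("ind", seq_len(ncol(dosage)))
  }
  rownames(dosage) <- locus_ids
  stopifnot(length(sites) == ncol(dosage), length(chromosome) == nrow(dosage))
  structure(list(dosage = dosage, locus_ids = locus_ids,
                 chromosome = chromosome, position = position,
                 individuals = colnames(dosage),
                 sites = as.character(sites)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "loci x", ncol(x$dosage),
      "individuals;", sum(is.na(x$dosage)), "missing calls;",
      length(unique(x$sites[!is.na(x$sites)])), "sites\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# Convert raw genotype calls (dosage numbers or two-letter allele pairs such
# as "AG"/"A/G") to alt-allele dosage; errors on loci with >2 alleles.
.calls_to_dosage <- function(m, locus_ids) {
  if (is.numeric(m)) {
    bad <- !is.na(m) & !(m %in% 0:2)
    if (any(bad)) stop("numeric genotype calls must be dosage 0/1/2",
                       call. = FALSE)
    return(m)
  }
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (l in seq_len(nrow(m))) {
    calls <- toupper(gsub("[/| ]", "", as.character(m[l, ])))
    calls[calls %in% c("", "NA", "--", "00", "??")] <- NA
    ok <- !is.na(calls)
    if (all(grepl("^[0-2]$", calls[ok]))) {
      out[l, ok] <- as.numeric(calls[ok])
      next
    }
    if (!all(nchar(calls[ok]) == 2)) {
      stop("unrecognised genotype call at locus ", locus_ids[l], call. = FALSE)
    }
    alleles <- sort(unique(unlist(strsplit(calls[ok], ""))))
    if (length(alleles) > 2) {
      stop("locus ", locus_ids[l], " is not biallelic (alleles ",
           paste(alleles, collapse = ","), ")", call. = FALSE)
    }
    alt <- alleles[length(alleles)]
    cnt <- vapply(strsplit(calls[ok], ""),
                  function(a) sum(a == alt), numeric(1))
    out[l, ok] <- cnt
  }
  out
}

#' Read a genotype matrix
#'
#' First three columns are locus id, chromosome and position; remaining
#' columns are individuals. Calls may be alt-allele dosages (0/1/2) or
#' two-letter allele pairs (e.g. `AG`); the encoding is auto-detected per
#' locus and triallelic loci raise an error naming the locus.
#'
#' @param path CSV path.
#' @param site_map optional data frame with columns `mouse_id` and `site`
#'   (or a named character vector) assigning individuals to sites.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, site_map = NULL) {
  df <- .read_table(path)
  if (ncol(df) < 4) {
    stop("genotype file needs locus/chromosome/position plus individuals",
         call. = FALSE)
  }
  ids <- as.character(df[[1]])
  calls <- as.matrix(df[, -(1:3), drop = FALSE])
  dosage <- .calls_to_dosage(calls, ids)
  colnames(dosage) <- colnames(calls)
  sites <- rep(NA_character_, ncol(dosage))
  if (!is.null(site_map)) {
    if (is.data.frame(site_map)) {
      site_map <- setNames(as.character(site_map$site),
                           as.character(site_map$mouse_id))
    }
    sites <- unname(site_map[colnames(dosage)])
  }
  genotype_matrix(dosage, locus_ids = ids,
                  chromosome = as.character(df[[2]]),
                  position = suppressWarnings(as.numeric(df[[3]])),
                  sites = sites)
}

#' Write a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param path output CSV path.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(locus_id = g$locus_ids, chromosome = g$chromosome,
                   position = g$position, check.names = FALSE)
  df <- cbind(df, as.data.frame(g$dosage, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

## ---- distance matrices and trees -------------------------------------

#' Validate and label a distance matrix
#'
#' @param values square numeric matrix.
#' @param labels entity labels (mice or sites); defaults to existing
#'   dimnames.
#' @param tol symmetry tolerance; asymmetry beyond it is an error.
#' @return A symmetric matrix with zero diagonal and dimnames set.
#' @export
distance_matrix <- function(values, labels = rownames(values), tol = 1e-9) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square",
                                         call. = FALSE)
  if (any(is.na(values))) stop("distance matrix contains missing values",
                               call. = FALSE)
  if (any(values < 0)) stop("distance matrix has negative entries",
                            call. = FALSE)
  if (max(abs(values - t(values))) > tol) {
    stop("distance matrix asymmetric beyond tolerance ", tol, call. = FALSE)
  }
  if (max(abs(diag(values))) > tol) {
    stop("distance matrix diagonal is not zero", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (is.null(labels)) labels <- paste0("e", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  values
}

#' Read a labelled square distance matrix from CSV
#'
#' @param path CSV with labels in the first column and header row.
#' @param tol symmetry tolerance.
#' @return Validated distance matrix (see [distance_matrix()]).
#' @export
read_distance_matrix <- function(path, tol = 1e-9) {
  df <- .read_table(path)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  distance_matrix(m, labels, tol = tol)
}

#' @rdname read_distance_matrix
#' @param dm distance matrix to write.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(label = rownames(dm), check.names = FALSE)
  df <- cbind(df, as.data.frame(dm, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a phylogenetic/cluster tree as Newick
#'
#' @param tree an [ape::phylo] object (branch lengths and any node labels,
#'   e.g. bootstrap support, are preserved).
#' @param path output file path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
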