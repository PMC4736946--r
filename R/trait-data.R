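#' Construct a binary trait matrix
#'
#' A trait matrix holds one row per taxon (population) and one column per
#' trait (e.g. a folktale type), with entries 0 (absent), 1 (present) or
#' `NA` (missing).
#'
#' @param x a numeric matrix with unique rownames (taxa) and colnames
#'   (trait ids), values in `{0, 1, NA}`.
#' @return an object of class `trait_matrix` (an integer matrix).
#' @export
trait_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("trait matrix needs taxon rownames and trait-id colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate taxon: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate trait id: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!(is.na(x) | x == 0 | x == 1), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-binary cell at taxon '", rownames(x)[bad[1, 1]], "', trait '",
         colnames(x)[bad[1, 2]], "': value ", x[bad[1, , drop = FALSE]])
  storage.mode(x) <- "integer"
  structure(x, class = c("trait_matrix", "matrix", "array"))
}

#' Read a trait matrix from CSV/TSV
#'
#' Expects a rectangular table with taxa in the first column and trait ids
#' in the header. Cells may be `0`, `1`, `NA` or `?` (read as missing).
#' Taxon and trait labels are whitespace-trimmed.
#'
#' @param path file path.
#' @param sep field separator; `NULL` guesses `\t` vs `,` from the header.
#' @return a `trait_matrix`.
#' @export
read_trait_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("trait matrix file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   na.strings = c("NA", "?", ""), stringsAsFactors = FALSE)
  taxa <- trimws(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- taxa
  colnames(m) <- trimws(colnames(m))
  trait_matrix(m)
}

#' Write a trait matrix
#'
#' Missing values are written as `NA`; `read_trait_matrix()` round-trips.
#'
#' @param m a `trait_matrix`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_trait_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(taxon = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-trait prevalence and missingness
#'
#' Prevalence is the number of taxa where the trait is present divided by
#' the number of non-missing entries; traits that never vary among scored
#' taxa are flagged constant (the D statistic is undefined for them).
#'
#' @param m a `trait_matrix`.
#' @return data frame: trait, n_present, n_absent, n_missing, prevalence,
#'   constant.
#' @export
trait_prevalence <- function(m) {
  n1 <- colSums(m == 1, na.rm = TRUE)
  n0 <- colSums(m == 0, na.rm = TRUE)
  nm <- colSums(is.na(m))
  data.frame(trait = colnames(m), n_present = n1, n_absent = n0,
             n_missing = nm, prevalence = n1 / pmax(n1 + n0, 1L),
             constant = (n1 == 0L | n0 == 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Set every trait state of one taxon (outgroup coding)
#'
#' The outgroup typically lacks trait data; depending on the stage it is
#' coded all-absent or all-present (signal screening, which cannot use
#' missing data) or all-missing (ancestral-state reconstruction, where
#' missing tips contribute flat partial likelihoods). Returns a modified
#' copy; the row is added if the taxon is new.
#'
#' @param m a `trait_matrix`.
#' @param taxon taxon label.
#' @param policy `"absent"`, `"present"` or `"missing"`.
#' @return a new `trait_matrix`.
#' @export
set_outgroup_state <- function(m, taxon, policy = c("absent", "present", "missing")) {
  policy <- match.arg(policy)
  value <- switch(policy, absent = 0L, present = 1L, missing = NA_integer_)
  x <- unclass(m)
  if (!taxon %in% rownames(x)) {
    x <- rbind(x, matrix(NA_integer_, 1, ncol(x), dimnames = list(taxon, colnames(x))))
  }
  x[taxon, ] <- value
  trait_matrix(x)
}

#' Rename taxa through an alias map
#'
#' Matches trait-matrix taxa to tree tips or metadata labels when spellings
#' diverge between sources.
#'
#' @param m a `trait_matrix`.
#' @param alias named character vector, `old name -> new name`.
#' @return a `trait_matrix` with renamed rows.
#' @export
rename_taxa <- function(m, alias) {
  x <- unclass(m)
  hit <- rownames(x) %in% names(alias)
  rownames(x)[hit] <- unname(alias[rownames(x)[hit]])
  trait_matrix(x)
}

#' Read society metadata
#'
#' A CSV/TSV with columns `society`, `lat`, `lon`, `subfamily` and
#' optionally `point_id`. Coordinates may be missing (e.g. for dispersed
#' groups with no single location); such societies are excluded from
#' spatial graphs. Subfamily `"none"` marks societies outside any subfamily.
#'
#' @param path file path.
#' @param sep field separator; `NULL` guesses from the header.
#' @return a validated data frame (class `society_metadata`).
#' @export
read_society_metadata <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  society_metadata(df)
}

#' @rdname read_society_metadata
#' @param df a data frame with the columns described above.
#' @export
society_metadata <- function(df) {
  need <- c("society", "lat", "lon", "subfamily")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  df$society <- trimws(as.character(df$society))
  if (anyDuplicated(df$society))
    stop("duplicate society: ",
         paste(unique(df$society[duplicated(df$society)]), collapse = ", "))
  ok <- is.na(df$lat) | (df$lat >= -90 & df$lat <= 90)
  if (!all(ok)) stop("latitude out of [-90, 90] for: ",
                     paste(df$society[!ok], collapse = ", "))
  ok <- is.na(df$lon) | (df$lon >= -180 & df$lon <= 180)
  if (!all(ok)) stop("longitude out of [-180, 180] for: ",
                     paste(df$society[!ok], collapse = ", "))
  df$subfamily <- as.character(df$subfamily)
  if (any(is.na(df$subfamily) | df$subfamily == ""))
    stop("subfamily must be non-empty (use 'none' for societies outside any subfamily)")
  if (is.null(df$point_id)) df$point_id <- seq_len(nrow(df))
  class(df) <- c("society_metadata", "data.frame")
  df
}

#' Write society metadata
#' @param meta a `society_metadata` data frame.
#' @param path output path.
#' @param sep field separator.
#' @export
write_society_metadata <- function(meta, path, sep = ",") {
  write.table(as.data.frame(meta), path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
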