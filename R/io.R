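# Plain-text readers/writers for the pipeline's interchange formats:
# tab-delimited matrices with an id column, metadata CSV, and GMT gene sets.

#' Write a numeric matrix as TSV with an id column
#'
#' @param m Matrix with rownames (feature ids) and colnames (sample ids).
#' @param path Output path.
#' @param id_col Header for the id column.
#' @param na String used for missing values (empty string for metabolite
#'   panels).
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id", na = "NA") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = na)
  invisible(path)
}

#' Read a feature-by-sample matrix from TSV
#'
#' First column holds feature ids, header row holds sample ids; empty cells
#' become `NA` (missing). Duplicate feature ids are an error.
#'
#' @param path TSV path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("parse error: matrix file needs id column plus samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("parse error: duplicate feature ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a sample metadata table
#'
#' CSV with at least `sample_id`, `bmi` and `batch` columns.
#'
#' @param path CSV path.
#' @return data.frame with `batch` as factor.
#' @export
read_metadata_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "bmi", "batch")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("parse error: metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("parse error: duplicate sample ids in metadata")
  df$batch <- factor(df$batch)
  df
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited format: set name, description, then member ids.
#' A line with fewer than 3 fields is a parse error reported with its line
#' number.
#'
#' @param path GMT path.
#' @return Named list of character vectors (unique members per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("parse error: GMT line %d has fewer than 3 fields", i))
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
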