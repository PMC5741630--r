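#' @keywords internal
"_PACKAGE"

## Canonical column order and categorical levels for ray-score tables.
RAY_COLUMNS <- c("fish_id", "fin_id", "ray_index", "injury", "escaper",
                 "inadvertent_injury", "regen_3dpi", "regen_7dpi")
INJURY_LEVELS <- c("none", "re_amputation", "epidermal_wound", "skin_wound")
RAY_LOGICAL_COLUMNS <- c("escaper", "inadvertent_injury", "regen_3dpi",
                         "regen_7dpi")

#' Construct a validated ray-score dataset
#'
#' A ray dataset is a data frame with one row per scored fin ray. The core
#' columns are `fish_id`, `fin_id`, `ray_index` (1-based position along the
#' fin), `injury` (one of `"none"`, `"re_amputation"`, `"epidermal_wound"`,
#' `"skin_wound"`), and the logical flags `escaper`, `inadvertent_injury`,
#' `regen_3dpi`, `regen_7dpi`. Extra columns are carried along untouched and
#' ignored by all analyses. Rows are normalized so that rays within a fin are
#' ordered by `ray_index`; fins keep their order of first appearance.
#'
#' Adjacency between rays is defined only between consecutive `ray_index`
#' values within the same `(fish_id, fin_id)` fin, never across fins or fish.
#'
#' @param df data frame containing at least the core columns.
#' @param label optional free-text experiment tag, stored as an attribute.
#' @return an object of class `ray_dataset` (a data frame).
#' @export
ray_dataset <- function(df, label = NULL) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(RAY_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$fish_id <- as.character(df$fish_id)
  df$fin_id <- as.character(df$fin_id)
  df$ray_index <- .parse_ray_index(df$ray_index)
  df$injury <- .parse_injury(df$injury)
  for (col in RAY_LOGICAL_COLUMNS) df[[col]] <- .parse_flag(df[[col]], col)
  df <- .normalize_ray_order(df)
  extras <- setdiff(names(df), RAY_COLUMNS)
  df <- df[, c(RAY_COLUMNS, extras), drop = FALSE]
  rownames(df) <- NULL
  structure(df, label = label, class = c("ray_dataset", "data.frame"))
}

.parse_ray_index <- function(x) {
  idx <- suppressWarnings(as.integer(as.character(x)))
  bad <- which(is.na(idx) | idx < 1L)
  if (length(bad) > 0L) {
    stop("non-positive or unparseable ray_index at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  idx
}

.parse_injury <- function(x) {
  inj <- tolower(trimws(as.character(x)))
  bad <- which(!inj %in% INJURY_LEVELS)
  if (length(bad) > 0L) {
    stop("unparseable injury value '", inj[bad[1L]], "' at row ", bad[1L],
         "; expected one of: ", paste(INJURY_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  inj
}

.parse_flag <- function(x, name) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "t")] <- TRUE
  out[v %in% c("0", "false", "f")] <- FALSE
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    stop("unparseable boolean in column '", name, "' at row ", bad[1L],
         " (value '", v[bad[1L]], "')", call. = FALSE)
  }
  out
}

.fin_key <- function(df) paste(df$fish_id, df$fin_id, sep = "\r")

.normalize_ray_order <- function(df) {
  key <- .fin_key(df)
  fin_rank <- match(key, unique(key))
  df[order(fin_rank, df$ray_index), , drop = FALSE]
}

#' Validate a ray dataset against its structural invariants
#'
#' Checks that `ray_index` values are unique and contiguous (1..K) within
#' every fin, that no `(fish_id, fin_id)` pair is duplicated across blocks,
#' and that escapers are uninjured (`injury == "none"`): escapers are by
#' definition uninjured rays that showed growth despite the regeneration
#' blockade.
#'
#' @param dataset a `ray_dataset`.
#' @return the dataset, invisibly, if valid; otherwise an error naming the
#'   offending fin.
#' @export
validate_ray_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "ray_dataset"))
  bad_escaper <- which(dataset$escaper & dataset$injury != "none")
  if (length(bad_escaper) > 0L) {
    stop("escaper with injury != none at row ", bad_escaper[1L],
         " (fish ", dataset$fish_id[bad_escaper[1L]], ", fin ",
         dataset$fin_id[bad_escaper[1L]], "): escapers are uninjured rays",
         call. = FALSE)
  }
  for (fin in split(seq_len(nrow(dataset)), .fin_key(dataset))) {
    idx <- sort(dataset$ray_index[fin])
    fish <- dataset$fish_id[fin[1L]]
    fin_id <- dataset$fin_id[fin[1L]]
    if (anyDuplicated(idx)) {
      stop("duplicate ray_index in fish ", fish, ", fin ", fin_id,
           call. = FALSE)
    }
    if (!identical(idx, seq_len(length(idx)))) {
      stop("non-contiguous ray_index in fish ", fish, ", fin ", fin_id,
           ": got ", paste(idx, collapse = ","), ", expected 1..",
           length(idx), call. = FALSE)
    }
  }
  invisible(dataset)
}

#' Split a ray dataset into its fins
#'
#' @param dataset a `ray_dataset`.
#' @return a list of data frames, one per `(fish_id, fin_id)` fin, each
#'   ordered by `ray_index`, in order of first appearance.
#' @export
fin_series <- function(dataset) {
  key <- .fin_key(dataset)
  idx <- split(seq_len(nrow(dataset)), factor(key, levels = unique(key)))
  lapply(idx, function(i) dataset[i, , drop = FALSE])
}

#' Read a tabular ray-score file
#'
#' Reads a UTF-8 TSV (default) or CSV file with a header row naming all core
#' ray columns (see [ray_dataset()]); extra columns are preserved as
#' character. Booleans are accepted as `0`/`1` or `true`/`false`; injury
#' classes are the lower-case category names. Parse and validation errors
#' report the offending data row.
#'
#' @param path path to the table.
#' @param dialect `"tsv"` or `"csv"`.
#' @param label optional experiment tag attached to the dataset.
#' @return a validated `ray_dataset`.
#' @export
read_ray_table <- function(path, dialect = c("tsv", "csv"), label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "", encoding = "UTF-8",
                          stringsAsFactors = FALSE)
  d <- ray_dataset(df, label = label)
  validate_ray_dataset(d)
  d
}

#' Write a ray dataset to a tabular file
#'
#' Serialization is byte-stable: columns are written in the canonical order
#' (core columns first, then extras in their stored order), booleans as
#' `0`/`1`, injury as the lower-case category names, and rows in normalized
#' fin/ray order, so [read_ray_table()] reproduces the dataset exactly.
#'
#' @param dataset a `ray_dataset`.
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_ray_table <- function(dataset, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  validate_ray_dataset(dataset)
  sep <- if (dialect == "tsv") "\t" else ","
  out <- as.data.frame(dataset, stringsAsFactors = FALSE)
  for (col in RAY_LOGICAL_COLUMNS) out[[col]] <- as.integer(out[[col]])
  extra <- setdiff(names(out), RAY_COLUMNS)
  for (col in extra) {
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.ray_dataset <- function(x, ...) {
  label <- attr(x, "label")
  n_fins <- length(unique(.fin_key(x)))
  cat("ray_dataset: ", nrow(x), " rays, ", n_fins, " fins",
      if (!is.null(label)) paste0(" [", label, "]"), "\n", sep = "")
  NextMethod()
}
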