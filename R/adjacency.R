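## Classed condition for statistics that are mathematically undefined on the
## given input (e.g. a bystander fraction with no regenerating rays).
.undefined <- function(msg) {
  stop(structure(class = c("rayregen_undefined", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

#' Construct a binary regeneration sequence
#'
#' A binary sequence is the 0/1 encoding of a regeneration outcome over an
#' ordered set of rays, together with the block structure that delimits
#' stretches of genuinely adjacent rays. `mode` records how the sequence is
#' meant to be scanned: `"pooled"` treats the values as one literal list
#' (blocks kept as annotation), `"per_fin"` keeps block boundaries as
#' adjacency breaks.
#'
#' @param values integer/logical vector of 0s and 1s.
#' @param blocks data frame with columns `start` (1-based) and `length`, or
#'   `NULL` for a single block spanning the sequence.
#' @param mode `"pooled"` or `"per_fin"`.
#' @return an object of class `binary_seq`.
#' @export
binary_sequence <- function(values, blocks = NULL,
                            mode = c("pooled", "per_fin")) {
  mode <- match.arg(mode)
  values <- as.integer(values)
  if (any(is.na(values) | !values %in% c(0L, 1L))) {
    stop("values must be 0/1", call. = FALSE)
  }
  n <- length(values)
  if (is.null(blocks)) {
    blocks <- data.frame(start = if (n > 0L) 1L else integer(0),
                         length = if (n > 0L) n else integer(0))
  }
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("start", "length") %in% names(blocks)))
  blocks$start <- as.integer(blocks$start)
  blocks$length <- as.integer(blocks$length)
  if (sum(blocks$length) != n ||
      (nrow(blocks) > 0L &&
       !identical(blocks$start,
                  as.integer(cumsum(c(1L, blocks$length[-nrow(blocks)])))))) {
    stop("blocks must be disjoint, ordered, and cover the sequence",
         call. = FALSE)
  }
  structure(list(values = values, blocks = blocks, mode = mode),
            class = "binary_seq")
}

#' Encode regeneration outcomes of ordered rays as a binary sequence
#'
#' Rays are taken in their normalized (fish, fin, ray_index) order and the
#' named outcome field becomes 1 (growth) or 0 (no growth). Block boundaries
#' are placed wherever biological adjacency breaks: at every fin change and
#' at every gap in `ray_index` (gaps arise when eligibility filters remove
#' rays between two retained ones).
#'
#' @param rays a `ray_dataset` (typically an eligible subset).
#' @param outcome_field name of a boolean column, e.g. `"regen_7dpi"`.
#' @param mode `"pooled"` or `"per_fin"`; stored on the result and used as
#'   the default scanning convention downstream.
#' @return a [binary_sequence()].
#' @export
encode_binary <- function(rays, outcome_field = "regen_7dpi",
                          mode = c("pooled", "per_fin")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rays, "ray_dataset"))
  if (!outcome_field %in% names(rays)) {
    stop("unknown outcome field: ", outcome_field, call. = FALSE)
  }
  rays <- .normalize_ray_order(rays)
  values <- as.integer(.parse_flag(rays[[outcome_field]], outcome_field))
  n <- nrow(rays)
  if (n == 0L) return(binary_sequence(integer(0), mode = mode))
  key <- .fin_key(rays)
  new_block <- c(TRUE, key[-1L] != key[-n] |
                   diff(rays$ray_index) != 1L)
  starts <- which(new_block)
  lengths <- diff(c(starts, n + 1L))
  binary_sequence(values, data.frame(start = starts, length = lengths),
                  mode = mode)
}

## Core scan: number of 1s whose every *existing* neighbor is 0. starts/ends
## give the segment boundaries within which neighbors are looked up; a 1 at
## a segment end has a single neighbor (no phantom zeros, no wraparound).
.iso_count <- function(values, starts, ends) {
  n <- length(values)
  if (n == 0L) return(0L)
  left <- c(0L, values[-n])
  right <- c(values[-1L], 0L)
  left[starts] <- 0L
  right[ends] <- 0L
  sum(values == 1L & left == 0L & right == 0L)
}

.seq_segments <- function(seq, respect_blocks) {
  n <- length(seq$values)
  if (respect_blocks && nrow(seq$blocks) > 0L) {
    list(starts = seq$blocks$start,
         ends = seq$blocks$start + seq$blocks$length - 1L)
  } else {
    list(starts = if (n > 0L) 1L else integer(0),
         ends = if (n > 0L) n else integer(0))
  }
}

#' Count isolated regenerators ("010" pattern)
#'
#' A 1 is isolated when every neighbor it actually has is 0. With
#' `respect_blocks = TRUE` neighbors are looked up within blocks only, so a
#' 1 at a block boundary can gain isolation relative to the pooled scan;
#' with `FALSE` the whole value list is scanned as one sequence.
#'
#' @param seq a [binary_sequence()].
#' @param respect_blocks logical; defaults to `TRUE` for `mode = "per_fin"`
#'   sequences and `FALSE` for pooled ones.
#' @return a list with `isolated` (count of isolated 1s) and `ones` (total
#'   1s). The isolated frequency is `isolated / ones`.
#' @export
count_isolated <- function(seq, respect_blocks = NULL) {
  stopifnot(inherits(seq, "binary_seq"))
  if (is.null(respect_blocks)) respect_blocks <- seq$mode == "per_fin"
  seg <- .seq_segments(seq, respect_blocks)
  list(isolated = .iso_count(seq$values, seg$starts, seg$ends),
       ones = sum(seq$values))
}

#' Isolated-regenerator frequency of a binary sequence
#'
#' @inheritParams count_isolated
#' @return `isolated / ones`; errors (class `rayregen_undefined`) when the
#'   sequence contains no 1s.
#' @export
isolated_frequency <- function(seq, respect_blocks = NULL) {
  ct <- count_isolated(seq, respect_blocks)
  if (ct$ones == 0L) {
    .undefined("isolated frequency undefined: no regenerating rays")
  }
  ct$isolated / ct$ones
}

#' Bystander fraction of a binary sequence
#'
#' The fraction of regenerating rays that have at least one regenerating
#' neighbor: exactly `1 - isolated frequency`.
#'
#' @inheritParams count_isolated
#' @return a fraction in `[0, 1]`; errors (class `rayregen_undefined`) when
#'   there are no regenerating rays.
#' @export
bystander_fraction <- function(seq, respect_blocks = NULL) {
  1 - isolated_frequency(seq, respect_blocks)
}

#' Fraction of focal rays with a regenerating neighbor
#'
#' For a focal category (escapers or an injury class), the fraction of focal
#' rays that have at least one immediate neighbor (same fin, ray_index
#' +/- 1) with the outcome field true. Used as a control: if escapers
#' associate with neighbor regeneration as often as deliberate injuries do,
#' bystander growth is not an artifact of undetected wounding.
#'
#' @param dataset a validated `ray_dataset`.
#' @param focal_category `"escaper"` or one of the injury classes.
#' @param outcome_field boolean outcome column, default `"regen_7dpi"`.
#' @return a fraction in `[0, 1]`; errors (class `rayregen_undefined`) when
#'   no focal ray exists.
#' @export
neighbor_association_rate <- function(dataset, focal_category,
                                      outcome_field = "regen_7dpi") {
  stopifnot(inherits(dataset, "ray_dataset"))
  focal_category <- match.arg(focal_category,
                              c("escaper",
                                INJURY_LEVELS[INJURY_LEVELS != "none"]))
  .check_rays(dataset)
  if (!outcome_field %in% names(dataset)) {
    stop("unknown outcome field: ", outcome_field, call. = FALSE)
  }
  focal <- if (focal_category == "escaper") {
    dataset$escaper
  } else {
    dataset$injury == focal_category
  }
  if (!any(focal)) {
    .undefined(paste0("no rays in focal category '", focal_category, "'"))
  }
  regen <- .parse_flag(dataset[[outcome_field]], outcome_field)
  has_regen_neighbor <- .neighbor_any(dataset, regen)
  mean(has_regen_neighbor[focal])
}

#' Fraction of rays with a positive regeneration call
#'
#' @param rays a `ray_dataset` subset.
#' @param outcome_field boolean outcome column.
#' @return `(# true) / (# rays)`, at full precision; errors (class
#'   `rayregen_undefined`) on an empty subset.
#' @export
regeneration_fraction <- function(rays, outcome_field = "regen_7dpi") {
  stopifnot(inherits(rays, "ray_dataset"))
  if (!outcome_field %in% names(rays)) {
    stop("unknown outcome field: ", outcome_field, call. = FALSE)
  }
  if (nrow(rays) == 0L) {
    .undefined("regeneration fraction undefined on an empty subset")
  }
  mean(.parse_flag(rays[[outcome_field]], outcome_field))
}

#' Construct a 2x2 contingency table of regeneration counts
#'
#' Rows are treatment groups, columns are regenerating / not regenerating.
#'
#' @param counts a 2x2 matrix, or four non-negative integers in row-major
#'   order (group1 regen, group1 not, group2 regen, group2 not).
#' @return an integer 2x2 matrix of class `contingency_table`.
#' @export
contingency_table <- function(counts) {
  if (!is.matrix(counts)) {
    counts <- matrix(as.numeric(counts), nrow = 2L, byrow = TRUE)
  }
  if (!all(dim(counts) == c(2L, 2L))) {
    stop("counts must form a 2x2 table", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("table must have a positive entry",
                             call. = FALSE)
  structure(matrix(as.integer(round(counts)), 2L, 2L,
                   dimnames = list(group = c("group1", "group2"),
                                   outcome = c("regen", "no_regen"))),
            class = c("contingency_table", "matrix"))
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param table a [contingency_table()] (or anything it accepts).
#' @param correction `"none"` (plain Pearson, the default) or `"yates"`
#'   (continuity correction).
#' @return a list with `statistic`, `df` (always 1), and `p_value`.
#' @export
chi_square_test <- function(table, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  if (!inherits(table, "contingency_table")) table <- contingency_table(table)
  m <- unclass(table)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) {
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  }
  res <- suppressWarnings(
    stats::chisq.test(m, correct = correction == "yates")
  )
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value),
                 correction = correction),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, p = %.4g (%s correction)\n",
              x$statistic, x$df, x$p_value,
              if (x$correction == "none") "no" else "Yates"))
  invisible(x)
}

#' @export
print.binary_seq <- function(x, ...) {
  cat("binary_seq: ", length(x$values), " values (", sum(x$values),
      " ones), ", nrow(x$blocks), " block(s), mode = ", x$mode, "\n",
      sep = "")
  invisible(x)
}
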