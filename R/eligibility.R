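#' Eligibility configuration for ray-level analyses
#'
#' Encodes the exclusion rules that define which rays enter an analysis.
#' The defaults reproduce the scoring protocol for spontaneous regeneration
#' of non-injured rays: escapers are excluded, and so is any ray directly
#' adjacent (ray_index +/- 1, same fin) to an escaper, a re-amputated ray,
#' or an epidermally wounded ray. Rays whose epidermis or bone was
#' inadvertently damaged during handling are dropped from the bystander
#' quantification.
#'
#' `exclude_adjacent_regenerators` covers an alternative reading of the
#' bystander exclusions in which rays that grew next to another regenerating
#' ray are themselves removed (leaving only isolated regenerators); it is
#' off by default because the bystander fraction is undefined once
#' bystanders are removed.
#'
#' @param exclude_escapers drop escaper rays themselves.
#' @param exclude_adjacent_to categories whose immediate neighbors are
#'   excluded; any subset of `"escaper"`, `"re_amputation"`,
#'   `"epidermal_wound"`, `"skin_wound"`.
#' @param exclude_inadvertent_injury drop rays with
#'   `inadvertent_injury == TRUE` from the bystander analysis.
#' @param exclude_adjacent_regenerators drop rays adjacent to a regenerating
#'   ray from the bystander analysis (alternative reading; default off).
#' @return an object of class `eligibility_config`.
#' @export
eligibility_config <- function(exclude_escapers = TRUE,
                               exclude_adjacent_to = c("escaper",
                                                       "re_amputation",
                                                       "epidermal_wound"),
                               exclude_inadvertent_injury = TRUE,
                               exclude_adjacent_regenerators = FALSE) {
  valid <- c("escaper", INJURY_LEVELS[INJURY_LEVELS != "none"])
  exclude_adjacent_to <- as.character(exclude_adjacent_to)
  bad <- setdiff(exclude_adjacent_to, valid)
  if (length(bad) > 0L) {
    stop("unknown exclusion categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(exclude_escapers = isTRUE(exclude_escapers),
                 exclude_adjacent_to = unique(exclude_adjacent_to),
                 exclude_inadvertent_injury =
                   isTRUE(exclude_inadvertent_injury),
                 exclude_adjacent_regenerators =
                   isTRUE(exclude_adjacent_regenerators)),
            class = "eligibility_config")
}

#' @export
print.eligibility_config <- function(x, ...) {
  cat("eligibility_config\n")
  cat("  exclude escapers:        ", x$exclude_escapers, "\n")
  cat("  exclude neighbors of:    ",
      if (length(x$exclude_adjacent_to)) {
        paste(x$exclude_adjacent_to, collapse = ", ")
      } else "(none)", "\n")
  cat("  exclude inadvertent inj.:", x$exclude_inadvertent_injury, "\n")
  cat("  exclude adj. regenerators:", x$exclude_adjacent_regenerators, "\n")
  invisible(x)
}

#' Read or write an eligibility configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_eligibility_config`, an `eligibility_config`; for
#'   `write_eligibility_config`, `path` invisibly.
#' @export
read_eligibility_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- eligibility_config()
  known <- names(defaults)
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    stop("unknown eligibility fields in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  args <- utils::modifyList(unclass(defaults), raw)
  do.call(eligibility_config, args)
}

#' @rdname read_eligibility_config
#' @param config an `eligibility_config`.
#' @export
write_eligibility_config <- function(config, path) {
  stopifnot(inherits(config, "eligibility_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Recompute escaper flags from a growth-at-relief field
#'
#' An escaper is an uninjured ray that shows regenerative growth at the end
#' of the blockade period (before any re-injury), i.e. a ray in which the
#' regeneration block failed. This sets `escaper = TRUE` exactly for rays
#' with `injury == "none"` whose named boolean field is true; injured rays
#' are never flagged.
#'
#' @param dataset a `ray_dataset`.
#' @param regen_field_at_relief name of a boolean column scoring growth at
#'   the time the blockade was relieved.
#' @return a copy of the dataset with recomputed `escaper`.
#' @export
flag_escapers <- function(dataset, regen_field_at_relief) {
  stopifnot(inherits(dataset, "ray_dataset"))
  if (!regen_field_at_relief %in% names(dataset)) {
    stop("unknown field: ", regen_field_at_relief, call. = FALSE)
  }
  grew <- .parse_flag(dataset[[regen_field_at_relief]],
                      regen_field_at_relief)
  dataset$escaper <- grew & dataset$injury == "none"
  dataset
}

## Category used for adjacency exclusions: "escaper" for escaper rays,
## otherwise the injury class ("none" for plain rays). Escapers have
## injury == "none" by invariant, so the two never collide.
.exclusion_category <- function(dataset) {
  ifelse(dataset$escaper, "escaper", dataset$injury)
}

## For each row, TRUE iff an immediate neighbor (ray_index +/- 1, same fin)
## has `flag` TRUE. Fin boundary rays have a single neighbor; no wraparound.
## Adjacency is decided on ray_index differences, so the computation is
## also correct on filtered subsets whose ray_index values have gaps.
.neighbor_any <- function(dataset, flag) {
  out <- logical(nrow(dataset))
  for (rows in split(seq_len(nrow(dataset)),
                     factor(.fin_key(dataset),
                            levels = unique(.fin_key(dataset))))) {
    f <- flag[rows]
    k <- length(f)
    adj <- diff(dataset$ray_index[rows]) == 1L
    out[rows] <- c(f[-1L] & adj, FALSE) | c(FALSE, f[-k] & adj)
  }
  out
}

## Light validation for analysis entry points: subsets produced by the
## filters legitimately have ray_index gaps, so only uniqueness and the
## escaper invariant are enforced here; full contiguity is checked at the
## I/O boundary by validate_ray_dataset().
.check_rays <- function(dataset) {
  stopifnot(inherits(dataset, "ray_dataset"))
  if (anyDuplicated(paste(.fin_key(dataset), dataset$ray_index))) {
    stop("duplicate (fish_id, fin_id, ray_index)", call. = FALSE)
  }
  bad <- which(dataset$escaper & dataset$injury != "none")
  if (length(bad) > 0L) {
    stop("escaper with injury != none at row ", bad[1L], call. = FALSE)
  }
  invisible(dataset)
}

#' Rays eligible for the analysis of non-injured regeneration
#'
#' Selects rays with `injury == "none"` that are not escapers (when
#' configured) and have no immediate neighbor in an excluded category.
#' This separates spontaneous/bystander growth of non-injured rays from
#' growth trivially explained by an adjacent injury or escaper.
#'
#' @param dataset a validated `ray_dataset`.
#' @param config an [eligibility_config()].
#' @return the eligible subset, a `ray_dataset` (possibly empty).
#' @export
eligible_noninjured <- function(dataset, config = eligibility_config()) {
  stopifnot(inherits(config, "eligibility_config"))
  .check_rays(dataset)
  dataset[.noninjured_mask(dataset, config), , drop = FALSE]
}

## Adjacency is always evaluated on the full, contiguous dataset; masks are
## combined before any subsetting so exclusions never create false
## adjacencies between surviving rays.
.noninjured_mask <- function(dataset, config) {
  keep <- dataset$injury == "none"
  if (config$exclude_escapers) keep <- keep & !dataset$escaper
  if (length(config$exclude_adjacent_to) > 0L) {
    in_cat <- .exclusion_category(dataset) %in% config$exclude_adjacent_to
    keep <- keep & !.neighbor_any(dataset, in_cat)
  }
  keep
}

#' Rays eligible for the bystander quantification
#'
#' Applies the non-injured eligibility rules of [eligible_noninjured()],
#' then drops rays whose epidermis or bone was inadvertently injured (when
#' configured), and optionally rays adjacent to a regenerating ray (the
#' alternative reading; see [eligibility_config()]).
#'
#' @inheritParams eligible_noninjured
#' @param outcome_field regeneration call used when
#'   `exclude_adjacent_regenerators` is set.
#' @return the eligible subset, a `ray_dataset`.
#' @export
eligible_bystander_analysis <- function(dataset,
                                        config = eligibility_config(),
                                        outcome_field = "regen_7dpi") {
  stopifnot(inherits(config, "eligibility_config"))
  .check_rays(dataset)
  keep <- .noninjured_mask(dataset, config)
  if (config$exclude_inadvertent_injury) {
    keep <- keep & !dataset$inadvertent_injury
  }
  if (config$exclude_adjacent_regenerators) {
    if (!outcome_field %in% names(dataset)) {
      stop("unknown field: ", outcome_field, call. = FALSE)
    }
    regen <- .parse_flag(dataset[[outcome_field]], outcome_field)
    keep <- keep & !.neighbor_any(dataset, regen)
  }
  dataset[keep, , drop = FALSE]
}
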