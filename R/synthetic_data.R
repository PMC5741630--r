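#' Parameters of the synthetic contagion model
#'
#' The generator emulates a re-injury experiment on regeneration-blocked
#' ("dormant") fins: each fish contributes one fin of `rays_per_fin` ordered
#' rays; a small number of rays per fish receive a deliberate injury; rays
#' regenerate spontaneously at a low rate or in response to injury at a high
#' rate; regeneration then spreads to immediate neighbors ("bystander"
#' conversion) in a fixed number of synchronous passes; finally, some
#' uninjured rays are marked as escapers (rays in which the blockade
#' failed). Defaults are calibrated so that, under the standard eligibility
#' rules, the marginal regeneration frequency of analyzable non-injured rays
#' is near 0.258 and most of those regenerators are bystanders.
#'
#' @param n_fish number of fish (one fin each).
#' @param rays_per_fin rays per fin (default 18, the scale of a caudal fin's
#'   principal rays).
#' @param p_spont probability a non-injured ray regenerates spontaneously.
#' @param p_injured_regen probability an injured ray regenerates.
#' @param p_bystander per-pass probability that a non-regenerating ray with
#'   at least one regenerating neighbor converts.
#' @param spread_rounds number of synchronous contagion passes (>= 0).
#' @param p_escaper probability an uninjured, non-regenerating ray is an
#'   escaper.
#' @param injuries_per_fish 0, 1 or 2 deliberate injuries per fish, placed
#'   uniformly at random and non-adjacent to each other when possible.
#' @param injury_type injury class assigned to injured rays.
#' @param p_early probability a regenerating ray already shows a blastema at
#'   the early (3 d.p.i.) timepoint.
#' @param seed integer seed; the draw is bit-reproducible.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_fish = 61L, rays_per_fin = 18L,
                       p_spont = 0.006, p_injured_regen = 0.74,
                       p_bystander = 0.9, spread_rounds = 4L,
                       p_escaper = 0.03, injuries_per_fish = 1L,
                       injury_type = "epidermal_wound",
                       p_early = 0.7, seed = 1L) {
  p <- list(n_fish = as.integer(n_fish),
            rays_per_fin = as.integer(rays_per_fin),
            p_spont = as.numeric(p_spont),
            p_injured_regen = as.numeric(p_injured_regen),
            p_bystander = as.numeric(p_bystander),
            spread_rounds = as.integer(spread_rounds),
            p_escaper = as.numeric(p_escaper),
            injuries_per_fish = as.integer(injuries_per_fish),
            injury_type = as.character(injury_type),
            p_early = as.numeric(p_early),
            seed = as.integer(seed))
  probs <- c("p_spont", "p_injured_regen", "p_bystander", "p_escaper",
             "p_early")
  for (nm in probs) {
    if (is.na(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1) {
      stop(nm, " must be a probability in [0, 1]", call. = FALSE)
    }
  }
  if (p$n_fish < 0L) stop("n_fish must be >= 0", call. = FALSE)
  if (p$rays_per_fin < 1L) stop("rays_per_fin must be >= 1", call. = FALSE)
  if (p$spread_rounds < 0L) stop("spread_rounds must be >= 0",
                                 call. = FALSE)
  if (!p$injuries_per_fish %in% 0:2) {
    stop("injuries_per_fish must be 0, 1 or 2", call. = FALSE)
  }
  if (p$injuries_per_fish > p$rays_per_fin) {
    stop("injuries_per_fish cannot exceed rays_per_fin", call. = FALSE)
  }
  if (!p$injury_type %in% INJURY_LEVELS[INJURY_LEVELS != "none"]) {
    stop("injury_type must be one of: ",
         paste(INJURY_LEVELS[INJURY_LEVELS != "none"], collapse = ", "),
         call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' Read simulation parameters from a YAML file
#'
#' @param path YAML file whose keys mirror the [sim_params()] arguments.
#' @return a `sim_params` object.
#' @export
read_sim_params <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(sim_params)))
  if (length(bad) > 0L) {
    stop("unknown sim_params fields in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(sim_params, raw)
}

## Pick `k` injury positions in 1..n, uniformly, pairwise non-adjacent when
## possible (mirrors one-or-two isolated re-injuries per fish).
.place_injuries <- function(n, k) {
  chosen <- integer(0)
  for (j in seq_len(k)) {
    pool <- setdiff(seq_len(n), c(chosen, chosen - 1L, chosen + 1L))
    if (length(pool) == 0L) pool <- setdiff(seq_len(n), chosen)
    if (length(pool) == 0L) break
    chosen <- c(chosen, pool[sample.int(length(pool), 1L)])
  }
  sort(chosen)
}

#' Simulate a ray-score dataset with ground-truth labels
#'
#' Runs the contagion model of [sim_params()] and returns both the scored
#' dataset and a per-ray truth table labelling every ray as
#' `injury_induced`, `spontaneous`, `bystander_converted`, `escaper`, or
#' `silent`. The truth table also carries the generator's own bookkeeping of
#' which rays are analyzable non-injured rays under the standard exclusion
#' rules (`eligible_noninjured` column), computed independently of the
#' filtering module.
#'
#' The dataset carries an extra `growth_at_relief` column (1 for escapers),
#' so [flag_escapers()] can be exercised against the generator's flags.
#'
#' @param params a [sim_params()] object.
#' @return a list with elements `dataset` (a `ray_dataset`) and `truth`
#'   (a data frame keyed by fish_id, fin_id, ray_index).
#' @export
simulate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(params$seed)

  K <- params$rays_per_fin
  fins <- vector("list", params$n_fish)
  truths <- vector("list", params$n_fish)
  for (f in seq_len(max(params$n_fish, 0L))) {
    injury <- rep("none", K)
    inj_pos <- .place_injuries(K, params$injuries_per_fish)
    injury[inj_pos] <- params$injury_type
    injured <- injury != "none"

    ## initial regenerators
    regen <- logical(K)
    regen[injured] <- stats::runif(sum(injured)) < params$p_injured_regen
    regen[!injured] <- stats::runif(sum(!injured)) < params$p_spont
    label <- rep("silent", K)
    label[injured & regen] <- "injury_induced"
    label[!injured & regen] <- "spontaneous"

    ## synchronous nearest-neighbor contagion
    for (round in seq_len(params$spread_rounds)) {
      has_nb <- c(regen[-1L], FALSE) | c(FALSE, regen[-K])
      cand <- which(!regen & has_nb)
      if (length(cand) == 0L) next
      converted <- cand[stats::runif(length(cand)) < params$p_bystander]
      regen[converted] <- TRUE
      label[converted] <- "bystander_converted"
    }

    ## escapers among uninjured, non-regenerating rays (scored before
    ## re-injury; they do not seed contagion in this model)
    escaper <- logical(K)
    pool <- which(!injured & !regen)
    escaper[pool] <- stats::runif(length(pool)) < params$p_escaper
    label[escaper] <- "escaper"

    regen_3 <- regen & (stats::runif(K) < params$p_early)

    ## generator's own eligibility bookkeeping (standard protocol rules):
    ## non-injured, non-escaper, no neighbor that is an escaper or carries
    ## a re-amputation/epidermal wound
    excl_cat <- escaper |
      injury %in% c("re_amputation", "epidermal_wound")
    nb_excl <- c(excl_cat[-1L], FALSE) | c(FALSE, excl_cat[-K])
    eligible <- !injured & !escaper & !nb_excl

    fish_id <- sprintf("fish%03d", f)
    fins[[f]] <- data.frame(fish_id = fish_id, fin_id = "caudal",
                            ray_index = seq_len(K), injury = injury,
                            escaper = escaper,
                            inadvertent_injury = FALSE,
                            regen_3dpi = regen_3, regen_7dpi = regen,
                            growth_at_relief = as.character(as.integer(escaper)),
                            stringsAsFactors = FALSE)
    truths[[f]] <- data.frame(fish_id = fish_id, fin_id = "caudal",
                              ray_index = seq_len(K), label = label,
                              eligible_noninjured = eligible,
                              stringsAsFactors = FALSE)
  }
  df <- if (params$n_fish > 0L) do.call(rbind, fins) else
    data.frame(fish_id = character(0), fin_id = character(0),
               ray_index = integer(0), injury = character(0),
               escaper = logical(0), inadvertent_injury = logical(0),
               regen_3dpi = logical(0), regen_7dpi = logical(0),
               growth_at_relief = character(0), stringsAsFactors = FALSE)
  truth <- if (params$n_fish > 0L) do.call(rbind, truths) else
    data.frame(fish_id = character(0), fin_id = character(0),
               ray_index = integer(0), label = character(0),
               eligible_noninjured = logical(0), stringsAsFactors = FALSE)
  dataset <- ray_dataset(df, label = "synthetic contagion model")
  validate_ray_dataset(dataset)
  list(dataset = dataset, truth = truth)
}

#' Write a simulation truth table as a sidecar TSV
#'
#' @param truth the `truth` element of [simulate_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(is.data.frame(truth))
  out <- truth
  out$eligible_noninjured <- as.integer(out$eligible_noninjured)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Rejection rate of the bystander test over a parameter grid
#'
#' For each parameter point, simulates `replicates` datasets, runs
#' [run_bystander_test()] on each, and reports the fraction of replicates
#' with `p <= alpha`. Datasets with no regenerating eligible ray (possible
#' at very low rates) count as non-rejections and are tallied in
#' `n_undefined`.
#'
#' @param params_grid list of [sim_params()] objects.
#' @param replicates simulated datasets per point.
#' @param alpha rejection threshold.
#' @param iterations Monte Carlo iterations per test.
#' @param config eligibility rules for the test.
#' @param outcome_field outcome column.
#' @param mode null-construction mode passed to [run_bystander_test()].
#' @param seed master seed from which per-replicate seeds are derived.
#' @return data frame with one row per parameter point: the main generative
#'   parameters, `rejections`, `n_undefined`, and `rejection_rate`.
#' @export
sweep_power <- function(params_grid, replicates = 200L, alpha = 0.05,
                        iterations = 999L, config = eligibility_config(),
                        outcome_field = "regen_7dpi",
                        mode = c("pooled", "stratified"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.list(params_grid), length(params_grid) >= 1L,
            replicates >= 1L)
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max,
                             length(params_grid) * replicates * 2L),
                  ncol = 2L)
  rows <- vector("list", length(params_grid))
  idx <- 0L
  for (g in seq_along(params_grid)) {
    pp <- params_grid[[g]]
    stopifnot(inherits(pp, "sim_params"))
    rej <- 0L
    undef <- 0L
    for (rep in seq_len(replicates)) {
      idx <- idx + 1L
      pp_rep <- pp
      pp_rep$seed <- seeds[idx, 1L]
      sim <- simulate_dataset(pp_rep)
      res <- tryCatch(
        run_bystander_test(sim$dataset, config, outcome_field,
                           iterations = iterations,
                           seed = seeds[idx, 2L], mode = mode),
        rayregen_undefined = function(e) NULL)
      if (is.null(res)) undef <- undef + 1L
      else if (res$p_value <= alpha) rej <- rej + 1L
    }
    rows[[g]] <- data.frame(point = g, n_fish = pp$n_fish,
                            rays_per_fin = pp$rays_per_fin,
                            p_spont = pp$p_spont,
                            p_bystander = pp$p_bystander,
                            spread_rounds = pp$spread_rounds,
                            injuries_per_fish = pp$injuries_per_fish,
                            replicates = as.integer(replicates),
                            rejections = rej, n_undefined = undef,
                            rejection_rate = rej / replicates)
  }
  do.call(rbind, rows)
}
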