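# Adaptive sampling: grow the reference dataset on the fly. Ensemble MD runs
# until the committee disagreement of a visited structure exceeds a
# threshold; that structure (and no later one) is labeled by the reference
# calculator, the ensemble is retrained (warm start by default), and
# dynamics restart from the problematic conformation. The loop ends when a
# full MD run stays below threshold or the reference-call budget is spent.
# "Upscaling" relabels the accumulated geometries with a higher-level
# reference, followed by refinement rounds at that level.

#' Adaptive-sampling settings
#'
#' @param uncertainty_threshold Committee-disagreement threshold (kcal/mol,
#'   or kcal/mol/atom with \code{per_atom}).
#' @param per_atom Use the per-atom-normalized uncertainty.
#' @param temperature Sampling temperature in K (default 500).
#' @param timestep Timestep in fs (default 0.5).
#' @param run_steps Length of one sampling MD run; a run that never exceeds
#'   the threshold ends the loop.
#' @param max_reference_calls Budget of reference-calculator invocations.
#' @param train_config A \code{\link{training_config}} used for (re)training
#'   the members.
#' @param warm_start Continue each member's Kalman state across retrains
#'   (default TRUE); FALSE retrains from scratch.
#' @param dedup_tol Geometry deduplication tolerance (Angstrom, on sorted
#'   interatomic distances); duplicates are not added.
#' @param seed Integer seed.
#' @return An object of class \code{sampling_config}.
#' @export
sampling_config <- function(uncertainty_threshold, per_atom = FALSE,
                            temperature = 500, timestep = 0.5,
                            run_steps = 500L, max_reference_calls = 50L,
                            train_config = training_config(),
                            warm_start = TRUE, dedup_tol = 1e-3,
                            seed = 1L) {
  if (uncertainty_threshold <= 0) stop("threshold must be positive")
  if (timestep <= 0) stop("timestep must be positive")
  structure(list(uncertainty_threshold = uncertainty_threshold,
                 per_atom = per_atom, temperature = temperature,
                 timestep = timestep, run_steps = as.integer(run_steps),
                 max_reference_calls = as.integer(max_reference_calls),
                 train_config = train_config, warm_start = warm_start,
                 dedup_tol = dedup_tol, seed = as.integer(seed)),
            class = "sampling_config")
}

.geom_signature <- function(config) {
  sort(as.vector(stats::dist(config$positions)))
}

.is_duplicate <- function(config, dataset, tol) {
  sig <- .geom_signature(config)
  for (d in dataset) {
    if (length(d$elements) != length(config$elements)) next
    s2 <- .geom_signature(d)
    if (length(s2) == length(sig) && max(abs(s2 - sig)) < tol) return(TRUE)
  }
  FALSE
}

# Retrain all ensemble members; returns list(ensemble, states).
.retrain_ensemble <- function(ens, dataset, cfg, states) {
  members <- ens$members
  for (j in seq_along(members)) {
    tc <- cfg$train_config
    tc$seed <- tc$seed + j
    fit <- train_hdnnp(members[[j]], dataset, tc,
                       kalman = if (cfg$warm_start) states[[j]],
                       refit_scaling = !cfg$warm_start || is.null(states[[j]]))
    members[[j]] <- fit$model
    states[[j]] <- fit$kalman
  }
  list(ensemble = hdnnp_ensemble(members), states = states)
}

#' Adaptive sampling loop
#'
#' @param ensemble An \code{hdnnp_ensemble} (untrained members are fine; they
#'   are trained on the seed dataset first).
#' @param reference Reference calculator labeling selected configurations.
#' @param seed_dataset Non-empty list of labeled \code{atomic_config}s.
#' @param cfg A \code{\link{sampling_config}}.
#' @param start_config Starting geometry (default: first seed record).
#' @return List with \code{dataset} (expanded), \code{ensemble} (retrained),
#'   \code{log} (data frame: iteration, md steps survived, uncertainty at
#'   stop, action, reference energy, dataset size) and
#'   \code{termination} ("converged" or "budget").
#' @export
adaptive_sample <- function(ensemble, reference, seed_dataset, cfg,
                            start_config = NULL) {
  if (!length(seed_dataset)) stop("seed dataset must be non-empty")
  dataset <- seed_dataset
  states <- vector("list", ensemble$J)
  rt <- .retrain_ensemble(ensemble, dataset, cfg, states)
  ensemble <- rt$ensemble; states <- rt$states
  if (is.null(start_config)) {
    start_config <- seed_dataset[[1]]
  }
  current <- atomic_config(start_config$elements, start_config$positions)
  thr <- cfg$uncertainty_threshold
  norm <- if (cfg$per_atom) n_atoms(current) else 1
  log_rows <- NULL
  n_ref <- 0L
  iteration <- 0L
  termination <- "budget"
  velocities <- NULL
  repeat {
    iteration <- iteration + 1L
    mdcfg <- md_config(timestep = cfg$timestep,
                       temperature = cfg$temperature,
                       thermostat = "langevin", friction = 0.02,
                       n_steps = cfg$run_steps, stride = cfg$run_steps,
                       seed = cfg$seed + iteration)
    traj <- run_md(ensemble, current, mdcfg, velocities = velocities,
                   stop_fn = function(config, info)
                     info$uncertainty / norm > thr)
    if (is.null(traj$stopped)) {
      termination <- "converged"
      log_rows <- rbind(log_rows, data.frame(
        iteration = iteration, steps = cfg$run_steps,
        uncertainty = NA_real_, action = "full-run-below-threshold",
        reference_energy = NA_real_, dataset_size = length(dataset)))
      break
    }
    bad <- traj$stopped$config
    u <- traj$stopped$info$uncertainty / norm
    labeled <- tryCatch(label_config(reference, bad), error = function(e) e)
    if (inherits(labeled, "error")) {
      # failed attempts still consume the reference budget, so a broken
      # reference cannot spin the loop forever
      n_ref <- n_ref + 1L
      log_rows <- rbind(log_rows, data.frame(
        iteration = iteration, steps = traj$stopped$step,
        uncertainty = u, action = "reference-failed-quarantined",
        reference_energy = NA_real_, dataset_size = length(dataset)))
      current <- atomic_config(start_config$elements, start_config$positions)
      velocities <- NULL
      if (n_ref >= cfg$max_reference_calls) break
      next
    }
    if (.is_duplicate(labeled, dataset, cfg$dedup_tol)) {
      action <- "duplicate-skipped"
    } else {
      dataset <- c(dataset, list(labeled))
      action <- "added"
    }
    n_ref <- n_ref + 1L
    log_rows <- rbind(log_rows, data.frame(
      iteration = iteration, steps = traj$stopped$step, uncertainty = u,
      action = action, reference_energy = labeled$energy,
      dataset_size = length(dataset)))
    if (action == "added") {
      rt <- .retrain_ensemble(ensemble, dataset, cfg, states)
      ensemble <- rt$ensemble; states <- rt$states
    }
    # restart dynamics from the problematic conformation
    current <- atomic_config(bad$elements, bad$positions)
    velocities <- traj$final$velocities
    if (n_ref >= cfg$max_reference_calls) {
      termination <- "budget"
      break
    }
  }
  list(dataset = dataset, ensemble = ensemble, log = log_rows,
       termination = termination, kalman_states = states)
}

#' Relabel a dataset with a higher-level reference ("upscaling")
#'
#' Geometries are untouched; labels are replaced by the high-level
#' calculator, independently per configuration. Per-configuration failures
#' are collected, not fatal. Label provenance of both levels is retained in
#' the \code{provenance} attribute of each record.
#'
#' @param dataset List of labeled \code{atomic_config}s.
#' @param high_level_reference The relabeling calculator.
#' @param level_name Name recorded in the provenance (default "high").
#' @return The relabeled dataset; attribute \code{failures} lists indices
#'   that could not be recomputed (their old labels are kept).
#' @export
upscale <- function(dataset, high_level_reference, level_name = "high") {
  failures <- integer(0)
  out <- lapply(seq_along(dataset), function(i) {
    d <- dataset[[i]]
    prev <- attr(d, "provenance")
    new <- tryCatch(
      label_config(high_level_reference,
                   atomic_config(d$elements, d$positions)),
      error = function(e) NULL)
    if (is.null(new)) {
      failures <<- c(failures, i)
      return(d)
    }
    attr(new, "provenance") <- c(prev, list(list(
      level = level_name, previous_energy = d$energy)))
    new
  })
  attr(out, "failures") <- failures
  out
}
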