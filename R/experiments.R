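## Scenario grids: enumerate the full experimental design (K direction x
## lambda direction x local adaptation x origin, optionally x landscape
## shape), run replicated simulations with stable per-replicate seeds, and
## aggregate peak-band votes, gradient strengths, provenance and occupancy.

## stable 31-bit string hash (polynomial, base 31) for seed derivation
.stable_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Derive a replicate seed
#'
#' Deterministic seed for one replicate of one scenario, depending only on
#' `(base_seed, scenario_id, replicate, attempt)` so that results are
#' independent of execution order.  `attempt` increments when a replicate
#' is redrawn after early clade extinction.
#'
#' @param base_seed integer base seed of the whole experiment.
#' @param scenario_id stable scenario identifier string.
#' @param replicate replicate number (1-based).
#' @param attempt attempt number (1-based).
#' @return integer seed in \[0, 2^31).
#' @export
replicate_seed <- function(base_seed, scenario_id, replicate, attempt = 1L) {
  as.integer((.stable_hash(scenario_id) + 7919 * as.numeric(base_seed) +
                104729 * as.numeric(replicate) + 130363 * as.numeric(attempt))
             %% 2147483647)
}

#' Enumerate the scenario grid
#'
#' Builds the full factorial design of evolutionary scenarios: three K
#' directions x three lambda directions x local adaptation on/off x
#' lowland/highland origin — 36 scenarios per landscape shape, each with a
#' stable identifier.
#'
#' @param K_directions,lambda_directions directions to cross (defaults:
#'   all three).
#' @param local_adaptation logical values to cross.
#' @param origins origin bands to cross.
#' @param landscape_shapes `"cone"`, `"plateau"` or both.
#' @param lambda_fold fold of the lambda profile (9, or 2 for the
#'   small-contrast robustness variant).
#' @param ... further arguments passed to [scenario_config()] (e.g.
#'   `total_cells`, `base_lambda`, `max_events`).
#' @return a `scenario_grid`: data frame with one row per scenario
#'   (`scenario_id` plus the varied factors) carrying the full
#'   [scenario_config()] objects in the `config` list-column.
#' @examples
#' nrow(enumerate_scenarios())                                  # 36
#' nrow(enumerate_scenarios(landscape_shapes = c("cone", "plateau")))  # 72
#' @export
enumerate_scenarios <- function(K_directions = c("uniform", "increase",
                                                 "decrease"),
                                lambda_directions = c("uniform", "increase",
                                                      "decrease"),
                                local_adaptation = c(FALSE, TRUE),
                                origins = c("lowland", "highland"),
                                landscape_shapes = "cone",
                                lambda_fold = 9, ...) {
  des <- expand.grid(K_direction = K_directions,
                     lambda_direction = lambda_directions,
                     local_adaptation = local_adaptation,
                     origin = origins,
                     landscape_shape = landscape_shapes,
                     stringsAsFactors = FALSE)
  ## canonical order independent of the factor order supplied
  des <- des[order(des$landscape_shape, des$K_direction, des$lambda_direction,
                   des$local_adaptation, des$origin), , drop = FALSE]
  rownames(des) <- NULL
  des$scenario_id <- sprintf("%s_K-%s_L-%s_LA-%s_orig-%s_fold%g",
                             des$landscape_shape,
                             substr(des$K_direction, 1, 3),
                             substr(des$lambda_direction, 1, 3),
                             ifelse(des$local_adaptation, "on", "off"),
                             substr(des$origin, 1, 4), lambda_fold)
  des$config <- lapply(seq_len(nrow(des)), function(i) {
    scenario_config(K_direction = des$K_direction[i],
                    lambda_direction = des$lambda_direction[i],
                    local_adaptation = des$local_adaptation[i],
                    origin = des$origin[i],
                    landscape_shape = des$landscape_shape[i],
                    lambda_fold = lambda_fold, ...)
  })
  class(des) <- c("scenario_grid", "data.frame")
  des
}

#' Run one replicate of a scenario, redrawing extinct clades
#'
#' Runs [run_simulation()] with the derived replicate seed; if the clade
#' dies out before equilibrium the replicate is redrawn with a fresh
#' derived seed (up to `max_attempts` times), so reported patterns are
#' conditioned on clade survival as is usual for radiations.
#'
#' @param config a [scenario_config()].
#' @param scenario_id,replicate,base_seed seed-derivation inputs.
#' @param landscape optional pre-built landscape.
#' @param max_attempts redraw budget before giving up on a surviving run.
#' @param ... passed to [run_simulation()].
#' @return the [run_simulation()] result of the first surviving attempt
#'   (or the last extinct one if all attempts die), with `replicate`,
#'   `attempts` and `seed` fields added.
#' @export
run_replicate <- function(config, scenario_id, replicate, base_seed = 1L,
                          landscape = NULL, max_attempts = 20L, ...) {
  res <- NULL
  for (attempt in seq_len(max_attempts)) {
    config$seed <- replicate_seed(base_seed, scenario_id, replicate, attempt)
    res <- run_simulation(config, landscape = landscape, ...)
    if (!res$extinct) break
  }
  res$replicate <- replicate
  res$attempts <- attempt
  res$seed <- config$seed
  res
}

#' Run a scenario grid with replication
#'
#' Runs every scenario of a grid for `replicates` surviving replicates and
#' aggregates the outcomes: which band holds the richness peak (vote
#' fractions), the mean gradient strength with its standard error, and the
#' per-band dispersal-provenance and proportional-occupancy means.
#' Replicate seeds derive only from `(base_seed, scenario_id, replicate,
#' attempt)`, so outputs are invariant to execution order.
#'
#' @param grid a [enumerate_scenarios()] grid (or subset of its rows).
#' @param replicates surviving replicates per scenario.
#' @param base_seed integer base seed.
#' @param measure_at `"equilibrium"` (state at the stopping point, which is
#'   where the detector fired) — kept for interface clarity.
#' @param out_dir optional directory; when given, writes
#'   `replicates.csv`, `scenarios.csv`, tidy `metrics.csv` and a JSON
#'   `manifest.json` of configurations and seeds.
#' @param ... passed to [run_replicate()] / [run_simulation()].
#' @return list of class `grid_result` with `replicates` (one row per
#'   replicate) and `scenarios` (aggregates, one row per scenario).
#' @export
run_grid <- function(grid, replicates = 50, base_seed = 1L,
                     measure_at = "equilibrium", out_dir = NULL, ...) {
  stopifnot(inherits(grid, "data.frame"), nrow(grid) >= 1)
  land_cache <- new.env(parent = emptyenv())
  rep_rows <- list()
  for (i in seq_len(nrow(grid))) {
    cfg <- grid$config[[i]]
    sid <- grid$scenario_id[i]
    lkey <- paste(cfg$landscape_shape, cfg$total_cells, cfg$K_direction,
                  cfg$lambda_direction, cfg$K_fold, cfg$lambda_fold,
                  sep = "|")
    if (is.null(land_cache[[lkey]]))
      land_cache[[lkey]] <- scenario_landscape(cfg)
    land <- land_cache[[lkey]]
    for (r in seq_len(replicates)) {
      row <- tryCatch({
        res <- run_replicate(cfg, sid, r, base_seed, landscape = land, ...)
        st <- res$state
        if (res$extinct) {
          data.frame(scenario_id = sid, replicate = r, seed = res$seed,
                     attempts = res$attempts, status = res$status,
                     time = st$time, extinct = TRUE,
                     regional_richness = 0, peak_band = NA_integer_,
                     strength = NA_real_,
                     t(setNames(rep(NA_real_, 12),
                                c(paste0("richness_band", 0:3),
                                  paste0("provenance_band", 0:3),
                                  paste0("occupancy_band", 0:3)))))
        } else {
          e <- edg_strength(st$band_richness)
          data.frame(scenario_id = sid, replicate = r, seed = res$seed,
                     attempts = res$attempts, status = res$status,
                     time = st$time, extinct = FALSE,
                     regional_richness = st$regional_richness,
                     peak_band = e$peak_band, strength = e$strength,
                     t(setNames(c(st$band_richness,
                                  dispersal_provenance(st),
                                  proportional_occupancy(st)),
                                c(paste0("richness_band", 0:3),
                                  paste0("provenance_band", 0:3),
                                  paste0("occupancy_band", 0:3)))))
        }
      }, error = function(e) {
        warning("replicate ", r, " of ", sid, " failed: ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(row)) rep_rows[[length(rep_rows) + 1L]] <- row
    }
  }
  reps <- do.call(rbind, rep_rows)
  scen <- aggregate_grid(reps)
  out <- structure(list(replicates = reps, scenarios = scen,
                        base_seed = base_seed), class = "grid_result")
  if (!is.null(out_dir)) write_grid_result(out, grid, out_dir)
  out
}

#' Aggregate per-replicate grid rows into per-scenario summaries
#'
#' @param reps the `replicates` data frame of a [run_grid()] result.
#' @return data frame, one row per scenario: replicate counts, peak-band
#'   vote fractions, mean +/- SE gradient strength, per-band provenance and
#'   occupancy means.
#' @export
aggregate_grid <- function(reps) {
  ok <- reps[!reps$extinct, , drop = FALSE]
  ids <- unique(reps$scenario_id)
  do.call(rbind, lapply(ids, function(sid) {
    x <- ok[ok$scenario_id == sid, , drop = FALSE]
    n <- nrow(x)
    votes <- if (n) tabulate(x$peak_band + 1L, nbins = 4L) / n else rep(NA, 4)
    data.frame(scenario_id = sid,
               n_surviving = n,
               n_extinct = sum(reps$scenario_id == sid & reps$extinct),
               t(setNames(votes, paste0("peak_frac_band", 0:3))),
               mean_strength = if (n) mean(x$strength) else NA_real_,
               se_strength = if (n > 1) sd(x$strength) / sqrt(n) else NA_real_,
               t(setNames(colMeans(x[paste0("richness_band", 0:3)],
                                   na.rm = TRUE),
                          paste0("mean_richness_band", 0:3))),
               t(setNames(colMeans(x[paste0("provenance_band", 0:3)],
                                   na.rm = TRUE),
                          paste0("mean_provenance_band", 0:3))),
               t(setNames(colMeans(x[paste0("occupancy_band", 0:3)],
                                   na.rm = TRUE),
                          paste0("mean_occupancy_band", 0:3))))
  }))
}

## tidy (scenario, replicate, time, band, metric, value) long table
.tidy_metrics <- function(reps) {
  out <- list()
  for (metric in c("richness", "provenance", "occupancy")) {
    cols <- paste0(metric, "_band", 0:3)
    for (b in 0:3) {
      out[[length(out) + 1L]] <-
        data.frame(scenario = reps$scenario_id, replicate = reps$replicate,
                   time = reps$time, band = b, metric = metric,
                   value = reps[[cols[b + 1L]]])
    }
  }
  res <- do.call(rbind, out)
  res[order(res$scenario, res$replicate, res$metric, res$band), ]
}

#' Write a grid result to disk
#'
#' Emits `replicates.csv` (one row per replicate), `scenarios.csv`
#' (aggregates), `metrics.csv` (tidy long format: scenario, replicate,
#' time, band, metric, value) and `manifest.json` (configurations, seeds,
#' base seed).
#'
#' @param result a [run_grid()] result.
#' @param grid the grid that produced it.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_grid_result <- function(result, grid, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$replicates, file.path(out_dir, "replicates.csv"),
                   row.names = FALSE)
  utils::write.csv(result$scenarios, file.path(out_dir, "scenarios.csv"),
                   row.names = FALSE)
  utils::write.csv(.tidy_metrics(result$replicates),
                   file.path(out_dir, "metrics.csv"), row.names = FALSE)
  manifest <- list(base_seed = result$base_seed,
                   scenarios = lapply(seq_len(nrow(grid)), function(i) {
                     cfg <- grid$config[[i]]
                     cfg$seed <- NULL
                     c(list(scenario_id = grid$scenario_id[i]),
                       cfg[!vapply(cfg, is.null, TRUE)])
                   }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
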