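## Summary statistics of simulated radiations: strength and direction of
## the elevational diversity gradient (EDG), cross-band dispersal
## provenance, proportional range occupancy, temperature mismatch and the
## richness-equilibrium detector.

#' Strength and peak of the elevational diversity gradient
#'
#' The peak band is the band with the highest species richness (ties go to
#' the lowest band index).  The gradient strength is the relative drop in
#' richness from the richest band to the next richest,
#' `(R_max - R_second) / R_max`, a scalar in \[0, 1\] that is 0 when the two
#' richest bands tie.  With `adjacent = TRUE`, `R_second` is instead the
#' richest band spatially adjacent to the peak.
#'
#' @param band_richness per-band species richness, lowland to highland.
#' @param adjacent compare the peak with its spatially adjacent band(s)
#'   instead of the overall second-richest band.
#' @return list with `peak_band` (0 = lowlands) and `strength`.
#' @examples
#' edg_strength(c(100, 80, 60, 40))  # lowland peak, strength 0.2
#' edg_strength(c(10, 20, 40, 80))   # highland peak, strength 0.5
#' @export
edg_strength <- function(band_richness, adjacent = FALSE) {
  stopifnot(is.numeric(band_richness), length(band_richness) >= 2,
            all(band_richness >= 0))
  if (all(band_richness == 0))
    stop("all bands empty: clade extinct, gradient undefined")
  peak <- which.max(band_richness)  # ties -> lowest band index
  r_max <- band_richness[peak]
  second <- if (adjacent) {
    nb <- intersect(c(peak - 1L, peak + 1L), seq_along(band_richness))
    max(band_richness[nb])
  } else {
    max(band_richness[-peak])
  }
  list(peak_band = peak - 1L, strength = (r_max - second) / r_max)
}

## resident species per band: list of species_id vectors, lowland->highland
.residents_by_band <- function(state, n_bands) {
  pops <- state$populations
  lapply(seq_len(n_bands) - 1L,
         function(b) unique(pops$species_id[pops$band == b]))
}

#' Dispersal provenance per band
#'
#' For each elevational band, the proportion of its resident species whose
#' origin band (the band where their founding population arose) differs
#' from it.  High values mean the band's standing diversity is maintained
#' by immigration from other elevations rather than in-situ origination.
#'
#' @param state a snapshot from [sim_state()] (or the `state` element of a
#'   [run_simulation()] result).
#' @return numeric vector of proportions, lowland to highland; `NA` for a
#'   band with no resident species.
#' @export
dispersal_provenance <- function(state) {
  n_bands <- length(state$band_richness)
  sp <- state$species
  origin <- sp$origin_band[match(
    unlist(res <- .residents_by_band(state, n_bands), use.names = FALSE),
    sp$species_id)]
  sizes <- lengths(res)
  band_of <- rep(seq_len(n_bands) - 1L, sizes)
  foreign <- tapply(origin != band_of, factor(band_of, levels = 0:(n_bands - 1L)),
                    mean)
  out <- as.numeric(foreign)
  out[sizes == 0] <- NA_real_
  out
}

#' Per-band provenance counts
#'
#' Companion to [dispersal_provenance()]: the number of resident species of
#' foreign origin per band, alongside richness.
#'
#' @inheritParams dispersal_provenance
#' @return data frame with `band`, `richness`, `n_foreign_origin`.
#' @export
provenance_counts <- function(state) {
  n_bands <- length(state$band_richness)
  res <- .residents_by_band(state, n_bands)
  sp <- state$species
  nf <- vapply(seq_len(n_bands), function(i) {
    ob <- sp$origin_band[match(res[[i]], sp$species_id)]
    sum(ob != (i - 1L))
  }, 0L)
  data.frame(band = seq_len(n_bands) - 1L,
             richness = lengths(res),
             n_foreign_origin = nf)
}

#' Proportional range occupancy per band
#'
#' For every species resident in a band, its range size within the band
#' (number of occupied cells) divided by the band's area (cell count);
#' averaged over the band's resident species.  Species-level values are
#' available with `by_species = TRUE`.
#'
#' @inheritParams dispersal_provenance
#' @param by_species return the species-by-band values instead of band
#'   means.
#' @return numeric vector of band means (lowland to highland, `NA` where a
#'   band is empty), or a data frame (`species_id`, `band`, `occupancy`)
#'   when `by_species = TRUE`.
#' @export
proportional_occupancy <- function(state, by_species = FALSE) {
  n_bands <- length(state$band_richness)
  pops <- state$populations
  area <- state$band_cell_counts
  tab <- as.data.frame(table(species_id = pops$species_id, band = pops$band),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  tab$band <- as.integer(as.character(tab$band))
  tab$species_id <- as.integer(as.character(tab$species_id))
  tab$occupancy <- tab$Freq / area[tab$band + 1L]
  if (by_species)
    return(data.frame(species_id = tab$species_id, band = tab$band,
                      occupancy = tab$occupancy))
  out <- rep(NA_real_, n_bands)
  means <- tapply(tab$occupancy, factor(tab$band, levels = 0:(n_bands - 1L)),
                  mean)
  out[!is.na(means)] <- means[!is.na(means)]
  out
}

#' Per-band summary of a simulation snapshot
#'
#' @inheritParams dispersal_provenance
#' @return data frame with one row per band: `band`, `richness`,
#'   `n_foreign_origin`, `provenance`, `mean_occupancy`, `mean_mismatch`.
#' @export
band_summary <- function(state) {
  pc <- provenance_counts(state)
  pops <- state$populations
  n_bands <- length(state$band_richness)
  mism <- tapply(abs(pops$temperature - pops$temperature_preference),
                 factor(pops$band, levels = 0:(n_bands - 1L)), mean)
  data.frame(band = pc$band,
             richness = pc$richness,
             n_foreign_origin = pc$n_foreign_origin,
             provenance = pc$n_foreign_origin / ifelse(pc$richness > 0,
                                                       pc$richness, NA),
             mean_occupancy = proportional_occupancy(state),
             mean_mismatch = as.numeric(mism))
}

#' Detect equilibrium in regional richness
#'
#' Declares a dynamic equilibrium at the first sampled time `t` such that
#' (i) the least-squares slope of regional richness over `[t - window, t]`
#' amounts to less than `slope_tol` species over one window, and (ii) the
#' mean richness in that window is within 5% of the mean over the
#' following window `[t, t + window]`.  Both settings are exposed; the
#' default window is 10% of the elapsed time.
#'
#' `slope_tol` is expressed in species per window, so rescaling time (and
#' `window` with it) leaves the verdict unchanged; rescaling richness units
#' requires rescaling `slope_tol` accordingly.
#'
#' A window only qualifies if its mean richness has reached `min_level`
#' times the maximum richness observed so far: a stochastic radiation sits
#' near-flat at one or two species before taking off, and without the
#' guard that lag phase would satisfy both window conditions.  Set
#' `min_level = 0` to recover the bare two-condition rule.
#'
#' @param time sample times (increasing).
#' @param richness regional richness at those times.
#' @param window averaging window in time units (`NULL`: 10% of elapsed).
#' @param slope_tol tolerated richness trend, in species per window.
#' @param min_level fraction of the series maximum a window's mean must
#'   reach before it can be declared an equilibrium.
#' @return list with `reached` (logical) and `time` (first detection time,
#'   `NA` if not reached).
#' @examples
#' t <- seq(0, 100, by = 0.5)
#' r <- 100 / (1 + exp(-(t - 30) / 4))   # logistic accumulation curve
#' detect_equilibrium(t, r)
#' @export
detect_equilibrium <- function(time, richness, window = NULL,
                               slope_tol = 0.5, min_level = 0.5) {
  n <- length(time)
  stopifnot(length(richness) == n)
  if (n < 4L) return(list(reached = FALSE, time = NA_real_))
  if (is.null(window)) window <- 0.1 * (time[n] - time[1L])
  if (window <= 0 || time[n] - time[1L] < 2 * window)
    return(list(reached = FALSE, time = NA_real_))
  level_floor <- min_level * max(richness)

  ct <- cumsum(time); ct2 <- cumsum(time^2)
  cr <- cumsum(richness); ctr <- cumsum(time * richness)
  win_sum <- function(cs, i, j) cs[j] - if (i > 1L) cs[i - 1L] else 0

  lo <- findInterval(time - window, time) + 1L  # first index with t >= t_i - w
  hi <- findInterval(time + window, time)       # last index with t <= t_i + w
  for (i in seq_len(n)) {
    j0 <- lo[i]
    if (j0 >= i) next                       # fewer than 2 points behind
    if (time[i] - time[1L] < window) next   # back window incomplete
    j1 <- hi[i]
    if (time[n] - time[i] < window) break   # forward window incomplete
    m <- i - j0 + 1L
    st <- win_sum(ct, j0, i); st2 <- win_sum(ct2, j0, i)
    sr <- win_sum(cr, j0, i); str_ <- win_sum(ctr, j0, i)
    denom <- m * st2 - st^2
    if (denom <= 0) next
    slope <- (m * str_ - st * sr) / denom
    if (abs(slope) * window > slope_tol) next
    back_mean <- sr / m
    if (back_mean < level_floor) next
    fwd_mean <- win_sum(cr, i, j1) / (j1 - i + 1L)
    if (back_mean == 0 && fwd_mean == 0) return(list(reached = TRUE,
                                                     time = time[i]))
    if (back_mean > 0 && abs(fwd_mean - back_mean) <= 0.05 * back_mean)
      return(list(reached = TRUE, time = time[i]))
  }
  list(reached = FALSE, time = NA_real_)
}

#' Temperature-mismatch trajectory
#'
#' Per-band mean absolute mismatch between cell temperature and population
#' temperature preference (`|T_c - T_p|`) over time, in tidy long format.
#' The founding population matches its cell exactly, so every band starts
#' at zero mismatch; in local-adaptation runs the mismatch equilibrates no
#' later than regional richness does.
#'
#' @param x a [run_simulation()] result or a [sim_series()] data frame.
#' @return data frame with `time`, `band`, `mismatch` (NA where a band has
#'   no populations).
#' @export
mismatch_series <- function(x) {
  series <- if (inherits(x, "clade_sim_result")) x$series else x
  cols <- grep("^mismatch_band", names(series), value = TRUE)
  bands <- as.integer(sub("^mismatch_band", "", cols))
  out <- do.call(rbind, lapply(seq_along(cols), function(i) {
    data.frame(time = series$time,
               band = rep(bands[i], nrow(series)),
               mismatch = series[[cols[i]]])
  }))
  out[order(out$time, out$band), , drop = FALSE]
}
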