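## Gridded mountain landscapes with concentric elevational bands.
##
## A landscape is a set of lattice cells grouped into elevational bands
## (band 0 = lowlands ... band 3 = highlands).  Cells are laid out along a
## square spiral from the center of a lattice with von Neumann
## (4-neighbour) adjacency; bands are consecutive segments of the spiral,
## so the innermost patch is the mountaintop, the outermost ring the
## lowlands, and every band is a connected path by construction.  Any
## realization satisfying the band-area, temperature, adjacency and
## connectivity invariants is conformant; the spiral is simply the
## realization used here.

#' Cone-shaped mountain landscape
#'
#' Builds a gridded, cone-shaped mountain with four concentric elevational
#' bands whose areas decrease with elevation: lowlands 58%, then 24%, 13%
#' and highlands 5.8% of the (nominal) total area.  Cell temperature is a
#' band property: `base_temperature` in the lowlands, decreasing 5 degrees
#' per band, so 5 degrees at the top for the default 20 degrees.
#'
#' Band cell counts are `round(fraction * total_cells)`.  The printed area
#' percentages sum to 100.8%, so the realized landscape contains
#' `sum(counts)` cells (1008 for the default 1000); each band is always
#' within one cell of its nominal target.
#'
#' @param total_cells nominal number of grid cells (default 1000); values
#'   below 20 are rejected because the highland band would round to zero.
#' @param base_temperature lowland temperature in degrees Celsius.
#' @param band_K per-band species-level carrying capacity (maximum number of
#'   species a cell can hold), lowland to highland.  See [band_rate_profile()].
#' @param band_lambda per-band per-population diversification rate, lowland
#'   to highland.
#' @return an object of class `elev_landscape`; see Details.
#' @details The returned list has elements `cells` (data frame with
#'   `cell_id`, `x`, `y`, `band`, `temperature`), `adjacency` (list of
#'   neighbour `cell_id` vectors), `n_bands`, `shape_tag`,
#'   `band_cell_counts` (lowland to highland), `band_K`, `band_lambda` and
#'   `base_temperature`.
#' @examples
#' mt <- build_cone_landscape(250)
#' mt$band_cell_counts   # about (145, 60, 33, 15)
#' @seealso [build_plateau_landscape()], [build_banded_landscape()]
#' @export
build_cone_landscape <- function(total_cells = 1000, base_temperature = 20,
                                 band_K = rep(10L, 4),
                                 band_lambda = rep(0.05, 4)) {
  build_banded_landscape(total_cells,
                         fractions = c(0.58, 0.24, 0.13, 0.058),
                         base_temperature = base_temperature,
                         shape_tag = "cone",
                         band_K = band_K, band_lambda = band_lambda)
}

#' Plateau-shaped mountain landscape
#'
#' As [build_cone_landscape()], but the mountaintop is flat and extensive:
#' highlands cover 40% of the nominal area and form a large contiguous
#' central block, surrounded by intermediate bands of 19% and 16% and an
#' outer lowland ring of 20%.  (The percentages sum to 95%, so the realized
#' landscape has about 95% of `total_cells` cells.)  Temperatures per band
#' are identical to the cone landscape.
#'
#' @inheritParams build_cone_landscape
#' @return an `elev_landscape` with `shape_tag = "plateau"`.
#' @examples
#' mt <- build_plateau_landscape(1000)
#' mt$band_cell_counts   # (200, 160, 190, 400)
#' @export
build_plateau_landscape <- function(total_cells = 1000, base_temperature = 20,
                                    band_K = rep(10L, 4),
                                    band_lambda = rep(0.05, 4)) {
  build_banded_landscape(total_cells,
                         fractions = c(0.20, 0.16, 0.19, 0.40),
                         base_temperature = base_temperature,
                         shape_tag = "plateau",
                         band_K = band_K, band_lambda = band_lambda)
}

#' General banded landscape
#'
#' Low-level constructor used by the cone and plateau builders; also handy
#' for synthetic geometries such as equal-area bands when testing for band
#' effects that are independent of geometry.
#'
#' @inheritParams build_cone_landscape
#' @param fractions per-band area fractions, lowland to highland.
#' @param shape_tag label stored on the landscape.
#' @export
build_banded_landscape <- function(total_cells, fractions,
                                   base_temperature = 20,
                                   shape_tag = "custom",
                                   band_K = rep(10L, length(fractions)),
                                   band_lambda = rep(0.05, length(fractions))) {
  n_bands <- length(fractions)
  if (n_bands < 2L) stop("need at least two bands")
  if (!is.numeric(total_cells) || length(total_cells) != 1L ||
      is.na(total_cells) || total_cells < 20) {
    stop("total_cells must be a single number >= 20 (smaller grids leave ",
         "the highland band empty)")
  }
  total_cells <- as.integer(total_cells)
  counts <- floor(fractions * total_cells + 0.5)  # round half up, stable
  if (any(counts < 1L)) {
    bad <- which(counts < 1L)[1L] - 1L
    stop("total_cells = ", total_cells, " leaves elevational band ", bad,
         " empty; increase total_cells")
  }
  stopifnot(length(band_K) == n_bands, length(band_lambda) == n_bands,
            all(band_K >= 1), all(band_lambda >= 0))
  n <- as.integer(sum(counts))

  ## lattice points along a square spiral from the origin; consecutive
  ## spiral cells are lattice neighbours, so any consecutive segment
  ## (in particular, each band) is connected
  sp <- spiral_path(n)
  x <- sp$x
  y <- sp$y

  ## innermost cells are the highest band
  band <- integer(n)
  hi <- 0L
  for (b in seq(n_bands - 1L, 0L)) {
    idx <- seq(hi + 1L, hi + counts[b + 1L])
    band[idx] <- b
    hi <- hi + counts[b + 1L]
  }

  half <- max(abs(c(x, y))) + 1L
  key <- function(px, py) (px + half) * (2L * half + 1L) + (py + half) + 1L
  pos <- integer((2L * half + 1L)^2)
  pos[key(x, y)] <- seq_len(n)
  adjacency <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- c(pos[key(x[i] + 1L, y[i])], pos[key(x[i] - 1L, y[i])],
            pos[key(x[i], y[i] + 1L)], pos[key(x[i], y[i] - 1L)])
    adjacency[[i]] <- sort(nb[nb > 0L])
  }

  for (i in seq_len(n)) {
    if (any(abs(band[adjacency[[i]]] - band[i]) > 1L)) {
      warning("grid too small for clean band seams: some cells touch a ",
              "non-adjacent band; use a larger total_cells")
      break
    }
  }

  cells <- data.frame(cell_id = seq_len(n), x = x, y = y, band = band,
                      temperature = base_temperature - 5 * band)
  structure(list(cells = cells,
                 adjacency = adjacency,
                 n_bands = n_bands,
                 shape_tag = shape_tag,
                 band_cell_counts = as.integer(counts),
                 band_K = as.numeric(band_K),
                 band_lambda = as.numeric(band_lambda),
                 base_temperature = base_temperature),
            class = "elev_landscape")
}

#' @export
print.elev_landscape <- function(x, ...) {
  cat("Elevational landscape (", x$shape_tag, "), ",
      nrow(x$cells), " cells, ", x$n_bands, " bands\n", sep = "")
  cat("  cells per band (lowland->highland):",
      paste(x$band_cell_counts, collapse = ", "), "\n")
  cat("  temperature per band:",
      paste(x$base_temperature - 5 * seq(0, x$n_bands - 1), collapse = ", "),
      "\n")
  cat("  K per band:      ", paste(x$band_K, collapse = ", "), "\n")
  cat("  lambda per band: ", paste(signif(x$band_lambda, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-band profile of a rate or carrying capacity
#'
#' Builds a monotone (or constant) per-band profile whose extremes differ by
#' a given fold, interpolated geometrically across bands (equal fold per
#' band step).  `base` is always the minimum of the profile: `increase`
#' places it in the lowlands, `decrease` in the highlands, and `uniform`
#' gives every band `base` regardless of `fold`.
#'
#' @param direction one of `"increase"`, `"decrease"`, `"uniform"` (with
#'   elevation).
#' @param fold ratio of the largest to the smallest value; must be >= 1
#'   (invert `direction` rather than using fold < 1).
#' @param base the smallest per-band value.
#' @param n_bands number of elevational bands.
#' @param integer_valued round to integers (used for carrying capacities,
#'   which count species).
#' @return numeric vector of length `n_bands`, lowland to highland.
#' @examples
#' band_rate_profile("increase", fold = 9, base = 0.05)   # nine-fold span
#' band_rate_profile("decrease", fold = 4, base = 10, integer_valued = TRUE)
#' @export
band_rate_profile <- function(direction = c("increase", "decrease", "uniform"),
                              fold, base, n_bands = 4L,
                              integer_valued = FALSE) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(fold), length(fold) == 1L,
            is.numeric(base), length(base) == 1L, base > 0)
  if (fold < 1) stop("fold must be >= 1; use the opposite direction instead")
  steps <- seq(0, 1, length.out = n_bands)
  prof <- switch(direction,
                 uniform  = rep(base, n_bands),
                 increase = base * fold^steps,
                 decrease = base * fold^rev(steps))
  if (integer_valued) prof <- floor(prof + 0.5)
  prof
}

## square spiral from the origin: (0,0), then legs of growing length
spiral_path <- function(n) {
  x <- integer(n)
  y <- integer(n)
  cx <- 0L; cy <- 0L; k <- 1L
  leg <- 1L
  dirs <- list(c(1L, 0L), c(0L, 1L), c(-1L, 0L), c(0L, -1L))
  di <- 1L
  while (k < n) {
    for (rep in 1:2) {
      d <- dirs[[di]]
      for (s in seq_len(leg)) {
        cx <- cx + d[1L]; cy <- cy + d[2L]
        k <- k + 1L
        if (k > n) break
        x[k] <- cx; y[k] <- cy
      }
      di <- di %% 4L + 1L
      if (k > n) break
    }
    leg <- leg + 1L
    if (k >= n) break
  }
  list(x = x, y = y)
}

## ---- connectivity / invariant helpers -------------------------------------

#' Connected components of a landscape's neighbour graph
#'
#' @param landscape an `elev_landscape`.
#' @param cells optional subset of cell ids (e.g. one band); defaults to all.
#' @return integer component label per requested cell.
#' @keywords internal
#' @export
landscape_components <- function(landscape, cells = landscape$cells$cell_id) {
  keep <- logical(nrow(landscape$cells))
  keep[cells] <- TRUE
  comp <- integer(nrow(landscape$cells))
  lab <- 0L
  for (s in cells) {
    if (comp[s] > 0L) next
    lab <- lab + 1L
    queue <- s
    comp[s] <- lab
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in landscape$adjacency[[v]]) {
        if (keep[w] && comp[w] == 0L) {
          comp[w] <- lab
          queue <- c(queue, w)
        }
      }
    }
  }
  comp[cells]
}

#' Validate landscape invariants
#'
#' Checks the structural invariants of a landscape: symmetric, irreflexive
#' adjacency; neighbours within one band of each other; the temperature
#' rule; band counts consistent; full-grid and per-band connectivity.
#'
#' @param landscape an `elev_landscape`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_landscape <- function(landscape) {
  cells <- landscape$cells
  adj <- landscape$adjacency
  n <- nrow(cells)
  if (length(adj) != n) stop("adjacency length != number of cells")
  for (i in seq_len(n)) {
    if (any(adj[[i]] == i)) stop("self-adjacency at cell ", i)
    for (j in adj[[i]]) {
      if (!(i %in% adj[[j]])) stop("asymmetric adjacency ", i, " -> ", j)
      if (abs(cells$band[i] - cells$band[j]) > 1L)
        stop("cells ", i, " and ", j, " are adjacent across non-adjacent bands")
    }
  }
  if (!all(cells$temperature ==
           landscape$base_temperature - 5 * cells$band))
    stop("temperature rule violated")
  tab <- tabulate(cells$band + 1L, nbins = landscape$n_bands)
  if (!all(tab == landscape$band_cell_counts))
    stop("band_cell_counts inconsistent with cells")
  if (sum(landscape$band_cell_counts) != n)
    stop("band_cell_counts do not sum to the cell total")
  if (length(unique(landscape_components(landscape))) != 1L)
    stop("landscape is not connected")
  for (b in seq(0L, landscape$n_bands - 1L)) {
    ids <- cells$cell_id[cells$band == b]
    if (length(unique(landscape_components(landscape, ids))) != 1L)
      stop("band ", b, " is not internally connected")
  }
  invisible(TRUE)
}

## ---- serialization --------------------------------------------------------

#' Write / read a landscape as plain text
#'
#' The file is a tab-separated table (`cell_id`, `x`, `y`, `band`,
#' `temperature`, `neighbors` as comma-separated ids) preceded by a single
#' `#`-prefixed JSON header holding `shape_tag`, `n_bands`,
#' `base_temperature`, `band_K` and `band_lambda`.
#'
#' @param landscape an `elev_landscape`.
#' @param path file path.
#' @return `write_landscape` returns `path` invisibly; `read_landscape`
#'   returns the landscape.
#' @export
write_landscape <- function(landscape, path) {
  hdr <- jsonlite::toJSON(list(shape_tag = landscape$shape_tag,
                               n_bands = landscape$n_bands,
                               base_temperature = landscape$base_temperature,
                               band_K = landscape$band_K,
                               band_lambda = landscape$band_lambda),
                          auto_unbox = TRUE, digits = NA)
  tab <- landscape$cells
  tab$neighbors <- vapply(landscape$adjacency, paste, "", collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", hdr), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#")) stop("missing JSON header line")
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1L]))
  tab <- utils::read.table(text = lines[-1L], header = TRUE, sep = "\t",
                           colClasses = c("integer", "integer", "integer",
                                          "integer", "numeric", "character"))
  adjacency <- lapply(strsplit(tab$neighbors, ","),
                      function(s) as.integer(s[nzchar(s)]))
  counts <- tabulate(tab$band + 1L, nbins = hdr$n_bands)
  structure(list(cells = tab[c("cell_id", "x", "y", "band", "temperature")],
                 adjacency = adjacency,
                 n_bands = hdr$n_bands,
                 shape_tag = hdr$shape_tag,
                 band_cell_counts = as.integer(counts),
                 band_K = as.numeric(hdr$band_K),
                 band_lambda = as.numeric(hdr$band_lambda),
                 base_temperature = hdr$base_temperature),
            class = "elev_landscape")
}
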