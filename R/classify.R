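#' Phenotype class regions on the E1-E2 plane
#'
#' The trait space under the trade-off surface is continuous, so the
#' specialist / generalist / parasite classes are regions of its E1-E2
#' projection: absolute specialists sit on the axes, absolute generalists on
#' the 45-degree line, the absolute parasite at the origin. The regions are
#' tested in the fixed order parasite, specialist, generalist, rest, so every
#' phenotype belongs to exactly one class. Defaults: parasites within
#' `e1 + e2 <= 1` (a tenth of `E_max = 10`), specialists within 0.5 activity
#' units of an axis, generalists with specialization `s <= 0.2`.
#'
#' @param parasite_sum_max Parasite region: `e1 + e2` at most this value.
#' @param specialist_minor_max Specialist region: `min(e1, e2)` at most this.
#' @param generalist_s_max Generalist region: [specialization()] at most this.
#' @return A list of class `mcrs_regions`.
#' @examples
#' class_regions()
#' @export
class_regions <- function(parasite_sum_max = 1.0,
                          specialist_minor_max = 0.5,
                          generalist_s_max = 0.2) {
  stopifnot(parasite_sum_max >= 0, specialist_minor_max >= 0,
            generalist_s_max >= 0)
  structure(
    list(parasite_sum_max = parasite_sum_max,
         specialist_minor_max = specialist_minor_max,
         generalist_s_max = generalist_s_max),
    class = "mcrs_regions"
  )
}

#' @export
print.mcrs_regions <- function(x, ...) {
  cat("<mcrs_regions>\n")
  cat(sprintf("  parasite:   e1 + e2 <= %g\n", x$parasite_sum_max))
  cat(sprintf("  specialist: min(e1, e2) <= %g\n", x$specialist_minor_max))
  cat(sprintf("  generalist: s(e1, e2) <= %g\n", x$generalist_s_max))
  invisible(x)
}

#' Classify phenotypes into specialist / generalist / parasite / rest
#'
#' Applies the class regions in fixed order: parasite if
#' `e1 + e2 <= parasite_sum_max`; else specialist if
#' `min(e1, e2) <= specialist_minor_max`; else generalist if
#' `s(e1, e2) <= generalist_s_max`; else rest. Any phenotype with
#' `e1 = e2 = 0` is a parasite regardless of `k`.
#'
#' @param e1,e2 Enzyme activities, recycled to common length.
#' @param regions A [class_regions()] object.
#' @return A factor with levels `specialist`, `generalist`, `parasite`,
#'   `rest`.
#' @examples
#' classify(c(0, 5, 6.0, 4), c(0, 5, 0.1, 2))
#' @export
classify <- function(e1, e2, regions = class_regions()) {
  n <- max(length(e1), length(e2))
  e1 <- rep_len(e1, n); e2 <- rep_len(e2, n)
  out <- rep("rest", n)
  s <- specialization(e1, e2)
  out[s <= regions$generalist_s_max] <- "generalist"
  out[pmin(e1, e2) <= regions$specialist_minor_max] <- "specialist"
  out[e1 + e2 <= regions$parasite_sum_max] <- "parasite"
  factor(out, levels = c("specialist", "generalist", "parasite", "rest"))
}

#' Per-generation lattice summary
#'
#' Exact counts over occupied sites: occupancy fraction, the four class
#' frequencies (fractions of occupied sites), and mean traits. An empty
#' lattice is flagged extinct with zero frequencies and `NA` trait means.
#'
#' @param lat An `mcrs_lattice`.
#' @param regions A [class_regions()] object.
#' @return A one-row tibble with columns `generation`, `occupancy`,
#'   `f_specialist`, `f_generalist`, `f_parasite`, `f_rest`, `mean_e1`,
#'   `mean_e2`, `mean_k`, `extinct`.
#' @examples
#' set.seed(1)
#' summarize_lattice(mcrs_init(mcrs_params(L = 10)))
#' @export
summarize_lattice <- function(lat, regions = class_regions()) {
  idx <- which(lat$occ)
  n <- length(idx)
  if (n == 0L) {
    return(tibble::tibble(
      generation = lat$generation, occupancy = 0,
      f_specialist = 0, f_generalist = 0, f_parasite = 0, f_rest = 0,
      mean_e1 = NA_real_, mean_e2 = NA_real_, mean_k = NA_real_,
      extinct = TRUE
    ))
  }
  cls <- classify(lat$e1[idx], lat$e2[idx], regions)
  tab <- table(cls) / n
  tibble::tibble(
    generation = lat$generation,
    occupancy = n / lat$L^2,
    f_specialist = as.numeric(tab[["specialist"]]),
    f_generalist = as.numeric(tab[["generalist"]]),
    f_parasite = as.numeric(tab[["parasite"]]),
    f_rest = as.numeric(tab[["rest"]]),
    mean_e1 = mean(lat$e1[idx]),
    mean_e2 = mean(lat$e2[idx]),
    mean_k = mean(lat$k[idx]),
    extinct = FALSE
  )
}

#' Two-dimensional enzyme-activity histogram
#'
#' Bins the occupied sites' `(e1, e2)` values on a `bins x bins` grid spanning
#' `[0, E_max]^2`; frequencies sum to 1 whenever the lattice holds at least
#' one replicator. This is the tabular equivalent of the published
#' activity-distribution surfaces.
#'
#' @param x An `mcrs_lattice`, or a data frame with columns `e1`, `e2`.
#' @param bins Number of bins per axis (>= 1).
#' @param E_max Axis extent; defaults to the lattice's `E_max` (10 for plain
#'   data frames).
#' @return A tibble in long format: `e1_bin_low`, `e2_bin_low`, `frequency`
#'   (all `bins^2` cells, zeros included).
#' @examples
#' set.seed(1)
#' h <- phenotype_histogram(mcrs_init(mcrs_params(L = 10)), bins = 5)
#' sum(h$frequency)
#' @export
phenotype_histogram <- function(x, bins = 20, E_max = NULL) {
  stopifnot(bins >= 1)
  bins <- as.integer(bins)
  if (inherits(x, "mcrs_lattice")) {
    if (is.null(E_max)) E_max <- x$params$E_max
    idx <- which(x$occ)
    e1 <- x$e1[idx]; e2 <- x$e2[idx]
  } else {
    stopifnot(all(c("e1", "e2") %in% names(x)))
    if (is.null(E_max)) E_max <- 10
    e1 <- x$e1; e2 <- x$e2
  }
  width <- E_max / bins
  lows <- (seq_len(bins) - 1L) * width
  grid <- tidyr::expand_grid(e1_bin_low = lows, e2_bin_low = lows)
  if (length(e1) == 0L) {
    grid$frequency <- 0
    return(grid)
  }
  i1 <- pmin(floor(e1 / width), bins - 1L)
  i2 <- pmin(floor(e2 / width), bins - 1L)
  cell <- i1 * bins + i2  # matches expand_grid order (e1 outer, e2 inner)
  counts <- tabulate(cell + 1L, nbins = bins^2)
  grid$frequency <- counts / length(e1)
  grid
}

#' Quasi-equilibrium summary of a run
#'
#' The published results report class frequencies at a single late generation
#' of a long run; at desk scale it is steadier to average over the tail.
#' Averages class frequencies, occupancy and trait means over the final
#' `window` fraction of the recorded series (at least one record).
#'
#' @param series A tibble of per-generation summaries, as produced by
#'   [run_single()] (columns as in [summarize_lattice()]).
#' @param window Fraction of records, in `(0, 1]`, to average over (default
#'   0.1, the final tenth).
#' @return A one-row tibble with the same summary columns; `generation` is
#'   the last recorded generation and `extinct` is the final record's flag.
#' @examples
#' ser <- tibble::tibble(generation = 1:10, occupancy = 0.5,
#'   f_specialist = seq(0, 0.9, by = 0.1), f_generalist = 0, f_parasite = 0,
#'   f_rest = 0, mean_e1 = 1, mean_e2 = 1, mean_k = 2, extinct = FALSE)
#' quasi_equilibrium(ser, window = 0.2)
#' @export
quasi_equilibrium <- function(series, window = 0.1) {
  stopifnot(nrow(series) > 0, window > 0, window <= 1)
  n <- nrow(series)
  tail_n <- max(1L, ceiling(window * n))
  tail_rows <- series[(n - tail_n + 1L):n, ]
  tibble::tibble(
    generation = series$generation[n],
    occupancy = mean(tail_rows$occupancy),
    f_specialist = mean(tail_rows$f_specialist),
    f_generalist = mean(tail_rows$f_generalist),
    f_parasite = mean(tail_rows$f_parasite),
    f_rest = mean(tail_rows$f_rest),
    mean_e1 = mean(tail_rows$mean_e1, na.rm = TRUE),
    mean_e2 = mean(tail_rows$mean_e2, na.rm = TRUE),
    mean_k = mean(tail_rows$mean_k, na.rm = TRUE),
    extinct = series$extinct[n]
  )
}
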