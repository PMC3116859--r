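#' Run a single replicator simulation
#'
#' Initializes a random lattice ([mcrs_init()]) and advances it
#' `params$generations` generations, recording a [summarize_lattice()] record
#' at each thinning point. The whole run is deterministic given `params`
#' (including its `seed`): the initializer uses R's RNG seeded with
#' `params$seed`, and the compiled kernel a counter-based stream expanded from
#' the same seed.
#'
#' @param params An [mcrs_params()] object.
#' @param regions A [class_regions()] object used for the recorded summaries.
#' @param thin Record a summary every `thin` generations; `NULL` (default)
#'   records every generation for runs up to 1,000 generations and every 10th
#'   beyond. Generation 0 and the final generation are always recorded.
#' @param engine `"cpp"` (compiled kernel, default) or `"r"` (the pure-R
#'   reference stepper [run_generation()]; only sensible for small lattices).
#' @return An object of class `mcrs_run`: a list with elements `params`,
#'   `regions`, `series` (tibble of summary records), `final` (the final
#'   `mcrs_lattice`) and `elapsed` (seconds).
#' @examples
#' run <- run_single(mcrs_params(L = 20, generations = 50, b = 0.4, D = 5,
#'                               seed = 1))
#' glance(run)
#' @export
run_single <- function(params, regions = class_regions(), thin = NULL,
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  validate_params(params)
  if (is.null(thin)) thin <- if (params$generations <= 1000L) 1L else 10L
  thin <- max(1L, as.integer(thin))
  t0 <- proc.time()[["elapsed"]]

  set.seed(params$seed)
  lat <- mcrs_init(params)
  series <- list(summarize_lattice(lat, regions))

  gens <- params$generations
  if (gens > 0L) {
    record_at <- unique(c(seq(thin, gens, by = thin), gens))
    if (engine == "cpp") {
      res <- .run_engine_cpp(
        occ = as.integer(lat$occ), e1 = as.numeric(lat$e1),
        e2 = as.numeric(lat$e2), k = as.numeric(lat$k),
        conf = as.integer(lat$conf),
        L = lat$L, par = unclass(params), generations = gens,
        start_generation = 0L, record_at = as.integer(record_at),
        regions = c(regions$parasite_sum_max, regions$specialist_minor_max,
                    regions$generalist_s_max),
        seed = as.double(bitwAnd(params$seed, 2147483647L))
      )
      L <- lat$L
      lat$occ <- matrix(res$occ == 1L, L, L)
      lat$e1 <- matrix(res$e1, L, L)
      lat$e2 <- matrix(res$e2, L, L)
      lat$k <- matrix(res$k, L, L)
      lat$conf <- matrix(res$conf, L, L)
      lat$generation <- res$generation
      sm <- tibble::as_tibble(as.data.frame(res$summary))
      sm$generation <- as.integer(sm$generation)
      sm$extinct <- sm$extinct > 0
      series <- c(series, list(sm))
    } else {
      for (g in seq_len(gens)) {
        lat <- run_generation(lat, params)
        if (g %in% record_at)
          series <- c(series, list(summarize_lattice(lat, regions)))
      }
    }
  }

  out <- structure(
    list(
      params = params,
      regions = regions,
      series = dplyr::bind_rows(series),
      final = lat,
      elapsed = proc.time()[["elapsed"]] - t0
    ),
    class = "mcrs_run"
  )
  out
}

#' @export
print.mcrs_run <- function(x, ...) {
  qe <- quasi_equilibrium(x$series)
  cat(sprintf("<mcrs_run> L = %d, %d generations, seed %d (%.1fs)\n",
              x$params$L, x$params$generations, x$params$seed, x$elapsed))
  cat(sprintf("  b = %g, g = %g, D = %g, k_max = %g, p_m = %g\n",
              x$params$b, x$params$g, x$params$D, x$params$k_max, x$params$p_m))
  if (qe$extinct) {
    cat("  population extinct\n")
  } else {
    cat(sprintf(
      "  quasi-equilibrium: occupancy %.2f | spec %.3f gen %.3f par %.3f rest %.3f\n",
      qe$occupancy, qe$f_specialist, qe$f_generalist, qe$f_parasite, qe$f_rest))
  }
  invisible(x)
}

#' Tidy the per-generation series of a run
#'
#' @param x An `mcrs_run`.
#' @param ... Unused.
#' @return The per-generation summary tibble (one row per recorded
#'   generation).
#' @export
tidy.mcrs_run <- function(x, ...) {
  x$series
}

#' One-row quasi-equilibrium summary of a run
#'
#' @param x An `mcrs_run`.
#' @param window Tail fraction passed to [quasi_equilibrium()].
#' @param ... Unused.
#' @return A one-row tibble: key parameters, quasi-equilibrium class
#'   frequencies, trait means and the extinction flag.
#' @export
glance.mcrs_run <- function(x, window = 0.1, ...) {
  qe <- quasi_equilibrium(x$series, window)
  dplyr::bind_cols(
    tibble::tibble(L = x$params$L, b = x$params$b, g = x$params$g,
                   D = x$params$D, k_max = x$params$k_max,
                   p_m = x$params$p_m, seed = x$params$seed),
    qe
  )
}

#' Generics for broom-style methods
#'
#' `tidy()` and `glance()` generics, re-exported so `mcrs` methods work
#' without attaching broom.
#' @param x Object to tidy.
#' @param ... Method arguments.
#' @return A tibble.
#' @name mcrs-generics
NULL

#' @rdname mcrs-generics
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname mcrs-generics
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot the class-frequency time series of a run
#'
#' @param object An `mcrs_run`.
#' @param ... Unused.
#' @return A ggplot: class frequencies among occupied sites over generations,
#'   with occupancy as a dashed reference line.
#' @export
autoplot.mcrs_run <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$series,
    cols = c("f_specialist", "f_generalist", "f_parasite", "f_rest"),
    names_to = "class", names_prefix = "f_", values_to = "frequency"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation,
                                     y = .data$frequency,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$occupancy),
                       colour = "grey40", linetype = "dashed") +
    ggplot2::labs(x = "generation", y = "frequency among occupied sites",
                  colour = "class",
                  title = sprintf("b = %g, g = %g, D = %g, k_max = %g",
                                  object$params$b, object$params$g,
                                  object$params$D, object$params$k_max)) +
    ggplot2::ylim(0, 1)
}

#' Plot the final enzyme-activity histogram of a run
#'
#' @param run An `mcrs_run`.
#' @param bins Bins per axis.
#' @return A ggplot tile map of the final `(e1, e2)` distribution.
#' @export
plot_phenotype_histogram <- function(run, bins = 20) {
  h <- phenotype_histogram(run$final, bins = bins)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$e1_bin_low, y = .data$e2_bin_low,
                                  fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "E1 activity", y = "E2 activity", fill = "frequency")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
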