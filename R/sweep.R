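#' Specify a one-parameter sweep
#'
#' A sweep varies one numeric model parameter over a grid of values, running
#' `replicates` independently seeded simulations per value from a common base
#' configuration.
#'
#' @param base An [mcrs_params()] object: the configuration shared by all
#'   runs.
#' @param axis Name of the parameter to vary (e.g. `"b"`, `"g"`, `"D"`,
#'   `"k_max"`, `"p_m"`); must be a numeric field of `base`.
#' @param values Non-empty numeric vector of parameter values.
#' @param replicates Number of replicate seeds per value (>= 1).
#' @param seeds Optional integer vector of length `replicates`; defaults to
#'   `base$seed + 0:(replicates - 1)`.
#' @return A list of class `mcrs_sweep_spec`.
#' @examples
#' sweep_spec(mcrs_params(L = 30, generations = 100), "b",
#'            values = c(0.4, 1, 1.67), replicates = 2)
#' @export
sweep_spec <- function(base, axis, values, replicates = 5, seeds = NULL) {
  validate_params(base)
  stopifnot(is.character(axis), length(axis) == 1L)
  if (!axis %in% names(unclass(base)) || !is.numeric(base[[axis]]))
    stop("axis must name a numeric parameter field, got: ", axis)
  if (length(values) == 0L) stop("values must be non-empty")
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  if (is.null(seeds)) seeds <- base$seed + seq_len(replicates) - 1L
  seeds <- as.integer(seeds)
  stopifnot(length(seeds) == replicates)
  structure(
    list(base = base, axis = axis, values = as.numeric(values),
         replicates = replicates, seeds = seeds),
    class = "mcrs_sweep_spec"
  )
}

#' @export
print.mcrs_sweep_spec <- function(x, ...) {
  cat(sprintf("<mcrs_sweep_spec> axis %s over {%s}, %d replicate(s)\n",
              x$axis, paste(signif(x$values, 4), collapse = ", "),
              x$replicates))
  invisible(x)
}

#' Run a parameter sweep
#'
#' Runs [run_single()] for every (value, replicate) pair of the spec and
#' reports the [quasi_equilibrium()] record per run: one tibble row per run,
#' `length(values) * replicates` rows in all. A failing run is recorded in
#' its row's `error` column and the sweep continues.
#'
#' @param spec A [sweep_spec()] object.
#' @param regions A [class_regions()] object.
#' @param window Tail fraction for [quasi_equilibrium()].
#' @param thin,engine Passed to [run_single()].
#' @param verbose Print one progress line per run.
#' @return A tibble with columns `value` (the swept parameter), `replicate`,
#'   `seed`, the quasi-equilibrium summary columns, and `error` (`NA` for
#'   clean runs). The swept parameter name is kept in attribute `"axis"`.
#' @examples
#' sp <- sweep_spec(mcrs_params(L = 15, generations = 30), "b",
#'                  values = c(0.4, 1.67), replicates = 1)
#' run_sweep(sp)
#' @export
run_sweep <- function(spec, regions = class_regions(), window = 0.1,
                      thin = NULL, engine = "cpp", verbose = FALSE) {
  stopifnot(inherits(spec, "mcrs_sweep_spec"))
  grid <- tidyr::expand_grid(value = spec$values,
                             replicate = seq_len(spec$replicates))
  rows <- purrr::pmap(grid, function(value, replicate) {
    seed <- spec$seeds[replicate]
    res <- tryCatch({
      params <- do.call(update_params,
                        c(list(spec$base),
                          stats::setNames(list(value), spec$axis),
                          list(seed = seed)))
      run <- run_single(params, regions = regions, thin = thin,
                        engine = engine)
      qe <- quasi_equilibrium(run$series, window)
      dplyr::bind_cols(
        tibble::tibble(value = value, replicate = replicate, seed = seed),
        qe, tibble::tibble(error = NA_character_)
      )
    }, error = function(e) {
      tibble::tibble(value = value, replicate = replicate, seed = seed,
                     generation = NA_integer_, occupancy = NA_real_,
                     f_specialist = NA_real_, f_generalist = NA_real_,
                     f_parasite = NA_real_, f_rest = NA_real_,
                     mean_e1 = NA_real_, mean_e2 = NA_real_,
                     mean_k = NA_real_, extinct = NA,
                     error = conditionMessage(e))
    })
    if (verbose)
      message(sprintf("%s = %g, replicate %d (seed %d) done",
                      spec$axis, value, replicate, seed))
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "axis") <- spec$axis
  out
}

#' Estimate the specialist/generalist crossover of a sweep
#'
#' The specialist fraction collapses in a phase-transition-like manner as the
#' enzyme/enzyme trade-off weakens; this locates the swept-parameter value
#' where the mean specialist and generalist frequencies cross, by linear
#' interpolation between adjacent sweep points. If one class dominates over
#' the whole grid, the crossover is censored at the corresponding end.
#'
#' @param table A sweep table from [run_sweep()] (needs columns `value`,
#'   `f_specialist`, `f_generalist`).
#' @return A one-row tibble: `crossover` (`NA` when censored) and `status`
#'   (`"crossed"`, `"censored_above"` when specialists dominate everywhere,
#'   `"censored_below"` when generalists do).
#' @examples
#' tab <- tibble::tibble(value = c(0.5, 0.7),
#'                       f_specialist = c(0.9, 0.05),
#'                       f_generalist = c(0.05, 0.9))
#' crossover_estimate(tab)  # 0.6
#' @export
crossover_estimate <- function(table) {
  stopifnot(all(c("value", "f_specialist", "f_generalist") %in% names(table)))
  means <- table |>
    dplyr::filter(!is.na(.data$f_specialist), !is.na(.data$f_generalist)) |>
    dplyr::group_by(.data$value) |>
    dplyr::summarise(f_specialist = mean(.data$f_specialist),
                     f_generalist = mean(.data$f_generalist),
                     .groups = "drop") |>
    dplyr::arrange(.data$value)
  if (nrow(means) < 2L)
    stop("need at least two sweep values with clean runs")
  d <- means$f_specialist - means$f_generalist
  if (all(d > 0))
    return(tibble::tibble(crossover = NA_real_, status = "censored_above"))
  if (all(d < 0))
    return(tibble::tibble(crossover = NA_real_, status = "censored_below"))
  zero <- which(d == 0)
  if (length(zero) > 0L)
    return(tibble::tibble(crossover = means$value[zero[1]],
                          status = "crossed"))
  i <- which(d[-length(d)] * d[-1] < 0)[1]
  v1 <- means$value[i]; v2 <- means$value[i + 1L]
  cross <- v1 + d[i] * (v2 - v1) / (d[i] - d[i + 1L])
  tibble::tibble(crossover = cross, status = "crossed")
}

#' Plot a sweep table
#'
#' @param table A sweep table from [run_sweep()].
#' @return A ggplot of mean class frequencies (with replicate points) against
#'   the swept parameter.
#' @export
plot_sweep <- function(table) {
  axis <- attr(table, "axis") %||% "value"
  long <- tidyr::pivot_longer(
    table, cols = c("f_specialist", "f_generalist", "f_parasite", "f_rest"),
    names_to = "class", names_prefix = "f_", values_to = "frequency"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$frequency,
                                     colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(x = axis, y = "quasi-equilibrium frequency",
                  colour = "class") +
    ggplot2::ylim(0, 1)
}

#' Published-experiment preset: the b-sweep at fixed mutation and trade-off
#'
#' The headline experiment of the model: sweep the enzyme/enzyme trade-off
#' shape `b` at `p_m = 0.01`, `g = 1.0`, `k_max = 2.5` and a chosen diffusion
#' intensity, then read off the specialist/generalist phase transition. The
#' default is desk scale (`L = 100`, 10,000 generations, 5 replicate seeds);
#' `full_scale = TRUE` restores the published `L = 300`, 150,000 generations.
#'
#' @param D Diffusion intensity (the published runs use 0 and 5).
#' @param b_values Grid of `b` values.
#' @param replicates Replicate seeds per value.
#' @param seed Base seed.
#' @param full_scale Use the published lattice size and run length.
#' @return A [sweep_spec()].
#' @examples
#' preset_fig3(D = 5)
#' @export
preset_fig3 <- function(D = 0,
                        b_values = c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2, 1.4,
                                     1.67, 2.0),
                        replicates = 5, seed = 1L, full_scale = FALSE) {
  base <- mcrs_params(
    L = if (full_scale) 300L else 100L,
    generations = if (full_scale) 150000L else 10000L,
    p_m = 0.01, g = 1.0, k_max = 2.5, D = D, p_d = 0.1, W_e = 20,
    seed = seed
  )
  sweep_spec(base, "b", values = b_values, replicates = replicates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
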