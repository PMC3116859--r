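#' Model parameters for a replicator simulation
#'
#' Collects every model constant and run control into a validated list of class
#' `mcrs_params`. Defaults follow the published parameterisation of the
#' metabolic replicator system: death probability `p_d = 0.1`, empty-site
#' weight `W_e = 20`, maximum enzyme activity `E_max = 10`, minimum replication
#' rate `k_min = 2`, and initial occupancy 0.8. The lattice side and generation
#' count default to desk scale (`L = 100`, 10,000 generations); the published
#' full scale (`L = 300`, 150,000 generations) is available through
#' [preset_fig3()] with `full_scale = TRUE`.
#'
#' @param L Lattice side length in sites; the habitat is an `L x L` torus.
#' @param p_d Death probability per elementary update of an occupied site,
#'   in `[0, 1]`.
#' @param p_m Mutation probability per replication event, in `[0, 1]`.
#' @param D Diffusion intensity: expected site-swap events per site update, so
#'   one generation interleaves `round(D * L^2)` swaps with its `L^2` site
#'   updates. `D = 0` disables explicit mixing (offspring placement still moves
#'   copies one site).
#' @param b Shape of the trade-off between the two enzyme activities. `b < 1`
#'   is convex (strong trade-off), `b = 1` the linear case `E1 + E2 = E_max`,
#'   `b > 1` concave (weak), and `b -> Inf` approaches no trade-off.
#' @param g Shape of the trade-off between total enzyme activity and
#'   replication rate: `g < 1` convex (strong), `g > 1` concave (weak).
#' @param E_max Maximum enzyme activity (activity units).
#' @param k_min,k_max Lowest and highest possible basic replication rates.
#' @param W_e Empty-site weight in the replication lottery: the larger it is,
#'   the more likely weakly claimed empty sites stay empty.
#' @param replication_neighbourhood `"vonNeumann"` (4 cells, default) or
#'   `"Moore"` (8 cells): the occupants competing for an adjacent empty site.
#' @param diffusion_neighbourhood `"Moore"` (default) or `"vonNeumann"`: where
#'   a swap partner is drawn from.
#' @param diffusion_occupied_only If `TRUE`, a swap is performed only when both
#'   chosen sites are occupied (the literal "two neighbouring replicators"
#'   reading); the default `FALSE` swaps any pair, which transports replicators
#'   into empty territory.
#' @param init_occupancy Fraction of sites occupied at generation 0.
#' @param generations Number of generations to simulate.
#' @param seed Integer seed; together with the parameters it fixes the run
#'   bit-for-bit.
#'
#' @return A list of class `mcrs_params`.
#' @examples
#' p <- mcrs_params(L = 30, generations = 100, b = 0.4, D = 5)
#' p$k_max
#' @export
mcrs_params <- function(L = 100L,
                        p_d = 0.1,
                        p_m = 0.01,
                        D = 0,
                        b = 1,
                        g = 1,
                        E_max = 10,
                        k_min = 2,
                        k_max = 2.5,
                        W_e = 20,
                        replication_neighbourhood = c("vonNeumann", "Moore"),
                        diffusion_neighbourhood = c("Moore", "vonNeumann"),
                        diffusion_occupied_only = FALSE,
                        init_occupancy = 0.8,
                        generations = 10000L,
                        seed = 1L) {
  replication_neighbourhood <- match.arg(replication_neighbourhood)
  diffusion_neighbourhood <- match.arg(diffusion_neighbourhood)
  p <- list(
    L = as.integer(L),
    p_d = as.numeric(p_d),
    p_m = as.numeric(p_m),
    D = as.numeric(D),
    b = as.numeric(b),
    g = as.numeric(g),
    E_max = as.numeric(E_max),
    k_min = as.numeric(k_min),
    k_max = as.numeric(k_max),
    W_e = as.numeric(W_e),
    replication_neighbourhood = replication_neighbourhood,
    metabolic_neighbourhood = "Moore",
    diffusion_neighbourhood = diffusion_neighbourhood,
    diffusion_occupied_only = isTRUE(diffusion_occupied_only),
    init_occupancy = as.numeric(init_occupancy),
    generations = as.integer(generations),
    seed = as.integer(seed)
  )
  class(p) <- "mcrs_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "mcrs_params"))
  chk <- function(ok, msg) if (!ok) stop("invalid parameters: ", msg, call. = FALSE)
  chk(length(p$L) == 1L && !is.na(p$L) && p$L >= 3L, "L must be an integer >= 3")
  chk(p$p_d >= 0 && p$p_d <= 1, "p_d must lie in [0, 1]")
  chk(p$p_m >= 0 && p$p_m <= 1, "p_m must lie in [0, 1]")
  chk(p$D >= 0, "D must be >= 0")
  chk(p$b > 0, "b must be > 0")
  chk(p$g > 0, "g must be > 0")
  chk(p$E_max > 0, "E_max must be > 0")
  chk(p$k_min > 0, "k_min must be > 0")
  chk(p$k_max >= p$k_min, "k_max must be >= k_min")
  chk(p$W_e > 0, "W_e must be > 0")
  chk(p$init_occupancy >= 0 && p$init_occupancy <= 1,
      "init_occupancy must lie in [0, 1]")
  chk(p$generations >= 0L, "generations must be >= 0")
  chk(!is.na(p$seed), "seed must be a finite integer")
  invisible(p)
}

#' @export
print.mcrs_params <- function(x, ...) {
  cat("<mcrs_params>\n")
  cat(sprintf("  lattice %d x %d torus, %d generations, seed %d\n",
              x$L, x$L, x$generations, x$seed))
  cat(sprintf("  p_d = %g, p_m = %g, D = %g, init_occupancy = %g\n",
              x$p_d, x$p_m, x$D, x$init_occupancy))
  cat(sprintf("  trade-off: b = %g, g = %g, E_max = %g, k in [%g, %g]\n",
              x$b, x$g, x$E_max, x$k_min, x$k_max))
  cat(sprintf("  lottery: W_e = %g, replication nbhd %s; diffusion nbhd %s%s\n",
              x$W_e, x$replication_neighbourhood, x$diffusion_neighbourhood,
              if (x$diffusion_occupied_only) " (occupied pairs only)" else ""))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#' Convenient when deriving sweep conditions from a base configuration.
#'
#' @param params An `mcrs_params` object.
#' @param ... Named fields to replace, e.g. `b = 0.4, D = 5`.
#' @return A new `mcrs_params` object.
#' @examples
#' base <- mcrs_params(L = 30, generations = 50)
#' update_params(base, b = 0.4, seed = 7)
#' @export
update_params <- function(params, ...) {
  dots <- list(...)
  if (length(dots) == 0L) return(params)
  nm <- names(dots)
  if (is.null(nm) || any(nm == "")) stop("all replacement fields must be named")
  unknown <- setdiff(nm, names(unclass(params)))
  if (length(unknown) > 0L)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  for (f in nm) params[[f]] <- dots[[f]]
  params$L <- as.integer(params$L)
  params$generations <- as.integer(params$generations)
  params$seed <- as.integer(params$seed)
  validate_params(params)
  params
}
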