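#' Toroidal replicator lattice
#'
#' Constructs an `L x L` toroidal lattice, each site empty or holding a single
#' replicator. Coordinates are 1-based `(row, col)` and both axes wrap. The
#' object stores trait matrices (`e1`, `e2`, `k`), an occupancy mask, a
#' conformation code matrix (0 = none, 1 = expresses E1, 2 = expresses E2) and
#' the generation counter, plus the parameter set used to build it.
#'
#' @param params An [mcrs_params()] object.
#' @param phenotypes Optional data frame with columns `row`, `col`, `e1`,
#'   `e2`, `k`, `conformation` placing replicators explicitly; sites not
#'   listed stay empty. Duplicated coordinates are an error.
#' @return An object of class `mcrs_lattice`.
#' @seealso [mcrs_init()] for random initialization.
#' @examples
#' p <- mcrs_params(L = 5)
#' ph <- tibble::tibble(row = 1, col = 1:2, e1 = c(9, 0), e2 = c(0, 4),
#'                      k = 2, conformation = c("E1", "E2"))
#' lat <- mcrs_lattice(p, ph)
#' tibble::as_tibble(lat)
#' @export
mcrs_lattice <- function(params, phenotypes = NULL) {
  L <- params$L
  lat <- structure(
    list(
      L = L,
      generation = 0L,
      occ = matrix(FALSE, L, L),
      e1 = matrix(0, L, L),
      e2 = matrix(0, L, L),
      k = matrix(params$k_min, L, L),
      conf = matrix(0L, L, L),
      params = params
    ),
    class = "mcrs_lattice"
  )
  if (!is.null(phenotypes)) {
    stopifnot(all(c("row", "col", "e1", "e2", "k", "conformation") %in%
                    names(phenotypes)))
    idx <- cbind(phenotypes$row, phenotypes$col)
    if (anyDuplicated(idx)) stop("duplicated site coordinates")
    if (any(idx < 1L) || any(idx > L)) stop("coordinates outside the lattice")
    if (!all(is_feasible(phenotypes$e1, phenotypes$e2, phenotypes$k, params)))
      stop("phenotypes must be feasible under the trade-off surface")
    lat$occ[idx] <- TRUE
    lat$e1[idx] <- phenotypes$e1
    lat$e2[idx] <- phenotypes$e2
    lat$k[idx] <- phenotypes$k
    lat$conf[idx] <- conf_code(phenotypes$conformation)
  }
  lat
}

conf_code <- function(label) {
  code <- match(label, c("none", "E1", "E2")) - 1L
  if (anyNA(code)) stop("conformation must be one of 'none', 'E1', 'E2'")
  code
}

conf_label <- function(code) c("none", "E1", "E2")[code + 1L]

#' @export
print.mcrs_lattice <- function(x, ...) {
  cat(sprintf("<mcrs_lattice> %d x %d torus, generation %d, %d/%d occupied\n",
              x$L, x$L, x$generation, sum(x$occ), x$L^2))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.mcrs_lattice <- function(x, ...) {
  idx <- which(x$occ, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  tibble::tibble(
    row = as.integer(idx[, 1]),
    col = as.integer(idx[, 2]),
    e1 = x$e1[idx],
    e2 = x$e2[idx],
    k = x$k[idx],
    conformation = conf_label(x$conf[idx])
  )
}

#' Random initial lattice
#'
#' Occupies exactly `round(init_occupancy * L^2)` sites, chosen uniformly
#' without replacement, each with an independent [sample_mutant()] phenotype —
#' the standard starting condition of the published simulations (80%
#' occupancy, random feasible phenotypes). Uses R's RNG.
#'
#' @param params An [mcrs_params()] object.
#' @return An `mcrs_lattice`.
#' @examples
#' set.seed(1)
#' lat <- mcrs_init(mcrs_params(L = 10))
#' sum(lat$occ)  # 80 of 100 sites
#' @export
mcrs_init <- function(params) {
  L <- params$L
  n_occ <- round(params$init_occupancy * L^2)
  lat <- mcrs_lattice(params)
  if (n_occ == 0) return(lat)
  sites <- sample.int(L^2, n_occ)
  ph <- sample_mutant(n_occ, params)
  lat$occ[sites] <- TRUE
  lat$e1[sites] <- ph$e1
  lat$e2[sites] <- ph$e2
  lat$k[sites] <- ph$k
  lat$conf[sites] <- conf_code(ph$conformation)
  lat
}

# toroidal wrap of 1-based indices
wrap <- function(i, L) ((i - 1L) %% L) + 1L

neighbour_offsets <- function(kind) {
  switch(kind,
    vonNeumann = cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L)),
    Moore = cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)),
    stop("unknown neighbourhood kind: ", kind)
  )
}

neighbour_sites <- function(site, L, kind) {
  off <- neighbour_offsets(kind)
  cbind(wrap(site[1] + off[, "dr"], L), wrap(site[2] + off[, "dc"], L))
}

#' Local metabolic supply at a site
#'
#' The metabolic supply of the replicator in `site` is the geometric mean of
#' the two expressed enzyme-activity totals over its metabolic (Moore, 3x3
#' including the focal site, `n = 9` sites) neighbourhood:
#' `m = sqrt(A1 * A2)` where `A1` sums `e1` of occupants currently in
#' conformation `"E1"` and `A2` sums `e2` of those in `"E2"`. If either
#' activity is absent from the neighbourhood, `m = 0` and the replicator
#' cannot be copied.
#'
#' @param lat An `mcrs_lattice`.
#' @param site Integer `c(row, col)`.
#' @return Metabolic supply `m >= 0` (activity units).
#' @examples
#' p <- mcrs_params(L = 5)
#' ph <- tibble::tibble(row = c(2, 4), col = c(3, 3), e1 = c(9, 0),
#'                      e2 = c(0, 4), k = 2, conformation = c("E1", "E2"))
#' local_metabolism(mcrs_lattice(p, ph), c(3, 3))  # sqrt(9 * 4) = 6
#' @export
local_metabolism <- function(lat, site) {
  L <- lat$L
  if (any(site < 1L) || any(site > L)) stop("site outside the lattice")
  nb <- rbind(matrix(as.integer(site), 1, 2),
              neighbour_sites(site, L, "Moore"))
  a1 <- 0; a2 <- 0
  for (i in seq_len(nrow(nb))) {
    r <- nb[i, 1]; c <- nb[i, 2]
    if (lat$occ[r, c]) {
      if (lat$conf[r, c] == 1L) a1 <- a1 + lat$e1[r, c]
      else if (lat$conf[r, c] == 2L) a2 <- a2 + lat$e2[r, c]
    }
  }
  sqrt(a1 * a2)
}

#' Replicator fitness
#'
#' The actual fitness of a replicator is the product of its basic replication
#' rate and its local metabolic supply, `w = k * m`: a fast template starves
#' without local metabolism, and a well-fed slow template still copies slowly.
#'
#' @param k Basic replication rate(s).
#' @param m Metabolic supply (from [local_metabolism()]).
#' @return `k * m`.
#' @examples
#' fitness(2.5, 2/3)
#' @export
fitness <- function(k, m) {
  if (any(m < 0)) stop("metabolic supply must be non-negative")
  k * m
}

#' Claim probabilities for an empty site
#'
#' Occupants of the replication neighbourhood of an empty site compete to
#' place a copy there. Claimant `i` wins with probability
#' `W_i / (W_e + sum_j W_j)` and the site stays empty with probability
#' `W_e / (W_e + sum_j W_j)`; each claimant's fitness uses the metabolic
#' neighbourhood centred on the claimant itself.
#'
#' @param lat An `mcrs_lattice`.
#' @param site Integer `c(row, col)` of an empty site.
#' @param params An [mcrs_params()] object.
#' @return A tibble with one row per outcome: columns `outcome`
#'   (`"claimant"` or `"empty"`), `row`, `col` (`NA` for the empty outcome),
#'   `w` and probability `p`. Probabilities sum to 1.
#' @examples
#' p <- mcrs_params(L = 5)
#' lottery_odds(mcrs_lattice(p), c(3, 3), p)  # no claimants: stays empty
#' @export
lottery_odds <- function(lat, site, params) {
  if (lat$occ[site[1], site[2]])
    stop("replication lottery called on an occupied site (scheduler bug)")
  nb <- neighbour_sites(site, lat$L, params$replication_neighbourhood)
  keep <- lat$occ[nb]
  nb <- nb[keep, , drop = FALSE]
  w <- vapply(seq_len(nrow(nb)), function(i) {
    fitness(lat$k[nb[i, 1], nb[i, 2]], local_metabolism(lat, nb[i, ]))
  }, numeric(1))
  wt <- c(w, params$W_e)
  tibble::tibble(
    outcome = c(rep("claimant", nrow(nb)), "empty"),
    row = c(nb[, 1], NA_integer_),
    col = c(nb[, 2], NA_integer_),
    w = wt,
    p = wt / sum(wt)
  )
}

#' Draw the replication lottery at an empty site
#'
#' Performs the categorical draw over the outcomes of [lottery_odds()] using
#' R's RNG.
#'
#' @inheritParams lottery_odds
#' @return Integer `c(row, col)` of the winning claimant, or `NULL` if the
#'   site stays empty.
#' @export
replication_lottery <- function(lat, site, params) {
  odds <- lottery_odds(lat, site, params)
  n_cl <- sum(odds$outcome == "claimant")
  if (n_cl == 0L) return(NULL)
  u <- stats::runif(1) * sum(odds$w)
  cum <- cumsum(odds$w[seq_len(n_cl)])
  hit <- which(u < cum)
  if (length(hit) == 0L) return(NULL)
  i <- hit[1]
  c(odds$row[i], odds$col[i])
}

#' Place an offspring copy onto an empty site
#'
#' Copies the winner's phenotype onto the empty site. With probability `p_m`
#' the copy's traits are replaced by an independent [sample_mutant()] draw
#' (mutants fall anywhere below the trade-off surface, regardless of the
#' parent). A faithful copy inherits the parent's conformation; a mutant's
#' conformation comes with the mutant draw.
#'
#' @param lat An `mcrs_lattice`.
#' @param winner Integer `c(row, col)` of the parent (occupied).
#' @param empty_site Integer `c(row, col)` of the target (empty).
#' @param params An [mcrs_params()] object.
#' @return The modified lattice.
#' @export
place_offspring <- function(lat, winner, empty_site, params) {
  stopifnot(lat$occ[winner[1], winner[2]],
            !lat$occ[empty_site[1], empty_site[2]])
  r <- empty_site[1]; c <- empty_site[2]
  if (stats::runif(1) < params$p_m) {
    mut <- sample_mutant(1L, params)
    lat$e1[r, c] <- mut$e1
    lat$e2[r, c] <- mut$e2
    lat$k[r, c] <- mut$k
    lat$conf[r, c] <- conf_code(mut$conformation)
  } else {
    lat$e1[r, c] <- lat$e1[winner[1], winner[2]]
    lat$e2[r, c] <- lat$e2[winner[1], winner[2]]
    lat$k[r, c] <- lat$k[winner[1], winner[2]]
    lat$conf[r, c] <- lat$conf[winner[1], winner[2]]
  }
  lat$occ[r, c] <- TRUE
  lat
}

#' Constant-rate death at a site
#'
#' An occupied site is vacated with probability `p_d`, independent of the
#' occupant's traits and neighbours (detachment from the surface and
#' hydrolysis are lumped into one rate). Empty sites are unchanged.
#'
#' @inheritParams place_offspring
#' @param site Integer `c(row, col)`.
#' @return The modified lattice.
#' @export
death_update <- function(lat, site, params) {
  if (lat$occ[site[1], site[2]] && stats::runif(1) < params$p_d)
    lat$occ[site[1], site[2]] <- FALSE
  lat
}

#' One site-swap diffusion event
#'
#' Replicators adhere reversibly to the mineral surface, so they random-walk
#' by swapping site contents: a uniform random site and a uniform random
#' neighbour in the diffusion neighbourhood exchange their contents. Either
#' partner may be empty unless `params$diffusion_occupied_only` is set, in
#' which case the event is a no-op when a partner is empty. Swaps conserve the
#' multiset of phenotypes and the occupancy count.
#'
#' @inheritParams place_offspring
#' @return The modified lattice.
#' @export
diffusion_step <- function(lat, params) {
  L <- lat$L
  i <- sample.int(L^2, 1L)
  site <- c(((i - 1L) %% L) + 1L, ((i - 1L) %/% L) + 1L)
  nb <- neighbour_sites(site, L, params$diffusion_neighbourhood)
  other <- nb[sample.int(nrow(nb), 1L), ]
  if (params$diffusion_occupied_only &&
      !(lat$occ[site[1], site[2]] && lat$occ[other[1], other[2]]))
    return(lat)
  for (f in c("occ", "e1", "e2", "k", "conf")) {
    tmp <- lat[[f]][site[1], site[2]]
    lat[[f]][site[1], site[2]] <- lat[[f]][other[1], other[2]]
    lat[[f]][other[1], other[2]] <- tmp
  }
  lat
}

#' Advance the lattice by one generation (reference implementation)
#'
#' One generation interleaves, in uniform random order, `L^2` elementary site
#' updates (a random site with replacement: occupied sites face death, empty
#' sites run the replication lottery and possibly receive an offspring) with
#' `round(D * L^2)` diffusion swap events; at the generation boundary every
#' occupant may switch conformation via [conformation_switch()]. This pure-R
#' stepper is the readable reference used for small lattices and
#' cross-checks; [run_single()] uses the compiled kernel by default.
#'
#' @inheritParams place_offspring
#' @return The lattice advanced by one generation.
#' @export
run_generation <- function(lat, params) {
  L <- lat$L
  n_site <- L^2
  n_diff <- round(params$D * n_site)
  schedule <- sample(rep(c(1L, 2L), c(n_site, n_diff)))
  for (ev in schedule) {
    if (ev == 2L) {
      lat <- diffusion_step(lat, params)
    } else {
      i <- sample.int(n_site, 1L)
      site <- c(((i - 1L) %% L) + 1L, ((i - 1L) %/% L) + 1L)
      if (lat$occ[site[1], site[2]]) {
        lat <- death_update(lat, site, params)
      } else {
        winner <- replication_lottery(lat, site, params)
        if (!is.null(winner))
          lat <- place_offspring(lat, winner, site, params)
      }
    }
  }
  occ_idx <- which(lat$occ)
  if (length(occ_idx) > 0L) {
    ph <- tibble::tibble(e1 = lat$e1[occ_idx], e2 = lat$e2[occ_idx],
                         conformation = conf_label(lat$conf[occ_idx]))
    ph <- conformation_switch(ph)
    lat$conf[occ_idx] <- conf_code(ph$conformation)
  }
  lat$generation <- lat$generation + 1L
  lat
}
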