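#' Three-way trade-off surface between enzyme activities and replication rate
#'
#' A replicator's heritable traits are two enzyme activities `(e1, e2)` and a
#' basic replication rate `k`. Good enzymes make poor templates and one enzyme
#' activity grows only at the other's expense, so `k` is capped by
#' \deqn{C(e_1, e_2) = k_{min} + (k_{max} - k_{min}) (1 - u)^{1/g}, \qquad
#'       u = \frac{(e_1^b + e_2^b)^{1/b}}{E_{max}},}
#' defined on the feasible enzyme region \eqn{u \le 1}. Parameter `b` controls
#' the enzyme/enzyme trade-off (`b < 1` convex/strong, `b = 1` the line
#' `e1 + e2 = E_max`, `b > 1` concave/weak) and `g` the enzymes/replication
#' trade-off (`g < 1` convex, `g > 1` concave). At the corners,
#' `C(0, 0) = k_max` and `C(E_max, 0) = C(0, E_max) = k_min`.
#'
#' @param e1,e2 Enzyme activities, non-negative; recycled to common length.
#' @param params An [mcrs_params()] object supplying `b`, `g`, `E_max`,
#'   `k_min`, `k_max`.
#' @return Numeric vector of replication-rate caps `C(e1, e2)`.
#' @seealso [is_feasible()], [sample_mutant()], [tradeoff_grid()]
#' @examples
#' p <- mcrs_params(b = 1, g = 1, k_max = 4)
#' tradeoff_surface(2.5, 2.5, p)  # u = 0.5, cap = 3
#' @export
tradeoff_surface <- function(e1, e2, params) {
  if (any(e1 < 0, na.rm = TRUE) || any(e2 < 0, na.rm = TRUE))
    stop("enzyme activities must be non-negative")
  u <- enzyme_load(e1, e2, params)
  if (any(u > 1 + 1e-12, na.rm = TRUE))
    stop("outside feasible enzyme region (u > 1)")
  u <- pmin(u, 1)
  params$k_min + (params$k_max - params$k_min) * (1 - u)^(1 / params$g)
}

# normalised enzyme investment u = ||(e1,e2)||_b / E_max
enzyme_load <- function(e1, e2, params) {
  b <- params$b
  # (e1^b + e2^b)^(1/b) overflows for large b; factor out the maximum
  m <- pmax(e1, e2)
  u <- ifelse(m == 0, 0, m * (pmax(e1 / m, 0)^b + pmax(e2 / m, 0)^b)^(1 / b))
  u / params$E_max
}

#' Is a phenotype inside the feasible trait volume?
#'
#' A phenotype `(e1, e2, k)` is feasible when both activities are non-negative,
#' the enzyme investment satisfies `u <= 1`, and `k_min <= k <= C(e1, e2)`.
#' Boundary points count as feasible, so absolute specialists
#' `(E_max, 0, k_min)` exist.
#'
#' @param e1,e2,k Trait vectors, recycled to common length.
#' @param params An [mcrs_params()] object.
#' @return Logical vector.
#' @examples
#' p <- mcrs_params(b = 1)
#' is_feasible(0, 0, p$k_max, p)            # absolute parasite: TRUE
#' is_feasible(p$E_max, p$E_max, p$k_min, p) # over-invested: FALSE
#' @export
is_feasible <- function(e1, e2, k, params) {
  n <- max(length(e1), length(e2), length(k))
  e1 <- rep_len(e1, n); e2 <- rep_len(e2, n); k <- rep_len(k, n)
  ok <- e1 >= 0 & e2 >= 0
  u <- enzyme_load(pmax(e1, 0), pmax(e2, 0), params)
  ok <- ok & u <= 1 + 1e-12
  cap <- params$k_min +
    (params$k_max - params$k_min) * pmax(1 - pmin(u, 1), 0)^(1 / params$g)
  ok & k >= params$k_min - 1e-12 & k <= cap + 1e-12
}

#' Draw random phenotypes uniformly from the feasible trait volume
#'
#' Mutant phenotypes are drawn uniformly from the volume below the trade-off
#' surface, by rejection from the bounding box
#' `[0, E_max]^2 x [k_min, k_max]`: mutants are independent of their parents
#' and the average mutation is deleterious, since selection pushes the
#' population towards the surface while mutants fall anywhere below it. Each
#' draw gets a conformation: uniform between the two expressible states when
#' both activities are positive, the single expressible state when one is, and
#' `"none"` for parasites (`e1 = e2 = 0`).
#'
#' When `k_max == k_min` the `k` dimension is degenerate and every draw has
#' `k = k_min` exactly, with `(e1, e2)` uniform on the region `u <= 1`.
#'
#' Uses R's RNG; call `set.seed()` for reproducibility.
#'
#' @param n Number of phenotypes to draw.
#' @param params An [mcrs_params()] object.
#' @return A tibble with columns `e1`, `e2`, `k`, `conformation`.
#' @examples
#' set.seed(1)
#' sample_mutant(5, mcrs_params(b = 0.6, g = 1))
#' @export
sample_mutant <- function(n, params) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  e1 <- numeric(n); e2 <- numeric(n); k <- numeric(n)
  degenerate <- params$k_max <= params$k_min
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 64L)
    c1 <- stats::runif(m, 0, params$E_max)
    c2 <- stats::runif(m, 0, params$E_max)
    u <- enzyme_load(c1, c2, params)
    if (degenerate) {
      ck <- rep(params$k_min, m)
      keep <- u <= 1
    } else {
      ck <- stats::runif(m, params$k_min, params$k_max)
      cap <- params$k_min +
        (params$k_max - params$k_min) * pmax(1 - pmin(u, 1), 0)^(1 / params$g)
      keep <- u <= 1 & ck <= cap
    }
    idx <- which(keep)
    if (length(idx) > 0L) {
      take <- idx[seq_len(min(length(idx), n - got))]
      span <- got + seq_along(take)
      e1[span] <- c1[take]; e2[span] <- c2[take]; k[span] <- ck[take]
      got <- got + length(take)
    }
  }
  conf <- draw_conformation(e1, e2)
  tibble::tibble(e1 = e1, e2 = e2, k = k, conformation = conf)
}

# uniform conformation among expressible (nonzero-activity) states
draw_conformation <- function(e1, e2) {
  n <- length(e1)
  conf <- rep("none", n)
  both <- e1 > 0 & e2 > 0
  conf[both] <- ifelse(stats::runif(sum(both)) < 0.5, "E1", "E2")
  conf[e1 > 0 & e2 == 0] <- "E1"
  conf[e1 == 0 & e2 > 0] <- "E2"
  conf
}

#' Degree of enzymatic specialization
#'
#' `s = |e1 - e2| / (e1 + e2)` on the 0–1 scale: 1 for pure specialists (one
#' activity only), 0 for perfectly symmetric generalists. Parasites
#' (`e1 = e2 = 0`) are assigned `s = 1`; they have no enzymatic fold to switch
#' between, so like specialists they never change conformation.
#'
#' @param e1,e2 Enzyme activities, non-negative; recycled to common length.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' specialization(c(7.3, 4, 3), c(0, 4, 1))  # 1, 0, 0.5
#' @export
specialization <- function(e1, e2) {
  if (any(e1 < 0, na.rm = TRUE) || any(e2 < 0, na.rm = TRUE))
    stop("enzyme activities must be non-negative")
  tot <- e1 + e2
  ifelse(tot > 0, abs(e1 - e2) / tot, 1)
}

#' Stochastic conformation switching between generations
#'
#' A replicator with two expressible secondary structures can only catalyse one
#' reaction per generation; between generations it refolds with probability
#' `1 - s(e1, e2)`. Pure specialists (`s = 1`) never switch, symmetric
#' generalists (`s = 0`) switch every generation, and parasites (conformation
#' `"none"`) are untouched. Switching only targets a state whose activity is
#' positive.
#'
#' Uses R's RNG; the decision is deterministic given the drawn uniform variate.
#'
#' @param phenotypes A data frame with columns `e1`, `e2`, `conformation`.
#' @return The input tibble with `conformation` updated.
#' @examples
#' set.seed(1)
#' ph <- tibble::tibble(e1 = c(5, 7, 0), e2 = c(5, 0, 0),
#'                      conformation = c("E1", "E1", "none"))
#' conformation_switch(ph)
#' @export
conformation_switch <- function(phenotypes) {
  stopifnot(all(c("e1", "e2", "conformation") %in% names(phenotypes)))
  s <- specialization(phenotypes$e1, phenotypes$e2)
  u <- stats::runif(nrow(phenotypes))
  switchable <- phenotypes$conformation != "none" &
    phenotypes$e1 > 0 & phenotypes$e2 > 0
  flip <- switchable & u < (1 - s)
  out <- phenotypes
  out$conformation[flip] <- ifelse(out$conformation[flip] == "E1", "E2", "E1")
  tibble::as_tibble(out)
}

#' Export the trade-off surface as a grid table
#'
#' Evaluates `C(e1, e2)` on a regular grid over `[0, E_max]^2` for inspection
#' or plotting; points outside the feasible enzyme region (`u > 1`) get
#' `NA`.
#'
#' @param params An [mcrs_params()] object.
#' @param n Grid resolution per axis.
#' @return A tibble with columns `e1`, `e2`, `C`.
#' @examples
#' tradeoff_grid(mcrs_params(b = 0.6, g = 0.6), n = 5)
#' @export
tradeoff_grid <- function(params, n = 51) {
  ax <- seq(0, params$E_max, length.out = n)
  grid <- tidyr::expand_grid(e1 = ax, e2 = ax)
  u <- enzyme_load(grid$e1, grid$e2, params)
  cap <- params$k_min +
    (params$k_max - params$k_min) * pmax(1 - pmin(u, 1), 0)^(1 / params$g)
  grid$C <- ifelse(u <= 1 + 1e-12, cap, NA_real_)
  grid
}
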