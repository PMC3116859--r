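test_that("trade-off surface hits its corner identities", {
  for (b in c(0.6, 1, 1.67)) for (g in c(0.6, 1, 1.67)) {
    p <- mcrs_params(b = b, g = g, E_max = 10, k_min = 2, k_max = 2.5)
    expect_equal(tradeoff_surface(0, 0, p), 2.5)
    expect_equal(tradeoff_surface(10, 0, p), 2)
    expect_equal(tradeoff_surface(0, 10, p), 2)
  }
  # hand-evaluated interior point: u = 0.5 at b = 1, linear in k at g = 1
  p <- mcrs_params(b = 1, g = 1, E_max = 10, k_min = 2, k_max = 4)
  expect_equal(tradeoff_surface(2.5, 2.5, p), 3)
})

test_that("trade-off surface rejects invalid input", {
  p <- mcrs_params(b = 1)
  expect_error(tradeoff_surface(-1, 0, p), "non-negative")
  expect_error(tradeoff_surface(8, 8, p), "feasible")
})

test_that("cap is non-increasing along rays from the origin", {
  for (b in c(0.6, 1, 1.67)) for (g in c(0.6, 1, 1.67)) {
    p <- mcrs_params(b = b, g = g)
    for (theta in seq(0, pi / 2, length.out = 7)) {
      # radius limit where u = 1 along this direction
      dir <- c(cos(theta), sin(theta))
      rmax <- p$E_max / (dir[1]^p$b + dir[2]^p$b)^(1 / p$b)
      r <- seq(0, rmax, length.out = 50)
      cap <- tradeoff_surface(r * dir[1], r * dir[2], p)
      expect_true(all(diff(cap) <= 1e-9),
                  info = sprintf("b=%g g=%g theta=%g", b, g, theta))
    }
  }
})

test_that("enzyme trade-off boundary is convex for b < 1, concave for b > 1", {
  e1 <- seq(0.2, 9.8, length.out = 60)
  boundary_e2 <- function(b) (10^b - e1^b)^(1 / b)
  # strong trade-off: boundary lies strictly inside the line e1 + e2 = E_max
  expect_true(all(e1 + boundary_e2(0.6) < 10))
  # weak trade-off: boundary lies strictly outside it
  expect_true(all(e1 + boundary_e2(1.67) > 10))
})

test_that("enzyme/replication trade-off convexity follows g", {
  t <- seq(0, 4.9, length.out = 40)  # e1 = e2 transect, feasible for b = 1
  second_diff <- function(g) {
    cap <- tradeoff_surface(t, t, mcrs_params(b = 1, g = g))
    diff(diff(cap))
  }
  expect_true(all(second_diff(0.6) >= -1e-9))   # convex
  expect_true(all(second_diff(1.67) <= 1e-9))   # concave
})

test_that("very large b approaches the no-trade-off square", {
  p <- mcrs_params(b = 1000)
  expect_true(is_feasible(0.99 * p$E_max, 0.99 * p$E_max, p$k_min, p))
})

test_that("feasibility includes the boundary and excludes over-investment", {
  p <- mcrs_params(b = 1, k_min = 2, k_max = 2.5)
  expect_true(is_feasible(0, 0, p$k_max, p))           # absolute parasite
  expect_false(is_feasible(10, 10, 2, p))              # beyond u = 1 at b = 1
  expect_true(is_feasible(5, 5, 2, p))                 # u = 1 boundary point
  expect_true(is_feasible(10, 0, 2, p))                # absolute specialist
  expect_false(is_feasible(1, 1, 1.99, p))             # below k_min
  expect_false(is_feasible(9, 0, 2.4, p))              # above the cap
})

test_that("every sampled mutant is feasible, for convex and concave shapes", {
  for (b in c(0.4, 1, 1.67)) for (g in c(0.6, 1.67)) {
    p <- mcrs_params(b = b, g = g)
    set.seed(42)
    ph <- sample_mutant(5000, p)
    expect_true(all(is_feasible(ph$e1, ph$e2, ph$k, p)))
  }
})

test_that("degenerate k interval always returns k = k_min exactly", {
  p <- mcrs_params(k_min = 2, k_max = 2)
  set.seed(7)
  ph <- sample_mutant(2000, p)
  expect_true(all(ph$k == 2))
  expect_true(all(is_feasible(ph$e1, ph$e2, ph$k, p)))
})

test_that("sampled conformations always point at a positive activity", {
  set.seed(11)
  ph <- sample_mutant(5000, mcrs_params(b = 0.6))
  expect_true(all(ph$conformation[ph$e1 == 0 & ph$e2 == 0] == "none"))
  expect_true(all(ph$e1[ph$conformation == "E1"] > 0))
  expect_true(all(ph$e2[ph$conformation == "E2"] > 0))
  # both-positive phenotypes split roughly evenly between the two folds
  both <- ph$conformation[ph$e1 > 0 & ph$e2 > 0]
  expect_gt(mean(both == "E1"), 0.45)
  expect_lt(mean(both == "E1"), 0.55)
})

test_that("mutant draws are uniform over the feasible volume", {
  # oracle: cell masses from independent Riemann integration of the cap
  p <- mcrs_params(b = 1, g = 1, k_min = 2, k_max = 2.5)
  n_draw <- 1e5
  set.seed(123)
  ph <- sample_mutant(n_draw, p)

  ebreaks <- c(0, 2, 4, 10)
  kbreaks <- c(2, 2.2, 2.5)
  grid_n <- 400
  ax <- (seq_len(grid_n) - 0.5) / grid_n * p$E_max
  cell_area <- (p$E_max / grid_n)^2
  ee <- expand.grid(e1 = ax, e2 = ax)
  cap <- oracle_cap(ee$e1, ee$e2, b = p$b, g = p$g, E_max = p$E_max,
                    k_min = p$k_min, k_max = p$k_max)
  cap[is.na(cap)] <- p$k_min  # infeasible: zero k-thickness
  i1 <- cut(ee$e1, ebreaks, labels = FALSE)
  i2 <- cut(ee$e2, ebreaks, labels = FALSE)
  expected <- numeric(0); observed <- numeric(0)
  for (a in seq_along(ebreaks)[-length(ebreaks)])
    for (b2 in seq_along(ebreaks)[-length(ebreaks)])
      for (kk in seq_along(kbreaks)[-length(kbreaks)]) {
        klo <- kbreaks[kk]; khi <- kbreaks[kk + 1]
        thick <- pmax(pmin(cap, khi) - klo, 0)
        vol <- sum(thick[i1 == a & i2 == b2]) * cell_area
        expected <- c(expected, vol)
        inside <- ph$e1 >= ebreaks[a] & ph$e1 < ebreaks[a + 1] &
          ph$e2 >= ebreaks[b2] & ph$e2 < ebreaks[b2 + 1] &
          ph$k >= klo & ph$k < khi
        observed <- c(observed, sum(inside))
      }
  probs <- expected / sum(expected)
  keep <- probs * n_draw >= 5
  chi <- sum((observed[keep] - n_draw * probs[keep])^2 /
               (n_draw * probs[keep]))
  pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("empirical acceptance rate matches the feasible-volume fraction", {
  # oracle: independent rejection count using the closed-form cap
  p <- mcrs_params(b = 1, g = 1, k_min = 2, k_max = 2.5)
  set.seed(5)
  n <- 2e5
  u1 <- runif(n, 0, 10); u2 <- runif(n, 0, 10); uk <- runif(n, 2, 2.5)
  cap <- oracle_cap(u1, u2, b = 1, g = 1)
  frac_mc <- mean(!is.na(cap) & uk <= cap)
  se <- sqrt(frac_mc * (1 - frac_mc) / n)
  # closed form at b = g = 1: volume = int (1 - u) dA * (kmax - kmin) over
  # the triangle, = (E_max^2/2) * (1/3) * 0.5; box = 100 * 0.5
  frac_exact <- (0.5 * 100 * (1 / 3) * 0.5) / (100 * 0.5)
  expect_lt(abs(frac_mc - frac_exact), 3 * se + 1e-6)
})

test_that("tradeoff_grid exports the surface with NA outside feasibility", {
  p <- mcrs_params(b = 1, g = 1, k_max = 4)
  g <- tradeoff_grid(p, n = 11)
  expect_equal(nrow(g), 121)
  expect_equal(g$C[g$e1 == 0 & g$e2 == 0], 4)
  expect_true(is.na(g$C[g$e1 == 10 & g$e2 == 10]))
  expect_equal(g$C[g$e1 == 2 & g$e2 == 3], 2 + 2 * 0.5)
})
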