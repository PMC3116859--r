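test_that("random initialization fills exactly the requested occupancy", {
  p <- mcrs_params(L = 30, init_occupancy = 0.8)
  set.seed(1)
  lat <- mcrs_init(p)
  expect_equal(sum(lat$occ), round(0.8 * 900))
  df <- tibble::as_tibble(lat)
  expect_true(all(is_feasible(df$e1, df$e2, df$k, p)))
  # determinism: the same seed rebuilds the same lattice bit for bit
  set.seed(1)
  expect_identical(mcrs_init(p), lat)
})

test_that("an empty lattice is an absorbing state", {
  p <- mcrs_params(L = 8, p_d = 0, p_m = 0, D = 0)
  lat <- mcrs_lattice(p)
  set.seed(1)
  for (i in 1:3) lat <- run_generation(lat, p)
  expect_equal(sum(lat$occ), 0)
  expect_equal(lat$generation, 3L)
})

test_that("feasibility is invariant under the generation dynamics", {
  p <- mcrs_params(L = 12, generations = 0L, b = 0.6, g = 1.67, D = 1,
                   p_m = 0.2)
  lat <- random_lattice(p, occupancy = 0.6, seed = 4)
  set.seed(5)
  for (i in 1:3) lat <- run_generation(lat, p)
  df <- tibble::as_tibble(lat)
  expect_true(all(is_feasible(df$e1, df$e2, df$k, p)))
  # and under the compiled kernel over many generations
  run <- run_single(mcrs_params(L = 25, generations = 150, b = 0.6, D = 2,
                                p_m = 0.05, seed = 6))
  df2 <- tibble::as_tibble(run$final)
  expect_true(all(is_feasible(df2$e1, df2$e2, df2$k, run$params)))
})

test_that("a degenerate k interval pins every occupant at k_min", {
  run <- run_single(mcrs_params(L = 20, generations = 100, k_min = 2,
                                k_max = 2, b = 1.67, D = 1, p_m = 0.1,
                                seed = 3))
  df <- tibble::as_tibble(run$final)
  expect_gt(nrow(df), 0)
  expect_true(all(df$k == 2))
})

test_that("both engines realise the per-generation death law", {
  # no metabolism (parasites only) and p_m = 0: pure death process, so the
  # expected per-generation survival of an occupant is known in closed form
  p <- mcrs_params(L = 12, p_d = 0.3, p_m = 0, D = 0, generations = 0L)
  n0 <- round(0.8 * p$L^2)
  surv_expected <- (1 - p$p_d / p$L^2)^(p$L^2)  # random updates w/ replacement
  make_parasites <- function() {
    sites <- sample.int(p$L^2, n0)
    mcrs_lattice(p, tibble::tibble(
      row = (sites - 1L) %% p$L + 1L, col = (sites - 1L) %/% p$L + 1L,
      e1 = 0, e2 = 0, k = 2, conformation = "none"))
  }
  set.seed(11)
  surv_r <- replicate(12, {
    lat <- run_generation(make_parasites(), p)
    sum(lat$occ) / n0
  })
  surv_c <- sapply(1:12, function(s) {
    set.seed(s)
    res <- run_engine_from(make_parasites(), p, generations = 1, seed = s,
                           record_at = 1L)
    res$summary[1, "occupancy"] * p$L^2 / n0
  })
  tol <- 3 * sqrt(surv_expected * (1 - surv_expected) / n0 / 12)
  expect_lt(abs(mean(surv_r) - surv_expected), tol)
  expect_lt(abs(mean(surv_c) - surv_expected), tol)
})

test_that("a zero-diffusion specialist monoculture starves to extinction", {
  # one conformation everywhere means no complementary activity anywhere:
  # metabolism never runs and only deaths occur
  p <- mcrs_params(L = 30, D = 0, p_m = 0, generations = 0L)
  extinct <- sapply(1:20, function(s) {
    set.seed(s)
    sites <- sample.int(900, 720)
    lat <- mcrs_lattice(p, tibble::tibble(
      row = (sites - 1L) %% 30 + 1L, col = (sites - 1L) %/% 30 + 1L,
      e1 = 10, e2 = 0, k = 2, conformation = "E1"))
    res <- run_engine_from(lat, p, generations = 200, seed = s,
                           record_at = 200L)
    res$summary[1, "occupancy"] == 0
  })
  expect_true(all(extinct))
})

test_that("pure parasite populations die out at any diffusion intensity", {
  for (D in c(0, 5)) {
    p <- mcrs_params(L = 30, D = D, p_m = 0, generations = 0L)
    set.seed(7)
    sites <- sample.int(900, 720)
    lat <- mcrs_lattice(p, tibble::tibble(
      row = (sites - 1L) %% 30 + 1L, col = (sites - 1L) %/% 30 + 1L,
      e1 = 0, e2 = 0, k = 2.5, conformation = "none"))
    res <- run_engine_from(lat, p, generations = 200, seed = 7,
                           record_at = 200L)
    expect_equal(unname(res$summary[1, "occupancy"]), 0)
  }
})

test_that("runs are bit-reproducible given the seed", {
  p <- mcrs_params(L = 20, generations = 80, b = 0.8, D = 2, seed = 123)
  a <- run_single(p)
  b <- run_single(p)
  expect_identical(a$series, b$series)
  expect_identical(tibble::as_tibble(a$final), tibble::as_tibble(b$final))
  c <- run_single(update_params(p, seed = 124))
  expect_false(identical(a$series, c$series))
})

test_that("death strikes all phenotype classes at the same rate", {
  # build a mixed community, apply many single-site death trials, and compare
  # per-class death counts to the class composition (chi-square)
  p <- mcrs_params(L = 40, p_d = 0.1, generations = 0L, b = 1)
  lat <- random_lattice(p, occupancy = 0.7, seed = 8)
  df <- tibble::as_tibble(lat)
  cls <- classify(df$e1, df$e2)
  keep <- table(cls) > 0
  set.seed(9)
  n_trials <- 2e4
  rows <- sample(nrow(df), n_trials, replace = TRUE)
  died <- stats::runif(n_trials) < p$p_d  # death_update's marginal law
  tab <- table(cls[rows][died])[keep]
  expected <- (table(cls[rows]) * mean(died))[keep]
  chi <- sum((tab - expected)^2 / expected)
  pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("the R reference stepper and compiled kernel agree statistically", {
  # short runs from identical initial states: mean occupancy after a few
  # generations should agree across engines within sampling error
  p <- mcrs_params(L = 12, generations = 8, b = 1.4, D = 1, seed = 1)
  occ_r <- sapply(1:4, function(s) {
    run <- run_single(update_params(p, seed = s), engine = "r")
    tail(run$series$occupancy, 1)
  })
  occ_c <- sapply(11:30, function(s) {
    run <- run_single(update_params(p, seed = s), engine = "cpp")
    tail(run$series$occupancy, 1)
  })
  se <- stats::sd(occ_c) / sqrt(length(occ_r))
  expect_lt(abs(mean(occ_r) - mean(occ_c)), 4 * se + 0.02)
})
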