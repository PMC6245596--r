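test_that("the chain LP reproduces the hand-solved solution", {
  # S v = 0 on the chain forces v1 = v2 = v3; seeding R1 at c = 1 pins the
  # scale, so v = (1,1,1) and the unit-weight objective is 3
  sn <- split_reversible(make_chain(2))
  sol <- solve_iteration(sn, 1)
  expect_equal(sol$v, c(1, 1, 1))
  expect_equal(sol$objective, 3)
  expect_identical(sol$support, 1:3)
})

test_that("a dead-end seed is reported infeasible, not an error", {
  sn <- split_reversible(dead_end_network())
  expect_null(solve_iteration(sn, 2))
  # seeding the producing-and-draining pair instead is fine
  expect_false(is.null(solve_iteration(sn, c(1, 3))))
})

test_that("seeding both diamond branches forces the full support", {
  sn <- split_reversible(make_parallel(2))
  sol <- solve_iteration(sn, c(2, 3))
  expect_identical(sol$support, 1:4)
})

test_that("solve_iteration validates seeds and weights", {
  sn <- split_reversible(make_chain(2))
  expect_error(solve_iteration(sn, 9), "within 1..3")
  expect_error(solve_iteration(sn, 1, w = c(1, 1)), "length")
  expect_error(solve_iteration(sn, 1, w = c(0.5, 1, 1)), ">= 1")
})

test_that("weights follow w = 1 + p*F and reject bad input", {
  expect_equal(compute_weights(c(0.9, 0.1, 0.0), 5), c(5.5, 1.5, 1.0))
  expect_equal(compute_weights(c(0.3, 0.7), 0), c(1, 1))
  expect_equal(compute_weights(1.0, 2), 3.0)
  expect_error(compute_weights(c(-0.1, 0.5), 2), "\\[0, 1\\]")
  expect_error(compute_weights(c(0.5), -1), ">= 0")
})

test_that("seed generation is in-range, distinct and deterministic", {
  set.seed(42)
  expect_identical(generate_seed(4, 4), 1:4)  # only one 4-subset
  expect_error(generate_seed(4, 5), "k must satisfy")
  set.seed(7); a <- generate_seed(154, 4)
  set.seed(7); b <- generate_seed(154, 4)
  expect_identical(a, b)
  expect_identical(anyDuplicated(a), 0L)
})

test_that("seed draws are uniform over reactions", {
  # chi-square goodness-of-fit of per-reaction inclusion counts against the
  # uniform expectation k*M/n over M draws
  set.seed(123)
  n <- 20; k <- 4; M <- 20000
  counts <- integer(n)
  for (i in seq_len(M)) {
    s <- generate_seed(n, k)
    counts[s] <- counts[s] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("state updates track occurrences, frequencies and weights", {
  st <- fluxpen:::new_extraction_state(3, p = 2)
  st$N <- 3L; st$O <- c(3L, 2L, 1L); st$F <- st$O / st$N
  sol <- structure(list(v = c(1, 0, 1), support = c(1L, 3L), seed = 1L,
                        objective = 2, elementary = NA),
                   class = "flux_solution")
  st <- update_state(st, sol)
  expect_identical(st$N, 4L)
  expect_identical(st$O, c(4L, 2L, 2L))
  expect_equal(st$F, c(1.0, 0.5, 0.5))
  expect_equal(st$w, 1 + 2 * st$F)

  # first solution ever covering everything -> F all ones, w = 1 + p
  st0 <- fluxpen:::new_extraction_state(3, p = 2)
  sol_all <- structure(list(v = c(1, 1, 1), support = 1:3, seed = 1L,
                            objective = 3, elementary = NA),
                       class = "flux_solution")
  st1 <- update_state(st0, sol_all)
  expect_equal(st1$F, c(1, 1, 1))
  expect_equal(st1$w, c(3, 3, 3))
})

test_that("extraction on the chain is degenerate: one support, F = 1", {
  res <- run_extraction(make_chain(2), N_target = 10, p = 3, k = 1,
                        rng_seed = 5)
  expect_identical(res$status, "complete")
  expect_identical(unique(result_support_keys(res)), "R1,R2,R3")
  expect_equal(res$state$F, c(1, 1, 1))
})

test_that("diamond solutions only ever use pathway supports", {
  sn <- split_reversible(make_parallel(2))
  # brute force over all supports: the only pathway supports are the two
  # EFMs and the full network
  legal <- c("B1,R_in,R_out", "B2,R_in,R_out", "B1,B2,R_in,R_out")
  res <- run_extraction(sn, N_target = 50, p = 0, k = 1, rng_seed = 2)
  expect_true(all(result_support_keys(res) %in% legal))
})

test_that("every feasible solution is at steady state and contains its seed", {
  for (seed in 1:5) {
    net <- test_random_network(seed)
    res <- run_extraction(net, N_target = 30, p = 5, k = 4, rng_seed = seed)
    sn <- res$split_net
    for (sol in res$solutions) {
      expect_lte(max(abs(sn$S %*% sol$v)), 1e-8 * (1 + max(sol$v)))
      expect_gte(min(sol$v), 0)
      expect_true(all(sol$seed %in% sol$support))
    }
  }
})

test_that("identical configuration reproduces identical supports", {
  net <- test_random_network(3)
  a <- run_extraction(net, 40, p = 2, k = 4, rng_seed = 11)
  b <- run_extraction(net, 40, p = 2, k = 4, rng_seed = 11)
  expect_identical(result_support_keys(a), result_support_keys(b))
  expect_identical(a$state$O, b$state$O)
})

test_that("p = 0 dynamic is equivalent to weight_mode = off", {
  net <- test_random_network(4)
  a <- run_extraction(net, 40, p = 0, k = 4, rng_seed = 9)
  b <- run_extraction(net, 40, p = 0, k = 4, rng_seed = 9,
                      weight_mode = "off")
  expect_identical(result_support_keys(a), result_support_keys(b))
  expect_identical(a$state$F, b$state$F)
})

test_that("weights stay inside [1, 1+p] at every iteration", {
  net <- test_random_network(5)
  sn <- split_reversible(net)
  n <- length(sn$reaction_ids)
  st <- fluxpen:::new_extraction_state(n, p = 7)
  set.seed(21)
  for (i in 1:30) {
    expect_true(all(st$w >= 1 & st$w <= 1 + 7))
    sol <- solve_iteration(sn, generate_seed(n, 3), st$w)
    if (!is.null(sol)) st <- update_state(st, sol)
  }
})

test_that("penalization spreads solutions over the parallel branches", {
  # 5 exchangeable branches with k = 1: strong penalization must reach at
  # least as many distinct supports on average as no penalization
  net <- make_parallel(5)
  distinct <- function(p) {
    vapply(1:8, function(s)
      deduplicate(run_extraction(net, 100, p = p, k = 1,
                                 rng_seed = 60 + s))$n_distinct,
      numeric(1))
  }
  expect_gte(mean(distinct(20)), mean(distinct(0)))
})

test_that("an infeasible-seed drought aborts with partial results", {
  # k = 3 forces the dead-end reaction R2 into every seed
  net <- dead_end_network()
  res <- run_extraction(net, N_target = 1e6, p = 0, k = 3, rng_seed = 1,
                        drought_cap = 25)
  expect_identical(res$status, "drought")
  expect_identical(length(res$solutions), 0L)
  expect_gte(res$n_infeasible, 25L)
})

test_that("two-cycle seeds can be excluded", {
  net <- make_chain(2, reversible_middle = TRUE)  # 4 split reactions
  res <- run_extraction(net, 30, p = 0, k = 2, rng_seed = 3,
                        no_two_cycle_seeds = TRUE)
  sn <- res$split_net
  for (sol in res$solutions)
    expect_false(fluxpen:::seed_has_two_cycle(sn, sol$seed))
})

test_that("solution and frequency TSVs round-trip", {
  net <- test_random_network(6)
  res <- run_extraction(net, 15, p = 2, k = 3, rng_seed = 8)
  fpath <- withr::local_tempfile(fileext = ".tsv")
  spath <- withr::local_tempfile(fileext = ".tsv")
  tab <- frequency_table(res)
  write_frequency_tsv(tab, fpath)
  back <- read_frequency_tsv(fpath)
  expect_equal(back$frequency, tab$frequency)
  expect_identical(back$reaction_id, tab$reaction_id)
  expect_equal(attr(back, "N"), 15)
  expect_equal(attr(back, "p"), 2)

  write_solutions_tsv(res, spath)
  sols <- read_solutions_tsv(spath)
  expect_identical(nrow(sols), 15L)
  expect_identical(sort(sols$support[[3]]),
                   canonical_support(res$solutions[[3]]$support, res$split_net))
  expect_true(startsWith(readLines(spath, n = 1), "#"))
})
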