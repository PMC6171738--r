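test_that("draw_count rounds, clips, and respects sd = 0", {
  expect_identical(draw_count(12.16, 0, 360), 12L)
  expect_identical(draw_count(0, 0, 360), 0L)
  expect_identical(draw_count(360, 0, 360), 360L)
  set.seed(1)
  draws <- replicate(500, draw_count(150.66, 16.79, 360))
  expect_true(all(draws >= 0 & draws <= 360))
  expect_true(all(draws == floor(draws)))
  expect_error(draw_count(400, 5, 360), "exceeds population")
  expect_error(draw_count(-1, 0, 360), ">= 0")
})

test_that("draw_count sample mean converges to the Normal mean", {
  set.seed(42)
  draws <- replicate(10000, draw_count(150.66, 16.79, 360))
  # CLT on the underlying Normal; rounding/clipping bias is negligible here
  expect_lt(abs(mean(draws) - 150.66), 3 * 16.79 / sqrt(10000))
})

test_that("assign_cells draws uniform subsets of exactly the right size", {
  expect_setequal(assign_cells(360, 360), 1:360)
  expect_identical(assign_cells(360, 0), integer(0))
  expect_error(assign_cells(10, 11), "in \\[0, n_cells\\]")
  set.seed(7)
  sizes <- replicate(200, length(assign_cells(50, 17)))
  expect_true(all(sizes == 17))
  # per-cell inclusion frequency is uniform: chi-square GOF on inclusion
  # counts over many draws
  set.seed(8)
  incl <- integer(60)
  for (i in 1:5000) {
    s <- assign_cells(60, 6)
    incl[s] <- incl[s] + 1L
  }
  expect_identical(sum(incl), 5000L * 6L)
  gof <- suppressWarnings(stats::chisq.test(incl))
  expect_gt(gof$p.value, 0.001)
})

test_that("simulate_population realizes drawn counts as column sums", {
  p1 <- transmitter_panel("A", 5, 0, population_mean = 10)
  set.seed(1)
  m <- simulate_population(p1)
  expect_identical(sum(m[, "A"]), 5L)

  # forced complete overlap when both counts equal the population
  p2 <- transmitter_panel(c("A", "B"), c(360, 360), c(0, 0), 360)
  set.seed(1)
  m2 <- simulate_population(p2)
  expect_true(all(m2))

  # noisy counts: column sums equal the drawn counts and respect bounds
  set.seed(3)
  m3 <- simulate_population(observed_panel())
  expect_equal(unname(colSums(m3)), unname(attr(m3, "drawn_counts")))
  expect_true(all(colSums(m3) <= nrow(m3)))
})

test_that("coexpression ratios satisfy identity, disjointness, emptiness", {
  m <- matrix(FALSE, 10, 3, dimnames = list(NULL, c("X", "Y", "Z")))
  m[1:4, "X"] <- TRUE
  m[5:8, "Y"] <- TRUE     # disjoint from X
  r <- coexpression_ratios(m)
  expect_equal(r$ratio["X", "X"], 1)
  expect_equal(r$ratio["X", "Y"], 0)
  expect_true(all(is.na(r$ratio["Z", ])))   # empty source: undefined
  expect_equal(r$overlap, t(r$overlap))     # overlap symmetric
  # ratio = overlap / source count wherever defined
  expect_equal(r$ratio["Y", "X"],
               unname(r$overlap["Y", "X"] / r$counts["Y"]))
})

test_that("model fits are deterministic given the seed", {
  panel <- observed_panel()
  f1 <- coexpr_model(panel, n_iterations = 30, seed = 11)
  f2 <- coexpr_model(panel, n_iterations = 30, seed = 11)
  expect_identical(f1$mean, f2$mean)
  expect_identical(f1$sd, f2$sd)
  f3 <- coexpr_model(panel, n_iterations = 30, seed = 12)
  expect_false(identical(f1$mean, f3$mean))
})

test_that("independent model matches closed-form and exhaustive oracles", {
  # forced overlap: counts 10 and 4 in a population of 10
  fit <- coexpr_model(tiny_panel(), n_iterations = 20, seed = 5)
  expect_equal(fit$mean["B", "A"], 1)     # every B cell is A-positive
  expect_equal(fit$mean["A", "B"], 0.4)
  expect_equal(fit$sd["A", "B"], 0)

  # hypergeometric mean at fixed counts: E(ratio X->Y) = n_Y / N
  fit20 <- coexpr_model(fixed_panel3(), n_iterations = 4000, seed = 2)
  for (s in c("X", "Y", "Z")) for (t in setdiff(c("X", "Y", "Z"), s)) {
    expected <- fixed_panel3()$count_mean[match(t, c("X", "Y", "Z"))] / 20
    se <- fit20$sd[s, t] / sqrt(fit20$n_defined[s, t])
    expect_lt(abs(fit20$mean[s, t] - expected), 4 * se + 1e-12)
  }

  # exhaustive enumeration at small N agrees with Monte Carlo
  small <- transmitter_panel(c("X", "Y"), c(3, 5), c(0, 0),
                             population_mean = 8)
  fit8 <- coexpr_model(small, n_iterations = 4000, seed = 9)
  exact <- enumerate_mean_ratio(8, 3, 5)
  expect_equal(exact, 5 / 8)  # oracle self-check: hypergeometric mean
  se <- fit8$sd["X", "Y"] / sqrt(fit8$n_defined["X", "Y"])
  expect_lt(abs(fit8$mean["X", "Y"] - exact), 4 * se)
})

test_that("pairwise overlaps obey inclusion-exclusion bounds", {
  panel <- observed_panel()
  for (i in 1:20) {
    set.seed(100 + i)
    m <- simulate_population(panel)
    ov <- coexpression_ratios(m)$overlap
    cnt <- diag(ov)
    n <- nrow(m)
    for (a in seq_along(cnt)) for (b in seq_along(cnt)) {
      expect_lte(ov[a, b], min(cnt[a], cnt[b]))
      expect_gte(ov[a, b], max(0, cnt[a] + cnt[b] - n))
    }
  }
})

test_that("skipped undefined pairs are logged via n_defined", {
  p <- transmitter_panel(c("A", "B"), c(0.4, 5), c(0.5, 0),
                         population_mean = 10)
  fit <- coexpr_model(p, n_iterations = 200, seed = 4)
  # A's count is 0 in a fair share of iterations -> skipped as source
  expect_lt(fit$n_defined["A", "B"], 200)
  expect_identical(unname(fit$n_defined["B", "A"]), 200L)
  expect_true(is.finite(fit$mean["A", "B"]))
})
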