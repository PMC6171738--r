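test_that("rule construction validates its fields", {
  expect_error(coexpr_rule("A", "A", 0.5), "must differ")
  expect_error(coexpr_rule("A", "B", 1.2), "\\[0, 1\\]")
  r <- coexpr_rule("TK", "MIP", 1)
  expect_s3_class(r, "coexpr_rule")
  panel <- observed_panel()
  expect_error(
    coexpr_model(panel, rules = list(coexpr_rule("TK", "nope", 1)),
                 n_iterations = 1, seed = 1),
    "absent from the panel")
  expect_error(
    coexpr_model(panel, rules = list(coexpr_rule("TK", "MIP", 1),
                                     coexpr_rule("TK", "MIP", 0.5)),
                 n_iterations = 1, seed = 1),
    "duplicate rule")
})

test_that("a rule clamps the directed ratio exactly in every realization", {
  panel <- observed_panel()
  rule <- coexpr_rule("TK", "MIP", 1.0)
  for (i in 1:10) {
    set.seed(200 + i)
    m <- simulate_population(panel, list(rule))
    r <- coexpression_ratios(m)
    expect_equal(unname(r$ratio["TK", "MIP"]), 1.0)
  }
  fit <- coexpr_model(panel, rules = list(rule), n_iterations = 300,
                      seed = 3)
  expect_equal(unname(fit$mean["TK", "MIP"]), 1.0)
  expect_equal(unname(fit$sd["TK", "MIP"]), 0.0)
})

test_that("fractional and zero rules clamp to rounding granularity", {
  # fixed counts so the granularity bound is exact: |mean - p| <= 0.5/n_X
  panel <- frozen_observed_panel()
  p <- 0.42
  fit <- coexpr_model(panel, rules = list(coexpr_rule("MIP", "Mas-AT", p)),
                      n_iterations = 200, seed = 6)
  expect_lt(abs(fit$mean["MIP", "Mas-AT"] - p), 0.5 / 151)
  expect_equal(unname(fit$sd["MIP", "Mas-AT"]), 0)

  fit0 <- coexpr_model(panel, rules = list(coexpr_rule("MIP", "Mas-AT", 0)),
                       n_iterations = 50, seed = 6)
  expect_equal(unname(fit0$mean["MIP", "Mas-AT"]), 0)
  set.seed(1)
  m <- simulate_population(panel, list(coexpr_rule("MIP", "Mas-AT", 0)))
  expect_identical(sum(m[, "MIP"] & m[, "Mas-AT"]), 0L)
})

test_that("the reverse of a clamped pair follows the overlap identity", {
  panel <- observed_panel()
  fit <- coexpr_model(panel, rules = list(coexpr_rule("TK", "MIP", 1.0)),
                      n_iterations = 2000, seed = 8)
  # overlap = n_TK, so ratio(MIP -> TK) = n_TK / n_MIP per iteration;
  # allow for E[n_TK/n_MIP] > E[n_TK]/E[n_MIP] (Jensen) via 4 MC SEs + the
  # second-order correction
  expected <- (12.16 / 150.66) * (1 + (16.79 / 150.66)^2)
  se <- fit$sd["MIP", "TK"] / sqrt(fit$n_defined["MIP", "TK"])
  expect_lt(abs(fit$mean["MIP", "TK"] - expected), 4 * se + 1e-4)
})

test_that("count conservation holds after rule application", {
  panel <- observed_panel()
  rules <- list(coexpr_rule("MIP", "Mas-AT", 0.42),
                coexpr_rule("TK", "MIP", 1.0))
  for (i in 1:10) {
    set.seed(300 + i)
    m <- simulate_population(panel, rules)
    expect_identical(unname(colSums(m)), unname(attr(m, "counts")))
    # no capping/inflation expected at these counts
    expect_length(attr(m, "rule_log"), 0)
  }
})

test_that("infeasible quotas are capped or inflated with a log entry", {
  # forced overlap bigger than the drawn target count -> inflation
  p <- transmitter_panel(c("A", "B"), c(8, 2), c(0, 0), population_mean = 10)
  set.seed(1)
  m <- simulate_population(p, list(coexpr_rule("A", "B", 1)))
  expect_identical(sum(m[, "B"]), 8L)
  expect_match(attr(m, "rule_log"), "inflated", all = FALSE)

  # residual quota larger than the non-source cells -> capped
  p2 <- transmitter_panel(c("A", "B"), c(8, 6), c(0, 0), population_mean = 10)
  set.seed(1)
  m2 <- simulate_population(p2, list(coexpr_rule("A", "B", 0)))
  # 6 B cells requested among only 2 non-A cells
  expect_identical(sum(m2[, "B"]), 2L)
  expect_match(attr(m2, "rule_log"), "capped", all = FALSE)
})

test_that("pairs not touched by a rule match the independent model", {
  panel <- observed_panel()
  ind <- coexpr_model(panel, n_iterations = 2000, seed = 21)
  con <- coexpr_model(panel, rules = list(coexpr_rule("TK", "MIP", 1.0)),
                      n_iterations = 2000, seed = 21)
  for (pair in list(c("FMRF", "AST-A"), c("AST-A", "FMRF"),
                    c("Mas-AT", "GABA"), c("FMRF", "Mas-AT"))) {
    s <- pair[1]; t <- pair[2]
    se <- sqrt(ind$sd[s, t]^2 / ind$n_defined[s, t] +
                 con$sd[s, t]^2 / con$n_defined[s, t])
    expect_lt(abs(ind$mean[s, t] - con$mean[s, t]), 4 * se)
  }
})

test_that("rule-model enumeration counts all subsets up to max_rules", {
  panel <- transmitter_panel(LETTERS[1:11], rep(5, 11), rep(0, 11), 100)
  mk <- function(n) lapply(seq_len(n), function(i)
    coexpr_rule(LETTERS[i], LETTERS[i + 1], 0.5))
  expect_length(rule_models(mk(5), 1, panel), 6)
  expect_length(rule_models(mk(10), 3, panel), 1 + 10 + 45 + 120)
  only <- rule_models(mk(5), 0, panel)
  expect_length(only, 1)
  expect_identical(only[[1]]$label, "independent")
  # deterministic ordering: by size then lexicographic rule index
  specs <- rule_models(mk(3), 2, panel)
  expect_identical(vapply(specs, `[[`, integer(1), "n_rules"),
                   c(0L, 1L, 1L, 1L, 2L, 2L, 2L))
})
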