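#' Coexpression rule
#'
#' A rule clamps one directed coexpression probability to a fixed value:
#' under rule `(X -> Y, p)`, exactly `round(p * n_X)` of the X-positive
#' cells in each realization are also Y-positive, instead of the overlap
#' emerging from independent assignment. A model is defined by its panel
#' plus a (possibly empty) list of rules; the empty list is the
#' independent-expression null model.
#'
#' @param source,target transmitter names (`source != target`).
#' @param probability clamped directed probability in `[0, 1]`.
#' @return An object of class `coexpr_rule`.
#' @examples
#' coexpr_rule("TK", "MIP", 1.0)    # every TK cell is MIP-positive
#' coexpr_rule("MIP", "Mas-AT", 0.42)
#' @export
coexpr_rule <- function(source, target, probability) {
  source <- as.character(source); target <- as.character(target)
  if (identical(source, target)) stop("rule source and target must differ")
  if (!is.finite(probability) || probability < 0 || probability > 1)
    stop("rule probability must be in [0, 1]")
  structure(list(source = source, target = target,
                 probability = as.numeric(probability)),
            class = "coexpr_rule")
}

#' @export
print.coexpr_rule <- function(x, ...) {
  cat(sprintf("rule %s -> %s @ %g\n", x$source, x$target, x$probability))
  invisible(x)
}

#' @export
format.coexpr_rule <- function(x, ...)
  sprintf("%s->%s@%g", x$source, x$target, x$probability)

validate_rules <- function(rules, panel) {
  if (is.null(rules)) return(list())
  if (inherits(rules, "coexpr_rule")) rules <- list(rules)
  if (!all(vapply(rules, inherits, logical(1), "coexpr_rule")))
    stop("rules must be coexpr_rule objects")
  key <- vapply(rules, function(r) paste(r$source, r$target, sep = "->"),
                character(1))
  if (anyDuplicated(key))
    stop("duplicate rule for pair ", key[duplicated(key)][1])
  tr <- panel$transmitter
  for (r in rules)
    if (!(r$source %in% tr) || !(r$target %in% tr))
      stop("rule ", format(r), " references a transmitter absent from the panel")
  rules
}

#' Fit a Monte Carlo coexpression model
#'
#' Runs the stochastic coexpression model defined by a transmitter panel
#' and an optional rule list for `n_iterations` Monte Carlo iterations,
#' and records the mean and standard deviation of every directed pairwise
#' coexpression ratio across iterations. With no rules this is the
#' independent-expression null model; each rule clamps one directed
#' probability to a fixed value (see [coexpr_rule()]).
#'
#' Reproducibility: the RNG stream of iteration `i` is seeded
#' deterministically with `seed + i`, so results are bit-identical for a
#' given `(panel, rules, n_iterations, seed)` and independent of how
#' iterations might be chunked.
#'
#' Pairs whose source set is empty in an iteration are skipped for that
#' iteration (their skip count is `n_iterations - n_defined`); a pair
#' undefined in every iteration is reported as `NA`.
#'
#' @param panel a [transmitter_panel()].
#' @param rules optional list of [coexpr_rule()] objects (default: none).
#' @param n_iterations number of Monte Carlo iterations (default 10000).
#' @param seed integer seed; mandatory so no run is silently wall-clock
#'   seeded.
#' @param label optional model label used in reports and rankings.
#' @return An object of class `coexpr_model` with components `mean`, `sd`
#'   (square matrices of per-pair ratio means/SDs across iterations, rows =
#'   source), `n_defined`, `panel`, `rules`, `n_iterations`, `seed`,
#'   `label`, `rule_log` (messages from rule capping/conflicts, with
#'   multiplicities).
#' @examples
#' panel <- transmitter_panel(c("A", "B"), c(10, 4), c(0, 0),
#'                            population_mean = 10)
#' fit <- coexpr_model(panel, n_iterations = 50, seed = 1)
#' coef(fit)["B", "A"]  # every B cell is A-positive: 1
#' @export
coexpr_model <- function(panel, rules = NULL, n_iterations = 10000,
                         seed, label = NULL) {
  stopifnot(inherits(panel, "transmitter_panel"))
  if (missing(seed)) stop("an explicit integer seed is required")
  seed <- as.integer(seed)
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  rules <- validate_rules(rules, panel)
  if (is.null(label))
    label <- if (length(rules) == 0) "independent" else
      paste(vapply(rules, format, character(1)), collapse = "+")

  k <- nrow(panel)
  tr <- panel$transmitter
  s1 <- matrix(0, k, k, dimnames = list(tr, tr))
  s2 <- matrix(0, k, k, dimnames = list(tr, tr))
  ndef <- matrix(0L, k, k, dimnames = list(tr, tr))
  log_all <- character(0)
  for (i in seq_len(n_iterations)) {
    set.seed(seed + i)
    M <- simulate_population(panel, rules)
    r <- coexpression_ratios(M)$ratio
    ok <- !is.na(r)
    s1[ok] <- s1[ok] + r[ok]
    s2[ok] <- s2[ok] + r[ok]^2
    ndef <- ndef + ok
    log_all <- c(log_all, attr(M, "rule_log"))
  }
  mean_r <- s1 / ndef
  mean_r[ndef == 0L] <- NA_real_
  var_r <- (s2 - s1^2 / ndef) / pmax(ndef - 1L, 1L)
  sd_r <- sqrt(pmax(var_r, 0))
  sd_r[ndef == 0L] <- NA_real_
  structure(list(mean = mean_r, sd = sd_r, n_defined = ndef,
                 panel = panel, rules = rules,
                 n_iterations = n_iterations, seed = seed, label = label,
                 rule_log = table(log_all)),
            class = "coexpr_model")
}

#' @export
print.coexpr_model <- function(x, digits = 3, ...) {
  cat("Monte Carlo coexpression model:", x$label, "\n")
  cat("  ", nrow(x$panel), " transmitters, population ",
      population_mean(x$panel),
      if (population_sd(x$panel) > 0)
        paste0(" (sd ", population_sd(x$panel), ")") else "",
      ", ", x$n_iterations, " iterations, seed ", x$seed, "\n", sep = "")
  if (length(x$rules))
    cat("  rules:", paste(vapply(x$rules, format, character(1)),
                          collapse = ", "), "\n")
  cat("Mean directed ratios (rows = source):\n")
  print(round(x$mean, digits))
  invisible(x)
}

#' @export
coef.coexpr_model <- function(object, ...) object$mean

#' @export
summary.coexpr_model <- function(object, ...) {
  tr <- rownames(object$mean)
  pairs <- expand.grid(source = tr, target = tr, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  out <- data.frame(pairs,
                    mean = object$mean[cbind(pairs$source, pairs$target)],
                    sd = object$sd[cbind(pairs$source, pairs$target)],
                    n_defined = object$n_defined[cbind(pairs$source,
                                                       pairs$target)],
                    row.names = NULL)
  attr(out, "label") <- object$label
  attr(out, "n_iterations") <- object$n_iterations
  class(out) <- c("summary.coexpr_model", "data.frame")
  out
}

#' @export
print.summary.coexpr_model <- function(x, digits = 4, ...) {
  cat("Model", attr(x, "label"), "-", attr(x, "n_iterations"),
      "iterations; per-pair ratio summaries:\n")
  y <- as.data.frame(x)
  y$mean <- round(y$mean, digits)
  y$sd <- round(y$sd, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Simulate population realizations from a fitted model
#'
#' Draws `nsim` fresh cell-population matrices under the model's panel and
#' rules, using the model's per-iteration seeding scheme offset so that
#' simulated realizations are reproducible but distinct from the fitting
#' iterations.
#'
#' @param object a `coexpr_model`.
#' @param nsim number of realizations.
#' @param seed optional integer overriding the derived seed offset.
#' @param ... unused.
#' @return A list of logical membership matrices (see
#'   [simulate_population()]).
#' @export
simulate.coexpr_model <- function(object, nsim = 1, seed = NULL, ...) {
  base <- if (is.null(seed)) object$seed + object$n_iterations else
    as.integer(seed)
  lapply(seq_len(nsim), function(i) {
    set.seed(base + i)
    simulate_population(object$panel, object$rules)
  })
}

#' Heatmap of a model's mean coexpression ratios
#'
#' @param x a `coexpr_model`.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.coexpr_model <- function(x, main = x$label, ...) {
  m <- x$mean
  k <- nrow(m)
  graphics::image(seq_len(k), seq_len(k), t(m[k:1, , drop = FALSE]),
                  axes = FALSE, xlab = "target", ylab = "source",
                  main = main, zlim = c(0, 1), ...)
  graphics::axis(1, at = seq_len(k), labels = colnames(m), las = 2)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(m)), las = 1)
  graphics::box()
  invisible(x)
}

#' Enumerate rule-combination model specifications
#'
#' Builds the model sweep used for rule selection: every subset of the
#' candidate rule pool of size `0 .. max_rules` defines one model; the
#' empty subset is the independent-expression model. Subsets are ordered
#' deterministically: by size, then lexicographically by rule index within
#' the pool.
#'
#' @param rule_pool list of candidate [coexpr_rule()] objects.
#' @param max_rules largest number of rules per model (>= 0).
#' @param panel the [transmitter_panel()] each spec will be fitted with.
#' @return A list of model specs; each spec is a list with `rules`,
#'   `n_rules` and `label`. Pass a spec's rules to [coexpr_model()], or use
#'   [rank_models()] to fit and rank the whole sweep.
#' @examples
#' pool <- list(coexpr_rule("A", "B", 0.5), coexpr_rule("B", "C", 0.2))
#' length(rule_models(pool, 1, transmitter_panel(c("A","B","C"),
#'        c(5,5,5), c(0,0,0), 20)))  # 1 + choose(2,1) = 3
#' @export
rule_models <- function(rule_pool, max_rules, panel) {
  if (max_rules < 0) stop("max_rules must be >= 0")
  for (r in rule_pool) validate_rules(list(r), panel)
  n <- length(rule_pool)
  specs <- list(list(rules = list(), n_rules = 0L, label = "independent"))
  for (size in seq_len(min(max_rules, n))) {
    idx <- utils::combn(n, size, simplify = FALSE)
    for (ii in idx) {
      rules <- rule_pool[ii]
      specs[[length(specs) + 1L]] <- list(
        rules = rules, n_rules = length(ii),
        label = paste(vapply(rules, format, character(1)), collapse = "+"))
    }
  }
  specs
}
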