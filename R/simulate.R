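#' Draw an integer cell count
#'
#' Draws one cell count from `Normal(mean, sd)`, rounds to the nearest
#' integer and clips to `[0, population]`. With `sd = 0` the draw is
#' deterministic: `round(mean)`. Uses the current RNG state.
#'
#' @param mean,sd count distribution parameters (`mean >= 0`, `sd >= 0`).
#' @param population upper clip bound (>= 1); `mean > population` is an
#'   error because such a panel is inconsistent with its population.
#' @return An integer in `[0, population]`.
#' @export
draw_count <- function(mean, sd, population) {
  if (mean < 0 || sd < 0) stop("mean and sd must be >= 0")
  if (population < 1) stop("population must be >= 1")
  if (mean > population)
    stop("count mean (", mean, ") exceeds population (", population, ")")
  x <- if (sd == 0) mean else stats::rnorm(1L, mean, sd)
  as.integer(min(population, max(0, round(x))))
}

#' Assign transmitter-positive labels to cells
#'
#' Chooses a uniformly random subset of exactly `count` cells out of
#' `n_cells`, without replacement (the random-assignment step of the
#' independent-expression model).
#'
#' @param n_cells population size.
#' @param count number of positive cells (`0 <= count <= n_cells`).
#' @return Integer vector of cell indices (possibly empty).
#' @export
assign_cells <- function(n_cells, count) {
  if (count < 0 || count > n_cells)
    stop("count must be in [0, n_cells]")
  if (count == 0L) return(integer(0))
  sample.int(n_cells, count)
}

## Applies one clamping rule (X -> Y, p) to the membership matrix under
## construction. Exactly round(p * n_X) X-positive cells are made
## Y-positive; the remaining Y quota goes to cells that are neither
## X-positive nor already Y-positive, so the realized ratio X -> Y is
## round(p * n_X) / n_X exactly. Returns the matrix plus a log of
## capped/inflated quotas and rule conflicts.
apply_rule <- function(M, assigned, counts, rule) {
  log <- character(0)
  x <- rule$source
  y <- rule$target
  if (!assigned[x])
    stop("rule source '", x, "' is not assigned before its rule fires; ",
         "reorder the rules so sources precede the rules that use them")
  x_cells <- which(M[, x])
  n_x <- length(x_cells)
  forced <- as.integer(round(rule$probability * n_x))
  if (forced > counts[y]) {
    log <- c(log, paste0("rule ", x, "->", y, ": forced count ", forced,
                         " exceeds drawn count ", counts[y],
                         "; target count inflated"))
    counts[y] <- forced
  }
  if (!assigned[y]) {
    if (forced > 0L)
      M[x_cells[sample.int(n_x, forced)], y] <- TRUE
    residual <- counts[y] - forced
    avail <- which(!M[, x] & !M[, y])
    if (residual > length(avail)) {
      log <- c(log, paste0("rule ", x, "->", y, ": residual quota ",
                           residual, " capped at ", length(avail),
                           " available non-", x, " cells"))
      residual <- length(avail)
      counts[y] <- forced + residual
    }
    if (residual > 0L)
      M[avail[sample.int(length(avail), residual)], y] <- TRUE
    assigned[y] <- TRUE
  } else {
    ## Y was already built by an earlier rule: memberships are set-only, so
    ## we can raise the X/Y overlap toward the forced count but never lower
    ## it. A surplus overlap is reported, not corrected.
    cur <- sum(M[, x] & M[, y])
    if (cur < forced) {
      pool <- which(M[, x] & !M[, y])
      add <- min(forced - cur, length(pool))
      if (add > 0L)
        M[pool[sample.int(length(pool), add)], y] <- TRUE
      counts[y] <- sum(M[, y])
      if (add < forced - cur)
        log <- c(log, paste0("rule ", x, "->", y,
                             ": could not reach forced overlap"))
    } else if (cur > forced) {
      log <- c(log, paste0("rule ", x, "->", y, ": overlap ", cur,
                           " from earlier rules exceeds forced ", forced,
                           "; left as is (set-only semantics)"))
    }
  }
  list(M = M, assigned = assigned, counts = counts, log = log)
}

#' Simulate one realization of the cell population
#'
#' Draws a population size and per-transmitter counts from the panel, then
#' assigns transmitter-positive labels to cells. Without rules every
#' transmitter is assigned independently and uniformly at random
#' (the independent-expression null model). With rules, rule-source
#' transmitters are assigned first (in rule order), then each rule clamps
#' its target's coexpression with its source (see [coexpr_rule()]), then
#' the remaining transmitters are assigned independently.
#'
#' Uses the current RNG state; seed management lives in [coexpr_model()].
#'
#' @param panel a [transmitter_panel()].
#' @param rules optional list of [coexpr_rule()] objects.
#' @return A logical matrix of `n_cells` rows x transmitters columns, with
#'   attributes `counts` (realized column sums), `drawn_counts` (counts as
#'   drawn, before any rule capping/inflation) and `rule_log` (character
#'   vector of capping/conflict messages, empty when clean).
#' @export
simulate_population <- function(panel, rules = NULL) {
  rules <- validate_rules(rules, panel)
  tr <- panel$transmitter
  pop_sd <- population_sd(panel)
  n <- if (pop_sd == 0) as.integer(round(population_mean(panel)))
       else max(1L, as.integer(round(stats::rnorm(1L, population_mean(panel),
                                                  pop_sd))))
  counts <- vapply(seq_along(tr), function(i)
    draw_count(min(panel$count_mean[i], n), panel$count_sd[i], n),
    integer(1))
  names(counts) <- tr
  drawn <- counts
  M <- matrix(FALSE, nrow = n, ncol = length(tr), dimnames = list(NULL, tr))
  assigned <- stats::setNames(rep(FALSE, length(tr)), tr)
  log <- character(0)

  sources <- unique(vapply(rules, `[[`, character(1), "source"))
  for (s in sources) {
    M[assign_cells(n, counts[s]), s] <- TRUE
    assigned[s] <- TRUE
  }
  for (rule in rules) {
    res <- apply_rule(M, assigned, counts, rule)
    M <- res$M; assigned <- res$assigned; counts <- res$counts
    log <- c(log, res$log)
  }
  for (s in tr[!assigned]) {
    M[assign_cells(n, counts[s]), s] <- TRUE
    assigned[s] <- TRUE
  }
  attr(M, "counts") <- colSums(M)
  attr(M, "drawn_counts") <- drawn
  attr(M, "rule_log") <- log
  M
}

#' Directed pairwise coexpression ratios of a cell matrix
#'
#' For every ordered transmitter pair (X, Y), computes
#' `ratio(X -> Y) = |X intersect Y| / |X|`: the fraction of X-positive
#' cells that are also Y-positive. Pairs whose source set is empty are
#' `NA` (undefined) and are skipped by downstream averaging.
#'
#' @param matrix logical cells x transmitters membership matrix.
#' @return An object of class `coexpr_ratios`: list with `ratio` (square
#'   matrix, rows = source), `overlap` (symmetric integer matrix of
#'   pairwise overlap counts), `counts` (per-transmitter positive counts)
#'   and `n_cells`.
#' @export
coexpression_ratios <- function(matrix) {
  if (is.data.frame(matrix)) matrix <- as.matrix(matrix)
  if (!is.logical(matrix)) {
    if (!all(matrix %in% c(0, 1)))
      stop("membership matrix must be boolean")
    storage.mode(matrix) <- "logical"
  }
  ov <- crossprod(matrix * 1L)
  cnt <- diag(ov)
  ratio <- sweep(ov, 1L, cnt, "/")
  ratio[cnt == 0L, ] <- NA_real_
  structure(list(ratio = ratio, overlap = ov, counts = cnt,
                 n_cells = nrow(matrix)),
            class = "coexpr_ratios")
}

#' @export
print.coexpr_ratios <- function(x, digits = 3, ...) {
  cat("Directed coexpression ratios (rows = source) over", x$n_cells,
      "cells\n")
  print(round(x$ratio, digits))
  invisible(x)
}
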