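## Half-up rounding (round() in R rounds half to even, which is the wrong
## convention for matching printed percentages like 84.6).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

## Brute-force search for an integer pair (k, n): n inside the allowed
## count window (candidates ordered by distance from the target count),
## k in 0..n, such that 100*k/n rounds (half-up, 1 decimal) exactly to the
## printed percentage. Printed 100% forces k = n; printed 0% forces k = 0.
## Returns list(n, k) for the first feasible n, with k minimizing
## |100*k/n - printed| (ties -> smaller k), or NULL.
search_count_ratio <- function(percents, window, target_n, digits = 1) {
  cand <- window[order(abs(window - target_n), window)]
  for (n in cand) {
    ks <- vapply(percents, function(p) best_k(p, n, digits), numeric(1))
    if (!anyNA(ks)) return(list(n = n, k = as.integer(ks)))
  }
  NULL
}

best_k <- function(percent, n, digits = 1) {
  if (percent == 100) return(n)
  if (percent == 0) return(0)
  k0 <- percent * n / 100
  ks <- max(0, floor(k0) - 2):min(n, ceiling(k0) + 2)
  ok <- ks[round_half_up(100 * ks / n, digits) ==
             round_half_up(percent, digits)]
  if (!length(ok)) return(NA_real_)
  ok[which.min(abs(100 * ok / n - percent))]
}

count_window <- function(mean, sd, replicates, n_max, widen = 1) {
  lo <- max(1, ceiling(replicates * (mean - widen * sd)))
  hi <- min(n_max, floor(replicates * (mean + widen * sd)))
  if (sd == 0) lo <- hi <- max(1, min(n_max, round(replicates * mean)))
  if (lo > hi) integer(0) else seq.int(lo, hi)
}

#' Reconstruct a per-cell fixture from published summary percentages
#'
#' Builds a deterministic boolean cells x transmitters matrix, at a pooled
#' scale of `replicates` ALs, whose per-transmitter counts lie inside
#' `replicates * (mean +- sd)` for the five neuropeptides and whose
#' recomputed directed coexpression percentages, rounded half-up to one
#' decimal, equal every published percentage: the five GABA-coexpression
#' percentages, TK -> MIP = 100, TK -> FMRF = 0, TK -> Mas-AT = 0,
#' MIP -> Mas-AT = 42 and Mas-AT -> FMRF = 22.
#'
#' Construction: for each constrained source an integer count `n` and
#' overlap `k` are found by brute-force search (window widened once to
#' +-2 sd if needed, then a hard error names the infeasible pair);
#' memberships are then placed greedily in a fixed deterministic order
#' (no RNG): TK first, fully nested in MIP and disjoint from FMRF and
#' Mas-AT; then the MIP/Mas-AT and Mas-AT/FMRF overlaps; then the GABA
#' overlaps, solved region by region.
#'
#' The GABA column is an exception: the published GABA total (~170 per AL)
#' cannot contain the published >= 84.6-97.5% GABA coexpression of all
#' five peptide populations simultaneously (their union alone needs close
#' to 300 GABA-positive cells per AL), so the published summary numbers
#' are mutually inconsistent there. Since GABA is never the *source* of a
#' published percentage, the fixture sets the GABA column to exactly the
#' union of the required overlap cells; the realized GABA count is
#' reported in the manifest.
#'
#' Pairs never measured (FMRF/MIP and all AST-A peptide pairs) are left
#' unconstrained — disjoint by construction — and flagged in the manifest.
#'
#' @param panel a [transmitter_panel()] with the six transmitters; default
#'   the packaged published panel.
#' @param ratios data frame of printed directed percentages
#'   (`source,target,percent`); default the packaged table
#'   ([observed_ratios()] without derived rows).
#' @param replicates pooling scale (default 12: both ALs of 6 brains).
#'   Per-AL integer counts cannot realize percentages like 84.6% at
#'   n ~ 12, and the published ratios were themselves computed from
#'   pooled counts.
#' @return An object of class `coexpr_fixture`: list with `matrix` (the
#'   boolean membership matrix), `counts`, `replicates`, `manifest`
#'   (per-constraint `(k, n)` solutions, realized GABA count,
#'   unconstrained-pair flags).
#' @examples
#' fx <- reconstruct_fixture()
#' r <- coexpression_ratios(fx$matrix)
#' round(100 * r$ratio["TK", "GABA"], 1)  # 84.6
#' @export
reconstruct_fixture <- function(panel = observed_panel(),
                                ratios = observed_ratios(derived = FALSE),
                                replicates = 12) {
  if (replicates < 1) stop("replicates must be >= 1")
  need <- c("TK", "FMRF", "Mas-AT", "MIP", "AST-A", "GABA")
  if (!all(need %in% panel$transmitter))
    stop("fixture reconstruction needs transmitters: ",
         paste(need, collapse = ", "))
  n_cells <- as.integer(round(replicates * population_mean(panel)))
  cm <- stats::setNames(panel$count_mean, panel$transmitter)
  cs <- stats::setNames(panel$count_sd, panel$transmitter)

  pct <- function(s, t) {
    row <- ratios$source == s & ratios$target == t
    if (!any(row)) stop("printed ratio ", s, " -> ", t, " missing")
    ratios$percent[row][1]
  }
  ## constrained targets per source (order fixed: GABA first, then peptide)
  spec <- list(
    "TK" = c(GABA = pct("TK", "GABA"), MIP = pct("TK", "MIP"),
             FMRF = pct("TK", "FMRF"), "Mas-AT" = pct("TK", "Mas-AT")),
    "FMRF" = c(GABA = pct("FMRF", "GABA")),
    "Mas-AT" = c(GABA = pct("Mas-AT", "GABA"),
                 FMRF = pct("Mas-AT", "FMRF")),
    "MIP" = c(GABA = pct("MIP", "GABA"), "Mas-AT" = pct("MIP", "Mas-AT")),
    "AST-A" = c(GABA = pct("AST-A", "GABA")))

  sol <- list()
  for (s in names(spec)) {
    found <- NULL
    for (widen in c(1, 2)) {
      win <- count_window(cm[s], cs[s], replicates, n_cells, widen)
      if (!length(win)) next
      found <- search_count_ratio(spec[[s]], win, replicates * cm[s])
      if (!is.null(found)) break
    }
    if (is.null(found))
      stop("no integer (k, n) reproduces the printed percentages for ",
           "source ", s, " (", paste(names(spec[[s]]), "=", spec[[s]],
                                     collapse = ", "),
           ") within the count window, even widened to +-2 sd")
    names(found$k) <- names(spec[[s]])
    sol[[s]] <- found
  }

  n_tk <- sol$TK$n; n_fm <- sol$FMRF$n; n_ma <- sol[["Mas-AT"]]$n
  n_mi <- sol$MIP$n; n_as <- sol[["AST-A"]]$n
  k_tk_g <- sol$TK$k[["GABA"]]
  k_fm_g <- sol$FMRF$k[["GABA"]]
  k_ma_g <- sol[["Mas-AT"]]$k[["GABA"]]
  k_mi_g <- sol$MIP$k[["GABA"]]
  k_as_g <- sol[["AST-A"]]$k[["GABA"]]
  k_mm <- sol$MIP$k[["Mas-AT"]]        # |MIP & Mas-AT|
  k_mf <- sol[["Mas-AT"]]$k[["FMRF"]]  # |Mas-AT & FMRF|
  if (sol$TK$k[["MIP"]] != n_tk || sol$TK$k[["FMRF"]] != 0 ||
      sol$TK$k[["Mas-AT"]] != 0)
    stop("TK constraints must be all-or-none (100 / 0 / 0)")
  if (k_mm > n_mi - n_tk)
    stop("MIP & Mas-AT overlap does not fit outside the TK-nested cells")
  if (k_mm + k_mf > n_ma)
    stop("Mas-AT overlaps with MIP and FMRF exceed the Mas-AT count")
  if (k_mf > n_fm) stop("Mas-AT & FMRF overlap exceeds the FMRF count")

  ## deterministic cell layout (disjoint index blocks)
  blk <- function(from, len) if (len > 0) seq.int(from, from + len - 1)
         else integer(0)
  r1 <- blk(1, n_tk)                         # TK (inside MIP)
  r2 <- blk(n_tk + 1, k_mm)                  # MIP & Mas-AT
  r3 <- blk(n_tk + k_mm + 1, n_mi - n_tk - k_mm)   # MIP only
  r4 <- blk(n_mi + 1, k_mf)                  # Mas-AT & FMRF (outside MIP)
  r5 <- blk(n_mi + k_mf + 1, n_ma - k_mm - k_mf)   # Mas-AT only
  r6 <- blk(n_mi + (n_ma - k_mm) + 1, n_fm - k_mf) # FMRF only
  r7 <- blk(n_mi + (n_ma - k_mm) + (n_fm - k_mf) + 1, n_as)  # AST-A only
  used <- n_mi + (n_ma - k_mm) + (n_fm - k_mf) + n_as
  if (used > n_cells)
    stop("fixture needs ", used, " cells but the pooled population is ",
         n_cells)

  ## GABA overlap per region: g_i cells of region i are GABA-positive,
  ## solved so every per-source GABA overlap is exact.
  cap <- vapply(list(r1, r2, r3, r4, r5, r6, r7), length, integer(1))
  g1 <- k_tk_g
  if (g1 > cap[1]) stop("TK & GABA overlap exceeds the TK count")
  g7 <- k_as_g
  if (g7 > cap[7]) stop("AST-A & GABA overlap exceeds the AST-A count")
  g2_lo <- max(0, (k_mi_g - g1) - cap[3])
  g2_hi <- min(cap[2], k_mi_g - g1)
  if (g2_lo > g2_hi) stop("MIP & GABA overlap cannot be placed")
  g4_lo <- max(0, k_fm_g - cap[6])
  g4_hi <- min(cap[4], k_fm_g)
  ## Mas-AT residual masres = k_ma_g - g2 must split as g4 + g5
  mres_lo <- g4_lo
  mres_hi <- g4_hi + cap[5]
  g2 <- min(g2_hi, max(g2_lo, k_ma_g - mres_hi))
  mres <- k_ma_g - g2
  if (mres < mres_lo || mres > mres_hi)
    stop("Mas-AT & GABA overlap cannot be placed")
  g4 <- max(g4_lo, mres - cap[5])
  if (g4 > g4_hi) stop("FMRF & GABA overlap cannot be placed")
  g5 <- mres - g4
  g6 <- k_fm_g - g4
  g3 <- k_mi_g - g1 - g2
  gs <- c(g1, g2, g3, g4, g5, g6, g7)
  if (any(gs < 0) || any(gs > cap))
    stop("GABA overlap placement infeasible")

  tr <- c("TK", "FMRF", "Mas-AT", "MIP", "AST-A", "GABA")
  M <- matrix(FALSE, n_cells, length(tr), dimnames = list(NULL, tr))
  M[r1, "TK"] <- TRUE
  M[c(r1, r2, r3), "MIP"] <- TRUE
  M[c(r2, r4, r5), "Mas-AT"] <- TRUE
  M[c(r4, r6), "FMRF"] <- TRUE
  M[r7, "AST-A"] <- TRUE
  regions <- list(r1, r2, r3, r4, r5, r6, r7)
  for (i in seq_along(regions))
    if (gs[i] > 0) M[regions[[i]][seq_len(gs[i])], "GABA"] <- TRUE

  ## verify every printed percentage at 1-decimal rounding
  rr <- coexpression_ratios(M)
  for (s in names(spec)) for (t in names(spec[[s]])) {
    got <- round_half_up(100 * rr$ratio[s, t], 1)
    want <- round_half_up(spec[[s]][[t]], 1)
    if (!isTRUE(all.equal(got, want)))
      stop("fixture verification failed: ", s, " -> ", t, " is ", got,
           " not ", want)
  }

  manifest <- list(
    replicates = replicates,
    n_cells = n_cells,
    counts = as.list(colSums(M)),
    solutions = lapply(sol, function(x) list(n = x$n, k = as.list(x$k))),
    gaba_count_note = paste0(
      "GABA column is the union of required overlaps (",
      sum(M[, "GABA"]), " cells, ~", round(sum(M[, "GABA"]) / replicates),
      " per AL); the published ~170 per AL cannot hold the published ",
      "coexpression percentages simultaneously"),
    unconstrained_pairs = c("FMRF/MIP (never measured; disjoint here)",
                            "AST-A with every peptide (never measured; disjoint here)"),
    deterministic = TRUE)
  structure(list(matrix = M, counts = colSums(M), replicates = replicates,
                 manifest = manifest),
            class = "coexpr_fixture")
}

#' @export
print.coexpr_fixture <- function(x, ...) {
  cat("Reconstructed per-cell fixture:", nrow(x$matrix), "cells (",
      x$replicates, "pooled ALs )\n")
  cat("Counts:\n")
  print(x$counts)
  cat("Recomputed percentages (rows = source):\n")
  print(round_half_up(100 * coexpression_ratios(x$matrix)$ratio, 1))
  invisible(x)
}

#' Observed reference table built from the fixture
#'
#' Combines the fixture's recomputed directed ratios and overlap counts
#' (rescaled to per-AL) with externally supplied per-pair standard
#' deviations (the published data never include per-pair SDs across
#' brains, so SDs must come from synthetic replicates or the user; see
#' [summarize_replicates()]).
#'
#' @param fixture a [reconstruct_fixture()] result.
#' @param sds a data frame with columns `source`, `target`, `sd` (ratio
#'   SDs on the proportion scale), e.g. the `ratio_summary` of
#'   [summarize_replicates()].
#' @return A [coexpr_observed()] table with per-AL overlap counts.
#' @export
fixture_observed <- function(fixture, sds) {
  rr <- coexpression_ratios(fixture$matrix)
  tr <- rownames(rr$ratio)
  pairs <- expand.grid(source = tr, target = tr, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  idx <- cbind(pairs$source, pairs$target)
  key <- function(s, t) paste(s, t, sep = "->")
  sd_map <- stats::setNames(sds$sd, key(sds$source, sds$target))
  coexpr_observed(pairs$source, pairs$target,
                  mean = rr$ratio[idx],
                  sd = sd_map[key(pairs$source, pairs$target)],
                  overlap = rr$overlap[idx] / fixture$replicates)
}
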