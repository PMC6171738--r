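#' Standard deviation index (SDI)
#'
#' Z-score-like discrepancy between a model's predicted mean coexpression
#' ratio and the observed one, scaled by the larger of the two standard
#' deviations:
#' `SDI = |mean_model - mean_observed| / max(sd_model, sd_observed)`.
#'
#' Interpretation scale: 0 = perfect consensus between model and data;
#' values up to 1 = the model is within one standard deviation of the
#' data and replicates it reasonably well; values of 2 or more = the
#' model does not replicate the data accurately.
#'
#' The absolute difference is used so per-pair indices are magnitudes and
#' cannot cancel when summed in [weighted_sdi()].
#'
#' @param mean_model,mean_observed per-pair mean ratios.
#' @param sd_model,sd_observed standard deviations; at least one of the
#'   two must be positive unless the means are equal (both zero with
#'   unequal means leaves the index undefined and is an error).
#' @return Non-negative numeric (vectorized).
#' @examples
#' sdi(0.42, 0.42, 0.05, 0.03)  # 0: perfect consensus
#' sdi(0.50, 0.40, 0.05, 0.10)  # 1
#' @export
sdi <- function(mean_model, mean_observed, sd_model, sd_observed) {
  sg <- pmax(sd_model, sd_observed)
  diff <- abs(mean_model - mean_observed)
  bad <- !is.na(sg) & sg == 0 & !is.na(diff) & diff > 0
  if (any(bad))
    stop("SDI undefined: both standard deviations are 0 but means differ")
  out <- ifelse(!is.na(diff) & diff == 0, 0, diff / sg)
  out
}

#' Weighted SDI over a pair set
#'
#' Sums per-pair SDI values weighted by each pair's prevalence in the
#' population: `sum(sdi * n_coexpressed / n_total)`, where `n_coexpressed`
#' is the observed number of coexpressing cells for the pair. Pairs
#' involving a larger share of the population therefore dominate the
#' model's overall score.
#'
#' @param sdi_values per-pair SDI values (see [sdi()]).
#' @param overlap_counts observed coexpressing-cell count per pair; must be
#'   supplied for every pair.
#' @param n_total total population size the weights refer to (> 0).
#' @return A single non-negative number.
#' @examples
#' weighted_sdi(c(1, 0.5), c(12, 144), 360)  # 1*(12/360) + 0.5*(144/360)
#' @export
weighted_sdi <- function(sdi_values, overlap_counts, n_total) {
  if (length(sdi_values) == 0) stop("no pairs supplied")
  if (length(overlap_counts) != length(sdi_values) ||
      any(is.na(overlap_counts)))
    stop("an observed overlap count is required for every pair")
  if (!is.finite(n_total) || n_total <= 0) stop("n_total must be > 0")
  sum(sdi_values * overlap_counts / n_total)
}

#' Percent improvement over the independent-expression model
#'
#' `(1 - weighted_sdi_x / weighted_sdi_independent) * 100`; positive when
#' model x fits better (smaller weighted SDI) than the independent
#' reference, negative when it fits worse.
#'
#' @param weighted_sdi_x weighted SDI of the model under evaluation.
#' @param weighted_sdi_independent weighted SDI of the reference
#'   independent-expression model (> 0).
#' @return Percent improvement (may be negative).
#' @examples
#' percent_improvement(0.36, 1.49)  # 75.84
#' @export
percent_improvement <- function(weighted_sdi_x, weighted_sdi_independent) {
  if (any(!is.finite(weighted_sdi_independent)) ||
      any(weighted_sdi_independent <= 0))
    stop("reference weighted SDI must be > 0")
  (1 - weighted_sdi_x / weighted_sdi_independent) * 100
}

interpret_sdi <- function(x) {
  cut(x, breaks = c(-Inf, .Machine$double.eps, 1, 2, Inf),
      labels = c("perfect consensus", "within 1 sd (replicates well)",
                 "within 2 sd (poor)", "not replicated"))
}

#' Observed-coexpression reference table
#'
#' Packs observed per-pair means, standard deviations and overlap counts
#' into the reference table [sdi_report()] compares models against. SDs
#' come from biological replicates (or a synthetic regeneration, see
#' [summarize_replicates()]); overlap counts are the observed number of
#' coexpressing cells and give the weights, so weights are constant across
#' the models being compared.
#'
#' @param source,target transmitter names per pair.
#' @param mean observed mean directed ratio (proportion in `[0, 1]`).
#' @param sd observed across-replicate SD of the ratio (`NA` allowed; such
#'   pairs are excluded from reports and listed).
#' @param overlap observed coexpressing-cell count per pair.
#' @return A data frame of class `coexpr_observed`.
#' @export
coexpr_observed <- function(source, target, mean, sd, overlap) {
  out <- data.frame(source = as.character(source),
                    target = as.character(target),
                    mean = as.numeric(mean), sd = as.numeric(sd),
                    overlap = as.numeric(overlap),
                    stringsAsFactors = FALSE)
  if (any(!is.na(out$mean) & (out$mean < 0 | out$mean > 1)))
    stop("observed means must be proportions in [0, 1]")
  class(out) <- c("coexpr_observed", "data.frame")
  out
}

#' Score one model against observed coexpression
#'
#' Computes the per-pair SDI of a fitted model against an observed
#' reference table, the prevalence weights, the weighted SDI and (when a
#' reference weighted SDI is given) the percent improvement.
#'
#' Pairs are used when both the model and the observed table define them
#' (finite mean and SD on both sides, non-missing overlap); excluded pairs
#' are listed in the report.
#'
#' @param model a [coexpr_model()] fit.
#' @param observed a [coexpr_observed()] table.
#' @param n_total population size for the weights; defaults to 360
#'   regardless of the model's own population constraint so weights are
#'   comparable across constrained and unconstrained models.
#' @param reference optional reference weighted SDI (a number or a fitted
#'   `sdi_report`) for percent improvement.
#' @return An object of class `sdi_report`: list with `pairs` (per-pair
#'   data frame: mean_model, mean_obs, sd_model, sd_obs, sdi, weight,
#'   interpretation), `weighted_sdi`, `percent_improvement` (or `NA`),
#'   `excluded`, `label`, `n_rules`.
#' @export
sdi_report <- function(model, observed, n_total = 360, reference = NULL) {
  stopifnot(inherits(model, "coexpr_model"))
  obs <- observed[observed$source != observed$target, , drop = FALSE]
  idx <- cbind(obs$source, obs$target)
  known <- obs$source %in% rownames(model$mean) &
    obs$target %in% colnames(model$mean)
  mm <- sm <- rep(NA_real_, nrow(obs))
  mm[known] <- model$mean[idx[known, , drop = FALSE]]
  sm[known] <- model$sd[idx[known, , drop = FALSE]]
  usable <- known & is.finite(mm) & is.finite(sm) &
    is.finite(obs$mean) & is.finite(obs$sd) & !is.na(obs$overlap)
  excluded <- paste(obs$source[!usable], obs$target[!usable], sep = "->")
  obs <- obs[usable, , drop = FALSE]
  mm <- mm[usable]; sm <- sm[usable]
  if (nrow(obs) == 0) stop("no usable pairs shared by model and observed")
  sdi_v <- sdi(mm, obs$mean, sm, obs$sd)
  weight <- obs$overlap / n_total
  pairs <- data.frame(source = obs$source, target = obs$target,
                      mean_model = mm, mean_obs = obs$mean,
                      sd_model = sm, sd_obs = obs$sd,
                      sdi = sdi_v, weight = weight,
                      interpretation = interpret_sdi(sdi_v),
                      stringsAsFactors = FALSE)
  wsdi <- weighted_sdi(sdi_v, obs$overlap, n_total)
  ref <- if (inherits(reference, "sdi_report")) reference$weighted_sdi
         else reference
  structure(list(pairs = pairs, weighted_sdi = wsdi,
                 percent_improvement = if (is.null(ref)) NA_real_ else
                   percent_improvement(wsdi, ref),
                 reference_weighted_sdi = if (is.null(ref)) NA_real_ else ref,
                 excluded = excluded, label = model$label,
                 n_rules = length(model$rules), n_total = n_total),
            class = "sdi_report")
}

#' @export
print.sdi_report <- function(x, digits = 4, ...) {
  cat("SDI report for model:", x$label, "\n")
  p <- x$pairs
  p$mean_model <- round(p$mean_model, digits)
  p$sd_model <- round(p$sd_model, digits)
  p$sdi <- round(p$sdi, digits)
  p$weight <- round(p$weight, digits)
  print(p, row.names = FALSE)
  cat("Weighted SDI:", round(x$weighted_sdi, digits), "\n")
  if (!is.na(x$percent_improvement))
    cat("Improvement over reference (weighted SDI ",
        round(x$reference_weighted_sdi, digits), "): ",
        round(x$percent_improvement, 2), "%\n", sep = "")
  if (length(x$excluded))
    cat("Excluded pairs:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Fit and rank a sweep of models against observed coexpression
#'
#' Fits every model spec (see [rule_models()]), scores each against the
#' observed table with [sdi_report()], and ranks models by ascending
#' weighted SDI (best first). Ties break toward fewer rules, then label.
#' Percent improvement is reported relative to the zero-rule (independent)
#' model in the sweep when present.
#'
#' @param specs list of model specs from [rule_models()], or a list of
#'   already-fitted `coexpr_model` objects.
#' @param observed a [coexpr_observed()] table.
#' @param panel panel used to fit specs (ignored for pre-fitted models).
#' @param n_iterations,seed Monte Carlo settings per model fit; every model
#'   reuses the same per-iteration seed schedule, which cancels shared
#'   Monte Carlo noise between models.
#' @param n_total population size for the SDI weights (default 360).
#' @return An object of class `coexpr_ranking`: data frame with one row
#'   per model (`rank`, `label`, `n_rules`, `weighted_sdi`,
#'   `percent_improvement`), with the per-model `sdi_report`s in attribute
#'   `reports` (in ranked order).
#' @export
rank_models <- function(specs, observed, panel = NULL,
                        n_iterations = 10000, seed = 1, n_total = 360) {
  fits <- lapply(specs, function(sp) {
    if (inherits(sp, "coexpr_model")) return(sp)
    coexpr_model(panel, rules = sp$rules, n_iterations = n_iterations,
                 seed = seed, label = sp$label)
  })
  reports <- lapply(fits, sdi_report, observed = observed, n_total = n_total)
  wsdi <- vapply(reports, `[[`, numeric(1), "weighted_sdi")
  nr <- vapply(reports, `[[`, numeric(1), "n_rules")
  lab <- vapply(reports, `[[`, character(1), "label")
  ord <- order(wsdi, nr, lab)
  ref <- wsdi[match("independent", lab)]
  imp <- if (!is.na(ref) && ref > 0) percent_improvement(wsdi, ref)
         else rep(NA_real_, length(wsdi))
  out <- data.frame(rank = seq_along(ord), label = lab[ord],
                    n_rules = nr[ord], weighted_sdi = wsdi[ord],
                    percent_improvement = imp[ord],
                    stringsAsFactors = FALSE)
  attr(out, "reports") <- reports[ord]
  class(out) <- c("coexpr_ranking", "data.frame")
  out
}

#' @export
print.coexpr_ranking <- function(x, digits = 4, ...) {
  cat("Model ranking by weighted SDI (best first):\n")
  y <- as.data.frame(x)
  y$weighted_sdi <- round(y$weighted_sdi, digits)
  y$percent_improvement <- round(y$percent_improvement, 2)
  print(y, row.names = FALSE)
  invisible(x)
}
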