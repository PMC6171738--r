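#' Design a synthetic multi-replicate coexpression dataset
#'
#' A design specifies how synthetic per-cell expression data are
#' generated: a panel of per-transmitter count means and SDs (replicate
#' SDs default to the published across-specimen SDs), a list of planted
#' coexpression dependencies (rules, applied with the same clamping
#' semantics as in [coexpr_model()]), the number of biological replicates
#' (default 12: both ALs of 6 brains) and a seed.
#'
#' Optionally, a two-group sex-difference mode replaces one transmitter's
#' mean with group-specific means for the first and second half of the
#' replicates (off by default).
#'
#' @param panel a [transmitter_panel()] (default: the published panel).
#' @param planted_rules list of [coexpr_rule()] objects planted in every
#'   replicate; feasibility (`round(p * mean_X) <= mean_Y` at mean counts)
#'   is checked up front.
#' @param n_replicates number of replicate ALs.
#' @param seed integer seed; replicate `r` uses stream `seed + r`.
#' @param sex_groups optional list
#'   `list(transmitter =, mean_first =, mean_second =)` enabling the
#'   two-group mode.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(panel = observed_panel(), planted_rules = NULL,
                             n_replicates = 12, seed = 1,
                             sex_groups = NULL) {
  planted_rules <- validate_rules(planted_rules, panel)
  cm <- stats::setNames(panel$count_mean, panel$transmitter)
  for (r in planted_rules)
    if (round(r$probability * cm[r$source]) > cm[r$target])
      stop("planted rule ", format(r), " is infeasible at mean counts: ",
           "forced overlap ", round(r$probability * cm[r$source]),
           " exceeds mean target count ", cm[r$target])
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!is.null(sex_groups)) {
    stopifnot(all(c("transmitter", "mean_first", "mean_second") %in%
                    names(sex_groups)))
    if (!sex_groups$transmitter %in% panel$transmitter)
      stop("sex_groups transmitter not in panel")
  }
  structure(list(panel = panel, planted_rules = planted_rules,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), sex_groups = sex_groups),
            class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("Synthetic design:", x$n_replicates, "replicates, seed", x$seed, "\n")
  if (length(x$planted_rules))
    cat("  planted:", paste(vapply(x$planted_rules, format, character(1)),
                            collapse = ", "), "\n")
  else cat("  no planted dependencies (null design)\n")
  print(x$panel)
  invisible(x)
}

#' Generate replicate cell-population matrices from a design
#'
#' Draws one membership matrix per replicate: per-replicate counts come
#' from `Normal(mean, sd)` (rounded, clipped), planted rules are applied
#' with the clamping semantics of the rule engine, and everything is
#' reproducible from the design seed.
#'
#' @param design a [synthetic_design()].
#' @return A list of logical membership matrices of class
#'   `synthetic_replicates`, with the design attached as an attribute.
#' @export
generate_replicates <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  out <- lapply(seq_len(design$n_replicates), function(r) {
    set.seed(design$seed + r)
    panel <- design$panel
    sg <- design$sex_groups
    if (!is.null(sg)) {
      i <- match(sg$transmitter, panel$transmitter)
      panel$count_mean[i] <- if (r <= design$n_replicates / 2)
        sg$mean_first else sg$mean_second
    }
    simulate_population(panel, design$planted_rules)
  })
  attr(out, "design") <- design
  class(out) <- "synthetic_replicates"
  out
}

#' Summarize replicate matrices into panel and ratio statistics
#'
#' Computes, across replicates, the per-transmitter count mean/SD and the
#' per-pair directed-ratio mean/SD plus mean overlap count — the "observed"
#' summary a replicated experiment would report, in the form
#' [sdi_report()] consumes.
#'
#' Pairs undefined in a replicate (empty source) are skipped for that
#' replicate; a pair defined in fewer than 2 replicates has `NA` SD.
#'
#' @param replicates a list of membership matrices
#'   (e.g. from [generate_replicates()]).
#' @return List with `panel_summary` (data frame: transmitter, count_mean,
#'   count_sd), `ratio_summary` (data frame: source, target, mean, sd,
#'   overlap, n_defined) and `observed` (the same ratio summary as a
#'   [coexpr_observed()] table).
#' @export
summarize_replicates <- function(replicates) {
  counts <- do.call(rbind, lapply(replicates, colSums))
  tr <- colnames(counts)
  panel_summary <- data.frame(
    transmitter = tr,
    count_mean = colMeans(counts),
    count_sd = apply(counts, 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE)

  rs <- lapply(replicates, function(m) coexpression_ratios(m))
  ratio_arr <- vapply(rs, function(x) x$ratio,
                      matrix(0, length(tr), length(tr)))
  over_arr <- vapply(rs, function(x) x$overlap + 0,
                     matrix(0, length(tr), length(tr)))
  pairs <- expand.grid(source = tr, target = tr, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  i <- match(pairs$source, tr); j <- match(pairs$target, tr)
  stat <- function(f) mapply(function(a, b)
    f(ratio_arr[a, b, ][!is.na(ratio_arr[a, b, ])]), i, j)
  mean_r <- stat(function(v) if (length(v)) mean(v) else NA_real_)
  sd_r <- stat(function(v) if (length(v) >= 2) stats::sd(v) else NA_real_)
  ndef <- stat(length)
  over <- mapply(function(a, b) mean(over_arr[a, b, ]), i, j)
  ratio_summary <- data.frame(pairs, mean = mean_r, sd = sd_r,
                              overlap = over, n_defined = ndef,
                              row.names = NULL, stringsAsFactors = FALSE)
  list(panel_summary = panel_summary,
       ratio_summary = ratio_summary,
       observed = coexpr_observed(ratio_summary$source,
                                  ratio_summary$target,
                                  ratio_summary$mean, ratio_summary$sd,
                                  ratio_summary$overlap))
}

#' Write a synthetic dataset to CSV/JSON files
#'
#' One CSV per replicate (`cell_id` plus one boolean column per
#' transmitter), a `summary_panel.csv`, a `summary_ratios.csv` and a
#' `design.json` recording the panel, planted rules and seed.
#'
#' @param replicates a `synthetic_replicates` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_replicates <- function(replicates, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(replicates)) {
    m <- replicates[[r]]
    df <- data.frame(cell_id = seq_len(nrow(m)), m * 1L,
                     check.names = FALSE)
    utils::write.csv(df, file.path(dir, sprintf("replicate_%02d.csv", r)),
                     row.names = FALSE, quote = FALSE)
  }
  sm <- summarize_replicates(replicates)
  utils::write.csv(sm$panel_summary, file.path(dir, "summary_panel.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sm$ratio_summary, file.path(dir, "summary_ratios.csv"),
                   row.names = FALSE, quote = FALSE)
  design <- attr(replicates, "design")
  if (!is.null(design))
    jsonlite::write_json(list(
      seed = design$seed, n_replicates = design$n_replicates,
      panel = as.data.frame(design$panel),
      population_mean = population_mean(design$panel),
      population_sd = population_sd(design$panel),
      planted_rules = lapply(design$planted_rules, unclass)),
      file.path(dir, "design.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Planted-dependency recovery experiment
#'
#' End-to-end validation of the model-selection logic: generates
#' `n_datasets` synthetic datasets from a design, treats each dataset's
#' replicate summary as the observed data, ranks the candidate models
#' (independent model plus all rule combinations up to `max_rules` from
#' `rule_pool`) against it, and reports
#' \itemize{
#'   \item the fraction of datasets in which every model containing a
#'     planted rule outranks the independent model (`planted_outranks`,
#'     only when rules are planted), and
#'   \item the fraction in which the independent model's weighted SDI
#'     exceeds 1 (`independent_rejected`) — under a null design this
#'     should be a minority.
#' }
#'
#' Candidate models are fitted once (they depend only on the panel and
#' rules, not on the datasets) and reused across datasets.
#'
#' @param design a [synthetic_design()]; its planted rules must be
#'   contained in `rule_pool` when non-empty.
#' @param rule_pool list of candidate [coexpr_rule()] objects.
#' @param max_rules maximum rules per candidate model (default 1).
#' @param n_datasets number of synthetic datasets (default 100).
#' @param n_iterations Monte Carlo iterations per candidate model fit.
#' @param seed integer seed governing both model fits and dataset
#'   generation.
#' @param n_total population size for SDI weights (default 360).
#' @return An object of class `recovery_report`: list with
#'   `planted_outranks`, `independent_rejected`, `per_dataset` (data
#'   frame) and the settings.
#' @export
recovery_experiment <- function(design, rule_pool, max_rules = 1,
                                n_datasets = 100, n_iterations = 2000,
                                seed = 1, n_total = 360) {
  stopifnot(inherits(design, "synthetic_design"))
  pool_keys <- vapply(rule_pool, format, character(1))
  planted_keys <- vapply(design$planted_rules, format, character(1))
  if (length(planted_keys) && !all(planted_keys %in% pool_keys))
    stop("planted rules must be contained in rule_pool")
  specs <- rule_models(rule_pool, max_rules, design$panel)
  fits <- lapply(specs, function(sp)
    coexpr_model(design$panel, rules = sp$rules,
                 n_iterations = n_iterations, seed = seed,
                 label = sp$label))
  has_planted <- vapply(specs, function(sp) {
    k <- vapply(sp$rules, format, character(1))
    length(k) > 0 && all(planted_keys %in% k)
  }, logical(1))

  res <- lapply(seq_len(n_datasets), function(d) {
    ds <- design
    ds$seed <- design$seed + 100000L + d * design$n_replicates
    obs <- summarize_replicates(generate_replicates(ds))$observed
    reports <- lapply(fits, sdi_report, observed = obs, n_total = n_total)
    wsdi <- vapply(reports, `[[`, numeric(1), "weighted_sdi")
    ind <- wsdi[vapply(specs, function(sp) sp$n_rules == 0, logical(1))][1]
    data.frame(dataset = d, independent_wsdi = ind,
               best_label = fits[[which.min(wsdi)]]$label,
               planted_outranks = if (any(has_planted))
                 all(wsdi[has_planted] < ind) else NA)
  })
  per_dataset <- do.call(rbind, res)
  structure(list(
    planted_outranks = if (any(has_planted))
      mean(per_dataset$planted_outranks) else NA_real_,
    independent_rejected = mean(per_dataset$independent_wsdi > 1),
    per_dataset = per_dataset,
    n_datasets = n_datasets, n_iterations = n_iterations, seed = seed,
    planted = planted_keys),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery experiment over", x$n_datasets, "synthetic datasets\n")
  if (length(x$planted)) {
    cat("  planted:", paste(x$planted, collapse = ", "), "\n")
    cat("  planted-rule model outranks independent in ",
        round(100 * x$planted_outranks, 1), "% of datasets\n", sep = "")
  } else cat("  null design (no planted dependencies)\n")
  cat("  independent model weighted SDI > 1 in ",
      round(100 * x$independent_rejected, 1), "% of datasets\n", sep = "")
  invisible(x)
}
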