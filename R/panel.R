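#' Transmitter panel
#'
#' A transmitter panel holds, for each transmitter (neuropeptide or
#' classical transmitter), the mean and standard deviation of the number of
#' cells per antennal lobe (AL) that express it, together with the size of
#' the local-interneuron (LN) population the counts refer to. The panel is
#' the sampling frame of the Monte Carlo coexpression models: in each
#' iteration a count is drawn for every transmitter from
#' `Normal(count_mean, count_sd)` (rounded, clipped to the population) and
#' that many cells are labelled positive.
#'
#' @param transmitters character vector of unique transmitter names.
#' @param count_mean numeric vector of mean cell counts per AL (>= 0, one
#'   per transmitter, each <= `population_mean`).
#' @param count_sd numeric vector of count standard deviations (>= 0).
#' @param population_mean total number of LNs in the population (> 0).
#' @param population_sd standard deviation of the population size; the
#'   default 0 keeps the population fixed. A positive value makes each
#'   iteration draw its own population size (used for the GABA-constrained
#'   model variant where the total is itself variable).
#'
#' @return An object of class `transmitter_panel`: a data frame with
#'   columns `transmitter`, `count_mean`, `count_sd` and attributes
#'   `population_mean`, `population_sd`.
#' @examples
#' transmitter_panel(c("TK", "MIP"), c(12.16, 150.66), c(0.55, 16.79))
#' @export
transmitter_panel <- function(transmitters, count_mean, count_sd,
                              population_mean = 360, population_sd = 0) {
  transmitters <- as.character(transmitters)
  if (anyDuplicated(transmitters))
    stop("transmitter names must be unique")
  if (length(count_mean) != length(transmitters) ||
      length(count_sd) != length(transmitters))
    stop("count_mean and count_sd must have one entry per transmitter")
  count_mean <- as.numeric(count_mean)
  count_sd <- as.numeric(count_sd)
  if (any(!is.finite(count_mean)) || any(count_mean < 0))
    stop("count_mean must be finite and >= 0")
  if (any(!is.finite(count_sd)) || any(count_sd < 0))
    stop("count_sd must be finite and >= 0")
  if (!is.finite(population_mean) || population_mean <= 0)
    stop("population_mean must be > 0")
  if (!is.finite(population_sd) || population_sd < 0)
    stop("population_sd must be >= 0")
  if (any(count_mean > population_mean))
    stop("count_mean exceeds population_mean for: ",
         paste(transmitters[count_mean > population_mean], collapse = ", "))
  out <- data.frame(transmitter = transmitters,
                    count_mean = count_mean,
                    count_sd = count_sd,
                    stringsAsFactors = FALSE)
  attr(out, "population_mean") <- as.numeric(population_mean)
  attr(out, "population_sd") <- as.numeric(population_sd)
  class(out) <- c("transmitter_panel", "data.frame")
  out
}

#' @export
print.transmitter_panel <- function(x, ...) {
  cat("Transmitter panel:", nrow(x), "transmitters, population",
      attr(x, "population_mean"))
  if (attr(x, "population_sd") > 0)
    cat(" (sd ", attr(x, "population_sd"), ")", sep = "")
  cat("\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

population_mean <- function(panel) attr(panel, "population_mean")
population_sd <- function(panel) attr(panel, "population_sd")

#' Read or write a transmitter panel CSV
#'
#' The CSV has a required header `transmitter,count_mean,count_sd`; extra
#' columns (e.g. provenance notes) are preserved on read and written back.
#' The population size is not part of the CSV; it is supplied when the
#' panel is constructed.
#'
#' @param path file path.
#' @param population_mean,population_sd population size parameters attached
#'   to the panel on read (see [transmitter_panel()]).
#' @return `read_panel_csv()` returns a `transmitter_panel`;
#'   `write_panel_csv()` returns `path` invisibly.
#' @export
read_panel_csv <- function(path, population_mean = 360, population_sd = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("transmitter", "count_mean", "count_sd")
  if (!all(need %in% names(df)))
    stop("panel CSV must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$count_mean)) || any(df$count_mean < 0))
    stop("panel CSV: count_mean must be numeric and >= 0 (row ",
         which(!is.finite(df$count_mean) | df$count_mean < 0)[1], ")")
  if (any(!is.finite(df$count_sd)) || any(df$count_sd < 0))
    stop("panel CSV: count_sd must be numeric and >= 0 (row ",
         which(!is.finite(df$count_sd) | df$count_sd < 0)[1], ")")
  panel <- transmitter_panel(df$transmitter, df$count_mean, df$count_sd,
                             population_mean, population_sd)
  extra <- setdiff(names(df), need)
  for (nm in extra) panel[[nm]] <- df[[nm]]
  panel
}

#' @rdname read_panel_csv
#' @param panel a `transmitter_panel`.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' The published cell-count panel
#'
#' Returns the packaged panel of per-AL cell-count means and standard
#' deviations for the five neuropeptides (TK, FMRF, Mas-AT, MIP, AST-A)
#' plus GABA (~170 cells, no published SD), in a population of 360 LNs.
#'
#' @param include_gaba include the GABA row (default `TRUE`).
#' @param population_mean,population_sd see [transmitter_panel()].
#' @return A `transmitter_panel`.
#' @export
observed_panel <- function(include_gaba = TRUE, population_mean = 360,
                           population_sd = 0) {
  path <- system.file("extdata", "table1_panel.csv", package = "coexnull",
                      mustWork = TRUE)
  panel <- read_panel_csv(path, population_mean, population_sd)
  if (!include_gaba)
    panel <- panel[panel$transmitter != "GABA", , drop = FALSE]
  attr(panel, "population_mean") <- as.numeric(population_mean)
  attr(panel, "population_sd") <- as.numeric(population_sd)
  class(panel) <- c("transmitter_panel", "data.frame")
  panel
}

#' Derive the reverse of a directed coexpression ratio
#'
#' The directed ratio `ratio(X -> Y)` is the fraction of X-positive cells
#' that are also Y-positive, so the overlap identity
#' `ratio(X -> Y) * n_X = |X intersect Y| = ratio(Y -> X) * n_Y`
#' determines the reverse ratio from the forward one and the two counts.
#'
#' @param ratio_xy forward ratio in `[0, 1]`.
#' @param count_x,count_y cell counts for X and Y (`count_y > 0`).
#' @return `ratio_xy * count_x / count_y`, clipped to `[0, 1]`.
#' @examples
#' derive_reverse_ratio(1.00, 12.16, 150.66) # MIP -> TK from TK -> MIP
#' @export
derive_reverse_ratio <- function(ratio_xy, count_x, count_y) {
  if (any(count_y <= 0)) stop("count_y must be > 0")
  pmin(1, pmax(0, ratio_xy * count_x / count_y))
}

#' Published directed coexpression percentages
#'
#' Returns the packaged table of observed directed coexpression
#' percentages: the five neuropeptide-with-GABA percentages, the TK
#' relationships (100% with MIP, never with FMRF or Mas-AT), MIP -> Mas-AT
#' (42%) and Mas-AT -> FMRF (22%), plus, when `derived = TRUE`, the reverse
#' directions completed through the overlap identity
#' (see [derive_reverse_ratio()]).
#'
#' FMRF/MIP coexpression and all AST-A peptide pairs were never measured
#' and are absent from the table.
#'
#' @param derived append overlap-identity-derived reverse rows
#'   (flagged in the `derived` column).
#' @return A data frame with columns `source`, `target`, `percent`,
#'   `derived`, `provenance`.
#' @export
observed_ratios <- function(derived = TRUE) {
  path <- system.file("extdata", "observed_ratios.csv",
                      package = "coexnull", mustWork = TRUE)
  tab <- read_ratio_csv(path)
  tab$derived <- FALSE
  if (!derived) return(tab)
  panel <- observed_panel()
  cnt <- stats::setNames(panel$count_mean, panel$transmitter)
  rev <- tab
  rev$source <- tab$target
  rev$target <- tab$source
  rev$percent <- 100 * derive_reverse_ratio(tab$percent / 100,
                                            cnt[tab$source], cnt[tab$target])
  rev$derived <- TRUE
  rev$provenance <- paste0("derived via overlap identity from ",
                           tab$source, "->", tab$target)
  out <- rbind(tab, rev)
  rownames(out) <- NULL
  out
}

#' Read or write a directed-ratio CSV
#'
#' Columns `source,target,percent` (percent in `[0, 100]`); extra columns
#' preserved. Percentages outside `[0, 100]` are a parse error naming the
#' offending row.
#'
#' @param path file path.
#' @return `read_ratio_csv()` returns a data frame; `write_ratio_csv()`
#'   returns `path` invisibly.
#' @export
read_ratio_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("source", "target", "percent")
  if (!all(need %in% names(df)))
    stop("ratio CSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(df$percent) | df$percent < 0 | df$percent > 100)
  if (length(bad))
    stop("ratio CSV: percent outside [0, 100] at row ", bad[1],
         " (", df$source[bad[1]], " -> ", df$target[bad[1]], ")")
  df
}

#' @rdname read_ratio_csv
#' @param ratios a data frame as returned by [read_ratio_csv()].
#' @export
write_ratio_csv <- function(ratios, path) {
  utils::write.csv(ratios, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
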