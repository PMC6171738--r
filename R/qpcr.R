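#' Nondetect test for qPCR Cq values
#'
#' A Cq value is nondetectable (ND) when it is missing (`NA`, e.g. a
#' not-assayed cell), exactly 0 (the instrument's encoding of "no
#' amplification"), or at/above the detection threshold. The default
#' threshold is 37 cycles: amplification that late is noise, and the
#' published N.D. calls (e.g. the TK receptor in lateral-cluster mRNA at
#' Cq 39 / 0 / 37.59) follow that convention.
#'
#' @param cq numeric Cq values.
#' @param threshold detection threshold in cycles (default 37; values
#'   `>= threshold` are ND).
#' @return Logical vector.
#' @export
is_nondetect <- function(cq, threshold = 37) {
  is.na(cq) | cq == 0 | cq >= threshold
}

#' Delta-Ct of a target against a reference gene
#'
#' `delta_ct = Cq_target - Cq_reference`, with nondetects propagated: if
#' either input is ND (see [is_nondetect()]) the result is `NA`, never a
#' number.
#'
#' @param ct_receptor,ct_reference Cq values (vectorized).
#' @param threshold nondetect threshold passed to [is_nondetect()].
#' @return Numeric vector with `NA` where either input is ND.
#' @examples
#' delta_ct(31.36, 22.91)  # 8.45
#' delta_ct(0, 22.91)      # NA: no amplification
#' @export
delta_ct <- function(ct_receptor, ct_reference, threshold = 37) {
  out <- ct_receptor - ct_reference
  out[is_nondetect(ct_receptor, threshold) |
        is_nondetect(ct_reference, threshold)] <- NA_real_
  out
}

#' Relative expression from a mean delta-Ct
#'
#' `2^(-delta_ct)`: expression of the target relative to the reference
#' gene; `delta_ct = 0` gives 1 (equal expression), each extra cycle
#' halves it. `NA` (ND) passes through.
#'
#' @param mean_delta_ct numeric.
#' @return `2^(-mean_delta_ct)`.
#' @export
relative_expression <- function(mean_delta_ct) 2^(-mean_delta_ct)

#' Read a Cq table CSV
#'
#' The layout mirrors a qPCR plate export: one row per (receptor, RT or
#' RT-) pair, identified by columns `receptor` and `rt`, followed by one
#' numeric column per sample. Cell values: a Cq in cycles, `0` for no
#' amplification, or `x` for not assayed (parsed to `NA`).
#'
#' @param path CSV path; defaults to the packaged published Cq table.
#' @return A data frame of class `cq_table` (receptor, rt, sample
#'   columns).
#' @export
read_cq_table <- function(path = system.file("extdata", "table3_cq.csv",
                                             package = "coexnull",
                                             mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!all(c("receptor", "rt") %in% names(df)))
    stop("Cq table must have 'receptor' and 'rt' columns")
  samples <- setdiff(names(df), c("receptor", "rt"))
  for (s in samples) {
    v <- trimws(df[[s]])
    v[v %in% c("x", "X", "")] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("Cq table: non-numeric value '", v[bad[1]], "' in column ", s,
           ", row ", bad[1])
    if (any(num < 0, na.rm = TRUE))
      stop("Cq table: negative Cq in column ", s)
    df[[s]] <- num
  }
  class(df) <- c("cq_table", "data.frame")
  df
}

#' @rdname read_cq_table
#' @param cq a `cq_table`.
#' @export
write_cq_table <- function(cq, path) {
  out <- as.data.frame(cq)
  samples <- setdiff(names(out), c("receptor", "rt"))
  for (s in samples) {
    v <- format(out[[s]], trim = TRUE, scientific = FALSE)
    v <- sub("\\.?0+$", "", v)  # drop trailing zeros introduced by format
    v[is.na(out[[s]])] <- "x"
    out[[s]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_tissue_grouping <- function() {
  list(antennae = c("ANTa", "ANTb", "ANTc"),
       brain = c("Ba", "Bb", "Bc"),
       medial = c("Ma", "Mb", "Mc"),
       lateral = c("La", "Lb", "Lc"))
}

#' Tissue-level relative expression from a Cq table
#'
#' For each receptor and tissue: per-sample delta-Ct against the reference
#' gene (computed per sample, then averaged — not on averaged Cqs), ND
#' samples excluded, tissue flagged ND only when all of its samples are
#' ND, and relative expression `2^-mean(delta_ct)`.
#'
#' The reference gene defaults to `RpS3`; receptors assayed at a
#' different annealing temperature can name their own reference row via
#' `reference_overrides` (the packaged table re-ran the reference at 52C
#' for the Mas-AT receptor, and its re-run control noise rows are already
#' encoded as 0 per the published convention).
#'
#' @param cq a [read_cq_table()] result.
#' @param receptors receptors to summarize (default: all non-reference RT
#'   rows).
#' @param grouping named list mapping tissue name to sample columns;
#'   default antennae/brain/medial/lateral triplets.
#' @param reference reference-gene row name (default `"RpS3"`).
#' @param reference_overrides named character vector
#'   (receptor -> reference row) for receptors using another reference
#'   run.
#' @param threshold nondetect threshold (default 37).
#' @return A data frame of class `relative_expression` with columns
#'   `receptor`, `tissue`, `mean_delta_ct`, `rel_expr`, `detectable`,
#'   `n_samples_used`.
#' @examples
#' qp <- qpcr_relative_expression(read_cq_table())
#' subset(qp, receptor == "TKr" & tissue == "lateral")$detectable  # FALSE
#' @export
qpcr_relative_expression <- function(cq, receptors = NULL,
                                     grouping = default_tissue_grouping(),
                                     reference = "RpS3",
                                     reference_overrides =
                                       c("Mas-ATr" = "RpS3_52C"),
                                     threshold = 37) {
  stopifnot(inherits(cq, "cq_table") || is.data.frame(cq))
  rt <- cq[cq$rt == "RT", , drop = FALSE]
  ref_names <- unique(c(reference, reference_overrides))
  if (is.null(receptors))
    receptors <- setdiff(rt$receptor, ref_names)
  out <- list()
  for (rec in receptors) {
    ref_row_name <- if (rec %in% names(reference_overrides))
      reference_overrides[[rec]] else reference
    rec_row <- rt[rt$receptor == rec, , drop = FALSE]
    ref_row <- rt[rt$receptor == ref_row_name, , drop = FALSE]
    if (nrow(rec_row) != 1)
      stop("receptor '", rec, "' not found (or duplicated) in Cq table")
    if (nrow(ref_row) != 1)
      stop("reference gene row '", ref_row_name, "' missing from Cq table")
    for (tis in names(grouping)) {
      cols <- grouping[[tis]]
      miss <- setdiff(cols, names(cq))
      if (length(miss))
        stop("sample column(s) ", paste(miss, collapse = ", "),
             " missing from Cq table")
      d <- delta_ct(as.numeric(rec_row[1, cols]),
                    as.numeric(ref_row[1, cols]), threshold)
      used <- sum(!is.na(d))
      mdct <- if (used > 0) mean(d, na.rm = TRUE) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        receptor = rec, tissue = tis, mean_delta_ct = mdct,
        rel_expr = relative_expression(mdct),
        detectable = used > 0, n_samples_used = used,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("relative_expression", "data.frame")
  res
}

#' @export
print.relative_expression <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$mean_delta_ct <- round(y$mean_delta_ct, 2)
  y$rel_expr <- signif(y$rel_expr, digits)
  y$rel_expr[!y$detectable] <- NA
  print(y, row.names = FALSE)
  cat("(rel_expr = 2^-mean(delta Ct); NA = nondetectable)\n")
  invisible(x)
}
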