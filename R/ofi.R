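#' Oxygenation Flow Index
#'
#' Summarises a correlation map into the OFI: the median of the valid
#' Pearson-coefficient distribution, expressed in percent.  The median (not
#' the mean) is used so the index reflects the central tendency even for
#' skewed correlation distributions; even pixel counts use the mean of the
#' two central order statistics.
#'
#' @param cmap A `bh_corrmap`.
#' @param mask Optional `bh_roi` restricting the pixels entering the index
#'   (defaults to every valid map pixel, i.e. the whole foot).
#' @param exclude_wound If `TRUE` (default) and `wound_mask` is supplied, the
#'   wound region is removed before taking the median — the convention for
#'   wound cases, where the index summarises the non-wound foot.
#' @param wound_mask Optional wound `bh_roi`.
#' @return An object of class `bh_ofi`: `ofi_pct`, `n_valid`, `quartiles`
#'   (q1, median, q3), `min`, `max`, and a `mask_descriptor` string.
#' @export
compute_ofi <- function(cmap, mask = NULL, exclude_wound = TRUE,
                        wound_mask = NULL) {
  stopifnot(inherits(cmap, "bh_corrmap"))
  sel <- !is.na(cmap$pcc)
  desc <- "all valid pixels"
  if (!is.null(mask)) {
    sel <- sel & mask$mask
    desc <- paste0("mask:", mask$label)
  }
  if (exclude_wound && !is.null(wound_mask)) {
    sel <- sel & !wound_mask$mask
    desc <- paste0(desc, " minus wound")
  }
  vals <- cmap$pcc[sel]
  if (length(vals) == 0) stop("no valid pixels under the OFI mask", call. = FALSE)
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(
    list(ofi_pct = 100 * stats::median(vals), n_valid = length(vals),
         quartiles = c(q1 = 100 * q[1], median = 100 * q[2], q3 = 100 * q[3]),
         min = 100 * min(vals), max = 100 * max(vals),
         mask_descriptor = desc),
    class = "bh_ofi"
  )
}

#' @export
print.bh_ofi <- function(x, ...) {
  cat(sprintf("OFI: %.1f%% (n = %d pixels; IQR %.1f to %.1f%%; %s)\n",
              x$ofi_pct, x$n_valid, x$quartiles["q1"], x$quartiles["q3"],
              x$mask_descriptor))
  invisible(x)
}

#' Classify an OFI against the healing-status threshold
#'
#' `"below"` iff `ofi_pct < threshold_pct` (strict inequality: a value
#' exactly at the threshold classifies `"above"`).  The default threshold of
#' 28% is the preliminary healing/non-healing cut-off reported by a companion
#' clinical study; it ships as a configurable default and is not validated
#' by this package.
#'
#' @param result A `bh_ofi` or a bare OFI value in percent.
#' @param threshold_pct Threshold in percent, in `[-100, 100]`.
#' @return `"above"` or `"below"`.
#' @examples
#' classify_ofi(33.4)  # "above"
#' classify_ofi(9.5)   # "below"
#' @export
classify_ofi <- function(result, threshold_pct = 28) {
  if (!is.finite(threshold_pct) || threshold_pct < -100 || threshold_pct > 100) {
    stop("threshold_pct must lie in [-100, 100]", call. = FALSE)
  }
  v <- if (inherits(result, "bh_ofi")) result$ofi_pct else as.numeric(result)
  if (v < threshold_pct) "below" else "above"
}

#' Append an OFI result to a summary table
#'
#' @param results Named list of `bh_ofi` objects (names = case labels).
#' @param path Optional CSV path; when given the table is also written.
#' @return data.frame with one row per case.
#' @export
ofi_table <- function(results, path = NULL) {
  df <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(case = nm, ofi_pct = r$ofi_pct, n_valid = r$n_valid,
               q1_pct = r$quartiles[["q1"]], q3_pct = r$quartiles[["q3"]],
               min_pct = r$min, max_pct = r$max, mask = r$mask_descriptor)
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
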