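#' Normality-gated log transform for one variable
#'
#' Tests the values against a normal distribution whose moments are estimated
#' from the data (one-sample Kolmogorov-Smirnov by default, as the classic
#' clinical-statistics workflow does; a Lilliefors-corrected variant is
#' available). If normality is rejected at `alpha` and all values are
#' strictly positive, the natural log is applied; otherwise the values are
#' returned unchanged (a rejected test with non-positive values yields a
#' warning and no transform).
#'
#' @param values Numeric vector, length >= 8, no missing values.
#' @param alpha Rejection threshold for the normality p-value. Default 0.05.
#' @param method `"ks"` (default) or `"lilliefors"` ([nortest::lillie.test()]).
#' @return A list with `values` (possibly log-transformed) and `report`, a
#'   one-row data.frame with `ks_p`, `transformed`, `note`.
#' @export
decide_log_transform <- function(values, alpha = 0.05,
                                 method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  if (length(values) < 8) stop_invalid("need at least 8 values")
  if (anyNA(values)) stop_invalid("missing values are not allowed")
  if (sd(values) == 0) stop_invalid("degenerate input: zero variance")
  p <- if (method == "ks") {
    suppressWarnings(
      ks.test(values, "pnorm", mean(values), sd(values))$p.value
    )
  } else {
    nortest::lillie.test(values)$p.value
  }
  transformed <- FALSE
  note <- ""
  out <- values
  if (p < alpha) {
    if (all(values > 0)) {
      out <- log(values)
      transformed <- TRUE
    } else {
      note <- "non-normal but non-positive values; not transformed"
      warning(note, call. = FALSE)
    }
  }
  list(
    values = out,
    report = data.frame(ks_p = p, transformed = transformed, note = note,
                        stringsAsFactors = FALSE)
  )
}

#' Apply the log-transform gate to every variable of a block
#'
#' @param block An [omics_block()].
#' @inheritParams decide_log_transform
#' @return A list with `block` (transformed) and `report` (one row per
#'   variable: `variable`, `ks_p`, `transformed`, `note`).
#' @export
transform_block <- function(block, alpha = 0.05, method = c("ks", "lilliefors")) {
  stopifnot(inherits(block, "omics_block"))
  method <- match.arg(method)
  res <- lapply(seq_len(ncol(block$data)), function(j) {
    decide_log_transform(block$data[, j], alpha = alpha, method = method)
  })
  newdata <- vapply(res, `[[`, numeric(nrow(block$data)), "values")
  dimnames(newdata) <- dimnames(block$data)
  report <- do.call(rbind, lapply(res, `[[`, "report"))
  report <- cbind(variable = block$variable_names, report)
  list(block = omics_block(newdata, block$block_label), report = report)
}

#' Mean-center a block within batches
#'
#' Removes additive batch effects (e.g. study center or diet arm) by
#' subtracting each batch's per-variable mean. With a single batch this is
#' global column centering; a batch containing a single subject has that
#' subject's values centered to exactly zero (allowed, by construction).
#'
#' @param block An [omics_block()].
#' @param batch Batch label per subject (length `nrow`). Default: one batch.
#' @return The centered [omics_block()].
#' @export
center_by_batch <- function(block, batch = NULL) {
  stopifnot(inherits(block, "omics_block"))
  n <- nrow(block$data)
  if (is.null(batch)) batch <- rep("all", n)
  if (length(batch) != n) stop_invalid("every subject needs a batch label")
  x <- block$data
  for (b in unique(batch)) {
    rows <- which(batch == b)
    mu <- colMeans(x[rows, , drop = FALSE])
    x[rows, ] <- sweep(x[rows, , drop = FALSE], 2, mu)
  }
  omics_block(x, block$block_label)
}

#' Classify weight change between two diet phases
#'
#' The change is `weight_wmd - weight_lcd` (weight after the maintenance
#' phase minus weight after the calorie-restriction phase). A loss of at
#' least 2 kg classifies the subject as a weight loser (`WL`), a regain of at
#' least 2 kg as a weight regainer (`WR`), anything in between as weight
#' stable (`WS`). The 2 kg boundary is inclusive on the WL/WR side.
#'
#' @param weight_lcd,weight_wmd Body weights in kg, strictly positive;
#'   vectorized.
#' @return A factor with levels `WL`, `WS`, `WR`.
#' @export
classify_weight_change <- function(weight_lcd, weight_wmd) {
  if (any(weight_lcd <= 0) || any(weight_wmd <= 0)) {
    stop_invalid("weights must be strictly positive")
  }
  delta <- weight_wmd - weight_lcd
  out <- ifelse(delta <= -2, "WL", ifelse(delta >= 2, "WR", "WS"))
  factor(out, levels = c("WL", "WS", "WR"))
}

#' Desaturation (product/precursor) index
#'
#' Ratio of a desaturation product to its precursor fatty acid (both as
#' percentages of total fatty-acid content), e.g. 14:1(cis-9)/14:0 as a proxy
#' for stearoyl-CoA desaturase activity.
#'
#' @param product_pct,precursor_pct Percentages; `precursor_pct` must be
#'   strictly positive. Vectorized.
#' @return The ratio.
#' @export
desaturation_index <- function(product_pct, precursor_pct) {
  if (any(precursor_pct <= 0)) stop_invalid("precursor_pct must be > 0")
  product_pct / precursor_pct
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up false-discovery-rate correction, delegated to
#' [stats::p.adjust()] after validating the input.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`, no missing values.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}
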