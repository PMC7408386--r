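# Normalization menu: total area, median centering, probabilistic quotient,
# quantile, rank, log transform, per-subclass application, and the strategy
# enumerator/dispatcher.
#
# All operations are defined on the canonical samples-by-glycans matrix and
# accept either a numeric matrix or a glycomics_dataset (returned in kind).

abund <- function(d) if (inherits(d, "glycomics_dataset")) d$abundance else d

with_abund <- function(d, m) {
  if (inherits(d, "glycomics_dataset")) { d$abundance <- m; d } else m
}

check_complete <- function(x, op) {
  if (anyNA(x))
    stop(op, ": missing values present; apply drop_incomplete_samples() first")
}

#' Total area (closure) normalization
#'
#' Each sample is divided by its total intensity, so that every sample's
#' values sum to one. This is the closure operation: the resulting data are
#' compositional, and the constant-sum constraint forces at least one
#' negative entry into every row of the covariance matrix.
#'
#' @param d A [glycomics_dataset()] or numeric samples-by-glycans matrix.
#' @return Normalized data of the same type as the input.
#' @export
total_area <- function(d) {
  x <- abund(d)
  check_complete(x, "total_area")
  rs <- rowSums(x)
  if (any(rs <= 0)) {
    bad <- rownames(x)[which(rs <= 0)[1]] %||% which(rs <= 0)[1]
    stop("total_area: non-positive total for sample ", bad)
  }
  with_abund(d, x / rs)
}

#' Median centering
#'
#' Subtracts a median from each value. `mode = "per_sample"` (default)
#' removes each sample's median across glycans — the constant per-sample
#' offset the method assumes; `mode = "per_glycan"` removes each glycan's
#' median across samples.
#'
#' @inheritParams total_area
#' @param mode `"per_sample"` or `"per_glycan"`.
#' @return Centered data of the same type as the input.
#' @export
median_center <- function(d, mode = c("per_sample", "per_glycan")) {
  mode <- match.arg(mode)
  x <- abund(d)
  check_complete(x, "median_center")
  out <- if (mode == "per_sample") {
    x - apply(x, 1, stats::median)
  } else {
    sweep(x, 2, apply(x, 2, stats::median))
  }
  with_abund(d, out)
}

#' Probabilistic quotient normalization
#'
#' Estimates a per-sample dilution factor against a reference sample (the
#' per-glycan median across all samples): for sample i the factor is the
#' median of the quotients x_ij / reference_j, and the sample is divided by
#' it. The estimated dilution factors are attached as attribute
#' `"dilution"` for audit.
#'
#' @inheritParams total_area
#' @return Normalized data of the same type as the input, with attribute
#'   `dilution` (named numeric, one factor per sample) on the abundance
#'   matrix (or on the returned matrix).
#' @export
probabilistic_quotient <- function(d) {
  x <- abund(d)
  check_complete(x, "probabilistic_quotient")
  ref <- apply(x, 2, stats::median)
  if (any(ref <= 0)) {
    bad <- colnames(x)[which(ref <= 0)[1]] %||% which(ref <= 0)[1]
    stop("probabilistic_quotient: non-positive reference for glycan ", bad)
  }
  q <- sweep(x, 2, ref, "/")
  f <- apply(q, 1, stats::median)
  if (any(f <= 0)) {
    bad <- rownames(x)[which(f <= 0)[1]] %||% which(f <= 0)[1]
    stop("probabilistic_quotient: non-positive dilution factor for sample ", bad)
  }
  out <- x / f
  names(f) <- rownames(x)
  attr(out, "dilution") <- f
  with_abund(d, out)
}

#' Dilution factors estimated by the last probabilistic quotient step
#' @param d Output of [probabilistic_quotient()] (dataset or matrix).
#' @return Named numeric vector of per-sample dilution factors.
#' @export
dilution_factors <- function(d) attr(abund(d), "dilution")

#' Total area followed by probabilistic quotient
#'
#' Fixed composition order: the closure first, then the quotient correction
#' on the closed data.
#'
#' @inheritParams total_area
#' @return Normalized data of the same type as the input.
#' @export
ta_quotient <- function(d) probabilistic_quotient(total_area(d))

#' Quantile normalization (per glycan)
#'
#' Forces all glycan columns to share one distribution: each value is
#' replaced by the mean, across glycans, of the values at its rank; ties
#' receive the average of the tied positions' means. Delegates to
#' limma's quantile normalizer with tie averaging.
#'
#' @inheritParams total_area
#' @return Normalized data of the same type as the input.
#' @export
quantile_normalize <- function(d) {
  x <- abund(d)
  check_complete(x, "quantile_normalize")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  with_abund(d, out)
}

#' Rank transform (per glycan)
#'
#' Replaces each glycan's values by their ranks 1..n across samples; ties
#' get average ranks.
#'
#' @inheritParams total_area
#' @return Transformed data of the same type as the input.
#' @export
rank_transform <- function(d) {
  x <- abund(d)
  check_complete(x, "rank_transform")
  out <- apply(x, 2, rank, ties.method = "average")
  dimnames(out) <- dimnames(x)
  with_abund(d, out)
}

#' Natural log transform
#'
#' @inheritParams total_area
#' @return Log-transformed data of the same type as the input. Non-positive
#'   values raise an error naming the first offending cell.
#' @export
log_transform <- function(d) {
  x <- abund(d)
  check_complete(x, "log_transform")
  if (any(x <= 0)) {
    ij <- which(x <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("log_transform: non-positive value at sample '%s', glycan '%s'",
                 rownames(x)[ij[1]] %||% ij[1], colnames(x)[ij[2]] %||% ij[2]))
  }
  with_abund(d, log(x))
}

#' Apply a normalization independently per glycan subclass
#'
#' Splits the glycan columns by their subclass label, applies `fun` to each
#' block independently, and reassembles the blocks in the original column
#' order.
#'
#' @param d A [glycomics_dataset()] whose `glycan_meta` has a `subclass`
#'   column, or a matrix together with `subclass`.
#' @param fun Function taking and returning a samples-by-glycans matrix.
#' @param subclass Optional character vector of per-column subclass labels
#'   (required when `d` is a bare matrix).
#' @return Data of the same type as the input.
#' @export
apply_per_subclass <- function(d, fun, subclass = NULL) {
  x <- abund(d)
  if (is.null(subclass)) {
    if (!inherits(d, "glycomics_dataset") || is.null(d$glycan_meta) ||
        is.null(d$glycan_meta$subclass))
      stop("per-subclass application requires glycan subclass labels")
    subclass <- as.character(d$glycan_meta$subclass)
  }
  stopifnot(length(subclass) == ncol(x))
  out <- x
  for (sc in unique(subclass)) {
    sel <- subclass == sc
    out[, sel] <- abund(fun(x[, sel, drop = FALSE]))
  }
  with_abund(d, out)
}

base_method_labels <- c(raw = "Raw", quantile = "Quantile", rank = "Rank",
                        ta = "TA", median = "Median", quotient = "Quotient",
                        taquotient = "TAQuotient")
subclass_eligible <- c("quantile", "rank", "ta", "quotient", "taquotient")

#' Normalization strategy specification
#'
#' A base method, an optional log transform, and an optional per-subclass
#' application. Median centering cannot be log-transformed (it produces
#' non-positive values); per-subclass variants exist only for the methods
#' whose parameters are sample-set dependent within a block (quantile, rank,
#' total area, quotient, TA+quotient).
#'
#' @param base One of `"raw"`, `"median"`, `"ta"`, `"quotient"`,
#'   `"taquotient"`, `"quantile"`, `"rank"`.
#' @param log Apply a natural log after the base method.
#' @param per_subclass Apply the whole chain independently per IgG subclass.
#' @return An object of class `"normalization_spec"` with an auto-generated
#'   `label` (e.g. `"TAQuotient log subclass"`).
#' @export
normalization_spec <- function(base, log = FALSE, per_subclass = FALSE) {
  base <- match.arg(base, names(base_method_labels))
  if (base == "median" && log)
    stop("median centering cannot be log-transformed")
  if (per_subclass && !(base %in% subclass_eligible))
    stop("per-subclass application is not defined for base method '", base, "'")
  label <- paste0(base_method_labels[[base]],
                  if (log) " log" else "",
                  if (per_subclass) " subclass" else "")
  structure(list(base = base, log = log, per_subclass = per_subclass,
                 label = label),
            class = "normalization_spec")
}

#' @export
print.normalization_spec <- function(x, ...) {
  cat(sprintf("<normalization strategy> %s\n", x$label))
  invisible(x)
}

#' Enumerate the evaluated normalization strategies
#'
#' Non-subclass platforms get the 13 base strategies (7 base methods plus
#' the 6 log variants — median centering has no log variant). The
#' subclass-resolved LC-ESI-MS platform additionally gets the 10
#' per-subclass variants, for 23 strategies in total.
#'
#' @param platform Platform tag, see [glycomics_dataset()].
#' @return List of [normalization_spec()] objects, labels unique.
#' @export
enumerate_strategies <- function(platform = "generic") {
  platform <- match.arg(platform, PLATFORMS)
  bases <- names(base_method_labels)
  specs <- c(lapply(bases, normalization_spec),
             lapply(setdiff(bases, "median"), normalization_spec, log = TRUE))
  if (platform == "lc-esi-ms") {
    specs <- c(specs,
               lapply(subclass_eligible, normalization_spec,
                      per_subclass = TRUE),
               lapply(subclass_eligible, normalization_spec, log = TRUE,
                      per_subclass = TRUE))
  }
  specs
}

#' Strategy labels
#' @param specs List of [normalization_spec()]s.
#' @return Character vector of labels.
#' @export
strategy_labels <- function(specs)
  vapply(specs, function(s) s$label, character(1))

base_method_fun <- function(base) {
  switch(base,
         raw = identity,
         median = median_center,
         ta = total_area,
         quotient = probabilistic_quotient,
         taquotient = ta_quotient,
         quantile = quantile_normalize,
         rank = rank_transform)
}

#' Apply a normalization strategy
#'
#' Dispatches a [normalization_spec()]: the base method, then the optional
#' log transform; per-subclass strategies apply that whole chain
#' independently within each subclass's column block.
#'
#' @param spec A [normalization_spec()] or a Table-of-strategies label
#'   understood by [normalization_spec()] components.
#' @param d A [glycomics_dataset()] or samples-by-glycans matrix (matrices
#'   are not allowed for per-subclass strategies unless `subclass` given).
#' @param subclass Optional per-column subclass labels for matrix input.
#' @return Normalized data of the same type as the input.
#' @export
apply_strategy <- function(spec, d, subclass = NULL) {
  stopifnot(inherits(spec, "normalization_spec"))
  chain <- function(m) {
    out <- base_method_fun(spec$base)(m)
    if (spec$log) out <- log_transform(out) else out
  }
  if (spec$per_subclass) {
    apply_per_subclass(d, chain, subclass = subclass)
  } else {
    with_abund(d, abund(chain(abund(d))))
  }
}
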