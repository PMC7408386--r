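# Scoring a normalization strategy by GGM-pathway overlap, bootstrap
# ranking of strategies, and the age-association secondary evaluation.

#' Contingency table of GGM edges vs pathway edges
#'
#' Classifies every unordered node pair: present in both the data-driven
#' GGM and the reference pathway (tp), only in the GGM (fp), only in the
#' pathway (fn), or in neither (tn). The four counts always sum to
#' `choose(p, 2)`.
#'
#' @param ggm A `"ggm"` object or a two-column edge matrix.
#' @param pathway A [glycan_pathway()] over the same node set as the GGM.
#' @param nodes Node set, required when `ggm` is a bare edge matrix.
#' @return Object of class `"overlap_table"`: named integer vector with
#'   elements tp, fp, fn, tn, plus attribute `n_nodes`.
#' @export
contingency_counts <- function(ggm, pathway, nodes = NULL) {
  stopifnot(inherits(pathway, "glycan_pathway"))
  if (inherits(ggm, "ggm")) {
    nodes <- ggm$nodes
    eg <- ggm$edges
  } else {
    stopifnot(!is.null(nodes))
    eg <- ggm
  }
  if (!setequal(nodes, pathway$nodes)) {
    d1 <- setdiff(nodes, pathway$nodes); d2 <- setdiff(pathway$nodes, nodes)
    stop("GGM and pathway node sets differ; only in GGM: {",
         paste(d1, collapse = ", "), "}, only in pathway: {",
         paste(d2, collapse = ", "), "}")
  }
  kg <- edge_keys(eg)
  kp <- edge_keys(pathway$edges)
  tp <- sum(kg %in% kp)
  fp <- length(kg) - tp
  fn <- length(kp) - tp
  tn <- choose(length(nodes), 2) - tp - fp - fn
  structure(c(tp = tp, fp = fp, fn = fn, tn = tn),
            n_nodes = length(nodes), class = "overlap_table")
}

#' Fisher's exact test p-value for GGM-pathway overlap
#'
#' Hypergeometric tail probability of the observed overlap: with M all
#' pairs, K pathway pairs, n GGM edges and k true positives, the default
#' one-sided alternative `"greater"` gives
#' `p = P(X >= k)` for `X ~ Hypergeom(M, K, n)` — lower p means higher
#' overlap. Computed exactly (log-gamma arithmetic), no chi-square
#' approximation.
#'
#' @param tab An `"overlap_table"` (or named vector with tp, fp, fn, tn).
#' @param alternative `"greater"` (enrichment, default) or `"two_sided"`.
#' @return The p-value.
#' @export
fisher_overlap_pvalue <- function(tab,
                                  alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  tp <- tab[["tp"]]; fp <- tab[["fp"]]; fn <- tab[["fn"]]; tn <- tab[["tn"]]
  stopifnot(all(c(tp, fp, fn, tn) >= 0))
  if (alternative == "greater") {
    # P(X >= tp), X ~ Hypergeom(m = K pathway pairs, n = M - K, k = n edges)
    stats::phyper(tp - 1, m = tp + fn, n = fp + tn, k = tp + fp,
                  lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(tp, fp, fn, tn), 2))$p.value
  }
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf("<overlap> tp=%d fp=%d fn=%d tn=%d (%d nodes)\n",
              x[["tp"]], x[["fp"]], x[["fn"]], x[["tn"]],
              attr(x, "n_nodes")))
  invisible(x)
}

# deterministic 31-bit seed substream per strategy label, independent of
# other strategies, so adding a strategy never perturbs existing replicates
strategy_seed <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 131 + c) %% 2147483647
  as.integer((seed %% 2147483647 + h) %% 2147483647)
}

#' Bootstrap evaluation of one normalization strategy
#'
#' For each of `B` bootstrap replicates: resample samples with replacement,
#' apply the normalization strategy (its sample-dependent parameters, e.g.
#' the quotient reference, are recomputed within the replicate unless
#' `renormalize = FALSE`, in which case the data are normalized once up
#' front and only the GGM is bootstrapped), infer the GGM, and score the
#' overlap with the reference pathway by Fisher's exact test. Replicates
#' that fail (e.g. a glycan becomes constant after resampling) are skipped
#' with a warning; more than 5% skips is an error.
#'
#' @param d Complete-case [glycomics_dataset()] (raw, pre-normalization).
#' @param spec A [normalization_spec()].
#' @param pathway Reference [glycan_pathway()] over the dataset's glycans.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; the replicate stream is derived from `seed`
#'   and the strategy label only.
#' @param q FDR level for GGM edge selection.
#' @param renormalize Recompute normalization inside each replicate
#'   (default `TRUE`).
#' @param alternative Fisher test sidedness, see [fisher_overlap_pvalue()].
#' @param ggm_method Significance method for [infer_ggm()].
#' @return Object of class `"strategy_evaluation"`: list with `label`,
#'   `pvals` (length `B`, `NA` for skipped replicates), `median_p`,
#'   `ci_low`, `ci_high` (2.5th/97.5th percentiles), `n_skipped`, `B`.
#' @export
bootstrap_evaluate <- function(d, spec, pathway, B = 1000, seed = 1,
                               q = 0.01, renormalize = TRUE,
                               alternative = "greater",
                               ggm_method = "null_density") {
  stopifnot(inherits(d, "glycomics_dataset"),
            inherits(spec, "normalization_spec"), B >= 1)
  check_complete(d$abundance, "bootstrap_evaluate")
  n <- nrow(d$abundance)
  set.seed(strategy_seed(seed, spec$label))
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  if (!renormalize) d <- apply_strategy(spec, d)
  pvals <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    pvals[b] <- tryCatch({
      db <- d
      db$abundance <- d$abundance[idx[b, ], , drop = FALSE]
      rownames(db$abundance) <- paste0("r", seq_len(n))
      if (renormalize) db <- apply_strategy(spec, db)
      g <- infer_ggm(db$abundance, q = q, method = ggm_method)
      g$nodes <- colnames(d$abundance)
      fisher_overlap_pvalue(contingency_counts(g, pathway),
                            alternative = alternative)
    }, error = function(e) NA_real_)
  }
  n_skipped <- sum(is.na(pvals))
  if (n_skipped > 0)
    warning(sprintf("strategy '%s': %d of %d replicates skipped",
                    spec$label, n_skipped, B))
  if (n_skipped > 0.05 * B)
    stop(sprintf("strategy '%s': %d of %d replicates failed (> 5%%)",
                 spec$label, n_skipped, B))
  ok <- pvals[!is.na(pvals)]
  structure(list(label = spec$label, pvals = pvals,
                 median_p = stats::median(ok),
                 ci_low = unname(stats::quantile(ok, 0.025)),
                 ci_high = unname(stats::quantile(ok, 0.975)),
                 n_skipped = n_skipped, B = B),
            class = "strategy_evaluation")
}

#' @export
print.strategy_evaluation <- function(x, ...) {
  cat(sprintf("<strategy '%s'> median Fisher p = %.3g [%.3g, %.3g] over %d replicates%s\n",
              x$label, x$median_p, x$ci_low, x$ci_high, x$B,
              if (x$n_skipped) sprintf(" (%d skipped)", x$n_skipped) else ""))
  invisible(x)
}

#' Rank strategies by bootstrap median overlap p-value
#'
#' Ascending by median p (lower p = higher pathway overlap = better
#' normalization); ties broken by label, so the ranking is stable under
#' permutation of the input.
#'
#' @param evaluations List of `"strategy_evaluation"` objects (or a
#'   `"norm_benchmark"`).
#' @return Data.frame with columns label, median_p, ci_low, ci_high, rank.
#' @export
rank_strategies <- function(evaluations) {
  if (inherits(evaluations, "norm_benchmark"))
    evaluations <- evaluations$evaluations
  if (inherits(evaluations, "strategy_evaluation"))
    evaluations <- list(evaluations)
  stopifnot(length(evaluations) >= 1)
  df <- data.frame(
    label = vapply(evaluations, `[[`, character(1), "label"),
    median_p = vapply(evaluations, `[[`, numeric(1), "median_p"),
    ci_low = vapply(evaluations, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(evaluations, `[[`, numeric(1), "ci_high"),
    stringsAsFactors = FALSE)
  df <- df[order(df$median_p, df$label), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Benchmark a set of normalization strategies
#'
#' Runs [bootstrap_evaluate()] for every strategy against the reference
#' pathway and ranks the results. This is the core experiment: strategies
#' whose normalized data yield GGMs that better recover known synthesis
#' steps rank higher (lower median Fisher p).
#'
#' @param d Complete-case [glycomics_dataset()].
#' @param pathway Reference [glycan_pathway()].
#' @param strategies List of [normalization_spec()]s (default: the full
#'   menu for the dataset's platform, [enumerate_strategies()]).
#' @inheritParams bootstrap_evaluate
#' @return Object of class `"norm_benchmark"`: list with `evaluations`,
#'   `ranking` (see [rank_strategies()]) and the call parameters.
#' @export
benchmark_normalizations <- function(d, pathway, strategies = NULL,
                                     B = 1000, seed = 1, q = 0.01,
                                     renormalize = TRUE,
                                     alternative = "greater",
                                     ggm_method = "null_density") {
  if (is.null(strategies)) strategies <- enumerate_strategies(d$platform)
  evals <- lapply(strategies, function(s)
    bootstrap_evaluate(d, s, pathway, B = B, seed = seed, q = q,
                       renormalize = renormalize, alternative = alternative,
                       ggm_method = ggm_method))
  structure(list(evaluations = evals, ranking = rank_strategies(evals),
                 B = B, seed = seed, q = q, renormalize = renormalize,
                 alternative = alternative),
            class = "norm_benchmark")
}

#' @export
print.norm_benchmark <- function(x, ...) {
  cat(sprintf("<normalization benchmark> %d strategies, B = %d, FDR q = %g\n",
              nrow(x$ranking), x$B, x$q))
  print(x$ranking, digits = 3)
  invisible(x)
}

#' @export
summary.norm_benchmark <- function(object, ...) object$ranking

#' Plot a normalization benchmark
#'
#' Horizontal bars of -log10 median Fisher p per strategy (best on top),
#' with 95% bootstrap CI whiskers.
#'
#' @param x A `"norm_benchmark"` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.norm_benchmark <- function(x, ...) {
  rk <- x$ranking[rev(seq_len(nrow(x$ranking))), ]
  eps <- .Machine$double.xmin
  v <- -log10(pmax(rk$median_p, eps))
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  mids <- graphics::barplot(v, names.arg = rk$label, horiz = TRUE, las = 1,
                            xlab = expression(-log[10] ~ "median Fisher p"),
                            xlim = c(0, max(-log10(pmax(rk$ci_low, eps)))),
                            ...)
  graphics::segments(-log10(pmax(rk$ci_high, eps)), mids,
                     -log10(pmax(rk$ci_low, eps)), mids)
  invisible(x)
}

#' Fraction of glycans significantly associated with age
#'
#' Per glycan, an ordinary least-squares fit of (normalized) abundance on
#' age with a two-sided t-test on the slope; BH correction across glycans
#' at FDR `q`; the summary is the fraction of significant glycans.
#' Constant glycan columns yield an undefined test and are counted as
#' non-significant with a warning.
#'
#' @param d A [glycomics_dataset()] whose `sample_meta` carries `age` for
#'   every sample (alternatively supply `age`).
#' @param q FDR level (default 0.01).
#' @param age Optional numeric age vector overriding `sample_meta$age`.
#' @return Object of class `"age_association"`: list with `table`
#'   (data.frame glycan, slope, p, significant) and `fraction`.
#' @export
age_fraction <- function(d, q = 0.01, age = NULL) {
  x <- abund(d)
  check_complete(x, "age_fraction")
  if (is.null(age)) {
    if (!inherits(d, "glycomics_dataset") || is.null(d$sample_meta) ||
        is.null(d$sample_meta$age))
      stop("age_fraction: no age in sample metadata")
    age <- d$sample_meta$age
  }
  if (anyNA(age)) stop("age_fraction: missing ages")
  stopifnot(length(age) == nrow(x))
  res <- t(apply(x, 2, function(y) {
    if (stats::sd(y) == 0) return(c(NA_real_, NA_real_))
    fit <- stats::lm(y ~ age)
    summary(fit)$coefficients["age", c("Estimate", "Pr(>|t|)")]
  }))
  if (anyNA(res[, 2]))
    warning("constant glycan column(s): treated as non-significant")
  padj <- stats::p.adjust(res[, 2], method = "BH")
  sig <- !is.na(padj) & padj <= q
  tab <- data.frame(glycan = colnames(x) %||% seq_len(ncol(x)),
                    slope = res[, 1], p = res[, 2], significant = sig,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, fraction = mean(sig), q = q),
            class = "age_association")
}

#' @export
print.age_association <- function(x, ...) {
  cat(sprintf("<age association> %d of %d glycans significant at FDR %g (fraction %.3f)\n",
              sum(x$table$significant), nrow(x$table), x$q, x$fraction))
  invisible(x)
}

#' Platform-weighted average of significant-association fractions
#'
#' Cohorts of the replicated platform group (default `"lc-esi-ms"`) are
#' first averaged among themselves; that average then enters a plain
#' arithmetic mean with each remaining cohort's fraction. No sample-size
#' weights are used.
#'
#' @param fractions Named numeric vector: one fraction per dataset.
#' @param groups Named character vector assigning each dataset to a
#'   platform group (names matching `fractions`).
#' @param first_average_group Group averaged first (default
#'   `"lc-esi-ms"`).
#' @return List with `group_average` (mean within the first group) and
#'   `overall` (the final average).
#' @export
weighted_average_fractions <- function(fractions, groups,
                                       first_average_group = "lc-esi-ms") {
  stopifnot(length(fractions) >= 1, !is.null(names(fractions)))
  groups <- groups[names(fractions)]
  if (anyNA(groups)) stop("every dataset must be assigned to a platform group")
  sel <- groups == first_average_group
  if (!any(sel)) stop("empty platform group '", first_average_group, "'")
  ga <- mean(fractions[sel])
  list(group_average = ga, overall = mean(c(ga, fractions[!sel])))
}
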