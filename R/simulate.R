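# Synthetic glycomics data with known pathway-structured dependence and
# known technical artifacts (per-sample dilution and additive offsets).
#
# The generator draws log-scale abundances from a multivariate normal whose
# precision matrix is nonzero exactly on the pathway edges, optionally adds
# linear age effects on the log scale, exponentiates to positive
# abundances, and then contaminates with multiplicative dilution factors
# and additive offsets. Closure is never pre-applied: total area is a
# strategy under test, not a generator step.

#' Simulation configuration
#'
#' @param pathway A [glycan_pathway()] defining the true conditional
#'   dependence structure.
#' @param n Number of samples.
#' @param rho Partial-correlation magnitude at pathway edges, in (0, 1)
#'   (default 0.3); signs are random (seeded).
#' @param sigma Log-scale marginal standard deviation (default 0.5, a
#'   realistic biological coefficient of variation for glycan abundances).
#' @param sigma_d Log-normal dilution sd (default 0: no dilution artifact).
#' @param sigma_o Additive offset sd, abundance scale (default 0).
#' @param age_slopes Optional named numeric vector of log-scale age slopes
#'   (per year) for a subset of glycans.
#' @param age_range Uniform age range in years (default c(18, 88)).
#' @param seed Integer RNG seed.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(pathway, n, rho = 0.3, sigma = 0.5,
                              sigma_d = 0, sigma_o = 0, age_slopes = NULL,
                              age_range = c(18, 88), seed = 1) {
  stopifnot(inherits(pathway, "glycan_pathway"), n >= 1,
            rho > 0, rho < 1, sigma >= 0, sigma_d >= 0, sigma_o >= 0)
  if (!is.null(age_slopes)) {
    stopifnot(!is.null(names(age_slopes)),
              all(names(age_slopes) %in% pathway$nodes))
  }
  structure(list(pathway = pathway, n = as.integer(n), rho = rho,
                 sigma = sigma, sigma_d = sigma_d, sigma_o = sigma_o,
                 age_slopes = age_slopes, age_range = age_range,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Precision matrix with support on pathway edges
#'
#' Unit diagonal, `-rho * s_ij` at pathway edges with random (seeded) signs
#' `s_ij`, zero elsewhere; if not positive definite, the diagonal is loaded
#' (and the matrix rescaled back to unit diagonal) until the smallest
#' eigenvalue is safely positive. The implied partial correlations are
#' nonzero exactly on the pathway edges.
#'
#' @param pathway A [glycan_pathway()].
#' @param rho Edge partial-correlation magnitude in (0, 1).
#' @param seed Optional seed for the random signs.
#' @return p-by-p precision matrix with pathway node dimnames.
#' @export
pathway_precision_matrix <- function(pathway, rho = 0.3, seed = NULL) {
  stopifnot(rho > 0, rho < 1)
  p <- length(pathway$nodes)
  Om <- diag(p)
  dimnames(Om) <- list(pathway$nodes, pathway$nodes)
  E <- pathway$edges
  if (nrow(E)) {
    if (!is.null(seed)) set.seed(seed)
    s <- sample(c(-1, 1), nrow(E), replace = TRUE)
    for (k in seq_len(nrow(E))) {
      Om[E[k, 1], E[k, 2]] <- Om[E[k, 2], E[k, 1]] <- -rho * s[k]
    }
  }
  ev <- min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 0.05) {
    delta <- 0.05 - ev
    Om <- (Om + delta * diag(p)) / (1 + delta)
  }
  Om
}

#' Sample clean abundances from the pathway model
#'
#' Draws `n` log-scale vectors from a multivariate normal whose correlation
#' is implied by [pathway_precision_matrix()] and whose marginal sd is
#' `sigma`; per-glycan baseline log-means are drawn once (seeded) from
#' N(0, 1); optional age effects enter on the log scale with ages uniform
#' over `age_range`. Abundances are the exponentials.
#'
#' @param config A [simulation_config()].
#' @return A [glycomics_dataset()] with ages in `sample_meta`, compositions
#'   in `glycan_meta` where the pathway provides them, and the ground truth
#'   (precision matrix, means, ages, slopes, config) in attribute
#'   `"truth"`.
#' @export
sample_abundances <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  pw <- config$pathway
  p <- length(pw$nodes)
  Om <- pathway_precision_matrix(pw, config$rho)
  S <- stats::cov2cor(solve(Om)) * config$sigma^2
  mu <- stats::rnorm(p)
  ages <- stats::runif(config$n, config$age_range[1], config$age_range[2])
  L <- if (config$sigma > 0) {
    matrix(stats::rnorm(config$n * p), config$n, p) %*% chol(S)
  } else matrix(0, config$n, p)
  L <- sweep(L, 2, mu, "+")
  slopes <- stats::setNames(rep(0, p), pw$nodes)
  if (!is.null(config$age_slopes)) {
    slopes[names(config$age_slopes)] <- config$age_slopes
    L <- L + outer(ages - mean(config$age_range), slopes[pw$nodes])
  }
  X <- exp(L)
  colnames(X) <- pw$nodes
  rownames(X) <- paste0("S", seq_len(config$n))
  gmeta <- NULL
  if (!is.null(pw$compositions)) {
    gmeta <- data.frame(
      composition = vapply(pw$nodes, function(nd) {
        cc <- pw$compositions[[nd]]
        if (is.null(cc)) NA_character_ else format(cc)
      }, character(1)),
      stringsAsFactors = FALSE)
  }
  d <- glycomics_dataset(X, sample_meta = data.frame(age = ages),
                         glycan_meta = gmeta)
  attr(d, "truth") <- list(pathway = pw, precision = Om, mu = mu,
                           ages = ages, slopes = slopes, config = config)
  d
}

#' Contaminate clean abundances with technical artifacts
#'
#' Multiplies each sample by a dilution factor `f_i ~ LogNormal(0,
#' sigma_d)` and adds a per-sample offset `o_i ~ Normal(0, sigma_o)`;
#' values that would become non-positive are clipped to a small positive
#' floor (a warning is issued if clipping touches more than 1% of cells).
#' The true factors and offsets are recorded in the `"truth"` attribute
#' for recovery tests.
#'
#' @param d Clean [glycomics_dataset()] from [sample_abundances()].
#' @param config The [simulation_config()] (uses `sigma_d`, `sigma_o`,
#'   `seed`).
#' @return The contaminated [glycomics_dataset()].
#' @export
apply_artifacts <- function(d, config) {
  stopifnot(inherits(d, "glycomics_dataset"),
            inherits(config, "simulation_config"))
  X <- d$abundance
  n <- nrow(X)
  set.seed(config$seed + 1L)
  f <- exp(stats::rnorm(n, 0, config$sigma_d))
  o <- stats::rnorm(n, 0, config$sigma_o)
  Y <- X * f + o
  floor_val <- 1e-6 * stats::median(X)
  n_clip <- sum(Y < floor_val)
  if (n_clip > 0.01 * length(Y))
    warning(sprintf("positivity clipping affected %.2f%% of cells",
                    100 * n_clip / length(Y)))
  Y[Y < floor_val] <- floor_val
  truth <- attr(d, "truth")
  truth$dilution <- stats::setNames(f, rownames(X))
  truth$offset <- stats::setNames(o, rownames(X))
  d$abundance <- Y
  attr(d, "truth") <- truth
  d
}

#' Ground truth of a simulated dataset
#' @param d A dataset produced by [sample_abundances()] /
#'   [apply_artifacts()].
#' @return The truth list (pathway, precision, dilution factors, ...).
#' @export
simulation_truth <- function(d) attr(d, "truth")

platform_panel <- function(platform) {
  switch(platform,
         "lc-esi-ms" = {
           pan <- igg_glycoforms()
           pw <- build_igg_fc_pathway(pan)
           list(pathway = pw, subclass = pan$subclass)
         },
         "uhplc-fld" = {
           pan <- uhplc_peak_panel()
           comps <- lapply(pan$composition, parse_composition,
                           dialect = "igg_short")
           names(comps) <- pan$label
           pw <- glycan_pathway(pan$label, enzymatic_edges(comps),
                                compositions = comps)
           list(pathway = pw, subclass = NULL)
         },
         "maldi-fticr-ms" = {
           comps <- plasma_composition_panel(61)
           masses <- vapply(comps, composition_mass, numeric(1))
           pw <- build_mass_pathway(comps, stats::setNames(masses,
                                                           names(comps)))
           # carry compositions over (one structure per mass here)
           pw$compositions <- stats::setNames(comps, names(comps))
           list(pathway = pw, subclass = NULL)
         },
         stop("no panel defined for platform ", platform))
}

#' Plasma N-glycome composition panel
#'
#' Enumerates plausible complex/hybrid/high-mannose N-glycan compositions
#' and returns the first `n` (breadth-first from the Man3GlcNAc2 core over
#' single-monosaccharide additions), each with a distinct mass — emulating
#' a mass-resolved total-plasma panel.
#'
#' @param n Number of compositions (default 61).
#' @return Named list of [glycan_composition()]s keyed by `HxNyFzSw`
#'   strings.
#' @export
plasma_composition_panel <- function(n = 61) {
  grid <- expand.grid(h = 3:8, nn = 2:6, f = 0:1, s = 0:4)
  grid <- grid[grid$s <= pmax(grid$nn - 2, 0), ]  # sialic acids need antennae
  key <- sprintf("H%dN%dF%dS%d", grid$h, grid$nn, grid$f, grid$s)
  comps <- mapply(function(h, nn, f, s, k)
    glycan_composition(h, nn, f, s, label = k),
    grid$h, grid$nn, grid$f, grid$s, key, SIMPLIFY = FALSE)
  names(comps) <- key
  # breadth-first from the core so the panel is pathway-connected
  edges <- enzymatic_edges(comps)
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  start <- "H3N2F0S0"
  seen <- character(0)
  queue <- start
  while (length(queue) && length(seen) < n) {
    cur <- queue[1]; queue <- queue[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    queue <- c(queue, sort(setdiff(adj[[cur]], seen)))
  }
  if (length(seen) < n)
    stop("panel enumeration exhausted before reaching ", n, " compositions")
  comps[seen]
}

#' Generate a synthetic benchmark on disk
#'
#' Emits delimited files in the package's I/O formats, shaped like the
#' glycomics panels of the three platforms (50 subclass-resolved
#' glycoforms, 24 chromatographic peaks, or 61 masses), together with a
#' JSON ground-truth file (seed, config, pathway edges, per-sample
#' dilution factors, age slopes).
#'
#' @param platform `"lc-esi-ms"`, `"uhplc-fld"` or `"maldi-fticr-ms"`.
#' @param dir Output directory (created if needed).
#' @param n Number of samples.
#' @param ... Further arguments to [simulation_config()] (`rho`, `sigma`,
#'   `sigma_d`, `sigma_o`, `age_slopes`, `seed`, ...).
#' @return Invisibly, a list with the dataset, pathway and file paths.
#' @export
generate_benchmark <- function(platform, dir, n = 300, ...) {
  platform <- match.arg(platform, setdiff(PLATFORMS, "generic"))
  pan <- platform_panel(platform)
  cfg <- simulation_config(pan$pathway, n = n, ...)
  d <- apply_artifacts(sample_abundances(cfg), cfg)
  d$platform <- platform
  if (!is.null(pan$subclass)) {
    d$glycan_meta <- data.frame(
      subclass = pan$subclass,
      composition = d$glycan_meta$composition %||% NA_character_,
      stringsAsFactors = FALSE)
    rownames(d$glycan_meta) <- colnames(d$abundance)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(abundance = file.path(dir, "abundance.tsv"),
                sample_meta = file.path(dir, "sample_meta.tsv"),
                glycan_meta = file.path(dir, "glycan_meta.tsv"),
                edges = file.path(dir, "pathway_edges.tsv"),
                nodes = file.path(dir, "pathway_nodes.tsv"),
                truth = file.path(dir, "truth.json"))
  utils::write.table(data.frame(sample_id = rownames(d$abundance),
                                d$abundance, check.names = FALSE),
                     paths$abundance, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(d$abundance),
                                d$sample_meta, check.names = FALSE),
                     paths$sample_meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(d$glycan_meta))
    utils::write.table(data.frame(glycan_id = colnames(d$abundance),
                                  d$glycan_meta, check.names = FALSE),
                       paths$glycan_meta, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_pathway(pan$pathway, paths$edges, paths$nodes)
  truth <- simulation_truth(d)
  jsonlite::write_json(
    list(seed = cfg$seed, n = cfg$n, rho = cfg$rho, sigma = cfg$sigma,
         sigma_d = cfg$sigma_d, sigma_o = cfg$sigma_o,
         platform = platform,
         edges = data.frame(from = pan$pathway$edges[, 1],
                            to = pan$pathway$edges[, 2],
                            stringsAsFactors = FALSE),
         dilution = as.list(truth$dilution),
         age_slopes = as.list(truth$slopes[truth$slopes != 0])),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(dataset = d, pathway = pan$pathway, paths = paths,
                 config = cfg))
}
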