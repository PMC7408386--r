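# Glycomics abundance container and delimited-text I/O.

PLATFORMS <- c("lc-esi-ms", "uhplc-fld", "maldi-fticr-ms", "generic")

#' Glycomics dataset container
#'
#' A samples-by-glycans abundance matrix plus optional per-sample metadata
#' (`age`) and per-glycan metadata (`subclass`, `composition`, `mass`).
#' All downstream computation is defined on this canonical orientation.
#'
#' @param abundance Numeric matrix, samples in rows, glycans in columns;
#'   non-negative reals, `NA` allowed before complete-case filtering.
#'   Dimnames are used as sample/glycan ids if `sample_ids`/`glycan_ids`
#'   are not given.
#' @param sample_meta Optional data.frame of per-sample metadata (one row
#'   per sample, same order).
#' @param glycan_meta Optional data.frame of per-glycan metadata.
#' @param platform One of `"lc-esi-ms"`, `"uhplc-fld"`, `"maldi-fticr-ms"`,
#'   `"generic"`.
#' @param sample_ids,glycan_ids Optional id vectors overriding dimnames.
#' @return An object of class `"glycomics_dataset"`.
#' @export
glycomics_dataset <- function(abundance, sample_meta = NULL,
                              glycan_meta = NULL, platform = "generic",
                              sample_ids = NULL, glycan_ids = NULL) {
  stopifnot(is.matrix(abundance), is.numeric(abundance))
  platform <- match.arg(platform, PLATFORMS)
  if (is.null(sample_ids))
    sample_ids <- rownames(abundance) %||% paste0("S", seq_len(nrow(abundance)))
  if (is.null(glycan_ids))
    glycan_ids <- colnames(abundance) %||% paste0("G", seq_len(ncol(abundance)))
  if (length(sample_ids) != nrow(abundance) ||
      length(glycan_ids) != ncol(abundance))
    stop("id lengths must match matrix dimensions")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(glycan_ids)) stop("duplicate glycan ids")
  dimnames(abundance) <- list(sample_ids, glycan_ids)
  if (any(abundance < 0, na.rm = TRUE))
    stop("abundances must be non-negative")
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    stopifnot(nrow(sample_meta) == nrow(abundance))
    rownames(sample_meta) <- sample_ids
  }
  if (!is.null(glycan_meta)) {
    glycan_meta <- as.data.frame(glycan_meta)
    stopifnot(nrow(glycan_meta) == ncol(abundance))
    rownames(glycan_meta) <- glycan_ids
  }
  structure(list(abundance = abundance, sample_meta = sample_meta,
                 glycan_meta = glycan_meta, platform = platform),
            class = "glycomics_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.glycomics_dataset <- function(x, ...) {
  cat(sprintf("<glycomics dataset> %d samples x %d glycans [%s]%s\n",
              nrow(x$abundance), ncol(x$abundance), x$platform,
              if (anyNA(x$abundance)) ", contains missing values" else ""))
  if (!is.null(x$glycan_meta) && "subclass" %in% names(x$glycan_meta)) {
    tb <- table(x$glycan_meta$subclass)
    cat("  subclasses:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.glycomics_dataset <- function(x) dim(x$abundance)

na_tokens <- c("", "na", "nan")

sniff_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited abundance table
#'
#' Reads a TSV/CSV table with a header row and an id column into a
#' [glycomics_dataset()] in canonical samples-by-glycans orientation.
#' Empty cells, `"NA"` and `"NaN"` (case-insensitive) are recorded as
#' missing. Duplicate ids, ragged rows and non-numeric cells raise errors
#' naming the offending location.
#'
#' @param path Path to the delimited file.
#' @param orientation `"samples_in_rows"` (default) or `"glycans_in_rows"`
#'   if the file is transposed.
#' @param sample_meta_path,glycan_meta_path Optional paths to delimited
#'   metadata tables (id column first) aligned by id.
#' @param platform Platform tag, see [glycomics_dataset()].
#' @param sep Field separator; sniffed from the extension when `NULL`
#'   (`.csv` is comma, everything else tab).
#' @return A [glycomics_dataset()].
#' @export
read_abundance_table <- function(path,
                                 orientation = c("samples_in_rows",
                                                 "glycans_in_rows"),
                                 sample_meta_path = NULL,
                                 glycan_meta_path = NULL,
                                 platform = "generic", sep = NULL) {
  orientation <- match.arg(orientation)
  sep <- sniff_sep(path, sep)
  nf <- utils::count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1)
    stop(sprintf("ragged rows in '%s': rows %s have differing field counts",
                 path, paste(utils::head(which(nf != nf[1]), 5), collapse = ", ")))
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"",
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate row ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cols <- colnames(raw)[-1]
  if (anyDuplicated(cols))
    stop("duplicate column ids: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  is_na <- is.na(vals) | tolower(trimws(vals)) %in% na_tokens
  num <- suppressWarnings(as.numeric(vals))
  bad <- which(is.na(num) & !is_na)
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(vals)) + 1
    j <- ((bad[1] - 1) %/% nrow(vals)) + 1
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                 vals[bad[1]], ids[i], cols[j], path))
  }
  m <- matrix(num, nrow = nrow(vals), dimnames = list(ids, cols))
  if (orientation == "glycans_in_rows") m <- t(m)
  smeta <- gmeta <- NULL
  if (!is.null(sample_meta_path)) {
    smeta <- read_meta_table(sample_meta_path, rownames(m))
  }
  if (!is.null(glycan_meta_path)) {
    gmeta <- read_meta_table(glycan_meta_path, colnames(m))
  }
  glycomics_dataset(m, sample_meta = smeta, glycan_meta = gmeta,
                    platform = platform)
}

read_meta_table <- function(path, ids) {
  tb <- utils::read.table(path, sep = sniff_sep(path), header = TRUE,
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  key <- as.character(tb[[1]])
  miss <- setdiff(ids, key)
  if (length(miss))
    stop("metadata in ", path, " missing ids: ",
         paste(utils::head(miss, 5), collapse = ", "))
  out <- tb[match(ids, key), -1, drop = FALSE]
  rownames(out) <- ids
  out
}

#' Drop samples with missing values
#'
#' Complete-case filter applied before normalization: every sample with at
#' least one missing abundance is removed; the order of the remaining
#' samples is preserved.
#'
#' @param d A [glycomics_dataset()].
#' @return A list with elements `dataset` (the filtered
#'   [glycomics_dataset()]) and `n_removed`.
#' @export
drop_incomplete_samples <- function(d) {
  stopifnot(inherits(d, "glycomics_dataset"))
  keep <- rowSums(is.na(d$abundance)) == 0
  if (!any(keep)) stop("all samples contain missing values")
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    d$abundance <- d$abundance[keep, , drop = FALSE]
    if (!is.null(d$sample_meta))
      d$sample_meta <- d$sample_meta[keep, , drop = FALSE]
  }
  list(dataset = d, n_removed = n_removed)
}

#' Read a pathway edge list
#'
#' Two-column delimited edge list resolved against a known node set.
#' Duplicate edge lines collapse to one canonical edge; unknown nodes and
#' self-loops are rejected.
#'
#' @param path Path to a two-column TSV/CSV (header optional, detected).
#' @param nodes Character vector of admissible node identifiers.
#' @return A [glycan_pathway()] over `nodes`.
#' @export
read_pathway_edges <- function(path, nodes) {
  sep <- sniff_sep(path)
  tb <- utils::read.table(path, sep = sep, header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          col.names = c("from", "to"))
  # tolerate a header line
  if (nrow(tb) && !(tb[1, 1] %in% nodes) && !(tb[1, 2] %in% nodes) &&
      any(tb[-1, 1] %in% nodes))
    tb <- tb[-1, , drop = FALSE]
  bad <- setdiff(unique(c(tb$from, tb$to)), nodes)
  if (length(bad))
    stop("unknown pathway node(s): ", paste(bad, collapse = ", "))
  glycan_pathway(nodes, as.matrix(tb))
}

#' Write a pathway as edge list and node attributes
#'
#' @param pathway A [glycan_pathway()].
#' @param edge_path Output TSV for the two-column edge list.
#' @param node_path Optional TSV for node attributes (composition string,
#'   mass where available).
#' @param graphml_path Optional GraphML export (via igraph).
#' @return Invisibly, `pathway`.
#' @export
write_pathway <- function(pathway, edge_path, node_path = NULL,
                          graphml_path = NULL) {
  stopifnot(inherits(pathway, "glycan_pathway"))
  utils::write.table(pathway$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("from", "to"))
  if (!is.null(node_path)) {
    comp <- if (!is.null(pathway$compositions))
      vapply(pathway$nodes, function(n) {
        cc <- pathway$compositions[[n]]
        if (is.null(cc)) NA_character_ else format(cc)
      }, character(1)) else NA_character_
    mass <- if (!is.null(pathway$mass))
      unname(pathway$mass[pathway$nodes]) else NA_real_
    utils::write.table(
      data.frame(node = pathway$nodes, composition = comp, mass = mass),
      node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(as.data.frame(pathway$edges),
                                       directed = FALSE,
                                       vertices = pathway$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(pathway)
}

#' Write a strategy ranking table
#'
#' One row per normalization strategy: label, bootstrap median Fisher
#' p-value, 95% CI bounds and rank, sorted by median p ascending with ties
#' broken by label. Values are written with 15 significant digits so that a
#' re-read reproduces them.
#'
#' @param evaluations A `"norm_benchmark"` object, a list of
#'   `"strategy_evaluation"` objects, or a ranking data.frame.
#' @param path Output TSV path.
#' @param header_comment Optional comment line(s) written as `# ...` before
#'   the header (e.g. a config hash).
#' @return Invisibly, the ranking data.frame as written.
#' @export
write_results <- function(evaluations, path, header_comment = NULL) {
  rk <- if (is.data.frame(evaluations)) evaluations
        else rank_strategies(evaluations)
  out <- data.frame(
    label = rk$label,
    median_p = sprintf("%.15g", rk$median_p),
    ci_low = sprintf("%.15g", rk$ci_low),
    ci_high = sprintf("%.15g", rk$ci_high),
    rank = rk$rank)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rk)
}

#' Read back a strategy ranking table
#'
#' @param path TSV written by [write_results()].
#' @return A data.frame with columns label, median_p, ci_low, ci_high, rank.
#' @export
read_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
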