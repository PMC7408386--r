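# Glycan compositions and rule-based synthesis pathway priors.
#
# Compositions are held at the monosaccharide-class level: hexose
# (mannose/galactose), HexNAc (GlcNAc, including core, antenna and bisecting
# residues), fucose (deoxyhexose) and NeuAc (sialic acid). Two glycans are
# joined by a pathway edge when they differ by the addition of exactly one
# monosaccharide, i.e. a single enzymatic synthesis step.

#' Glycan monosaccharide composition
#'
#' Construct a composition-level description of one glycan or glycopeptide:
#' counts of hexose, HexNAc, fucose and NeuAc residues.
#'
#' @param hexose,hexnac,fucose,neuac Non-negative integer residue counts;
#'   at least one must be positive.
#' @param label Free-text original name of the glycan (kept for reporting).
#' @return An object of class `"glycan_composition"`.
#' @examples
#' glycan_composition(5, 4, 1, 1, label = "H5N4F1S1")
#' @export
glycan_composition <- function(hexose, hexnac = 0L, fucose = 0L, neuac = 0L,
                               label = NULL) {
  counts <- c(hexose = hexose, hexnac = hexnac, fucose = fucose, neuac = neuac)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("composition counts must be non-negative integers")
  if (sum(counts) == 0)
    stop("composition must contain at least one residue")
  structure(list(hexose = as.integer(hexose), hexnac = as.integer(hexnac),
                 fucose = as.integer(fucose), neuac = as.integer(neuac),
                 label = label),
            class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(sprintf("<glycan composition%s> H%dN%dF%dS%d\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$hexose, x$hexnac, x$fucose, x$neuac))
  invisible(x)
}

#' @export
format.glycan_composition <- function(x, ...) {
  sprintf("H%dN%dF%dS%d", x$hexose, x$hexnac, x$fucose, x$neuac)
}

comp_counts <- function(x) {
  c(hexose = x$hexose, hexnac = x$hexnac, fucose = x$fucose, neuac = x$neuac)
}

#' Parse a glycan name into a composition
#'
#' Two nomenclature dialects are supported:
#' \describe{
#'   \item{`"hnfs"`}{Literal composition strings such as `"H5N4F1S1"`
#'     (hexose, HexNAc, fucose, NeuAc; `F`/`S` parts optional).}
#'   \item{`"igg_short"`}{Short names used for IgG Fc glycoforms.  Both the
#'     `G`-style (`G0F`, `G1FN`, `G2FS2`: core Man3GlcNAc2 plus two antenna
#'     GlcNAc, optional core fucose `F`, bisecting GlcNAc `N`, `Gx`
#'     galactoses, `Sx` sialic acids) and the Oxford style (`FA2G2S1`,
#'     `A2BG2`: `F` core fucose, `Ax` antenna GlcNAcs, `B` bisecting GlcNAc,
#'     `Gx` galactoses, `Sx` NeuAc) are recognised, as are high-mannose names
#'     `M5`..`M9`.}
#' }
#' The IgG core Man3GlcNAc2 contributes hexose = 3, hexnac = 2; antenna and
#' bisecting GlcNAcs add to hexnac, galactoses to hexose.
#'
#' @param name Glycan name string.
#' @param dialect `"igg_short"` or `"hnfs"`.
#' @return A [glycan_composition()] with `label = name`.
#' @examples
#' parse_composition("H5N4F1S1", "hnfs")
#' parse_composition("FA2G2S1", "igg_short")  # same composition
#' parse_composition("G2FS1", "igg_short")    # same composition
#' @export
parse_composition <- function(name, dialect = c("igg_short", "hnfs")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(name), length(name) == 1L, !is.na(name))
  if (dialect == "hnfs") {
    m <- regmatches(name, regexec("^H([0-9]+)N([0-9]+)(F([0-9]+))?(S([0-9]+))?$",
                                  name))[[1]]
    if (length(m) == 0)
      stop(sprintf("cannot parse '%s' as an hnfs composition string", name))
    num <- function(s) if (nzchar(s)) as.integer(s) else 0L
    return(glycan_composition(num(m[2]), num(m[3]), num(m[5]), num(m[7]),
                              label = name))
  }
  # igg_short: high-mannose
  m <- regmatches(name, regexec("^M([0-9])$", name))[[1]]
  if (length(m) > 0)
    return(glycan_composition(as.integer(m[2]), 2L, 0L, 0L, label = name))
  # igg_short: Oxford style, e.g. FA2BG2S1
  m <- regmatches(name,
                  regexec("^(F)?A([0-9])(B)?(G([0-9]))?(S([0-9]))?$", name))[[1]]
  if (length(m) > 0) {
    ant <- as.integer(m[3])
    gal <- if (nzchar(m[6])) as.integer(m[6]) else 0L
    sia <- if (nzchar(m[8])) as.integer(m[8]) else 0L
    return(glycan_composition(3L + gal, 2L + ant + (m[4] == "B"),
                              as.integer(m[2] == "F"), sia, label = name))
  }
  # igg_short: G style, e.g. G2FNS1 (core = Man3GlcNAc2 + 2 antenna GlcNAc)
  m <- regmatches(name,
                  regexec("^G([0-9])(F)?(N)?(S([0-9])?)?$", name))[[1]]
  if (length(m) > 0) {
    gal <- as.integer(m[2])
    sia <- if (nzchar(m[5])) {
      if (nzchar(m[6])) as.integer(m[6]) else 1L
    } else 0L
    return(glycan_composition(3L + gal, 4L + (m[4] == "N"),
                              as.integer(m[3] == "F"), sia, label = name))
  }
  stop(sprintf("cannot parse '%s' in dialect 'igg_short'", name))
}

#' Monoisotopic residue masses (Da)
#'
#' Residue (water-loss) monoisotopic masses used to compare glycan
#' compositions by mass. Constant offsets such as the reducing-end water or
#' the peptide moiety cancel in equality comparisons, so they are excluded.
#'
#' @return Named numeric vector with entries `hexose`, `hexnac`, `fucose`
#'   (deoxyhexose) and `neuac`.
#' @export
monosaccharide_masses <- function() {
  c(hexose = 162.05282, hexnac = 203.07937,
    fucose = 146.05791, neuac = 291.09542)
}

#' Mass of a glycan composition
#'
#' @param composition A [glycan_composition()].
#' @param masses Residue mass table, see [monosaccharide_masses()].
#' @return Summed residue mass in Da.
#' @export
composition_mass <- function(composition, masses = monosaccharide_masses()) {
  stopifnot(inherits(composition, "glycan_composition"),
            all(c("hexose", "hexnac", "fucose", "neuac") %in% names(masses)),
            all(masses > 0))
  sum(comp_counts(composition) *
        masses[c("hexose", "hexnac", "fucose", "neuac")])
}

# canonical unordered edge matrix: two character columns, first < second,
# rows deduplicated and sorted
canonical_edges <- function(a, b = NULL) {
  if (is.null(b)) {
    if (length(a) == 0) return(matrix(character(), ncol = 2))
    stopifnot(is.matrix(a), ncol(a) == 2)
    b <- a[, 2]; a <- a[, 1]
  }
  lo <- unname(pmin(a, b)); hi <- unname(pmax(a, b))
  keep <- !duplicated(paste(lo, hi, sep = "\x1f"))
  m <- cbind(lo[keep], hi[keep])
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

edge_keys <- function(edges) {
  if (nrow(edges) == 0) return(character())
  paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]),
        sep = "\x1f")
}

#' Single-step enzymatic edges between compositions
#'
#' Two glycans are connected by a synthesis edge when their compositions
#' differ by exactly one residue in exactly one monosaccharide class
#' (equivalently, Manhattan distance one between count vectors): the
#' incremental addition of a single monosaccharide.
#'
#' @param compositions Named list of [glycan_composition()] objects; names
#'   are the glycan identifiers and must be unique.
#' @return A two-column character matrix of unordered node pairs in
#'   canonical order.
#' @export
enzymatic_edges <- function(compositions) {
  stopifnot(is.list(compositions), length(compositions) >= 2)
  ids <- names(compositions)
  if (is.null(ids) || anyDuplicated(ids))
    stop("compositions must be uniquely named")
  cm <- t(vapply(compositions, comp_counts, numeric(4)))
  d <- as.matrix(stats::dist(cm, method = "manhattan"))
  hit <- which(d == 1 & upper.tri(d), arr.ind = TRUE)
  canonical_edges(ids[hit[, 1]], ids[hit[, 2]])
}

#' Reference glycan synthesis pathway
#'
#' An undirected graph over glycan identifiers whose edges represent single
#' enzymatic synthesis steps. Node attributes (compositions and/or masses)
#' are optional.
#'
#' @param nodes Character vector of unique node identifiers.
#' @param edges Two-column character matrix (or data.frame) of node pairs;
#'   self-loops are rejected, storage is canonical and deduplicated.
#' @param compositions Optional named list of [glycan_composition()]s.
#' @param mass Optional named numeric vector of node masses (Da).
#' @return An object of class `"glycan_pathway"`.
#' @export
glycan_pathway <- function(nodes, edges = NULL, compositions = NULL,
                           mass = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate pathway node identifiers")
  if (is.null(edges)) edges <- matrix(character(), ncol = 2)
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  edges <- matrix(as.character(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    bad <- setdiff(c(edges), nodes)
    if (length(bad))
      stop("edge endpoints not in node set: ", paste(bad, collapse = ", "))
    edges <- canonical_edges(edges)
  }
  if (!is.null(compositions)) {
    bad <- setdiff(names(compositions), nodes)
    if (length(bad))
      stop("composition attributes for unknown nodes: ",
           paste(bad, collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges,
                 compositions = compositions, mass = mass),
            class = "glycan_pathway")
}

#' @export
print.glycan_pathway <- function(x, ...) {
  cat(sprintf("<glycan pathway> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges in a pathway
#' @param pathway A [glycan_pathway()].
#' @return Integer edge count.
#' @export
n_edges <- function(pathway) nrow(pathway$edges)

#' Build the subclass-resolved IgG Fc synthesis pathway
#'
#' For glycopeptide data resolved by IgG subclass, the same glycosylation
#' pathway is assumed within each subclass; nodes are subclass-qualified
#' labels and within-subclass edges follow the single-monosaccharide rule
#' ([enzymatic_edges()]). Cross-subclass edges (between identical
#' compositions carried by different subclasses) can optionally be added.
#'
#' @param glycans A data.frame with columns `label`, `subclass` and
#'   `composition` (name strings in `dialect`), or a list with those
#'   components where `composition` may be a list of
#'   [glycan_composition()]s.
#' @param include_cross_subclass Add edges between identical compositions in
#'   different subclasses (default `FALSE`).
#' @param dialect Nomenclature dialect for composition strings.
#' @param sep Separator between subclass and label in node identifiers.
#' @return A [glycan_pathway()] whose node ids are
#'   `paste(subclass, label, sep = sep)`.
#' @export
build_igg_fc_pathway <- function(glycans, include_cross_subclass = FALSE,
                                 dialect = "igg_short", sep = " ") {
  label <- as.character(glycans$label)
  subclass <- as.character(glycans$subclass)
  stopifnot(length(label) == length(subclass), length(label) > 0)
  comps <- glycans$composition
  if (is.character(comps))
    comps <- lapply(comps, parse_composition, dialect = dialect)
  stopifnot(length(comps) == length(label))
  if (anyDuplicated(paste(subclass, label)))
    stop("labels must be unique within subclass")
  ids <- paste(subclass, label, sep = sep)
  names(comps) <- ids
  ed <- list()
  for (sc in unique(subclass)) {
    sel <- subclass == sc
    if (sum(sel) >= 2) ed[[sc]] <- enzymatic_edges(comps[sel])
  }
  edges <- do.call(rbind, c(ed, list(matrix(character(), ncol = 2))))
  if (include_cross_subclass) {
    key <- vapply(comps, format.glycan_composition, character(1))
    for (k in unique(key)) {
      grp <- ids[key == k]
      if (length(grp) >= 2) {
        pairs <- utils::combn(sort(grp), 2)
        cross <- cbind(pairs[1, ], pairs[2, ])
        # only across different subclasses
        sc_of <- subclass[match(c(cross), ids)]
        dim(sc_of) <- dim(cross)
        edges <- rbind(edges, cross[sc_of[, 1] != sc_of[, 2], , drop = FALSE])
      }
    }
  }
  glycan_pathway(ids, edges, compositions = comps)
}

#' Build a mass-merged compositional pathway
#'
#' For platforms that resolve only molecular masses (not structures), the
#' structure-level pathway is collapsed: all structures of equal mass are
#' merged into a single node (union of incident edges, self-loops dropped),
#' and nodes whose mass does not match any measured mass are removed.
#' Optionally, pairs of retained nodes that were connected through a removed
#' node receive a direct bridging edge.
#'
#' @param structures Named list of [glycan_composition()]s (names = structure
#'   labels).
#' @param measured_masses Numeric vector of measured mass keys; retained
#'   nodes are named by these keys (as formatted by `names(measured_masses)`
#'   if present, else by the numeric value).
#' @param masses Residue mass table.
#' @param bridge_removed Add direct edges between retained neighbours of a
#'   removed node (default `FALSE`: edges through removed nodes are lost).
#' @param tol Mass-matching tolerance in Da (default 0.5).
#' @return A [glycan_pathway()] over the measured mass keys. Measured masses
#'   matching no structure produce a warning and are kept as degree-0 nodes.
#' @export
build_mass_pathway <- function(structures, measured_masses,
                               masses = monosaccharide_masses(),
                               bridge_removed = FALSE, tol = 0.5) {
  stopifnot(length(structures) >= 2)
  labs <- names(structures)
  if (is.null(labs) || anyDuplicated(labs))
    stop("structures must be uniquely named")
  mkeys <- names(measured_masses)
  if (is.null(mkeys)) mkeys <- format(measured_masses, trim = TRUE)
  mvals <- as.numeric(measured_masses)
  if (any(is.na(mvals))) stop("measured masses must be numeric")

  full <- enzymatic_edges(structures)
  smass <- vapply(structures, composition_mass, numeric(1), masses = masses)

  # merge structures of equal mass (exact up to rounding noise)
  grp <- match(round(smass, 4), unique(round(smass, 4)))
  gmass <- vapply(split(smass, grp), mean, numeric(1))

  # map each merged group to a measured mass key within tolerance
  hit <- vapply(gmass, function(m) {
    i <- which(abs(mvals - m) <= tol)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
  node_of <- ifelse(is.na(hit[grp]), NA_character_, mkeys[hit[grp]])
  names(node_of) <- labs

  unmatched <- setdiff(seq_along(mvals), hit[!is.na(hit)])
  if (length(unmatched))
    warning(sprintf("%d measured mass(es) match no structure (kept, degree 0): %s",
                    length(unmatched),
                    paste(mkeys[unmatched], collapse = ", ")))

  # project structure edges onto merged/retained nodes
  keep_edges <- matrix(character(), ncol = 2)
  if (nrow(full)) {
    a <- node_of[full[, 1]]; b <- node_of[full[, 2]]
    ok <- !is.na(a) & !is.na(b) & a != b
    keep_edges <- cbind(unname(a[ok]), unname(b[ok]))
  }
  if (bridge_removed && nrow(full)) {
    removed <- labs[is.na(node_of)]
    for (rn in removed) {
      inc <- full[full[, 1] == rn | full[, 2] == rn, , drop = FALSE]
      nb <- setdiff(c(inc), rn)
      nb <- unique(stats::na.omit(node_of[nb]))
      if (length(nb) >= 2) {
        pr <- utils::combn(sort(nb), 2)
        keep_edges <- rbind(keep_edges, cbind(pr[1, ], pr[2, ]))
      }
    }
  }
  node_mass <- mvals
  names(node_mass) <- mkeys
  glycan_pathway(mkeys, keep_edges, mass = node_mass)
}

#' Standard IgG Fc glycoform panel
#'
#' The subclass-resolved glycopeptide panel typically quantified for IgG Fc:
#' 20 glycoforms for IgG1, 20 for IgG2/3 (identical peptide moieties, not
#' separable by mass) and 10 for the low-abundance IgG4.
#'
#' @return A data.frame with columns `label`, `subclass`, `composition`
#'   (igg_short names) — suitable input for [build_igg_fc_pathway()].
#' @export
igg_glycoforms <- function() {
  g20 <- c("G0", "G0F", "G0N", "G0FN",
           "G1", "G1F", "G1N", "G1FN",
           "G2", "G2F", "G2N", "G2FN",
           "G1S1", "G1FS1", "G2S1", "G2FS1",
           "G2NS1", "G2FNS1", "G2S2", "G2FS2")
  g10 <- c("G0", "G0F", "G1", "G1F", "G2", "G2F",
           "G1FS1", "G2S1", "G2FS1", "G2FS2")
  data.frame(
    label = c(g20, g20, g10),
    subclass = rep(c("IgG1", "IgG2/3", "IgG4"), c(20, 20, 10)),
    composition = c(g20, g20, g10),
    stringsAsFactors = FALSE)
}

#' Predominant-structure panel for chromatographic total-IgG glycans
#'
#' A 24-peak panel where each chromatographic peak is approximated by its
#' single most abundant glycan structure (Oxford nomenclature).
#'
#' @return A data.frame with columns `label` and `composition`.
#' @export
uhplc_peak_panel <- function() {
  labs <- c("A1", "FA1", "A2", "FA2", "A2B", "FA2B", "M5", "M6", "M7",
            "A2G1", "FA2G1", "FA2BG1", "A2G2", "FA2G2", "FA2BG2", "A2BG2",
            "A2G1S1", "FA2G1S1", "A2G2S1", "FA2G2S1", "FA2BG2S1",
            "A2G2S2", "FA2G2S2", "FA2BG2S2")
  data.frame(label = labs, composition = labs, stringsAsFactors = FALSE)
}
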