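#' Dated ultrametric phylogenies
#'
#' A `dated_tree` wraps an [ape::phylo] object together with node ages in
#' millions of years before present (Ma). All likelihood machinery in the
#' package consumes this class. Construction validates that the tree is
#' rooted, ultrametric (all tip ages equal 0 within `tol`) and, optionally,
#' fully bifurcating -- cladogenetic range-evolution models are only defined
#' on bifurcating trees.
#'
#' @param phy an object of class `phylo` with branch lengths in Ma.
#' @param tol ultrametricity tolerance in Ma. Published dated trees carry
#'   rounding noise, so the default is loose relative to machine precision.
#' @param force_ultrametric if `TRUE`, accept a non-ultrametric tree anyway
#'   (ages are taken from the root-to-node path lengths; tip ages are reset
#'   to zero for bookkeeping). Use only when you understand why your tree
#'   fails the check.
#' @param require_bifurcating reject polytomies when `TRUE`.
#'
#' @return an object of class `dated_tree`: a list with elements `phy`
#'   (the `phylo`), `ages` (numeric vector of node ages, Ma, indexed by ape
#'   node number), `root_age` and `n_tips`.
#' @export
dated_tree <- function(phy, tol = 1e-6, force_ultrametric = FALSE,
                       require_bifurcating = FALSE) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a \"phylo\" object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (any(phy$edge.length < 0)) stop("negative branch lengths are not allowed")
  n <- ape::Ntip(phy)
  if (n < 2L) stop("need at least 2 tips")
  depths <- ape::node.depth.edgelength(phy)  # root-to-node path lengths
  root_age <- max(depths[seq_len(n)])
  tip_err <- max(abs(depths[seq_len(n)] - root_age))
  if (tip_err > tol && !force_ultrametric) {
    stop(sprintf(paste0(
      "tree is not ultrametric: tip depths differ by up to %.3g Ma ",
      "(tolerance %.3g); pass force_ultrametric = TRUE to override"),
      tip_err, tol))
  }
  if (require_bifurcating && phy$Nnode != n - 1L) {
    stop("tree contains polytomies; cladogenesis models require a fully bifurcating tree")
  }
  ages <- root_age - depths
  ages[seq_len(n)] <- 0  # tips are the present
  structure(
    list(phy = phy, ages = ages, root_age = root_age, n_tips = n),
    class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("Dated ultrametric tree: %d tips, root age %.4f Ma\n",
              x$n_tips, x$root_age))
  cat("Tips:", paste(utils::head(x$phy$tip.label, 8), collapse = ", "),
      if (x$n_tips > 8) "..." else "", "\n")
  invisible(x)
}

#' Parse a Newick string or file into a dated tree
#'
#' Light syntactic pre-checks report the character offset of unbalanced
#' parentheses or a missing terminal semicolon; grammar-level parsing is
#' delegated to [ape::read.tree()]. Square-bracket comments are stripped,
#' quoted labels are supported by ape.
#'
#' @param text a Newick string (with branch lengths), or `NULL` if `file`
#'   is given.
#' @param file path to a Newick file.
#' @inheritParams dated_tree
#' @return a [dated_tree].
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2):0;")
#' tr$root_age  # 2
#' @export
parse_newick <- function(text = NULL, file = NULL, tol = 1e-6,
                         force_ultrametric = FALSE,
                         require_bifurcating = FALSE) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'text' or 'file'")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- gsub("\\[[^]]*\\]", "", text)  # drop comments
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("malformed Newick: unmatched ')' at character %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' by character %d",
                 depth, length(chars)))
  if (!grepl(";", text))
    stop(sprintf("malformed Newick: missing ';' terminator by character %d",
                 length(chars)))
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("ape could not parse the Newick string")
  dated_tree(phy, tol = tol, force_ultrametric = force_ultrametric,
             require_bifurcating = require_bifurcating)
}

#' Write a dated tree as Newick
#'
#' Branch lengths are emitted with `digits` decimal places (default 6).
#'
#' @param tree a [dated_tree].
#' @param file optional path; when `NULL` the Newick string is returned.
#' @param digits decimal places for branch lengths.
#' @export
write_newick <- function(tree, file = NULL, digits = 6) {
  stopifnot(inherits(tree, "dated_tree"))
  phy <- tree$phy
  phy$edge.length <- round(phy$edge.length, digits)
  txt <- ape::write.tree(phy, digits = digits + 4)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Phylogenetic covariance matrix
#'
#' Returns the matrix C with entry (i, j) equal to the shared path length
#' (Ma) from the root to the most recent common ancestor of tips i and j --
#' the covariance structure of Brownian motion on the tree (up to the rate
#' sigma^2). Symmetric, positive semidefinite; the diagonal equals the root
#' age for ultrametric trees.
#'
#' @param tree a [dated_tree].
#' @return a square numeric matrix with tip labels as dimnames.
#' @export
vcv_matrix <- function(tree) {
  stopifnot(inherits(tree, "dated_tree"))
  ape::vcv.phylo(tree$phy)
}

#' Epoch specification for time-stratified models
#'
#' Defines geological time slices and one areas-by-areas dispersal
#' multiplier matrix per slice. Boundaries run from the oldest (>= root
#' age of any tree the spec is used with) strictly down to 0 Ma.
#'
#' @param boundaries numeric vector of epoch boundaries in Ma, strictly
#'   decreasing, ending at 0 (e.g. `c(50, 35, 15, 5, 0)` gives four
#'   epochs).
#' @param multipliers a list with one non-negative areas x areas matrix per
#'   epoch (oldest epoch first), or `NULL` for all-ones multipliers.
#' @param areas character vector of area labels (required when
#'   `multipliers` is `NULL` and the spec is used for biogeography).
#' @return an object of class `epoch_spec`.
#' @export
epoch_spec <- function(boundaries, multipliers = NULL, areas = NULL) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L) stop("need at least two boundaries")
  if (any(diff(boundaries) >= 0))
    stop("boundaries must be strictly decreasing from oldest to youngest")
  if (utils::tail(boundaries, 1) != 0)
    stop("the youngest boundary must be 0 Ma (the present)")
  n_epochs <- length(boundaries) - 1L
  if (is.null(multipliers)) {
    if (is.null(areas)) stop("supply 'areas' when multipliers are omitted")
    m <- matrix(1, length(areas), length(areas),
                dimnames = list(areas, areas))
    multipliers <- rep(list(m), n_epochs)
  }
  if (length(multipliers) != n_epochs)
    stop(sprintf("expected %d multiplier matrices, got %d",
                 n_epochs, length(multipliers)))
  multipliers <- lapply(multipliers, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != ncol(m)) stop("multiplier matrices must be square")
    if (any(m < 0)) stop("multiplier entries must be >= 0")
    m
  })
  if (is.null(areas)) areas <- rownames(multipliers[[1]])
  structure(list(boundaries = boundaries, multipliers = multipliers,
                 areas = areas, n_epochs = n_epochs),
            class = "epoch_spec")
}

#' @export
print.epoch_spec <- function(x, ...) {
  cat(sprintf("Epoch specification: %d epochs over [%g, 0] Ma\n",
              x$n_epochs, x$boundaries[1]))
  for (i in seq_len(x$n_epochs))
    cat(sprintf("  epoch %d: %g - %g Ma\n", i, x$boundaries[i],
                x$boundaries[i + 1]))
  invisible(x)
}

#' Slice tree branches by epochs
#'
#' Cuts every branch of the tree at the epoch boundaries. A branch crossing
#' k boundaries yields k + 1 segments; segment durations sum to the branch
#' length exactly. Segments are reported oldest first.
#'
#' @param tree a [dated_tree].
#' @param epochs an [epoch_spec] covering `[0, root_age]`.
#' @return a data frame with columns `edge` (row index into
#'   `tree$phy$edge`), `epoch` (1 = oldest), `start` and `end` (Ma, start >
#'   end) and `duration`.
#' @export
slice_branches <- function(tree, epochs) {
  stopifnot(inherits(tree, "dated_tree"), inherits(epochs, "epoch_spec"))
  if (epochs$boundaries[1] < tree$root_age - 1e-9)
    stop(sprintf("epochs cover only [%g, 0] Ma but the root age is %g Ma",
                 epochs$boundaries[1], tree$root_age))
  edge <- tree$phy$edge
  ages <- tree$ages
  out <- vector("list", nrow(edge))
  b <- epochs$boundaries
  for (i in seq_len(nrow(edge))) {
    a_start <- ages[edge[i, 1]]  # parent, older
    a_end <- ages[edge[i, 2]]
    segs <- list()
    for (k in seq_len(epochs$n_epochs)) {
      lo <- b[k + 1]; hi <- b[k]
      s <- min(a_start, hi)
      e <- max(a_end, lo)
      if (s > e + 1e-12) segs[[length(segs) + 1L]] <-
          data.frame(edge = i, epoch = k, start = s, end = e,
                     duration = s - e)
    }
    if (length(segs) == 0L)  # zero-length branch: keep one degenerate segment
      segs[[1L]] <- data.frame(edge = i, epoch = epoch_of(a_start, epochs),
                               start = a_start, end = a_end, duration = 0)
    out[[i]] <- do.call(rbind, segs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# epoch index containing age a (1 = oldest); boundaries are half-open
# [b_k, b_{k+1}) except the youngest epoch which includes 0.
epoch_of <- function(a, epochs) {
  b <- epochs$boundaries
  for (k in seq_len(epochs$n_epochs))
    if (a <= b[k] + 1e-12 && a > b[k + 1] - 1e-12) return(k)
  if (a <= 1e-12) return(epochs$n_epochs)
  stop(sprintf("age %g Ma outside the epoch span [%g, 0]", a, b[1]))
}

#' Read a lagrange-style geography file
#'
#' Format: a header line `n_species n_areas (A B C D)` followed by one line
#' per species, `label<TAB>0101`, with a binary presence digit per area.
#' Tabs and runs of spaces are both accepted as separators.
#'
#' @param file path to the geography file.
#' @return a named list: `areas` (character) and `ranges`, a named list of
#'   character vectors of occupied areas per species.
#' @export
read_geography <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr <- lines[1]
  m <- regmatches(hdr, regexec("^(\\d+)\\s+(\\d+)\\s*\\(([^)]*)\\)", hdr))[[1]]
  if (length(m) != 4) stop("malformed geography header: ", hdr)
  n_sp <- as.integer(m[2]); n_ar <- as.integer(m[3])
  areas <- strsplit(trimws(m[4]), "\\s+")[[1]]
  if (length(areas) != n_ar)
    stop("header declares ", n_ar, " areas but names ", length(areas))
  body <- lines[-1]
  if (length(body) != n_sp)
    stop("header declares ", n_sp, " species but file has ", length(body))
  ranges <- list()
  for (ln in body) {
    parts <- strsplit(ln, "\\s+")[[1]]
    lab <- parts[1]; code <- parts[length(parts)]
    bits <- as.integer(strsplit(code, "")[[1]])
    if (length(bits) != n_ar || any(!bits %in% c(0L, 1L)))
      stop("bad range coding for ", lab, ": ", code)
    if (sum(bits) == 0L) stop("species ", lab, " has an empty range")
    ranges[[lab]] <- areas[bits == 1L]
  }
  list(areas = areas, ranges = ranges)
}

#' Write a lagrange-style geography file
#'
#' @param ranges named list of character vectors (areas per species).
#' @param areas character vector of all area labels, fixing column order.
#' @param file output path.
#' @export
write_geography <- function(ranges, areas, file) {
  hdr <- sprintf("%d\t%d\t(%s)", length(ranges), length(areas),
                 paste(areas, collapse = " "))
  body <- vapply(names(ranges), function(sp) {
    bits <- as.integer(areas %in% ranges[[sp]])
    sprintf("%s\t%s", sp, paste(bits, collapse = ""))
  }, character(1))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read an epoch specification from a YAML file
#'
#' The file must contain `boundaries` (Ma, oldest to 0) and `areas`;
#' `multipliers` is optional (list of matrices, oldest epoch first; all
#' ones when absent).
#'
#' @param file path to the YAML file.
#' @return an [epoch_spec].
#' @export
read_epochs <- function(file) {
  y <- yaml::read_yaml(file)
  if (is.null(y$boundaries)) stop("epoch YAML lacks 'boundaries'")
  mult <- NULL
  if (!is.null(y$multipliers)) {
    mult <- lapply(y$multipliers, function(m) {
      m <- do.call(rbind, lapply(m, as.numeric))
      dimnames(m) <- list(y$areas, y$areas)
      m
    })
  }
  epoch_spec(y$boundaries, multipliers = mult, areas = y$areas)
}
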