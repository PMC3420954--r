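#' Read a time-calibrated tree from newick text or file
#'
#' Thin, validating wrapper around [ape::read.tree()]. Branch lengths are
#' expected in millions of years (MY). The tree must be rooted, every
#' non-root edge must carry a branch length, and tip labels must be unique.
#' Polytomies are accepted and treated as hard.
#'
#' @param file path to a newick file, or `NULL` when `text` is given.
#' @param text newick string (alternative to `file`).
#' @return an object of class `phylo` that has passed [validate_chronogram()].
#' @seealso [write_chronogram()], [node_age()], [mrca_node()]
#' @export
read_chronogram <- function(file = NULL, text = NULL) {
  if (is.null(file) && is.null(text))
    stopf("supply either a file path or newick text")
  if (!is.null(text)) {
    tr <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr)) stopf("malformed newick: %s", describe_newick_error(text))
  } else {
    if (!file.exists(file)) stopf("tree file not found: %s", file)
    tr <- tryCatch(ape::read.tree(file = file),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(tr))
      stopf("malformed newick in %s: %s", file,
            describe_newick_error(paste(readLines(file, warn = FALSE),
                                        collapse = "")))
  }
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_chronogram(tr)
  tr
}

# Locate the first unbalanced parenthesis (1-based character offset) so the
# parse error names where the newick text breaks.
describe_newick_error <- function(text) {
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        return(sprintf("unbalanced ')' at character offset %d", i))
    }
  }
  if (depth > 0L)
    return(sprintf("%d unclosed '(' (text ends at offset %d)",
                   depth, length(chars)))
  "unparseable newick syntax"
}

#' Validate a chronogram
#'
#' Checks the structural invariants assumed by every downstream analysis:
#' a single root, unique non-empty tip labels, a branch length on every
#' non-root edge, and non-negative branch lengths.
#'
#' @param tree a `phylo` object.
#' @return `tree`, invisibly; errors otherwise.
#' @export
validate_chronogram <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a 'phylo' object")
  if (is.null(tree$edge.length))
    stopf("tree has no branch lengths; a chronogram requires them (in MY)")
  if (anyNA(tree$edge.length))
    stopf("missing branch length on %d edge(s)", sum(is.na(tree$edge.length)))
  if (any(tree$edge.length < 0))
    stopf("negative branch lengths are not allowed")
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate tip labels: %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  if (any(!nzchar(tree$tip.label))) stopf("empty tip labels")
  ntip <- length(tree$tip.label)
  # exactly one root: one node that never appears as a child
  kids <- tree$edge[, 2L]
  parents <- tree$edge[, 1L]
  roots <- setdiff(unique(parents), kids)
  if (length(roots) != 1L) stopf("tree must have exactly one root")
  # every tip reachable from the root
  if (!all(seq_len(ntip) %in% kids)) stopf("tips unreachable from the root")
  invisible(tree)
}

#' Write a chronogram to newick
#'
#' @param tree a validated `phylo` object.
#' @param file output path; when `NULL` the newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return newick string (invisibly when writing to file).
#' @export
write_chronogram <- function(tree, file = NULL, digits = 10) {
  validate_chronogram(tree)
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Test ultrametricity of a chronogram
#'
#' A chronogram is ultrametric when all root-to-tip path lengths agree to a
#' relative tolerance (default 1e-6; published chronograms carry rounding
#' error).
#'
#' @param tree a `phylo` object.
#' @param tol relative tolerance on root-to-tip depth spread.
#' @return logical.
#' @export
is_ultrametric_chronogram <- function(tree, tol = 1e-6) {
  validate_chronogram(tree)
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  scale <- max(d)
  if (scale == 0) return(TRUE)
  (max(d) - min(d)) / scale <= tol
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of tip labels (non-empty). The MRCA of a
#'   single tip is that tip itself.
#' @return integer node id (ape numbering: tips `1..n`, internals `n+1..`).
#' @export
mrca_node <- function(tree, taxa) {
  validate_chronogram(tree)
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stopf("empty taxon set")
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stopf("unknown tip label(s): %s", paste(unknown, collapse = ", "))
  if (length(taxa) == 1L) return(match(taxa, tree$tip.label))
  ape::getMRCA(tree, taxa)
}

#' Node ages on an ultrametric tree
#'
#' The age of a node is its distance (MY) to any descendant tip; tips have
#' age 0.
#'
#' @param tree an ultrametric `phylo` object.
#' @param node optional integer node id(s); default all nodes.
#' @param tol ultrametricity tolerance passed to
#'   [is_ultrametric_chronogram()].
#' @return numeric vector of ages in MY.
#' @export
node_age <- function(tree, node = NULL, tol = 1e-6) {
  if (!is_ultrametric_chronogram(tree, tol = tol))
    stopf("node ages require an ultrametric tree")
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth[seq_along(tree$tip.label)]) - depth
  age[age < 0] <- 0
  if (is.null(node)) return(age)
  if (any(node < 1L | node > length(age))) stopf("node id out of range")
  age[node]
}

#' Resolve a two-tip node specification
#'
#' Internal nodes are addressed as `"A|B"`, the MRCA of tips A and B. This
#' addressing is stable under ladderization, unlike figure-position node
#' letters. A bare tip label addresses that tip.
#'
#' @param tree a `phylo` object.
#' @param spec character vector of specs like `"A|B"` or `"A"`.
#' @return integer node ids.
#' @export
resolve_node_spec <- function(tree, spec) {
  vapply(spec, function(s) {
    parts <- strsplit(s, "|", fixed = TRUE)[[1L]]
    parts <- trimws(parts[nzchar(trimws(parts))])
    if (length(parts) == 0L) stopf("empty node spec")
    mrca_node(tree, parts)
  }, integer(1L), USE.NAMES = FALSE)
}

#' Read a binary character from two-column delimited text
#'
#' Expected columns: taxon label and state in `{0, 1, NA}`. Missing states
#' (unavailable expression data) are `NA`.
#'
#' @param file path to delimited text (tab or comma separated, with or
#'   without a header line).
#' @return named integer vector (names = taxa, values 0/1/NA).
#' @export
read_binary_character <- function(file) {
  if (!file.exists(file)) stopf("character file not found: %s", file)
  first <- readLines(file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- !grepl("^[^\t,]+[\t,](0|1|NA)\\s*$", first)
  d <- utils::read.table(file, sep = sep, header = has_header,
                         stringsAsFactors = FALSE, na.strings = c("NA", "?"))
  if (ncol(d) < 2L) stopf("character file needs two columns: taxon, state")
  states <- suppressWarnings(as.integer(d[[2L]]))
  bad <- !is.na(d[[2L]]) & (is.na(states) | !(states %in% c(0L, 1L)))
  if (any(bad))
    stopf("invalid state value(s): %s", paste(unique(d[[2L]][bad]), collapse = ", "))
  stats::setNames(states, as.character(d[[1L]]))
}

#' Write a binary character to delimited text
#'
#' @param states named 0/1/NA vector.
#' @param file output path.
#' @export
write_binary_character <- function(states, file) {
  utils::write.table(
    data.frame(taxon = names(states), state = unname(states)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# Check a binary character against a tree's tips; returns the vector aligned
# to tree$tip.label order.
align_character <- function(tree, states) {
  if (is.null(names(states))) stopf("character must be a named vector")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stopf("character lacks tips: %s", paste(miss, collapse = ", "))
  x <- states[tree$tip.label]
  if (!all(x %in% c(0, 1, NA)))
    stopf("states must be 0, 1 or NA")
  if (sum(!is.na(x)) < 2L)
    stopf("need at least two non-missing tip states")
  x
}
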