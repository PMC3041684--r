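#' Read a dated tree (chronogram) from a Newick string or file
#'
#' Parses a rooted tree whose branch lengths are absolute time (Ma) and whose
#' internal node labels, when they parse as a number in \[0, 1\], are taken to
#' be posterior-probability clade supports (the usual way a BEAST maximum
#' clade credibility tree is exported to plain Newick).  Square-bracketed
#' comments (BEAST/NHX annotations) are stripped, not parsed.
#'
#' Tips carry implicit support 1.0: an observed terminal taxon is certain, and
#' the supported-branch filter of [count_shifts()] relies on this.
#'
#' @param text a Newick string (single tree, trailing semicolon required).
#' @param file alternatively, path to a file containing one Newick tree.
#' @return an object of class `c("chronogram", "phylo")`: an \pkg{ape} tree
#'   with an extra numeric element `support` of length `Ntip + Nnode`, indexed
#'   like \pkg{ape} node numbers (tips first).  Tip supports are 1; internal
#'   supports are the parsed labels or `NA` where absent/unparseable.
#' @seealso [write_newick()], [mk_asr()]
#' @examples
#' tr <- read_newick("((A:1,B:1)0.99:1,C:2);")
#' tr$support
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply `text` or `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- gsub("\\[[^]]*\\]", "", text)  # strip bracketed comments
  text <- gsub("[ \t\r\n]", "", text)    # whitespace outside labels
  .check_newick_syntax(text)
  phy <- ape::read.tree(text = text)
  if (is.null(phy)) stop("Newick parse failed")
  if (inherits(phy, "multiPhylo")) stop("expected exactly one tree")
  as_chronogram(phy)
}

# Cheap structural scan so syntax errors name a character offset, which
# ape's parser does not do.
.check_newick_syntax <- function(text) {
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
  if (depth > 0L)
    stop(sprintf("malformed Newick: %d unclosed '(' by character %d",
                 depth, length(chars)))
  if (!grepl(";\\s*$", text))
    stop(sprintf("malformed Newick: missing terminal ';' (ends at character %d)",
                 nchar(text)))
  invisible(TRUE)
}

#' Coerce an ape tree to a chronogram
#'
#' Validates the invariants assumed downstream (unique non-empty tip labels,
#' non-negative branch lengths; polytomies are fine, ultrametricity is not
#' enforced) and attaches the `support` vector.
#'
#' @param phy a `phylo` object, or an existing `chronogram`.
#' @param support optional numeric vector of length `Ntip + Nnode` overriding
#'   supports; otherwise internal node labels are parsed.
#' @return a `chronogram`.
#' @export
as_chronogram <- function(phy, support = NULL) {
  if (inherits(phy, "chronogram") && is.null(support)) return(phy)
  if (!inherits(phy, "phylo")) stop("`phy` must be a phylo object")
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  if (any(phy$tip.label == "")) stop("empty tip label")
  dup <- phy$tip.label[duplicated(phy$tip.label)]
  if (length(dup))
    stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0))
    stop("negative branch length")
  if (is.null(support)) {
    support <- rep(NA_real_, ntip + nnode)
    support[seq_len(ntip)] <- 1.0
    if (!is.null(phy$node.label)) {
      lab <- suppressWarnings(as.numeric(phy$node.label))
      lab[!is.na(lab) & (lab < 0 | lab > 1)] <- NA_real_
      support[ntip + seq_len(nnode)] <- lab
    }
  } else {
    if (length(support) != ntip + nnode)
      stop("`support` must have length Ntip + Nnode")
  }
  phy$support <- support
  class(phy) <- unique(c("chronogram", class(phy)))
  phy
}

#' Write a chronogram to Newick
#'
#' Internal supports are emitted as node labels (the dialect [read_newick()]
#' reads back), so a write/read round trip preserves topology, branch
#' lengths, tip labels and supports.
#'
#' @param tree a `chronogram` (or plain `phylo`).
#' @param file optional path; if `NULL` the Newick string is returned.
#' @param digits number of significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  phy <- tree
  if (!is.null(phy$support)) {
    ntip <- length(phy$tip.label)
    sup <- phy$support[ntip + seq_len(phy$Nnode)]
    phy$node.label <- ifelse(is.na(sup), "", format(sup, digits = 6,
                                                    trim = TRUE))
  }
  class(phy) <- "phylo"
  s <- ape::write.tree(phy, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

# depth (edge count from the root) of every node; used by the basal-node
# exclusion rule in count_shifts()
.node_depths <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  root <- ntip + 1L
  depth <- rep(NA_integer_, nn)
  depth[root] <- 0L
  eo <- ape::reorder.phylo(phy, "cladewise")$edge
  for (i in seq_len(nrow(eo))) depth[eo[i, 2]] <- depth[eo[i, 1]] + 1L
  depth
}
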