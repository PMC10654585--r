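#' Read a rooted binary tree from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] that enforces what the
#' reconciliation dynamic program assumes: a single rooted tree, strictly
#' binary, with unique non-empty leaf labels. Quoted labels are supported
#' and comments in square brackets are stripped by the parser.
#'
#' @param path Newick file containing exactly one tree.
#' @param text optional Newick string given directly instead of a file.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stop_hostspec(
      paste0("Newick parse failure: ", conditionMessage(e)),
      "hostspec_parse_error"))
  if (is.null(tr))
    stop_hostspec("Newick parse failure: no tree found", "hostspec_parse_error")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop_hostspec("expected a single tree per file", "hostspec_parse_error")
    tr <- tr[[1L]]
  }
  validate_binary_tree(tr)
}

validate_binary_tree <- function(tr) {
  if (!inherits(tr, "phylo"))
    stop_hostspec("not a phylogenetic tree", "hostspec_parse_error")
  if (anyNA(tr$tip.label) || any(!nzchar(tr$tip.label)))
    stop_hostspec("empty leaf label", "hostspec_parse_error")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop_hostspec(paste0("duplicate leaf label(s): ",
                         paste(dup, collapse = ", ")),
                  "hostspec_parse_error")
  ## name the offending clade of any polytomy by its leaf set (a basal
  ## trifurcation -- what ape calls an unrooted tree -- is reported this
  ## way too)
  deg <- tabulate(tr$edge[, 1], nbins = ape::Ntip(tr) + tr$Nnode)
  poly <- which(deg > 2)
  if (length(poly)) {
    tips <- tr$tip.label[unlist(phangorn_free_descendants(tr, poly[1]))]
    stop_hostspec(paste0("polytomy at clade {",
                         paste(sort(tips), collapse = ","), "}"),
                  "hostspec_parse_error")
  }
  if (ape::Ntip(tr) >= 2 && !ape::is.rooted(tr))
    stop_hostspec("tree must be rooted", "hostspec_parse_error")
  tr
}

## tips descending from an internal node (no phangorn dependency)
phangorn_free_descendants <- function(tr, node) {
  n_tip <- ape::Ntip(tr)
  kids <- function(v) tr$edge[tr$edge[, 1] == v, 2]
  acc <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= n_tip) acc <- c(acc, v) else stack <- c(stack, kids(v))
  }
  list(acc)
}

#' Write a tree to Newick with canonical child ordering
#'
#' Children are ordered by the lexicographically smallest leaf label of
#' their subtree ("ladderized by label"), so writing the same topology
#' always produces the same string and read/write round-trips are
#' topology-lossless.
#'
#' @param tr an [ape::phylo] tree.
#' @param path output file; when `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tr, path = NULL) {
  tr <- ape::rotateConstr(tr, sort(tr$tip.label))
  s <- ape::write.tree(tr)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read an aligned FASTA file
#'
#' Sequences must be of equal length (an alignment) over the alphabet
#' A, C, G, T, `-`, N (case-insensitive; normalised to upper case).
#'
#' @param path FASTA file.
#' @return a named character vector of upper-case aligned sequences, in
#'   file order.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1])
    stop_hostspec("not a FASTA file (no leading '>')", "hostspec_parse_error")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  seqs <- toupper(gsub("\\s", "", seqs))
  names(seqs) <- ids
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop_hostspec(paste0("illegal character(s) in sequence(s): ",
                         paste(ids[bad], collapse = ", ")),
                  "hostspec_alphabet_error")
  if (length(unique(nchar(seqs))) > 1)
    stop_hostspec("sequences are not aligned (unequal lengths)",
                  "hostspec_alignment_error")
  seqs
}

#' Write aligned sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @return `seqs`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(seqs)
}
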