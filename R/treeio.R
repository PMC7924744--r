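#' Parse a Newick string into a validated rooted phylogeny
#'
#' Wraps [ape::read.tree()] and enforces the invariants the downstream
#' comparative machinery relies on: a single root, binary internal nodes,
#' non-negative branch lengths, and unique tip labels.
#'
#' @param text A Newick string (terminated by `;`), or a path via `file`.
#' @param file Optional path to a Newick file; exactly one of `text`/`file`.
#' @param resolve_polytomies If `TRUE`, multifurcations are resolved
#'   arbitrarily with zero-length branches ([ape::multi2di()]); by default
#'   polytomies are an error, since dated ML trees are binary.
#' @param normalize_labels If `TRUE`, tip labels are normalized (underscores
#'   to spaces collapsed, case folded) before uniqueness checks. Off by
#'   default to avoid silent mismatches.
#' @return An object of class `phylo`, rooted and binary.
#' @export
parse_newick <- function(text = NULL, file = NULL, resolve_polytomies = FALSE,
                         normalize_labels = FALSE) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `text` or `file`")
  }
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  if (!grepl(";", text, fixed = TRUE)) {
    stop("Newick parse error: no terminating ';' (offset ", nchar(text), ")")
  }
  bal <- cumsum(ifelse(strsplit(text, "")[[1]] == "(", 1L,
                       ifelse(strsplit(text, "")[[1]] == ")", -1L, 0L)))
  if (any(bal < 0) || bal[length(bal)] != 0) {
    off <- if (any(bal < 0)) which(bal < 0)[1] else length(bal)
    stop("Newick parse error: unbalanced parentheses at character offset ", off)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: ape could not read the string")
  if (normalize_labels) tree$tip.label <- normalize_tip_labels(tree$tip.label)
  validate_tree(tree, resolve_polytomies = resolve_polytomies)
}

#' @keywords internal
normalize_tip_labels <- function(x) {
  tolower(gsub("[ _]+", "_", trimws(x)))
}

#' Validate (and optionally repair) a phylo object
#'
#' @param tree A `phylo` object.
#' @param resolve_polytomies Resolve multifurcations with zero-length
#'   branches instead of erroring.
#' @return The validated `phylo`, invisibly modified if polytomies were
#'   resolved.
#' @export
validate_tree <- function(tree, resolve_polytomies = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) stop("tree has NA branch lengths")
  if (any(tree$edge.length < 0)) {
    stop("validation error: negative branch length(s) at edge(s) ",
         paste(which(tree$edge.length < 0), collapse = ", "))
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("validation error: duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  nchild <- tabulate(tree$edge[, 1])
  if (any(nchild > 2)) {
    if (resolve_polytomies) {
      tree <- ape::multi2di(tree)
    } else {
      stop("tree contains polytomies; pass resolve_polytomies = TRUE to ",
           "resolve them arbitrarily with zero-length branches")
    }
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (any(tree$edge.length == 0)) {
    message("note: ", sum(tree$edge.length == 0),
            " branch(es) of exactly zero length (dating artifact?)")
  }
  tree
}

#' Serialize a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Printed precision for branch lengths.
#' @return The Newick string (invisibly, if written to file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Join a tip trait table onto a phylogeny
#'
#' Strict by default: every table key must match exactly one tip label and
#' (in strict mode) every tip must have a row. No label normalization is
#' performed unless requested, so `"S_rogeri"` will not silently match
#' `"S. rogeri"`.
#'
#' @param tree A `phylo` object.
#' @param table A data.frame whose first column (or `key` column) holds
#'   species names matching tip labels.
#' @param key Name of the key column (default `"species"`).
#' @param strict If `TRUE` (default), tips without a table row are an error;
#'   if `FALSE` they are reported in the `missing` attribute.
#' @param normalize Normalize labels on both sides before matching.
#' @return The table reordered to tip order (one row per tip; rows of
#'   missing tips are NA in lenient mode), with attribute `missing` listing
#'   tips lacking records.
#' @export
join_tips <- function(tree, table, key = "species", strict = TRUE,
                      normalize = FALSE) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(table))
  if (!key %in% names(table)) stop("key column '", key, "' not found in table")
  keys <- as.character(table[[key]])
  tips <- tree$tip.label
  if (normalize) {
    keys <- normalize_tip_labels(keys)
    tips <- normalize_tip_labels(tips)
  }
  if (anyDuplicated(keys)) {
    stop("duplicate table keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  unknown <- setdiff(keys, tips)
  if (length(unknown)) {
    stop("table keys not present among tip labels: ",
         paste(unknown, collapse = ", "))
  }
  idx <- match(tips, keys)
  missing <- tree$tip.label[is.na(idx)]
  if (strict && length(missing)) {
    stop("tips lacking trait records (strict mode): ",
         paste(missing, collapse = ", "))
  }
  out <- table[idx, , drop = FALSE]
  out[[key]] <- tree$tip.label
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  out
}

#' Stable identifiers for internal branches
#'
#' Each internal branch is keyed by the sorted tip set of its child node,
#' collapsed with `";"` — stable across node renumbering and tree rotations.
#'
#' @param tree A `phylo` object.
#' @return Character vector over edges of `tree$edge` (tip-child edges get
#'   the tip label itself).
#' @export
branch_ids <- function(tree) {
  tipsets <- clade_tip_sets(tree)
  vapply(tree$edge[, 2], function(ch) {
    paste(sort(tree$tip.label[tipsets[[ch]]]), collapse = ";")
  }, character(1))
}

# tip indices below each node, postorder accumulation
#' @keywords internal
clade_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Per-branch counts of potentially quartet-informative loci
#'
#' For each internal branch, counts loci present in at least one tip of each
#' of the four tip sets induced by the branches incident to its endpoints:
#' the two child subtrees below the branch, and the sister subtree plus the
#' remainder of the tree above it. A locus passing all four is capable of
#' informing the quartet around that branch, the standard audit for whether
#' RAD missing data is phylogenetically structured.
#'
#' For a branch whose parent is the root, the "above" side is the root's
#' other child; its two child subtrees serve as the third and fourth sets
#' (the two root edges describe the same unrooted branch). If that sibling
#' is a tip the four-subtree rule cannot apply and `NA` is returned.
#'
#' @param tree Rooted binary `phylo`.
#' @param mat Binary matrix, rows named by tip labels, columns = loci.
#' @return data.frame with `branch_id`, `child_node`, and `n_informative`
#'   (NA where the rule is inapplicable), one row per internal branch.
#' @export
quartet_informative_counts <- function(tree, mat) {
  validate_tree(tree)
  n_tip <- length(tree$tip.label)
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("presence matrix must have tip-labelled rows")
  if (!all(mat %in% c(0, 1))) stop("presence matrix cells must be 0/1")
  absent <- setdiff(tree$tip.label, rownames(mat))
  if (length(absent)) {
    stop("tips without a matrix row: ", paste(absent, collapse = ", "))
  }
  mat <- mat[tree$tip.label, , drop = FALSE]
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  # per-clade per-locus presence counts, accumulated postorder
  cnt <- matrix(0L, n_node, ncol(mat))
  cnt[seq_len(n_tip), ] <- mat
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    cnt[po$edge[e, 1], ] <- cnt[po$edge[e, 1], ] + cnt[po$edge[e, 2], ]
  }
  total <- cnt[root, ]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  parent <- integer(n_node); parent[tree$edge[, 2]] <- tree$edge[, 1]
  internal <- tree$edge[, 2][tree$edge[, 2] > n_tip]
  ids <- branch_ids(tree)
  names(ids) <- tree$edge[, 2]
  res <- vapply(internal, function(v) {
    ch <- kids[[as.character(v)]]
    below1 <- cnt[ch[1], ] > 0
    below2 <- cnt[ch[2], ] > 0
    p <- parent[v]
    sib <- setdiff(kids[[as.character(p)]], v)
    if (p == root) {
      if (sib <= n_tip) return(NA_integer_)
      gk <- kids[[as.character(sib)]]
      above1 <- cnt[gk[1], ] > 0
      above2 <- cnt[gk[2], ] > 0
    } else {
      above1 <- cnt[sib, ] > 0
      above2 <- (total - cnt[p, ]) > 0
    }
    sum(below1 & below2 & above1 & above2)
  }, integer(1))
  data.frame(branch_id = unname(ids[as.character(internal)]),
             child_node = internal, n_informative = res,
             stringsAsFactors = FALSE)
}
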