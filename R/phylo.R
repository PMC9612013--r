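# Distance-based phylogeny: p-distances, neighbor joining with a
# deterministic tie-break, column bootstrap, outgroup rooting and
# monophyly queries.

#' Pairwise p-distance matrix of an alignment
#'
#' `d(i,j)` is the proportion of mismatching sites over columns where both
#' sequences have an unambiguous base (pairwise deletion of gaps and N).
#' `snv_only` restricts the comparison to SNV columns as defined by
#' [classify_columns()].
#'
#' @param al A [new_alignment()] with >= 2 sequences.
#' @param mode `"all_columns"` or `"snv_only"`.
#' @param min_minor_count Passed to [classify_columns()] for `snv_only`.
#' @return Symmetric numeric matrix with zero diagonal, labelled by
#'   sequence id.
#' @export
p_distance_matrix <- function(al, mode = c("all_columns", "snv_only"),
                              min_minor_count = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(al, "plastid_alignment"))
  if (length(al) < 2) {
    abort("Need at least two sequences.", class = "plastidkit_param_error")
  }
  m <- alignment_matrix(al)
  if (mode == "snv_only") {
    cols <- classify_columns(al, min_minor_count)$variants$column
    m <- m[, cols, drop = FALSE]
  }
  ids <- rownames(m)
  n <- length(ids)
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      if (nc == 0) {
        abort(paste0("No comparable columns between '", ids[i], "' and '",
                     ids[j], "'."),
              class = "plastidkit_param_error")
      }
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining: at each step the pair minimizing the
#' Q-criterion is joined, with Studier-Keppler branch lengths. Ties in Q
#' are broken deterministically by the lexicographically smallest pair of
#' cluster representatives (the smallest leaf label in each cluster).
#' Negative branch lengths are clamped to zero and the total clamped
#' deficit recorded in the `clamped` attribute of the result.
#'
#' @param dm Symmetric distance matrix with labelled rows/columns, zero
#'   diagonal, >= 3 labels.
#' @return An unrooted `ape::phylo`.
#' @examples
#' d <- matrix(c(0,5,6,6, 5,0,9,9, 6,9,0,6, 6,9,6,0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' nj_tree(d)
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm) ||
      is.null(rownames(dm)) ||
      max(abs(dm - t(dm))) > 1e-12 || any(diag(dm) != 0)) {
    abort("`dm` must be a labelled symmetric matrix with zero diagonal.",
          class = "plastidkit_param_error")
  }
  n0 <- nrow(dm)
  if (n0 < 3) abort("Need >= 3 labels.", class = "plastidkit_param_error")
  labels <- rownames(dm)
  D <- dm
  # newick fragment and representative (smallest leaf label) per cluster
  frag <- labels
  rep_lab <- labels
  clamped <- 0
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped - x; 0 } else x
  }
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break on sorted representative labels
    keys <- apply(cand, 1, function(ij) {
      paste(sort(c(rep_lab[ij[1]], rep_lab[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    bj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(bi), frag[j], fmt(bj))
    new_rep <- min(rep_lab[i], rep_lab[j])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    du <- du[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, du), c(du, 0))
    frag <- c(frag[-c(i, j)], new_frag)
    rep_lab <- c(rep_lab[-c(i, j)], new_rep)
    rownames(D) <- colnames(D) <- rep_lab
  }
  # final three clusters joined at the anchor node
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  b1 <- clamp((d12 + d13 - d23) / 2)
  b2 <- clamp((d12 + d23 - d13) / 2)
  b3 <- clamp((d13 + d23 - d12) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(b1), frag[2], fmt(b2), frag[3], fmt(b3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal edge of the tree built from the
#' full alignment with the percentage of replicates containing the same
#' bipartition. Reproducible for a fixed seed.
#'
#' @param al A [new_alignment()].
#' @param n_reps Number of bootstrap replicates (>= 1). 5000 matches a
#'   full-scale analysis; 100-200 is plenty at desk scale.
#' @param seed Integer RNG seed.
#' @param mode Distance mode, see [p_distance_matrix()].
#' @return The NJ `phylo` with integer percent supports in `node.label`
#'   (the root/anchor label is empty).
#' @export
bootstrap_support <- function(al, n_reps, seed = 1,
                              mode = c("all_columns", "snv_only")) {
  mode <- match.arg(mode)
  if (n_reps < 1) abort("`n_reps` must be >= 1.", class = "plastidkit_param_error")
  tree <- nj_tree(p_distance_matrix(al, mode))
  m <- alignment_matrix(al)
  nc <- ncol(m)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(nc, nc, replace = TRUE)
      alr <- new_alignment(apply(m[, cols, drop = FALSE], 1, paste,
                                 collapse = ""))
      nj_tree(p_distance_matrix(alr, mode))
    })
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- as.integer(round(100 * counts / n_reps))
  lab <- as.character(supports)
  lab[1] <- ""  # basal trifurcation of the unrooted tree, not a split
  tree$node.label <- lab
  tree
}

#' Root a tree on an outgroup
#'
#' Checks that the outgroup forms a clade (one side of a bipartition) in
#' the unrooted tree and places the root at the midpoint of the edge
#' separating outgroup from ingroup. Node labels (bootstrap supports) are
#' preserved as edge-associated labels.
#'
#' @param tree An `ape::phylo` (rooting state ignored; treated unrooted).
#' @param outgroup Character vector of outgroup tip labels.
#' @return A rooted `ape::phylo`.
#' @export
root_tree <- function(tree, outgroup) {
  tips <- tree$tip.label
  if (!all(outgroup %in% tips)) {
    abort(paste0("Unknown outgroup label(s): ",
                 paste(setdiff(outgroup, tips), collapse = ", ")),
          class = "plastidkit_param_error")
  }
  if (length(outgroup) == length(tips)) {
    abort("Outgroup cannot contain every tip.", class = "plastidkit_param_error")
  }
  tr <- ape::unroot(tree)
  ingroup <- setdiff(tips, outgroup)
  # anchor the stored root inside the ingroup so the outgroup, if it is a
  # split, appears as a monophyletic clade
  tr2 <- ape::root(tr, outgroup = ingroup[1], resolve.root = TRUE,
                   edgelabel = TRUE)
  node <- if (length(outgroup) == 1) {
    which(tr2$tip.label == outgroup)
  } else {
    ape::getMRCA(tr2, outgroup)
  }
  desc <- tr2$tip.label[descendant_tips(tr2, node)]
  if (!setequal(desc, outgroup)) {
    abort("Outgroup does not form a clade in the unrooted tree.",
          class = "plastidkit_structure_error")
  }
  edge_i <- which(tr2$edge[, 2] == node)
  el <- tr2$edge.length[edge_i]
  phytools::reroot(tr2, node, position = el / 2)
}

# tip indices descending from a node (the node itself if a tip)
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    ch <- kids[[as.character(nd)]]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

#' Test monophyly of a set of leaves in a rooted tree
#'
#' Reports whether the query labels form a single clade, and the smallest
#' number of maximal clades whose leaf union is exactly the query set
#' (counting maximal query-pure subtrees, which is provably minimal on a
#' tree).
#'
#' @param tree A rooted `ape::phylo`.
#' @param query Character vector of leaf labels.
#' @return A `monophyly_report`: list with `query`, `is_monophyletic`,
#'   `min_clades` and `clades` (list of leaf-label sets).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")
#' clade_test(tr, c("A", "C"))$min_clades  # 2
#' @export
clade_test <- function(tree, query) {
  tips <- tree$tip.label
  if (!all(query %in% tips)) {
    abort(paste0("Unknown label(s): ",
                 paste(setdiff(query, tips), collapse = ", ")),
          class = "plastidkit_param_error")
  }
  ntip <- length(tips)
  nnode <- tree$Nnode
  in_query <- tips %in% query
  parent <- rep(NA_integer_, ntip + nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  pure <- c(in_query, vapply((ntip + 1):(ntip + nnode), function(nd) {
    all(in_query[descendant_tips(tree, nd)])
  }, logical(1)))
  maximal <- which(pure & (is.na(parent) | !pure[parent]))
  clades <- lapply(maximal, function(nd) tips[descendant_tips(tree, nd)])
  covered <- sort(unlist(clades))
  stopifnot(identical(covered, sort(query)))
  structure(list(query = query,
                 is_monophyletic = length(maximal) == 1,
                 min_clades = length(maximal),
                 clades = clades),
            class = "monophyly_report")
}

#' @export
print.monophyly_report <- function(x, ...) {
  cat(sprintf("Monophyly of {%s}: %s (min_clades = %d)\n",
              paste(x$query, collapse = ", "),
              if (x$is_monophyletic) "monophyletic" else "NOT monophyletic",
              x$min_clades))
  invisible(x)
}

#' Write a distance matrix as TSV
#'
#' @param dm Labelled distance matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  df <- as_tibble(as.data.frame(dm), rownames = "id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
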