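#' Rooted binary trees for the likelihood engine
#'
#' The engine uses a fixed node numbering: tips `1..n` in taxon order,
#' internal nodes `n+1 .. 2n-1` assigned in postorder (so the root is
#' always `2n-1`). Each non-root node carries the length of the edge to
#' its parent, in expected substitutions per site.
#'
#' @name pw_tree
#' @keywords internal
NULL

# Build a pw_tree from a generic edge list with arbitrary positive-integer
# node ids. `tip_ids` lists the tip ids in taxon order; internals are
# renumbered in postorder with the root last.
tree_from_edges <- function(parent, child, lengths, tip_ids, tip_labels) {
  M <- max(parent, child)
  kid1 <- integer(M); kid2 <- integer(M)
  elen <- numeric(M)
  for (e in seq_along(parent)) {
    p <- parent[e]
    if (kid1[p] == 0L) kid1[p] <- child[e]
    else if (kid2[p] == 0L) kid2[p] <- child[e]
    else pw_stop("node with more than two children")
    elen[child[e]] <- lengths[e]
  }
  root_old <- setdiff(unique(parent), child)
  if (length(root_old) != 1) pw_stop("edge list does not describe one rooted tree")
  n <- length(tip_ids)
  nn <- 2L * n - 1L
  map <- integer(M)
  map[tip_ids] <- seq_len(n)
  new_parent <- rep(NA_integer_, nn)
  new_children <- matrix(NA_integer_, nn, 2)
  new_len <- rep(NA_real_, nn)
  counter <- n
  assign_post <- function(v) {
    if (kid1[v] == 0L) {
      id <- map[v]
      if (id == 0L) pw_stop("tip id ", v, " not listed in tip_ids")
      return(id)
    }
    if (kid2[v] == 0L) pw_stop("internal node with a single child")
    a <- assign_post(kid1[v])
    b <- assign_post(kid2[v])
    counter <<- counter + 1L
    id <- counter
    new_children[id, ] <<- c(a, b)
    new_parent[a] <<- id
    new_parent[b] <<- id
    new_len[a] <<- elen[kid1[v]]
    new_len[b] <<- elen[kid2[v]]
    id
  }
  root_new <- assign_post(root_old)
  if (root_new != nn) pw_stop("tree is not binary: expected ", nn, " nodes")
  structure(list(n_tips = n, tip_labels = tip_labels,
                 parent = new_parent, children = new_children,
                 edge_length = new_len, root = nn),
            class = "pw_tree")
}

#' @export
print.pw_tree <- function(x, ...) {
  cat(sprintf("<pw_tree: %d tips, %d nodes, total length %.4g>\n",
              x$n_tips, 2L * x$n_tips - 1L,
              sum(x$edge_length, na.rm = TRUE)))
  invisible(x)
}

is_tip <- function(tree, v) v <= tree$n_tips

#' Read a Newick tree
#'
#' Parses a Newick string or file. A bifurcating root is kept as is; an
#' unrooted tree (trifurcating root) is rooted deterministically by
#' inserting a root on the first-listed child edge, splitting its length
#' equally — an arbitrary but fixed choice, since the likelihood of a
#' reversible model does not depend on root placement. Missing branch
#' lengths default to zero with a warning.
#'
#' @param x a file path or a Newick string.
#' @param taxa optional character vector fixing the taxon (tip) order,
#'   e.g. the taxon names of an alignment; every tip label must occur.
#' @return a `pw_tree`.
#' @export
read_newick <- function(x, taxa = NULL) {
  txt <- if (length(x) == 1 && !grepl("\\(", x) && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "") else x
  phy <- ape::read.tree(text = txt)
  if (is.null(phy)) pw_stop("could not parse Newick input")
  from_phylo(phy, taxa = taxa)
}

# Convert an ape "phylo" object, rooting a trifurcating root if needed.
from_phylo <- function(phy, taxa = NULL) {
  n <- length(phy$tip.label)
  if (n < 2) pw_stop("tree needs at least 2 tips")
  parent <- phy$edge[, 1]
  child <- phy$edge[, 2]
  el <- phy$edge.length
  if (is.null(el)) {
    warning("tree has no branch lengths; defaulting to 0")
    el <- rep(0, length(parent))
  }
  if (anyNA(el)) {
    warning("missing branch lengths default to 0")
    el[is.na(el)] <- 0
  }
  root <- n + 1L
  rk <- which(parent == root)
  if (length(rk) == 3) {
    first <- rk[1]
    newroot <- max(parent, child) + 1L
    L <- el[first]
    parent <- c(parent, newroot)
    child <- c(child, root)
    el <- c(el, L / 2)
    parent[first] <- newroot
    el[first] <- L / 2
  } else if (length(rk) != 2) {
    pw_stop("tree must be binary (a trifurcating root is accepted)")
  }
  if (is.null(taxa)) {
    tip_ids <- seq_len(n)
    labels <- phy$tip.label
  } else {
    tip_ids <- match(taxa, phy$tip.label)
    if (anyNA(tip_ids))
      pw_stop("taxa not in tree: ", paste(taxa[is.na(tip_ids)], collapse = ", "))
    if (length(taxa) != n) pw_stop("tree and taxa differ in tip count")
    labels <- taxa
  }
  tree_from_edges(parent, child, el, tip_ids, labels)
}

#' Write a tree as a Newick string
#'
#' Branch lengths are written with 17 significant digits so a
#' write-then-read round trip reproduces them exactly.
#' @param tree a `pw_tree`.
#' @param path optional file; when `NULL` the string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  rec <- function(v) {
    if (is_tip(tree, v)) return(tree$tip_labels[v])
    k <- tree$children[v, ]
    paste0("(", rec(k[1]), ":", sprintf("%.17g", tree$edge_length[k[1]]),
           ",", rec(k[2]), ":", sprintf("%.17g", tree$edge_length[k[2]]), ")")
  }
  s <- paste0(rec(tree$root), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

as_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}

#' Deterministic example topologies
#'
#' `balanced_tree()` builds a fully balanced tree over `2^k` tips;
#' `caterpillar_tree()` builds a maximally unbalanced (pectinate) tree.
#' Useful for exercising the traversal scheduler, whose wave count is the
#' internal-node height of the tree.
#' @param n_tips number of tips (a power of two for `balanced_tree`).
#' @param edge_length length assigned to every edge.
#' @export
balanced_tree <- function(n_tips, edge_length = 0.1) {
  k <- log2(n_tips)
  if (n_tips < 2 || abs(k - round(k)) > 1e-9)
    pw_stop("n_tips must be a power of two >= 2")
  ids <- seq_len(n_tips)
  nxt <- n_tips
  parent <- integer(0); child <- integer(0)
  while (length(ids) > 1) {
    up <- integer(0)
    for (j in seq(1, length(ids), by = 2)) {
      nxt <- nxt + 1L
      parent <- c(parent, nxt, nxt)
      child <- c(child, ids[j], ids[j + 1])
      up <- c(up, nxt)
    }
    ids <- up
  }
  tree_from_edges(parent, child, rep(edge_length, length(parent)),
                  seq_len(n_tips), paste0("t", seq_len(n_tips)))
}

#' @rdname balanced_tree
#' @export
caterpillar_tree <- function(n_tips, edge_length = 0.1) {
  if (n_tips < 2) pw_stop("n_tips must be >= 2")
  parent <- integer(0); child <- integer(0)
  cur <- 1L
  nxt <- n_tips
  for (i in 2:n_tips) {
    nxt <- nxt + 1L
    parent <- c(parent, nxt, nxt)
    child <- c(child, cur, i)
    cur <- nxt
  }
  tree_from_edges(parent, child, rep(edge_length, length(parent)),
                  seq_len(n_tips), paste0("t", seq_len(n_tips)))
}

# Undirected edge list of the unrooted tree underlying a pw_tree: the two
# root edges merge into one. Each row: (u, v, length); the merged edge is
# listed first with v = first root child.
unrooted_edge_list <- function(tree) {
  rk <- tree$children[tree$root, ]
  merged <- c(rk[2], rk[1],
              tree$edge_length[rk[1]] + tree$edge_length[rk[2]])
  others <- lapply(seq_len(2L * tree$n_tips - 1L), function(v) {
    p <- tree$parent[v]
    if (is.na(p) || p == tree$root) return(NULL)
    c(p, v, tree$edge_length[v])
  })
  do.call(rbind, c(list(merged), others[!vapply(others, is.null, TRUE)]))
}

#' Reroot a tree on the edge above a node
#'
#' Places a new root on the unrooted edge above `node` (if `node`'s parent
#' is the current root, this is the merged edge through the root). All
#' pairwise tip-to-tip path lengths are preserved; `split` controls how the
#' edge length is divided between the two new root edges (default: equal
#' halves). For reversible models the likelihood is invariant under this
#' operation.
#'
#' @param tree a `pw_tree`.
#' @param node a non-root node id; the new root subdivides the edge
#'   between `node` and the rest of the tree.
#' @param split optional numeric length-2 vector `c(toward node, away)`;
#'   must sum to the edge length.
#' @return a `pw_tree` over the same taxa.
#' @export
reroot_tree <- function(tree, node, split = NULL) {
  n <- tree$n_tips
  if (node < 1 || node >= 2L * n - 1L) pw_stop("node must be a non-root node")
  rk <- tree$children[tree$root, ]
  if (node == rk[2]) node <- rk[1]   # same unrooted edge as the first child

  ed <- unrooted_edge_list(tree)
  hit <- which(ed[, 2] == node)
  if (length(hit) != 1) pw_stop("internal error: edge above node not found")
  u <- ed[hit, 1]; L <- ed[hit, 3]
  if (is.null(split)) split <- c(L / 2, L / 2)
  if (abs(sum(split) - L) > 1e-9 * max(1, L))
    pw_stop("split must sum to the edge length")
  newroot <- 2L * n
  parent <- c(ed[-hit, 1], newroot, newroot)
  child <- c(ed[-hit, 2], node, u)
  lens <- c(ed[-hit, 3], split[1], split[2])
  # orient away from the new root
  oriented <- orient_edges(parent, child, lens, newroot)
  tree_from_edges(oriented$parent, oriented$child, oriented$len,
                  seq_len(n), tree$tip_labels)
}

# Orient an undirected edge list away from `root` via BFS.
orient_edges <- function(a, b, len, root) {
  M <- max(a, b)
  adj <- vector("list", M)
  for (e in seq_along(a)) {
    adj[[a[e]]] <- c(adj[[a[e]]], e)
    adj[[b[e]]] <- c(adj[[b[e]]], e)
  }
  np <- integer(0); nc <- integer(0); nl <- numeric(0)
  seen <- logical(M)
  queue <- root; seen[root] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (e in adj[[v]]) {
      w <- if (a[e] == v) b[e] else a[e]
      if (seen[w]) next
      seen[w] <- TRUE
      np <- c(np, v); nc <- c(nc, w); nl <- c(nl, len[e])
      queue <- c(queue, w)
    }
  }
  list(parent = np, child = nc, len = nl)
}

# Internal nodes in left-first postorder (children before parents).
postorder_internal <- function(tree) {
  out <- integer(0)
  rec <- function(v) {
    if (is_tip(tree, v)) return(invisible(NULL))
    rec(tree$children[v, 1])
    rec(tree$children[v, 2])
    out <<- c(out, v)
  }
  rec(tree$root)
  out
}

# Height above the tips for every node: tips 0, internal 1 + max(children).
node_heights <- function(tree) {
  nn <- 2L * tree$n_tips - 1L
  h <- integer(nn)
  for (v in postorder_internal(tree))
    h[v] <- 1L + max(h[tree$children[v, ]])
  h
}
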