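#' Validate and build a species network
#'
#' Builds a rooted binary phylogenetic network from a directed edge list and a
#' leaf labelling, checking the structural requirements: a unique root of
#' indegree 0 and outdegree 2, internal nodes that are either speciations
#' (indegree 1, outdegree 2) or hybridizations (indegree 2, outdegree 1),
#' labelled leaves of outdegree 0 with pairwise distinct labels, and
#' acyclicity.
#'
#' Node identifiers must be the integers \code{1..n}. The returned object
#' caches the topological order, the reachability relation and the
#' loss-counting distance matrix (see \code{\link{node_dist}}), all of which
#' the reconciliation algorithms consume.
#'
#' @param edges two-column integer matrix of directed edges (parent, child).
#' @param leaf_labels character vector of species names, named by the node id
#'   of the corresponding leaf (names may be given as integers or strings).
#' @return an object of class \code{dl_network}.
#' @export
validate_network <- function(edges, leaf_labels) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (ncol(edges) != 2L || nrow(edges) < 1L)
    stop("edges must be a two-column matrix with at least one edge")
  n <- max(edges)
  if (any(edges < 1L)) stop("node ids must be positive integers")
  if (any(edges[, 1L] == edges[, 2L]))
    stop("self-loop at node ", edges[which(edges[, 1L] == edges[, 2L])[1L], 1L])
  m <- nrow(edges)

  indeg <- tabulate(edges[, 2L], nbins = n)
  outdeg <- tabulate(edges[, 1L], nbins = n)
  if (any(indeg == 0L & outdeg == 0L))
    stop("isolated node ", which(indeg == 0L & outdeg == 0L)[1L])

  roots <- which(indeg == 0L)
  if (length(roots) != 1L)
    stop("network must have exactly one root; indegree-0 nodes: ",
         paste(roots, collapse = ", "))
  root <- roots
  if (outdeg[root] != 2L)
    stop("non-binary: root node ", root, " has outdegree ", outdeg[root])

  kind <- character(n)
  kind[root] <- "root"
  for (v in seq_len(n)) {
    if (v == root) next
    if (indeg[v] == 1L && outdeg[v] == 2L) kind[v] <- "speciation"
    else if (indeg[v] == 2L && outdeg[v] == 1L) kind[v] <- "hybridization"
    else if (indeg[v] == 1L && outdeg[v] == 0L) kind[v] <- "leaf"
    else stop("non-binary degrees at node ", v,
              " (indegree ", indeg[v], ", outdegree ", outdeg[v], ")")
  }

  children <- child_edges <- parents <- parent_edges <- vector("list", n)
  for (v in seq_len(n)) {
    ce <- which(edges[, 1L] == v)
    pe <- which(edges[, 2L] == v)
    child_edges[[v]] <- ce
    children[[v]] <- edges[ce, 2L]
    parent_edges[[v]] <- pe
    parents[[v]] <- edges[pe, 1L]
  }

  ## Kahn topological sort; leftovers indicate a directed cycle.
  topo <- integer(0)
  deg <- indeg
  queue <- root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    topo <- c(topo, v)
    for (w in children[[v]]) {
      deg[w] <- deg[w] - 1L
      if (deg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(topo) != n)
    stop("cycle through node ", setdiff(seq_len(n), topo)[1L])

  leaves <- which(kind == "leaf")
  label <- rep(NA_character_, n)
  if (is.null(names(leaf_labels)))
    stop("leaf_labels must be named by node id")
  ids <- as.integer(names(leaf_labels))
  if (anyNA(ids) || any(ids < 1L) || any(ids > n))
    stop("leaf_labels names must be node ids")
  label[ids] <- as.character(leaf_labels)
  unl <- leaves[is.na(label[leaves])]
  if (length(unl)) stop("unlabelled leaf node ", unl[1L])
  if (any(!is.na(label[kind != "leaf"])))
    stop("label on non-leaf node ",
         which(!is.na(label) & kind != "leaf")[1L])
  if (anyDuplicated(label[leaves]))
    stop("duplicate leaf label '",
         label[leaves][duplicated(label[leaves])][1L], "'")

  ## reach[i, j]: j is reachable from i, i.e. j <= i in the network order.
  reach <- matrix(FALSE, n, n)
  for (v in rev(topo)) {
    reach[v, v] <- TRUE
    for (w in children[[v]]) reach[v, ] <- reach[v, ] | reach[w, ]
  }

  net <- structure(list(
    n = n, m = m, edge = edges, kind = kind, label = label, root = root,
    children = children, child_edges = child_edges,
    parents = parents, parent_edges = parent_edges,
    topo = topo, reach = reach,
    h = sum(kind == "hybridization"),
    leaves = leaves,
    leaf_of = stats::setNames(leaves, label[leaves])
  ), class = "dl_network")
  net$distmat <- dl_dist_matrix(net)
  net$level <- network_level(net)
  net
}

## Pairwise loss-counting distances over the whole DAG.  dist[x, y] is the
## minimum, over directed paths from x down to y, of the number of
## speciation-or-root nodes z with y < z <= x: the top endpoint contributes
## when it is a speciation or the root, the bottom endpoint never does, and
## hybridization nodes are never counted.  Inf when y is not reachable from x.
dl_dist_matrix <- function(net) {
  n <- net$n
  w <- as.numeric(net$kind %in% c("root", "speciation"))
  d <- matrix(Inf, n, n)
  rt <- rev(net$topo)
  for (y in seq_len(n)) {
    dy <- rep(Inf, n)
    dy[y] <- 0
    for (x in rt) {
      if (x == y) next
      ch <- net$children[[x]]
      if (!length(ch)) next
      best <- min(dy[ch])
      if (is.finite(best)) dy[x] <- w[x] + best
    }
    d[, y] <- dy
  }
  d
}

#' Partial order of a network or switching
#'
#' \code{node_leq(x, a, b)} is \code{TRUE} when \code{a <= b}, i.e. there is a
#' directed path (possibly reduced to a single node) from \code{b} down to
#' \code{a}.  On a switching only switched-on edges define paths.
#'
#' @param x a \code{dl_network} or \code{dl_switching}.
#' @param a,b node ids.
#' @export
node_leq <- function(x, a, b) {
  UseMethod("node_leq")
}

#' @export
node_leq.dl_network <- function(x, a, b) {
  check_node(x, a); check_node(x, b)
  x$reach[b, a]
}

#' Loss-counting distance
#'
#' The number of loss-inducing nodes on a cheapest directed path from \code{b}
#' down to \code{a}: speciation (and root) nodes \code{z} with
#' \code{a < z <= b}.  On a network the minimum is taken over all paths; on a
#' switching the on-path is unique and only nodes untouched by switched-off
#' edges are counted.  \code{Inf} when \code{a} is not below \code{b}.
#'
#' @param x a \code{dl_network} or \code{dl_switching}.
#' @param b,a top and bottom node ids.
#' @export
node_dist <- function(x, b, a) {
  UseMethod("node_dist")
}

#' @export
node_dist.dl_network <- function(x, b, a) {
  check_node(x, a); check_node(x, b)
  x$distmat[b, a]
}

check_node <- function(net, v) {
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1L || v > net$n)
    stop("unknown node id: ", v)
  invisible(v)
}

#' @export
print.dl_network <- function(x, ...) {
  cat("Rooted binary species network\n")
  cat("  nodes:", x$n, " edges:", x$m,
      " leaves:", length(x$leaves), "\n")
  cat("  hybridization nodes:", x$h, " level:", x$level, "\n")
  cat("  species:", paste(sort(x$label[x$leaves]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.dl_genetree <- function(x, ...) {
  cat("Rooted binary gene tree\n")
  cat("  nodes:", x$n, " leaves:", length(x$leaves), "\n")
  cat("  species represented:",
      paste(sort(unique(x$label[x$leaves])), collapse = ", "), "\n")
  invisible(x)
}

#' Validate and build a gene tree
#'
#' A rooted binary tree whose leaves are labelled by the species that carry
#' the genes; several leaves may share a species label.
#'
#' @param edges two-column integer matrix of directed edges (parent, child).
#' @param leaf_labels character vector of species names named by leaf node id.
#' @return an object of class \code{dl_genetree}.
#' @export
validate_gene_tree <- function(edges, leaf_labels) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  n <- max(edges)
  indeg <- tabulate(edges[, 2L], nbins = n)
  outdeg <- tabulate(edges[, 1L], nbins = n)
  if (any(indeg > 1L))
    stop("not a tree: node ", which(indeg > 1L)[1L], " has two parents")
  roots <- which(indeg == 0L & outdeg > 0L)
  if (length(roots) != 1L) stop("gene tree must have exactly one root")
  root <- roots
  bad <- which(outdeg != 0L & outdeg != 2L)
  if (length(bad))
    stop("polytomy or unary node: node ", bad[1L],
         " has outdegree ", outdeg[bad[1L]])

  children <- vector("list", n)
  par <- rep(NA_integer_, n)
  for (e in seq_len(nrow(edges))) {
    children[[edges[e, 1L]]] <- c(children[[edges[e, 1L]]], edges[e, 2L])
    par[edges[e, 2L]] <- edges[e, 1L]
  }
  leaves <- which(outdeg == 0L)

  topo <- integer(0)
  queue <- root
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    topo <- c(topo, v)
    queue <- c(queue, children[[v]])
  }
  if (length(topo) != n) stop("disconnected gene tree")

  label <- rep(NA_character_, n)
  ids <- as.integer(names(leaf_labels))
  label[ids] <- as.character(leaf_labels)
  if (any(is.na(label[leaves]))) stop("unlabelled gene-tree leaf")

  structure(list(
    n = n, edge = edges, children = children, par = par, root = root,
    label = label, leaves = leaves, topo = topo,
    postorder = rev(topo)
  ), class = "dl_genetree")
}

#' Collapse single-species subtrees of a gene tree
#'
#' Replaces every maximal subtree whose leaves all carry the same species
#' label by a single leaf with that label.  The collapsed internal nodes are
#' in-species duplications: in any most parsimonious reconciliation they map
#' to the species leaf with a duplication event and no losses, so a solution
#' for the collapsed tree extends to one for the original tree by adding one
#' duplication per removed internal node.
#'
#' @param gt a \code{dl_genetree}.
#' @return a list with the collapsed tree (\code{tree}), a map from new node
#'   ids to original ids (\code{orig_of}), the number of removed internal
#'   nodes (\code{n_collapsed}), and for each collapsed subtree its original
#'   members (\code{collapsed}).
#' @export
normalize_gene_tree <- function(gt) {
  n <- gt$n
  labsets <- vector("list", n)
  for (v in gt$postorder) {
    labsets[[v]] <- if (is.na(gt$label[v])) {
      sort(unique(unlist(labsets[gt$children[[v]]])))
    } else gt$label[v]
  }
  single <- vapply(labsets, length, 1L) == 1L
  ## maximal single-species internal nodes
  collapse_root <- vapply(seq_len(n), function(v) {
    single[v] && is.na(gt$label[v]) &&
      (v == gt$root || !single[gt$par[v]])
  }, TRUE)

  inside <- rep(FALSE, n)
  for (v in gt$topo) {
    if (inside[v]) next
    if (collapse_root[v]) {
      stack <- gt$children[[v]]
      while (length(stack)) {
        w <- stack[1L]; stack <- stack[-1L]
        inside[w] <- TRUE
        stack <- c(stack, gt$children[[w]])
      }
    }
  }

  keep <- which(!inside)
  new_id <- rep(NA_integer_, n)
  new_id[keep] <- seq_along(keep)
  edges <- NULL
  labels <- character(0)
  collapsed <- list()
  for (v in keep) {
    if (collapse_root[v] || !is.na(gt$label[v])) {
      labels[as.character(new_id[v])] <- labsets[[v]][1L]
      if (collapse_root[v]) {
        sub <- which(inside & vapply(seq_len(n), function(w)
          is_tree_desc(gt, w, v), TRUE))
        collapsed[[length(collapsed) + 1L]] <- list(
          new_leaf = new_id[v], orig_root = v,
          orig_internal = c(v, sub[is.na(gt$label[sub])]),
          orig_leaves = sub[!is.na(gt$label[sub])],
          label = labsets[[v]][1L])
      }
    } else {
      for (w in gt$children[[v]])
        edges <- rbind(edges, c(new_id[v], new_id[w]))
    }
  }

  if (is.null(edges)) {
    ## whole tree collapses to a single leaf
    tree <- structure(list(
      n = 1L, edge = matrix(integer(0), 0, 2), children = list(integer(0)),
      par = NA_integer_, root = 1L, label = labsets[[gt$root]][1L],
      leaves = 1L, topo = 1L, postorder = 1L), class = "dl_genetree")
  } else {
    tree <- validate_gene_tree(edges, labels)
  }
  ## every internal node of a collapsed subtree (its root included) is
  ## replaced by one duplication when the solution is expanded back
  list(tree = tree, orig_of = keep, new_id = new_id,
       n_collapsed = sum(inside & is.na(gt$label)) + length(collapsed),
       collapsed = collapsed)
}

is_tree_desc <- function(gt, w, v) {
  while (!is.na(w)) {
    if (w == v) return(TRUE)
    w <- gt$par[w]
  }
  FALSE
}
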