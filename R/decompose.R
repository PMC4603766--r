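#' Biconnected-component decomposition of a network
#'
#' Computes the biconnected components of the underlying undirected graph and
#' assembles the component tree obtained by contracting each non-trivial
#' component to its root.  Components are the nodes of that tree: non-trivial
#' blobs (with at least two edges) and the single nodes lying outside every
#' blob; bridges are its edges.  Each component carries its elementary
#' network — the component plus the cut-edges leaving it — on which the
#' per-component switchings are enumerated.
#'
#' @param net a \code{dl_network}.
#' @return an object of class \code{dl_decomposition} with, per component:
#'   member nodes, internal (block) edges, root node, cut-edges out, hybrid
#'   nodes, parent/children components, and whether the component is a leaf.
#' @export
decompose_network <- function(net) {
  g <- igraph::graph_from_edgelist(net$edge, directed = FALSE)
  bc <- igraph::biconnected_components(g)
  blocks <- lapply(bc$component_edges, as.integer)
  nontrivial <- blocks[vapply(blocks, length, 1L) > 1L]

  n <- net$n
  blob_of <- rep(NA_integer_, n)      # non-trivial blob membership per node
  blob_root <- integer(length(nontrivial))
  for (b in seq_along(nontrivial)) {
    eids <- nontrivial[[b]]
    vs <- unique(as.integer(net$edge[eids, ]))
    tgt <- unique(net$edge[eids, 2L])
    r <- setdiff(vs, tgt)
    if (length(r) != 1L)
      stop("internal error: biconnected component without a unique root")
    blob_root[b] <- r
    blob_of[vs] <- b
  }

  ## component ids: one per non-trivial blob, one per remaining free node
  free <- which(is.na(blob_of) | (seq_len(n) %in% blob_root))
  free <- setdiff(free, blob_root)    # blob roots represent their blob
  p <- length(nontrivial) + length(free)
  comp_nodes <- c(lapply(seq_along(nontrivial), function(b)
    sort(unique(as.integer(net$edge[nontrivial[[b]], ])))),
    as.list(free))
  comp_edges <- c(nontrivial, rep(list(integer(0)), length(free)))
  comp_root <- c(blob_root, free)

  comp_of <- rep(NA_integer_, n)      # component of each node (roots included)
  for (ci in seq_len(p)) comp_of[comp_nodes[[ci]]] <- ci
  for (b in seq_along(nontrivial)) comp_of[blob_root[b]] <- b

  in_block <- rep(FALSE, net$m)
  for (eids in nontrivial) in_block[eids] <- TRUE
  bridges <- which(!in_block)

  cut_out <- vector("list", p)
  parent <- rep(NA_integer_, p)
  for (e in bridges) {
    src <- comp_of[net$edge[e, 1L]]
    tgtnode <- net$edge[e, 2L]
    tgt <- comp_of[tgtnode]
    ## the bridge target is the root of the child component
    if (comp_root[tgt] != tgtnode)
      stop("internal error: bridge target is not a component root")
    cut_out[[src]] <- c(cut_out[[src]], e)
    parent[tgt] <- src
  }
  ## a non-trivial blob's root may itself sit below a bridge handled above;
  ## blob members other than the root never head a component
  root_comp <- comp_of[net$root]

  depth <- rep(NA_integer_, p)
  depth[root_comp] <- 0L
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    for (ci in todo)
      if (!is.na(depth[parent[ci]])) depth[ci] <- depth[parent[ci]] + 1L
  }

  hybrids <- lapply(comp_nodes, function(vs)
    sort(vs[net$kind[vs] == "hybridization"]))
  is_leaf_comp <- vapply(seq_len(p), function(ci)
    length(comp_nodes[[ci]]) == 1L &&
      net$kind[comp_root[ci]] == "leaf", TRUE)

  structure(list(
    net = net, p = p,
    nodes = comp_nodes, block_edges = comp_edges, root = comp_root,
    cut_out = cut_out, parent = parent, depth = depth,
    comp_of = comp_of, root_comp = root_comp,
    hybrids = hybrids, is_leaf = is_leaf_comp,
    level = max(c(0L, vapply(hybrids, length, 1L)))
  ), class = "dl_decomposition")
}

## level of a network = max hybridization count over biconnected components
network_level <- function(net) {
  if (net$h == 0L) return(0L)
  decompose_network(net)$level
}

#' @export
print.dl_decomposition <- function(x, ...) {
  nt <- sum(vapply(x$block_edges, length, 1L) > 1L)
  cat("Biconnected-component decomposition:", x$p, "components (",
      nt, "non-trivial ), level", x$level, "\n")
  invisible(x)
}

## LCA of two components in the component tree
comp_lca <- function(dec, a, b) {
  while (a != b) {
    if (dec$depth[a] >= dec$depth[b]) a <- dec$parent[a] else b <- dec$parent[b]
  }
  a
}

#' Gene-tree labelling by biconnected components
#'
#' Labels every gene-tree node with the lowest component whose subnetwork
#' contains all species of the gene subtree (leaves get their species' leaf
#' component, internal nodes the component-tree LCA of their children's
#' labels), then inserts one artificial pass-through node per component
#' skipped along each gene-tree edge.  The result is the augmented gene tree
#' on which the per-component forests are built.
#'
#' The gene tree must have no internal node whose subtree spans a single
#' species (see \code{\link{normalize_gene_tree}}).
#'
#' @param gt a \code{dl_genetree}, single-species subtrees collapsed.
#' @param net a \code{dl_network} with \code{species(gt)} among its labels.
#' @param dec the decomposition of \code{net}.
#' @return an object of class \code{dl_augmented}: parent/children arrays,
#'   component label \code{comp}, \code{artificial} flags and the map
#'   \code{orig} back to gene-tree nodes.
#' @export
augment_gene_tree <- function(gt, net, dec) {
  missing <- setdiff(gt$label[gt$leaves], net$label[net$leaves])
  if (length(missing))
    stop("gene-tree species absent from network: ",
         paste(missing, collapse = ", "))

  ngt <- gt$n
  Bcomp <- rep(NA_integer_, ngt)
  for (u in gt$postorder) {
    if (!is.na(gt$label[u])) {
      Bcomp[u] <- dec$comp_of[net$leaf_of[[gt$label[u]]]]
    } else {
      ch <- gt$children[[u]]
      Bcomp[u] <- comp_lca(dec, Bcomp[ch[1L]], Bcomp[ch[2L]])
    }
  }

  ## grow arrays while inserting artificial chains on each edge
  par <- gt$par
  children <- gt$children
  comp <- Bcomp
  artificial <- rep(FALSE, ngt)
  orig <- seq_len(ngt)
  nn <- ngt
  for (u in which(is.na(gt$label))) {
    for (v in gt$children[[u]]) {
      chain <- integer(0)                 # components strictly between
      c0 <- dec$parent[Bcomp[v]]
      while (!is.na(c0) && c0 != Bcomp[u] && dec$depth[c0] > dec$depth[Bcomp[u]]) {
        chain <- c(chain, c0)
        c0 <- dec$parent[c0]
      }
      if (!length(chain)) next
      prev <- u
      for (ci in rev(chain)) {            # top-down insertion
        nn <- nn + 1L
        par[nn] <- prev
        children[[prev]] <- replace(children[[prev]],
                                    children[[prev]] == v, nn)
        comp[nn] <- ci
        artificial[nn] <- TRUE
        orig[nn] <- NA_integer_
        children[[nn]] <- v
        prev <- nn
      }
      par[v] <- prev
    }
  }

  topo <- integer(0)
  queue <- gt$root
  while (length(queue)) {
    w <- queue[1L]; queue <- queue[-1L]
    topo <- c(topo, w)
    queue <- c(queue, children[[w]])
  }

  structure(list(
    gt = gt, net = net, dec = dec,
    n = nn, par = par, children = children, comp = comp,
    artificial = artificial, orig = orig, root = gt$root,
    topo = topo, postorder = rev(topo),
    label = c(gt$label, rep(NA_character_, nn - ngt))
  ), class = "dl_augmented")
}

#' Per-component forests of the augmented gene tree
#'
#' For every component that is not a leaf, the maximal connected subgraphs of
#' the augmented gene tree whose internal nodes are all labelled by that
#' component.  Each subgraph is either a binary tree or a single edge hanging
#' from an artificial node; its leaves are labelled by child components.
#'
#' @param aug a \code{dl_augmented}.
#' @return a list indexed by component id; each element is a list of
#'   subgraphs with fields \code{root}, \code{internal}, \code{leaves} (node
#'   ids of \code{aug}) and \code{is_edge}.
#' @export
component_forest <- function(aug) {
  dec <- aug$dec
  is_internal <- vapply(seq_len(aug$n), function(v)
    length(aug$children[[v]]) > 0L, TRUE)
  forests <- rep(list(list()), dec$p)

  grp <- rep(NA_integer_, aug$n)
  ngrp <- 0L
  for (v in aug$topo) {
    if (!is_internal[v]) next
    pv <- aug$par[v]
    if (!is.na(pv) && is_internal[pv] && aug$comp[pv] == aug$comp[v]) {
      grp[v] <- grp[pv]
    } else {
      ngrp <- ngrp + 1L
      grp[v] <- ngrp
    }
  }
  for (g in seq_len(ngrp)) {
    members <- which(!is.na(grp) & grp == g)
    ci <- aug$comp[members[1L]]
    root <- members[which.min(match(members, aug$topo))]
    kids <- setdiff(unique(unlist(aug$children[members])), members)
    forests[[ci]][[length(forests[[ci]]) + 1L]] <- list(
      root = root, internal = members, leaves = sort(kids),
      is_edge = length(members) == 1L && aug$artificial[members])
  }
  ## deterministic order inside each forest
  for (ci in seq_len(dec$p)) {
    f <- forests[[ci]]
    if (length(f) > 1L)
      forests[[ci]] <- f[order(vapply(f, function(H) H$root, 1L))]
  }
  forests
}
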