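## Propagation closure of an off-edge set inside an edge subset.  An edge is
## additionally switched off when its target still has outgoing edges in the
## subset but all of them are off; leaves never trigger propagation.
propagate_off <- function(net, off, edge_set) {
  off <- sort(unique(off))
  repeat {
    changed <- FALSE
    for (e in setdiff(edge_set, off)) {
      v <- net$edge[e, 2L]
      outs <- intersect(net$child_edges[[v]], edge_set)
      if (length(outs) && all(outs %in% off)) {
        off <- c(off, e)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(off)
}

#' Build a switching of a network
#'
#' A switching keeps, for every hybridization node, exactly one incoming
#' edge; the discarded edges — together with edges starved by the propagation
#' closure — are switched off, and the remaining on-edges display a tree.
#' \code{V_on}, the nodes not touching any off edge, determines which nodes
#' count towards losses.
#'
#' @param net a \code{dl_network}.
#' @param choice integer vector, one kept incoming edge id per hybridization
#'   node, named by hybridization node id; alternatively \code{off} may be
#'   given directly.
#' @param off pre-propagation off edge ids (overrides \code{choice}).
#' @return an object of class \code{dl_switching}.
#' @export
switching <- function(net, choice = NULL, off = NULL) {
  if (is.null(off)) {
    hybs <- which(net$kind == "hybridization")
    off <- integer(0)
    for (hv in hybs) {
      pe <- net$parent_edges[[hv]]
      keep <- choice[[as.character(hv)]]
      if (is.null(keep) || !(keep %in% pe))
        stop("choice must select one incoming edge of hybridization node ", hv)
      off <- c(off, setdiff(pe, keep))
    }
  }
  off <- propagate_off(net, off, seq_len(net$m))
  build_switching(net, off)
}

build_switching <- function(net, off) {
  on <- rep(TRUE, net$m)
  on[off] <- FALSE
  n <- net$n

  von <- rep(TRUE, n)
  von[unique(as.integer(net$edge[off, ]))] <- FALSE

  ## on-tree structure over the part reachable from the root
  onpar <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  depth[net$root] <- 0L
  for (v in net$topo) {
    if (is.na(depth[v])) next
    for (e in net$child_edges[[v]]) {
      if (!on[e]) next
      w <- net$edge[e, 2L]
      onpar[w] <- v
      depth[w] <- depth[v] + 1L
    }
  }
  ## nodes that count for switching-aware losses: in V_on and internal
  count <- von & net$kind != "leaf"

  structure(list(
    net = net, off = sort(off), on = on, von = von,
    onpar = onpar, depth = depth, count = count,
    root_on = net$root,
    key = paste(sort(off), collapse = ",")
  ), class = "dl_switching")
}

#' @export
print.dl_switching <- function(x, ...) {
  cat("Switching:", sum(!x$on), "edges off;", sum(x$von), "of", x$net$n,
      "nodes in V_on\n")
  cat("  displayed tree:", write_switching(x), "\n")
  invisible(x)
}

#' @export
node_leq.dl_switching <- function(x, a, b) {
  check_node(x$net, a); check_node(x$net, b)
  v <- a
  while (!is.na(v)) {
    if (v == b) return(TRUE)
    v <- x$onpar[v]
  }
  FALSE
}

#' @export
node_dist.dl_switching <- function(x, b, a) {
  check_node(x$net, a); check_node(x$net, b)
  tr_dist(x$onpar, x$count, b, a)
}

## unique-path distance: number of counting nodes z with a < z <= b
tr_dist <- function(par, count, b, a) {
  if (a == b) return(0)
  d <- 0
  v <- par[a]
  while (!is.na(v)) {
    d <- d + as.numeric(count[v])
    if (v == b) return(d)
    v <- par[v]
  }
  Inf
}

tr_lca <- function(par, depth, a, b) {
  while (a != b) {
    if (is.na(depth[a]) || is.na(depth[b])) stop("node outside the on-tree")
    if (depth[a] >= depth[b]) a <- par[a] else b <- par[b]
  }
  a
}

## child of b on the unique on-path down to a (a < b assumed)
tr_step_child <- function(par, a, b) {
  v <- a
  repeat {
    pv <- par[v]
    if (is.na(pv)) stop("internal error: no on-path")
    if (pv == b) return(v)
    v <- pv
  }
}

#' Enumerate the switchings of an elementary network
#'
#' Lists the distinct post-propagation switchings of the elementary network
#' of one component: every combination of kept incoming edges over the
#' component's hybridization nodes, closed under propagation and
#' de-duplicated.  A component with \code{k} hybridization nodes yields at
#' most \code{2^k} switchings; cut-edges are always on.  Order is
#' deterministic (choices iterate by hybridization node id, then kept-edge
#' source id).
#'
#' @param dec a \code{dl_decomposition}.
#' @param ci component index.
#' @return list of component switchings (class \code{dl_comp_switching}).
#' @export
enumerate_switchings <- function(dec, ci) {
  net <- dec$net
  edge_set <- sort(c(dec$block_edges[[ci]], dec$cut_out[[ci]]))
  hybs <- dec$hybrids[[ci]]
  if (!length(hybs))
    return(list(comp_switching(dec, ci, integer(0), edge_set)))
  pe_list <- lapply(hybs, function(hv) {
    pe <- net$parent_edges[[hv]]
    pe[order(net$edge[pe, 1L])]              # by parent id
  })
  grid <- expand.grid(rev(lapply(pe_list, seq_along)))[, length(hybs):1L,
                                                       drop = FALSE]
  out <- list()
  seen <- character(0)
  for (i in seq_len(nrow(grid))) {
    off0 <- unlist(lapply(seq_along(hybs), function(j)
      pe_list[[j]][-grid[i, j]]))
    sw <- comp_switching(dec, ci, off0, edge_set)
    if (!(sw$key %in% seen)) {
      seen <- c(seen, sw$key)
      out[[length(out) + 1L]] <- sw
    }
  }
  out
}

## switching of the elementary network N(B): on/off over the component's own
## edges plus its cut-edges, with V_on and the loss-counting mask restricted
## to that subgraph (cut-edge targets are its leaves and never count)
comp_switching <- function(dec, ci, off0, edge_set = NULL) {
  net <- dec$net
  if (is.null(edge_set))
    edge_set <- sort(c(dec$block_edges[[ci]], dec$cut_out[[ci]]))
  off <- propagate_off(net, off0, edge_set)
  nodes <- sort(unique(as.integer(net$edge[edge_set, ])))
  root <- dec$root[ci]

  onpar <- rep(NA_integer_, net$n)
  depth <- rep(NA_integer_, net$n)
  depth[root] <- 0L
  for (v in intersect(net$topo, nodes)) {
    if (is.na(depth[v])) next
    for (e in intersect(net$child_edges[[v]], edge_set)) {
      if (e %in% off) next
      w <- net$edge[e, 2L]
      onpar[w] <- v
      depth[w] <- depth[v] + 1L
    }
  }
  von <- rep(FALSE, net$n)
  von[nodes] <- TRUE
  von[unique(as.integer(net$edge[off, ]))] <- FALSE
  has_out <- rep(FALSE, net$n)
  has_out[unique(net$edge[edge_set, 1L])] <- TRUE
  count <- von & has_out

  structure(list(
    comp = ci, dec = dec, edge_set = edge_set, off = off,
    nodes = nodes, root = root,
    onpar = onpar, depth = depth, von = von, count = count,
    key = paste(sort(off), collapse = ","),
    on_key = paste(sprintf("%05d", setdiff(edge_set, off)), collapse = ",")
  ), class = "dl_comp_switching")
}

#' Assemble a global switching from per-component choices
#'
#' The union of the per-component off-edge sets defines a switching of the
#' whole network whose restriction to each elementary network equals the
#' chosen component switching (propagation never crosses cut-edges).
#'
#' @param dec a \code{dl_decomposition}.
#' @param choices list of \code{dl_comp_switching}, at most one per
#'   component; components without an entry keep all edges on.
#' @return a \code{dl_switching} of the full network.
#' @export
assemble_switching <- function(dec, choices) {
  off <- sort(unique(unlist(lapply(choices, function(s) s$off))))
  off2 <- propagate_off(dec$net, off, seq_len(dec$net$m))
  if (!identical(off, off2))
    stop("internal error: propagation crossed a cut-edge")
  build_switching(dec$net, off)
}
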