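#' Meeting set of two nodes
#'
#' The set of nodes \code{z} that have two separated paths down to \code{x}
#' and \code{y} — paths whose first edges go through different children of
#' \code{z}.  All members are speciation (or root) nodes; on a tree with
#' \code{x, y} incomparable the set is the singleton \{LCA(x, y)\}.  These
#' are the feasible placements of a speciation whose daughter lineages end up
#' at \code{x} and \code{y}.
#'
#' @param net a \code{dl_network}.
#' @param x,y node ids.
#' @return integer vector of node ids (sorted).
#' @export
meeting_set <- function(net, x, y) {
  check_node(net, x); check_node(net, y)
  out <- integer(0)
  for (z in which(net$kind %in% c("root", "speciation"))) {
    ch <- net$children[[z]]
    if ((net$reach[ch[1L], x] && net$reach[ch[2L], y]) ||
        (net$reach[ch[2L], x] && net$reach[ch[1L], y]))
      out <- c(out, z)
  }
  sort(out)
}

#' Minimal meeting set of two nodes
#'
#' The subset of \code{\link{meeting_set}} obtained by discarding every
#' member \code{z} for which some other member lies on every path from
#' \code{z} to \code{x} and on every path from \code{z} to \code{y}: only the
#' lowest, non-dominated speciation placements remain.  Two routes are
#' provided: \code{"sweep"} is the upward dominator propagation used by the
#' network dynamic programme, \code{"enumerate"} is a direct reachability
#' check used as its oracle.
#'
#' @inheritParams meeting_set
#' @param method computation route; both must agree.
#' @export
min_meeting_set <- function(net, x, y, method = c("sweep", "enumerate")) {
  method <- match.arg(method)
  if (method == "sweep") return(meeting_sweep(net, x, y)$min_set)
  M <- meeting_set(net, x, y)
  keep <- vapply(M, function(z) {
    !any(vapply(setdiff(M, z), function(w)
      dominates(net, w, z, x) && dominates(net, w, z, y), TRUE))
  }, TRUE)
  M[keep]
}

## TRUE when every directed path from z down to t passes through w,
## established by deleting w and retesting reachability.
dominates <- function(net, w, z, t) {
  if (!net$reach[z, t]) return(FALSE)
  if (w == z || w == t) return(w == t)
  seen <- rep(FALSE, net$n)
  stack <- z
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == w || seen[v]) next
    if (v == t) return(FALSE)
    seen[v] <- TRUE
    stack <- c(stack, net$children[[v]])
  }
  TRUE
}

#' Minimal meeting set by upward sweep
#'
#' Performs the two upward traversals from \code{y} and \code{z} (over
#' reversed edges), propagating for every node strictly above both the lowest
#' node through which all of its paths to \code{y} and \code{z} must pass;
#' nodes that are their own such "low" point and have separated paths form
#' the minimal meeting set.  Also returns the loss-counting distances from
#' every visited ancestor down to \code{y} and \code{z}.
#'
#' @param net a \code{dl_network}.
#' @param y,z node ids.
#' @return list with \code{min_set}, and named distance vectors
#'   \code{dist_y}, \code{dist_z} over the visited ancestors.
#' @export
meeting_sweep <- function(net, y, z) {
  check_node(net, y); check_node(net, z)
  n <- net$n
  above_y <- net$reach[, y]          # BFS(y): nodes above or equal to y
  above_z <- net$reach[, z]
  ## dominator chains: dom[[v]] = nodes lying on every path from v to y
  ## and on every path from v to z (v itself included)
  dom_to <- function(above, target) {
    dom <- vector("list", n)
    for (v in rev(net$topo)[rev(net$topo) %in% which(above)]) {
      if (v == target) { dom[[v]] <- v; next }
      ch <- net$children[[v]][above[net$children[[v]]]]
      acc <- dom[[ch[1L]]]
      for (c2 in ch[-1L]) acc <- intersect(acc, dom[[c2]])
      dom[[v]] <- c(v, acc)
    }
    dom
  }
  dom_y <- dom_to(above_y, y)
  dom_z <- dom_to(above_z, z)

  M <- meeting_set(net, y, z)
  min_set <- M[vapply(M, function(v) {
    shared <- setdiff(intersect(dom_y[[v]], dom_z[[v]]), v)
    !any(shared %in% M)
  }, TRUE)]

  vy <- which(above_y)
  vz <- which(above_z)
  list(min_set = sort(min_set),
       dist_y = stats::setNames(net$distmat[vy, y], vy),
       dist_z = stats::setNames(net$distmat[vz, z], vz))
}

#' Meeting set of a set of leaves
#'
#' For a single leaf, the leaf itself; otherwise all nodes above every leaf
#' of \code{L} that have separated paths to two distinct leaves of \code{L}.
#' Candidate images of a gene node whose descendant genes live in the species
#' of \code{L} all belong to this set, whose size is bounded by the number of
#' hybridization nodes plus a small constant.
#'
#' @param net a \code{dl_network}.
#' @param L integer vector of leaf node ids.
#' @export
meeting_set_leaves <- function(net, L) {
  if (!length(L)) stop("L must contain at least one leaf")
  for (l in L) {
    check_node(net, l)
    if (net$kind[l] != "leaf") stop("non-leaf member of L: node ", l)
  }
  L <- sort(unique(L))
  if (length(L) == 1L) return(L)
  out <- integer(0)
  for (m in which(net$kind %in% c("root", "speciation"))) {
    if (!all(net$reach[m, L])) next
    ch <- net$children[[m]]
    A <- L[net$reach[ch[1L], L]]
    B <- L[net$reach[ch[2L], L]]
    if (length(A) && length(B) &&
        !(length(A) == 1L && length(B) == 1L && A == B))
      out <- c(out, m)
  }
  sort(out)
}
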