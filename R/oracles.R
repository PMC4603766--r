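#' Brute-force minimum over all switchings
#'
#' Enumerates every pre-propagation switching of the network (one kept
#' incoming edge per hybridization node), closes each under propagation,
#' de-duplicates, and reconciles the gene tree with each displayed tree by
#' LCA reconciliation.  Exponential in the total number of hybridization
#' nodes; guarded.
#'
#' @inheritParams best_switching
#' @param max_h refuse networks with more hybridization nodes than this.
#' @return list with the minimal \code{cost}, the number of distinct
#'   switchings (\code{n_switchings}) and the best \code{switching}.
#' @export
oracle_best_switching <- function(gt, net, dup_cost = 1, loss_cost = 1,
                                  max_h = 12L) {
  check_costs(dup_cost, loss_cost)
  if (net$h > max_h)
    stop("oracle guard exceeded: ", net$h, " hybridization nodes (max ",
         max_h, ")")
  hybs <- which(net$kind == "hybridization")
  pe_list <- lapply(hybs, function(hv) net$parent_edges[[hv]])
  idx <- rep(list(1:2), length(hybs))
  grid <- if (length(hybs)) expand.grid(idx) else data.frame(dummy = 1)
  best <- NULL; best_cost <- Inf; seen <- character(0); nsw <- 0L
  for (i in seq_len(nrow(grid))) {
    off <- if (length(hybs))
      unlist(lapply(seq_along(hybs), function(j)
        pe_list[[j]][-grid[i, j]])) else integer(0)
    sw <- switching(net, off = off)
    if (sw$key %in% seen) next
    seen <- c(seen, sw$key)
    nsw <- nsw + 1L
    rec <- lca_reconcile(gt, sw, dup_cost, loss_cost)
    if (rec$cost < best_cost) {
      best_cost <- rec$cost
      best <- sw
    }
  }
  list(cost = best_cost, n_switchings = nsw, switching = best)
}

#' Brute-force minimum reconciliation with a network
#'
#' Exhaustive search over the feasible set of the reconciliation definition:
#' every mapping of every gene node to every network node is considered via
#' a full table over (gene node, network node) pairs, with events validated
#' directly — speciations by the separated-paths test on the two children's
#' images, duplications by comparability — and losses from shortest-path
#' distances.  No candidate pruning, minimal-meeting-set or merge machinery
#' is involved, so this is an independent route from
#' \code{\link{reconcile_network}}.  Guarded to small instances.
#'
#' @inheritParams best_switching
#' @param max_internal,max_nodes guards on the gene tree's internal node
#'   count and the network size.
#' @return the minimal cost (a number).
#' @export
oracle_reconcile_network <- function(gt, net, dup_cost = 1, loss_cost = 1,
                                     max_internal = 6L, max_nodes = 25L) {
  check_costs(dup_cost, loss_cost)
  g <- gt
  n_int <- sum(is.na(g$label))
  if (n_int > max_internal)
    stop("oracle guard exceeded: ", n_int, " internal gene nodes (max ",
         max_internal, ")")
  if (net$n > max_nodes)
    stop("oracle guard exceeded: ", net$n, " network nodes (max ",
         max_nodes, ")")

  nN <- net$n
  d <- net$distmat
  reach <- net$reach
  Tbl <- matrix(Inf, g$n, nN)
  for (u in g$postorder) {
    if (!is.na(g$label[u])) {
      Tbl[u, net$leaf_of[[g$label[u]]]] <- 0
      next
    }
    ch <- g$children[[u]]
    c1 <- Tbl[ch[1L], ]; c2 <- Tbl[ch[2L], ]
    for (x in seq_len(nN)) {
      xc <- net$children[[x]]
      ## duplication at x: both children's images weakly below x
      dupc <- dup_cost +
        min(c1 + loss_cost * d[x, ]) + min(c2 + loss_cost * d[x, ])
      best <- dupc
      if (length(xc) == 2L) {
        ## speciation at x: separated paths through the two children;
        ## infeasible pairings carry infinite distances
        P <- pmin(outer(d[xc[1L], ], d[xc[2L], ], "+"),
                  outer(d[xc[2L], ], d[xc[1L], ], "+"))
        tot <- outer(c1, c2, "+") + loss_cost * P
        best <- min(best, suppressWarnings(min(tot)))
      }
      Tbl[u, x] <- best
    }
  }
  min(Tbl[g$root, ])
}
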