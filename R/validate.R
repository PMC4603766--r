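#' Check a reconciliation against the model definition
#'
#' Verifies the three defining constraints of a duplication-loss
#' reconciliation of a gene tree with a network (or switching): contemporary
#' events exactly at gene leaves mapped to same-species leaves; speciations
#' placed at nodes with separated paths to the children's images; and the
#' no-time-travel ordering along gene-tree edges (descendant images weakly
#' below under a duplication, strictly below otherwise).  Loss counts and
#' the total cost are recomputed from the image map alone.
#'
#' Checking the ordering edge by edge is equivalent to checking all
#' ancestor-descendant pairs: a speciation forces a strict drop and strictness
#' propagates along any chain.
#'
#' @param gt a \code{dl_genetree}.
#' @param target a \code{dl_network} or \code{dl_switching}.
#' @param alpha data.frame with columns \code{node}, \code{image},
#'   \code{event} (\code{"S"}, \code{"D"} or \code{"C"}) covering every node
#'   of \code{gt}.
#' @param dup_cost,loss_cost positive event costs.
#' @return list with \code{valid}, the first violated \code{clause} (or
#'   \code{NA}), and recomputed \code{d}, \code{l}, \code{cost} and per-node
#'   \code{losses} when valid.
#' @export
validate_reconciliation <- function(gt, target, alpha, dup_cost = 1,
                                    loss_cost = 1) {
  check_costs(dup_cost, loss_cost)
  on_network <- inherits(target, "dl_network")
  net <- if (on_network) target else target$net

  img <- ev <- NULL
  img <- stats::setNames(alpha$image, alpha$node)
  ev <- stats::setNames(alpha$event, alpha$node)
  if (any(!(as.character(seq_len(gt$n)) %in% names(img))))
    return(bad("unmapped gene-tree node"))

  leq2 <- function(a, b) node_leq(target, a, b)
  dist2 <- function(b, a) node_dist(target, b, a)
  fail <- NULL
  losses <- stats::setNames(rep(0, gt$n), seq_len(gt$n))

  for (u in seq_len(gt$n)) {
    k <- as.character(u)
    x <- img[[k]]
    is_leaf <- length(gt$children[[u]]) == 0L
    if (is_leaf != (ev[[k]] == "C"))
      return(bad("contemporary events must occur exactly at gene leaves"))
    if (is_leaf) {
      if (net$kind[x] != "leaf" || net$label[x] != gt$label[u])
        return(bad(paste0("leaf ", u, " mapped to a non-matching node")))
      next
    }
    ch <- gt$children[[u]]
    i1 <- img[[as.character(ch[1L])]]
    i2 <- img[[as.character(ch[2L])]]
    if (ev[[k]] == "S") {
      ok <- if (on_network) x %in% meeting_set(net, i1, i2) else
        switching_separated(target, x, i1, i2)
      if (!ok)
        return(bad(paste0("speciation at node ", u,
                          " lacks separated paths to its children's images")))
    } else if (ev[[k]] != "D") {
      return(bad(paste0("unknown event '", ev[[k]], "' at node ", u)))
    }
    strict <- ev[[k]] == "S"
    for (i in c(i1, i2)) {
      if (!leq2(i, x) || (strict && i == x))
        return(bad(paste0("ordering violated on edge into node ", u)))
    }
    ## recompute losses
    if (ev[[k]] == "D") {
      losses[k] <- dist2(x, i1) + dist2(x, i2)
    } else {
      xc <- if (on_network) net$children[[x]] else {
        ad <- target_adapter(target)
        ad$children_on(x)
      }
      losses[k] <- min(dist2(xc[1L], i1) + dist2(xc[2L], i2),
                       dist2(xc[1L], i2) + dist2(xc[2L], i1))
    }
    if (!is.finite(losses[k]))
      return(bad(paste0("no path supporting the event at node ", u)))
  }
  d <- sum(ev[as.character(which(is.na(gt$label)))] == "D")
  l <- sum(losses)
  list(valid = TRUE, clause = NA_character_, d = d, l = l,
       losses = losses, cost = d * dup_cost + l * loss_cost)
}

bad <- function(msg) list(valid = FALSE, clause = msg, d = NA, l = NA,
                          losses = NULL, cost = NA)

## separated paths on a switching: x has two on-children leading to the two
## images (in either pairing)
switching_separated <- function(sw, x, i1, i2) {
  ad <- target_adapter(sw)
  ch <- ad$children_on(x)
  if (length(ch) != 2L) return(FALSE)
  onleq <- function(a, b) node_leq(sw, a, b)
  (onleq(i1, ch[1L]) && onleq(i2, ch[2L])) ||
    (onleq(i1, ch[2L]) && onleq(i2, ch[1L]))
}
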