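#' Minimum duplication-loss reconciliation with a whole network
#'
#' Dynamic programme over candidate mapping sets: in gene-tree post-order,
#' every node keeps the pairs (network node, minimal cost of reconciling its
#' subtree there).  For each pair of child candidates, speciation placements
#' range over the minimal meeting set of the two images (with the cheaper of
#' the two loss pairings), and a duplication placement at the higher image is
#' added when the images are comparable.  Per network node only the cheapest
#' pair survives a merge, which keeps candidate sets small — their size is
#' bounded by the number of hybridization nodes plus two.
#'
#' @param gt a \code{dl_genetree}.
#' @param net a \code{dl_network}.
#' @param dup_cost,loss_cost positive event costs.
#' @return an object of class \code{dl_network_dp}: minimal \code{cost},
#'   event totals, the explicit backtracked \code{reconciliation} of the
#'   gene tree, candidate \code{tables} per gene node,
#'   and \code{max_candidates}, the largest candidate-set size encountered.
#' @export
reconcile_network <- function(gt, net, dup_cost = 1, loss_cost = 1) {
  check_costs(dup_cost, loss_cost)
  missing <- setdiff(gt$label[gt$leaves], net$label[net$leaves])
  if (length(missing))
    stop("gene-tree species absent from network: ",
         paste(missing, collapse = ", "))
  ## The DP runs on the gene tree as given: collapsing single-species
  ## subtrees is exact on trees and switchings but not on networks, where a
  ## node above a hybridization can have two separated paths to one leaf and
  ## explain such a subtree by speciations instead of duplications.
  g <- gt
  dmat <- net$distmat
  reach <- net$reach

  sweep_cache <- new.env(parent = emptyenv())
  min_set <- function(y, z) {
    k <- paste(sort(c(y, z)), collapse = "_")
    got <- sweep_cache[[k]]
    if (is.null(got)) {
      got <- meeting_sweep(net, y, z)$min_set
      sweep_cache[[k]] <- got
    }
    got
  }

  C <- vector("list", g$n)      # per gene node: data.frame of candidates
  max_c <- 0L
  nspecies <- integer(g$n)      # species spanned by each subtree
  spset <- vector("list", g$n)
  for (u in g$postorder) {
    if (!is.na(g$label[u])) {
      spset[[u]] <- g$label[u]
      nspecies[u] <- 1L
      C[[u]] <- data.frame(x = net$leaf_of[[g$label[u]]], c = 0,
                           event = "C", y = NA_integer_, z = NA_integer_,
                           losses = 0)
      next
    }
    spset[[u]] <- unique(unlist(spset[g$children[[u]]]))
    nspecies[u] <- length(spset[[u]])
    ch <- g$children[[u]]
    cand <- list()
    for (i in seq_len(nrow(C[[ch[1L]]]))) {
      for (j in seq_len(nrow(C[[ch[2L]]]))) {
        y <- C[[ch[1L]]]$x[i]; c1 <- C[[ch[1L]]]$c[i]
        z <- C[[ch[2L]]]$x[j]; c2 <- C[[ch[2L]]]$c[j]
        for (x in min_set(y, z)) {
          xc <- net$children[[x]]
          lo <- min(dmat[xc[1L], y] + dmat[xc[2L], z],
                    dmat[xc[1L], z] + dmat[xc[2L], y])
          if (is.finite(lo))
            cand[[length(cand) + 1L]] <-
              list(x = x, c = c1 + c2 + loss_cost * lo, event = "S",
                   y = y, z = z, losses = lo)
        }
        if (y == z) {
          cand[[length(cand) + 1L]] <-
            list(x = z, c = dup_cost + c1 + c2, event = "D",
                 y = y, z = z, losses = 0)
        } else if (reach[z, y]) {        # y < z: duplication at z
          lo <- dmat[z, y]
          cand[[length(cand) + 1L]] <-
            list(x = z, c = dup_cost + loss_cost * lo + c1 + c2,
                 event = "D", y = y, z = z, losses = lo)
        } else if (reach[y, z]) {        # z < y: duplication at y
          lo <- dmat[y, z]
          cand[[length(cand) + 1L]] <-
            list(x = y, c = dup_cost + loss_cost * lo + c1 + c2,
                 event = "D", y = y, z = z, losses = lo)
        }
      }
    }
    if (!length(cand))
      stop("internal error: empty candidate set at gene node ", u)
    tab <- do.call(rbind, lapply(cand, as.data.frame))
    ## merge: keep, per network node, the first minimal-cost pair
    tab <- tab[order(tab$x, tab$c), , drop = FALSE]
    tab <- tab[!duplicated(tab$x), , drop = FALSE]
    rownames(tab) <- NULL
    C[[u]] <- tab
    ## the h+2 size bound is stated for nodes spanning at least two species
    if (nspecies[u] >= 2L) max_c <- max(max_c, nrow(tab))
  }

  root_tab <- C[[g$root]]
  best <- which(root_tab$c <= min(root_tab$c) + 1e-12)
  best <- best[which.min(root_tab$x[best])]
  rec_norm <- backtrack_candidates(g, C, root_tab$x[best])
  rec_norm <- as_reconciliation(list(
    node = rec_norm$node, image = rec_norm$image, event = rec_norm$event,
    losses = rec_norm$losses,
    d = sum(rec_norm$event == "D"), l = sum(rec_norm$losses),
    cost = sum(rec_norm$event == "D") * dup_cost +
      sum(rec_norm$losses) * loss_cost), dup_cost, loss_cost)
  if (abs(rec_norm$cost - root_tab$c[best]) > 1e-9)
    stop("internal error: backtracked cost differs from the table minimum")
  rec <- rec_norm

  structure(list(
    cost = rec$cost, d = rec$d, l = rec$l,
    reconciliation = rec, tables = C,
    max_candidates = max_c, h = net$h,
    dup_cost = dup_cost, loss_cost = loss_cost
  ), class = "dl_network_dp")
}

## Recover one optimal assignment from the candidate tables, starting from a
## chosen root image; ties inside the tables were resolved at merge time
## (first minimal pair per network node), so the output is deterministic.
backtrack_candidates <- function(g, C, root_x) {
  node <- integer(0); image <- integer(0); event <- character(0)
  losses <- numeric(0)
  recur <- function(u, x) {
    tab <- C[[u]]
    row <- tab[tab$x == x, , drop = FALSE][1L, ]
    node <<- c(node, u); image <<- c(image, row$x)
    event <<- c(event, row$event); losses <<- c(losses, row$losses)
    if (row$event == "C") return(invisible())
    ch <- g$children[[u]]
    recur(ch[1L], row$y)
    recur(ch[2L], row$z)
  }
  recur(g$root, root_x)
  o <- order(node)
  list(node = node[o], image = image[o], event = event[o],
       losses = losses[o])
}

#' @export
print.dl_network_dp <- function(x, ...) {
  cat("Network DL reconciliation: cost", x$cost, "(", x$d, "duplications,",
      x$l, "losses )\n")
  cat("  largest candidate set:", x$max_candidates,
      "( bound h + 2 =", x$h + 2, ")\n")
  invisible(x)
}
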