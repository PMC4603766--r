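#' Random binary species network
#'
#' Grows a random binary tree by sequential leaf attachment, then adds the
#' requested number of hybridization events: each event subdivides two
#' distinct edges and connects the upper subdivision point (a new speciation
#' node) to the lower one (a new hybridization node), rejecting choices that
#' would create a directed cycle.  Node ids follow construction order.
#'
#' @param n_leaves number of species (at least 2).
#' @param n_hybridizations number of hybridization nodes (at least 0).
#' @param seed integer seed; the same seed reproduces the same network.
#' @param max_tries retries per reticulation before giving up.
#' @return a \code{dl_network} with exactly \code{n_hybridizations}
#'   hybridization nodes; the realized level is in \code{$level}.
#' @export
random_network <- function(n_leaves, n_hybridizations = 0L, seed = 1L,
                           max_tries = 500L) {
  if (n_leaves < 2L) stop("n_leaves must be at least 2")
  if (n_hybridizations < 0L) stop("n_hybridizations must be non-negative")
  withr::with_seed(seed, {
    ## random tree: root -> two leaves, then attach leaves on random edges
    edges <- matrix(c(1L, 2L, 1L, 3L), 2, 2, byrow = TRUE)
    nn <- 3L
    leaves <- c(2L, 3L)
    while (length(leaves) < n_leaves) {
      e <- sample.int(nrow(edges), 1L)
      mid <- nn + 1L; lf <- nn + 2L; nn <- nn + 2L
      tgt <- edges[e, 2L]
      edges[e, 2L] <- mid
      edges <- rbind(edges, c(mid, tgt), c(mid, lf))
      leaves <- c(leaves, lf)
    }
    added <- 0L
    tries <- 0L
    while (added < n_hybridizations) {
      tries <- tries + 1L
      if (tries > max_tries * max(1L, n_hybridizations))
        stop("could not place ", n_hybridizations,
             " reticulations on ", n_leaves, " leaves")
      es <- sample.int(nrow(edges), 2L)
      e1 <- es[1L]; e2 <- es[2L]
      ## cycle check: the new edge a -> b (a on e1, b on e2) is safe unless
      ## the source of e1 is reachable from the target of e2
      if (reachable_in(edges, edges[e2, 2L], edges[e1, 1L])) next
      a <- nn + 1L; b <- nn + 2L; nn <- nn + 2L
      t1 <- edges[e1, 2L]; t2 <- edges[e2, 2L]
      edges[e1, 2L] <- a
      edges[e2, 2L] <- b
      edges <- rbind(edges, c(a, t1), c(b, t2), c(a, b))
      added <- added + 1L
    }
    labels <- stats::setNames(paste0("s", seq_along(leaves)), leaves)
    validate_network(edges, labels)
  })
}

reachable_in <- function(edges, from, to) {
  if (from == to) return(TRUE)
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nxt <- edges[edges[, 1L] %in% frontier, 2L]
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

#' Simulate a gene family inside a species network
#'
#' Picks a uniform random switching of the network and evolves a single gene
#' lineage down its displayed tree: at every speciation node untouched by
#' switched-off edges the lineage first duplicates with probability
#' \code{dup_rate}, then follows both children, each child copy being lost
#' with probability \code{loss_rate}; hybridization nodes and nodes bypassed
#' by the switching are crossed silently.  Extinct side branches are pruned
#' and only events visible in the surviving history are counted, so the
#' recorded duplication and loss counts \code{d_true}, \code{l_true} give a
#' certificate: the LCA reconciliation of the simulated tree with the true
#' switching costs at most \code{dup_cost * d_true + loss_cost * l_true}.
#'
#' @param net a \code{dl_network}.
#' @param dup_rate,loss_rate event probabilities in [0, 1).
#' @param seed integer seed (drives both the switching choice and the
#'   evolution).
#' @param max_tries resample attempts when the family goes extinct or keeps
#'   fewer than two genes.
#' @return a list of class \code{dl_simulation}: \code{gene_tree},
#'   \code{switching}, \code{d_true}, \code{l_true}, \code{seed},
#'   \code{dup_rate}, \code{loss_rate}.
#' @export
simulate_gene_tree <- function(net, dup_rate = 0.1, loss_rate = 0.1,
                               seed = 1L, max_tries = 100L) {
  if (dup_rate < 0 || dup_rate >= 1 || loss_rate < 0 || loss_rate >= 1)
    stop("rates must lie in [0, 1)")
  withr::with_seed(seed, {
    hybs <- which(net$kind == "hybridization")
    off <- unlist(lapply(hybs, function(hv) {
      pe <- net$parent_edges[[hv]]
      pe[-sample.int(2L, 1L)]
    }))
    sw <- switching(net, off = if (length(off)) off else integer(0))
    ad <- target_adapter(sw)

    for (try in seq_len(max_tries)) {
      hist <- evolve_lineage(net, sw, ad, net$root, dup_rate, loss_rate)
      pruned <- prune_history(hist)
      if (!is.null(pruned) && pruned$n_leaves >= 2L) {
        gt <- history_to_genetree(pruned$tree)
        return(structure(list(
          gene_tree = gt, switching = sw,
          d_true = pruned$d, l_true = pruned$l,
          seed = seed, dup_rate = dup_rate, loss_rate = loss_rate
        ), class = "dl_simulation"))
      }
    }
    stop("simulation kept going extinct; raise max_tries or lower loss_rate")
  })
}

## history nodes: list(type = "leaf"|"spec"|"dup"|"loss", children, label)
evolve_lineage <- function(net, sw, ad, v, dup_rate, loss_rate) {
  repeat {
    if (net$kind[v] == "leaf")
      return(list(type = "leaf", label = net$label[v]))
    ch <- ad$children_on(v)
    if (length(ch) == 1L || !sw$von[v]) {   # silent crossing
      v <- if (length(ch) == 1L) ch else {
        ## von is FALSE yet two on-children cannot happen: a node with an
        ## off edge has at most one on child
        stop("internal error: off-touched node with two on-children")
      }
      next
    }
    break
  }
  if (stats::runif(1) < dup_rate) {
    return(list(type = "dup", children = list(
      speciate(net, sw, ad, v, dup_rate, loss_rate),
      speciate(net, sw, ad, v, dup_rate, loss_rate))))
  }
  speciate(net, sw, ad, v, dup_rate, loss_rate)
}

speciate <- function(net, sw, ad, v, dup_rate, loss_rate) {
  ch <- ad$children_on(v)
  branch <- function(w) {
    if (stats::runif(1) < loss_rate) list(type = "loss")
    else evolve_lineage(net, sw, ad, w, dup_rate, loss_rate)
  }
  list(type = "spec", children = list(branch(ch[1L]), branch(ch[2L])))
}

## keep only the surviving skeleton; a dead side branch below a surviving
## node is one loss, events inside extinct subtrees are invisible
prune_history <- function(h) {
  if (h$type == "loss") return(NULL)
  if (h$type == "leaf")
    return(list(tree = h, d = 0L, l = 0L, n_leaves = 1L))
  a <- prune_history(h$children[[1L]])
  b <- prune_history(h$children[[2L]])
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a) || is.null(b)) {
    s <- if (is.null(a)) b else a
    extra_loss <- if (h$type == "spec") 1L else 0L
    return(list(tree = s$tree, d = s$d, l = s$l + extra_loss,
                n_leaves = s$n_leaves))
  }
  list(tree = list(type = h$type, children = list(a$tree, b$tree)),
       d = a$d + b$d + if (h$type == "dup") 1L else 0L,
       l = a$l + b$l, n_leaves = a$n_leaves + b$n_leaves)
}

history_to_genetree <- function(tree) {
  edges <- NULL
  labels <- character(0)
  nn <- 1L
  rec <- function(node, id) {
    force(id)
    if (node$type == "leaf") {
      labels[as.character(id)] <<- node$label
      return(invisible())
    }
    for (chd in node$children) {
      nn <<- nn + 1L
      edges <<- rbind(edges, c(id, nn))
      rec(chd, nn)
    }
  }
  rec(tree, 1L)
  validate_gene_tree(edges, labels)
}

#' @export
print.dl_simulation <- function(x, ...) {
  cat("Simulated gene family:", length(x$gene_tree$leaves), "genes;",
      x$d_true, "duplications,", x$l_true,
      "losses visible in the surviving history\n")
  invisible(x)
}
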