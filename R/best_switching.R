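#' Best switching of a species network for a gene tree
#'
#' Finds a switching of the network whose displayed tree minimises the
#' duplication-loss reconciliation cost with the gene tree, over all
#' switchings.  The search is carried out independently per biconnected
#' component: the total cost of any switching decomposes into per-component
#' contributions of the augmented gene tree's subgraphs, so each elementary
#' network only needs its at most \code{2^k} switchings evaluated (\code{k}
#' being the component's hybridization count), never the \code{2^h} global
#' combinations.
#'
#' @param gt a \code{dl_genetree}.
#' @param net a \code{dl_network} containing all species of \code{gt}.
#' @param dup_cost,loss_cost positive event costs.
#' @return an object of class \code{dl_best_switching}: the optimal
#'   \code{switching}, its \code{reconciliation} (LCA reconciliation of the
#'   original gene tree on the displayed tree), the total \code{cost},
#'   per-component cost tables, and the number of component switchings
#'   evaluated (\code{n_evaluated}).
#' @export
best_switching <- function(gt, net, dup_cost = 1, loss_cost = 1) {
  check_costs(dup_cost, loss_cost)
  prep <- prepare_components(gt, net)
  sol <- optimise_components(prep, dup_cost, loss_cost)
  finish_best_switching(prep, sol, dup_cost, loss_cost, all_optima = FALSE)
}

#' All optimal switchings
#'
#' Every combination of co-optimal component switchings; each assembled
#' global switching attains the same minimal cost.
#'
#' @inheritParams best_switching
#' @param max_results cap on the number of assembled switchings.
#' @return list with \code{cost} and \code{switchings} (list of
#'   \code{dl_switching}).
#' @export
all_optimal_switchings <- function(gt, net, dup_cost = 1, loss_cost = 1,
                                   max_results = 10000L) {
  check_costs(dup_cost, loss_cost)
  prep <- prepare_components(gt, net)
  sol <- optimise_components(prep, dup_cost, loss_cost)
  combos <- list(list())
  for (ci in seq_along(sol$per_comp)) {
    opts <- sol$per_comp[[ci]]$co_optimal
    combos <- unlist(lapply(combos, function(cmb)
      lapply(opts, function(o) c(cmb, list(o)))), recursive = FALSE)
    if (length(combos) > max_results)
      stop("more than max_results optimal switchings")
  }
  fits <- lapply(combos, function(cmb) assemble_switching(prep$dec, cmb))
  res <- finish_best_switching(prep, sol, dup_cost, loss_cost,
                               all_optima = FALSE)
  list(cost = res$cost, switchings = fits)
}

prepare_components <- function(gt, net) {
  norm <- normalize_gene_tree(gt)
  dec <- decompose_network(net)
  degenerate <- norm$tree$n == 1L
  if (!degenerate) {
    aug <- augment_gene_tree(norm$tree, net, dec)
    forests <- component_forest(aug)
    root_comp_g <- aug$comp[aug$root]
  } else {
    aug <- NULL
    forests <- rep(list(list()), dec$p)
    root_comp_g <- dec$comp_of[net$leaf_of[[norm$tree$label[1L]]]]
  }
  list(gt = gt, net = net, norm = norm, dec = dec, aug = aug,
       forests = forests, root_comp_g = root_comp_g, degenerate = degenerate)
}

optimise_components <- function(prep, dup_cost, loss_cost) {
  dec <- prep$dec
  n_evaluated <- 0L
  per_comp <- list()
  for (ci in seq_len(dec$p)) {
    if (prep$is_leaf_skip <- dec$is_leaf[ci]) next
    sws <- enumerate_switchings(dec, ci)
    forest <- prep$forests[[ci]]
    if (!length(forest)) {
      ## no gene structure here: any switching works, keep the
      ## lexicographically least on-edge set, contribute 0
      pick <- sws[[order(vapply(sws, function(s) s$on_key, ""))[1L]]]
      per_comp[[as.character(ci)]] <- list(
        comp = ci, best = pick, cost = 0, co_optimal = list(pick),
        costs = numeric(0))
      next
    }
    costs <- vapply(sws, function(sw) {
      sum(vapply(forest, function(H)
        component_cost(prep$aug, H, sw, dup_cost, loss_cost,
                       is_root_comp = ci == prep$root_comp_g), 0))
    }, 0)
    n_evaluated <- n_evaluated + length(sws)
    best_cost <- min(costs)
    co <- which(costs <= best_cost + 1e-9)
    keys <- vapply(sws[co], function(s) s$on_key, "")
    pick <- sws[[co[order(keys)[1L]]]]
    per_comp[[as.character(ci)]] <- list(
      comp = ci, best = pick, cost = best_cost,
      co_optimal = sws[co[order(keys)]], costs = costs)
  }
  list(per_comp = per_comp, n_evaluated = n_evaluated,
       total = sum(vapply(per_comp, function(x) x$cost, 0)))
}

finish_best_switching <- function(prep, sol, dup_cost, loss_cost,
                                  all_optima) {
  sw <- assemble_switching(prep$dec,
                           lapply(sol$per_comp, function(x) x$best))
  rec_norm <- lca_reconcile(prep$norm$tree, sw, dup_cost, loss_cost)
  if (abs(rec_norm$cost - sol$total) > 1e-6)
    stop("internal consistency error: per-component cost sum ", sol$total,
         " differs from the displayed-tree reconciliation cost ",
         rec_norm$cost)
  rec <- expand_reconciliation(prep$gt, prep$norm, rec_norm,
                               dup_cost, loss_cost)
  structure(list(
    switching = sw, reconciliation = rec, cost = rec$cost,
    d = rec$d, l = rec$l,
    n_evaluated = sol$n_evaluated,
    component_costs = lapply(sol$per_comp, function(x)
      list(comp = x$comp, cost = x$cost, costs = x$costs)),
    dup_cost = dup_cost, loss_cost = loss_cost
  ), class = "dl_best_switching")
}

## Lift a reconciliation of the collapsed gene tree back to the original
## tree: nodes inside collapsed single-species subtrees become duplications
## (internal) or contemporary events (leaves) at the species leaf, with no
## losses.
expand_reconciliation <- function(gt, norm, rec, dup_cost, loss_cost) {
  if (!length(norm$collapsed) && norm$tree$n == gt$n) return(rec)
  tab <- rec$table
  img_new <- stats::setNames(tab$image, tab$node)
  ev_new <- stats::setNames(tab$event, tab$node)
  loss_new <- stats::setNames(tab$losses, tab$node)

  node <- integer(0); image <- integer(0); event <- character(0)
  losses <- numeric(0)
  inside <- rep(FALSE, gt$n)
  for (cl in norm$collapsed) {
    leaf_img <- img_new[[as.character(cl$new_leaf)]]
    for (v in cl$orig_internal) {
      node <- c(node, v); image <- c(image, leaf_img)
      event <- c(event, "D"); losses <- c(losses, 0)
    }
    for (v in cl$orig_leaves) {
      node <- c(node, v); image <- c(image, leaf_img)
      event <- c(event, "C"); losses <- c(losses, 0)
    }
    inside[c(cl$orig_internal, cl$orig_leaves)] <- TRUE
  }
  for (v in which(!inside)) {
    k <- as.character(norm$new_id[v])
    node <- c(node, v); image <- c(image, img_new[[k]])
    ## a collapsed subtree root appears in both lists; keep the expanded row
    event <- c(event, ev_new[[k]]); losses <- c(losses, loss_new[[k]])
  }
  keep <- !duplicated(node)
  o <- order(node[keep])
  tab2 <- data.frame(node = node[keep][o], image = image[keep][o],
                     event = event[keep][o], losses = losses[keep][o])
  d <- sum(tab2$event == "D")
  l <- sum(tab2$losses)
  structure(list(table = tab2, d = d, l = l,
                 cost = d * dup_cost + l * loss_cost,
                 dup_cost = dup_cost, loss_cost = loss_cost),
            class = "dl_reconciliation")
}

#' @export
print.dl_best_switching <- function(x, ...) {
  cat("Best switching: cost", x$cost, "(", x$d, "duplications,",
      x$l, "losses )\n")
  cat("  displayed tree:", write_switching(x$switching), "\n")
  cat("  component switchings evaluated:", x$n_evaluated, "\n")
  invisible(x)
}
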