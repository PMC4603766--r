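## Adapter giving a tree view of a reconciliation target: parent pointers,
## depths, the loss-counting mask and the label->leaf map.  Targets are a
## tree-shaped dl_network, a dl_switching (on-edges only) or a
## dl_comp_switching.
target_adapter <- function(target) {
  if (inherits(target, "dl_network")) {
    if (target$h > 0L)
      stop("LCA reconciliation needs a tree or a switching, not a network ",
           "with hybridization nodes")
    par <- rep(NA_integer_, target$n)
    for (v in seq_len(target$n))
      if (length(target$parents[[v]])) par[v] <- target$parents[[v]][1L]
    depth <- rep(NA_integer_, target$n)
    depth[target$root] <- 0L
    for (v in target$topo[-1L]) depth[v] <- depth[par[v]] + 1L
    list(par = par, depth = depth,
         count = target$kind != "leaf",
         leaf_of = target$leaf_of, root = target$root,
         children_on = function(v) target$children[[v]])
  } else if (inherits(target, "dl_switching")) {
    net <- target$net
    on <- target$on
    list(par = target$onpar, depth = target$depth, count = target$count,
         leaf_of = net$leaf_of, root = target$root_on,
         children_on = function(v)
           net$children[[v]][on[net$child_edges[[v]]]])
  } else if (inherits(target, "dl_comp_switching")) {
    net <- target$dec$net
    list(par = target$onpar, depth = target$depth, count = target$count,
         leaf_of = net$leaf_of, root = target$root,
         children_on = function(v) {
           es <- setdiff(intersect(net$child_edges[[v]], target$edge_set),
                         target$off)
           net$edge[es, 2L]
         })
  } else stop("unsupported reconciliation target")
}

## Core LCA reconciliation: maps each leaf through `leafimage`, each internal
## node to the LCA of its children's images; duplication when the images are
## comparable, speciation otherwise; losses by unique-path distances over the
## counting mask.
lca_core <- function(postorder, children_of, is_leaf, leafimage, ad,
                     dup_cost, loss_cost) {
  nodes <- postorder
  image <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  event <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  losses <- stats::setNames(rep(0, length(nodes)), nodes)
  key <- as.character
  for (u in nodes) {
    if (is_leaf(u)) {
      image[key(u)] <- leafimage(u)
      event[key(u)] <- "C"
      next
    }
    ch <- children_of(u)
    i1 <- image[key(ch[1L])]; i2 <- image[key(ch[2L])]
    x <- tr_lca(ad$par, ad$depth, i1, i2)
    image[key(u)] <- x
    if (x == i1 || x == i2) {
      event[key(u)] <- "D"
      losses[key(u)] <- tr_dist(ad$par, ad$count, x, i1) +
        tr_dist(ad$par, ad$count, x, i2)
    } else {
      event[key(u)] <- "S"
      c1 <- tr_step_child(ad$par, i1, x)
      c2 <- tr_step_child(ad$par, i2, x)
      losses[key(u)] <- tr_dist(ad$par, ad$count, c1, i1) +
        tr_dist(ad$par, ad$count, c2, i2)
    }
  }
  d <- sum(event == "D")
  l <- sum(losses)
  list(node = nodes, image = unname(image), event = unname(event),
       losses = unname(losses), d = d, l = l,
       cost = d * dup_cost + l * loss_cost)
}

#' LCA reconciliation of a gene tree with a tree or switching
#'
#' The unique minimum-cost duplication-loss reconciliation onto a tree:
#' leaves map to the leaf carrying their species, every internal node to the
#' LCA of its children's images, with a duplication exactly when those images
#' are comparable.  Losses are counted along the unique paths between images;
#' on a switching only nodes untouched by switched-off edges count, so
#' lineages routed around the unused parent of a hybridization incur no
#' penalty there.
#'
#' @param gt a \code{dl_genetree}.
#' @param target a tree-shaped \code{dl_network} or a \code{dl_switching}.
#' @param dup_cost,loss_cost positive event costs.
#' @return an object of class \code{dl_reconciliation}: a per-node table
#'   (\code{table}) plus totals \code{d}, \code{l}, \code{cost}.
#' @export
lca_reconcile <- function(gt, target, dup_cost = 1, loss_cost = 1) {
  check_costs(dup_cost, loss_cost)
  ad <- target_adapter(target)
  missing <- setdiff(gt$label[gt$leaves], names(ad$leaf_of))
  if (length(missing))
    stop("species absent from target: ", paste(missing, collapse = ", "))
  res <- lca_core(gt$postorder,
                  children_of = function(u) gt$children[[u]],
                  is_leaf = function(u) length(gt$children[[u]]) == 0L,
                  leafimage = function(u) ad$leaf_of[[gt$label[u]]],
                  ad, dup_cost, loss_cost)
  as_reconciliation(res, dup_cost, loss_cost)
}

as_reconciliation <- function(res, dup_cost, loss_cost) {
  structure(list(
    table = data.frame(node = res$node, image = res$image,
                       event = res$event, losses = res$losses),
    d = res$d, l = res$l, cost = res$cost,
    dup_cost = dup_cost, loss_cost = loss_cost
  ), class = "dl_reconciliation")
}

#' @export
print.dl_reconciliation <- function(x, ...) {
  cat("DL reconciliation: cost", x$cost,
      "(", x$d, "duplications,", x$l, "losses; dup_cost =", x$dup_cost,
      ", loss_cost =", x$loss_cost, ")\n")
  invisible(x)
}

check_costs <- function(dup_cost, loss_cost) {
  if (!is.numeric(dup_cost) || dup_cost <= 0 ||
      !is.numeric(loss_cost) || loss_cost <= 0)
    stop("event costs must be positive")
}

#' Reconciliation of a component subtree with a component switching
#'
#' The LCA reconciliation of one subgraph \code{H} of the augmented gene
#' tree onto a switching of its component's elementary network, with each
#' leaf of \code{H} pre-mapped to the root of the child component it is
#' labelled by.
#'
#' @param aug a \code{dl_augmented}.
#' @param H a subgraph from \code{\link{component_forest}} (a tree, not an
#'   edge).
#' @param csw a \code{dl_comp_switching} of the same component.
#' @param dup_cost,loss_cost positive event costs.
#' @return a \code{dl_reconciliation} over the nodes of \code{H}.
#' @export
beta_reconcile <- function(aug, H, csw, dup_cost = 1, loss_cost = 1) {
  if (H$is_edge) stop("H is an edge; it has no internal structure")
  ad <- target_adapter(csw)
  nodes <- c(H$internal, H$leaves)
  post <- aug$postorder[aug$postorder %in% nodes]
  res <- lca_core(post,
                  children_of = function(u) aug$children[[u]],
                  is_leaf = function(u) u %in% H$leaves,
                  leafimage = function(u) aug$dec$root[aug$comp[u]],
                  ad, dup_cost, loss_cost)
  as_reconciliation(res, dup_cost, loss_cost)
}

#' Cost contribution of one component subtree under a component switching
#'
#' For a tree subgraph: the cost of its reconciliation with the component
#' switching, plus (except in the gene root's component) the loss cost of the
#' path from the component root down to the image of the subgraph's root.
#' For an edge subgraph: the loss cost of the path from the component root
#' down to the child-component root its leaf is labelled by.  Distances count
#' only nodes of the elementary network that are untouched by off edges and
#' are not its leaves.
#'
#' @inheritParams beta_reconcile
#' @param is_root_comp whether the component hosts the gene-tree root.
#' @export
component_cost <- function(aug, H, csw, dup_cost = 1, loss_cost = 1,
                           is_root_comp = FALSE) {
  if (H$is_edge) {
    u <- H$leaves[1L]
    tgt <- aug$dec$root[aug$comp[u]]
    return(loss_cost * tr_dist(csw$onpar, csw$count, csw$root, tgt))
  }
  beta <- beta_reconcile(aug, H, csw, dup_cost, loss_cost)
  extra <- if (is_root_comp) 0 else {
    rimg <- beta$table$image[beta$table$node == H$root]
    loss_cost * tr_dist(csw$onpar, csw$count, csw$root, rimg)
  }
  beta$cost + extra
}
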