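# Shared fixtures: tiny hand-checked networks and a random gene-tree builder.

# smallest hybridization gadget: r -> a,b; a -> X,h; b -> h,Y; h -> Z
diamond <- function() read_species_network("((X,(Z)#H1),(#H1,Y));")

# node ids of the diamond as parsed (tips first): X=1, Z=2, Y=3, r=4, a=5,
# h=6, b=7
diamond_ids <- list(X = 1L, Z = 2L, Y = 3L, r = 4L, a = 5L, h = 6L, b = 7L)

# caterpillar species tree ((X,Y),C)
cat3 <- function() read_species_network("((X,Y),C);")

# network where switching off one hybrid edge starves a speciation node:
# r -> a,b; a -> h1,h2; b -> h1,h2; keeping both hybrids on the a side
# leaves b with no live outgoing edge, so (r,b) is propagated off
starving_net <- function() read_species_network("(((X)#H1,(Y)#H2),(#H1,#H2));")

# stacked-meet pattern: m3's separated paths to x,y both funnel through a
# single hybridization into m2, so m3 is pruned from the minimal meeting
# set while m2 and the independent meet m1 survive
stacked_meets <- function() {
  # r -> m1,m3; m1 -> hx,hy; m3 -> u,v; u -> h,lu; v -> h,lv; h -> m2;
  # m2 -> hx,hy; hx -> x; hy -> y
  edges <- rbind(
    c(1L, 2L), c(1L, 3L),        # r -> m1, m3
    c(2L, 8L), c(2L, 9L),        # m1 -> hx, hy
    c(3L, 4L), c(3L, 5L),        # m3 -> u, v
    c(4L, 6L), c(4L, 10L),       # u -> h, lu
    c(5L, 6L), c(5L, 11L),       # v -> h, lv
    c(6L, 7L),                   # h -> m2
    c(7L, 8L), c(7L, 9L),        # m2 -> hx, hy
    c(8L, 12L), c(9L, 13L))      # hx -> x, hy -> y
  validate_network(edges, c("10" = "lu", "11" = "lv", "12" = "x", "13" = "y"))
}

# three serial level-2 components, 6 hybridization nodes in total
level2_chain <- function() {
  blk <- function(inner, t1, t2, l2, l3, l4)
    sprintf("(((%s)#H%d,((%s)#H%d,%s)),(#H%d,(#H%d,%s)))",
            inner, t1, l2, t2, l3, t1, t2, l4)
  read_species_network(paste0(
    blk(blk(blk("c1", 5, 6, "c2", "c3", "c4"), 3, 4, "b2", "b3", "b4"),
        1, 2, "a2", "a3", "a4"), ";"))
}

# random binary gene tree with leaf labels sampled (with replacement) from
# the given species
random_gene_tree <- function(labels, n_leaves, seed) {
  withr::with_seed(seed, {
    edges <- matrix(c(1L, 2L, 1L, 3L), 2, 2, byrow = TRUE)
    nn <- 3L
    lv <- c(2L, 3L)
    while (length(lv) < n_leaves) {
      e <- sample.int(nrow(edges), 1L)
      mid <- nn + 1L; lf <- nn + 2L; nn <- nn + 2L
      tgt <- edges[e, 2L]
      edges[e, 2L] <- mid
      edges <- rbind(edges, c(mid, tgt), c(mid, lf))
      lv <- c(lv, lf)
    }
    validate_gene_tree(edges, stats::setNames(
      sample(labels, length(lv), replace = TRUE), lv))
  })
}

# a uniformly random switching of a network
random_switching <- function(net, seed) {
  off <- withr::with_seed(seed, unlist(lapply(
    which(net$kind == "hybridization"), function(hv) {
      pe <- net$parent_edges[[hv]]
      pe[-sample.int(2L, 1L)]
    })))
  switching(net, off = if (length(off)) off else integer(0))
}
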