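test_that("with no hybridization the network programme collapses to LCA", {
  for (seed in 1:25) {
    net <- random_network(3 + seed %% 6, 0L, seed = 3200 + seed)
    gt <- random_gene_tree(net$label[net$leaves], 3 + seed %% 5,
                           seed = 3300 + seed)
    dp <- reconcile_network(gt, net)
    expect_equal(dp$cost, lca_reconcile(gt, net)$cost)
    expect_equal(dp$cost, best_switching(gt, net)$cost)
  }
})

test_that("diamond instances match the exhaustive search", {
  dia <- diamond()
  dp1 <- reconcile_network(read_gene_tree("((X,Z),Y);"), dia)
  # one loss is unavoidable against the whole network: the Y-lineage passes
  # the speciation node above Y, which counts on the network even though a
  # switching would exclude it
  expect_identical(dp1$cost, 1)
  expect_identical(dp1$reconciliation$table$event[
    is.na(read_gene_tree("((X,Z),Y);")$label)], c("S", "S"))
  expect_identical(
    sort(dp1$reconciliation$table$image[
      dp1$reconciliation$table$event == "S"]),
    c(diamond_ids$r, diamond_ids$a))

  dp2 <- reconcile_network(read_gene_tree("((X,Y),Z);"), dia)
  expect_identical(dp2$cost, 5)
  for (g in list("((X,Z),Y);", "((X,Y),Z);", "((Z,Z),(X,Y));")) {
    gt <- read_gene_tree(g)
    expect_equal(reconcile_network(gt, dia)$cost,
                 oracle_reconcile_network(gt, dia))
    expect_equal(oracle_reconcile_network(gt, dia),
                 flat_min_reconciliation(gt, dia))
  }
})

test_that("a same-species cherry can speciate through a hybridization", {
  # collapsing the cherry would force a duplication and overprice this
  net <- read_species_network("(s1,((s2,(s3)#H1),(#H1,s4)));")
  gt <- read_gene_tree("((s3,s3),(s4,s2));")
  dp <- reconcile_network(gt, net)
  expect_identical(dp$cost, 5)
  expect_equal(dp$cost, oracle_reconcile_network(gt, net))
  cherry <- which(vapply(seq_len(gt$n), function(u)
    length(gt$children[[u]]) == 2L &&
      all(gt$label[gt$children[[u]]] == "s3"), TRUE))
  row <- dp$reconciliation$table[dp$reconciliation$table$node == cherry, ]
  expect_identical(row$event, "S")
})

test_that("the dynamic programme equals the exhaustive oracle on random instances", {
  maxc_excess <- -10L
  for (seed in 1:80) {
    net <- random_network(3 + seed %% 5, seed %% 5, seed = 3400 + seed)
    gt <- random_gene_tree(net$label[net$leaves], 3 + seed %% 5,
                           seed = 3500 + seed)
    dp <- reconcile_network(gt, net)
    expect_equal(dp$cost, oracle_reconcile_network(gt, net))
    expect_lte(dp$max_candidates, net$h + 2L)
    maxc_excess <- max(maxc_excess, dp$max_candidates - net$h)
    v <- validate_reconciliation(gt, net, dp$reconciliation$table)
    expect_true(v$valid)
    expect_equal(v$cost, dp$cost)
  }
  expect_lte(maxc_excess, 2L)
})

test_that("the two oracles agree with the literal flat enumeration", {
  for (seed in 1:10) {
    net <- random_network(3 + seed %% 3, seed %% 3, seed = 3600 + seed)
    gt <- random_gene_tree(net$label[net$leaves], 3 + seed %% 2,
                           seed = 3700 + seed)
    if (sum(is.na(gt$label)) > 4L || net$n > 16L) next
    expect_equal(oracle_reconcile_network(gt, net),
                 flat_min_reconciliation(gt, net))
  }
})

test_that("stored candidates stay inside the leaf meeting sets", {
  for (seed in 1:12) {
    net <- random_network(4 + seed %% 4, seed %% 5, seed = 3800 + seed)
    gt <- random_gene_tree(net$label[net$leaves], 3 + seed %% 4,
                           seed = 3900 + seed)
    dp <- reconcile_network(gt, net)
    span <- function(u) {
      if (!is.na(gt$label[u])) return(gt$label[u])
      unique(unlist(lapply(gt$children[[u]], span)))
    }
    for (u in which(is.na(gt$label))) {
      sp <- span(u)
      if (length(sp) < 2L) next            # bound assumed multi-species
      Lids <- unname(net$leaf_of[sp])
      allowed <- meeting_set_leaves(net, Lids)
      expect_true(all(dp$tables[[u]]$x %in% allowed))
    }
  }
})
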