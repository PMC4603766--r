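test_that("decomposition isolates blobs and partitions the edges", {
  tree <- cat3()
  dec_t <- decompose_network(tree)
  # a tree has only trivial components: one per node
  expect_identical(dec_t$p, tree$n)
  expect_true(all(vapply(dec_t$block_edges, length, 1L) == 0L))

  dia <- diamond()
  dec <- decompose_network(dia)
  nt <- which(vapply(dec$block_edges, length, 1L) > 0L)
  expect_length(nt, 1L)
  expect_setequal(dec$nodes[[nt]],
                  c(diamond_ids$r, diamond_ids$a, diamond_ids$b,
                    diamond_ids$h))
  expect_identical(dec$root[nt], diamond_ids$r)
  expect_identical(dec$level, 1L)

  chain <- level2_chain()
  dec2 <- decompose_network(chain)
  expect_identical(sum(vapply(dec2$block_edges, length, 1L) > 0L), 3L)
  expect_identical(dec2$level, 2L)
  expect_identical(chain$h, 6L)

  # edge partition: block edges plus bridges cover every edge once
  for (seed in 1:10) {
    net <- random_network(4 + seed %% 4, seed %% 6, seed = 1500 + seed)
    d <- decompose_network(net)
    eids <- c(unlist(d$block_edges),
              unlist(d$cut_out))
    expect_setequal(eids, seq_len(net$m))
    expect_identical(anyDuplicated(eids), 0L)
  }
})

test_that("component labels obey the ancestry rules along augmented edges", {
  for (seed in 1:12) {
    net <- random_network(4 + seed %% 5, seed %% 5, seed = 1600 + seed)
    gt0 <- random_gene_tree(net$label[net$leaves], 3 + seed %% 6,
                            seed = 1700 + seed)
    norm <- normalize_gene_tree(gt0)
    if (norm$tree$n == 1L) next
    dec <- decompose_network(net)
    aug <- augment_gene_tree(norm$tree, net, dec)
    for (u in seq_len(aug$n)) {
      for (v in aug$children[[u]]) {
        if (aug$artificial[u]) {
          expect_identical(dec$parent[aug$comp[v]], aug$comp[u])
          expect_identical(dec$parent[aug$comp[u]], aug$comp[aug$par[u]])
        } else {
          same <- aug$comp[v] == aug$comp[u]
          expect_true(same || dec$parent[aug$comp[v]] == aug$comp[u])
        }
      }
    }
    # size bound: at most p artificial nodes per gene-tree edge
    expect_lte(aug$n, norm$tree$n * (1L + dec$p))
  }
})

test_that("component forests are trees or artificial-rooted edges", {
  dia <- diamond()
  gt <- normalize_gene_tree(read_gene_tree("((X,Z),Y);"))$tree
  dec <- decompose_network(dia)
  aug <- augment_gene_tree(gt, dia, dec)
  forests <- component_forest(aug)
  nt <- which(vapply(dec$block_edges, length, 1L) > 0L)
  expect_identical(length(forests[[nt]]), 1L)
  expect_false(forests[[nt]][[1L]]$is_edge)

  for (seed in 1:12) {
    net <- random_network(4 + seed %% 5, seed %% 5, seed = 1800 + seed)
    gt0 <- random_gene_tree(net$label[net$leaves], 3 + seed %% 6,
                            seed = 1900 + seed)
    norm <- normalize_gene_tree(gt0)
    if (norm$tree$n == 1L) next
    dec <- decompose_network(net)
    aug <- augment_gene_tree(norm$tree, net, dec)
    forests <- component_forest(aug)
    # the gene root's component carries exactly one subgraph, a tree
    rootf <- forests[[aug$comp[aug$root]]]
    expect_identical(length(rootf), 1L)
    expect_false(rootf[[1L]]$is_edge)
    seen <- integer(0)
    for (ci in seq_along(forests)) {
      expect_false(dec$is_leaf[ci] && length(forests[[ci]]) > 0L)
      for (H in forests[[ci]]) {
        if (H$is_edge) expect_true(aug$artificial[H$internal])
        # every leaf of H is labelled by a child component
        for (lf in H$leaves)
          expect_identical(dec$parent[aug$comp[lf]], ci)
        seen <- c(seen, H$internal)
      }
    }
    # the internal nodes of all subgraphs partition those of the
    # augmented tree
    expect_setequal(seen,
                    which(vapply(seq_len(aug$n), function(v)
                      length(aug$children[[v]]) > 0L, TRUE)))
    expect_identical(anyDuplicated(seen), 0L)
  }
})

test_that("switch enumeration respects propagation and deduplication", {
  dia <- diamond()
  dec <- decompose_network(dia)
  nt <- which(vapply(dec$block_edges, length, 1L) > 0L)
  expect_length(enumerate_switchings(dec, nt), 2L)

  # a component with no hybridization has a single all-on switching
  tree <- cat3()
  dect <- decompose_network(tree)
  inner <- which(!dect$is_leaf)
  for (ci in inner) expect_length(enumerate_switchings(dect, ci), 1L)

  # starving pattern: sending both hybrids to one parent switches off the
  # other parent's incoming edge as well
  st <- starving_net()
  b <- which(vapply(seq_len(st$n), function(v)
    st$kind[v] == "speciation" &&
      all(st$kind[st$children[[v]]] == "hybridization"), TRUE))
  dec_s <- decompose_network(st)
  nts <- which(vapply(dec_s$block_edges, length, 1L) > 0L)
  sws <- enumerate_switchings(dec_s, nts)
  starve <- Filter(function(s) !s$von[b[1L]] && is.na(s$onpar[b[1L]]), sws)
  expect_gte(length(starve), 1L)
  for (s in starve)
    expect_true(all(st$child_edges[[b[1L]]] %in% s$off) &&
                  all(st$parent_edges[[b[1L]]] %in% s$off))
})

test_that("assembled switchings restrict to their component choices", {
  chain <- level2_chain()
  dec <- decompose_network(chain)
  nts <- which(vapply(dec$block_edges, length, 1L) > 0L)
  choices <- lapply(nts, function(ci) enumerate_switchings(dec, ci)[[2L]])
  sw <- assemble_switching(dec, choices)
  expect_s3_class(sw, "dl_switching")
  for (ch in choices)
    expect_identical(sort(intersect(sw$off, ch$edge_set)), ch$off)
  # displayed tree has every species exactly once
  shown <- ape::read.tree(text = write_switching(sw))
  expect_setequal(shown$tip.label, chain$label[chain$leaves])
})
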