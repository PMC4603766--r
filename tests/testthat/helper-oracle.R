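# Literal flat enumeration of every image assignment of the internal gene
# nodes with per-node event validation.  Exponential; only usable on tiny
# instances, where it cross-checks oracle_reconcile_network itself.
flat_min_reconciliation <- function(gt, net, dup_cost = 1, loss_cost = 1) {
  ints <- which(is.na(gt$label))
  stopifnot(length(ints) <= 4L, net$n <= 16L)
  img0 <- vapply(seq_len(gt$n), function(u)
    if (!is.na(gt$label[u])) net$leaf_of[[gt$label[u]]] else NA_integer_, 1L)
  d <- net$distmat
  grid <- expand.grid(rep(list(seq_len(net$n)), length(ints)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    img <- img0
    img[ints] <- as.integer(grid[r, ])
    cost <- 0
    ok <- TRUE
    for (u in ints) {
      ch <- gt$children[[u]]
      x <- img[u]; i1 <- img[ch[1L]]; i2 <- img[ch[2L]]
      xc <- net$children[[x]]
      s_ok <- length(xc) == 2L &&
        ((net$reach[xc[1L], i1] && net$reach[xc[2L], i2]) ||
         (net$reach[xc[2L], i1] && net$reach[xc[1L], i2]))
      s_cost <- if (s_ok)
        loss_cost * min(d[xc[1L], i1] + d[xc[2L], i2],
                        d[xc[1L], i2] + d[xc[2L], i1]) else Inf
      d_ok <- net$reach[x, i1] && net$reach[x, i2]
      d_cost <- if (d_ok)
        dup_cost + loss_cost * (d[x, i1] + d[x, i2]) else Inf
      ec <- min(s_cost, d_cost)
      if (!is.finite(ec)) { ok <- FALSE; break }
      cost <- cost + ec
    }
    if (ok) best <- min(best, cost)
  }
  best
}
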