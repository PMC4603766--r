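#' Read a gene tree from Newick
#'
#' Leaf names are species labels and may repeat (several gene copies in one
#' species).  Polytomies and unrooted (trifurcating) inputs are rejected.
#'
#' @param text Newick string, or \code{NULL} to read from \code{file}.
#' @param file path to a Newick file.
#' @return a \code{dl_genetree}.
#' @export
read_gene_tree <- function(text = NULL, file = NULL) {
  phy <- parse_newick(text, file, "gene tree")
  if (!is.null(phy$node.label) && any(grepl("^#", phy$node.label)))
    stop("gene tree may not contain hybrid (#H) tags")
  edges <- phy$edge
  outdeg <- tabulate(edges[, 1L], nbins = max(edges))
  bad <- which(outdeg != 0L & outdeg != 2L)
  if (length(bad))
    stop("gene tree is not binary (polytomy or unrooted input at node ",
         bad[1L], ")")
  validate_gene_tree(edges,
                     stats::setNames(phy$tip.label, seq_along(phy$tip.label)))
}

#' Read a species network from extended Newick
#'
#' Parses eNewick with \code{#H} hybrid tags (each tag appears exactly twice,
#' once carrying the hybrid subtree and once as the second parent attachment)
#' and validates the result as a rooted binary network.
#'
#' @inheritParams read_gene_tree
#' @return a \code{dl_network}.
#' @export
read_species_network <- function(text = NULL, file = NULL) {
  src <- if (!is.null(text)) text else paste(readLines(file), collapse = "")
  tags <- regmatches(src, gregexpr("#H?[0-9]+", src))[[1L]]
  cnt <- table(tags)
  if (any(cnt != 2L))
    stop("unmatched hybrid tag: ", names(cnt)[cnt != 2L][1L],
         " occurs ", cnt[cnt != 2L][1L], " time(s), expected 2")
  ev <- if (grepl("#", src, fixed = TRUE)) {
    tryCatch(ape::read.evonet(text = src),
             error = function(e) stop("eNewick parse error: ",
                                      conditionMessage(e), call. = FALSE))
  } else {
    phy <- parse_newick(src, NULL, "species network")
    phy$reticulation <- matrix(integer(0), 0, 2)
    phy
  }
  if (any(grepl("^#", ev$tip.label)))
    stop("unmatched hybrid tag: ",
         ev$tip.label[grepl("^#", ev$tip.label)][1L])
  edges <- rbind(ev$edge, ev$reticulation)
  ## nodes whose children are all bare #H references come back as tips with
  ## an empty label; they are internal nodes, not leaves
  lab <- stats::setNames(ev$tip.label, seq_along(ev$tip.label))
  lab <- lab[nzchar(lab)]
  validate_network(edges, lab)
}

parse_newick <- function(text, file, what) {
  src <- if (!is.null(text)) text else paste(readLines(file), collapse = "")
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = src)),
                  error = function(e) stop(what, " parse error: ",
                                           conditionMessage(e),
                                           call. = FALSE))
  if (is.null(phy)) stop(what, " parse error: empty or malformed Newick")
  phy
}

#' Write a gene tree or displayed tree as Newick
#'
#' @param gt a \code{dl_genetree}.
#' @return a Newick string (with trailing semicolon).
#' @export
write_gene_tree <- function(gt) {
  rec <- function(v) {
    ch <- gt$children[[v]]
    if (!length(ch)) return(gt$label[v])
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")")
  }
  paste0(rec(gt$root), ";")
}

#' Write a species network as extended Newick
#'
#' Hybrid nodes are tagged \code{#H1, #H2, ...} in depth-first discovery
#' order; the first parent encountered carries the hybrid subtree, the second
#' refers to it by tag.
#'
#' @param net a \code{dl_network}.
#' @return an eNewick string.
#' @export
write_species_network <- function(net) {
  tag <- rep(NA_integer_, net$n)
  ntag <- 0L
  seen <- rep(FALSE, net$n)
  rec <- function(v) {
    if (net$kind[v] == "hybridization") {
      if (is.na(tag[v])) {
        ntag <<- ntag + 1L
        tag[v] <<- ntag
      }
      if (seen[v]) return(paste0("#H", tag[v]))
      seen[v] <<- TRUE
      return(paste0("(", rec(net$children[[v]][1L]), ")#H", tag[v]))
    }
    if (net$kind[v] == "leaf") return(net$label[v])
    paste0("(", paste(vapply(net$children[[v]], rec, ""), collapse = ","), ")")
  }
  paste0(rec(net$root), ";")
}

#' Displayed tree of a switching
#'
#' Removes the switched-off edges of a switching and suppresses the resulting
#' indegree-1/outdegree-1 nodes, returning the displayed tree as a Newick
#' string.
#'
#' @param sw a \code{dl_switching}.
#' @return a Newick string.
#' @export
write_switching <- function(sw) {
  net <- sw$net
  on_children <- function(v)
    net$children[[v]][sw$on[net$child_edges[[v]]]]
  rec <- function(v) {
    ch <- on_children(v)
    while (length(ch) == 1L) {      # suppress pass-through nodes
      v <- ch
      ch <- on_children(v)
    }
    if (!length(ch)) return(net$label[v])
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")")
  }
  paste0(rec(sw$root_on), ";")
}

#' Serialize a reconciliation report
#'
#' A report is a list with a problem tag, cost parameters, event totals and a
#' per-gene-node table; for the best-switching problem it additionally
#' carries the chosen switching (edge status table) and its displayed tree.
#' Reports round-trip through \code{\link{read_report}}.
#'
#' @param report a report list as produced by the solvers.
#' @param file output path.
#' @param format \code{"json"} or \code{"tsv"}.
#' @export
write_report <- function(report, file, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
  } else {
    hdr <- report[setdiff(names(report), c("table", "edges"))]
    con <- file(file, "w")
    on.exit(close(con))
    for (k in names(hdr))
      writeLines(sprintf("# %s\t%s", k, as.character(hdr[[k]])), con)
    utils::write.table(report$table, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_report
#' @export
read_report <- function(file, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    rep <- jsonlite::read_json(file, simplifyVector = TRUE)
    if (!is.null(rep$table)) rep$table <- as.data.frame(rep$table)
    return(rep)
  }
  lines <- readLines(file)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  hdr <- list()
  for (l in hdr_lines) {
    kv <- strsplit(sub("^# ", "", l), "\t")[[1L]]
    val <- suppressWarnings(as.numeric(kv[2L]))
    hdr[[kv[1L]]] <- if (is.na(val)) kv[2L] else val
  }
  tab <- utils::read.table(text = lines[!grepl("^# ", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  c(hdr, list(table = tab))
}

build_report <- function(problem, dup_cost, loss_cost, rec, extra = list()) {
  c(list(problem = problem, dup_cost = dup_cost, loss_cost = loss_cost,
         cost = rec$cost, duplications = rec$d, losses = rec$l,
         table = rec$table),
    extra)
}
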