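#' Read a STRING-style interaction edge list
#'
#' Expects a TSV with two node-identifier columns and an optional combined
#' score on the usual 0-1000 scale. Edges below `score_min` are dropped
#' (default 400, the conventional medium-confidence cutoff); when the file
#' carries no score column all edges are kept and a warning is raised.
#' Reversed duplicates collapse to a single undirected edge. STRING's
#' numeric taxon prefixes (e.g. `10090.`) are stripped from identifiers by
#' default; set `strip_prefix = NULL` to disable.
#'
#' @param path TSV file path.
#' @param score_min minimum combined score for an edge to be kept.
#' @param cols named character vector mapping `a`, `b`, `score` to the
#'   file's column names.
#' @param strip_prefix regular expression removed from the start of every
#'   node identifier, or `NULL`.
#' @return an undirected simple [igraph::igraph] with a `score` edge
#'   attribute when available.
#' @export
read_edges <- function(path, score_min = 400,
                       cols = c(a = "protein1", b = "protein2",
                                score = "combined_score"),
                       strip_prefix = "^[0-9]+\\.") {
  df <- read_tsv_file(path)
  require_columns(df, unname(cols[c("a", "b")]), path)
  a <- trimws(as.character(df[[cols[["a"]]]]))
  b <- trimws(as.character(df[[cols[["b"]]]]))
  bad <- which(is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad))
    stop_evhub(sprintf("%s: malformed row at line %d (empty node identifier)",
                       path, bad[1] + 1L))
  if (!is.null(strip_prefix)) {
    a <- sub(strip_prefix, "", a)
    b <- sub(strip_prefix, "", b)
  }
  has_score <- cols[["score"]] %in% names(df)
  if (has_score) {
    score <- as.numeric(df[[cols[["score"]]]])
    keep <- !is.na(score) & score >= score_min
    a <- a[keep]; b <- b[keep]; score <- score[keep]
  } else {
    warning(path, ": no '", cols[["score"]],
            "' column; all edges kept without score filtering")
    score <- NULL
  }
  edf <- data.frame(from = a, to = b, stringsAsFactors = FALSE)
  if (!is.null(score)) edf$score <- score
  g <- igraph::graph_from_data_frame(edf, directed = FALSE)
  igraph::simplify(g, edge.attr.comb = list(score = "max"))
}

#' Enumerate all maximal cliques
#'
#' Bron-Kerbosch enumeration with Tomita pivoting. Every returned vertex
#' set is a clique contained in no larger clique, and the collection is
#' exhaustive (isolated vertices appear as singleton cliques). A node-count
#' guard protects against pathologically large inputs.
#'
#' @param graph an undirected [igraph::igraph] (self-loops and multi-edges
#'   are removed).
#' @param max_nodes guard on the number of vertices (default 5000).
#' @return list of character vectors of vertex names, each sorted.
#' @export
maximal_cliques <- function(graph, max_nodes = 5000L) {
  if (!igraph::is_igraph(graph)) stop_evhub("`graph` must be an igraph object")
  graph <- igraph::simplify(graph)
  n <- igraph::vcount(graph)
  if (n > max_nodes)
    stop_evhub(sprintf("graph has %d nodes, above the guard of %d", n, max_nodes))
  vnames <- igraph::V(graph)$name %||% as.character(seq_len(n))
  if (n == 0L) return(list())
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"),
                function(v) sort(as.integer(v)))
  out <- new.env(parent = emptyenv())
  out$cliques <- vector("list", 64L)
  out$n <- 0L
  emit <- function(r) {
    out$n <- out$n + 1L
    if (out$n > length(out$cliques))
      out$cliques <- c(out$cliques, vector("list", length(out$cliques)))
    out$cliques[[out$n]] <- r
  }
  bk <- function(r, p, x) {
    if (!length(p) && !length(x)) { emit(r); return(invisible()) }
    # pivot: vertex of P union X with most neighbours in P
    cand <- c(p, x)
    deg <- vapply(cand, function(u) length(intersect(adj[[u]], p)), integer(1))
    u <- cand[which.max(deg)]
    for (v in setdiff(p, adj[[u]])) {
      nv <- adj[[v]]
      bk(c(r, v), intersect(p, nv), intersect(x, nv))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
    invisible()
  }
  bk(integer(0), seq_len(n), integer(0))
  lapply(out$cliques[seq_len(out$n)], function(idx) sort(vnames[idx]))
}

#' Maximal clique centrality and degree per gene
#'
#' MCC of a vertex v is the sum of `(|C| - 1)!` over all maximal cliques C
#' of size >= 2 that contain v; an isolated vertex scores 0. On a
#' triangle-free graph every maximal clique is an edge, so MCC reduces to
#' the degree.
#'
#' @inheritParams maximal_cliques
#' @return data.frame with columns `gene`, `mcc`, `degree`, sorted by gene.
#' @export
mcc_scores <- function(graph, max_nodes = 5000L) {
  cliques <- maximal_cliques(graph, max_nodes = max_nodes)
  graph <- igraph::simplify(graph)
  vnames <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  mcc <- setNames(numeric(length(vnames)), vnames)
  for (cl in cliques) {
    if (length(cl) < 2L) next
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1L)
  }
  deg <- igraph::degree(graph)
  df <- data.frame(gene = vnames, mcc = unname(mcc),
                   degree = as.integer(unname(deg[vnames])),
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Rank hub candidates by MCC
#'
#' Orders genes by MCC descending, breaking ties by degree descending and
#' then lexicographically, reports the top `top_k` and selects the leading
#' `n_candidates` among them under the same ordering.
#'
#' @param scores data.frame with `gene`, `mcc`, `degree` (e.g. from
#'   [mcc_scores()]).
#' @param top_k size of the reported top list (default 30).
#' @param n_candidates hub candidates taken from the top list (default 5).
#' @return list with elements `top` and `candidates` (data.frames in rank
#'   order).
#' @export
rank_hubs <- function(scores, top_k = 30L, n_candidates = 5L) {
  require_columns(scores, c("gene", "mcc", "degree"), "scores")
  top_k <- assert_count(top_k, "top_k")
  n_candidates <- assert_count(n_candidates, "n_candidates")
  if (top_k > nrow(scores)) {
    warning(sprintf("top_k = %d exceeds the %d scored genes; returning all",
                    top_k, nrow(scores)))
    top_k <- nrow(scores)
  }
  ord <- order(-scores$mcc, -scores$degree, scores$gene)
  top <- head(scores[ord, , drop = FALSE], top_k)
  rownames(top) <- NULL
  candidates <- head(top, min(n_candidates, nrow(top)))
  list(top = top, candidates = candidates)
}

#' Count each miRNA's targets among the top-ranked genes
#'
#' @param top_genes character vector of top-ranked gene symbols (or the
#'   list returned by [rank_hubs()]).
#' @param target_map a [build_target_map()] result.
#' @return data.frame with `mirna`, `direction`, `n_top_targets`; the sum
#'   of `n_top_targets` is the comparison's total link count.
#' @export
mirna_hub_links <- function(top_genes, target_map) {
  if (is.list(top_genes) && !is.null(top_genes$top)) top_genes <- top_genes$top$gene
  if (!inherits(target_map, "target_map"))
    stop_evhub("`target_map` must be a target_map")
  sel <- target_map$selection
  n <- vapply(sel$mirna, function(m)
    length(intersect(target_map$per_mirna[[m]], top_genes)), integer(1))
  data.frame(mirna = sel$mirna, direction = sel$direction,
             n_top_targets = unname(n), stringsAsFactors = FALSE)
}

#' Export a network for Cytoscape
#'
#' [write_sif()] writes simple-interaction-format lines (`a <type> b`);
#' [write_graphml()] delegates to [igraph::write_graph()].
#'
#' @param graph an [igraph::igraph].
#' @param path output file.
#' @param interaction interaction type written in the middle SIF column.
#' @export
write_sif <- function(graph, path, interaction = "pp") {
  el <- igraph::as_edgelist(graph)
  lines <- if (nrow(el)) paste(el[, 1], interaction, el[, 2]) else character(0)
  iso <- setdiff(igraph::V(graph)$name, c(el))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
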