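#' Assign each gene its regulating miRNA and inferred regulation direction
#'
#' Among the comparison's selected miRNAs that target a gene, the miRNA with
#' the most negative context score is assigned (ties break lexicographically
#' by miRNA id). The gene's inferred regulation is the opposite of the
#' miRNA's loading direction: an up-loaded miRNA is inferred to down-regulate
#' its targets, and vice versa. Genes targeted by no selected miRNA are
#' returned with an explicit `unassigned` status, never dropped.
#'
#' @param genes character vector of gene symbols.
#' @param target_map a [build_target_map()] result for the comparison.
#' @return data.frame with columns `gene`, `regulating_mirna`,
#'   `mirna_direction`, `inferred_gene_regulation`, `status`
#'   (`assigned`/`unassigned`).
#' @export
assign_regulation <- function(genes, target_map) {
  if (!inherits(target_map, "target_map"))
    stop_evhub("`target_map` must be a target_map")
  rec <- target_map$records
  sel <- target_map$selection
  dir_of <- setNames(sel$direction, sel$mirna)
  rows <- lapply(genes, function(g) {
    cand <- rec[rec$gene == g & rec$mirna %in% sel$mirna, , drop = FALSE]
    if (!nrow(cand))
      return(data.frame(gene = g, regulating_mirna = NA_character_,
                        mirna_direction = NA_character_,
                        inferred_gene_regulation = NA_character_,
                        status = "unassigned", stringsAsFactors = FALSE))
    cand <- cand[order(cand$cwcs, cand$mirna), , drop = FALSE]
    m <- cand$mirna[1]
    md <- unname(dir_of[m])
    data.frame(gene = g, regulating_mirna = m, mirna_direction = md,
               inferred_gene_regulation = if (md == "up") "down" else "up",
               status = "assigned", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge global-network and keyword-branch candidates into a report
#'
#' Takes the GD branch's hub candidates (from [rank_hubs()]) and the SK
#' branch's degree-selected genes (from [select_by_degree()]), deduplicates
#' genes (retaining both branch provenances when a gene appears in both),
#' annotates every candidate with its regulating miRNA via
#' [assign_regulation()], and reports per-branch and total counts.
#'
#' @param gd_candidates data.frame with `gene`, `mcc`, `degree` (or a
#'   character vector of genes).
#' @param sk_candidates data.frame with `gene`, `degree`, `keywords` (or a
#'   character vector of genes).
#' @param target_map the comparison's [build_target_map()] result.
#' @param comparison report label; defaults to the map's comparison.
#' @return an object of class `comparison_report`: list with `comparison`,
#'   `candidates` (data.frame `gene`, `branch`, `evidence`,
#'   `regulating_mirna`, `mirna_direction`, `inferred_gene_regulation`,
#'   `status`) and `counts` (`gd`, `sk`, `total`).
#' @export
merge_candidates <- function(gd_candidates, sk_candidates, target_map,
                             comparison = NULL) {
  if (!inherits(target_map, "target_map"))
    stop_evhub("`target_map` must be a target_map")
  comparison <- comparison %||% target_map$comparison
  if (is.list(gd_candidates) && !is.null(gd_candidates$candidates))
    gd_candidates <- gd_candidates$candidates
  gd <- normalize_branch(gd_candidates, function(df)
    sprintf("MCC=%s, degree=%s", format(df$mcc, trim = TRUE), df$degree))
  sk <- normalize_branch(sk_candidates, function(df)
    sprintf("keywords: %s", df$keywords))
  genes <- unique(c(gd$gene, sk$gene))
  branch <- vapply(genes, function(g) {
    paste(c("GD"[g %in% gd$gene], "SK"[g %in% sk$gene]), collapse = "+")
  }, character(1))
  evidence <- vapply(genes, function(g) {
    paste(c(gd$evidence[match(g, gd$gene)], sk$evidence[match(g, sk$gene)])[
      !is.na(c(gd$evidence[match(g, gd$gene)], sk$evidence[match(g, sk$gene)]))],
      collapse = "; ")
  }, character(1))
  reg <- assign_regulation(genes, target_map)
  candidates <- cbind(
    data.frame(gene = genes, branch = unname(branch),
               evidence = unname(evidence), stringsAsFactors = FALSE),
    reg[, c("regulating_mirna", "mirna_direction",
            "inferred_gene_regulation", "status")])
  rownames(candidates) <- NULL
  structure(list(comparison = comparison, candidates = candidates,
                 counts = list(gd = nrow(gd), sk = nrow(sk),
                               total = nrow(candidates))),
            class = "comparison_report")
}

normalize_branch <- function(x, evidence_fun) {
  if (is.character(x))
    return(data.frame(gene = x, evidence = rep(NA_character_, length(x)),
                      stringsAsFactors = FALSE))
  if (is.null(x) || !nrow(x))
    return(data.frame(gene = character(0), evidence = character(0),
                      stringsAsFactors = FALSE))
  ev <- tryCatch(evidence_fun(x), error = function(e) rep(NA_character_, nrow(x)))
  data.frame(gene = as.character(x$gene), evidence = ev,
             stringsAsFactors = FALSE)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s: %d candidates (GD %d, SK %d)\n",
              x$comparison, x$counts$total, x$counts$gd, x$counts$sk))
  if (nrow(x$candidates)) {
    print(x$candidates[, c("gene", "branch", "regulating_mirna",
                           "mirna_direction", "inferred_gene_regulation")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Serialize / deserialize a comparison report as JSON
#'
#' Round-trips losslessly: `report_from_json(report_to_json(r))` restores
#' the comparison label, candidate table and counts.
#'
#' @param report a [comparison_report][merge_candidates()].
#' @param path optional file path; when given the JSON is written there.
#' @return [report_to_json()] returns the JSON string (invisibly when
#'   written to a file); [report_from_json()] returns the restored report.
#' @export
report_to_json <- function(report, path = NULL) {
  if (!inherits(report, "comparison_report"))
    stop_evhub("`report` must be a comparison_report")
  js <- jsonlite::toJSON(
    list(comparison = report$comparison, candidates = report$candidates,
         counts = report$counts),
    dataframe = "rows", auto_unbox = TRUE, na = "null", digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname report_to_json
#' @param json JSON string or file path produced by [report_to_json()].
#' @export
report_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  cand <- as.data.frame(x$candidates, stringsAsFactors = FALSE)
  if (!nrow(cand))
    cand <- data.frame(gene = character(0), branch = character(0),
                       evidence = character(0),
                       regulating_mirna = character(0),
                       mirna_direction = character(0),
                       inferred_gene_regulation = character(0),
                       status = character(0), stringsAsFactors = FALSE)
  structure(list(comparison = x$comparison, candidates = cand,
                 counts = lapply(x$counts, as.integer)),
            class = "comparison_report")
}

#' Run one comparison end to end
#'
#' Convenience wrapper chaining the volcano filter, top-k selection,
#' context-score target mapping, both hub branches and the integrated
#' report for a single comparison.
#'
#' @param stats per-miRNA stats data.frame (`mirna`, `log2fc`, `p`), e.g.
#'   from [compute_mirna_stats()] or [read_stats()].
#' @param target_records target-record data.frame (`mirna`, `gene`,
#'   `cwcs`), e.g. from [read_targetscan()].
#' @param ppi_graph interaction [igraph::igraph] over the target genes,
#'   e.g. from [read_edges()]; it is restricted to the comparison's target
#'   union before scoring.
#' @param annotations annotation corpus (`gene`, `description`).
#' @param lexicon a [keyword_lexicon()].
#' @param comparison report label.
#' @param fc_thresh,p_thresh volcano thresholds (see [classify_mirnas()]).
#' @param k_per_direction top-k per direction (see [select_top_mirnas()]).
#' @param cwcs_max context-score threshold (see [filter_targets()]).
#' @param top_k,n_candidates GD ranking sizes (see [rank_hubs()]).
#' @param min_degree SK selection threshold (see [select_by_degree()]).
#' @return list with the intermediate objects (`selection`, `target_map`,
#'   `scores`, `ranking`, `keyword_network`, `sk_selected`, `links`) and
#'   the final `report`.
#' @export
run_comparison <- function(stats, target_records, ppi_graph, annotations,
                           lexicon = keyword_lexicon(),
                           comparison = "comparison",
                           fc_thresh = 2, p_thresh = 0.05,
                           k_per_direction = 4L, cwcs_max = -0.4,
                           top_k = 30L, n_candidates = 5L, min_degree = 4L) {
  classified <- classify_mirnas(stats, fc_thresh = fc_thresh,
                                p_thresh = p_thresh)
  selection <- select_top_mirnas(classified, k_per_direction)
  filtered <- filter_targets(target_records, cwcs_max = cwcs_max)
  map <- build_target_map(selection, filtered, comparison = comparison)
  union_genes <- unique(c(map$groups$up, map$groups$down))
  sub <- igraph::induced_subgraph(
    ppi_graph, intersect(igraph::V(ppi_graph)$name, union_genes))
  scores <- mcc_scores(sub)
  ranking <- rank_hubs(scores, top_k = min(top_k, max(nrow(scores), 1L)),
                       n_candidates = n_candidates)
  net <- build_keyword_network(annotations, lexicon, genes = union_genes)
  sk_sel <- select_by_degree(net, min_degree)
  report <- merge_candidates(ranking$candidates, sk_sel, map)
  list(selection = selection, target_map = map, scores = scores,
       ranking = ranking, keyword_network = net, sk_selected = sk_sel,
       links = mirna_hub_links(ranking, map), report = report)
}
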