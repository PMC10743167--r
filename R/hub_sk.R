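default_lexicon_categories <- list(
  "Immune Responses" = c("Immune", "Cytotoxicity", "Phagocytosis"),
  "Immune Cells" = c("T cell", "B cell", "Dendritic", "Helper",
                     "Macrophage", "Myeloid"),
  "Inflammation Signaling" = c("Inflammation", "Cytokine", "Interleukin",
                               "NF-kappaB", "TGF-beta", "JAK/Stat",
                               "CD3", "CD4", "CD8"))

default_lexicon_synonyms <- list(
  "T cell" = c("T cells", "T-cell", "T lymphocyte", "T lymphocytes"),
  "B cell" = c("B cells", "B-cell", "B lymphocyte", "B lymphocytes"),
  "Dendritic" = c("Dendritic cell", "Dendritic cells"),
  "Helper" = c("Helper cell", "Helper cells", "T helper"),
  "Macrophage" = c("Macrophages"),
  "Cytokine" = c("Cytokines"),
  "Interleukin" = c("Interleukins"),
  "NF-kappaB" = c("NF-kB", "NF-κB", "NFkB",
                  "nuclear factor kappa B", "nuclear factor-kappaB"),
  "TGF-beta" = c("TGF-β", "TGFbeta", "TGFb",
                 "transforming growth factor beta"),
  "JAK/Stat" = c("JAK-STAT", "JAK STAT", "JAK/STAT"))

#' Keyword lexicon for the specific-keyword branch
#'
#' The default lexicon holds the 18 canonical keywords of the pipeline's
#' three categories (immune responses, immune cells, inflammation
#' signaling) together with a synonym table covering common surface
#' variants (plurals, hyphenations, Greek letters, spelled-out forms).
#' Both parts are user-overridable.
#'
#' @param categories named list: category -> character vector of canonical
#'   keywords.
#' @param synonyms named list: canonical keyword -> character vector of
#'   variant strings; names must be canonical keywords.
#' @return an object of class `keyword_lexicon`.
#' @export
keyword_lexicon <- function(categories = default_lexicon_categories,
                            synonyms = default_lexicon_synonyms) {
  kws <- unlist(categories, use.names = FALSE)
  if (!length(kws)) stop_evhub("lexicon must contain at least one keyword")
  if (anyDuplicated(kws))
    stop_evhub("duplicate canonical keyword(s): ",
               paste(unique(kws[duplicated(kws)]), collapse = ", "))
  bad <- setdiff(names(synonyms), kws)
  if (length(bad))
    stop_evhub("synonyms refer to unknown keyword(s): ",
               paste(bad, collapse = ", "))
  structure(list(categories = categories, synonyms = synonyms),
            class = "keyword_lexicon")
}

#' @rdname keyword_lexicon
#' @param lexicon a `keyword_lexicon`.
#' @return [lexicon_keywords()] returns the canonical keyword vector.
#' @export
lexicon_keywords <- function(lexicon) {
  if (!inherits(lexicon, "keyword_lexicon"))
    stop_evhub("`lexicon` must be a keyword_lexicon")
  unlist(lexicon$categories, use.names = FALSE)
}

#' @export
print.keyword_lexicon <- function(x, ...) {
  cat(sprintf("<keyword_lexicon> %d keywords in %d categories\n",
              length(lexicon_keywords(x)), length(x$categories)))
  invisible(x)
}

#' Read a lexicon from YAML or TSV
#'
#' YAML files hold `categories` (category -> keyword list) and optionally
#' `synonyms`; TSV files need `keyword` and `category` columns plus an
#' optional `synonyms` column with `|`-separated variants.
#'
#' @param path file path (`.yml`/`.yaml` or tab-separated text).
#' @return a [keyword_lexicon()].
#' @export
read_lexicon <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    if (is.null(y$categories)) stop_evhub(path, ": missing 'categories'")
    syn <- lapply(y$synonyms %||% list(), function(s) as.character(unlist(s)))
    return(keyword_lexicon(lapply(y$categories, as.character), syn))
  }
  df <- read_tsv_file(path)
  require_columns(df, c("keyword", "category"), path)
  cats <- split(as.character(df$keyword), as.character(df$category))
  syn <- list()
  if ("synonyms" %in% names(df)) {
    has <- !is.na(df$synonyms) & nzchar(df$synonyms)
    syn <- setNames(strsplit(as.character(df$synonyms[has]), "|", fixed = TRUE),
                    as.character(df$keyword[has]))
  }
  keyword_lexicon(cats, syn)
}

# fold case, turn hyphens and slashes into spaces, collapse whitespace
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[-/]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# one boundary-anchored regex per canonical keyword, covering all variants
keyword_patterns <- function(lexicon) {
  kws <- lexicon_keywords(lexicon)
  vapply(kws, function(k) {
    variants <- unique(normalize_text(c(k, lexicon$synonyms[[k]])))
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", variants)
    paste0("(?<![[:alnum:]])(", paste(esc, collapse = "|"),
           ")(?![[:alnum:]])")
  }, character(1))
}

#' Match lexicon keywords in an annotation text
#'
#' Case-insensitive, token-boundary matching after normalising hyphens,
#' slashes and whitespace, so `"T-cell"` matches the keyword `"T cell"`
#' while `"CD34"` does not match `"CD3"`. A keyword matches if any of its
#' variants occurs as a bounded token sequence; each canonical keyword is
#' reported at most once.
#'
#' @param text a single free-text annotation description.
#' @param lexicon a [keyword_lexicon()].
#' @return character vector of matched canonical keywords (lexicon order).
#' @export
match_keywords <- function(text, lexicon = keyword_lexicon()) {
  if (length(text) != 1L) stop_evhub("`text` must be a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  norm <- normalize_text(text)
  pats <- keyword_patterns(lexicon)
  names(pats)[vapply(pats, function(p) grepl(p, norm, perl = TRUE), logical(1))]
}

#' Build the keyword-gene bipartite network
#'
#' Runs the keyword matcher over every gene's annotation and records one
#' (keyword, gene) edge per matched canonical keyword. A gene's bipartite
#' degree is the number of distinct keywords matched; genes with degree
#' >= 1 form the network's gene set. Genes listed in `genes` but missing
#' from the corpus are reported with degree 0 (with a message).
#'
#' @param annotations data.frame with columns `gene`, `description`.
#' @param lexicon a [keyword_lexicon()].
#' @param genes optional character vector restricting (and completing) the
#'   gene universe.
#' @return an object of class `keyword_network`: list with `hits`
#'   (data.frame `gene`, `degree`, `keywords` comma-collapsed), `matched`
#'   (named list of keyword sets) and `edges` (data.frame `keyword`,
#'   `gene`).
#' @export
build_keyword_network <- function(annotations, lexicon = keyword_lexicon(),
                                  genes = NULL) {
  require_columns(annotations, c("gene", "description"), "annotations")
  ann <- annotations
  if (!is.null(genes)) {
    missing <- setdiff(genes, ann$gene)
    if (length(missing))
      message(length(missing), " gene(s) without annotation; degree 0 assigned")
    ann <- ann[ann$gene %in% genes, , drop = FALSE]
    ann <- rbind(ann, data.frame(gene = missing, description = "",
                                 stringsAsFactors = FALSE))
  }
  if (anyDuplicated(ann$gene)) stop_evhub("duplicate gene annotation rows")
  pats <- keyword_patterns(lexicon)
  norm <- normalize_text(ann$description)
  matched <- lapply(norm, function(txt) {
    if (!nzchar(txt)) return(character(0))
    names(pats)[vapply(pats, function(p) grepl(p, txt, perl = TRUE), logical(1))]
  })
  names(matched) <- ann$gene
  degree <- vapply(matched, length, integer(1))
  hits <- data.frame(gene = ann$gene, degree = unname(degree),
                     keywords = vapply(matched, paste, character(1),
                                       collapse = ", "),
                     stringsAsFactors = FALSE)
  edges <- data.frame(
    keyword = unlist(matched, use.names = FALSE) %||% character(0),
    gene = rep(ann$gene, degree), stringsAsFactors = FALSE)
  structure(list(hits = hits, matched = matched, edges = edges,
                 network_genes = sort(hits$gene[hits$degree >= 1L])),
            class = "keyword_network")
}

#' @export
print.keyword_network <- function(x, ...) {
  cat(sprintf("<keyword_network> %d annotated genes, %d in network, %d edges\n",
              nrow(x$hits), length(x$network_genes), nrow(x$edges)))
  invisible(x)
}

#' Select genes by bipartite keyword degree
#'
#' @param network a [build_keyword_network()] result (or its `hits`
#'   data.frame).
#' @param min_degree minimum number of matched keywords (default 4).
#' @return data.frame of selected hits ordered by degree descending, then
#'   gene symbol.
#' @export
select_by_degree <- function(network, min_degree = 4L) {
  hits <- if (inherits(network, "keyword_network")) network$hits else network
  require_columns(hits, c("gene", "degree"), "hits")
  min_degree <- assert_count(min_degree, "min_degree")
  out <- hits[hits$degree >= min_degree, , drop = FALSE]
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write gene annotation corpora
#'
#' TSV with columns `gene` and `description`.
#'
#' @param path file path.
#' @return [read_annotations()] returns the corpus data.frame.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_file(path)
  require_columns(df, c("gene", "description"), path)
  df$gene <- trimws(as.character(df$gene))
  df$description <- as.character(df$description)
  df
}

#' @rdname read_annotations
#' @param annotations corpus data.frame.
#' @export
write_annotations <- function(annotations, path) {
  require_columns(annotations, c("gene", "description"), "annotations")
  write_tsv_file(annotations, path)
}

#' Export the bipartite keyword network
#'
#' @param network a [keyword_network][build_keyword_network()].
#' @param path output file.
#' @param format `"sif"` (`keyword kw gene` lines) or `"tsv"` edge table.
#' @export
write_keyword_edges <- function(network, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (!inherits(network, "keyword_network"))
    stop_evhub("`network` must be a keyword_network")
  if (format == "sif") {
    writeLines(paste(network$edges$keyword, "kw", network$edges$gene), path)
  } else {
    write_tsv_file(network$edges, path)
  }
  invisible(path)
}
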