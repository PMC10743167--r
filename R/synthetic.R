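#' Simulation specification for EV miRNA count data
#'
#' Describes a seeded negative-binomial small-RNA count simulation with two
#' conditions (`A`, the reference, and `B`) and optional planted log2 fold
#' changes. Defaults emulate an overdispersed small-RNA-seq experiment:
#' per-miRNA baseline abundances are drawn log-normally around
#' `baseline_mean` (log-sd `mean_sdlog`) so the matrix spans a realistic
#' dynamic range, and counts are negative binomial with the given dispersion
#' (`variance = mu + dispersion * mu^2`).
#'
#' @param seed integer seed; the generator is a pure function of the spec,
#'   so a fixed seed yields byte-identical output.
#' @param n_mirnas number of miRNAs to simulate.
#' @param n_per_group samples per condition.
#' @param planted_effects named numeric vector of true log2 fold changes
#'   (B over A); names must be among [sim_mirna_ids()]`(n_mirnas)`.
#'   Unnamed miRNAs have no effect.
#' @param dispersion negative-binomial dispersion, > 0.
#' @param baseline_mean expected baseline count scale, > 0.
#' @param mean_sdlog log-sd of the per-miRNA baseline abundance draw;
#'   0 gives every miRNA the same baseline mean.
#' @return an object of class `sim_spec`.
#' @seealso [gen_counts()]
#' @export
sim_spec <- function(seed, n_mirnas, n_per_group, planted_effects = numeric(),
                     dispersion = 0.1, baseline_mean = 500, mean_sdlog = 1) {
  seed <- assert_count(seed, "seed")
  n_mirnas <- assert_count(n_mirnas, "n_mirnas", min = 1L)
  n_per_group <- assert_count(n_per_group, "n_per_group", min = 1L)
  assert_scalar_number(dispersion, "dispersion", positive = TRUE)
  assert_scalar_number(baseline_mean, "baseline_mean", positive = TRUE)
  assert_scalar_number(mean_sdlog + 1, "mean_sdlog")  # finite check
  if (mean_sdlog < 0) stop_evhub("`mean_sdlog` must be >= 0")
  if (length(planted_effects)) {
    if (is.null(names(planted_effects)) || any(names(planted_effects) == ""))
      stop_evhub("`planted_effects` must be a named numeric vector")
    bad <- setdiff(names(planted_effects), sim_mirna_ids(n_mirnas))
    if (length(bad))
      stop_evhub("planted_effects name(s) outside the simulated miRNA ids: ",
                 paste(bad, collapse = ", "))
  }
  structure(
    list(seed = seed, n_mirnas = n_mirnas, n_per_group = n_per_group,
         planted_effects = planted_effects, dispersion = dispersion,
         baseline_mean = baseline_mean, mean_sdlog = mean_sdlog),
    class = "sim_spec")
}

#' miRNA identifiers used by the count simulator
#'
#' @param n number of ids.
#' @return character vector `miR-sim-001`, `miR-sim-002`, ...
#' @export
sim_mirna_ids <- function(n) sprintf("miR-sim-%03d", seq_len(n))

#' Expression matrix with group labels
#'
#' Container for a miRNA x sample count matrix and its two-group design.
#'
#' @param counts non-negative integer matrix, miRNAs in rows (rownames set),
#'   samples in columns (colnames set).
#' @param groups named character vector mapping every sample to `"A"` or
#'   `"B"`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(counts, groups) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_evhub("`counts` must be a matrix with row and column names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop_evhub("duplicate miRNA or sample identifiers")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop_evhub("`counts` must contain non-negative integers")
  groups <- groups[colnames(counts)]
  if (any(is.na(groups)) || !all(groups %in% c("A", "B")))
    stop_evhub("every sample must be labelled 'A' or 'B' in `groups`")
  if (!all(c("A", "B") %in% groups))
    stop_evhub("each group must contain at least one sample")
  structure(list(counts = counts, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d miRNAs x %d samples (A: %d, B: %d)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$groups == "A"), sum(x$groups == "B")))
  invisible(x)
}

#' Simulate a two-condition miRNA count matrix
#'
#' Draws negative-binomial counts for two conditions. Condition B means are
#' the baseline means scaled by `2^planted_effects`; miRNAs without a
#' planted effect are null.
#'
#' @param spec a [sim_spec()].
#' @return an [expression_matrix()] with samples `A1..An, B1..Bn`.
#' @export
gen_counts <- function(spec) {
  if (!inherits(spec, "sim_spec")) stop_evhub("`spec` must be a sim_spec")
  ids <- sim_mirna_ids(spec$n_mirnas)
  lfc <- setNames(numeric(spec$n_mirnas), ids)
  lfc[names(spec$planted_effects)] <- spec$planted_effects
  n <- spec$n_per_group
  set.seed(spec$seed)
  mu <- rlnorm(spec$n_mirnas, meanlog = log(spec$baseline_mean),
               sdlog = spec$mean_sdlog)
  size <- 1 / spec$dispersion
  a <- matrix(rnbinom(spec$n_mirnas * n, mu = rep(mu, n), size = size),
              nrow = spec$n_mirnas)
  b <- matrix(rnbinom(spec$n_mirnas * n, mu = rep(mu * 2^lfc, n), size = size),
              nrow = spec$n_mirnas)
  counts <- cbind(a, b)
  rownames(counts) <- ids
  colnames(counts) <- c(sprintf("A%d", seq_len(n)), sprintf("B%d", seq_len(n)))
  groups <- setNames(rep(c("A", "B"), each = n), colnames(counts))
  expression_matrix(counts, groups)
}

#' Specification of a synthetic miRNA target table
#'
#' @param per_mirna_counts named integer vector: number of target genes per
#'   miRNA.
#' @param overlap_mode `"disjoint"` (every miRNA gets a fresh, pairwise
#'   disjoint gene set) or `"random"` (each link reuses an already-created
#'   gene with probability `overlap_p`).
#' @param overlap_p reuse probability for `overlap_mode = "random"`.
#' @param cwcs_range length-2 interval (both <= 0) from which cumulative
#'   weighted context++ scores are drawn uniformly.
#' @return an object of class `target_table_spec`.
#' @export
target_table_spec <- function(per_mirna_counts,
                              overlap_mode = c("disjoint", "random"),
                              overlap_p = 0, cwcs_range = c(-2, -0.4)) {
  overlap_mode <- match.arg(overlap_mode)
  if (!is.numeric(per_mirna_counts) || is.null(names(per_mirna_counts)) ||
      any(names(per_mirna_counts) == ""))
    stop_evhub("`per_mirna_counts` must be a named numeric vector")
  if (any(per_mirna_counts < 0) || any(per_mirna_counts != floor(per_mirna_counts)))
    stop_evhub("per-miRNA counts must be non-negative integers")
  if (overlap_p < 0 || overlap_p > 1) stop_evhub("`overlap_p` must be in [0, 1]")
  if (length(cwcs_range) != 2L || any(!is.finite(cwcs_range)) ||
      cwcs_range[1] > cwcs_range[2] || cwcs_range[2] > 0)
    stop_evhub("`cwcs_range` must be an interval with both ends <= 0")
  structure(list(per_mirna_counts = per_mirna_counts,
                 overlap_mode = overlap_mode, overlap_p = overlap_p,
                 cwcs_range = cwcs_range),
            class = "target_table_spec")
}

#' Generate a synthetic miRNA -> target-gene score table
#'
#' Produces one record per (miRNA, gene) pair with a context score drawn
#' from `cwcs_range`. In disjoint mode gene labels are allocated
#' sequentially so the per-miRNA sets are pairwise disjoint and union sizes
#' are exactly additive.
#'
#' @param spec a [target_table_spec()].
#' @param seed integer seed.
#' @return data.frame with columns `mirna`, `gene`, `cwcs`.
#' @export
gen_target_table <- function(spec, seed) {
  if (!inherits(spec, "target_table_spec"))
    stop_evhub("`spec` must be a target_table_spec")
  seed <- assert_count(seed, "seed")
  set.seed(seed)
  counts <- spec$per_mirna_counts
  out <- vector("list", length(counts))
  pool <- character()
  next_id <- 1L
  for (i in seq_along(counts)) {
    k <- counts[[i]]
    if (k == 0L) { out[[i]] <- NULL; next }
    if (spec$overlap_mode == "disjoint") {
      genes <- sprintf("G%05d", seq.int(next_id, length.out = k))
      next_id <- next_id + k
    } else {
      genes <- character(0)
      while (length(genes) < k) {
        reuse <- length(pool) > 0 && runif(1) < spec$overlap_p
        g <- if (reuse) pool[sample.int(length(pool), 1L)] else {
          id <- sprintf("G%05d", next_id); next_id <- next_id + 1L; id
        }
        if (!g %in% genes) genes <- c(genes, g)
      }
    }
    pool <- union(pool, genes)
    out[[i]] <- data.frame(
      mirna = names(counts)[i], gene = genes,
      cwcs = runif(k, spec$cwcs_range[1], spec$cwcs_range[2]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(mirna = character(), gene = character(),
                      cwcs = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Generate a protein-interaction graph with planted cliques
#'
#' Background nodes (`bg...`) form an Erdos-Renyi graph; each planted clique
#' is a complete subgraph on fresh nodes carrying the reserved `clique`
#' prefix, kept disconnected from the background so tests can identify
#' planted hubs without the labels influencing any score.
#'
#' @param n_background number of background nodes.
#' @param edge_prob background edge probability in \[0, 1\].
#' @param planted_cliques integer vector of clique sizes (each >= 2).
#' @param seed integer seed.
#' @return an undirected [igraph::igraph] object.
#' @export
gen_ppi <- function(n_background, edge_prob, planted_cliques = integer(),
                    seed = 1L) {
  n_background <- assert_count(n_background, "n_background")
  if (edge_prob < 0 || edge_prob > 1) stop_evhub("`edge_prob` must be in [0, 1]")
  if (length(planted_cliques) && any(planted_cliques < 2))
    stop_evhub("planted clique sizes must be >= 2")
  seed <- assert_count(seed, "seed")
  set.seed(seed)
  bg <- sprintf("bg%03d", seq_len(n_background))
  edges <- character(0)
  if (n_background >= 2) {
    pairs <- utils::combn(bg, 2)
    keep <- runif(ncol(pairs)) < edge_prob
    edges <- c(pairs[, keep, drop = FALSE])
  }
  clq_nodes <- character(0)
  for (i in seq_along(planted_cliques)) {
    members <- sprintf("clique%d_n%02d", i, seq_len(planted_cliques[i]))
    clq_nodes <- c(clq_nodes, members)
    edges <- c(edges, c(utils::combn(members, 2)))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(bg) + length(clq_nodes),
                            name = c(bg, clq_nodes))
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::simplify(g)
}

# fixed filler vocabulary for annotation prose; deliberately free of every
# default lexicon keyword and synonym token so decoy texts can never match
filler_words <- c(
  "protein", "binding", "membrane", "transport", "kinase", "phosphatase",
  "nuclear", "cytoplasmic", "domain", "complex", "assembly", "vesicle",
  "trafficking", "mitochondrial", "ribosomal", "translation", "transcription",
  "promoter", "enhancer", "chromatin", "histone", "ubiquitin", "ligase",
  "proteasome", "degradation", "folding", "chaperone", "secretion",
  "endosome", "lysosome", "golgi", "reticulum", "glycosylation", "lipid",
  "metabolism", "oxidase", "reductase", "synthase", "hydrolase", "polymerase",
  "helicase", "replication", "repair", "division", "spindle", "microtubule",
  "actin", "myosin", "adhesion", "junction", "matrix", "collagen", "integrin",
  "receptor", "ligand", "channel", "calcium", "potassium", "sodium",
  "gradient", "homeostasis", "development", "differentiation", "morphogenesis",
  "axon", "synapse", "exocytosis", "isoform", "localization", "substrate")

#' Generate an annotation corpus with planted keywords
#'
#' Each planned gene receives a free-text description of filler prose with
#' exactly its planned keywords embedded at random positions; decoy genes
#' receive filler prose containing at most `decoy_max_keywords` lexicon
#' keywords (default none). The filler vocabulary is a fixed keyword-free
#' word list shipped with the package, so accidental matches cannot occur.
#'
#' @param keyword_plan named list mapping gene symbol to a character vector
#'   of canonical lexicon keywords to embed.
#' @param n_decoys number of decoy genes (`decoy...`).
#' @param lexicon a [keyword_lexicon()].
#' @param seed integer seed.
#' @param decoy_max_keywords lexicon keywords allowed per decoy text.
#' @return data.frame with columns `gene`, `description`.
#' @export
gen_annotations <- function(keyword_plan = list(), n_decoys = 0L,
                            lexicon = keyword_lexicon(), seed = 1L,
                            decoy_max_keywords = 0L) {
  n_decoys <- assert_count(n_decoys, "n_decoys")
  decoy_max_keywords <- assert_count(decoy_max_keywords, "decoy_max_keywords")
  seed <- assert_count(seed, "seed")
  canon <- lexicon_keywords(lexicon)
  planned <- unique(unlist(keyword_plan))
  bad <- setdiff(planned, canon)
  if (length(bad))
    stop_evhub("planned keyword(s) outside the lexicon: ",
               paste(bad, collapse = ", "))
  set.seed(seed)
  make_text <- function(kw) {
    words <- sample(filler_words, sample(30:50, 1L), replace = TRUE)
    for (k in kw) {
      pos <- sample.int(length(words) + 1L, 1L) - 1L
      words <- append(words, k, after = pos)
    }
    paste(words, collapse = " ")
  }
  genes <- names(keyword_plan)
  rows <- lapply(genes, function(g) {
    data.frame(gene = g, description = make_text(keyword_plan[[g]]),
               stringsAsFactors = FALSE)
  })
  decoys <- lapply(seq_len(n_decoys), function(i) {
    kw <- if (decoy_max_keywords > 0)
      sample(canon, sample.int(decoy_max_keywords, 1L)) else character(0)
    data.frame(gene = sprintf("decoy%03d", i), description = make_text(kw),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, decoys))
  if (is.null(res))
    res <- data.frame(gene = character(), description = character(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Read / write count matrices with group labels
#'
#' The count TSV has samples as header columns and miRNA ids in the first
#' column; the group TSV has columns `sample` and `group` (values `A`/`B`).
#'
#' @param counts_path,groups_path file paths.
#' @return [read_counts()] returns an [expression_matrix()].
#' @export
read_counts <- function(counts_path, groups_path) {
  tab <- read_tsv_file(counts_path)
  if (ncol(tab) < 2L) stop_evhub(counts_path, ": expected id column plus samples")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(counts) <- "double"
  rownames(counts) <- as.character(tab[[1]])
  grp <- read_tsv_file(groups_path)
  require_columns(grp, c("sample", "group"), groups_path)
  groups <- setNames(as.character(grp$group), as.character(grp$sample))
  expression_matrix(counts, groups)
}

#' @rdname read_counts
#' @param x an [expression_matrix()].
#' @export
write_counts <- function(x, counts_path, groups_path) {
  if (!inherits(x, "expression_matrix")) stop_evhub("`x` must be an expression_matrix")
  df <- data.frame(mirna = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, counts_path)
  write_tsv_file(data.frame(sample = names(x$groups), group = unname(x$groups),
                            stringsAsFactors = FALSE), groups_path)
  invisible(c(counts_path, groups_path))
}
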