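# Brute-force maximal-clique enumeration over all vertex subsets, using
# bitmask arithmetic; independent of the package's Bron-Kerbosch path.
# Only feasible for n <= ~16 vertices.
brute_force_cliques <- function(graph) {
  graph <- igraph::simplify(graph)
  n <- igraph::vcount(graph)
  stopifnot(n <= 16)
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(n))
  if (n == 0) return(list())
  adj_mask <- integer(n)
  el <- igraph::as_edgelist(graph, names = FALSE)
  for (k in seq_len(nrow(el))) {
    i <- el[k, 1]; j <- el[k, 2]
    adj_mask[i] <- bitwOr(adj_mask[i], bitwShiftL(1L, j - 1L))
    adj_mask[j] <- bitwOr(adj_mask[j], bitwShiftL(1L, i - 1L))
  }
  subsets <- seq_len(2^n - 1L)  # non-empty subsets as bitmasks
  is_clique <- rep(TRUE, length(subsets))
  for (v in seq_len(n)) {
    bit <- bitwShiftL(1L, v - 1L)
    inS <- bitwAnd(subsets, bit) > 0L
    others <- bitwAnd(subsets[inS], bitwNot(bit))
    is_clique[inS] <- is_clique[inS] &
      bitwAnd(adj_mask[v], others) == others
  }
  cl <- subsets[is_clique]
  # maximal: no outside vertex adjacent to every member
  maximal <- rep(TRUE, length(cl))
  for (v in seq_len(n)) {
    bit <- bitwShiftL(1L, v - 1L)
    outS <- bitwAnd(cl, bit) == 0L
    maximal[outS] <- maximal[outS] &
      bitwAnd(adj_mask[v], cl[outS]) != cl[outS]
  }
  lapply(cl[maximal], function(mask) {
    sort(vnames[bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L) == 1L])
  })
}

# MCC from an arbitrary clique list (size-2+ cliques only), as a data.frame
# comparable with mcc_scores()
brute_force_mcc <- function(graph) {
  cliques <- brute_force_cliques(graph)
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(igraph::vcount(graph)))
  mcc <- setNames(numeric(length(vnames)), vnames)
  for (cl in cliques) {
    if (length(cl) < 2) next
    mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  }
  data.frame(gene = sort(vnames), mcc = unname(mcc[sort(vnames)]),
             stringsAsFactors = FALSE)
}

canonical_cliques <- function(cliques) {
  keys <- vapply(cliques, paste, character(1), collapse = "|")
  cliques[order(keys)]
}

# Printed per-comparison miRNA summary used as fixture truth: selection
# tables (log2 fold change, direction) and per-miRNA target-set sizes.
mirna_summary_fixture <- function() {
  nanog <- data.frame(
    mirna = c("miR-18a-5p", "miR-3473e", "miR-19a-3p", "miR-3473b",
              "miR-210-3p", "miR-369-3p", "miR-122-5p", "miR-706"),
    log2fc = c(2.46, 1.75, 1.20, 1.18, -3.62, -2.52, -1.79, -1.28),
    direction = rep(c("up", "down"), each = 4),
    n_targets = c(42, 6, 126, 127, 6, 7, 29, 62),
    stringsAsFactors = FALSE)
  ips <- data.frame(
    mirna = c("miR-466h-3p", "miR-706", "miR-323-3p", "miR-466f-3p",
              "miR-30a-3p", "miR-342-5p", "let-7c-5p", "miR-423-3p"),
    log2fc = c(7.62, 6.23, 6.23, 6.07, -4.99, -4.74, -4.63, -4.36),
    direction = rep(c("up", "down"), each = 4),
    n_targets = c(58, 62, 10, 145, 49, 335, 2, 8),
    stringsAsFactors = FALSE)
  list(nanog = nanog, ips = ips)
}

# Disjoint target-record fixture for one comparison with exactly the
# printed per-miRNA set sizes, via the package's generator.
target_fixture <- function(summary_df, seed) {
  spec <- target_table_spec(
    setNames(summary_df$n_targets, summary_df$mirna),
    overlap_mode = "disjoint", cwcs_range = c(-2, -0.4))
  gen_target_table(spec, seed = seed)
}

# Printed GD hub-candidate tables (MCC score, degree) per comparison.
gd_scores_fixture <- function() {
  list(
    nanog = data.frame(
      gene = c("Trp53", "Hif1a", "Esr1", "Atm", "Cdkn1b"),
      mcc = c(1058, 990, 919, 872, 847),
      degree = c(23, 19, 11, 9, 7), stringsAsFactors = FALSE),
    ips = data.frame(
      gene = c("Ins1", "Kitl", "Fgf16", "Grb2", "Fgf1"),
      mcc = c(13801, 13493, 13254, 11784, 11640),
      degree = c(19, 15, 11, 15, 11), stringsAsFactors = FALSE))
}

# Printed keyword assignments of the degree-4 SK genes (canonical forms).
sk_keyword_plan <- function() {
  list(
    nanog = list(
      Rnf11 = c("Immune", "Cytokine", "NF-kappaB", "TGF-beta")),
    ips = list(
      Malt1 = c("Immune", "T cell", "B cell", "Helper"),
      Il1f6 = c("T cell", "Dendritic", "Interleukin", "NF-kappaB"),
      Cmklr1 = c("Immune", "Macrophage", "Inflammation", "NF-kappaB"),
      Siglec1 = c("T cell", "Macrophage", "B cell", "CD8"),
      Cd28 = c("Cytotoxicity", "Immune", "T cell", "CD4")))
}

# Regulating miRNA printed for each hub candidate, with loading direction.
regulation_fixture <- function() {
  data.frame(
    gene = c("Trp53", "Hif1a", "Esr1", "Atm", "Cdkn1b", "Rnf11",
             "Ins1", "Kitl", "Fgf16", "Grb2", "Fgf1",
             "Malt1", "Il1f6", "Cmklr1", "Siglec1", "Cd28"),
    mirna = c("miR-3473b", "miR-18a-5p", "miR-18a-5p", "miR-18a-5p",
              "miR-706", "miR-19a-3p",
              "miR-466f-3p", "miR-466f-3p", "miR-466f-3p", "miR-466f-3p",
              "miR-342-5p",
              "miR-466f-3p", "miR-30a-3p", "miR-342-5p", "miR-342-5p",
              "miR-342-5p"),
    direction = c("up", "up", "up", "up", "down", "up",
                  "up", "up", "up", "up", "down",
                  "up", "down", "down", "down", "down"),
    comparison = rep(c("nanog", "ips"), c(6, 10)),
    stringsAsFactors = FALSE)
}

# Target records that make the printed regulating-miRNA assignments the
# unique most-negative-CWCS choice for the listed hub genes.
regulation_records_fixture <- function(comp) {
  reg <- regulation_fixture()
  reg <- reg[reg$comparison == comp, , drop = FALSE]
  primary <- data.frame(mirna = reg$mirna, gene = reg$gene, cwcs = -1.2,
                        stringsAsFactors = FALSE)
  # add a weaker competing selected miRNA for one gene per comparison, to
  # exercise the most-negative-CWCS tie-break
  competitor <- if (comp == "nanog") {
    data.frame(mirna = "miR-3473e", gene = "Trp53", cwcs = -0.6,
               stringsAsFactors = FALSE)
  } else {
    data.frame(mirna = "miR-323-3p", gene = "Cd28", cwcs = -0.5,
               stringsAsFactors = FALSE)
  }
  # every selected miRNA also gets a filler target so none is absent from
  # the record table
  sel <- mirna_summary_fixture()[[comp]]$mirna
  filler <- data.frame(mirna = sel, gene = paste0("filler_", sel),
                       cwcs = -0.8, stringsAsFactors = FALSE)
  rbind(primary, competitor, filler)
}
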