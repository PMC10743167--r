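graph_from_pairs <- function(...) {
  igraph::graph_from_data_frame(
    as.data.frame(matrix(c(...), ncol = 2, byrow = TRUE)), directed = FALSE)
}

test_that("STRING edge lists parse with score filtering and deduplication", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "10090.a\t10090.b\t300",
               "10090.b\t10090.c\t400",
               "10090.c\t10090.d\t700",
               "10090.d\t10090.a\t900"), path)
  g <- read_edges(path)
  expect_equal(igraph::ecount(g), 3)  # the 300 edge is dropped
  expect_setequal(igraph::V(g)$name, c("a", "b", "c", "d"))  # prefix stripped

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "x\ty\t500", "y\tx\t500"), dup)
  expect_equal(igraph::ecount(read_edges(dup)), 1)

  noscore <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2", "x\ty", "y\tz"), noscore)
  expect_warning(g2 <- read_edges(noscore), "all edges kept")
  expect_equal(igraph::ecount(g2), 2)

  malformed <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "x\ty\t500", "\tz\t600"), malformed)
  expect_error(read_edges(malformed), "line 3")
})

test_that("maximal cliques are exact on canonical small graphs", {
  k3 <- graph_from_pairs("a", "b", "b", "c", "a", "c")
  expect_equal(maximal_cliques(k3), list(c("a", "b", "c")))
  path_g <- graph_from_pairs("a", "b", "b", "c")
  expect_equal(canonical_cliques(maximal_cliques(path_g)),
               canonical_cliques(list(c("a", "b"), c("b", "c"))))
  expect_equal(maximal_cliques(igraph::make_empty_graph(0, directed = FALSE)),
               list())
  expect_error(maximal_cliques(k3, max_nodes = 2), "guard")
})

test_that("clique enumeration matches brute force and igraph on random graphs", {
  set.seed(101)
  for (r in 1:25) {
    g <- igraph::sample_gnp(12, 0.4)
    igraph::V(g)$name <- sprintf("v%02d", 1:12)
    mine <- canonical_cliques(maximal_cliques(g))
    expect_equal(mine, canonical_cliques(brute_force_cliques(g)))
    ig <- lapply(igraph::max_cliques(g, min = 1),
                 function(v) sort(igraph::V(g)$name[as.integer(v)]))
    expect_equal(mine, canonical_cliques(ig))
  }
})

test_that("MCC scoring follows the factorial clique formula", {
  k3 <- graph_from_pairs("a", "b", "b", "c", "a", "c")
  expect_equal(mcc_scores(k3)$mcc, rep(2, 3))  # (3-1)! per member
  path_g <- graph_from_pairs("a", "b", "b", "c")
  sc <- mcc_scores(path_g)
  expect_equal(sc$mcc[sc$gene == "b"], 2)  # two size-2 cliques, 1 each
  # isolated vertex scores zero
  iso <- igraph::add_vertices(path_g, 1, name = "z")
  expect_equal(mcc_scores(iso)$mcc[mcc_scores(iso)$gene == "z"], 0)
  # triangle-free graphs: mcc equals degree (star and 5-cycle)
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- letters[1:6]
  expect_equal(mcc_scores(star)$mcc, as.numeric(mcc_scores(star)$degree))
  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- letters[1:5]
  expect_equal(mcc_scores(ring)$mcc, as.numeric(mcc_scores(ring)$degree))
})

test_that("clique-cover invariants hold on random graphs", {
  set.seed(77)
  for (r in 1:5) {
    g <- igraph::sample_gnp(11, 0.35)
    igraph::V(g)$name <- sprintf("v%02d", 1:11)
    cl <- maximal_cliques(g)
    sizes <- lengths(cl)
    sc <- mcc_scores(g)
    expect_equal(sum(sc$mcc),
                 sum(sizes[sizes >= 2] * factorial(sizes[sizes >= 2] - 1)))
    # every edge lies in at least one maximal clique, so mcc >= degree
    expect_true(all(sc$mcc[sc$degree >= 1] >= sc$degree[sc$degree >= 1]))
  }
})

test_that("hub ranking orders by MCC with degree and name tie-breaks", {
  fx <- gd_scores_fixture()$nanog
  extra <- data.frame(gene = sprintf("bg%02d", 1:25),
                      mcc = seq(800, 80, length.out = 25), degree = 3,
                      stringsAsFactors = FALSE)
  ranked <- rank_hubs(rbind(extra, fx), top_k = 30, n_candidates = 5)
  expect_equal(ranked$candidates$gene,
               c("Trp53", "Hif1a", "Esr1", "Atm", "Cdkn1b"))
  expect_equal(ranked$candidates$mcc[1], 1058)
  expect_equal(nrow(ranked$top), 30)
  # permutation invariance
  set.seed(5)
  perm <- rbind(extra, fx)[sample(30), ]
  expect_equal(rank_hubs(perm, 30, 5)$top, ranked$top)
  # all-equal scores fall back to lexicographic order
  flat <- data.frame(gene = c("c", "a", "b"), mcc = 5, degree = 2,
                     stringsAsFactors = FALSE)
  expect_equal(rank_hubs(flat, 3, 3)$candidates$gene, c("a", "b", "c"))
  expect_equal(nrow(rank_hubs(flat, 3, 0)$candidates), 0)
  expect_warning(rank_hubs(flat, 10, 2), "exceeds")
})

test_that("per-miRNA link counts over the top genes are exact", {
  sel <- data.frame(mirna = c("miR-a", "miR-b"), direction = c("up", "down"),
                    stringsAsFactors = FALSE)
  rec <- data.frame(
    mirna = c(rep("miR-a", 6), rep("miR-b", 3)),
    gene = c(sprintf("t%d", 1:6), sprintf("t%d", 5:7)),
    cwcs = -1, stringsAsFactors = FALSE)
  map <- build_target_map(sel, rec)
  links <- mirna_hub_links(c("t1", "t2", "t3", "t4", "t5"), map)
  expect_equal(links$n_top_targets, c(4L + 1L, 1L))
  expect_equal(mirna_hub_links(character(0), map)$n_top_targets, c(0L, 0L))
})

test_that("network exports are readable back", {
  g <- graph_from_pairs("a", "b", "b", "c")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(g, sif)
  expect_equal(readLines(sif), c("a pp b", "b pp c"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  h <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(h)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(h), igraph::ecount(g))
})
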