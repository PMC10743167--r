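test_that("the default lexicon carries 18 keywords in three categories", {
  lex <- keyword_lexicon()
  expect_length(lexicon_keywords(lex), 18)
  expect_length(lex$categories, 3)
  expect_error(keyword_lexicon(list(a = c("x", "x"))), "duplicate")
  expect_error(keyword_lexicon(list(a = "x"), list(y = "z")), "unknown")
})

test_that("keyword matching is token-bounded and variant-aware", {
  lex <- keyword_lexicon()
  expect_setequal(
    match_keywords(paste("Involved in cytotoxicity of immune effectors;",
                         "expressed on T cell surface with CD4"), lex),
    c("Cytotoxicity", "Immune", "T cell", "CD4"))
  expect_equal(match_keywords("", lex), character(0))
  # token boundaries: CD3 must not fire inside CD34
  expect_equal(match_keywords("CD34+ hematopoietic cells", lex), character(0))
  expect_equal(match_keywords("engages CD3 on thymocytes", lex), "CD3")
  # synonym and punctuation variants
  expect_equal(match_keywords("NF-kB signaling", lex), "NF-kappaB")
  expect_equal(match_keywords("nuclear factor kappa B activation", lex),
               "NF-kappaB")
  expect_equal(match_keywords("TGF-β receptor ligand", lex), "TGF-beta")
  expect_equal(match_keywords("JAK-STAT cascade member", lex), "JAK/Stat")
  # hyphen/space and case invariance
  expect_equal(match_keywords("t-cell receptor", lex), "T cell")
  expect_equal(match_keywords("T CELL RECEPTOR", lex), "T cell")
  # each canonical keyword reported once
  expect_equal(match_keywords("immune and immune and Immune", lex), "Immune")
})

test_that("matching is invariant to case and hyphen/space substitution", {
  lex <- keyword_lexicon()
  kws <- lexicon_keywords(lex)
  for (k in kws) {
    base <- sprintf("protein linked to %s in tissue", k)
    variants <- c(toupper(base), tolower(base),
                  sprintf("protein linked to %s in tissue", gsub(" ", "-", k)))
    for (v in variants) expect_true(k %in% match_keywords(v, lex), label = v)
  }
})

test_that("bipartite networks count degrees and edges consistently", {
  lex <- keyword_lexicon()
  ann <- data.frame(
    gene = sprintf("g%d", 1:5),
    description = c("macrophage activation via interleukin release",
                    "ribosomal assembly factor", "membrane transport",
                    "chromatin remodeling", "actin binding"),
    stringsAsFactors = FALSE)
  net <- build_keyword_network(ann, lex)
  expect_equal(net$network_genes, "g1")
  expect_equal(nrow(net$edges), 2)
  expect_equal(sum(net$hits$degree), nrow(net$edges))
  # degree sums equal on both sides of the bipartite graph
  expect_equal(sum(table(net$edges$gene)), sum(table(net$edges$keyword)))
  # idempotence
  net2 <- build_keyword_network(ann, lex)
  expect_identical(net$edges, net2$edges)
  # missing annotations get degree 0
  expect_message(net3 <- build_keyword_network(ann, lex,
                                               genes = c("g1", "g9")),
                 "without annotation")
  expect_equal(net3$hits$degree[net3$hits$gene == "g9"], 0L)
})

test_that("degree selection is thresholded, ordered and nested", {
  lex <- keyword_lexicon()
  plan <- sk_keyword_plan()$ips
  ann <- gen_annotations(plan, n_decoys = 20, lexicon = lex, seed = 31)
  net <- build_keyword_network(ann, lex)
  sel4 <- select_by_degree(net, 4)
  expect_setequal(sel4$gene, names(plan))
  expect_equal(sel4$gene, sort(names(plan)))  # equal degree -> lexicographic
  # decoy-only corpus selects nothing even at degree 1
  decoys <- ann[grepl("^decoy", ann$gene), ]
  expect_equal(nrow(select_by_degree(build_keyword_network(decoys, lex), 1)), 0)
  # min_degree = 0 keeps degree-0 genes
  expect_equal(nrow(select_by_degree(net, 0)), nrow(ann))
  # nesting under a rising threshold
  for (d in 1:4)
    expect_true(all(select_by_degree(net, d + 1)$gene %in%
                      select_by_degree(net, d)$gene))
})

test_that("lexicons and annotation corpora read from files", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("categories:",
               "  Responses: [Immune, Cytotoxicity]",
               "  Cells: [T cell]",
               "synonyms:",
               "  T cell: [T-cell, T lymphocyte]"), yml)
  lex <- read_lexicon(yml)
  expect_length(lexicon_keywords(lex), 3)
  expect_equal(match_keywords("a T lymphocyte antigen", lex), "T cell")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("keyword\tcategory\tsynonyms",
               "Immune\tResponses\t",
               "T cell\tCells\tT-cell|T lymphocyte"), tsv)
  lex2 <- read_lexicon(tsv)
  expect_setequal(lexicon_keywords(lex2), c("Immune", "T cell"))
  expect_equal(match_keywords("T lymphocyte marker", lex2), "T cell")

  ann <- data.frame(gene = "g1", description = "immune factor",
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, path)
  expect_equal(read_annotations(path), ann)
})
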