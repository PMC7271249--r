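pairkeys <- function(e) paste(pmin(e$entrez_a, e$entrez_b),
                              pmax(e$entrez_a, e$entrez_b))
pair_strings <- function(a, b) paste(pmin(a, b), pmax(a, b))

test_that("network assembly computes degrees and mean incident scores", {
  # triangle A-B, B-C, A-C with scores 0.2 / 0.4 / 0.6
  tri <- data.frame(entrez_a = c(1, 2, 1), entrez_b = c(2, 3, 3),
                    score = c(0.2, 0.4, 0.6))
  net <- net_from_edges(tri)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(net$nodes$degree, c(2L, 2L, 2L))
  expect_equal(net$nodes$mean_score[net$nodes$entrez == 2], (0.2 + 0.4) / 2)
  # 5 pairs over 6 proteins
  five <- data.frame(entrez_a = c(1, 1, 2, 3, 5), entrez_b = c(2, 3, 4, 5, 6),
                     score = rep(0.5, 5))
  n5 <- net_from_edges(five)
  expect_equal(nrow(n5$nodes), 6L)
  expect_equal(nrow(n5$edges), 5L)
  # self-loops count once toward degree
  loop <- net_from_edges(data.frame(entrez_a = c(1, 1), entrez_b = c(1, 2),
                                    score = c(0.3, 0.7)))
  expect_equal(loop$nodes$degree[loop$nodes$entrez == 1], 2L)
  # empty network
  expect_equal(nrow(net_from_edges(five[0, ])$nodes), 0L)
})

hippo_net <- function() {
  ref <- build_reference(hippo_dir())
  ref
}

test_that("protein queries resolve any identifier type and sort by score", {
  ref <- hippo_net()
  by_symbol <- protein_query(ref$network, "Lats2")
  by_entrez <- protein_query(ref$network, "50523")
  by_uniprot <- protein_query(ref$network,
                              ref$idmap$uniprot[ref$idmap$symbol == "Lats2"])
  expect_equal(by_symbol, by_entrez)
  expect_equal(by_symbol, by_uniprot)
  expect_setequal(by_symbol$partner_symbol, c("Stk4", "Sav1", "Yap1", "Wwtr1"))
  expect_true(all(diff(by_symbol$score) <= 0))
  expect_true(all(lengths(by_symbol$publications) == 3))
  expect_error(protein_query(ref$network, "NotAGene"),
               class = "ppiref_notfound_error")
})

test_that("ambiguous symbols raise an error listing candidates", {
  idmap <- read_idmap(write_idmap_fixture(data.frame(
    provider_id = c("u:A", "u:B"), entrez = c(1, 2),
    symbol = c("Dup", "Dup"), mgi = c("m1", "m2"), uniprot = c("p1", "p2"))))
  net <- net_from_edges(data.frame(entrez_a = 1, entrez_b = 2, score = 0.5),
                        idmap = idmap)
  expect_error(protein_query(net, "Dup"), "1, 2",
               class = "ppiref_notfound_error")
})

test_that("layers=0 keeps edges within the input set; all-nodes input recovers everything", {
  set.seed(13)
  edges <- random_scored_edges(15, 40)
  net <- net_from_edges(edges)
  all_ids <- as.character(net$nodes$entrez)
  sub <- network_query(net, proteins = all_ids, opts = query_options(layers = 0))
  expect_equal(nrow(sub$edges), nrow(net$edges))
  some <- as.character(net$nodes$entrez[1:5])
  sub0 <- network_query(net, proteins = some, opts = query_options(layers = 0))
  in_set <- net$edges$entrez_a %in% net$nodes$entrez[1:5] &
    net$edges$entrez_b %in% net$nodes$entrez[1:5]
  expect_equal(nrow(sub0$edges), sum(in_set))
})

test_that("queried pairs absent from the network get pseudo-score -1", {
  ref <- hippo_net()
  # Stk4-Lats2 exists; Stk4-Tead4 does not
  sub <- network_query(ref$network, pairs = rbind(c("Stk4", "Lats2"),
                                                  c("Stk4", "Tead4")),
                       opts = query_options(layers = 0))
  hit <- sub$edges[!sub$edges$pseudo, ]
  expect_true(any(hit$entrez_a == 50523 & hit$entrez_b == 58231))
  miss <- sub$edges[sub$edges$pseudo, ]
  expect_equal(nrow(miss), 1L)
  expect_equal(miss$score, -1)
  # pseudo rows survive any confidence filter
  f <- filter_confidence(sub, 0.99)
  expect_true(any(f$edges$pseudo & f$edges$score == -1))
})

test_that("min_connections prunes weakly attached neighbors like a brute-force scan", {
  # star: inputs 1,2,3; neighbor 10 touches all, 11 touches one
  edges <- data.frame(entrez_a = c(1, 2, 3, 1, 10),
                      entrez_b = c(10, 10, 10, 11, 11),
                      score = rep(0.8, 5))
  net <- net_from_edges(edges)
  sub2 <- network_query(net, proteins = c("1", "2", "3"),
                        opts = query_options(layers = 1, min_connections = 2))
  expect_false(11 %in% c(sub2$edges$entrez_a, sub2$edges$entrez_b))
  expect_true(10 %in% sub2$nodes$entrez)
  set.seed(17)
  for (rep in 1:5) {
    e <- random_scored_edges(12, 30)
    n <- net_from_edges(e)
    input <- sample(n$nodes$entrez, 4)
    for (mc in 1:3) {
      sub <- network_query(n, proteins = as.character(input),
                           opts = query_options(min_connections = mc,
                                                include_neighbor_edges = FALSE))
      # brute force: neighbors with >= mc distinct input partners
      adj <- function(v) unique(c(e$entrez_b[e$entrez_a == v], e$entrez_a[e$entrez_b == v]))
      nbs <- setdiff(unique(unlist(lapply(input, adj))), input)
      kept_nb <- nbs[vapply(nbs, function(v) length(intersect(adj(v), input)) >= mc,
                            logical(1))]
      sel <- union(input, kept_nb)
      want <- e[(e$entrez_a %in% input | e$entrez_b %in% input) &
                  e$entrez_a %in% sel & e$entrez_b %in% sel, ]
      expect_equal(nrow(sub$edges), nrow(want))
    }
  }
})

test_that("raising threshold or min_connections never adds edges", {
  set.seed(19)
  e <- random_scored_edges(14, 45)
  n <- net_from_edges(e)
  input <- as.character(sample(n$nodes$entrez, 4))
  prev_edges <- Inf
  for (th in c(0, 0.3, 0.6, 0.9)) {
    sub <- network_query(n, proteins = input,
                         opts = query_options(threshold = th))
    expect_lte(nrow(sub$edges), prev_edges)
    prev_edges <- nrow(sub$edges)
  }
  prev_edges <- Inf
  for (mc in 1:4) {
    sub <- network_query(n, proteins = input,
                         opts = query_options(min_connections = mc))
    expect_lte(nrow(sub$edges), prev_edges)
    prev_edges <- nrow(sub$edges)
  }
})

test_that("confidence filter is inclusive and matches a counting oracle", {
  set.seed(23)
  e <- random_scored_edges(12, 20)
  scored <- as_scored(e)
  expect_equal(nrow(filter_confidence(scored, 0)), nrow(scored))
  expect_equal(nrow(filter_confidence(scored, max(e$score) + 0.001)), 0L)
  med <- unname(stats::median(e$score))
  expect_equal(nrow(filter_confidence(scored, med)), sum(e$score >= med))
  # named presets resolve through the published constants
  e2 <- e; e2$score <- c(0.53, rep(0.2, nrow(e) - 1))
  expect_equal(nrow(filter_confidence(as_scored(e2), "medium")), 1L)
})

test_that("confidence and tissue filters commute", {
  ref <- hippo_net()
  calls <- presence_calls(read_expression(file.path(hippo_dir(), "expression.tsv")))
  prot <- c("Stk4", "Lats2", "Tead4")
  both <- network_query(ref$network, proteins = prot,
                        opts = query_options(threshold = 0.6,
                                             tissue_filter = "stem cell"),
                        calls = calls)
  conf_first <- filter_confidence(
    network_query(ref$network, proteins = prot,
                  opts = query_options(tissue_filter = "stem cell"),
                  calls = calls), 0.6)
  expect_equal(sort(pairkeys(both$edges)), sort(pairkeys(conf_first$edges)))
})

test_that("term filters keep only interactions whose both partners carry the term", {
  ref <- hippo_net()
  dag <- read_ontology(file.path(hippo_dir(), "ontology.tsv"))
  ann <- read_annotations(file.path(hippo_dir(), "annotations.tsv"))
  # T00002 marks the kinases Stk4 and Lats2 only
  sub <- network_query(ref$network, proteins = c("Stk4", "Lats2", "Tead4"),
                       opts = query_options(term_filters = "T00002"),
                       annotations = ann, dag = dag)
  real <- sub$edges[!sub$edges$pseudo, ]
  expect_equal(nrow(real), 1L)
  expect_equal(sort(c(real$entrez_a, real$entrez_b)), c(50523, 58231))
  # the root term covers every gene
  sub_all <- network_query(ref$network, proteins = c("Stk4", "Lats2", "Tead4"),
                           opts = query_options(term_filters = "T00001"),
                           annotations = ann, dag = dag)
  expect_equal(nrow(sub_all$edges), 7L)
})

test_that("screen annotation returns stored scores or -1, preserving order", {
  ref <- hippo_net()
  pairs <- data.frame(a = c("Stk4", "Lats2", "Stk4", "Nope", "Yap1"),
                      b = c("Sav1", "Yap1", "Tead4", "Stk4", "Tead4"))
  out <- screen_annotate(pairs, ref$network)
  expect_equal(ncol(out), 3L)
  expect_equal(out$id_a, pairs$a)
  expect_equal(out$score[4], -1)   # unknown identifier
  expect_equal(out$score[3], -1)   # known proteins, absent pair
  expect_true(all(out$score[c(1, 2, 5)] > 0))
  # scores agree with protein_query for present pairs
  pq <- protein_query(ref$network, "Stk4")
  expect_equal(out$score[1], pq$score[pq$partner_symbol == "Sav1"])
})

test_that("screen files accept tab, comma and semicolon separators", {
  ref <- hippo_net()
  f <- tempfile()
  writeLines(c("Stk4\tSav1", "Lats2,Yap1", "Wwtr1;Tead4"), f)
  out <- screen_annotate(f, ref$network)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$score > 0))
  writeLines(c("Stk4\tSav1", "lonetoken"), f)
  expect_error(screen_annotate(f, ref$network), "line 2",
               class = "ppiref_format_error")
})

test_that("exports round-trip (mitab) and carry the right structure (tsv, json)", {
  ref <- hippo_net()
  sub <- network_query(ref$network, proteins = c("Stk4", "Lats2", "Tead4"))
  # TSV: one data line per edge
  tsv <- tempfile(); export_network(sub, tsv, "tsv")
  expect_equal(length(readLines(tsv)) - 1L, nrow(sub$edges))
  # MITAB: re-parse and compare pair sets
  mt <- tempfile(); export_network(sub, mt, "mitab")
  back <- parse_mitab(mt)
  back_pairs <- pair_strings(as.integer(sub("entrez gene/locuslink:", "", back$id_a)),
                             as.integer(sub("entrez gene/locuslink:", "", back$id_b)))
  expect_setequal(back_pairs, pair_strings(sub$edges$entrez_a, sub$edges$entrez_b))
  # JSON graph: node count equals subnetwork order
  js <- tempfile(); export_network(sub, js, "json-graph")
  parsed <- jsonlite::read_json(js)
  expect_equal(length(parsed$nodes), nrow(sub$nodes))
  expect_equal(length(parsed$edges), nrow(sub$edges))
  expect_error(export_network(sub, tempfile(), "xml"),
               class = "ppiref_usage_error")
})

test_that("REST-style protein strings parse into proteins and explicit pairs", {
  p <- parse_protein_input("Stk4,Lats2;Tead4|Yap1")
  expect_equal(p$proteins, c("Stk4", "Lats2", "Tead4", "Yap1"))
  expect_null(p$pairs)
  q <- parse_protein_input("Stk4:Lats2,Tead4")
  expect_equal(q$proteins, "Tead4")
  expect_equal(unname(q$pairs[1, ]), c("Stk4", "Lats2"))
  expect_error(parse_protein_input(""), class = "ppiref_usage_error")
})
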