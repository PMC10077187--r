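test_that("cross-kingdom extraction keeps exactly the mixed pairs", {
  euk <- c("e1", "e2"); bact <- c("b1", "b2")
  e <- make_edges(c("e1", "b1", "e1"), c("b1", "b2", "e2"),
                  c(0.7, 0.8, 0.9))
  out <- extract_cross_kingdom(e, euk, bact)
  expect_identical(nrow(out), 1L)
  expect_identical(out$source, "e1")
  expect_identical(out$target, "b1")
  # orientation flip when the bacterium is listed first
  e2 <- make_edges("b1", "e1", 0.7)
  out2 <- extract_cross_kingdom(e2, euk, bact)
  expect_identical(out2$source, "e1")
  expect_identical(extract_cross_kingdom(e[0, ], euk, bact), e[0, ])
  expect_error(extract_cross_kingdom(make_edges("x9", "b1", 0.7), euk, bact),
               "unknown kingdom")
})

test_that("sign splitting conserves edges and duplicates mixed-sign nodes", {
  e <- make_edges(c("e1", "e1", "e2"), c("b1", "b2", "b1"),
                  c(0.7, -0.8, 0.65))
  nets <- split_by_sign(e)
  expect_identical(sum(nets$positive$weights > 0) +
                     sum(nets$negative$weights > 0), nrow(e))
  expect_equal(unname(nets$negative$weights["e1", "b2"]), 0.8)  # |rho|
  # e1 and b1 have both signs -> present in both networks
  expect_true("e1" %in% rownames(nets$positive$weights) &&
                "e1" %in% rownames(nets$negative$weights))
  # all-positive input leaves the negative network empty
  nets2 <- split_by_sign(make_edges("e1", "b1", 0.7))
  expect_identical(nrow(nets2$negative$weights), 0L)
})

test_that("core taxa are the both-sign nodes with degree coverage", {
  pos <- split_by_sign(make_edges(c("A", "B", "B", "B"),
                                  c("x", "x", "y", "z"),
                                  c(0.7, 0.7, 0.7, 0.7)))$positive
  neg <- split_by_sign(make_edges(c("B", "C"), c("x", "y"),
                                  c(-0.7, -0.7)))$negative
  core <- core_taxa(pos, neg)
  expect_setequal(core$nodes$id[core$nodes$guild == "microeukaryote"], "B")
  b <- core$nodes[core$nodes$id == "B", ]
  expect_identical(b$d_pos, 3)
  expect_identical(b$d_neg, 1)
  expect_equal(b$asymmetry, 0.5)           # (3 - 1) / (3 + 1)
  # x holds both signs too
  expect_true("x" %in% core$nodes$id)
  # coverage: degrees incident to core nodes over all degrees
  expect_gt(core$coverage[["overall"]], 0)
  expect_lte(core$coverage[["overall"]], 1)
  # disjoint networks -> empty core, zero coverage
  pos2 <- split_by_sign(make_edges("A", "x", 0.7))$positive
  neg2 <- split_by_sign(make_edges("B", "y", -0.7))$negative
  core2 <- core_taxa(pos2, neg2)
  expect_identical(nrow(core2$nodes), 0L)
  expect_equal(unname(core2$coverage[["overall"]]), 0)
})

test_that("phylum summary yields percentages that sum to 100 per guild", {
  tax <- data.frame(otu_id = c("e1", "e2", "b1", "b2", "b3"),
                    phylum = c("Chlorophyta", "Fungi", "Proteobacteria",
                               "Proteobacteria", "Proteobacteria"))
  e <- make_edges(c("e1", "e1", "e1", "e2"), c("b1", "b2", "b3", "b3"),
                  c(0.7, 0.7, 0.8, 0.7))
  net <- split_by_sign(e, taxonomy = tax)$positive
  ps <- phylum_summary(net)
  euk <- ps[ps$guild == "microeukaryote", ]
  expect_equal(sum(euk$node_pct), 100, tolerance = 0.1)
  expect_equal(sum(euk$degree_pct), 100, tolerance = 0.1)
  # degrees 3 vs 1 -> 75% / 25%
  expect_equal(euk$degree_pct[euk$phylum == "Chlorophyta"], 75)
  expect_equal(euk$degree_pct[euk$phylum == "Fungi"], 25)
  bac <- ps[ps$guild == "bacteria", ]
  expect_identical(nrow(bac), 1L)          # single phylum -> 100 / 100
  expect_equal(bac$node_pct, 100)
  expect_equal(bac$degree_pct, 100)
  # unknown nodes fall back to "unclassified"
  net2 <- split_by_sign(e, taxonomy = tax[-1, ])$positive
  expect_true("unclassified" %in% phylum_summary(net2)$phylum)
})

test_that("GraphML export round-trips the edge set with attributes", {
  tax <- data.frame(otu_id = c("e1", "e2", "b1", "b2"),
                    phylum = c("Chlorophyta", "Fungi", "Proteobacteria",
                               "Bacteroidetes"))
  e <- make_edges(c("e1", "e2", "e2"), c("b1", "b1", "b2"),
                  c(0.7, 0.9, 0.8), p = 0.02)
  net <- split_by_sign(e, habitat = "water", taxonomy = tax)$positive
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_identical(igraph::ecount(g), 3)
  expect_setequal(igraph::edge_attr(g, "sign"), "positive")
  got <- igraph::as_data_frame(g, "edges")
  expect_setequal(paste(got$from, got$to), paste(e$source, e$target))
  expect_setequal(round(got$rho, 6), c(0.7, 0.9, 0.8))
  verts <- igraph::as_data_frame(g, "vertices")
  expect_setequal(verts$guild, c("microeukaryote", "bacteria"))
  expect_true(all(nchar(verts$phylum) > 0))
})
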