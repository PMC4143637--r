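# small enrichment tables and databases built directly
make_enr <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(pathway_id = r[[1]], trait = r[[2]],
               n_members_in_data = 5L, p = 0.01,
               enriched_at_nominal = r[[3]], stringsAsFactors = FALSE)))
}
make_db <- function(...) structure(list(...), class = "pathway_db")

test_that("pathways sharing a functional gene across adjacent exams crosstalk", {
  db <- make_db(P = list(description = "", genes = c("f1", "a", "b")),
                Q = list(description = "", genes = c("f1", "c", "d")),
                R = list(description = "", genes = c("a", "c", "e")))
  enr <- make_enr(list("P", "T1", TRUE), list("P", "T2", FALSE),
                  list("Q", "T1", FALSE), list("Q", "T2", TRUE),
                  list("R", "T1", TRUE), list("R", "T2", TRUE))
  net <- build_crosstalk(enr, db, truth_genes = "f1", c("T1", "T2"))
  expect_setequal(net$nodes$pathway_id, c("P", "Q", "R"))
  expect_identical(nrow(net$edges), 1L)   # P-Q via f1; R shares only non-truth
  expect_identical(sort(c(net$edges$from, net$edges$to)), c("P", "Q"))
  expect_identical(net$edges$shared_functional_genes, "f1")
  expect_false(net$edges$both_enriched_both_times)
  # orientation symmetry: swapping which exam each endpoint is enriched at
  enr2 <- make_enr(list("P", "T1", FALSE), list("P", "T2", TRUE),
                   list("Q", "T1", TRUE), list("Q", "T2", FALSE))
  net2 <- build_crosstalk(enr2, db, "f1", c("T1", "T2"))
  expect_identical(nrow(net2$edges), 1L)
  expect_error(build_crosstalk(enr, db, character(), c("T1", "T2")), "non-empty")
  expect_error(build_crosstalk(enr, db, "f1", c("T1", "T9")), "lacks exam")
})

test_that("three persistently enriched pathways sharing one true gene form a flagged 3-clique", {
  db <- make_db(A = list(description = "", genes = c("f1", "x1")),
                B = list(description = "", genes = c("f1", "x2")),
                C = list(description = "", genes = c("f1", "x3")))
  enr <- do.call(rbind, lapply(c("A", "B", "C"), function(pw)
    make_enr(list(pw, "T1", TRUE), list(pw, "T2", TRUE), list(pw, "T3", TRUE))))
  for (tp in list(c("T1", "T2"), c("T2", "T3"))) {
    net <- build_crosstalk(enr, db, "f1", tp)
    expect_identical(nrow(net$nodes), 3L)       # persistent across both pairs
    expect_identical(nrow(net$edges), 3L)       # the 3-clique
    expect_true(all(net$edges$both_enriched_both_times))
    expect_true(all(net$nodes$category == "enriched_both"))
    expect_true(all(net$nodes$enriched_at == "T1,T2,T3"))
  }
})

test_that("growing the truth set never removes edges; tightening enrichment never adds nodes", {
  set.seed(1)
  genes <- paste0("g", 1:30)
  db <- structure(setNames(lapply(1:8, function(i)
    list(description = "", genes = sample(genes, 6))), paste0("P", 1:8)),
    class = "pathway_db")
  enr <- do.call(rbind, lapply(names(db), function(pw)
    make_enr(list(pw, "T1", runif(1) < 0.6), list(pw, "T2", runif(1) < 0.6))))
  t_small <- sample(genes, 3)
  t_big <- union(t_small, sample(genes, 5))
  n1 <- build_crosstalk(enr, db, t_small, c("T1", "T2"))
  n2 <- build_crosstalk(enr, db, t_big, c("T1", "T2"))
  key <- function(n) paste(n$edges$from, n$edges$to)
  expect_true(all(key(n1) %in% key(n2)))
  enr_tight <- enr
  enr_tight$enriched_at_nominal <- enr$enriched_at_nominal & runif(nrow(enr)) < 0.5
  n3 <- build_crosstalk(enr_tight, db, t_small, c("T1", "T2"))
  expect_true(all(n3$nodes$pathway_id %in% n1$nodes$pathway_id))
})

test_that("networks survive a GraphML round trip and export tidy SIF", {
  db <- make_db(P = list(description = "", genes = c("f1", "a")),
                Q = list(description = "", genes = c("f1", "b")))
  enr <- make_enr(list("P", "T1", TRUE), list("Q", "T2", TRUE))
  net <- build_crosstalk(enr, db, "f1", c("T1", "T2"))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges[order(back$edges$from), ],
               net$edges[order(net$edges$from), ])
  expect_identical(back$time_pair, net$time_pair)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_identical(readLines(sif), "P\tcrosstalk_T1_T2\tQ")

  # empty network: valid, loadable documents
  empty <- build_crosstalk(make_enr(list("P", "T1", FALSE), list("P", "T2", FALSE)),
                           db, "f1", c("T1", "T2"))
  expect_identical(nrow(empty$nodes), 0L)
  export_network(empty, gml, "graphml")
  expect_identical(nrow(import_network(gml)$edges), 0L)
  export_network(empty, sif, "sif")
  expect_length(readLines(sif), 0)
})
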