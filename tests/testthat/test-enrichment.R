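test_that("hypergeometric tail matches exact enumeration on small instances", {
  # worked instance: N=10, n=5, m=4
  expect_equal(hypergeom_tail(3, 10, 4, 5), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_tail(3, 10, 4, 5, tail = "gt"), 6 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 10, 4, 5), 1)
  # closed form when the whole query hits the whole term: 1 / C(N, m)
  expect_equal(hypergeom_tail(5, 20, 5, 5), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_error(hypergeom_tail(5, 10, 4, 5), "invalid contingency")
  expect_error(hypergeom_tail(1, 10, 11, 5), "invalid contingency")
})

test_that("tail agrees with combinatorial brute force for all N <= 12", {
  for (N in 2:12) {
    for (n in 0:N) {
      for (m in c(0, 1, N %/% 2, N)) {
        for (k in 0:min(n, m)) {
          expect_equal(hypergeom_tail(k, N, m, n),
                       brute_hyper_tail(k, N, m, n, "ge"),
                       tolerance = 1e-10,
                       info = sprintf("ge k=%d N=%d m=%d n=%d", k, N, m, n))
          expect_equal(hypergeom_tail(k, N, m, n, tail = "gt"),
                       brute_hyper_tail(k, N, m, n, "gt"),
                       tolerance = 1e-10,
                       info = sprintf("gt k=%d N=%d m=%d n=%d", k, N, m, n))
        }
      }
    }
  }
})

test_that("pmf sums to one and tail identities hold", {
  for (N in c(10, 25, 60)) {
    for (m in c(0, 3, N %/% 2, N)) {
      for (n in c(1, N %/% 3, N)) {
        ks <- 0:min(n, m)
        expect_lt(abs(sum(vapply(ks, hypergeom_pmf, 0, N = N, m = m, n = n)) - 1),
                  1e-12)
        # p(gt, k) = p(ge, k + 1); ge tail non-increasing in k
        pge <- vapply(ks, hypergeom_tail, 0, N = N, m = m, n = n)
        expect_true(all(diff(pge) <= 1e-15))
        for (k in ks[-length(ks)])
          expect_equal(hypergeom_tail(k, N, m, n, tail = "gt"),
                       hypergeom_tail(k + 1, N, m, n), tolerance = 1e-12)
      }
    }
  }
  # independent distributional oracle at larger N
  expect_equal(hypergeom_tail(40, 5000, 300, 400),
               phyper(39, 300, 4700, 400, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("annotation propagation closes sets over is_a ancestry", {
  dag <- read_obo(fixture_obo())
  raw <- read_gene2go(fixture_gene2go(), taxon = 9606, dag = dag)
  closed <- propagate_annotations(dag, raw)
  expect_setequal(closed$biological_process$GA, c("GO:0000002", "GO:0000001"))
  # diamond: the shared root appears once
  expect_setequal(closed$cellular_component$GB,
                  c("GO:0000013", "GO:0000011", "GO:0000012", "GO:0000010"))
  expect_equal(sum(closed$cellular_component$GB == "GO:0000010"), 1)
  # closure never removes an annotation
  for (nsp in names(raw))
    for (g in names(raw[[nsp]]))
      expect_true(all(raw[[nsp]][[g]] %in% closed[[nsp]][[g]]))
  # the namespace root accumulates every annotated gene
  sim <- simulate_ontology(synthetic_spec(n_hkg = 5, n_ce = 30, n_ie = 30,
                                          seed = 3))
  cl <- propagate_annotations(sim$dag, sim$annotations)
  root <- sim$dag$terms$id[sim$dag$terms$namespace == "cellular_component" &
                             !grepl("leaf|branch", sim$dag$terms$name)][1]
  has_root <- vapply(cl$cellular_component, function(t) root %in% t, TRUE)
  expect_true(all(has_root))
})

test_that("term enrichment ranks deterministically with correct contingencies", {
  # background of 20 genes, term T1 with m = 5, query = exactly those 5
  genes <- sprintf("g%02d", 1:20)
  ann <- annotation_map_from_long(
    gene = c(genes, genes[1:5]),
    term = c(rep("GO:0000002", 20), rep("GO:0000013", 5)),
    namespace = rep("biological_process", 25))
  res <- enrich_terms(genes[1:5], ann, "biological_process", fdr = FALSE)
  top <- res[res$id == "GO:0000013", ]
  expect_equal(top$N, 20); expect_equal(top$n, 5)
  expect_equal(top$m, 5); expect_equal(top$k, 5)
  expect_equal(top$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(top$rank, 1)
  # query = whole background: every term has k = m and p(ge) = 1
  all_res <- enrich_terms(genes, ann, "biological_process")
  expect_equal(all_res$k, all_res$m)
  expect_true(all(all_res$p_value == 1))
  # order invariance + deduplication
  res2 <- enrich_terms(rev(c(genes[1:5], genes[1:2])), ann,
                       "biological_process", fdr = FALSE)
  expect_equal(as.data.frame(res2), as.data.frame(res))
  expect_error(enrich_terms("absent", ann, "biological_process"),
               "disjoint.*absent")
})

test_that("pathway enrichment applies strict coverage and p-value thresholds", {
  pw <- structure(list(full = sprintf("q%02d", 1:10),
                       partial = c(sprintf("q%02d", 1:8), "x1", "x2"),
                       boundary = c(sprintf("q%02d", 1:4), "x3"),
                       other = sprintf("x%02d", 1:20)),
                  class = "pathway_collection")
  query <- sprintf("q%02d", 1:10)
  res <- enrich_pathways(query, pw, percent_min = 80, p_max = 1e-3)
  df <- as.data.frame(res)
  expect_equal(df$percent[df$id == "full"], 100)
  expect_equal(df$percent[df$id == "partial"], 80)
  # exactly 80% is NOT significant: threshold is strict
  expect_false(df$significant[df$id == "partial"])
  expect_equal(df$percent[df$id == "boundary"], 80)
  expect_false(df$significant[df$id == "boundary"])
  # and the fully covered pathway is, provided p clears the bar
  N <- df$N[1]; n <- df$n[1]
  p_full <- hypergeom_tail(10, N, 10, n)
  expect_equal(df$p_value[df$id == "full"], p_full, tolerance = 1e-12)
  expect_identical(df$significant[df$id == "full"], p_full < 1e-3)

  # brute-force pmf-sum check of the printed "gt" convention
  res_gt <- enrich_pathways(query, pw, tail = "gt")
  dfg <- as.data.frame(res_gt)
  k <- dfg$k[dfg$id == "partial"]; m <- dfg$m[dfg$id == "partial"]
  manual <- sum(vapply((k + 1):m, hypergeom_pmf, 0, N = N, m = m, n = n))
  expect_equal(dfg$p_value[dfg$id == "partial"], manual, tolerance = 1e-12)
})

test_that("planted enrichment signal is recovered from simulated data", {
  # balanced strata: pathway significance presumes the query is not a
  # dominant share of the pathway universe
  spec <- synthetic_spec(n_hkg = 20, n_ce = 600, n_ie = 600, seed = 8)
  sim <- simulate_matrix(spec)
  onto <- simulate_ontology(spec, sim$truth)
  closed <- propagate_annotations(onto$dag, onto$annotations)
  ce <- sim$truth$gene[sim$truth$stratum == "ce"]
  res <- enrich_terms(ce, closed, "cellular_component", dag = onto$dag)
  expect_lte(res$rank[res$id == onto$planted$ce_term], 3)
  # the planted pathway is flagged significant for the CE query
  pres <- enrich_pathways(ce, onto$pathways)
  prow <- as.data.frame(pres)[pres$id == onto$planted$ce_pathway, ]
  expect_gt(prow$percent, 80)
  expect_true(prow$significant)
})
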