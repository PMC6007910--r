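test_that("well-formed expression tables round-trip through write/read", {
  path <- write_tsv_lines(c("gene\tsC4\tsC5\tsC6\tsC8",
                            "GA\t5.1\t3.2\t7.7\t4.0",
                            "GB\t0\t2.1\t0\t0",
                            "GC\t100\t120\t90\t110"))
  m <- read_expression_table(path)
  expect_identical(dim(m), c(3L, 4L))
  expect_identical(rownames(m), c("GA", "GB", "GC"))
  expect_identical(colnames(m), c("sC4", "sC5", "sC6", "sC8"))
  expect_equal(m["GB", "sC5"], 2.1)

  # write -> read is the identity, bit for bit
  m2 <- simulate_matrix(synthetic_spec(n_hkg = 3, n_ce = 1, n_ie = 1,
                                       n_silenced_hkg = 1, seed = 7))$matrix
  f <- tempfile(fileext = ".tsv")
  write_expression_table(m2, f)
  expect_identical(read_expression_table(f), m2)
  expect_true(file.exists(paste0(f, ".json")))  # provenance sidecar
})

test_that("malformed expression tables are rejected with located errors", {
  neg <- write_tsv_lines(c("gene\tA\tB", "GA\t1\t2", "GB\t-1.0\t3"))
  expect_error(read_expression_table(neg), "negative FPKM.*GB.*A")
  txt <- write_tsv_lines(c("gene\tA\tB", "GA\t1\tx"))
  expect_error(read_expression_table(txt), "non-numeric.*'x'.*GA.*B")
  dup <- write_tsv_lines(c("gene\tA\tB", "GA\t1\t2", "GA\t5\t6"))
  expect_error(read_expression_table(dup), "duplicate gene symbols: GA")
})

test_that("duplicate policy 'max' keeps the row with largest mean FPKM", {
  dup <- write_tsv_lines(c("gene\tA\tB", "GA\t1\t2", "GB\t9\t9", "GA\t5\t6"))
  m <- read_expression_table(dup, duplicate_policy = "max")
  expect_identical(rownames(m), c("GA", "GB"))
  expect_equal(unname(m["GA", ]), c(5, 6))
})

test_that("expression matrix invariants are enforced", {
  m <- toy_matrix()
  expect_silent(validate_expression_matrix(m))
  bad <- m; bad[1, 1] <- -0.5
  expect_error(validate_expression_matrix(bad), "negative")
  bad <- m; bad[2, 3] <- NA
  expect_error(validate_expression_matrix(bad), "non-finite")
  expect_error(validate_expression_matrix(m[, 1, drop = FALSE]),
               "at least 2 libraries")
  nn <- m; rownames(nn) <- NULL
  expect_error(validate_expression_matrix(nn), "row names")
})

test_that("OBO 1.2 parsing collects terms, namespaces, edges and alt ids", {
  dag <- read_obo(fixture_obo())
  expect_equal(nrow(dag$terms), 8)
  expect_equal(sort(as.integer(table(dag$terms$namespace))), c(2, 2, 4))
  expect_setequal(ontology_ancestors(dag, "GO:0000002"), "GO:0000001")
  # diamond: both mids and the shared root, root counted once
  expect_setequal(ontology_ancestors(dag, "GO:0000013"),
                  c("GO:0000011", "GO:0000012", "GO:0000010"))
  expect_identical(resolve_term_id(dag, c("GO:0000099", "GO:0000001", "nope")),
                   c("GO:0000013", "GO:0000001", NA))
  # obsolete terms are flagged and carry no propagation edges
  expect_true(dag$terms$obsolete[dag$terms$id == "GO:0000021"])
  expect_length(ontology_ancestors(dag, "GO:0000021"), 0)
})

test_that("OBO errors: cycles and missing namespaces are fatal", {
  cyc <- write_tsv_lines(c(
    "[Term]", "id: A", "name: a", "namespace: biological_process", "is_a: B",
    "", "[Term]", "id: B", "name: b", "namespace: biological_process",
    "is_a: A"), ext = ".obo")
  expect_error(read_obo(cyc), "cycle")
  nons <- write_tsv_lines(c("[Term]", "id: A", "name: a"), ext = ".obo")
  expect_error(read_obo(nons), "namespace")
})

test_that("ancestor sets are transitively closed (brute-force oracle)", {
  dag <- simulate_ontology(synthetic_spec(n_hkg = 5, n_ce = 20, n_ie = 20,
                                          seed = 11))$dag
  expect_lte(nrow(dag$terms), 100)
  for (id in sample(dag$terms$id, 10)) {
    anc <- ontology_ancestors(dag, id)
    expect_identical(sort(anc), brute_ancestors(dag, id))
    for (a in anc)
      expect_true(all(ontology_ancestors(dag, a) %in% anc))
  }
})

test_that("gene2go reading filters taxon and NOT qualifiers, set semantics", {
  dag <- read_obo(fixture_obo())
  ann <- read_gene2go(fixture_gene2go(), taxon = 9606, dag = dag)
  expect_identical(names(ann$biological_process), "GA")
  expect_identical(ann$biological_process$GA, "GO:0000002")
  # duplicate annotation collapsed; NOT row and mouse rows absent
  expect_identical(ann$cellular_component$GB, "GO:0000013")
  expect_false("GC" %in% names(ann$cellular_component))
  expect_false("GD" %in% names(ann$biological_process))
  # malformed rows are skipped with a warning and counted
  bad <- write_tsv_lines(c(readLines(fixture_gene2go()), "9606\tonly_two"))
  expect_warning(ann2 <- read_gene2go(bad, taxon = 9606), "malformed")
  expect_gte(attr(ann2, "n_skipped"), 1)
})

test_that("GMT reading/writing round-trips and rejects degenerate input", {
  pc <- read_gmt(fixture_gmt())
  expect_length(pc, 2)
  expect_equal(lengths(pc), c(pw_small = 3L, pw_large = 5L))
  f <- tempfile(fileext = ".gmt")
  write_gmt(pc, f)
  pc2 <- read_gmt(f)
  expect_equal(pc2, pc)

  expect_error(read_gmt(write_tsv_lines("lonely\tdesc")), "no members")
  expect_error(read_gmt(write_tsv_lines(c("pw\td\tGA", "pw\td\tGB"))),
               "duplicate pathway")
})

test_that("gene lists drop blanks, comments and duplicates", {
  f <- write_tsv_lines(c("# housekeeping panel", "GAPDH", "", "ACTB", "GAPDH"))
  gl <- read_gene_list(f, name = "hkg")
  expect_identical(as.character(gl), c("GAPDH", "ACTB"))
  expect_error(read_gene_list(write_tsv_lines("#only comment")), "empty")
})
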