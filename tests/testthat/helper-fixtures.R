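# In-code fixtures shared across the suite. Everything is generated at test
# time; nothing is read from disk except files these helpers write to
# tempdir().

mat4 <- function(values, genes, libs = NULL) {
  m <- if (is.matrix(values)) values else
    matrix(values, nrow = length(genes), byrow = TRUE)
  if (is.null(libs)) libs <- paste0("L", seq_len(ncol(m)))
  dimnames(m) <- list(genes, libs)
  validate_expression_matrix(m)
  m
}

# a 5-gene, 4-library toy matrix: 2 consistent, 2 inconsistent, 1 silent
toy_matrix <- function() {
  mat4(rbind(c(5.1, 3.2, 7.7, 4.0),
             c(100, 120, 90, 110),
             c(0, 2.1, 0, 0),
             c(1.5, 0, 2.0, 0.5),
             c(0, 0, 0, 0)),
       genes = c("GA", "GB", "GC", "GD", "GE"))
}

write_tsv_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# minimal OBO 1.2 document: three namespaces, a diamond motif in
# cellular_component, one obsolete term, one alt_id
fixture_obo <- function() {
  write_tsv_lines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: bp root",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: bp child",
    "namespace: biological_process",
    "is_a: GO:0000001 ! bp root",
    "",
    "[Term]",
    "id: GO:0000010",
    "name: cc root",
    "namespace: cellular_component",
    "",
    "[Term]",
    "id: GO:0000011",
    "name: cc mid a",
    "namespace: cellular_component",
    "is_a: GO:0000010",
    "",
    "[Term]",
    "id: GO:0000012",
    "name: cc mid b",
    "namespace: cellular_component",
    "is_a: GO:0000010",
    "",
    "[Term]",
    "id: GO:0000013",
    "name: cc diamond leaf",
    "namespace: cellular_component",
    "alt_id: GO:0000099",
    "is_a: GO:0000011",
    "is_a: GO:0000012",
    "",
    "[Term]",
    "id: GO:0000020",
    "name: mf root",
    "namespace: molecular_function",
    "",
    "[Term]",
    "id: GO:0000021",
    "name: retired mf term",
    "namespace: molecular_function",
    "is_obsolete: true"
  ), ext = ".obo")
}

fixture_gene2go <- function() {
  row <- function(tax, gene, go, qual, cat)
    paste(tax, gene, go, "IEA", qual, "term", "-", cat, sep = "\t")
  write_tsv_lines(c(
    "#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory",
    row(9606, "GA", "GO:0000002", "-", "Process"),
    row(9606, "GB", "GO:0000013", "-", "Component"),
    row(9606, "GB", "GO:0000013", "-", "Component"),  # duplicate annotation
    row(9606, "GC", "GO:0000011", "NOT", "Component"),
    row(10090, "GD", "GO:0000002", "-", "Process"),
    row(10090, "GE", "GO:0000013", "-", "Component")
  ))
}

fixture_gmt <- function() {
  write_tsv_lines(c(
    "pw_small\tdesc\tGA\tGB\tGC",
    "pw_large\tdesc\tGA\tGB\tGC\tGD\tGE"
  ), ext = ".gmt")
}

# Independent oracle: hypergeometric tail by exhaustive enumeration of all
# C(N, n) draws from a population with m annotated members.
brute_hyper_tail <- function(k, N, m, n, tail = "ge") {
  if (n == 0) return(as.numeric(if (tail == "ge") k <= 0 else k < 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= m)          # annotated = elements 1..m
  if (tail == "ge") mean(hits >= k) else mean(hits > k)
}

# Independent oracle: ancestor sets by brute-force closure of the edge list.
brute_ancestors <- function(dag, id) {
  edges <- do.call(rbind, lapply(names(dag$parents), function(ch) {
    if (length(dag$parents[[ch]]) == 0) return(NULL)
    cbind(ch, dag$parents[[ch]])
  }))
  anc <- character()
  frontier <- id
  repeat {
    nxt <- setdiff(edges[edges[, 1] %in% frontier, 2], anc)
    if (length(nxt) == 0) break
    anc <- c(anc, nxt)
    frontier <- nxt
  }
  sort(anc)
}
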