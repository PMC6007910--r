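#' Validate a gene-by-library FPKM matrix
#'
#' The expression matrix is the pipeline's primary input: a base numeric
#' matrix with unique gene symbols as row names and unique library names as
#' column names, holding non-negative finite FPKM values. Undetected genes
#' carry an explicit 0, never `NA`.
#'
#' @param x numeric matrix, genes x libraries.
#' @param min_libraries minimum number of library columns required
#'   (consistency analysis needs at least 2).
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x, min_libraries = 2L) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene row names and library column names",
         call. = FALSE)
  if (ncol(x) < min_libraries)
    stop(sprintf("at least %d libraries are required, got %d",
                 min_libraries, ncol(x)), call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene symbols: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate library names", call. = FALSE)
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite or negative FPKM at gene '%s', library '%s'",
                 rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]]), call. = FALSE)
  invisible(x)
}

#' Construct an expression matrix from values and names
#'
#' @param values numeric matrix or data frame of FPKM values.
#' @param gene_ids,library_ids optional dimension names; taken from `values`
#'   when omitted.
#' @return validated numeric matrix (genes x libraries).
#' @export
expression_matrix <- function(values, gene_ids = NULL, library_ids = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (!is.null(gene_ids)) rownames(m) <- gene_ids
  if (!is.null(library_ids)) colnames(m) <- library_ids
  validate_expression_matrix(m)
  m
}

#' Read a gene-by-library FPKM table
#'
#' Plain UTF-8 TSV: header row of library names, first column of gene
#' symbols, numeric FPKM body. Gene symbol matching throughout the package
#' is case-sensitive and exact; duplicate gene rows indicate upstream
#' annotation collisions and are an error by default.
#'
#' @param path path to the TSV file.
#' @param duplicate_policy `"error"` (default) rejects duplicated gene
#'   symbols; `"max"` keeps, per symbol, the row with the largest mean FPKM.
#' @return validated expression matrix.
#' @export
read_expression_table <- function(path, duplicate_policy = c("error", "max")) {
  duplicate_policy <- match.arg(duplicate_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL)
  if (ncol(df) < 3)
    stop("expression table needs a gene column and >= 2 library columns",
         call. = FALSE)
  genes <- df[[1]]
  libs <- colnames(df)[-1]
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric FPKM value '%s' at gene '%s', library '%s'",
                 body[bad[1, 1], bad[1, 2]], genes[bad[1, 1]], libs[bad[1, 2]]),
         call. = FALSE)
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative FPKM at gene '%s', library '%s'",
                 genes[neg[1, 1]], libs[neg[1, 2]]), call. = FALSE)
  if (anyDuplicated(genes)) {
    if (duplicate_policy == "error")
      stop("duplicate gene symbols: ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "),
           call. = FALSE)
    keep <- order(genes, -rowMeans(num))
    num <- num[keep, , drop = FALSE]
    genes <- genes[keep]
    first <- !duplicated(genes)
    num <- num[first, , drop = FALSE]
    genes <- genes[first]
    # restore original encounter order of the surviving symbols
    ord <- order(match(genes, df[[1]]))
    num <- num[ord, , drop = FALSE]
    genes <- genes[ord]
  }
  rownames(num) <- genes
  colnames(num) <- libs
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix as TSV with a provenance sidecar
#'
#' Emits `gene<TAB>lib1<TAB>...` with full numeric precision, plus
#' `<path>.json` recording provenance (written file hash is of the TSV).
#'
#' @param x validated expression matrix.
#' @param path output TSV path.
#' @param provenance optional named list merged into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, provenance = list()) {
  validate_expression_matrix(x)
  # %.17g keeps the decimal representation exact, so read-back is identity
  body <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  df <- data.frame(gene = rownames(x), body, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(path, c(list(format = "expression_table",
                             n_genes = nrow(x), n_libraries = ncol(x)),
                        provenance))
  invisible(path)
}

write_sidecar <- function(path, fields) {
  side <- c(list(file = basename(path),
                 md5 = unname(tools::md5sum(path)),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            fields)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' Blank lines and lines starting with `#` are ignored; duplicates are
#' collapsed. Used for housekeeping-gene reference panels.
#'
#' @param path file path.
#' @param name label for the list (defaults to the file name).
#' @return character vector of unique symbols with attribute `"name"`.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  x <- unique(x)
  if (length(x) == 0)
    stop("gene list '", name, "' is empty", call. = FALSE)
  attr(x, "name") <- name
  x
}

# ---------------------------------------------------------------------------
# OBO 1.2 ontology
# ---------------------------------------------------------------------------

#' Parse an OBO 1.2 ontology into a DAG
#'
#' Reads `[Term]` stanzas: `id`, `name`, `namespace`, `is_a`, `alt_id`,
#' `is_obsolete`. Only `is_a` edges are collected by default (other
#' relationships such as `part_of` may be requested); obsolete terms are
#' retained but flagged and carry no edges for propagation. The edge set is
#' verified acyclic on load.
#'
#' @param path path to an OBO 1.2 file.
#' @param relationships relationship tags to treat as parent edges, in
#'   addition to `is_a` (e.g. `"part_of"`); default none.
#' @return an object of class `ontology_dag`: list with `terms` (data frame
#'   id/name/namespace/obsolete), `parents` (named list id -> parent ids) and
#'   `alt_ids` (named character, alternate -> primary).
#' @export
read_obo <- function(path, relationships = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (length(starts) == 0) stop("no stanzas found in OBO file", call. = FALSE)
  ends <- c(starts[-1] - 1L, length(lines))
  ids <- character(); names_ <- character(); ns <- character(); obs <- logical()
  parents <- list(); alt_from <- character(); alt_to <- character()
  for (s in seq_along(starts)) {
    if (lines[starts[s]] != "[Term]") next
    block <- lines[(starts[s] + 1L):ends[s]]
    block <- block[nzchar(block)]
    kv <- regmatches(block, regexpr(":", block), invert = TRUE)
    keys <- vapply(kv, function(p) trimws(p[1]), "")
    vals <- vapply(kv, function(p) if (length(p) > 1) trimws(p[2]) else "", "")
    # strip trailing comments ("GO:x ! name")
    vals <- sub("\\s*!.*$", "", vals)
    id <- vals[keys == "id"][1]
    if (is.na(id)) stop("term stanza without id", call. = FALSE)
    nm <- vals[keys == "name"][1]
    nsp <- vals[keys == "namespace"][1]
    if (is.na(nsp))
      stop("term ", id, " has no namespace", call. = FALSE)
    obsolete <- any(keys == "is_obsolete" & vals == "true")
    ids <- c(ids, id); names_ <- c(names_, if (is.na(nm)) "" else nm)
    ns <- c(ns, nsp); obs <- c(obs, obsolete)
    par <- vals[keys == "is_a"]
    if (length(relationships) > 0) {
      rel <- vals[keys == "relationship"]
      if (length(rel) > 0) {
        rp <- strsplit(rel, "\\s+")
        keep <- vapply(rp, function(p) p[1] %in% relationships, TRUE)
        par <- c(par, vapply(rp[keep], function(p) p[2], ""))
      }
    }
    parents[[id]] <- if (obsolete) character() else unique(par)
    av <- vals[keys == "alt_id"]
    if (length(av) > 0) {
      alt_from <- c(alt_from, av)
      alt_to <- c(alt_to, rep(id, length(av)))
    }
  }
  known_ns <- c("biological_process", "cellular_component", "molecular_function")
  if (!all(ns %in% known_ns))
    stop("unknown namespace: ", paste(setdiff(ns, known_ns), collapse = ", "),
         call. = FALSE)
  dangling <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(dangling) > 0)
    stop("is_a edge to unknown term(s): ", paste(dangling, collapse = ", "),
         call. = FALSE)
  dag <- structure(
    list(terms = data.frame(id = ids, name = names_, namespace = ns,
                            obsolete = obs, stringsAsFactors = FALSE),
         parents = parents,
         alt_ids = stats::setNames(alt_to, alt_from)),
    class = "ontology_dag")
  assert_acyclic(dag)
  dag
}

# Kahn's algorithm on the child -> parent edge list; stops on a cycle.
assert_acyclic <- function(dag) {
  out_deg <- lengths(dag$parents)                 # edges child -> parent
  children <- split(rep(names(dag$parents), lengths(dag$parents)),
                    unlist(dag$parents, use.names = FALSE))
  queue <- names(out_deg)[out_deg == 0]
  head <- 1L; seen <- 0L
  while (head <= length(queue)) {
    v <- queue[[head]]; head <- head + 1L; seen <- seen + 1L
    for (ch in children[[v]]) {
      out_deg[[ch]] <- out_deg[[ch]] - 1L
      if (out_deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(dag$parents))
    stop("ontology contains a cycle", call. = FALSE)
  invisible(dag)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms (%d obsolete), %d is_a edges\n",
              nrow(x$terms), sum(x$terms$obsolete),
              sum(lengths(x$parents))))
  print(table(x$terms$namespace))
  invisible(x)
}

#' Resolve a term id through the alternate-id table
#'
#' @param dag an `ontology_dag`.
#' @param ids character vector of term ids.
#' @return primary term ids; `NA` where unresolvable.
#' @export
resolve_term_id <- function(dag, ids) {
  alt <- dag$alt_ids[ids]
  out <- ifelse(is.na(alt), ids, alt)
  out[!(out %in% dag$terms$id)] <- NA_character_
  unname(out)
}

#' All is_a ancestors of a term
#'
#' Transitive closure over parent edges; excludes the term itself. Obsolete
#' terms have no ancestors (they carry no propagation edges).
#'
#' @param dag an `ontology_dag`.
#' @param id a single primary term id.
#' @return character vector of ancestor ids (possibly empty).
#' @export
ontology_ancestors <- function(dag, id) {
  if (!(id %in% names(dag$parents)))
    stop("unknown term: ", id, call. = FALSE)
  seen <- character()
  frontier <- dag$parents[[id]]
  while (length(frontier) > 0) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(dag$parents[new], use.names = FALSE))
  }
  seen
}

# ---------------------------------------------------------------------------
# NCBI gene2go annotations
# ---------------------------------------------------------------------------

.g2g_namespace <- c(Process = "biological_process",
                    Component = "cellular_component",
                    Function = "molecular_function")

#' Read an NCBI gene2go annotation file
#'
#' Expects the NCBI tab format (`tax_id`, `GeneID`, `GO_ID`, `Evidence`,
#' `Qualifier`, `GO_term`, `PubMed`, `Category`), optionally gzipped, with or
#' without the leading `#` header line. Rows whose Qualifier contains `NOT`
#' are skipped, as are rows for other taxa. The default expects the GeneID
#' column to carry gene symbols (a pre-mapped file); supply `symbol_map`
#' (named character, GeneID -> symbol) to adapt a raw NCBI file.
#'
#' @param path file path (plain or `.gz`).
#' @param taxon taxon id to retain (e.g. `9606`); `NULL` keeps all rows.
#' @param symbol_map optional named character vector mapping the GeneID
#'   column to gene symbols; unmapped rows are dropped and counted.
#' @param dag optional `ontology_dag` used to resolve alternate ids and drop
#'   annotations to unknown terms (with a warning).
#' @return an object of class `annotation_map`: list of three named lists
#'   (`biological_process`, `cellular_component`, `molecular_function`), each
#'   mapping gene symbol -> character vector of term ids, with attributes
#'   `provenance` and `n_skipped`.
#' @export
read_gene2go <- function(path, taxon = NULL, symbol_map = NULL, dag = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE); close(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  skipped <- sum(lengths(fields) < 8)
  if (skipped > 0)
    warning(skipped, " malformed gene2go row(s) skipped")
  fields <- fields[lengths(fields) >= 8]
  tab <- do.call(rbind, fields)
  if (is.null(tab)) tab <- matrix(character(), ncol = 8)
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(taxon)) keep <- keep & tab[, 1] == as.character(taxon)
  keep <- keep & !grepl("NOT", tab[, 5], fixed = TRUE)
  tab <- tab[keep, , drop = FALSE]
  gene <- tab[, 2]
  if (!is.null(symbol_map)) {
    gene <- unname(symbol_map[gene])
    mapped <- !is.na(gene)
    skipped <- skipped + sum(!mapped)
    tab <- tab[mapped, , drop = FALSE]; gene <- gene[mapped]
  }
  term <- tab[, 3]
  nsp <- unname(.g2g_namespace[tab[, 8]])
  if (anyNA(nsp))
    stop("unknown gene2go Category: ",
         paste(unique(tab[is.na(nsp), 8]), collapse = ", "), call. = FALSE)
  if (!is.null(dag)) {
    res <- resolve_term_id(dag, term)
    drop <- is.na(res)
    if (any(drop))
      warning(sum(drop), " annotation(s) to unknown term ids dropped")
    gene <- gene[!drop]; nsp <- nsp[!drop]; term <- res[!drop]
    skipped <- skipped + sum(drop)
  }
  annotation_map_from_long(gene, term, nsp,
                           provenance = basename(path),
                           taxon = taxon, n_skipped = skipped)
}

annotation_map_from_long <- function(gene, term, namespace,
                                     provenance = NA_character_,
                                     taxon = NULL, n_skipped = 0L) {
  out <- lapply(unname(.g2g_namespace), function(n) {
    i <- namespace == n
    if (!any(i)) return(structure(list(), names = character()))
    lapply(split(term[i], gene[i]), unique)
  })
  names(out) <- unname(.g2g_namespace)
  structure(out, class = "annotation_map", provenance = provenance,
            taxon = taxon, n_skipped = n_skipped)
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map:",
      paste(sprintf("%s: %d genes", names(x), lengths(x)), collapse = ", "),
      "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# GMT pathway gene sets
# ---------------------------------------------------------------------------

#' Read GMT gene sets
#'
#' One set per tab-separated line: name, description, member genes. Empty
#' member lists and duplicate pathway names are rejected.
#'
#' @param path file path.
#' @return object of class `pathway_collection`: named list of character
#'   member vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short))
    stop("GMT line(s) with no members: ",
         paste(vapply(fields[short], `[`, "", 1), collapse = ", "),
         call. = FALSE)
  nm <- vapply(fields, `[`, "", 1)
  if (anyDuplicated(nm))
    stop("duplicate pathway name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  structure(sets, class = "pathway_collection",
            descriptions = stats::setNames(vapply(fields, `[`, "", 2), nm))
}

#' Write GMT gene sets
#'
#' @param x a `pathway_collection` (or plain named list of character vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  desc <- attr(x, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(x)), names(x))
  lines <- vapply(names(x), function(n)
    paste(c(n, desc[[n]], x[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways, %d-%d members\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}
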