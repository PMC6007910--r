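#' Upper-tail hypergeometric probability
#'
#' Exact tail probability for drawing `k` annotated genes when `n` genes are
#' sampled without replacement from a background of `N` genes of which `m`
#' are annotated to the term or pathway:
#' \deqn{P[X \ge k] = \sum_{i=k}^{\min(n,m)}
#'   \binom{m}{i}\binom{N-m}{n-i} / \binom{N}{n}.}
#' Terms are accumulated in log space (via `lchoose`) for numerical
#' stability at large `N`. Two tail conventions are provided: `"ge"`
#' (\eqn{P[X \ge k]}, the conventional over-representation p-value, default)
#' and `"gt"` (\eqn{P[X > k]}, the sum starting at `k + 1`).
#'
#' @param k observed count of query genes annotated to the term.
#' @param N background size; `m` annotated genes in background; `n` query
#'   genes within background.
#' @param m,n see above.
#' @param tail `"ge"` or `"gt"`.
#' @return tail probability in \[0, 1\].
#' @export
hypergeom_tail <- function(k, N, m, n, tail = c("ge", "gt")) {
  tail <- match.arg(tail)
  stopifnot(length(k) == 1, length(N) == 1, length(m) == 1, length(n) == 1)
  if (any(c(k, N, m, n) < 0) || any(c(k, N, m, n) != floor(c(k, N, m, n))))
    stop("k, N, m, n must be non-negative integers", call. = FALSE)
  if (m > N || n > N || k > min(n, m))
    stop(sprintf("invalid contingency: k=%d, N=%d, m=%d, n=%d", k, N, m, n),
         call. = FALSE)
  lo <- if (tail == "ge") k else k + 1L
  hi <- min(n, m)
  if (lo > hi) return(0)
  i <- lo:hi
  logp <- lchoose(m, i) + lchoose(N - m, n - i) - lchoose(N, n)
  # log-sum-exp, then clamp the float sum into [0, 1]
  mx <- max(logp)
  min(1, exp(mx) * sum(exp(logp - mx)))
}

#' Hypergeometric point mass
#'
#' Probability of exactly `k` annotated genes in the query, on the same
#' parameterisation as [hypergeom_tail()]. Used for the tail accumulation's
#' property checks.
#'
#' @inheritParams hypergeom_tail
#' @return probability in \[0, 1\].
#' @export
hypergeom_pmf <- function(k, N, m, n) {
  if (k > min(n, m) || k < max(0, n - (N - m))) return(0)
  exp(lchoose(m, k) + lchoose(N - m, n - k) - lchoose(N, n))
}

#' Propagate annotations up the ontology DAG
#'
#' Closes each gene's term set under is_a ancestry within the term's
#' namespace: a gene annotated to a specific term is implicitly annotated to
#' every more general ancestor. Set semantics (no multiplicity); annotations
#' to unknown terms are skipped with a warning. The closed map is always a
#' superset of the raw map.
#'
#' @param dag an `ontology_dag`.
#' @param annotations an `annotation_map`.
#' @return a new `annotation_map` closed over ancestors.
#' @export
propagate_annotations <- function(dag, annotations) {
  # memoised ancestors-including-self per term
  cache <- new.env(parent = emptyenv())
  up <- function(id) {
    if (!is.null(cache[[id]])) return(cache[[id]])
    res <- c(id, ontology_ancestors(dag, id))
    cache[[id]] <- res
    res
  }
  ns_of <- stats::setNames(dag$terms$namespace, dag$terms$id)
  skipped <- 0L
  out <- lapply(names(annotations), function(nsp) {
    genes <- annotations[[nsp]]
    closed <- lapply(genes, function(terms) {
      terms <- resolve_term_id(dag, terms)
      unknown <- is.na(terms)
      skipped <<- skipped + sum(unknown)
      terms <- terms[!unknown]
      terms <- terms[ns_of[terms] == nsp]
      if (length(terms) == 0) return(character())
      unique(unlist(lapply(terms, up), use.names = FALSE))
    })
    closed[lengths(closed) > 0]
  })
  names(out) <- names(annotations)
  if (skipped > 0)
    warning(skipped, " annotation(s) to unknown terms skipped")
  structure(out, class = "annotation_map",
            provenance = attr(annotations, "provenance"),
            taxon = attr(annotations, "taxon"),
            n_skipped = attr(annotations, "n_skipped"),
            propagated = TRUE)
}

rank_results <- function(df) {
  if (nrow(df) == 0) { df$rank <- integer(); return(df) }
  ord <- order(df$p_value, -df$k, df$id)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' GO term over-representation for a query gene set
#'
#' For every term of the chosen namespace with at least one query gene
#' annotated, tests whether the query contains more annotated genes than
#' expected under sampling without replacement from the background. The
#' background `N` is the set of genes annotated in that namespace (the
#' domain's annotation file), not the whole genome; query genes outside the
#' background are dropped and reported. Results are ranked ascending by
#' p-value with deterministic tie-breaking (larger `k` first, then term id).
#'
#' @param query character vector of query gene symbols (deduplicated).
#' @param annotations an `annotation_map`, normally propagated through
#'   [propagate_annotations()].
#' @param namespace one of `"biological_process"`, `"cellular_component"`,
#'   `"molecular_function"`.
#' @param dag optional `ontology_dag` used to attach term names.
#' @param tail tail convention, see [hypergeom_tail()].
#' @param min_k terms with fewer than `min_k` query genes are omitted
#'   (default 1: terms never hit by the query are uninformative, p = 1).
#' @param fdr add a Benjamini-Hochberg adjusted column (an extension beyond
#'   raw-p ranking; default `TRUE`).
#' @return object of class `enrichment_result`: data frame with columns id,
#'   name, namespace, N, n, m, k, percent (100 k / m), p_value, rank (and
#'   p_adjust when `fdr`), plus attributes `dropped_query` and `tail`.
#' @export
enrich_terms <- function(query, annotations, namespace, dag = NULL,
                         tail = c("ge", "gt"), min_k = 1L, fdr = TRUE) {
  tail <- match.arg(tail)
  if (!namespace %in% names(annotations))
    stop("unknown namespace: ", namespace, call. = FALSE)
  genes <- annotations[[namespace]]
  background <- names(genes)
  query <- unique(as.character(query))
  in_bg <- query %in% background
  if (!any(in_bg))
    stop("query disjoint from annotated background; unmatched: ",
         paste(utils::head(query, 10), collapse = ", "),
         if (length(query) > 10) ", ..." else "", call. = FALSE)
  dropped <- query[!in_bg]
  query <- query[in_bg]
  N <- length(background)
  n <- length(query)
  term_genes <- split(rep(background, lengths(genes)),
                      unlist(genes, use.names = FALSE))
  m_all <- lengths(term_genes)
  k_all <- vapply(term_genes, function(g) sum(g %in% query), 0L)
  keep <- k_all >= min_k
  ids <- names(term_genes)[keep]
  m <- unname(m_all[keep]); k <- unname(k_all[keep])
  p <- vapply(seq_along(ids), function(i)
    hypergeom_tail(k[i], N, m[i], n, tail = tail), 0)
  nm <- if (!is.null(dag))
    dag$terms$name[match(ids, dag$terms$id)] else NA_character_
  df <- data.frame(id = ids, name = nm, namespace = namespace,
                   N = N, n = n, m = m, k = k,
                   percent = 100 * k / m, p_value = p,
                   stringsAsFactors = FALSE)
  df <- rank_results(df)
  if (fdr) df$p_adjust <- stats::p.adjust(df$p_value, method = "BH")
  structure(df, class = c("enrichment_result", "data.frame"),
            dropped_query = dropped, tail = tail)
}

#' Pathway over-representation with coverage filtering
#'
#' Tests each pathway for over-representation of the query among its
#' members and reports the gene coverage rate `percent = 100 k / m`. The
#' background `N` is the set of genes appearing in the pathway collection;
#' `n` is the query intersected with it. Pathways are flagged significant
#' when `percent > percent_min` AND `p_value < p_max` (both strict, so a
#' coverage of exactly `percent_min` does not qualify); all pathways with at
#' least one query member are retained in the output with the flag.
#'
#' @param query character vector of query gene symbols.
#' @param pathways a `pathway_collection` (named list of member vectors).
#' @param percent_min coverage threshold in percent (default 80).
#' @param p_max p-value threshold (default 1e-3).
#' @inheritParams enrich_terms
#' @return object of class `enrichment_result`: data frame with columns id,
#'   name, namespace (`"pathway"`), N, n, m, k, percent, p_value,
#'   significant, rank (and p_adjust), attributes as in [enrich_terms()].
#' @export
enrich_pathways <- function(query, pathways, percent_min = 80, p_max = 1e-3,
                            tail = c("ge", "gt"), min_k = 1L, fdr = TRUE) {
  tail <- match.arg(tail)
  if (length(pathways) == 0) stop("pathway collection is empty", call. = FALSE)
  sets <- lapply(pathways, unique)
  background <- unique(unlist(sets, use.names = FALSE))
  query <- unique(as.character(query))
  dropped <- setdiff(query, background)
  query <- intersect(query, background)
  if (length(query) == 0)
    stop("query disjoint from pathway background", call. = FALSE)
  N <- length(background); n <- length(query)
  m <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, query)), 0L)
  keep <- k >= min_k
  df <- data.frame(id = names(sets)[keep], name = names(sets)[keep],
                   namespace = "pathway", N = N, n = n,
                   m = unname(m[keep]), k = unname(k[keep]),
                   stringsAsFactors = FALSE)
  df$percent <- 100 * df$k / df$m
  df$p_value <- vapply(seq_len(nrow(df)), function(i)
    hypergeom_tail(df$k[i], N, df$m[i], n, tail = tail), 0)
  df$significant <- df$percent > percent_min & df$p_value < p_max
  df <- rank_results(df)
  if (fdr) df$p_adjust <- stats::p.adjust(df$p_value, method = "BH")
  structure(df, class = c("enrichment_result", "data.frame"),
            dropped_query = dropped, tail = tail,
            percent_min = percent_min, p_max = p_max)
}

#' @export
print.enrichment_result <- function(x, n = 10, ...) {
  cat(sprintf("enrichment_result: %d tested (tail '%s', N = %d, n = %d)\n",
              nrow(x), attr(x, "tail"),
              if (nrow(x)) x$N[1] else NA, if (nrow(x)) x$n[1] else NA))
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' Write an enrichment result as TSV with a JSON parameter summary
#'
#' @param x an `enrichment_result`.
#' @param path output TSV path.
#' @param extra named list merged into the JSON sidecar (e.g. a config hash).
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path, extra = list()) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_sidecar(path, c(extra, list(
    format = "enrichment_result",
    tail = attr(x, "tail"),
    percent_min = attr(x, "percent_min"),
    p_max = attr(x, "p_max"),
    background = if (nrow(x)) x$N[1] else NA,
    query_in_background = if (nrow(x)) x$n[1] else NA,
    dropped_query = length(attr(x, "dropped_query")))))
  invisible(path)
}
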