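#' Specification for the synthetic expression generator
#'
#' Describes a seeded gene-by-library FPKM matrix with three gene strata
#' emulating the structure the consistency analysis assumes:
#' a housekeeping-like stratum (high expression, low fluctuation, including
#' a small number of fully silenced control genes), a consistently expressed
#' stratum (mid expression), and an inconsistently expressed stratum (low
#' expression with per-library dropout).
#'
#' Per-gene base expression is log-normal around the stratum's log10
#' location `mu` with log10 spread `base_sd`; per-library values multiply the
#' base by mean-one log-normal noise whose coefficient of variation is
#' `noise_cv` (log-scale sd `sqrt(log(1 + cv^2))`). Inconsistent genes
#' receive independent Bernoulli(`p_detect`) per-library detection masks,
#' redrawn (rejection, preserving exchangeability across libraries) until the
#' mask is neither all-true nor all-false, so every such gene is genuinely
#' inconsistent. Silenced housekeeping genes are all-zero.
#'
#' @param n_libraries number of libraries (columns), >= 2.
#' @param n_hkg,n_ce,n_ie stratum sizes.
#' @param n_silenced_hkg how many housekeeping genes are fully silenced.
#' @param mu log10 expression locations, named hkg/ce/ie. The defaults place
#'   the strata at roughly 10^3.2, 10^1.9 and 10^0 FPKM.
#' @param base_sd per-stratum log10 sd of the gene base expression.
#' @param noise_cv per-stratum CV of the multiplicative library noise.
#' @param p_detect per-library detection probability for inconsistent genes,
#'   in (0, 1).
#' @param seed integer RNG seed; the matrix generator uses `seed` and the
#'   ontology generator `seed + 1`, so partial re-runs are stable.
#' @return object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_libraries = 4L, n_hkg = 143L, n_ce = 2000L,
                           n_ie = 2000L, n_silenced_hkg = 1L,
                           mu = c(hkg = 3.2, ce = 1.9, ie = 0.0),
                           base_sd = c(hkg = 0.15, ce = 0.20, ie = 0.20),
                           noise_cv = c(hkg = 0.4, ce = 0.9, ie = 0.5),
                           p_detect = 0.5, seed = 1L) {
  spec <- list(n_libraries = as.integer(n_libraries),
               n_hkg = as.integer(n_hkg), n_ce = as.integer(n_ce),
               n_ie = as.integer(n_ie),
               n_silenced_hkg = as.integer(n_silenced_hkg),
               mu = mu[c("hkg", "ce", "ie")],
               base_sd = base_sd[c("hkg", "ce", "ie")],
               noise_cv = noise_cv[c("hkg", "ce", "ie")],
               p_detect = p_detect, seed = as.integer(seed))
  if (spec$n_libraries < 2) stop("need >= 2 libraries", call. = FALSE)
  if (any(c(spec$n_hkg, spec$n_ce, spec$n_ie, spec$n_silenced_hkg) < 0))
    stop("stratum sizes must be >= 0", call. = FALSE)
  if (spec$n_silenced_hkg > spec$n_hkg)
    stop("more silenced housekeeping genes than housekeeping genes",
         call. = FALSE)
  if (anyNA(spec$mu) || anyNA(spec$base_sd) || anyNA(spec$noise_cv) ||
      any(spec$base_sd < 0) || any(spec$noise_cv < 0))
    stop("mu, base_sd, noise_cv must be named hkg/ce/ie, sds and CVs >= 0",
         call. = FALSE)
  if (!(p_detect > 0 && p_detect < 1))
    stop("p_detect must lie strictly in (0, 1)", call. = FALSE)
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_spec: %d libraries; strata hkg=%d (silenced %d), ce=%d, ie=%d\n",
    x$n_libraries, x$n_hkg, x$n_silenced_hkg, x$n_ce, x$n_ie))
  cat(sprintf("  mu(log10) %s | base_sd %s | noise_cv %s | p_detect %.2f | seed %d\n",
              paste(x$mu, collapse = "/"), paste(x$base_sd, collapse = "/"),
              paste(x$noise_cv, collapse = "/"), x$p_detect, x$seed))
  invisible(x)
}

#' Analytic target group means implied by a synthetic spec
#'
#' The expected per-gene mean FPKM in each stratum: `10^mu *
#' exp((base_sd * ln 10)^2 / 2)` (library noise has mean one), times, for the
#' inconsistent stratum, the expected detected fraction of a
#' Bernoulli(`p_detect`) mask conditioned on being neither all-true nor
#' all-false. Silenced housekeeping genes are excluded from the hkg target
#' (group means are computed over expressed genes).
#'
#' @param spec a `synthetic_spec`.
#' @return named numeric vector `c(hkg, ce, ie)` of expected group mean FPKM.
#' @export
target_means <- function(spec) {
  e_base <- 10^spec$mu * exp((spec$base_sd * log(10))^2 / 2)
  nl <- spec$n_libraries; p <- spec$p_detect
  p0 <- stats::dbinom(0, nl, p); pn <- stats::dbinom(nl, nl, p)
  frac <- (nl * p - nl * pn) / (nl * (1 - p0 - pn))
  detected_frac <- c(hkg = 1, ce = 1, ie = frac)
  stats::setNames(as.numeric(e_base * detected_frac), c("hkg", "ce", "ie"))
}

# mean-one multiplicative log-normal noise at a given CV
rlnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Simulate a gene-by-library FPKM matrix with truth labels
#'
#' Output is a pure function of the spec (including its seed): identical
#' specs give bit-identical matrices. Draw order is fixed (housekeeping
#' bases and noise, then consistent, then inconsistent bases, noise and
#' detection masks).
#'
#' @param spec a `synthetic_spec`.
#' @return object of class `synthetic_sct`: list with `matrix` (validated
#'   expression matrix), `truth` (data frame: gene, stratum in hkg_ce /
#'   hkg_silenced / ce / ie, base, n_detected) and `spec`.
#' @export
simulate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  nl <- spec$n_libraries
  libs <- sprintf("sim%02d", seq_len(nl))

  stratum_block <- function(n, mu, bsd, cv, prefix) {
    if (n == 0) return(list(values = matrix(0, 0, nl), base = numeric(),
                            genes = character()))
    base <- 10^stats::rnorm(n, mu, bsd)
    noise <- matrix(rlnoise(n * nl, cv), n, nl)
    list(values = base * noise, base = base,
         genes = sprintf("%s%05d", prefix, seq_len(n)))
  }

  hkg <- stratum_block(spec$n_hkg, spec$mu[["hkg"]], spec$base_sd[["hkg"]],
                       spec$noise_cv[["hkg"]], "HKG")
  if (spec$n_silenced_hkg > 0) {
    sil <- seq(spec$n_hkg - spec$n_silenced_hkg + 1L, spec$n_hkg)
    hkg$values[sil, ] <- 0
    hkg$base[sil] <- 0
  } else sil <- integer()
  ce <- stratum_block(spec$n_ce, spec$mu[["ce"]], spec$base_sd[["ce"]],
                      spec$noise_cv[["ce"]], "CE")
  ie <- stratum_block(spec$n_ie, spec$mu[["ie"]], spec$base_sd[["ie"]],
                      spec$noise_cv[["ie"]], "IE")
  if (spec$n_ie > 0) {
    masks <- matrix(FALSE, spec$n_ie, nl)
    for (i in seq_len(spec$n_ie)) {
      for (tries in seq_len(10000L)) {
        mk <- stats::rbinom(nl, 1, spec$p_detect) == 1
        if (any(mk) && !all(mk)) break
        if (tries == 10000L)
          stop("detection-mask rejection did not terminate; p_detect too extreme",
               call. = FALSE)
      }
      masks[i, ] <- mk
    }
    ie$values <- ie$values * masks
    n_det_ie <- rowSums(masks)
  } else n_det_ie <- integer()

  values <- rbind(hkg$values, ce$values, ie$values)
  rownames(values) <- c(hkg$genes, ce$genes, ie$genes)
  colnames(values) <- libs
  validate_expression_matrix(values)

  stratum <- c(
    ifelse(seq_len(spec$n_hkg) %in% sil, "hkg_silenced", "hkg_ce"),
    rep("ce", spec$n_ce), rep("ie", spec$n_ie))
  n_det_hkg <- rep(nl, spec$n_hkg)
  n_det_hkg[sil] <- 0L
  truth <- data.frame(
    gene = rownames(values),
    stratum = stratum,
    base = c(hkg$base, ce$base, ie$base),
    n_detected = c(n_det_hkg, rep(nl, spec$n_ce), n_det_ie),
    stringsAsFactors = FALSE)
  structure(list(matrix = values, truth = truth, spec = spec),
            class = "synthetic_sct")
}

#' @export
print.synthetic_sct <- function(x, ...) {
  cat(sprintf("synthetic_sct: %d genes x %d libraries (seed %d)\n",
              nrow(x$matrix), ncol(x$matrix), x$spec$seed))
  print(table(x$truth$stratum))
  invisible(x)
}

#' Simulate a small ontology, annotations and pathways with planted signal
#'
#' Builds a three-namespace DAG (< 100 terms, each namespace a root, two
#' mid-level terms, a diamond motif and a layer of leaves), then annotates
#' the simulated genes to leaf terms. In the cellular-component namespace one
#' designated "intracellular-like" leaf is preferentially annotated to
#' consistent-stratum genes and one "membrane-like" leaf to
#' inconsistent-stratum genes (probabilities `planted_prob` vs
#' `background_prob`), mirroring the biological contrast the analysis is
#' meant to detect. One pathway is constructed so the consistent stratum
#' covers 90% of its members; the remaining pathways are random draws.
#'
#' Uses `spec$seed + 1`, so the companion matrix from [simulate_matrix()] is
#' unchanged by generating (or regenerating) the ontology.
#'
#' @param spec a `synthetic_spec`.
#' @param truth truth-label data frame from [simulate_matrix()]; simulated
#'   afresh from `spec` when omitted.
#' @param n_leaves leaf terms per namespace (default 18).
#' @param leaf_prob background probability a gene is annotated to any given
#'   unplanted leaf (default 0.05).
#' @param planted_prob annotation probability of the planted leaf within its
#'   target stratum (default 0.9).
#' @param background_prob annotation probability of the planted leaf outside
#'   its target stratum (default 0.1).
#' @return list with `dag` (`ontology_dag`), `annotations`
#'   (`annotation_map`, unpropagated), `pathways` (`pathway_collection`) and
#'   `planted` (list: ce_term, ie_term, ce_pathway).
#' @export
simulate_ontology <- function(spec, truth = NULL, n_leaves = 18L,
                              leaf_prob = 0.05, planted_prob = 0.9,
                              background_prob = 0.1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(truth)) truth <- simulate_matrix(spec)$truth
  set.seed(spec$seed + 1L)
  namespaces <- c("biological_process", "cellular_component",
                  "molecular_function")

  ids <- character(); names_ <- character(); ns <- character()
  parents <- list()
  counter <- 0L
  new_term <- function(name, nsp, par) {
    counter <<- counter + 1L
    id <- sprintf("GO:9%06d", counter)
    ids <<- c(ids, id); names_ <<- c(names_, name); ns <<- c(ns, nsp)
    parents[[id]] <<- par
    id
  }
  leaf_ids <- list()
  for (nsp in namespaces) {
    root <- new_term(paste("simulated", nsp, "root"), nsp, character())
    mid_a <- new_term(paste(nsp, "branch a"), nsp, root)
    mid_b <- new_term(paste(nsp, "branch b"), nsp, root)
    # diamond motif: one leaf with two parents sharing the root
    diamond <- new_term(paste(nsp, "diamond leaf"), nsp, c(mid_a, mid_b))
    leaves <- c(diamond, vapply(seq_len(n_leaves - 1L), function(i)
      new_term(sprintf("%s leaf %02d", nsp, i), nsp,
               if (i %% 2 == 0) mid_a else mid_b), ""))
    leaf_ids[[nsp]] <- leaves
  }
  # one obsolete term per the OBO fixtures the parsers must tolerate
  obs_id <- new_term("retired term", "biological_process", character())
  dag <- structure(
    list(terms = data.frame(id = ids, name = names_, namespace = ns,
                            obsolete = ids == obs_id,
                            stringsAsFactors = FALSE),
         parents = parents,
         alt_ids = stats::setNames(character(), character())),
    class = "ontology_dag")
  assert_acyclic(dag)

  genes <- truth$gene
  is_ce_like <- truth$stratum %in% c("ce", "hkg_ce")
  is_ie <- truth$stratum == "ie"
  cc_leaves <- leaf_ids[["cellular_component"]]
  planted_ce <- cc_leaves[2]
  planted_ie <- cc_leaves[3]

  gene_v <- character(); term_v <- character(); ns_v <- character()
  add_ann <- function(g, term, nsp) {
    gene_v <<- c(gene_v, g); term_v <<- c(term_v, rep(term, length(g)))
    ns_v <<- c(ns_v, rep(nsp, length(g)))
  }
  for (nsp in namespaces) {
    for (leaf in leaf_ids[[nsp]]) {
      if (leaf == planted_ce) {
        pr <- ifelse(is_ce_like, planted_prob, background_prob)
      } else if (leaf == planted_ie) {
        pr <- ifelse(is_ie, planted_prob, background_prob)
      } else pr <- rep(leaf_prob, length(genes))
      hit <- stats::runif(length(genes)) < pr
      if (any(hit)) add_ann(genes[hit], leaf, nsp)
    }
  }
  annotations <- annotation_map_from_long(gene_v, term_v, ns_v,
                                          provenance = "simulate_ontology")

  ce_pool <- genes[truth$stratum == "ce"]
  ie_pool <- genes[truth$stratum == "ie"]
  planted_members <- c(sample(ce_pool, min(18L, length(ce_pool))),
                       sample(ie_pool, min(2L, length(ie_pool))))
  # enough unplanted pathways that the collection's background is not
  # dominated by the planted members themselves
  pw <- list(planted_ce_pathway = planted_members)
  for (i in seq_len(9L))
    pw[[sprintf("random_pathway_%d", i)]] <-
      sample(genes, min(length(genes), sample(30:60, 1)))
  pathways <- structure(pw, class = "pathway_collection",
                        descriptions = stats::setNames(
                          rep("simulated", length(pw)), names(pw)))
  list(dag = dag, annotations = annotations, pathways = pathways,
       planted = list(ce_term = planted_ce, ie_term = planted_ie,
                      ce_pathway = "planted_ce_pathway"))
}

#' Null calibration of the over-representation p-value
#'
#' Repeatedly annotates one term by independent equal-probability coin flips
#' over the background (so the query's overlap with the term is exactly
#' hypergeometric under the null) and records the over-representation
#' p-value of a fixed query. With a fine-grained table the p-values are
#' near-uniform and the false-positive rate at any cutoff approaches the
#' cutoff from below (the test is discrete, hence conservative).
#'
#' @param n_reps number of replicates.
#' @param n_genes background size.
#' @param n_query query size.
#' @param annot_prob probability each background gene carries the term.
#' @param tail tail convention, see [hypergeom_tail()].
#' @param seed RNG seed.
#' @return numeric vector of `n_reps` null p-values.
#' @export
null_enrichment_pvalues <- function(n_reps = 400L, n_genes = 2000L,
                                    n_query = 500L, annot_prob = 0.2,
                                    tail = "ge", seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_reps), function(r) {
    ann <- stats::runif(n_genes) < annot_prob
    m <- sum(ann)
    k <- sum(ann[seq_len(n_query)])
    if (m == 0) return(1)
    hypergeom_tail(k, n_genes, m, n_query, tail = tail)
  }, 0)
}
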