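test_that("gene CV matches hand computation and excludes zero means", {
  expect_equal(gene_cv(c(1, 1, 1, 1))[["cv"]], 0)
  r <- gene_cv(c(2, 4, 4, 2))
  expect_equal(r[["mean"]], 3)
  expect_equal(r[["sd"]], sqrt(4 / 3))        # sample sd, n - 1 denominator
  expect_equal(r[["cv"]], sqrt(4 / 3) / 3, tolerance = 1e-12)
  expect_true(is.na(gene_cv(c(0, 0, 0))[["cv"]]))
  expect_error(gene_cv(5), "at least 2")
  # zeros = "exclude" measures dispersion among detected libraries only
  expect_equal(gene_cv(c(0, 2, 0, 4), zeros = "exclude")[["mean"]], 3)
})

test_that("CV is scale invariant", {
  set.seed(9)
  for (i in 1:20) {
    x <- rexp(4) + 0.1
    c_scaled <- gene_cv(x * runif(1, 0.01, 1000))[["cv"]]
    expect_equal(c_scaled, gene_cv(x)[["cv"]], tolerance = 1e-10)
  }
})

test_that("CV distributions bin to percentages summing to 100", {
  d <- cv_distribution(c(0.1, 0.2, 0.6, 0.9), c(0, 0.55, 1.0))
  expect_equal(d$percent, c(50, 50))
  expect_equal(cv_distribution(rep(0.3, 7), c(0, 1))$percent, 100)
  expect_error(cv_distribution(numeric(), c(0, 1)), "no CV")
  expect_error(cv_distribution(0.5, c(1, 0)), "increasing")
  # Monte-Carlo: uniform CVs land ~10% per decile bin
  set.seed(101)
  u <- runif(10000)
  d10 <- cv_distribution(u, seq(0, 1, 0.1))
  expect_equal(sum(d10$percent), 100)
  expect_true(all(abs(d10$percent - 10) < 1))   # binomial tolerance at n = 1e4
})

test_that("group CV summaries order groups by their noise levels", {
  sim <- simulate_matrix(synthetic_spec(n_hkg = 143, n_ce = 400, n_ie = 400,
                                        seed = 5))
  part <- partition_genes(call_expressed(sim$matrix))
  hkg <- sim$truth$gene[sim$truth$stratum == "hkg_ce"]
  s <- group_cv_summary(sim$matrix, part, hkg)
  pg <- s$per_gene
  # generator noise CVs: ce (0.9) > ie (0.5) ~ hkg (0.4)
  expect_gt(pg$mean_cv[pg$group == "CE"], pg$mean_cv[pg$group == "IE"])
  expect_gt(pg$mean_cv[pg$group == "CE"], pg$mean_cv[pg$group == "HKG"])
  expect_identical(sort(s$per_library$group[s$per_library$library == "sim01"]),
                   c("CE", "HKG", "IE"))
  # genes identical across libraries have group mean CV zero
  m <- mat4(rbind(c(2, 2, 2), c(7, 7, 7)), c("GA", "GB"))
  p0 <- partition_genes(call_expressed(m))
  expect_warning(s0 <- group_cv_summary(m, p0), "omitted.*IE")
  expect_equal(s0$per_gene$mean_cv, 0)
})

test_that("percentile profiles use half-up nearest-rank sampling", {
  means <- 10^(1:10)
  pr <- percentile_profile(means)
  expect_equal(pr$log10_fpkm, 1:10)           # rank i at level (2i-1)/20
  one <- percentile_profile(42, levels = c(0.2, 0.8))
  expect_equal(one$log10_fpkm, rep(log10(42), 2))
  expect_error(percentile_profile(c(1, 0)), "positive")
  expect_error(percentile_profile(numeric()), "no per-gene")
  expect_error(percentile_profile(1:3, levels = c(0, 0.5)), "in \\(0, 1\\)")
  # monotone in level for arbitrary data
  set.seed(12)
  for (i in 1:10) {
    pr <- percentile_profile(rlnorm(sample(3:200, 1), 2, 1.5))
    expect_true(all(diff(pr$log10_fpkm) >= 0))
  }
})

test_that("group means average all libraries and report fold ratios", {
  m <- mat4(rbind(c(4, 0, 0, 0),
                  c(10, 10, 10, 10),
                  c(500, 600, 550, 520)), c("GD", "GC", "GH"))
  part <- partition_genes(call_expressed(m))
  gm <- group_means(m, part, hkg = "GH")
  df <- as.data.frame(gm)
  expect_equal(df$mean_fpkm[df$group == "IE"], 1.0)      # (4+0+0+0)/4
  expect_equal(df$mean_fpkm[df$group == "HKG"], 542.5)
  expect_equal(df$mean_fpkm[df$group == "CE"], (10 + 542.5) / 2)
  expect_equal(df$mean_fpkm[df$group == "expressed"], (1 + 10 + 542.5) / 3)
  fr <- attr(gm, "fold_ratios")
  expect_equal(fr[["CE_vs_IE"]], 276.25)
  # fold ratio undefined when the denominator group is absent
  m2 <- m[c("GC", "GH"), ]
  gm2 <- group_means(m2, partition_genes(call_expressed(m2)), hkg = "GH")
  expect_true(is.na(attr(gm2, "fold_ratios")[["CE_vs_IE"]]))
})

test_that("pairwise correlations behave on exact and simulated data", {
  m <- toy_matrix()
  expect_equal(pairwise_correlation(m, "L1", "L1"), 1)
  lin <- mat4(rbind(c(1, 2), c(2, 4), c(3, 6), c(4, 8)),
              c("a", "b", "c", "d"), c("A", "B"))
  expect_equal(pairwise_correlation(lin, "A", "B", transform = "raw"), 1)
  expect_error(pairwise_correlation(m, "L1", "nope"), "not in matrix")
  tiny <- mat4(rbind(c(0, 0), c(0, 0), c(1, 1)), c("a", "b", "c"))
  expect_error(pairwise_correlation(tiny, "L1", "L2"), "fewer than 3")

  # analytic attenuation oracle: log-scale r = tau^2 / (tau^2 + s^2)
  set.seed(77)
  tau <- 0.8; s <- 0.4; n <- 5000
  g <- rnorm(n, 3, tau)
  x <- mat4(cbind(10^(g + rnorm(n, 0, s)), 10^(g + rnorm(n, 0, s))),
            sprintf("g%04d", 1:n), c("A", "B"))
  r <- pairwise_correlation(x, "A", "B")       # log10(x+1), +1 negligible here
  expect_equal(r, tau^2 / (tau^2 + s^2), tolerance = 0.05)
})

test_that("overlaps report dual percentages and a consistent Venn decomposition", {
  ov <- overlap_analysis(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(ov$pairwise$common, 2)
  expect_equal(ov$pairwise$pct_a, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(ov$pairwise$pct_b, 100 * 2 / 3, tolerance = 1e-12)
  same <- overlap_analysis(list(A = letters[1:5], B = letters[1:5]))
  expect_equal(same$pairwise$pct_a, 100)
  expect_equal(same$pairwise$pct_b, 100)
  expect_warning(overlap_analysis(list(A = "a", B = character())), "empty set")

  # brute-force cross-check on random 4-set fixtures
  set.seed(33)
  for (rep in 1:5) {
    sets <- lapply(1:4, function(i) sample(letters, sample(3:15, 1)))
    names(sets) <- paste0("S", 1:4)
    ov <- overlap_analysis(sets)
    universe <- unique(unlist(sets))
    expect_equal(sum(ov$venn$count), length(universe))
    for (r in seq_len(nrow(ov$pairwise))) {
      a <- ov$pairwise$set_a[r]; b <- ov$pairwise$set_b[r]
      # pairwise common equals the sum of Venn regions containing both sets
      ia <- match(a, names(sets)); ib <- match(b, names(sets))
      both <- vapply(ov$venn$pattern, function(p) {
        bits <- strsplit(p, "")[[1]]
        bits[ia] == "1" && bits[ib] == "1"
      }, TRUE)
      expect_equal(ov$pairwise$common[r], sum(ov$venn$count[both]))
    }
  }
})

test_that("statistics are invariant to gene row order", {
  sim <- simulate_matrix(synthetic_spec(n_hkg = 10, n_ce = 50, n_ie = 50,
                                        seed = 21))
  m <- sim$matrix
  shuf <- m[sample(rownames(m)), ]
  p1 <- partition_genes(call_expressed(m))
  p2 <- partition_genes(call_expressed(shuf))
  g1 <- as.data.frame(group_means(m, p1))
  g2 <- as.data.frame(group_means(shuf, p2))
  expect_equal(g1, g2)
  expect_equal(pairwise_correlation(m, "sim01", "sim02"),
               pairwise_correlation(shuf, "sim01", "sim02"))
  pr1 <- percentile_profile(rowMeans(m)[rowMeans(m) > 0])
  pr2 <- percentile_profile(rowMeans(shuf)[rowMeans(shuf) > 0])
  expect_equal(pr1, pr2)
})
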