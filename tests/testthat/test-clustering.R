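test_that("Minkowski distances match their closed forms", {
  u <- rep(0, 6); v <- rep(1, 6)
  d <- minkowski_distance_matrix(rbind(a = u, b = v), p = 1)
  expect_equal(as.numeric(d), 6)
  expect_equal(as.numeric(minkowski_distance_matrix(rbind(u, u))), 0)

  set.seed(12)
  x <- matrix(runif(24), 4)
  d2 <- as.matrix(minkowski_distance_matrix(x, p = 2))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(d2[i, j], sqrt(sum((x[i, ] - x[j, ])^2)))
  }
  expect_error(minkowski_distance_matrix(matrix(1, 1, 6)), ">= 2")
  expect_error(minkowski_distance_matrix(x, p = 0.5), ">= 1")
})

test_that("Ward.D2 handles elementary cases by hand-applied recurrence", {
  # two leaves merge at their distance
  m <- matrix(c(0, 3.2, 3.2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  d <- ward_d2_linkage(m)
  expect_equal(d$height, 3.2)
  expect_equal(sort(d$merge[1, ]), c(-2, -1))

  # collinear points {0, 1, 10}: first merge {0,1} at 1, then
  # d2 = (2*100 + 2*81 - 1)/3 = 361/3
  m3 <- as.matrix(dist(c(0, 1, 10)))
  d3 <- ward_d2_linkage(m3)
  expect_equal(d3$height, c(1, sqrt(361 / 3)))
})

test_that("Lance-Williams agglomeration matches the from-scratch Ward oracle", {
  set.seed(101)
  for (r in 1:30) {
    n <- sample(3:7, 1)
    m <- random_distance_matrix(n)
    mine <- ward_d2_linkage(m)
    oracle <- ward_oracle(m)
    expect_equal(mine$height, oracle$heights, tolerance = 1e-9)
    expect_equal(unname(cophenetic_matrix(mine)), oracle$cophenetic,
                 tolerance = 1e-9)
  }
})

test_that("Ward.D2 agrees with the reference hclust implementation", {
  set.seed(55)
  for (r in 1:15) {
    n <- sample(3:10, 1)
    x <- matrix(runif(n * 6, 400, 900), n)
    rownames(x) <- paste0("cond", seq_len(n))
    d <- minkowski_distance_matrix(x, p = 1)
    mine <- ward_d2_linkage(d)
    ref <- hclust(d, method = "ward.D2")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-9)
    cm <- cophenetic_matrix(mine)
    cr <- as.matrix(cophenetic(ref))
    expect_equal(cm[rownames(cr), colnames(cr)], cr, tolerance = 1e-9)
  }
})

test_that("cophenetic matrices are ultrametric with zero diagonal", {
  set.seed(77)
  for (r in 1:10) {
    n <- sample(3:9, 1)
    dend <- ward_d2_linkage(random_distance_matrix(n))
    cm <- cophenetic_matrix(dend)
    expect_equal(diag(cm), setNames(rep(0, n), rownames(cm)))
    expect_equal(cm, t(cm))
    expect_true(is_ultrametric(cm))
    expect_true(all(diff(dend$height) >= -1e-12))
  }
})

test_that("exact cost ties break toward the lexicographically first pair", {
  # equilateral triple: all three pairs cost the same; {1,2} must merge first
  m <- matrix(1, 3, 3); diag(m) <- 0
  rownames(m) <- colnames(m) <- c("x", "y", "z")
  d <- ward_d2_linkage(m)
  expect_equal(sort(d$merge[1, ]), c(-2, -1))
})

test_that("malformed distance inputs are rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(ward_d2_linkage(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2)
  expect_error(ward_d2_linkage(neg), "non-negative")
})

test_that("subset dendrograms mirror the per-regime / per-time panels", {
  ds <- generate_dataset(table1_specs(n_samples = 40), seed = 8)
  by_regime <- subset_dendrograms(ds, group_by = "regime",
                                  location_filter = "in")
  expect_named(by_regime, c("0%", "10%", "20%"))
  for (d in by_regime) {
    expect_s3_class(d, "lifetime_dendrogram")
    expect_setequal(d$labels, c("5min", "10min", "20min"))
  }
  by_time <- subset_dendrograms(ds, group_by = "time_post_admin",
                                location_filter = "in")
  expect_named(by_time, c("5min", "10min", "20min"))
  for (d in by_time) expect_setequal(d$labels, c("0%", "10%", "20%"))

  # a design missing a whole regime level skips it with a warning
  sub <- ds[ds$regime != "20", , drop = FALSE]
  class(sub) <- c("lifetime_dataset", "data.frame")
  expect_warning(out <- subset_dendrograms(sub, "regime", "in"),
                 "empty subset")
  expect_named(out, c("0%", "10%"))
})

test_that("newick export round-trips through an independent parser", {
  skip_if_not_installed("ape")
  # two leaves at height h -> (A:h/2,B:h/2);
  m <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  nwk <- export_newick(ward_d2_linkage(m))
  expect_match(nwk, "^\\(A:2,B:2\\);$|^\\(B:2,A:2\\);$")

  set.seed(19)
  x <- matrix(runif(36, 400, 900), 6)
  rownames(x) <- c("0% 5min", "0% 10min", "10% 5min", "10% 10min",
                   "20% 5min", "20% 10min")
  dend <- ward_d2_linkage(minkowski_distance_matrix(x))
  nwk <- export_newick(dend)
  # labels with spaces are single-quoted
  expect_match(nwk, "'0% 5min'", fixed = TRUE)
  tree <- ape::read.tree(text = nwk)
  tips <- gsub("^'|'$", "", tree$tip.label)
  expect_setequal(tips, rownames(x))
  # cophenetic distances survive the round trip (topology + heights)
  cp <- ape::cophenetic.phylo(tree)
  rownames(cp) <- colnames(cp) <- tips
  cm <- cophenetic_matrix(dend)
  expect_equal(cp[rownames(cm), colnames(cm)], cm, tolerance = 1e-9)
})

test_that("dendrogram JSON and distance-matrix text exports are readable", {
  x <- matrix(runif(18, 400, 900), 3)
  rownames(x) <- c("a", "b", "c")
  d <- minkowski_distance_matrix(x)
  dend <- ward_d2_linkage(d)
  jp <- tempfile(fileext = ".json")
  write_dendrogram_json(dend, jp)
  parsed <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(parsed$labels, dend$labels)
  expect_equal(parsed$heights, dend$height)
  dp <- tempfile(fileext = ".tsv")
  write_distance_matrix(d, dp)
  m <- as.matrix(read.table(dp, sep = "\t", header = TRUE, row.names = 1))
  expect_equal(unname(m), unname(as.matrix(d)), tolerance = 1e-9)
})
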