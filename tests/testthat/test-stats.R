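test_that("six-number summary follows the interpolated-quartile convention", {
  expect_equal(summary_vector(c(1, 2, 3, 4, 5)),
               c(minimum = 1, q1 = 2, mean = 3, median = 3, q3 = 4,
                 maximum = 5))
  expect_equal(unname(summary_vector(700)), rep(700, 6))
  # hand-computed type-7 quartiles at positions 1 + 3p:
  # q1 at 1.75 -> 600 + 0.75*50; q3 at 3.25 -> 700 + 0.25*200
  sv <- summary_vector(c(600, 650, 700, 900))
  expect_equal(sv[["q1"]], 637.5)
  expect_equal(sv[["q3"]], 750)
  expect_error(summary_vector(numeric(0)), "non-empty")
})

test_that("summary vector and rel_md are permutation invariant and ordered", {
  set.seed(31)
  for (i in 1:10) {
    x <- runif(sample(3:50, 1), 400, 900)
    xp <- sample(x)
    expect_identical(summary_vector(x), summary_vector(xp))
    expect_identical(rel_md(x), rel_md(xp))
    sv <- summary_vector(x)
    expect_true(sv[["minimum"]] <= sv[["q1"]] &&
                  sv[["q1"]] <= sv[["median"]] &&
                  sv[["median"]] <= sv[["q3"]] &&
                  sv[["q3"]] <= sv[["maximum"]])
    expect_true(sv[["minimum"]] <= sv[["mean"]] &&
                  sv[["mean"]] <= sv[["maximum"]])
  }
})

test_that("rel_md matches direct arithmetic and vanishes for symmetry", {
  expect_equal(rel_md(c(1, 2, 3, 4, 100)), -1.52)
  expect_equal(rel_md(c(1, 2, 3, 4, 5)), 0)
  expect_equal(rel_md(rep(710.8, 10)), 0)
  # a sample with median 730 and mean 710.8
  x <- c(672.4, 730, 730)
  expect_equal(mean(x), 710.8)
  expect_equal(rel_md(x), 2 * (730 - 710.8) / (730 + 710.8))
  expect_error(rel_md(numeric(0)), "non-empty")
})

test_that("rel_md and rel_oi are scale invariant", {
  set.seed(7)
  x <- runif(25, 500, 900)
  for (c_ in c(0.1, 3, 1e3)) {
    expect_equal(rel_md(c_ * x), rel_md(x), tolerance = 1e-12)
    expect_equal(rel_oi(c_ * 733.6, c_ * 710.8), rel_oi(733.6, 710.8),
                 tolerance = 1e-12)
  }
})

test_that("rel_oi reproduces the published contrasts and is antisymmetric", {
  expect_equal(round(rel_oi(733.6, 710.8), 3), 0.032)
  expect_equal(round(rel_oi(683.3, 616.6), 3), 0.103) # the outlier pair
  expect_equal(rel_oi(650, 650), 0)
  expect_equal(rel_oi(710.8, 733.6), -rel_oi(733.6, 710.8))
  expect_error(rel_oi(-1, 700), "finite and > 0")
  expect_error(rel_oi(700, 0), "finite and > 0")
})

test_that("condition table reproduces published oxygenation from matching means", {
  pub <- published_condition_table()
  # constant samples per cell make the cell mean exactly the target
  parts <- lapply(seq_len(nrow(pub)), function(i) {
    lifetime_dataset(rep(pub$mean_tau[i], 4), pub$regime[i], pub$time[i],
                     pub$loc[i])
  })
  ds <- do.call(rbind, parts)
  class(ds) <- c("lifetime_dataset", "data.frame")
  tab <- condition_table(ds)
  expect_equal(nrow(tab), 18)
  expect_equal(tab$percent_o2_printed, pub$percent_o2)
  # fixed chronological ordering: regime blocks, then time, then in/out
  expect_equal(as.character(tab$regime), pub$regime)
  expect_equal(as.character(tab$location), pub$loc)
  # rel_OI sits only on 'out' rows
  expect_true(all(is.na(tab$rel_oi[tab$location == "in"])))
  expect_true(all(!is.na(tab$rel_oi[tab$location == "out"])))
  expect_equal(tab$rel_oi[tab$location == "out"],
               pub$rel_oi[pub$loc == "out"], tolerance = 0.03)
})

test_that("rel_OI negates when in/out means swap, and missing partners warn", {
  ds <- rbind(lifetime_dataset(rep(733.6, 3), 0, 5, "out"),
              lifetime_dataset(rep(710.8, 3), 0, 5, "in"))
  class(ds) <- c("lifetime_dataset", "data.frame")
  swapped <- rbind(lifetime_dataset(rep(710.8, 3), 0, 5, "out"),
                   lifetime_dataset(rep(733.6, 3), 0, 5, "in"))
  class(swapped) <- c("lifetime_dataset", "data.frame")
  t1 <- condition_table(ds)
  t2 <- condition_table(swapped)
  expect_equal(t2$rel_oi[t2$location == "out"],
               -t1$rel_oi[t1$location == "out"])

  lone <- lifetime_dataset(rep(700, 5), 10, 10, "out")
  expect_warning(tab <- condition_table(lone), "no 'in' partner")
  expect_equal(nrow(tab), 1)
  expect_true(is.na(tab$rel_oi))

  single_in <- lifetime_dataset(c(700, 710), 20, 20, "in")
  tab_in <- condition_table(single_in)
  expect_equal(nrow(tab_in), 1)
  expect_true(is.na(tab_in$rel_oi))
})

test_that("condition-table oxygenation always equals the calibrated mean", {
  ds <- generate_dataset(table1_specs(n_samples = 30), seed = 2)
  tab <- condition_table(ds)
  expect_equal(tab$percent_o2, tau_to_oxygen(tab$mean_tau)$percent_o2)
})

test_that("lifetime datasets validate labels and round-trip through text", {
  expect_error(lifetime_dataset(700, 5, 5, "in"), "regime")
  expect_error(lifetime_dataset(700, 0, 7, "in"), "time_post_admin")
  expect_error(lifetime_dataset(700, 0, 5, "inside"), "location")
  expect_error(lifetime_dataset(-1, 0, 5, "in"), "finite and > 0")

  ds <- generate_dataset(table1_specs(n_samples = 5), seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_lifetime_dataset(ds, path)
  back <- read_lifetime_dataset(path)
  expect_equal(back$tau, ds$tau, tolerance = 1e-12)
  expect_equal(as.character(back$regime), as.character(ds$regime))
  expect_equal(as.character(back$location), as.character(ds$location))
})
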