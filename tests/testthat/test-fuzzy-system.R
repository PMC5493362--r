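make_toy_system <- function(resolution = 1001L) {
  x <- fuzzy_variable("x", c(0, 10), list(
    mf_trapezoid("lo", c(0, 0, 3, 6)),
    mf_trapezoid("hi", c(3, 6, 10, 10))))
  out <- fuzzy_variable("y", c(0, 16), list(
    mf_trapezoid("small", c(0, 0, 4, 8)),
    mf_trapezoid("big", c(7, 11, 16, 16))))
  fuzzy_system(list(x), out,
               list(fuzzy_rule(c(x = "lo"), "small"),
                    fuzzy_rule(c(x = "hi"), "big")),
               resolution = resolution)
}

test_that("fire_strength is the minimum of antecedent degrees", {
  rule <- fuzzy_rule(c(a = "t", b = "t", c = "t", d = "t"), "out")
  fz <- list(a = c(t = 0.8), b = c(t = 0.3), c = c(t = 1.0), d = c(t = 0.6))
  expect_equal(fire_strength(rule, fz), 0.3)
  fz$b <- c(t = 0)
  expect_equal(fire_strength(rule, fz), 0)    # any zero deactivates the rule
  fz <- lapply(fz, function(x) c(t = 1))
  expect_equal(fire_strength(rule, fz), 1)
  expect_error(fire_strength(rule, fz[c("a", "b")]), "no fuzzified degrees")
})

test_that("aggregation clips consequents at rule strength and takes pointwise max", {
  sys <- make_toy_system()
  grid <- seq(0, 16, length.out = sys$resolution)
  small <- sys$output$terms$small
  big <- sys$output$terms$big

  # single rule at full strength: the aggregated set is the consequent itself
  agg <- aggregate_rules(sys, c(1, 0))
  expect_equal(agg$degrees, membership(small, grid))
  expect_true(all(diff(agg$grid) > 0))

  # single rule at strength 0.4: pointwise min with 0.4
  agg <- aggregate_rules(sys, c(0.4, 0))
  expect_equal(agg$degrees, pmin(membership(small, grid), 0.4))

  # two rules with (almost) disjoint consequents: pointwise max of clips
  agg <- aggregate_rules(sys, c(0.4, 0.7))
  expect_equal(agg$degrees, pmax(pmin(membership(small, grid), 0.4),
                                 pmin(membership(big, grid), 0.7)))
  expect_true(all(agg$degrees >= 0 & agg$degrees <= 1))

  expect_error(aggregate_rules(sys, 1), "one degree per rule")
  expect_error(aggregate_rules(sys, c(1.2, 0)), "in \\[0, 1\\]")
})

test_that("centroid defuzzification matches symmetry and a fine-grid oracle", {
  out <- fuzzy_variable("y", c(0, 16), list(
    mf_trapezoid("tri", c(6, 8, 8, 10)),
    mf_trapezoid("all", c(0, 0, 16, 16)),
    mf_trapezoid("shoulder", c(12, 14, 16, 16))))
  x <- fuzzy_variable("x", c(0, 1),
                      list(mf_trapezoid("any", c(0, 0, 1, 1))))
  sys <- fuzzy_system(list(x), out,
                      list(fuzzy_rule(c(x = "any"), "tri"),
                           fuzzy_rule(c(x = "any"), "all"),
                           fuzzy_rule(c(x = "any"), "shoulder")))

  # fully activated symmetric triangle centred at 8
  expect_equal(defuzzify_centroid(aggregate_rules(sys, c(1, 0, 0))), 8,
               tolerance = 1e-6)
  # rectangle over the whole universe
  expect_equal(defuzzify_centroid(aggregate_rules(sys, c(0, 1, 0))), 8,
               tolerance = 1e-6)
  # right shoulder vs >= 1e5-point quadrature oracle
  oracle <- centroid_fine_grid(
    list(list(strength = 1, mf = out$terms$shoulder)), c(0, 16))
  expect_equal(defuzzify_centroid(aggregate_rules(sys, c(0, 0, 1))), oracle,
               tolerance = 0.05)

  expect_error(defuzzify_centroid(aggregate_rules(sys, c(0, 0, 0))),
               "degenerate")
})

test_that("centroid at default resolution tracks the quadrature oracle for random activations", {
  sys <- asthma_system()
  set.seed(31)
  for (i in 1:20) {
    strengths <- stats::runif(16)
    coarse <- defuzzify_centroid(aggregate_rules(sys, strengths))
    rules <- lapply(seq_along(sys$rules), function(r)
      list(strength = strengths[r],
           mf = sys$output$terms[[sys$rules[[r]]$consequent]]))
    expect_equal(coarse, centroid_fine_grid(rules, c(0, 16), 1e5),
                 tolerance = 0.05)
  }
})

test_that("infer reduces to the single active rule's centroid at saturated inputs", {
  sys <- make_toy_system()
  small_centroid <- centroid_fine_grid(
    list(list(strength = 1, mf = sys$output$terms$small)), c(0, 16))
  big_centroid <- centroid_fine_grid(
    list(list(strength = 1, mf = sys$output$terms$big)), c(0, 16))
  expect_equal(infer(sys, c(x = 1)), small_centroid, tolerance = 0.01)
  expect_equal(infer(sys, c(x = 9)), big_centroid, tolerance = 0.01)
  expect_error(infer(sys, c(z = 1)), "missing crisp input")
})

test_that("infer stays inside the output universe and off the extremes", {
  sys <- make_toy_system()
  set.seed(41)
  xs <- stats::runif(200, -5, 15)
  preds <- infer_frame(sys, data.frame(x = xs))
  expect_true(all(preds > 0 & preds < 16))
})

test_that("disabling a zero-strength rule never changes the output", {
  sys <- asthma_system()
  set.seed(51)
  for (i in 1:10) {
    inputs <- c(pm10 = stats::runif(1, 0, 120), o3 = stats::runif(1, 0, 200),
                so2 = stats::runif(1, 0, 30),
                temp_apparent = stats::runif(1, 0, 30))
    fz <- lapply(sys$inputs, function(v) fuzzify(v, inputs[[v$name]]))
    strengths <- vapply(sys$rules, fire_strength, numeric(1), fuzzified = fz)
    dead <- which(strengths == 0)
    if (!length(dead)) next
    pruned <- fuzzy_system(sys$inputs, sys$output, sys$rules[-dead],
                           resolution = sys$resolution)
    expect_equal(infer(pruned, inputs), infer(sys, inputs), tolerance = 1e-12)
  }
})

test_that("doubling the resolution barely moves the inferred value", {
  coarse <- make_toy_system(501L)
  fine <- make_toy_system(1001L)
  set.seed(61)
  for (x in stats::runif(20, 0, 10))
    expect_lt(abs(infer(coarse, c(x = x)) - infer(fine, c(x = x))), 0.02)
})

test_that("vectorised inference agrees with scalar inference", {
  sys <- asthma_system()
  set.seed(71)
  df <- data.frame(pm10 = stats::runif(30, 0, 120),
                   o3 = stats::runif(30, 0, 200),
                   so2 = stats::runif(30, 0, 30),
                   temp_apparent = stats::runif(30, 0, 30))
  vec <- infer_frame(sys, df, chunk = 7L)  # force multiple chunks
  scal <- vapply(seq_len(30), function(i) infer(sys, unlist(df[i, ])),
                 numeric(1))
  expect_equal(vec, scal, tolerance = 1e-12)
})

test_that("system configuration round-trips losslessly through YAML and JSON", {
  sys <- asthma_system(resolution = 501L)
  grid <- expand.grid(pm10 = c(10, 40, 80), o3 = c(50, 150), so2 = c(5, 25),
                      temp_apparent = c(5, 20))
  baseline <- infer_frame(sys, grid)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_model_config(sys, path)
    reloaded <- read_model_config(path)
    expect_equal(infer_frame(reloaded, grid), baseline, tolerance = 1e-12)
    # a second round trip is byte-stable
    path2 <- withr::local_tempfile(fileext = paste0(".", ext))
    write_model_config(reloaded, path2)
    expect_identical(readLines(path), readLines(path2))
  }
  expect_error(write_model_config(sys, "model.txt"), "unsupported")
  expect_error(fuzzy_system(sys$inputs, sys$output, sys$rules,
                            resolution = 50L), ">= 101")
})
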