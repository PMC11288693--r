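test_that("density threshold finds the valley of an equal-weight mixture", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    v <- c(rnorm(5000), rnorm(5000, 6))
    dt <- density_threshold(v)
    expect_equal(dt$mode, "valley")
    abs(dt$threshold - 3) <= 0.15
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("density threshold tracks the analytic minimum of a skewed mixture", {
  f <- function(x) 0.9 * dnorm(x) + 0.1 * dnorm(x, 5)
  amin <- optimize(f, c(0, 5))$minimum
  thr <- vapply(1:5, function(s) {
    set.seed(s)
    density_threshold(c(rnorm(9000), rnorm(1000, 5)))$threshold
  }, 0)
  expect_lte(abs(median(thr) - amin), 0.2)
})

test_that("density threshold falls back to the quantile when unimodal", {
  set.seed(30)
  v <- rnorm(20000)
  dt <- density_threshold(v, fallback_percentile = 0.95)
  expect_equal(dt$mode, "fallback")
  expect_lte(abs(dt$threshold - qnorm(0.95)), 0.1)
  expect_error(density_threshold(rnorm(50)), "insufficient")
})

test_that("valley thresholds are equivariant under location shifts", {
  set.seed(31)
  v <- c(rnorm(6000), rnorm(6000, 6))
  t0 <- density_threshold(v)$threshold
  t5 <- density_threshold(v + 5)$threshold
  expect_lte(abs((t5 - t0) - 5), 0.1)
})

test_that("polygon membership uses even-odd with boundary inside", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_true(polygon_membership(cbind(0.5, 0.5), sq))
  expect_false(polygon_membership(cbind(2, 2), sq))
  expect_true(polygon_membership(cbind(0, 0.5), sq))    # on edge
  expect_true(polygon_membership(cbind(1, 1), sq))      # on vertex
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygon_membership(cbind(0.5, 0.5), bow), "self-intersecting")
})

test_that("polygon membership matches a winding-number oracle on random points", {
  set.seed(32)
  poly <- rbind(c(0, 0), c(4, -1), c(5, 3), c(2.5, 5), c(-1, 2.5))
  pts <- cbind(runif(1000, -2, 6), runif(1000, -2, 6))
  mine <- polygon_membership(pts, poly)
  oracle <- vapply(seq_len(nrow(pts)),
                   function(i) oracle_point_in_polygon(pts[i, 1], pts[i, 2], poly),
                   TRUE)
  expect_identical(mine, oracle)
})

mixture_events <- function(n = 10000, w = 0.7, seed = 33) {
  set.seed(seed)
  n1 <- rbinom(1, n, w)
  m <- cbind(Time = sort(runif(n, 0, 10)),
             M1 = c(rnorm(n1, 0), rnorm(n - n1, 6)))
  m <- m[sample(n), ]
  m[, "Time"] <- sort(m[, "Time"])
  make_events(m, c(Time = "time", M1 = "marker"))
}

test_that("a two-node tree recovers a 70/30 mixture within 2%", {
  ev <- mixture_events()
  tree <- gating_tree(list(
    Low = list(parent = "All", gate = gate_spec("threshold1d", "M1", side = "below")),
    High = list(parent = "All", gate = gate_spec("threshold1d", "M1", side = "above"))))
  pc <- apply_gating_tree(ev, tree)
  expect_lte(abs(pc$counts[["Low"]] - 7000), 0.02 * 10000)
  expect_lte(abs(pc$counts[["High"]] - 3000), 0.02 * 10000)
  expect_equal(pc$counts[["Low"]] + pc$counts[["High"]], 10000)
})

test_that("a polygon child covering the parent keeps every event", {
  ev <- mixture_events(2000, seed = 34)
  big <- rbind(c(-100, -100), c(100, -100), c(100, 100), c(-100, 100))
  tree <- gating_tree(list(
    Box = list(parent = "All",
               gate = gate_spec("polygon", c("Time", "M1"), vertices = big))))
  pc <- apply_gating_tree(ev, tree)
  expect_equal(pc$counts[["Box"]], pc$counts[["All"]])
})

test_that("an empty parent flags the node and zeroes descendants", {
  ev <- mixture_events(1000, seed = 35)
  tree <- gating_tree(list(
    None = list(parent = "All",
                gate = gate_spec("threshold1d", "M1", side = "above",
                                 threshold = 1e9)),
    Child = list(parent = "None",
                 gate = gate_spec("threshold1d", "M1", side = "above",
                                  threshold = 0))))
  pc <- apply_gating_tree(ev, tree)
  expect_equal(pc$counts[["None"]], 0)
  expect_equal(pc$counts[["Child"]], 0)
  expect_equal(unname(pc$flags["Child"]), "empty_parent")
})

test_that("gating hierarchy is monotone on a generated sample", {
  cfg <- cohort_config(n_subjects = 1, events_per_sample = 8000, seed = 36)
  co <- simulate_cohort(cfg)
  ev <- transform_events(co$samples[[1]], default_transform_spec(co$samples[[1]]))
  tree <- default_gating_tree("innate")
  pc <- apply_gating_tree(ev, tree)
  for (nm in names(tree$nodes)) {
    expect_lte(pc$counts[[nm]], pc$counts[[tree$nodes[[nm]]$parent]])
  }
})

test_that("gating trees validate structure and read back from YAML and JSON", {
  expect_error(gating_tree(list(A = list(parent = "B",
                                         gate = gate_spec("threshold1d", "M1")))),
               "undefined parent")
  expect_error(gating_tree(list(
    A = list(parent = "B", gate = gate_spec("threshold1d", "M1")),
    B = list(parent = "A", gate = gate_spec("threshold1d", "M1")))),
    "cycle")
  tree <- default_gating_tree("innate")
  yml <- list(nodes = lapply(tree$nodes, function(n) {
    g <- n$gate
    list(parent = n$parent,
         gate = list(kind = g$kind, channels = as.list(g$channels),
                     side = as.list(g$side), threshold = g$threshold,
                     vertices = if (!is.null(g$vertices))
                       lapply(seq_len(nrow(g$vertices)),
                              function(i) as.numeric(g$vertices[i, ])),
                     fallback_percentile = g$fallback_percentile,
                     min_peak_frac = g$min_peak_frac))
  }))
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(yml, fy)
  back <- read_gating_tree(fy)
  expect_equal(names(back$nodes), names(tree$nodes))
  expect_equal(back$nodes$Singlets$gate$vertices, tree$nodes$Singlets$gate$vertices)
  fj <- tempfile(fileext = ".json")
  jsonlite::write_json(yml, fj, auto_unbox = TRUE, digits = NA)
  backj <- read_gating_tree(fj)
  expect_equal(backj$nodes$Monocytes$gate$side, c("above", "above"))
  expect_error(read_gating_tree("no/such/file.yaml"), "not found")
})

test_that("bead normalization follows the counting-bead formula", {
  expect_equal(beads_normalize(1000, 100, 10000, 225), 1000 * 100 / 225)
  expect_equal(round(beads_normalize(1000, 100, 10000, 225), 1), 444.4)
  expect_equal(beads_normalize(1000, 200, 10000, 225),
               beads_normalize(1000, 100, 10000, 225) / 2)
  # linear in population events
  expect_equal(beads_normalize(c(10, 20, 40), 100, 10000, 225),
               c(1, 2, 4) * beads_normalize(10, 100, 10000, 225))
  expect_error(beads_normalize(1000, 0, 10000, 225), "bead_events")
  expect_error(beads_normalize(1000, 100, 10000, 0), "volume")
})

test_that("the shipped innate tree file matches the built-in default", {
  path <- system.file("extdata", "innate_tree.yaml", package = "neonflow")
  expect_true(nzchar(path))
  shipped <- read_gating_tree(path)
  builtin <- default_gating_tree("innate")
  expect_identical(names(shipped$nodes), names(builtin$nodes))
  for (nm in names(builtin$nodes)) {
    expect_equal(shipped$nodes[[nm]]$gate[c("kind", "channels", "side",
                                            "threshold", "vertices")],
                 builtin$nodes[[nm]]$gate[c("kind", "channels", "side",
                                            "threshold", "vertices")],
                 label = nm)
  }
})
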