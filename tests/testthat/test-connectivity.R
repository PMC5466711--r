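test_that("motion expansion produces the documented 24 columns", {
  T_ <- 20
  zero <- matrix(0, T_, 6)
  expect_equal(build_motion_regressors(zero), matrix(0, T_, 24),
               ignore_attr = TRUE)

  # single unit step in parameter 3 at t = 10: affects p3, p3^2, d3, d3^2
  p <- zero
  p[10:T_, 3] <- 1
  out <- build_motion_regressors(p)
  nonzero_cols <- which(colSums(abs(out)) > 0)
  expect_equal(sort(colnames(out)[nonzero_cols]),
               sort(c("p3", "p3_sq", "d3", "d3_sq")))
  # derivative is the backward difference with zero first row
  expect_equal(out[, "d3"], c(rep(0, 9), 1, rep(0, 10)))
  expect_equal(out[, "d3_sq"], out[, "d3"]^2)
  expect_equal(out[, "p3_sq"], p[, 3]^2)

  # constant parameter: derivative columns identically zero
  cst <- matrix(2, T_, 6)
  outc <- build_motion_regressors(cst)
  expect_true(all(outc[, 13:24] == 0))
  expect_true(all(outc[, 1:6] == 2) && all(outc[, 7:12] == 4))

  expect_error(build_motion_regressors(matrix(0, T_, 5)), "6 motion")
})

test_that("nuisance regression removes trends and confound signal", {
  T_ <- 100
  trend <- matrix(seq_len(T_), T_, 3) * c(1, -2, 0.5)[col(matrix(0, T_, 3))]
  res <- nuisance_regress(trend, poly_order = 1)
  expect_lt(max(abs(res)), 1e-8)

  set.seed(1)
  conf <- matrix(rnorm(T_), T_, 1)
  noise <- rnorm(T_, sd = 0.5)
  ts <- cbind(3 * conf[, 1] + noise)
  res2 <- nuisance_regress(ts, confounds = conf, poly_order = 0)
  expect_equal(var(as.vector(res2)), var(noise), tolerance = 0.1)

  # poly_order = 0 is demeaning only
  set.seed(2)
  zm <- scale(matrix(rnorm(T_ * 4), T_, 4), scale = FALSE)
  expect_equal(nuisance_regress(zm, poly_order = 0), unclass(zm),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("residuals are orthogonal to the retained design columns", {
  T_ <- 80
  set.seed(3)
  ts <- matrix(rnorm(T_ * 5), T_, 5)
  conf <- build_motion_regressors(matrix(rnorm(T_ * 6, sd = 0.1), T_, 6))
  res <- nuisance_regress(ts, confounds = conf, poly_order = 2)
  design <- cbind(1, stats::poly(seq_len(T_), 2), conf)
  ip <- crossprod(design, res)
  norms <- outer(sqrt(colSums(design^2)), sqrt(colSums(res^2)))
  expect_lt(max(abs(ip) / norms), 1e-8)
})

test_that("exactly collinear confounds are dropped with a warning", {
  T_ <- 60
  set.seed(4)
  conf <- matrix(rnorm(T_ * 2), T_, 2)
  conf <- cbind(conf, dup = conf[, 1])
  ts <- matrix(rnorm(T_ * 2), T_, 2)
  expect_warning(res <- nuisance_regress(ts, confounds = conf),
                 "collinear")
  expect_equal(dim(res), dim(ts))
})

test_that("pairwise connectivity matches brute-force Pearson and flags degeneracy", {
  x <- c(1, 3, 2, 5, 4)
  ts <- cbind(a = x, b = x, c = -x)
  m <- roi_connectivity(ts + matrix(rnorm(15, sd = 1e-9), 5, 3) * 0)
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)

  set.seed(5)
  ts3 <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("r1", "r2", "r3")))
  m3 <- roi_connectivity(ts3)
  for (a in 1:2) for (b in (a + 1):3) {
    expect_equal(m3[a, b], brute_force_pearson(ts3[, a], ts3[, b]),
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(unclass(m3), tol = 1e-12))
  expect_true(all(diag(m3) == 1))

  bad <- cbind(r1 = rnorm(10), flat = rep(1, 10))
  expect_error(roi_connectivity(bad), "flat")
})

test_that("connectivity is invariant to affine rescaling of columns", {
  set.seed(6)
  ts <- matrix(rnorm(200 * 4), 200, 4)
  m1 <- roi_connectivity(ts)
  ts2 <- sweep(sweep(ts, 2, c(2, 3, 0.5, 10), `*`), 2, c(1, -5, 0, 2), `+`)
  m2 <- roi_connectivity(ts2)
  expect_lt(max(abs(unclass(m1) - unclass(m2))), 1e-12)
})

test_that("edge vectorization follows the canonical network-block order", {
  m <- matrix(0.5, 4, 4); diag(m) <- 1
  rownames(m) <- colnames(m) <- paste0("roi", 1:4)
  part <- network_partition(rownames(m), rep("default", 4))
  ev <- vectorize_edges(m, part, to_fisher_z = FALSE)
  expect_length(ev$values, 6)
  expect_equal(ev$edge_labels,
               c("roi1--roi2", "roi1--roi3", "roi1--roi4",
                 "roi2--roi3", "roi2--roi4", "roi3--roi4"))

  # mixed partition: blocks ordered by the canonical network list
  part2 <- network_partition(rownames(m),
                             c("default", "visual", "visual", "no_overlap"))
  ev2 <- vectorize_edges(m, part2, to_fisher_z = FALSE)
  expect_equal(unique(ev2$blocks),
               c("visual--visual", "visual--default", "visual--no_overlap",
                 "default--no_overlap"))
  expect_equal(ev2$within, ev2$blocks == "visual--visual")
})

test_that("Fisher z transform is applied with closed-form values and clipping", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0
  m[1, 3] <- m[3, 1] <- 0.5
  m[2, 3] <- m[3, 2] <- -0.25
  rownames(m) <- colnames(m) <- paste0("roi", 1:3)
  part <- network_partition(rownames(m), rep("default", 3))
  ev <- vectorize_edges(m, part, to_fisher_z = TRUE)
  expect_equal(unname(ev$values["roi1--roi2"]), 0)
  expect_equal(unname(ev$values["roi1--roi3"]), atanh(0.5), tolerance = 1e-12)
  expect_equal(round(atanh(0.5), 4), 0.5493)
  expect_equal(unname(ev$values["roi2--roi3"]), atanh(-0.25), tolerance = 1e-12)

  m[1, 2] <- m[2, 1] <- 1
  expect_error(vectorize_edges(m, part, to_fisher_z = TRUE), "roi1--roi2")
  ev_clip <- vectorize_edges(m, part, to_fisher_z = TRUE, clip = TRUE)
  expect_true(is.finite(ev_clip$values["roi1--roi2"]))
})

test_that("vectorization is permutation consistent and invertible", {
  set.seed(7)
  ts <- matrix(rnorm(120 * 5), 120, 5,
               dimnames = list(NULL, paste0("roi", 1:5)))
  m <- roi_connectivity(ts)
  nets <- c("visual", "default", "visual", "limbic", "no_overlap")
  part <- network_partition(colnames(ts), nets)
  ev <- vectorize_edges(m, part, to_fisher_z = FALSE)

  perm <- c(4, 1, 5, 2, 3)
  m_perm <- roi_connectivity(ts[, perm])
  ev_perm <- vectorize_edges(m_perm, part, to_fisher_z = FALSE)
  a <- ev$values[order(names(ev$values))]
  b <- ev_perm$values[order(names(ev_perm$values))]
  expect_equal(a, b, tolerance = 1e-12)

  # reassembly reconstructs the matrix exactly
  back <- edges_to_matrix(ev, colnames(ts))
  expect_equal(back, unclass(m), ignore_attr = TRUE, tolerance = 0)
})

test_that("a 200-ROI parcellation yields 19900 network-sorted edges", {
  labs <- sprintf("roi%03d", 1:200)
  nets <- rep(canonical_networks(), length.out = 200)
  part <- network_partition(labs, nets)
  eo <- fcreliab:::edge_order(part)
  expect_equal(nrow(eo), 19900)
  expect_equal(anyDuplicated(eo$edge_label), 0)
})

test_that("partition TSV reader validates coverage and labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("roi_label\tnetwork", "roi1\tvisual", "roi2\tbogus"), path)
  expect_error(read_partition_tsv(path), "bogus")
  writeLines(c("roi_label\tnetwork", "roi1\tvisual", "roi2\tdefault"), path)
  part <- read_partition_tsv(path)
  expect_s3_class(part, "network_partition")
  expect_error(fcreliab:::edge_order(part, c("roi1", "roi9")), "roi9")
})
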