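test_that("gen_params validates its inputs", {
  expect_error(gen_params(level_probs = numeric(0)), "nonempty")
  expect_error(gen_params(cluster_rho = 1.2))
  expect_error(gen_params(unilateral_prob = -0.1))
  expect_error(gen_params(dvf_sd_mm = -1))
})

test_that("node-count law has median 2, support 1..11, small tail", {
  pmf <- nodalmap:::node_count_pmf(gen_params()$node_count_dist)
  expect_length(pmf, 11L)
  cdf <- cumsum(pmf)
  expect_lt(cdf[1], 0.5)   # median is 2 ...
  expect_gte(cdf[2], 0.5)  # ... by the inverse-CDF definition
  expect_equal(sum(pmf), 1)
})

test_that("same seed reproduces the cohort bit-identically", {
  atlas <- small_atlas()
  gp <- gen_params(n_patients = 15, seed = 42)
  c1 <- sample_cohort(gp, atlas, make_dvfs = FALSE)
  c2 <- sample_cohort(gp, atlas, make_dvfs = FALSE)
  expect_identical(c1$nodes, c2$nodes)
  expect_identical(c1$patients, c2$patients)
  expect_identical(ground_truth_table(c1), ground_truth_table(c2))
})

test_that("cluster_rho = 1 confines every patient to one level family", {
  atlas <- small_atlas()
  co <- sample_cohort(gen_params(n_patients = 30, cluster_rho = 1, seed = 3),
                      atlas, make_dvfs = FALSE)
  n_lv <- vapply(split(co$nodes$level, co$nodes$patient_id),
                 function(x) length(unique(x)), integer(1))
  expect_true(all(n_lv == 1L))
})

test_that("node levels are consistent with classify_point of template positions", {
  atlas <- small_atlas()
  co <- sample_cohort(gen_params(n_patients = 40, seed = 5), atlas,
                      make_dvfs = FALSE)
  cl <- classify_points(as.matrix(
    co$nodes[, c("x_template_mm", "y_template_mm", "z_template_mm")]), atlas)
  expect_identical(cl$level, co$nodes$level)
  expect_identical(cl$side, co$nodes$side)
})

test_that("Monte-Carlo recovery of generating parameters at large n", {
  atlas <- small_atlas()
  gp <- gen_params(n_patients = 2000, seed = 11)
  co <- sample_cohort(gp, atlas, make_dvfs = FALSE)
  # anchor frequencies match the generating anchor distribution within 3 SE
  # (involvement frequencies exceed anchor probabilities by construction:
  # adjacency spillover; see the methods vignette)
  p_anchor <- gp$level_probs / sum(gp$level_probs)
  # surgery suppresses some anchors; restrict to non-surgery patients where
  # the anchor law is exactly level_probs
  pat <- co$patients[!co$patients$surgery, ]
  freq <- table(factor(pat$anchor_level, levels = names(p_anchor)))
  n <- nrow(pat)
  for (f in names(p_anchor)) {
    se <- sqrt(p_anchor[[f]] * (1 - p_anchor[[f]]) / n)
    expect_lt(abs(freq[[f]] / n - p_anchor[[f]]), 3 * se + 1e-12)
  }
  # involvement frequency is rank-consistent with the anchor law for the
  # well-separated probabilities
  gt <- ground_truth_table(co)
  inv <- gt$per_level_involvement
  expect_gt(inv[["external_iliac"]], inv[["presacral"]])
  expect_gt(inv[["internal_iliac"]], inv[["inguinal"]])
  # node-count law: median 2, range within 1..11
  expect_equal(stats::median(gt$node_counts), 2)
  expect_gte(min(gt$node_counts), 1L)
  expect_lte(max(gt$node_counts), 11L)
  # strictly unilateral fraction close to the target
  u <- gp$unilateral_prob
  expect_lt(abs(gt$unilateral_fraction - u), 3 * sqrt(u * (1 - u) / 2000))
  # realized laterality matches the flag
  sides <- vapply(split(co$nodes$side, co$nodes$patient_id),
                  function(s) length(unique(s[s != "none"])), integer(1))
  flagged <- co$patients$unilateral[match(names(sides), co$patients$patient_id)]
  expect_true(all(sides[!flagged] == 2L))
  expect_true(all(sides[flagged] <= 1L))
})

test_that("ground-truth table conserves node counts", {
  atlas <- small_atlas()
  co <- sample_cohort(gen_params(n_patients = 25, seed = 9), atlas,
                      make_dvfs = FALSE)
  gt <- ground_truth_table(co)
  expect_equal(sum(unlist(gt$per_level_node_counts)), nrow(co$nodes))
  expect_equal(sum(gt$node_counts), nrow(co$nodes))
  # single-patient, single-node cohort: that level has proportion 1
  co1 <- sample_cohort(gen_params(
    n_patients = 1, node_count_dist = list(type = "table", probs = 1),
    seed = 2), atlas, make_dvfs = FALSE)
  expect_equal(nrow(co1$nodes), 1L)
  gt1 <- ground_truth_table(co1)
  expect_equal(gt1$per_level_involvement[[co1$nodes$level]], 1)
})

test_that("surgery effect suppresses the right external iliac anchor", {
  atlas <- small_atlas()
  co <- sample_cohort(gen_params(n_patients = 3000, seed = 13), atlas,
                      make_dvfs = FALSE)
  pat <- co$patients
  rate <- function(surg) mean(
    pat$anchor_level[pat$surgery == surg] == "external_iliac" &
      pat$side_pref[pat$surgery == surg] == "right")
  expect_lt(rate(TRUE), 0.6 * rate(FALSE))
})

test_that("make_dvf honors the zero-field and magnitude contracts", {
  grid <- template_grid(c(24L, 24L, 30L), c(8, 8, 8))
  d0 <- make_dvf(grid, 0, 25, seed = 1)
  expect_true(all(d0$forward$vectors == 0))
  expect_true(all(d0$inverse$vectors == 0))
  d <- make_dvf(grid, 3, 25, seed = 4, invert = FALSE)
  # control-point displacement SD within 15% of the requested sd
  expect_lt(abs(stats::sd(as.vector(d$forward$vectors)) - 3) / 3, 0.15)
})

test_that("exact inversion round-trips random points within 0.2 mm", {
  grid <- template_grid(c(64L, 64L, 80L), c(4, 4, 4))
  d <- make_dvf(grid, 3, 25, seed = 8, invert = FALSE)
  set.seed(21)
  pts <- cbind(runif(1000, 10, 240), runif(1000, 10, 240), runif(1000, 10, 300))
  native <- pts + nodalmap:::dvf_displacement(d$forward, pts)
  back <- invert_points(d$forward, native)
  expect_lt(max(sqrt(rowSums((back - pts)^2))), 0.2)
})

test_that("the gridded inverse field is a coarser, documented approximation", {
  grid <- template_grid(c(64L, 64L, 80L), c(4, 4, 4))
  d <- make_dvf(grid, 3, 25, seed = 8)
  set.seed(22)
  pts <- cbind(runif(300, 20, 230), runif(300, 20, 230), runif(300, 20, 290))
  native <- pts + nodalmap:::dvf_displacement(d$forward, pts)
  back <- apply_dvf(native, d$inverse)
  err <- sqrt(rowSums((back - pts)^2))
  expect_lt(max(err), 4)     # interpolation-limited, not exact
  expect_lt(mean(err), 1)
})

test_that("slowly contracting deformations exceed the iteration cap loudly", {
  # linear forward field F(x) = -0.9 (x - c): contraction factor 0.9, far
  # from converged after 5 iterations at 0.05 mm tolerance
  grid <- template_grid(c(6L, 6L, 6L), c(20, 20, 20))
  ctr <- c(50, 50, 50)
  idx <- as.matrix(expand.grid(1:6, 1:6, 1:6))
  w <- nodalmap:::index_to_world(grid, idx)
  vec <- array(0, c(6, 6, 6, 3))
  for (k in 1:3) vec[, , , k] <- array(-0.9 * (w[, k] - ctr[k]), c(6, 6, 6))
  fwd <- displacement_field(vec, grid, "template_to_native")
  expect_error(invert_points(fwd, rbind(c(30, 40, 60)), max_iter = 5),
               "did not converge")
})

test_that("homogeneous and iid spatial modes produce valid cohorts", {
  atlas <- small_atlas()
  for (mode in c("homogeneous", "iid")) {
    co <- sample_cohort(gen_params(n_patients = 20, seed = 6), atlas,
                        make_dvfs = FALSE, spatial_mode = mode)
    cl <- classify_points(as.matrix(
      co$nodes[, c("x_template_mm", "y_template_mm", "z_template_mm")]), atlas)
    expect_identical(cl$level, co$nodes$level)
    expect_true(all(co$nodes$level %in% atlas$table$level))
  }
})
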