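test_that("template grid validates inputs and maps indices to world", {
  expect_error(template_grid(c(0, 10, 10)), "shape")
  expect_error(template_grid(c(4, 4, 4), c(2, 0, 2)), "spacing")
  g <- template_grid(c(10, 12, 14), c(1, 2, 3), c(5, -5, 0))
  expect_equal(voxel_volume_cm3(g), 6 / 1000)
  w <- nodalmap:::index_to_world(g, rbind(c(1, 1, 1), c(10, 12, 14)))
  expect_equal(w[1, ], c(5, -5, 0))
  expect_equal(w[2, ], c(5 + 9 * 1, -5 + 11 * 2, 0 + 13 * 3))
  expect_equal(nodalmap:::world_to_index(g, w), rbind(c(1, 1, 1), c(10, 12, 14)))
})

test_that("default atlas has all level families, mirror pairs, positive volumes", {
  atlas <- small_atlas()
  expect_setequal(unique(atlas$table$level), level_families())
  # 8 of 9 families side-split; presacral unsided
  expect_equal(nrow(atlas$table), 17L)
  expect_equal(sum(atlas$table$side == "none"), 1L)
  expect_true(all(atlas$table$volume_cm3 > 0))
  # paired levels have identical volumes (exact mirror construction)
  for (f in setdiff(level_families(), "presacral")) {
    v <- atlas$table$volume_cm3[atlas$table$level == f]
    expect_identical(v[1], v[2])
  }
  # deterministic rebuild
  atlas2 <- build_template(default_template_config(c(64L, 64L, 80L), c(4, 4, 4)))
  expect_identical(atlas$labels, atlas2$labels)
})

test_that("box primitive volume is exact on a 1 mm grid", {
  # 20 x 25 x 40 mm box positioned so voxel centers tile it exactly
  cfg <- list(
    grid = template_grid(c(60L, 60L, 60L), c(1, 1, 1)),
    levels = list(list(name = "obturator", sided = FALSE, consensus = TRUE,
                       pelvic = TRUE, shape = "box",
                       center = c(0, 25, 30.5), half = c(10, 12.5, 20))))
  atlas <- build_template(cfg)
  expect_equal(atlas$table$volume_cm3, 20.0)
})

test_that("overlapping and zero-volume primitives are rejected with names", {
  cfg <- toy_config()
  cfg$levels[[2]] <- list(name = "presacral", sided = FALSE, consensus = TRUE,
                          pelvic = TRUE, shape = "box",
                          center = c(8, 12, 14), half = c(5, 5, 5))
  expect_error(build_template(cfg), "presacral.*obturator|obturator.*presacral")
  cfg2 <- toy_config()
  cfg2$levels[[1]]$half <- c(0.1, 0.1, 0.1)  # no voxel center inside
  expect_error(build_template(cfg2), "zero-volume.*obturator")
})

test_that("mirror symmetry: reflecting a point swaps left/right labels", {
  atlas <- small_atlas()
  mid <- nodalmap:::atlas_midline(atlas$grid)
  set.seed(41)
  pts <- cbind(runif(3000, 0, 252), runif(3000, 0, 252), runif(3000, 0, 316))
  a <- classify_points(pts, atlas)
  b <- classify_points(cbind(2 * mid - pts[, 1], pts[, 2], pts[, 3]), atlas)
  flip <- c(left = "right", right = "left", none = "none")
  expect_identical(b$level, a$level)
  expect_identical(b$side, unname(flip[a$side]))
})

test_that("volumes are additive: levels plus background equal the grid", {
  atlas <- small_atlas()
  n_lab <- sum(atlas$labels > 0)
  expect_identical(sum(atlas$table$volume_cm3),
                   n_lab * voxel_volume_cm3(atlas$grid))
  expect_equal(n_lab + sum(atlas$labels == 0), prod(atlas$grid$shape))
})

test_that("expand_levels: identity at 0, ball volume, monotonicity, nearest-level ties", {
  atlas <- toy_atlas()
  expect_identical(expand_levels(atlas, margin_spec(0)), atlas)

  # single-voxel level dilated by 7 mm on a 1 mm grid is a 7 mm ball
  cfg <- list(grid = template_grid(c(21L, 21L, 21L), c(1, 1, 1)),
              levels = list(list(name = "obturator", sided = FALSE,
                                 consensus = TRUE, pelvic = TRUE,
                                 shape = "box", center = c(0, 10, 10),
                                 half = c(0.4, 0.4, 0.4))))
  a1 <- build_template(cfg)
  expect_equal(sum(a1$labels > 0), 1L)
  ex <- expand_levels(a1, margin_spec(7, "obturator"))
  v_ball <- 4 / 3 * pi * 0.7^3
  expect_lt(abs(ex$table$volume_cm3 - v_ball) / v_ball, 0.05)

  # monotone in margin on the real geometry
  atlas4 <- small_atlas()
  e7 <- expand_levels(atlas4, margin_spec(7))
  e10 <- expand_levels(atlas4, margin_spec(10))
  expect_true(all(e10$labels[e7$labels > 0] > 0))
  expect_true(all(e10$table$volume_cm3 >= e7$table$volume_cm3))

  # expansion never overwrites existing labels
  keep <- atlas4$labels > 0
  expect_identical(e10$labels[keep], atlas4$labels[keep])
})

test_that("expanded-overlap voxels go to the nearest level, ties to lowest label", {
  # two single-voxel levels 6 mm apart, margin 7: midpoint voxels equidistant
  cfg <- list(grid = template_grid(c(25L, 15L, 15L), c(1, 1, 1)),
              levels = list(
                list(name = "obturator", sided = FALSE, consensus = TRUE,
                     pelvic = TRUE, shape = "box", center = c(-3, 7, 7),
                     half = c(0.4, 0.4, 0.4)),
                list(name = "presacral", sided = FALSE, consensus = TRUE,
                     pelvic = TRUE, shape = "box", center = c(3, 7, 7),
                     half = c(0.4, 0.4, 0.4))))
  a <- build_template(cfg)
  ex <- expand_levels(a, margin_spec(7, c("obturator", "presacral")))
  # voxel at x=11 is nearer label 1; x=13 nearer label 2; x=12 is a tie
  expect_equal(ex$labels[12, 8, 8], 1L)
  expect_equal(ex$labels[14, 8, 8], 2L)
  expect_equal(ex$labels[13, 8, 8], 1L)  # tie -> lowest label id
})

test_that("classify_point handles centroids, margins and bad input", {
  atlas <- fine_atlas()
  # centroid of the left obturator tube (midline + 52, 120, 140)
  mid <- nodalmap:::atlas_midline(atlas$grid)
  cl <- classify_point(c(mid + 52, 120, 140), atlas)
  expect_equal(cl$level, "obturator")
  expect_equal(cl$side, "left")
  # point 5 mm lateral of the common iliac tube surface: outside at margin 0,
  # inside after a 7 mm vessel margin
  p <- c(mid + 25 + 14, 116, 262.5)
  expect_equal(classify_point(p, atlas)$level, "outside")
  ex <- expand_levels(atlas, margin_spec(7))
  expect_equal(classify_point(p, ex)$level, "common_iliac")
  # out-of-grid and non-finite
  expect_equal(classify_point(c(-500, 0, 0), atlas)$level, "outside")
  expect_error(classify_point(c(NA, 0, 0), atlas), "finite")
})

test_that("classify_points agrees with an exhaustive voxel-scan oracle", {
  atlas <- toy_atlas()
  g <- atlas$grid
  centers <- nodalmap:::index_to_world(g, as.matrix(expand.grid(
    seq_len(g$shape[1]), seq_len(g$shape[2]), seq_len(g$shape[3]))))
  set.seed(7)
  n <- 10000
  ext <- nodalmap:::grid_extent(g)
  pts <- cbind(runif(n, ext[1, 1] - 3, ext[1, 2] + 3),
               runif(n, ext[2, 1] - 3, ext[2, 2] + 3),
               runif(n, ext[3, 1] - 3, ext[3, 2] + 3))
  got <- classify_points(pts, atlas)
  lab_oracle <- integer(n)
  half <- g$spacing / 2
  inside <- pts[, 1] >= ext[1, 1] - half[1] & pts[, 1] <= ext[1, 2] + half[1] &
            pts[, 2] >= ext[2, 1] - half[2] & pts[, 2] <= ext[2, 2] + half[2] &
            pts[, 3] >= ext[3, 1] - half[3] & pts[, 3] <= ext[3, 2] + half[3]
  for (i in seq_len(n)) {
    if (!inside[i]) next
    d2 <- (centers[, 1] - pts[i, 1])^2 + (centers[, 2] - pts[i, 2])^2 +
          (centers[, 3] - pts[i, 3])^2
    lab_oracle[i] <- atlas$labels[which.min(d2)]
  }
  expect_identical(got$label, lab_oracle)
})

test_that("consensus_coverage flags non-consensus and outside nodes per patient", {
  atlas <- small_atlas()
  mid <- nodalmap:::atlas_midline(atlas$grid)
  # all nodes inside a consensus level -> fraction 0
  inside <- make_nodes(rbind(c(mid + 52, 120, 140), c(mid + 52, 120, 150)),
                       c("A", "B"))
  cov <- consensus_coverage(inside, atlas, margins = 7)
  expect_equal(cov$margin_7mm$fraction_uncovered, 0)
  # perirectal (non-consensus) node makes a patient uncovered
  mix <- rbind(inside,
               make_nodes(c(mid + 18, 150, 130), "C", level = "perirectal"))
  cov2 <- consensus_coverage(mix, atlas, margins = 7)
  expect_equal(cov2$margin_7mm$n_uncovered_patients, 1L)
  expect_equal(cov2$margin_7mm$per_level_uncovered$perirectal, 1L)
  # native-space input is rejected
  bad <- inside; bad$space <- "native"
  expect_error(consensus_coverage(bad, atlas), "template")
})

test_that("a node on a dilated boundary voxel counts as covered", {
  atlas <- small_atlas()
  ex <- expand_levels(atlas, margin_spec(7))
  # find a voxel claimed by dilation at the largest distance <= 7 mm
  lab_common <- atlas$table$label[atlas$table$level == "common_iliac" &
                                    atlas$table$side == "left"]
  d <- nodalmap:::edt_mm(atlas$labels == lab_common, atlas$grid$spacing)
  claimed <- which(ex$labels == lab_common & atlas$labels == 0L)
  vox <- claimed[which.max(d[claimed])]
  expect_lte(d[vox], 7)
  idx <- arrayInd(vox, atlas$grid$shape)
  p <- nodalmap:::index_to_world(atlas$grid, idx)
  nodes <- make_nodes(p, "A", level = "common_iliac")
  cov <- consensus_coverage(nodes, atlas, margins = 7)
  expect_equal(cov$margin_7mm$fraction_uncovered, 0)
})

test_that("percent formatting is half-up at one decimal", {
  expect_identical(percent_halfup(26, 75), 34.7)
  expect_identical(percent_halfup(28, 75), 37.3)
  expect_identical(percent_halfup(1, 8), 12.5)
  expect_identical(percent_halfup(0, 5), 0)
})
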