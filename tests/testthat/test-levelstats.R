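fake_atlas <- function(levels, volumes) {
  structure(list(table = data.frame(
    label = seq_along(levels), level = levels, side = "none",
    consensus = TRUE, pelvic = TRUE, volume_cm3 = volumes,
    stringsAsFactors = FALSE)), class = "level_atlas")
}

test_that("binary involvement: single-patient example and brute-force oracle", {
  atlas <- small_atlas()
  one <- make_nodes(c(0, 0, 0), "A", level = "obturator", side = "left")
  bi <- binary_involvement(one, atlas)
  expect_equal(bi$combined$percent[bi$combined$level == "obturator"], 100)
  expect_equal(sum(bi$combined$percent), 100)
  bs <- bi$by_side
  expect_equal(bs$percent[bs$level == "obturator" & bs$side == "left"], 100)
  expect_equal(sum(bs$percent), 100)
  expect_error(binary_involvement(one[0, ], atlas), "empty")

  co <- sample_cohort(gen_params(n_patients = 40, seed = 19), atlas,
                      make_dvfs = FALSE)
  nt <- node_table(co, "template")
  got <- binary_involvement(nt, atlas)
  for (f in unique(atlas$table$level)) {
    n_oracle <- sum(vapply(split(nt$level, nt$patient_id),
                           function(x) f %in% x, logical(1)))
    expect_equal(got$combined$n[got$combined$level == f], n_oracle)
  }
  # per-patient "any side" involvement is implied by each single side
  for (r in seq_len(nrow(got$by_side)))
    expect_lte(got$by_side$n[r],
               got$combined$n[got$combined$level == got$by_side$level[r]])
})

test_that("Fisher exact: trivial, exact-fraction and error cases", {
  expect_equal(fisher_exact_2x2(matrix(c(0, 10, 0, 10), 2, byrow = TRUE))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p_value,
               34 / 70)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 0, 0), 2)), "empty")
})

test_that("Fisher exact matches a dhyper enumeration oracle on small tables", {
  oracle <- function(m) {
    r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
    k <- max(0, c1 - r2):min(r1, c1)
    pr <- stats::dhyper(k, r1, r2, c1)
    obs <- stats::dhyper(m[1, 1], r1, r2, c1)
    min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
  }
  # every table with total <= 12 (exhaustive), plus random larger tables
  for (N in 0:12) for (a in 0:N) for (b in 0:(N - a)) for (cc in 0:(N - a - b)) {
    m <- matrix(c(a, b, cc, N - a - b - cc), 2, byrow = TRUE)
    if (sum(m) == 0) next
    expect_equal(fisher_exact_2x2(m)$p_value, oracle(m), tolerance = 1e-12)
  }
  set.seed(4)
  for (i in 1:200) {
    m <- matrix(rpois(4, 20), 2)
    expect_equal(fisher_exact_2x2(m)$p_value, oracle(m), tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(m)$p_value,
                 stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("bonferroni adjusts, caps, and validates", {
  expect_equal(bonferroni(0.002, m = 11), 0.022)
  expect_equal(bonferroni(0.2, m = 11), 1)
  expect_equal(bonferroni(0.37), 0.37)  # m = 1 identity
  p <- c(0.01, 0.02, 0.5)
  expect_equal(bonferroni(p), pmin(1, 3 * p))
  expect_true(all(diff(bonferroni(sort(p))) >= 0))  # monotone
  expect_error(bonferroni(1.2), "\\[0,1\\]")
})

test_that("surgery contrasts test 11 regions with Bonferroni m recorded", {
  co <- sample_cohort(gen_params(n_patients = 60, seed = 3), small_atlas(),
                      make_dvfs = FALSE)
  sc <- surgery_contrasts(node_table(co, "template"), small_atlas())
  expect_equal(nrow(sc), 11L)
  expect_equal(attr(sc, "n_adjust"), 11L)
  expect_equal(sc$p_adjusted, pmin(1, 11 * sc$p))
})

test_that("relative proportions: worked examples and conservation", {
  nodes <- rbind(
    make_nodes(matrix(0, 2, 3), c("A", "A"), level = "external_iliac"),
    make_nodes(c(0, 0, 0), "A", level = "obturator"),
    make_nodes(c(0, 0, 0), "B", level = "perirectal"),
    make_nodes(c(0, 0, 0), "C", level = "inguinal"))  # not considered
  rp <- relative_proportions(nodes)
  expect_equal(rp$profiles$external_iliac[rp$profiles$patient_id == "A"], 2 / 3)
  expect_equal(rp$profiles$obturator[rp$profiles$patient_id == "A"], 1 / 3)
  expect_equal(rp$dropped_patients, "C")
  # rows sum to 1, so the level means sum to 1
  expect_equal(rowSums(rp$profiles[, rp$considered_levels]), rep(1, 2),
               ignore_attr = TRUE)
  expect_equal(sum(colMeans(rp$profiles[, rp$considered_levels])), 1)
  # single-node patients yield indicator rows
  expect_true(all(rp$profiles[2, rp$considered_levels] %in% c(0, 1)))
  expect_error(relative_proportions(nodes, considered_levels = character(0)),
               "nonempty")
})

test_that("volume-normalized means: arithmetic, reference, scaling", {
  atlas <- fake_atlas(c("A", "B"), c(10, 40))
  prop <- list(profiles = data.frame(patient_id = c("p1", "p2"),
                                     A = c(1, 0.5), B = c(0, 0.5),
                                     check.names = FALSE),
               considered_levels = c("A", "B"))
  vn <- volume_normalized_means(prop, atlas)
  expect_equal(vn$table$value_permille_cm3, c(75, 6.25))
  expect_equal(vn$reference_permille_cm3, 20)
  # doubling volumes halves values and reference
  vn2 <- volume_normalized_means(prop, fake_atlas(c("A", "B"), c(20, 80)))
  expect_equal(vn2$table$value_permille_cm3, vn$table$value_permille_cm3 / 2)
  expect_equal(vn2$reference_permille_cm3, 10)
  expect_error(volume_normalized_means(prop, fake_atlas(c("A", "B"), c(0, 40))),
               "zero-volume")
})

test_that("homogeneous cohorts sit at the reference for every level", {
  atlas <- small_atlas()
  co <- sample_cohort(gen_params(n_patients = 600, seed = 41), atlas,
                      make_dvfs = FALSE, spatial_mode = "homogeneous")
  rp <- relative_proportions(node_table(co, "template"))
  vn <- volume_normalized_means(rp, atlas)
  for (lv in vn$table$level) {
    vals <- 1000 * rp$profiles[[lv]] /
      vn$table$volume_cm3[vn$table$level == lv]
    se <- stats::sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - vn$reference_permille_cm3), 3 * se)
  }
})

test_that("BCa CI: degenerate samples and the symmetric large-sample limit", {
  d <- bca_ci(rep(3.5, 10), bootstrap_spec(B = 100))
  expect_equal(c(d$ci_low, d$ci_high), c(3.5, 3.5))
  expect_error(bca_ci(numeric(0)), "empty")
  set.seed(6)
  x <- rnorm(2000)
  spec <- bootstrap_spec(B = 4000, seed = 7)
  ci <- bca_ci(x, spec)
  prep <- nodalmap:::bca_prep(x, spec)
  perc <- stats::quantile(prep$boot, c(0.025, 0.975), names = FALSE)
  w_bca <- ci$ci_high - ci$ci_low
  w_perc <- perc[2] - perc[1]
  expect_lt(abs(w_bca - w_perc) / w_perc, 0.05)
  expect_lt(abs(prep$z0), 0.1)
  expect_lt(abs(prep$a), 0.01)
})

test_that("bootstrap mean test: null, strong shift, degenerate", {
  set.seed(8)
  x <- rnorm(60, mean = 10, sd = 1)
  spec <- bootstrap_spec(B = 2000, seed = 9)
  expect_gt(bootstrap_mean_test(x, mean(x), spec)$p_value, 0.5)
  expect_lte(bootstrap_mean_test(x, 10 - 8 / sqrt(60), spec)$p_value, 0.001)
  expect_equal(bootstrap_mean_test(rep(2, 5), 2, spec)$p_value, 1)
  expect_error(bootstrap_mean_test(numeric(0), 0, spec), "empty")
})

test_that("planted enrichment is recovered and depletion is rejected more often", {
  atlas <- small_atlas()
  vols <- vapply(c("external_iliac", "internal_iliac", "obturator",
                   "common_iliac", "presacral", "perirectal"), function(f)
    sum(atlas$table$volume_cm3[atlas$table$level == f]), numeric(1))
  base <- vols / sum(vols)  # flat volume-normalized baseline
  probs <- base
  probs["obturator"] <- probs["obturator"] * 4     # enriched
  probs["presacral"] <- probs["presacral"] * 0.25  # depleted
  top <- 0
  rej <- matrix(0, 40, 6, dimnames = list(NULL, names(vols)))
  for (r in 1:40) {
    co <- sample_cohort(gen_params(n_patients = 75, level_probs = probs,
                                   seed = 100 + r), atlas, make_dvfs = FALSE)
    rp <- relative_proportions(node_table(co, "template"))
    vn <- volume_normalized_means(rp, atlas)
    top <- top + (vn$table$level[which.max(vn$table$value_permille_cm3)] ==
                    "obturator")
    for (lv in names(vols)) {
      vals <- 1000 * rp$profiles[[lv]] /
        vn$table$volume_cm3[vn$table$level == lv]
      tst <- bootstrap_mean_test(vals, vn$reference_permille_cm3,
                                 bootstrap_spec(B = 499, seed = r * 13))
      rej[r, lv] <- tst$p_value < 0.05
    }
  }
  expect_gte(top / 40, 0.9)
  others <- setdiff(names(vols), c("presacral", "obturator"))
  expect_gt(mean(rej[, "presacral"]), mean(rej[, others]))
})
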