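#' Binary involvement frequencies per nodal region
#'
#' Per region, the number and percentage of patients with at least one node
#' in it, reported both per level family (combined) and split by side.
#' Percentages are rounded half-up to one decimal place for report parity.
#'
#' @param nodes node table (classified, i.e. with `level` and `side`
#'   columns) or a `node_cohort`.
#' @param atlas a `level_atlas` (defines the region list; regions without
#'   any node report 0).
#' @return list with `n_patients`, `combined` (data.frame: level, n,
#'   percent) and `by_side` (data.frame: level, side, n, percent).
#' @export
binary_involvement <- function(nodes, atlas) {
  if (inherits(nodes, "node_cohort")) nodes <- node_table(nodes, "template")
  if (nrow(nodes) == 0) stop("empty cohort")
  pats <- unique(nodes$patient_id)
  P <- length(pats)
  fams <- unique(atlas$table$level)
  by_pat_level <- unique(nodes[, c("patient_id", "level")])
  combined <- data.frame(
    level = fams,
    n = vapply(fams, function(f)
      sum(by_pat_level$level == f), integer(1)),
    stringsAsFactors = FALSE)
  combined$percent <- percent_halfup(combined$n, P)
  by_pat_side <- unique(nodes[, c("patient_id", "level", "side")])
  sided <- atlas$table[atlas$table$side != "none", c("level", "side")]
  by_side <- data.frame(
    level = sided$level, side = sided$side,
    n = vapply(seq_len(nrow(sided)), function(r)
      sum(by_pat_side$level == sided$level[r] &
            by_pat_side$side == sided$side[r]), integer(1)),
    stringsAsFactors = FALSE)
  by_side$percent <- percent_halfup(by_side$n, P)
  rownames(combined) <- rownames(by_side) <- NULL
  list(n_patients = P, combined = combined, by_side = by_side)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact enumeration in log space of all tables with the observed margins;
#' the two-sided p-value is the sum of hypergeometric point probabilities
#' not exceeding that of the observed table (minimum-likelihood rule, with a
#' relative tolerance of 1e-7 on the comparison to absorb rounding).
#'
#' @param table 2x2 matrix of nonnegative integer counts (rows: groups,
#'   columns: outcome yes/no).
#' @return a `test_result`; the statistic is the sample odds ratio.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (sum(table) == 0) stop("empty table")
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1])
  k <- max(0, c1 - r2):min(r1, c1)
  # log hypergeometric pmf via lgamma (log-space enumeration)
  lp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(r1 + r2, c1)
  lobs <- lp[match(table[1, 1], k)]
  p <- sum(exp(lp[lp <= lobs + 1e-7]))
  p <- min(1, p)
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  test_result(or, p, method = "fisher_exact")
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` with `m = length(p_values)` (or an explicit `m`).
#'
#' @param p_values numeric vector of p-values in [0,1].
#' @param m number of comparisons (defaults to the vector length).
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0,1]")
  pmin(1, m * p_values)
}

#' Subgroup contrasts of binary involvement (Fisher + Bonferroni)
#'
#' Compares involvement of each sided region (and unsided families) between
#' two patient groups (e.g. prior surgery vs none) with Fisher's exact test,
#' Bonferroni-adjusted over the number of region rows tested.
#'
#' @param nodes classified node table with a logical `surgery` column (or a
#'   `node_cohort`).
#' @param atlas a `level_atlas`.
#' @param regions data.frame with `level` and `side` columns selecting the
#'   rows to test; defaults to all sided pelvic regions plus unsided
#'   families (presacral), excluding paraaortic, inguinal and prevesical --
#'   the 11-row layout of the involvement-contrast report.
#' @return data.frame: level, side, percent in each group, raw and adjusted
#'   p-values; attribute `n_adjust`.
#' @export
surgery_contrasts <- function(nodes, atlas, regions = NULL) {
  if (inherits(nodes, "node_cohort")) nodes <- node_table(nodes, "template")
  stopifnot(!is.null(nodes$surgery))
  if (is.null(regions)) {
    t <- atlas$table
    keep <- t$pelvic & !(t$level %in% c("inguinal", "prevesical"))
    regions <- t[keep, c("level", "side")]
  }
  pat <- unique(nodes[, c("patient_id", "surgery")])
  inv <- unique(nodes[, c("patient_id", "level", "side")])
  rows <- lapply(seq_len(nrow(regions)), function(r) {
    lv <- regions$level[r]; sd_ <- regions$side[r]
    hit <- inv$patient_id[inv$level == lv &
                            (sd_ == "none" | inv$side == sd_)]
    pat$involved <- pat$patient_id %in% hit
    a <- sum(!pat$surgery & pat$involved); b <- sum(!pat$surgery & !pat$involved)
    c_ <- sum(pat$surgery & pat$involved); d <- sum(pat$surgery & !pat$involved)
    ft <- fisher_exact_2x2(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    data.frame(level = lv, side = sd_,
               pct_no_surgery = percent_halfup(a, a + b),
               pct_surgery = percent_halfup(c_, c_ + d),
               p = ft$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p, m = nrow(out))
  attr(out, "n_adjust") <- nrow(out)
  out
}

#' Per-patient relative level proportions
#'
#' For each patient, the share of that patient's counted pelvic nodes that
#' falls in each considered level: `r_l = n_nodes(l) / n_nodes(considered)`.
#' Working with per-patient shares (rather than pooled node counts) removes
#' the bias toward patients with many metastases. Patients with zero nodes
#' in the considered set contribute nothing and are reported as dropped.
#'
#' @param nodes classified node table or `node_cohort`.
#' @param considered_levels level families entering the analysis; default
#'   the consensus families plus perirectal.
#' @return list with `profiles` (data.frame, one row per retained patient,
#'   one column per level, rows summing to 1), `dropped_patients`.
#' @export
relative_proportions <- function(nodes,
                                 considered_levels = c("external_iliac",
                                                       "internal_iliac",
                                                       "obturator",
                                                       "common_iliac",
                                                       "presacral",
                                                       "perirectal")) {
  if (inherits(nodes, "node_cohort")) nodes <- node_table(nodes, "template")
  if (length(considered_levels) == 0) stop("considered_levels must be nonempty")
  keep <- nodes$level %in% considered_levels
  pats <- unique(nodes$patient_id)
  counted <- nodes[keep, ]
  by_pat <- split(counted$level, counted$patient_id)
  retained <- names(by_pat)
  prof <- t(vapply(by_pat, function(ls) {
    cnt <- vapply(considered_levels, function(l) sum(ls == l), numeric(1))
    cnt / sum(cnt)
  }, numeric(length(considered_levels))))
  colnames(prof) <- considered_levels
  profiles <- data.frame(patient_id = retained, prof,
                         check.names = FALSE, stringsAsFactors = FALSE,
                         row.names = NULL)
  list(profiles = profiles,
       dropped_patients = setdiff(pats, retained),
       considered_levels = considered_levels)
}

#' Volume-normalized mean level proportions and homogeneous reference
#'
#' `value_l = 1000 * mean_p(r_{p,l}) / V_l` in per-mille per cm^3, where
#' `V_l` is the level volume from the atlas (sides pooled for sided
#' families). The reference expected under a spatially homogeneous
#' distribution of metastases is `1000 / sum_l V_l`, identical for all
#' levels (a uniform density puts mass proportional to volume in each level,
#' so dividing by volume flattens it).
#'
#' @param proportions result of [relative_proportions()].
#' @param atlas a `level_atlas`.
#' @return list with `table` (data.frame: level, mean_r, volume_cm3,
#'   value_permille_cm3) and `reference_permille_cm3`.
#' @export
volume_normalized_means <- function(proportions, atlas) {
  lv <- proportions$considered_levels
  vol <- vapply(lv, function(f)
    sum(atlas$table$volume_cm3[atlas$table$level == f]), numeric(1))
  if (any(vol <= 0)) stop("zero-volume level among considered levels")
  mean_r <- colMeans(as.matrix(proportions$profiles[, lv, drop = FALSE]))
  tab <- data.frame(level = lv, mean_r = as.numeric(mean_r),
                    volume_cm3 = as.numeric(vol),
                    value_permille_cm3 = 1000 * as.numeric(mean_r) / vol,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, reference_permille_cm3 = 1000 / sum(vol))
}

#' Bootstrap specification
#'
#' @param B number of bootstrap samples (>= 1000 recommended for reported
#'   results; default 10000).
#' @param alpha two-sided CI level complement (default 0.05).
#' @param seed RNG seed.
#' @export
bootstrap_spec <- function(B = 10000L, alpha = 0.05, seed = 1L) {
  stopifnot(B >= 1, alpha > 0, alpha < 1)
  structure(list(B = as.integer(B), method = "BCa", alpha = alpha,
                 seed = as.integer(seed)),
            class = "bootstrap_spec")
}

# bootstrap machinery shared by bca_ci and bootstrap_mean_test:
# returns sorted bootstrap means, z0 and acceleration a
bca_prep <- function(sample, spec) {
  n <- length(sample)
  set.seed(spec$seed)
  idx <- matrix(sample.int(n, n * spec$B, replace = TRUE), nrow = n)
  boot <- colMeans(matrix(sample[idx], nrow = n))
  obs <- mean(sample)
  frac <- (sum(boot < obs) + 0.5 * sum(boot == obs)) / spec$B
  frac <- min(max(frac, 1 / (2 * spec$B)), 1 - 1 / (2 * spec$B))
  z0 <- stats::qnorm(frac)
  jack <- (sum(sample) - sample) / (n - 1)  # leave-one-out means
  dj <- mean(jack) - jack
  denom <- sum(dj^2)^1.5
  a <- if (denom == 0) 0 else sum(dj^3) / (6 * denom)
  list(boot = sort(boot), z0 = z0, a = a, obs = obs)
}

# BCa-adjusted percentile for nominal percentile(s) q in (0,1)
bca_adjust <- function(prep, q) {
  zq <- stats::qnorm(q)
  stats::pnorm(prep$z0 + (prep$z0 + zq) / (1 - prep$a * (prep$z0 + zq)))
}

#' BCa bootstrap confidence interval for the mean
#'
#' Bias-corrected and accelerated interval: the bias correction z0 comes
#' from the fraction of bootstrap means below the observed mean, the
#' acceleration a from the jackknife skewness, and the interval reads off
#' the BCa-adjusted percentiles of the bootstrap distribution
#' (linear-interpolation quantiles). A degenerate sample (zero variance)
#' returns the point value for both bounds.
#'
#' @param sample numeric vector (n >= 2 for a nondegenerate interval).
#' @param spec a `bootstrap_spec`.
#' @return a `test_result` with `ci_low`/`ci_high`; statistic = sample mean,
#'   p is `NA` (see [bootstrap_mean_test()] for tests).
#' @export
bca_ci <- function(sample, spec = bootstrap_spec()) {
  if (length(sample) == 0) stop("empty sample")
  if (stats::var(sample) == 0 || length(sample) == 1)
    return(test_result(mean(sample), NA_real_, sample[1], sample[1],
                       "bca_bootstrap"))
  prep <- bca_prep(sample, spec)
  q <- bca_adjust(prep, c(spec$alpha / 2, 1 - spec$alpha / 2))
  ci <- stats::quantile(prep$boot, q, names = FALSE, type = 7)
  test_result(prep$obs, NA_real_, ci[1], ci[2], "bca_bootstrap")
}

#' Bootstrapped one-sample test of the mean (BCa inversion)
#'
#' Two-sided p-value by confidence-interval inversion on a shared replicate
#' set: the smallest alpha on a grid (step 0.001) for which `mu0` falls
#' outside the BCa (1 - alpha) interval; 1 if `mu0` is inside at every grid
#' point. Used where normality cannot be assumed (e.g. per-patient relative
#' proportions against the homogeneous reference).
#'
#' @param sample numeric vector.
#' @param mu0 null value of the mean.
#' @param spec a `bootstrap_spec`.
#' @return a `test_result` with the alpha-grid p-value and the BCa CI at
#'   `spec$alpha`.
#' @export
bootstrap_mean_test <- function(sample, mu0, spec = bootstrap_spec()) {
  if (length(sample) == 0) stop("empty sample")
  if (stats::var(sample) == 0 || length(sample) == 1) {
    c0 <- mean(sample)
    return(test_result(c0, if (isTRUE(all.equal(c0, mu0))) 1 else 0.001,
                       c0, c0, "bootstrap_mean_test"))
  }
  prep <- bca_prep(sample, spec)
  alphas <- seq(0.001, 0.999, by = 0.001)
  lo_q <- bca_adjust(prep, alphas / 2)
  hi_q <- bca_adjust(prep, 1 - alphas / 2)
  qs <- stats::quantile(prep$boot, c(lo_q, hi_q), names = FALSE, type = 7)
  lo <- qs[seq_along(alphas)]
  hi <- qs[length(alphas) + seq_along(alphas)]
  outside <- mu0 < lo | mu0 > hi
  p <- if (any(outside)) alphas[which(outside)[1]] else 1
  ci <- stats::quantile(prep$boot,
                        bca_adjust(prep, c(spec$alpha / 2, 1 - spec$alpha / 2)),
                        names = FALSE, type = 7)
  test_result(prep$obs, p, ci[1], ci[2], "bootstrap_mean_test")
}
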