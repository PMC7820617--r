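#' Pairwise distance sets
#'
#' The clustering analysis contrasts two distance populations: unordered
#' pairwise Euclidean distances *within* each patient (concatenated over
#' patients) and pairwise distances across *all* mapped nodes of the cohort.
#' If every patient's metastases sit in a confined region while different
#' patients' regions differ, the intra-patient mean falls below the
#' cohort-level mean. Paraaortic nodes are excluded from all pelvic distance
#' computations by default, matching the analysis population.
#'
#' @name distance_sets
NULL

distance_set <- function(distances, scope, points) {
  structure(list(distances = as.numeric(distances), scope = scope,
                 n_points = nrow(points),
                 n_patients = length(unique(points$patient_id)),
                 points = points),
            class = "distance_set")
}

#' @export
print.distance_set <- function(x, ...) {
  cat(sprintf("distance_set (%s): %d distances from %d points, %d patients, mean %.1f mm\n",
              x$scope, length(x$distances), x$n_points, x$n_patients,
              mean(x$distances)))
  invisible(x)
}

filter_pelvic <- function(nodes, include_paraaortic) {
  if (!include_paraaortic && !is.null(nodes$level))
    nodes <- nodes[nodes$level != "paraaortic", , drop = FALSE]
  nodes
}

#' Intra-patient pairwise distances
#'
#' @param nodes node table with `patient_id`, `x_mm`, `y_mm`, `z_mm` and a
#'   `space` column; or a `node_cohort` (then `space` selects coordinates).
#' @param space `"native"` or `"template"`.
#' @param include_paraaortic keep paraaortic nodes (default FALSE).
#' @return a `distance_set` with scope `intra_patient_<space>`; patients
#'   with a single node contribute no distances.
#' @export
intra_patient_distances <- function(nodes, space = c("native", "template"),
                                    include_paraaortic = FALSE) {
  space <- match.arg(space)
  if (inherits(nodes, "node_cohort")) nodes <- node_table(nodes, space)
  if (!is.null(nodes$space) && !all(nodes$space == space))
    stop("nodes are not in the requested space '", space, "'")
  nodes <- filter_pelvic(nodes, include_paraaortic)
  ds <- unlist(lapply(split(seq_len(nrow(nodes)), nodes$patient_id),
                      function(rows) {
    if (length(rows) < 2) return(numeric(0))
    as.numeric(stats::dist(nodes[rows, c("x_mm", "y_mm", "z_mm")]))
  }), use.names = FALSE)
  distance_set(ds, paste0("intra_patient_", space), nodes)
}

#' Cohort-level pairwise distances between mapped nodes
#'
#' All n(n-1)/2 unordered pairwise distances across the whole mapped cohort.
#'
#' @inheritParams intra_patient_distances
#' @return a `distance_set` with scope `cohort_template`.
#' @export
cohort_distances <- function(nodes, include_paraaortic = FALSE) {
  if (inherits(nodes, "node_cohort")) nodes <- node_table(nodes, "template")
  if (!is.null(nodes$space) && !all(nodes$space == "template"))
    stop("cohort distances require template-space nodes")
  nodes <- filter_pelvic(nodes, include_paraaortic)
  if (nrow(nodes) < 2) stop("need at least 2 nodes")
  ds <- as.numeric(stats::dist(nodes[, c("x_mm", "y_mm", "z_mm")]))
  distance_set(ds, "cohort_template", nodes)
}

#' Statistical comparison result
#'
#' Common container for every statistical comparison in the package.
#'
#' @param statistic test statistic or effect estimate.
#' @param p_value p in [0,1].
#' @param ci_low,ci_high confidence bounds (`NA` if not computed).
#' @param method method tag.
#' @param n_adjust number of comparisons any multiplicity adjustment used.
#' @export
test_result <- function(statistic, p_value, ci_low = NA_real_,
                        ci_high = NA_real_, method = "", n_adjust = 1L) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value outside [0,1]")
  if (!is.na(ci_low) && !is.na(ci_high) && ci_low > ci_high)
    stop("ci_low > ci_high")
  structure(list(statistic = statistic, p_value = p_value, ci_low = ci_low,
                 ci_high = ci_high, method = method,
                 n_adjust = as.integer(n_adjust)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("test_result [%s]: statistic %.4g, p = %.4g", x$method,
              x$statistic, x$p_value))
  if (!is.na(x$ci_low)) cat(sprintf(", CI [%.4g, %.4g]", x$ci_low, x$ci_high))
  if (x$n_adjust > 1) cat(sprintf(" (adjusted for %d comparisons)", x$n_adjust))
  cat("\n")
  invisible(x)
}

#' Compare mean distances of two distance sets
#'
#' Two routes are offered because pairwise distances within either set are
#' statistically dependent. `"pooled_t"` is the naive route: a Welch
#' two-sample t-test on the raw distance lists, mirroring the style of
#' headline comparisons in patterns-of-failure reports. `"patient_bootstrap"`
#' resamples *patients* with replacement, recomputes both means per
#' replicate, and reports a percentile CI of the mean difference and a
#' two-sided p from the bootstrap distribution's sign balance (with a +1
#' continuity correction, so the smallest attainable p is 2/(B+1)).
#'
#' @param a,b `distance_set`s (`a` typically intra-patient, `b` cohort).
#' @param method `"pooled_t"` or `"patient_bootstrap"`.
#' @param B bootstrap replicates (patient_bootstrap only).
#' @param seed RNG seed (patient_bootstrap only).
#' @return a `test_result` whose statistic is `mean(a) - mean(b)` in mm.
#' @export
compare_means <- function(a, b, method = c("pooled_t", "patient_bootstrap"),
                          B = 1000L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(a, "distance_set"), inherits(b, "distance_set"))
  if (length(a$distances) == 0 || length(b$distances) == 0)
    stop("both distance sets must be nonempty")
  diff_obs <- mean(a$distances) - mean(b$distances)
  if (method == "pooled_t") {
    if (identical(a$distances, b$distances))
      return(test_result(0, 1, 0, 0, "pooled_t"))
    tt <- stats::t.test(a$distances, b$distances)
    return(test_result(diff_obs, tt$p.value, tt$conf.int[1], tt$conf.int[2],
                       "pooled_t"))
  }
  # patient bootstrap: both sets recomputed from resampled patients.
  # Within-patient distances do not change under patient resampling, so the
  # intra mean per replicate is assembled from precomputed per-patient sums;
  # only the cohort pool is recomputed.
  coords_a <- lapply(split(seq_len(nrow(a$points)), a$points$patient_id),
                     function(rw) as.matrix(a$points[rw, c("x_mm", "y_mm", "z_mm")]))
  intra_sum <- vapply(coords_a, function(m)
    if (nrow(m) < 2) 0 else sum(stats::dist(m)), numeric(1))
  intra_cnt <- vapply(coords_a, function(m) nrow(m) * (nrow(m) - 1) / 2,
                      numeric(1))
  coords_b <- lapply(split(seq_len(nrow(b$points)), b$points$patient_id),
                     function(rw) as.matrix(b$points[rw, c("x_mm", "y_mm", "z_mm")]))
  pids <- union(names(coords_a), names(coords_b))
  set.seed(seed)
  diffs <- numeric(B)
  for (r in seq_len(B)) {
    take <- sample(pids, length(pids), replace = TRUE)
    cnt <- sum(intra_cnt[take], na.rm = TRUE)
    pool <- do.call(rbind, coords_b[take[take %in% names(coords_b)]])
    if (cnt == 0 || is.null(pool) || nrow(pool) < 2) {
      diffs[r] <- NA_real_
      next
    }
    diffs[r] <- sum(intra_sum[take], na.rm = TRUE) / cnt -
      mean(stats::dist(pool))
  }
  diffs <- diffs[!is.na(diffs)]
  Bk <- length(diffs)
  p <- min(1, 2 * min((1 + sum(diffs <= 0)) / (Bk + 1),
                      (1 + sum(diffs >= 0)) / (Bk + 1)))
  ci <- stats::quantile(diffs, c(0.025, 0.975), names = FALSE)
  test_result(diff_obs, p, ci[1], ci[2], "patient_bootstrap")
}

#' Quantiles of the per-patient maximum node distance
#'
#' Computes, over patients with at least two (pelvic) nodes, the maximum
#' intra-patient pairwise distance, and returns its median, 75th and 95th
#' percentiles using the linear-interpolation quantile convention
#' (`stats::quantile` type 7).
#'
#' @inheritParams intra_patient_distances
#' @return named numeric: `median`, `q75`, `q95` (mm), with attribute
#'   `per_patient_max` holding the underlying maxima.
#' @export
max_intra_distance_quantiles <- function(nodes, space = c("native", "template"),
                                         include_paraaortic = FALSE) {
  space <- match.arg(space)
  if (inherits(nodes, "node_cohort")) nodes <- node_table(nodes, space)
  nodes <- filter_pelvic(nodes, include_paraaortic)
  mx <- vapply(split(seq_len(nrow(nodes)), nodes$patient_id), function(rows) {
    if (length(rows) < 2) return(NA_real_)
    max(stats::dist(nodes[rows, c("x_mm", "y_mm", "z_mm")]))
  }, numeric(1))
  mx <- mx[!is.na(mx)]
  if (length(mx) == 0) stop("no patient with >= 2 nodes")
  q <- stats::quantile(mx, c(0.5, 0.75, 0.95), names = FALSE, type = 7)
  structure(c(median = q[1], q75 = q[2], q95 = q[3]), per_patient_max = mx)
}
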