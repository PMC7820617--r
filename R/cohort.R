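#' Generator parameters for synthetic cohorts
#'
#' The defaults encode the cohort structure the analysis emulates: ~75
#' patients, 1-11 pelvic nodes each with median 2 (zero-truncated negative
#' binomial, size 1.5, mean 2.0, hard-truncated at 11, giving median 2 and
#' P(X > 11) < 0.01 before truncation), strictly unilateral involvement in
#' ~77% of patients, per-level anchor probabilities taken from the observed
#' per-level involvement frequencies, spatial clustering of a patient's
#' nodes around an anchor level (probability `cluster_rho` that a further
#' node joins the anchor, otherwise an anatomically adjacent level), a prior
#' prostatectomy/dissection subgroup (`surgery_prob`) whose right external
#' iliac involvement is suppressed (multiplier 0.25), and smooth per-patient
#' deformations (control-point sd 3 mm on a 25 mm lattice).
#'
#' @param n_patients number of patients.
#' @param level_probs named anchor-level weights over pelvic level families.
#' @param node_count_dist list: `type = "ztnb"` with `size`, `mu`,
#'   `max_nodes`, or `type = "table"` with `probs` over counts 1..length.
#' @param cluster_rho probability in [0,1] that a node beyond the first
#'   joins the patient's anchor level (the first node always anchors, which
#'   guarantees pelvic involvement).
#' @param unilateral_prob target fraction of strictly unilateral patients.
#' @param surgery_prob probability of the prior-surgery flag.
#' @param surgery_effects named multipliers on anchor weights, keyed by
#'   `"family"` or `"family:side"`, applied to surgery patients.
#' @param dvf_sd_mm,dvf_grid_mm displacement-field control-point sd and
#'   lattice spacing (mm).
#' @param seed master RNG seed; per-patient child seeds are derived from it
#'   so patients are independent and reproducible.
#' @return list of class `gen_params`.
#' @export
gen_params <- function(n_patients = 75L,
                       level_probs = c(external_iliac = 0.373,
                                       internal_iliac = 0.253,
                                       perirectal = 0.253,
                                       common_iliac = 0.227,
                                       obturator = 0.200,
                                       presacral = 0.107,
                                       inguinal = 0.040,
                                       prevesical = 0.040),
                       node_count_dist = list(type = "ztnb", size = 1.5,
                                              mu = 2.0, max_nodes = 11L),
                       cluster_rho = 0.8,
                       unilateral_prob = 0.768,
                       surgery_prob = 0.733,
                       surgery_effects = c("external_iliac:right" = 0.25),
                       dvf_sd_mm = 3,
                       dvf_grid_mm = 25,
                       seed = 1L) {
  if (length(level_probs) == 0) stop("level_probs must be nonempty")
  stopifnot(all(level_probs >= 0), any(level_probs > 0),
            cluster_rho >= 0, cluster_rho <= 1,
            unilateral_prob >= 0, unilateral_prob <= 1,
            surgery_prob >= 0, surgery_prob <= 1,
            dvf_sd_mm >= 0, dvf_grid_mm > 0)
  structure(list(n_patients = as.integer(n_patients),
                 level_probs = level_probs,
                 node_count_dist = node_count_dist,
                 cluster_rho = cluster_rho,
                 unilateral_prob = unilateral_prob,
                 surgery_prob = surgery_prob,
                 surgery_effects = surgery_effects,
                 dvf_sd_mm = dvf_sd_mm,
                 dvf_grid_mm = dvf_grid_mm,
                 seed = as.integer(seed)),
            class = "gen_params")
}

# pmf over node counts 1..max for a node_count_dist spec
node_count_pmf <- function(dist) {
  if (dist$type == "ztnb") {
    k <- seq_len(dist$max_nodes)
    p <- stats::dnbinom(k, size = dist$size, mu = dist$mu)
    p / sum(p)
  } else if (dist$type == "table") {
    dist$probs / sum(dist$probs)
  } else stop("unknown node_count_dist type: ", dist$type)
}

# anatomical adjacency between level families; left/right sides communicate
# only through the unsided presacral level (a node that hops to presacral and
# a bilateral patient's cross-side nodes are the only cross-midline routes)
level_adjacency <- function() {
  list(external_iliac = c("obturator", "common_iliac", "inguinal"),
       obturator = c("external_iliac", "internal_iliac", "prevesical"),
       internal_iliac = c("obturator", "perirectal", "presacral"),
       perirectal = "internal_iliac",
       presacral = "internal_iliac",
       common_iliac = c("external_iliac", "paraaortic"),
       paraaortic = "common_iliac",
       inguinal = "external_iliac",
       prevesical = "obturator")
}

# uniformly sample world positions inside a label's mask (voxel + jitter)
sample_in_mask <- function(n, labels_lin, grid) {
  if (length(labels_lin) == 0) stop("anchor level has zero volume")
  lin <- labels_lin[sample.int(length(labels_lin), n, replace = TRUE)]
  lin0 <- lin - 1L
  i <- lin0 %% grid$shape[1]
  j <- (lin0 %/% grid$shape[1]) %% grid$shape[2]
  k <- lin0 %/% (grid$shape[1] * grid$shape[2])
  ctr <- cbind(i, j, k) * rep(grid$spacing, each = n) +
    rep(grid$origin, each = n)
  jit <- matrix(stats::runif(3 * n, -0.5, 0.5), n, 3) *
    rep(grid$spacing, each = n)
  ctr + jit
}

#' Sample a synthetic cohort
#'
#' Draws patients with surgery status, laterality, an anchor level,
#' a node count, spatially clustered node positions inside the atlas level
#' masks, and (optionally) a smooth per-patient deformation field from which
#' native-space coordinates are derived as
#' `native = template + forward displacement`.
#'
#' Three spatial modes are available. `"clustered"` is the stated generative
#' model (anchor + adjacency). `"iid"` draws every node's level
#' independently from the same pooled mixture, which removes intra-patient
#' clustering while keeping the marginal level distribution -- the null
#' model for the clustering contrast. `"homogeneous"` places nodes uniformly
#' over the union of pelvic level masks (every labeled voxel equally
#' likely), the reference world for volume-normalized calibration tests.
#'
#' @param params a `gen_params`.
#' @param atlas a `level_atlas`.
#' @param make_dvfs logical; generate per-patient displacement fields
#'   (needed for mapping studies; statistical calibration studies can skip
#'   them, in which case native coordinates equal template coordinates).
#' @param spatial_mode `"clustered"`, `"iid"` or `"homogeneous"`.
#' @return object of class `node_cohort`: list with `nodes` (one row per
#'   node, template and native coordinates), `patients`, `dvfs` (named list
#'   or NULL), `params`, `spatial_mode`.
#' @export
sample_cohort <- function(params, atlas, make_dvfs = TRUE,
                          spatial_mode = c("clustered", "iid", "homogeneous")) {
  spatial_mode <- match.arg(spatial_mode)
  stopifnot(inherits(params, "gen_params"), inherits(atlas, "level_atlas"))
  bad <- setdiff(names(params$level_probs), atlas$table$level)
  if (length(bad) > 0)
    stop("level_probs names not in atlas: ", paste(bad, collapse = ", "))

  # voxel index cache per (family, side) region and per family
  tab <- atlas$table
  region_lin <- lapply(seq_len(nrow(tab)), function(r)
    which(atlas$labels == tab$label[r]))
  names(region_lin) <- paste0(tab$level, ":", tab$side)
  pelvic_lin <- which(atlas$labels %in% tab$label[tab$pelvic])
  adj <- level_adjacency()
  pmf <- node_count_pmf(params$node_count_dist)
  p_multi <- 1 - pmf[1]
  # bilateral probability among multi-node patients chosen so the overall
  # strictly-unilateral fraction equals unilateral_prob
  p_bilat_multi <- min(1, (1 - params$unilateral_prob) / p_multi)

  set.seed(params$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, params$n_patients)

  weight_for <- function(family, side, surgery) {
    w <- params$level_probs[family]
    if (surgery && length(params$surgery_effects) > 0) {
      keys <- c(paste0(family, ":", side), family)
      hit <- keys[keys %in% names(params$surgery_effects)]
      if (length(hit) > 0) w <- w * params$surgery_effects[[hit[1]]]
    }
    w
  }
  draw_family <- function(side, surgery) {
    fams <- names(params$level_probs)
    w <- vapply(fams, function(f) {
      s <- if (tab$side[match(f, tab$level)] == "none") "none" else side
      weight_for(f, s, surgery)
    }, numeric(1))
    sample(fams, 1, prob = w)
  }
  region_of <- function(family, side) {
    s <- if (tab$side[match(family, tab$level)] == "none") "none" else side
    paste0(family, ":", s)
  }

  node_rows <- vector("list", params$n_patients)
  pat_rows <- vector("list", params$n_patients)
  dvfs <- if (make_dvfs) vector("list", params$n_patients) else NULL

  for (p in seq_len(params$n_patients)) {
    set.seed(child_seeds[p])
    dvf_seed <- sample.int(.Machine$integer.max - 1L, 1)
    pid <- sprintf("P%03d", p)
    surgery <- stats::runif(1) < params$surgery_prob
    n_p <- sample.int(length(pmf), 1, prob = pmf)

    if (spatial_mode == "homogeneous") {
      pos <- sample_in_mask(n_p, pelvic_lin, atlas$grid)
      cl <- classify_points(pos, atlas)
      fam <- cl$level; sd_ <- cl$side
      anchor <- NA_character_; unilateral <- NA; side_pref <- NA_character_
    } else {
      side_pref <- sample(c("left", "right"), 1)
      unilateral <- if (n_p == 1L) TRUE else stats::runif(1) >= p_bilat_multi
      anchor <- draw_family(side_pref, surgery)
      if (spatial_mode == "iid") {
        fam <- character(n_p); sides <- character(n_p)
        for (i in seq_len(n_p)) {
          sides[i] <- sample(c("left", "right"), 1)
          fam[i] <- draw_family(sides[i], surgery)
        }
      } else {
        # node sides: unilateral -> all on side_pref; bilateral -> random
        # split guaranteed to place >= 1 node on each side
        sides <- rep(side_pref, n_p)
        if (!unilateral) {
          other <- setdiff(c("left", "right"), side_pref)
          k <- sample.int(n_p - 1L, 1)
          sides[sample.int(n_p, k)] <- other
        }
        # first node always at the anchor; later nodes join it with
        # probability cluster_rho, else hop to an adjacent level
        fam <- character(n_p)
        fam[1] <- anchor
        if (n_p > 1) for (i in 2:n_p) {
          fam[i] <- if (stats::runif(1) < params$cluster_rho) anchor
                    else sample(adj[[anchor]], 1)
        }
        # bilaterality is defined over sided levels only: if the designated
        # cross-side nodes all hopped to an unsided level (presacral), flip
        # another sided node, or degrade the flag if no second sided node
        # exists
        if (!unilateral) {
          is_sided <- tab$side[match(fam, tab$level)] != "none"
          lat <- unique(sides[is_sided])
          if (length(lat) < 2L) {
            miss <- setdiff(c("left", "right"), lat)[1]
            cand <- which(is_sided & sides != miss)
            if (length(cand) >= 2L) sides[cand[length(cand)]] <- miss
            else unilateral <- TRUE
          }
        }
      }
      pos <- matrix(NA_real_, n_p, 3)
      sd_ <- character(n_p)
      for (i in seq_len(n_p)) {
        reg <- region_of(fam[i], sides[i])
        if (!reg %in% names(region_lin))  # family absent from atlas (e.g. paraaortic hop)
          reg <- region_of(fam[i], "left")
        pos[i, ] <- sample_in_mask(1, region_lin[[reg]], atlas$grid)
        sd_[i] <- sub("^.*:", "", reg)
      }
    }

    native <- pos
    if (make_dvfs) {
      dvfs[[p]] <- make_dvf(atlas$grid, params$dvf_sd_mm,
                            params$dvf_grid_mm, seed = dvf_seed,
                            invert = FALSE)
      native <- pos + dvf_displacement(dvfs[[p]]$forward, pos)
    }
    node_rows[[p]] <- data.frame(
      patient_id = pid, node_id = seq_len(n_p), level = fam, side = sd_,
      x_template_mm = pos[, 1], y_template_mm = pos[, 2],
      z_template_mm = pos[, 3],
      x_native_mm = native[, 1], y_native_mm = native[, 2],
      z_native_mm = native[, 3],
      surgery = surgery, stringsAsFactors = FALSE)
    pat_rows[[p]] <- data.frame(
      patient_id = pid, surgery = surgery, n_nodes = n_p,
      side_pref = side_pref, anchor_level = anchor,
      unilateral = unilateral, stringsAsFactors = FALSE)
  }
  if (make_dvfs) names(dvfs) <- sprintf("P%03d", seq_len(params$n_patients))
  structure(list(nodes = do.call(rbind, node_rows),
                 patients = do.call(rbind, pat_rows),
                 dvfs = dvfs, params = params, spatial_mode = spatial_mode),
            class = "node_cohort")
}

#' @export
print.node_cohort <- function(x, ...) {
  cat(sprintf("node_cohort: %d patients, %d nodes (%s mode)%s\n",
              nrow(x$patients), nrow(x$nodes), x$spatial_mode,
              if (is.null(x$dvfs)) ", no DVFs" else ""))
  invisible(x)
}

#' Flat node-record table for one coordinate space
#'
#' @param cohort a `node_cohort`.
#' @param space `"template"` or `"native"`.
#' @return data.frame with columns `patient_id`, `node_id`, `x_mm`, `y_mm`,
#'   `z_mm`, `space`, `level`, `side`, `surgery`.
#' @export
node_table <- function(cohort, space = c("template", "native")) {
  space <- match.arg(space)
  pre <- if (space == "template") "template" else "native"
  n <- cohort$nodes
  data.frame(patient_id = n$patient_id, node_id = n$node_id,
             x_mm = n[[paste0("x_", pre, "_mm")]],
             y_mm = n[[paste0("y_", pre, "_mm")]],
             z_mm = n[[paste0("z_", pre, "_mm")]],
             space = space, level = n$level, side = n$side,
             surgery = n$surgery, stringsAsFactors = FALSE)
}

#' Generating-parameter summary of a cohort
#'
#' Exposes the ground truth a cohort was drawn with, for parameter-recovery
#' tests: the anchor-level probabilities, clustering parameter, per-patient
#' node counts, per-level node counts, and the realized unilateral fraction.
#'
#' @param cohort a `node_cohort`.
#' @return list of summaries.
#' @export
ground_truth_table <- function(cohort) {
  nt <- cohort$nodes
  fam_count <- table(nt$level)
  per_level_inv <- vapply(names(cohort$params$level_probs), function(f)
    mean(vapply(split(nt$level, nt$patient_id),
                function(ls) f %in% ls, logical(1))), numeric(1))
  list(level_probs = cohort$params$level_probs,
       cluster_rho = cohort$params$cluster_rho,
       node_counts = cohort$patients$n_nodes,
       per_level_node_counts = as.list(fam_count),
       per_level_involvement = per_level_inv,
       unilateral_fraction = mean(cohort$patients$unilateral, na.rm = TRUE),
       seed = cohort$params$seed)
}
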