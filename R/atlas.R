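#' Synthetic nodal-level atlas in the template space
#'
#' The real consensus contouring atlas for pelvic nodal levels cannot be
#' redistributed, so the package builds a geometric stand-in: each nodal
#' level is a simple primitive (a tube along a polyline centerline, a box, or
#' an ellipsoid) placed in the template grid. Paired levels are constructed
#' mirror-symmetric about the mid-sagittal plane. The atlas carries per-level
#' volumes (cm^3) and a consensus flag marking levels included in the
#' consensus clinical target volume; perirectal, inguinal and prevesical
#' default to non-consensus and the paraaortic region is excluded from
#' pelvic analyses.
#'
#' @name level_atlas
NULL

#' Default synthetic atlas geometry
#'
#' Returns the configuration consumed by [build_template()]: the grid and one
#' primitive per level family. Lateral (x) coordinates of primitives are
#' expressed as offsets from the mid-sagittal plane so that the geometry
#' adapts to any grid and left/right masks are exact mirror images.
#'
#' @param shape,spacing,origin grid parameters (see [template_grid()]). The
#'   default 128 x 128 x 160 grid at 2 mm spans 254 x 254 x 318 mm, enough
#'   for the full pelvis plus the caudal paraaortic region.
#' @return list with elements `grid` and `levels`.
#' @export
default_template_config <- function(shape = c(128L, 128L, 160L),
                                    spacing = c(2, 2, 2),
                                    origin = c(0, 0, 0)) {
  tube <- function(name, consensus, pelvic, centerline, radius)
    list(name = name, sided = TRUE, consensus = consensus, pelvic = pelvic,
         shape = "tube", centerline = centerline, radius = radius)
  list(
    grid = template_grid(shape, spacing, origin),
    levels = list(
      # iliac vessel tubes: centerline given as (x-offset from midline, y, z)
      tube("common_iliac", TRUE, TRUE,
           rbind(c(20, 120, 290), c(30, 112, 235)), 9),
      tube("external_iliac", TRUE, TRUE,
           rbind(c(34, 98, 222), c(48, 96, 130)), 9),
      tube("internal_iliac", TRUE, TRUE,
           rbind(c(32, 132, 222), c(44, 146, 150)), 8),
      tube("obturator", TRUE, TRUE,
           rbind(c(52, 120, 115), c(52, 120, 165)), 8),
      list(name = "presacral", sided = FALSE, consensus = TRUE, pelvic = TRUE,
           shape = "box", center = c(0, 150, 200), half = c(14, 10, 30)),
      list(name = "perirectal", sided = TRUE, consensus = FALSE, pelvic = TRUE,
           shape = "ellipsoid", center = c(18, 150, 130), semi = c(10, 14, 30)),
      list(name = "inguinal", sided = TRUE, consensus = FALSE, pelvic = TRUE,
           shape = "ellipsoid", center = c(55, 85, 95), semi = c(12, 10, 20)),
      list(name = "prevesical", sided = TRUE, consensus = FALSE, pelvic = TRUE,
           shape = "box", center = c(11, 96, 130), half = c(9, 8, 20)),
      tube("paraaortic", FALSE, FALSE,
           rbind(c(14, 120, 306), c(14, 120, 316)), 6)
    )
  )
}

#' Names of the nodal level families in the default atlas
#' @return character vector
#' @export
level_families <- function() {
  c("external_iliac", "internal_iliac", "obturator", "common_iliac",
    "presacral", "perirectal", "inguinal", "prevesical", "paraaortic")
}

# world x of the mid-sagittal plane (mirror plane of paired levels)
atlas_midline <- function(grid) {
  grid$origin[1] + (grid$shape[1] - 1) * grid$spacing[1] / 2
}

# Rasterize one primitive on the LEFT side (x = midline + offset); returns
# linear voxel indices of inside voxels (voxel-center inclusion).
rasterize_primitive <- function(spec, grid, midline) {
  place <- function(p) c(midline + p[1], p[2], p[3])
  if (spec$shape == "tube") {
    cl <- t(apply(spec$centerline, 1, place))
    lo <- apply(cl, 2, min) - spec$radius
    hi <- apply(cl, 2, max) + spec$radius
  } else if (spec$shape == "box") {
    ctr <- place(spec$center); lo <- ctr - spec$half; hi <- ctr + spec$half
  } else if (spec$shape == "ellipsoid") {
    ctr <- place(spec$center); lo <- ctr - spec$semi; hi <- ctr + spec$semi
  } else stop("unknown primitive shape: ", spec$shape)
  ilo <- pmax(ceiling((lo - grid$origin) / grid$spacing) + 1, 1)
  ihi <- pmin(floor((hi - grid$origin) / grid$spacing) + 1, grid$shape)
  if (any(ihi < ilo)) return(integer(0))
  xs <- grid$origin[1] + (seq(ilo[1], ihi[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq(ilo[2], ihi[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq(ilo[3], ihi[3]) - 1) * grid$spacing[3]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  px <- rep(xs, times = ny * nz)
  py <- rep(rep(ys, each = nx), times = nz)
  pz <- rep(zs, each = nx * ny)
  inside <- switch(spec$shape,
    tube = {
      dmin <- rep(Inf, length(px))
      for (s in seq_len(nrow(spec$centerline) - 1)) {
        a <- place(spec$centerline[s, ]); b <- place(spec$centerline[s + 1, ])
        ab <- b - a; len2 <- sum(ab^2)
        t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2] + (pz - a[3]) * ab[3]) / len2
        t <- pmin(pmax(t, 0), 1)
        d2 <- (px - a[1] - t * ab[1])^2 + (py - a[2] - t * ab[2])^2 +
              (pz - a[3] - t * ab[3])^2
        dmin <- pmin(dmin, d2)
      }
      dmin <= spec$radius^2
    },
    box = {
      ctr <- place(spec$center)
      abs(px - ctr[1]) <= spec$half[1] & abs(py - ctr[2]) <= spec$half[2] &
        abs(pz - ctr[3]) <= spec$half[3]
    },
    ellipsoid = {
      ctr <- place(spec$center)
      ((px - ctr[1]) / spec$semi[1])^2 + ((py - ctr[2]) / spec$semi[2])^2 +
        ((pz - ctr[3]) / spec$semi[3])^2 <= 1
    })
  if (!any(inside)) return(integer(0))
  ii <- rep(seq(ilo[1], ihi[1]), times = ny * nz)[inside]
  jj <- rep(rep(seq(ilo[2], ihi[2]), each = nx), times = nz)[inside]
  kk <- rep(seq(ilo[3], ihi[3]), each = nx * ny)[inside]
  ii + (jj - 1) * grid$shape[1] + (kk - 1) * prod(grid$shape[1:2])
}

# mirror linear voxel indices across the mid-sagittal plane (x axis flip)
mirror_indices <- function(lin, shape) {
  lin0 <- lin - 1
  i <- lin0 %% shape[1]
  rest <- lin0 %/% shape[1]
  (shape[1] - 1 - i) + rest * shape[1] + 1
}

#' Build the synthetic template atlas
#'
#' Rasterizes the configured level primitives into a label map. Left-side
#' masks are rasterized geometrically and right-side masks are produced by
#' reflecting the left voxel set across the mid-sagittal plane, so paired
#' levels are bit-exact mirror images. Labels are assigned in configuration
#' order (left before right). The build is fully deterministic; `seed` is
#' accepted for interface symmetry with the stochastic modules.
#'
#' @param config as returned by [default_template_config()].
#' @param seed integer, unused by the deterministic build.
#' @return a `level_atlas`: list with `grid`, `labels` (integer 3D array,
#'   0 = background), `table` (data.frame: label, level, side, consensus,
#'   pelvic, volume_cm3).
#' @export
build_template <- function(config = default_template_config(), seed = 1L) {
  grid <- config$grid
  mid <- atlas_midline(grid)
  labels <- array(0L, dim = grid$shape)
  rows <- list()
  lab <- 0L
  for (spec in config$levels) {
    left <- rasterize_primitive(spec, grid, mid)
    if (length(left) == 0)
      stop("zero-volume primitive for level '", spec$name, "'")
    sides <- if (isTRUE(spec$sided)) c("left", "right") else "none"
    for (side in sides) {
      lin <- if (side == "right") mirror_indices(left, grid$shape) else left
      hit <- labels[lin] != 0L
      if (any(hit)) {
        other <- unique(labels[lin][hit])
        onames <- vapply(other, function(l) {
          r <- rows[[l]]; paste0(r$level, "/", r$side) }, character(1))
        stop("overlapping primitives: level '", spec$name, "/", side,
             "' collides with ", paste(onames, collapse = ", "))
      }
      lab <- lab + 1L
      labels[lin] <- lab
      rows[[lab]] <- data.frame(label = lab, level = spec$name, side = side,
                                consensus = isTRUE(spec$consensus),
                                pelvic = isTRUE(spec$pelvic),
                                volume_cm3 = length(lin) * voxel_volume_cm3(grid),
                                stringsAsFactors = FALSE)
    }
  }
  structure(list(grid = grid, labels = labels,
                 table = do.call(rbind, rows), config = config),
            class = "level_atlas")
}

#' @export
print.level_atlas <- function(x, ...) {
  cat(sprintf("level_atlas: %d levels on %s grid, total %.1f cm3 labeled\n",
              nrow(x$table), paste(x$grid$shape, collapse = "x"),
              sum(x$table$volume_cm3)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

# recompute per-label volumes from the label map
recompute_volumes <- function(atlas) {
  cnt <- tabulate(atlas$labels, nbins = max(atlas$table$label))
  atlas$table$volume_cm3 <- cnt[atlas$table$label] * voxel_volume_cm3(atlas$grid)
  atlas
}

#' Margin specification for level expansion
#'
#' Margins model the clinical practice of expanding vessel-based nodal levels
#' by a fixed distance around the vessels (7 mm standard, 10 mm generous).
#'
#' @param margin_mm nonnegative expansion distance in mm.
#' @param applies_to level family names to expand; defaults to the three
#'   vessel-following iliac levels.
#' @export
margin_spec <- function(margin_mm,
                        applies_to = c("external_iliac", "internal_iliac",
                                       "common_iliac")) {
  margin_mm <- as.numeric(margin_mm)
  if (length(margin_mm) != 1 || !is.finite(margin_mm) || margin_mm < 0)
    stop("margin_mm must be a single nonnegative number")
  structure(list(margin_mm = margin_mm, applies_to = applies_to),
            class = "margin_spec")
}

#' Expand selected levels by a Euclidean margin
#'
#' Each selected level mask grows to all background voxels whose center lies
#' within `margin_mm` of the original mask (anisotropy-aware distance
#' transform threshold). Voxels claimed by several expanded levels go to the
#' nearest original level; exact ties go to the lowest label id. Existing
#' labels are never overwritten. Volumes are recomputed.
#'
#' @param atlas a `level_atlas`.
#' @param margin a `margin_spec` (or a single number, expanded with the
#'   default `applies_to` set).
#' @return the expanded `level_atlas`.
#' @export
expand_levels <- function(atlas, margin) {
  if (is.numeric(margin)) margin <- margin_spec(margin)
  stopifnot(inherits(margin, "margin_spec"))
  if (margin$margin_mm == 0) return(atlas)
  sel <- atlas$table$label[atlas$table$level %in% margin$applies_to]
  if (length(sel) == 0) return(atlas)
  shp <- atlas$grid$shape
  sp <- atlas$grid$spacing
  best_d <- array(Inf, dim = shp)
  best_l <- array(0L, dim = shp)
  pad <- ceiling(margin$margin_mm / sp) + 1L
  for (l in sel) {
    w <- which(atlas$labels == l, arr.ind = TRUE)
    lo <- pmax(apply(w, 2, min) - pad, 1L)
    hi <- pmin(apply(w, 2, max) + pad, shp)
    sub <- atlas$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == l
    d <- edt_mm(sub, sp)
    reg_d <- best_d[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    reg_l <- best_l[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    take <- d <= margin$margin_mm &
      (d < reg_d - 1e-9 | (abs(d - reg_d) <= 1e-9 & l < reg_l))
    reg_d[take] <- d[take]
    reg_l[take] <- l
    best_d[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- reg_d
    best_l[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- reg_l
  }
  claim <- best_l > 0L & atlas$labels == 0L
  atlas$labels[claim] <- best_l[claim]
  recompute_volumes(atlas)
}

#' Classify world points into atlas levels
#'
#' Looks up the label of the voxel containing each point (voxel-center
#' convention: the nearest voxel center). Points beyond the grid extent
#' classify as `"outside"` rather than raising an error, since mapped points
#' can legitimately leave the field of view.
#'
#' @param pts n x 3 matrix (or length-3 vector) of world coordinates, mm.
#' @param atlas a `level_atlas`.
#' @return data.frame with columns `level` (name or "outside"), `side`,
#'   `label` (0 for background/outside).
#' @export
classify_points <- function(pts, atlas) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  if (any(!is.finite(pts))) stop("non-finite point coordinates")
  idx <- world_to_nearest_index(atlas$grid, pts)
  shp <- atlas$grid$shape
  inb <- idx[, 1] >= 1 & idx[, 1] <= shp[1] &
         idx[, 2] >= 1 & idx[, 2] <= shp[2] &
         idx[, 3] >= 1 & idx[, 3] <= shp[3]
  lab <- integer(nrow(pts))
  if (any(inb)) {
    lin <- idx[inb, 1] + (idx[inb, 2] - 1) * shp[1] +
      (idx[inb, 3] - 1) * shp[1] * shp[2]
    lab[inb] <- atlas$labels[lin]
  }
  level <- rep("outside", nrow(pts))
  side <- rep("none", nrow(pts))
  nz <- lab > 0L
  if (any(nz)) {
    m <- match(lab[nz], atlas$table$label)
    level[nz] <- atlas$table$level[m]
    side[nz] <- atlas$table$side[m]
  }
  level[inb & lab == 0L] <- "outside"
  data.frame(level = level, side = side, label = lab,
             stringsAsFactors = FALSE)
}

#' @rdname classify_points
#' @param p a single point (length-3 numeric), mm.
#' @export
classify_point <- function(p, atlas) classify_points(rbind(p), atlas)

#' Coverage of nodes by the consensus target volume
#'
#' Flags, per patient, nodes that classify as "outside" every level or into a
#' non-consensus level, after expanding vessel-based levels by each requested
#' margin. Reports the fraction of patients with at least one uncovered node
#' (the headline coverage statistic) and per-level uncovered counts, for each
#' margin, giving the 7 vs 10 mm sensitivity side by side. Boundary voxels of
#' a dilated level count as covered (inclusive membership).
#'
#' @param nodes node table (template space) with columns `patient_id`,
#'   `x_mm`, `y_mm`, `z_mm`, `space`.
#' @param atlas a `level_atlas`.
#' @param margins numeric vector of margins (mm) to evaluate, or a list of
#'   `margin_spec`s.
#' @return list of per-margin reports; each has `margin_mm`, `per_patient`
#'   (data.frame), `n_uncovered_patients`, `fraction_uncovered`,
#'   `percent_uncovered` (half-up, 1 dp), `per_level_uncovered`.
#' @export
consensus_coverage <- function(nodes, atlas, margins = c(7, 10)) {
  stopifnot(all(c("patient_id", "x_mm", "y_mm", "z_mm") %in% names(nodes)))
  if (!is.null(nodes$space) && any(nodes$space != "template"))
    stop("nodes must be in template space; map native-space nodes first")
  if (!is.list(margins)) margins <- lapply(margins, margin_spec)
  reports <- lapply(margins, function(m) {
    ex <- expand_levels(atlas, m)
    cl <- classify_points(as.matrix(nodes[, c("x_mm", "y_mm", "z_mm")]), ex)
    cov_level <- ex$table$level[ex$table$consensus]
    uncovered <- !(cl$level %in% cov_level)
    pat <- split(uncovered, nodes$patient_id)
    per_patient <- data.frame(
      patient_id = names(pat),
      n_nodes = vapply(pat, length, integer(1)),
      n_uncovered = vapply(pat, sum, integer(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    per_patient$uncovered <- per_patient$n_uncovered > 0L
    n_pat <- nrow(per_patient)
    n_unc <- sum(per_patient$uncovered)
    lvl_tab <- table(cl$level[uncovered])
    list(margin_mm = m$margin_mm,
         per_patient = per_patient,
         n_patients = n_pat,
         n_uncovered_patients = n_unc,
         fraction_uncovered = n_unc / n_pat,
         percent_uncovered = percent_halfup(n_unc, n_pat),
         per_level_uncovered = as.list(lvl_tab))
  })
  names(reports) <- paste0("margin_", vapply(reports, `[[`, 0, "margin_mm"), "mm")
  reports
}

#' Percentage rounded half-up to one decimal place
#'
#' Report formatting used throughout: `percent_halfup(26, 75)` is 34.7,
#' `percent_halfup(28, 75)` is 37.3.
#'
#' @param num,den numerator and denominator (den > 0).
#' @return numeric percentage with one decimal place, ties rounded up.
#' @export
percent_halfup <- function(num, den) {
  stopifnot(all(den > 0))
  floor(1000 * num / den + 0.5) / 10
}
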