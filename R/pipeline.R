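#' Pipeline run configuration
#'
#' Assembles the stage toggles and per-stage parameters of an end-to-end
#' run: simulate -> map -> density -> distances -> levelstats -> report.
#' One master seed fans out to per-stage child seeds; all randomness flows
#' through them, so identical configurations reproduce byte-identical
#' outputs.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param stages character vector of enabled stages (subset of
#'   `c("simulate","map","density","distances","levelstats","report")`).
#' @param atlas_shape,atlas_spacing grid of the synthetic template.
#' @param gen list of [gen_params()] overrides (e.g. `n_patients`).
#' @param kde list of [kde_config()] overrides.
#' @param bootstrap list of [bootstrap_spec()] overrides (e.g. `B`).
#' @param margins coverage margins in mm.
#' @param write_dvfs also write per-patient forward displacement fields as
#'   NRRD (off by default; the dense inverse fields are kept in memory only).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       stages = c("simulate", "map", "density", "distances",
                                  "levelstats", "report"),
                       atlas_shape = c(128L, 128L, 160L),
                       atlas_spacing = c(2, 2, 2),
                       gen = list(),
                       kde = list(),
                       bootstrap = list(B = 2000L),
                       margins = c(7, 10),
                       write_dvfs = FALSE) {
  known <- c("simulate", "map", "density", "distances", "levelstats", "report")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 atlas_shape = atlas_shape, atlas_spacing = atlas_spacing,
                 gen = gen, kde = kde, bootstrap = bootstrap,
                 margins = margins, write_dvfs = write_dvfs),
            class = "run_config")
}

#' Load a run configuration from a JSON file
#' @param path JSON file with fields of [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, cfg)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[nodalmap] %s: %s", stage, sprintf(...)))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order on a synthetic cohort and writes all
#' artifacts plus a manifest (`manifest.json`: inputs, outputs, seeds, file
#' checksums) and a machine-readable results summary (`results.json`) from
#' which [write_report()] renders the human-readable report. A stage failure
#' halts the run with the failing stage named.
#'
#' @param config a `run_config` (or path to its JSON form).
#' @return the manifest list, invisibly; all artifacts under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 8)
  outputs <- character(0)
  results <- list(seed = config$seed, stages = config$stages)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # template atlas is infrastructure for every stage; with no stages enabled
  # the run produces the manifest only
  atlas <- NULL
  if (length(config$stages) > 0) {
    atlas_cfg <- default_template_config(config$atlas_shape, config$atlas_spacing)
    atlas <- run_stage("template", function() build_template(atlas_cfg))
    p_atlas <- file.path(config$out_dir, "atlas.nrrd")
    write_atlas(atlas, p_atlas)
    outputs <- c(outputs, p_atlas, sub("\\.nrrd$", ".json", p_atlas))
    pipeline_log("template", "atlas with %d levels, %.1f cm3 labeled",
                 nrow(atlas$table), sum(atlas$table$volume_cm3))
  }

  cohort <- NULL
  mapped <- NULL
  if ("simulate" %in% config$stages) {
    gp <- do.call(gen_params, utils::modifyList(
      list(seed = stage_seeds[1]), config$gen))
    need_dvf <- "map" %in% config$stages
    cohort <- run_stage("simulate", function()
      sample_cohort(gp, atlas, make_dvfs = need_dvf))
    p_nodes <- file.path(config$out_dir, "nodes_native.csv")
    write_nodes_csv(node_table(cohort, "native"), p_nodes)
    outputs <- c(outputs, p_nodes)
    if (config$write_dvfs && need_dvf) {
      for (pid in names(cohort$dvfs)) {
        p <- file.path(config$out_dir, sprintf("dvf_forward_%s.nrrd", pid))
        write_dvf(cohort$dvfs[[pid]]$forward, p)
        outputs <- c(outputs, p)
      }
    }
    results$simulate <- list(n_patients = nrow(cohort$patients),
                             n_nodes = nrow(cohort$nodes),
                             median_nodes = stats::median(cohort$patients$n_nodes),
                             unilateral_fraction =
                               mean(cohort$patients$unilateral, na.rm = TRUE))
    pipeline_log("simulate", "%d patients, %d nodes",
                 nrow(cohort$patients), nrow(cohort$nodes))
  }

  if ("map" %in% config$stages) {
    if (is.null(cohort)) stop("pipeline stage 'map' failed: no cohort (enable 'simulate')")
    mapped <- run_stage("map", function()
      map_cohort(node_table(cohort, "native"), cohort$dvfs))
    p_mapped <- file.path(config$out_dir, "nodes_mapped.csv")
    write_nodes_csv(mapped, p_mapped)
    outputs <- c(outputs, p_mapped)
    results$map <- list(n_records = nrow(mapped),
                        mean_displacement_mm = mean(mapped$displacement_mm))
    pipeline_log("map", "%d records, mean |displacement| %.2f mm",
                 nrow(mapped), mean(mapped$displacement_mm))
  }
  # downstream stages fall back to ground-truth template coordinates when
  # the mapping stage is disabled
  tmpl_nodes <- if (!is.null(mapped)) mapped
                else if (!is.null(cohort)) node_table(cohort, "template")
                else NULL

  if ("density" %in% config$stages) {
    if (is.null(tmpl_nodes)) stop("pipeline stage 'density' failed: no nodes")
    kcfg <- do.call(kde_config, config$kde)
    dens <- run_stage("density", function() {
      pel <- tmpl_nodes[tmpl_nodes$level != "paraaortic", ]
      w <- patient_weights(pel)
      m <- kde3d(as.matrix(pel[, c("x_mm", "y_mm", "z_mm")]), w, kcfg,
                 atlas$grid)
      smooth_density(m, kcfg$smoothing_sigma_mm)
    })
    p_dens <- file.path(config$out_dir, "density.nrrd")
    write_density(dens, p_dens)
    outputs <- c(outputs, p_dens, sub("\\.nrrd$", ".json", p_dens))
    hs <- hotspot_summary(dens, atlas, 0.99)
    p_hs <- file.path(config$out_dir, "hotspots.csv")
    utils::write.csv(hs, p_hs, row.names = FALSE)
    outputs <- c(outputs, p_hs)
    results$density <- list(peak_permille_cm3 = max(dens$values),
                            total_mass = dens$meta$total_mass,
                            n_hotspots = nrow(hs),
                            top_hotspot_levels =
                              if (nrow(hs) > 0) hs$levels[1] else NA)
    pipeline_log("density", "peak %.2f permille/cm3, mass %.3f",
                 max(dens$values), dens$meta$total_mass)
  }

  if ("distances" %in% config$stages) {
    if (is.null(cohort)) stop("pipeline stage 'distances' failed: no cohort")
    res <- run_stage("distances", function() {
      intra_nat <- intra_patient_distances(cohort, "native")
      intra_tmp <- distance_set_from(tmpl_nodes, "intra")
      coh <- distance_set_from(tmpl_nodes, "cohort")
      ct_t <- compare_means(intra_tmp, coh, "pooled_t")
      ct_b <- compare_means(intra_tmp, coh, "patient_bootstrap",
                            B = 1000L, seed = stage_seeds[3])
      q <- max_intra_distance_quantiles(cohort, "native")
      list(n_intra_native = length(intra_nat$distances),
           n_intra_template = length(intra_tmp$distances),
           n_cohort = length(coh$distances),
           mean_intra_native_cm = mean(intra_nat$distances) / 10,
           mean_intra_template_cm = mean(intra_tmp$distances) / 10,
           mean_cohort_cm = mean(coh$distances) / 10,
           pooled_t = unclass(ct_t), patient_bootstrap = unclass(ct_b),
           max_intra_quantiles_cm = as.list(unclass(q) / 10))
    })
    p_d <- file.path(config$out_dir, "distances.json")
    jsonlite::write_json(res, p_d, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, p_d)
    results$distances <- res
    pipeline_log("distances", "intra %.1f cm vs cohort %.1f cm",
                 res$mean_intra_template_cm, res$mean_cohort_cm)
  }

  if ("levelstats" %in% config$stages) {
    if (is.null(tmpl_nodes)) stop("pipeline stage 'levelstats' failed: no nodes")
    res <- run_stage("levelstats", function() {
      # classify mapped coordinates against the atlas (expert-assessment arm)
      cls <- classify_points(as.matrix(tmpl_nodes[, c("x_mm", "y_mm", "z_mm")]),
                             atlas)
      nodes_cls <- tmpl_nodes
      nodes_cls$level <- cls$level
      nodes_cls$side <- cls$side
      nodes_cls <- nodes_cls[nodes_cls$level != "outside", ]
      inv <- binary_involvement(nodes_cls, atlas)
      contr <- surgery_contrasts(nodes_cls, atlas)
      rp <- relative_proportions(nodes_cls)
      vn <- volume_normalized_means(rp, atlas)
      bs <- do.call(bootstrap_spec, utils::modifyList(
        list(seed = stage_seeds[4]), config$bootstrap))
      per_level <- lapply(vn$table$level, function(lv) {
        r <- rp$profiles[[lv]]
        vol <- vn$table$volume_cm3[vn$table$level == lv]
        vals <- 1000 * r / vol
        ci <- bca_ci(vals, bs)
        tst <- bootstrap_mean_test(vals, vn$reference_permille_cm3, bs)
        list(level = lv, value = mean(vals), ci_low = ci$ci_low,
             ci_high = ci$ci_high, p_vs_homogeneous = tst$p_value)
      })
      cov <- consensus_coverage(
        nodes_cls[, c("patient_id", "x_mm", "y_mm", "z_mm", "space")],
        atlas, config$margins)
      cov_sum <- lapply(cov, function(cr)
        list(margin_mm = cr$margin_mm,
             percent_uncovered = cr$percent_uncovered,
             n_uncovered = cr$n_uncovered_patients,
             n_patients = cr$n_patients,
             per_level_uncovered = cr$per_level_uncovered))
      list(involvement_combined = inv$combined,
           involvement_by_side = inv$by_side,
           n_patients = inv$n_patients,
           surgery_contrasts = contr,
           n_proportion_patients = nrow(rp$profiles),
           dropped_patients = rp$dropped_patients,
           volume_normalized = vn$table,
           homogeneous_reference = vn$reference_permille_cm3,
           per_level_tests = per_level,
           coverage = cov_sum)
    })
    p_l <- file.path(config$out_dir, "levelstats.json")
    jsonlite::write_json(res, p_l, auto_unbox = TRUE, digits = NA)
    p_i <- file.path(config$out_dir, "involvement.csv")
    utils::write.csv(res$involvement_combined, p_i, row.names = FALSE)
    outputs <- c(outputs, p_l, p_i)
    results$levelstats <- res
    pipeline_log("levelstats", "%d patients, reference %.2f permille/cm3",
                 res$n_patients, res$homogeneous_reference)
  }

  if (length(config$stages) > 0) {
    p_res <- file.path(config$out_dir, "results.json")
    jsonlite::write_json(results, p_res, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, p_res)
    if ("report" %in% config$stages) {
      p_rep <- file.path(config$out_dir, "report.txt")
      write_report(p_res, p_rep)
      outputs <- c(outputs, p_rep)
    }
  }

  manifest <- list(
    package = "nodalmap",
    version = as.character(utils::packageVersion("nodalmap")),
    seed = config$seed,
    stages = config$stages,
    config = unclass(config),
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# helper: build a distance_set from a flat template-space node table
distance_set_from <- function(nodes, kind) {
  if (kind == "intra") {
    nodes2 <- nodes
    nodes2$space <- "template"
    intra_patient_distances(nodes2, "template")
  } else {
    nodes2 <- nodes
    nodes2$space <- "template"
    cohort_distances(nodes2)
  }
}

#' Render the human-readable report
#'
#' Regenerates the plain-text summary purely from `results.json`, so the
#' same results file always yields identical text. Sections appear only for
#' stages that ran: cohort, mapping, density atlas, distance statistics and
#' level statistics (involvement table, subgroup contrasts, volume-normalized
#' proportions, consensus coverage at each margin).
#'
#' @param results_json path to a pipeline `results.json`.
#' @param path output text file.
#' @return the report lines, invisibly.
#' @export
write_report <- function(results_json, path) {
  r <- jsonlite::read_json(results_json, simplifyVector = TRUE)
  L <- c("nodalmap pipeline report", sprintf("seed: %d", r$seed), "")
  if (!is.null(r$simulate)) {
    L <- c(L, "== Cohort ==",
           sprintf("%d patients, %d nodes (median %g per patient); strictly unilateral: %.1f%%",
                   r$simulate$n_patients, r$simulate$n_nodes,
                   r$simulate$median_nodes,
                   100 * r$simulate$unilateral_fraction), "")
  }
  if (!is.null(r$map)) {
    L <- c(L, "== Mapping ==",
           sprintf("%d node records mapped into the template; mean displacement %.2f mm",
                   r$map$n_records, r$map$mean_displacement_mm), "")
  }
  if (!is.null(r$density)) {
    L <- c(L, "== Density atlas ==",
           sprintf("peak density %.2f permille/cm3; probability mass on grid %.3f",
                   r$density$peak_permille_cm3, r$density$total_mass),
           sprintf("%d hotspot component(s); top component overlaps: %s",
                   r$density$n_hotspots, r$density$top_hotspot_levels), "")
  }
  if (!is.null(r$distances)) {
    d <- r$distances
    L <- c(L, "== Distance statistics ==",
           sprintf("intra-patient (native): %d distances, mean %.1f cm",
                   d$n_intra_native, d$mean_intra_native_cm),
           sprintf("intra-patient (template): %d distances, mean %.1f cm",
                   d$n_intra_template, d$mean_intra_template_cm),
           sprintf("cohort-level: %d distances, mean %.1f cm",
                   d$n_cohort, d$mean_cohort_cm),
           sprintf("intra vs cohort: diff %.1f cm, Welch p = %.3g, patient-bootstrap p = %.3g",
                   d$pooled_t$statistic / 10, d$pooled_t$p_value,
                   d$patient_bootstrap$p_value),
           sprintf("max intra-patient distance: median %.1f / 75th %.1f / 95th %.1f cm",
                   d$max_intra_quantiles_cm$median, d$max_intra_quantiles_cm$q75,
                   d$max_intra_quantiles_cm$q95), "")
  }
  if (!is.null(r$levelstats)) {
    ls_ <- r$levelstats
    inv <- as.data.frame(ls_$involvement_combined)
    L <- c(L, "== Level statistics ==",
           sprintf("binary involvement (n = %d patients):", ls_$n_patients),
           sprintf("  %-16s %3d (%.1f%%)", inv$level, inv$n, inv$percent))
    sc <- as.data.frame(ls_$surgery_contrasts)
    L <- c(L, "surgery subgroup contrasts (Fisher exact, Bonferroni-adjusted):",
           sprintf("  %-16s %-5s no-surgery %5.1f%% vs surgery %5.1f%%: p = %.3f (adj %.3f)",
                   sc$level, sc$side, sc$pct_no_surgery, sc$pct_surgery,
                   sc$p, sc$p_adjusted))
    vn <- as.data.frame(ls_$volume_normalized)
    pl <- ls_$per_level_tests
    L <- c(L, sprintf("volume-normalized mean proportions (n = %d; homogeneous reference %.2f permille/cm3):",
                      ls_$n_proportion_patients, ls_$homogeneous_reference),
           vapply(seq_len(nrow(vn)), function(i) {
             t <- if (is.data.frame(pl)) as.list(pl[i, ]) else pl[[i]]
             sprintf("  %-16s %6.2f permille/cm3 [%.2f, %.2f], p vs homogeneous = %.3f",
                     vn$level[i], vn$value_permille_cm3[i],
                     t$ci_low, t$ci_high, t$p_vs_homogeneous)
           }, character(1)))
    cov <- ls_$coverage
    L <- c(L, "consensus coverage:",
           vapply(cov, function(cr)
             sprintf("  margin %g mm: %.1f%% of patients (%d/%d) with >= 1 node outside consensus",
                     cr$margin_mm, cr$percent_uncovered, cr$n_uncovered,
                     cr$n_patients), character(1)), "")
  }
  writeLines(L, path)
  invisible(L)
}
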