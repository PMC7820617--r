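# shared fixtures, built once per test run

# coarse (4 mm) default-geometry atlas used by most tests
.fixture_env <- new.env()

small_atlas <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- build_template(
      default_template_config(c(64L, 64L, 80L), c(4, 4, 4)))
  }
  .fixture_env$small
}

# full-resolution (2 mm) default atlas, for boundary-sensitive geometry tests
fine_atlas <- function() {
  if (is.null(.fixture_env$fine)) {
    .fixture_env$fine <- build_template(default_template_config())
  }
  .fixture_env$fine
}

# tiny custom atlas: two unsided boxes on a small 2 mm grid (fast oracles)
toy_config <- function(spacing = 2) {
  list(
    grid = template_grid(c(24L, 20L, 20L), rep(spacing, 3)),
    levels = list(
      list(name = "obturator", sided = TRUE, consensus = TRUE, pelvic = TRUE,
           shape = "box", center = c(10, 12, 14), half = c(5, 6, 7)),
      list(name = "presacral", sided = FALSE, consensus = TRUE, pelvic = TRUE,
           shape = "ellipsoid", center = c(0, 28, 24), semi = c(6, 5, 7))
    )
  )
}

toy_atlas <- function() {
  if (is.null(.fixture_env$toy)) .fixture_env$toy <- build_template(toy_config())
  .fixture_env$toy
}

# hand-built node table (template space)
make_nodes <- function(xyz, patient_id, level = "obturator", side = "left",
                       surgery = FALSE) {
  xyz <- matrix(xyz, ncol = 3)
  data.frame(patient_id = patient_id,
             node_id = stats::ave(seq_len(nrow(xyz)), patient_id,
                                  FUN = seq_along),
             x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
             space = "template", level = level, side = side,
             surgery = surgery, stringsAsFactors = FALSE)
}
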