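threshold_ini <- function() {
  system.file("extdata/plugins/threshold_plugin.ini", package = "sketchkit")
}

test_that("the threshold plugin configuration parses into a validated spec", {
  spec <- parse_config(threshold_ini())
  expect_s3_class(spec, "plugin_spec")
  expect_identical(spec$name, "threshold_demo")
  expect_identical(spec$module_type, "segmentation")
  expect_length(spec$inputs, 3)
  expect_identical(spec$inputs$threshold$kind, "number")
  expect_equal(spec$inputs$threshold$default, 100)
  expect_identical(spec$inputs$direction$choices, c("above", "below"))
  expect_length(spec$widgets, 4)
  expect_identical(spec$widgets[[2]]$binds, "threshold")
  expect_true(file.exists(spec$program))
})

test_that("configuration errors carry line numbers and name the offender", {
  td <- withr_tempdir()
  bad <- file.path(td, "bad.ini")

  writeLines(c("[module]", "name = x", "type = segmentation", "program = p",
               "[widget.1]", "widget = text_box", "label = T",
               "binds = nothere"), bad)
  expect_error(parse_config(bad), "undeclared input parameter 'nothere'")

  writeLines(c("[module]", "name = x", "type = segmentation", "program = p",
               "shade = blue"), bad)
  expect_error(parse_config(bad), "line 5: unknown key 'shade'")

  writeLines(c("[input.t]", "kind = number"), bad)
  expect_error(parse_config(bad), "missing required \\[module\\]")

  writeLines(c("[module]", "name = x", "type = sorcery", "program = p"), bad)
  expect_error(parse_config(bad), "must be one of")

  writeLines(c("[module]", "name = x", "type = analysis", "program = p",
               "[input.c]", "kind = choice"), bad)
  expect_error(parse_config(bad), "choices")
})

test_that("a minimal configuration yields an empty-widget spec and write/parse is identity", {
  td <- withr_tempdir()
  minimal <- file.path(td, "min.ini")
  writeLines(c("[module]", "name = tiny", "type = analysis",
               "program = /bin/true"), minimal)
  spec <- parse_config(minimal)
  expect_length(spec$widgets, 0)
  expect_length(spec$inputs, 0)

  full <- parse_config(threshold_ini())
  p <- file.path(td, "roundtrip.ini")
  write_config(full, p)
  again <- parse_config(p)
  expect_equal(unclass(again), unclass(full))
})

test_that("staging validates before writing and is byte-deterministic", {
  spec <- parse_config(threshold_ini())
  ph <- make_phantom(phantom_spec("itss_cube", size = 12, roi_start = 2L))
  td <- file.path(withr_tempdir(), "fresh")
  expect_error(stage_inputs(spec, list(threshold = 120), td),
               "missing required input 'image'")
  expect_false(dir.exists(td))   # nothing written before validation passed
  expect_error(stage_inputs(spec, list(image = "not an image"), td),
               "does not match declared kind")
  expect_error(stage_inputs(spec, list(image = ph$image, bogus = 1), td),
               "undeclared input")

  man <- stage_inputs(spec, list(image = ph$image, threshold = 120), td)
  expect_identical(man$status, "staged")
  expect_true(all(file.exists(file.path(td, c("image.nii.gz", "params.json",
                                              "manifest.json")))))
  p1 <- readBin(file.path(td, "params.json"), "raw", 1e4)
  td2 <- file.path(withr_tempdir(), "again")
  stage_inputs(spec, list(threshold = 120, image = ph$image), td2)
  p2 <- readBin(file.path(td2, "params.json"), "raw", 1e4)
  expect_identical(p1, p2)
})

test_that("a threshold stub run through the disk protocol matches the in-process result", {
  spec <- parse_config(threshold_ini())
  ph <- make_phantom(phantom_spec("itss_cube", size = 16, noise_sigma = 10,
                                  seed = 5, roi_start = 4L))
  wd <- plugin_workdir(withr_tempdir())
  man <- stage_inputs(spec, list(image = ph$image, threshold = 100,
                                 direction = "above"), wd)
  out <- run_plugin(spec, man)
  whole <- label_mask(array(1L, dim(ph$image$voxels)), ph$image)
  ref <- extract_threshold(ph$image, whole, 100, "above")
  expect_identical(out$mask$labels, ref$mask$labels)
  expect_identical(jsonlite::fromJSON(file.path(wd, "manifest.json"))$status,
                   "done")
})

test_that("the identity shell-script stub round-trips all exchange formats", {
  spec <- parse_config(system.file("extdata/plugins/identity_plugin.ini",
                                   package = "sketchkit"))
  ph <- make_phantom(phantom_spec("cube", size = 10, noise_sigma = 4, seed = 3))
  mesh <- sphere_mesh(c(0.5, -1.5, 2), 7.125, 6, 9)
  ann <- annotation_set(
    image_ref = "case9",
    landmarks = list(landmark("carina", c(12.3456789, -0.1, 77))),
    contours = list(circle_contour(c(3, 4), 9, 24, slice_index = 5L)))
  wd <- plugin_workdir(withr_tempdir())
  man <- stage_inputs(spec, list(image = ph$image, mesh = mesh,
                                 annotation = ann), wd)
  out <- run_plugin(spec, man)
  expect_identical(out$out_image$voxels, ph$image$voxels)
  expect_lt(max(abs(out$out_mesh$vertices - mesh$vertices)), 1e-9)
  expect_identical(out$out_mesh$faces, mesh$faces)
  expect_annotation_sets_equal(ann, out$out_annotation)
})

test_that("exit, timeout, and missing-output failures raise distinct conditions", {
  td <- withr_tempdir()
  mk <- function(lines, name) {
    p <- file.path(td, name)
    writeLines(c("#!/bin/sh", lines), p)
    p
  }
  run1 <- function(spec, timeout = 60) {
    wd <- plugin_workdir(td)
    man <- stage_inputs(spec, list(), wd)
    run_plugin(spec, man, timeout = timeout)
  }
  fails <- plugin_spec("fails", "analysis", mk("exit 3", "f.sh"))
  err <- tryCatch(run1(fails), error = identity)
  expect_s3_class(err, "plugin_exit_error")
  expect_match(conditionMessage(err), "status 3")

  slow <- plugin_spec("slow", "analysis", mk("sleep 30", "s.sh"))
  err <- tryCatch(run1(slow, timeout = 1), error = identity)
  expect_s3_class(err, "plugin_timeout_error")

  silent <- plugin_spec("silent", "analysis", mk("exit 0", "n.sh"),
                        outputs = list(out = param_decl("out", "image")))
  err <- tryCatch(run1(silent), error = identity)
  expect_s3_class(err, "plugin_output_error")
  expect_match(conditionMessage(err), "out.nii.gz")
  # every failure is also a generic plugin_error
  expect_s3_class(err, "plugin_error")
})
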