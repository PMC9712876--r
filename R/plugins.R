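PLUGIN_MODULE_TYPES <- c("segmentation", "registration", "annotation",
                         "analysis", "aid")
PARAM_KINDS <- c("image", "mesh", "annotation", "mask", "number", "text",
                 "choice")
WIDGET_KINDS <- c("drop_menu", "text_box", "press_button", "explanatory_text")

plugin_abort <- function(class, msg, ...) {
  stop(structure(class = c(class, "plugin_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

#' Parse a plugin configuration file
#'
#' Reads the line-oriented INI dialect that declares an extension module:
#' section `[module]` (keys `name`, `type`, `program`), one
#' `[input.<key>]` / `[output.<key>]` section per parameter (keys `kind`,
#' `required`, `default`, `choices`), and ordered `[widget.<n>]` sections
#' (keys `widget`, `label`, `binds`). Unknown sections or keys are rejected
#' with their line number. Every widget that edits a parameter must bind a
#' declared input; a `drop_menu` must bind a `choice` parameter.
#'
#' @param path Path to the configuration file.
#' @return A `plugin_spec` with fields `name`, `module_type`, `program`,
#'   `inputs`, `outputs`, `widgets`.
#' @seealso [write_config()], [stage_inputs()], [run_plugin()]
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("parse_config: no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  sections <- list()   # name -> list(lineno, entries = named list(value, lineno))
  cur <- NULL
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    line <- sub("[;#].*$", "", raw)
    line <- trimws(line)
    if (!nzchar(line)) next
    m <- regmatches(line, regexec("^\\[([A-Za-z0-9_.]+)\\]$", line))[[1]]
    if (length(m) == 2L) {
      cur <- m[2]
      if (!is.null(sections[[cur]])) {
        plugin_abort("plugin_config_error",
                     "line %d: duplicate section [%s]", ln, cur)
      }
      sections[[cur]] <- list(lineno = ln, entries = list())
      next
    }
    kv <- regmatches(line, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) {
      plugin_abort("plugin_config_error", "line %d: cannot parse '%s'", ln, raw)
    }
    if (is.null(cur)) {
      plugin_abort("plugin_config_error",
                   "line %d: key outside any [section]", ln)
    }
    sections[[cur]]$entries[[kv[2]]] <- list(value = trimws(kv[3]), lineno = ln)
  }
  if (is.null(sections$module)) {
    plugin_abort("plugin_config_error", "missing required [module] section")
  }

  get_entry <- function(sec, key, required = FALSE, allowed = NULL) {
    e <- sections[[sec]]$entries[[key]]
    if (is.null(e)) {
      if (required) {
        plugin_abort("plugin_config_error",
                     "section [%s]: missing required key '%s'", sec, key)
      }
      return(NULL)
    }
    if (!is.null(allowed) && !e$value %in% allowed) {
      plugin_abort("plugin_config_error",
                   "line %d: '%s = %s' must be one of: %s",
                   e$lineno, key, e$value, paste(allowed, collapse = ", "))
    }
    e$value
  }
  check_keys <- function(sec, known) {
    for (k in names(sections[[sec]]$entries)) {
      if (!k %in% known) {
        plugin_abort("plugin_config_error", "line %d: unknown key '%s' in [%s]",
                     sections[[sec]]$entries[[k]]$lineno, k, sec)
      }
    }
  }

  check_keys("module", c("name", "type", "program"))
  name <- get_entry("module", "name", required = TRUE)
  module_type <- get_entry("module", "type", required = TRUE,
                           allowed = PLUGIN_MODULE_TYPES)
  program <- get_entry("module", "program", required = TRUE)

  inputs <- list()
  outputs <- list()
  widgets <- list()
  widget_order <- integer(0)
  for (sec in names(sections)) {
    if (sec == "module") next
    parts <- strsplit(sec, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% c("input", "output", "widget")) {
      plugin_abort("plugin_config_error", "line %d: unknown section [%s]",
                   sections[[sec]]$lineno, sec)
    }
    if (parts[1] %in% c("input", "output")) {
      check_keys(sec, c("kind", "required", "default", "choices"))
      kind <- get_entry(sec, "kind", required = TRUE, allowed = PARAM_KINDS)
      choices <- get_entry(sec, "choices")
      if (kind == "choice" && (is.null(choices) || !nzchar(choices))) {
        plugin_abort("plugin_config_error",
                     "section [%s]: choice parameter needs a non-empty 'choices' list", sec)
      }
      decl <- param_decl(
        key = parts[2], kind = kind,
        required = identical(tolower(get_entry(sec, "required") %||% "false"), "true"),
        default = parse_default(get_entry(sec, "default"), kind),
        choices = if (is.null(choices)) NULL else trimws(strsplit(choices, ",")[[1]]))
      if (parts[1] == "input") inputs[[decl$key]] <- decl
      else outputs[[decl$key]] <- decl
    } else {
      check_keys(sec, c("widget", "label", "binds"))
      widgets[[length(widgets) + 1L]] <- widget_decl(
        widget = get_entry(sec, "widget", required = TRUE, allowed = WIDGET_KINDS),
        label = get_entry(sec, "label") %||% "",
        binds = get_entry(sec, "binds"))
      widget_order <- c(widget_order, suppressWarnings(as.integer(parts[2])))
    }
  }
  if (length(widgets) && !anyNA(widget_order)) {
    widgets <- widgets[order(widget_order)]
  }
  # resolve a program path given relative to the configuration file
  if (!file.exists(program)) {
    cand <- file.path(dirname(path), program)
    if (file.exists(cand)) program <- normalizePath(cand)
  }
  plugin_spec(name = name, module_type = module_type, program = program,
              inputs = inputs, outputs = outputs, widgets = widgets)
}

parse_default <- function(x, kind) {
  if (is.null(x)) return(NULL)
  if (kind == "number") as.numeric(x) else x
}

#' Typed parameter declaration of a plugin
#'
#' @param key Parameter name (unique within the spec).
#' @param kind One of image, mesh, annotation, mask, number, text, choice.
#' @param required Logical.
#' @param default Optional default value (scalar kinds only).
#' @param choices Character vector of options (required for kind "choice").
#' @return A `param_decl`.
#' @export
param_decl <- function(key, kind, required = FALSE, default = NULL,
                       choices = NULL) {
  kind <- match.arg(kind, PARAM_KINDS)
  if (kind == "choice" && !length(choices)) {
    stop("param_decl: choice parameters need a non-empty choices vector")
  }
  structure(list(key = key, kind = kind, required = isTRUE(required),
                 default = default, choices = choices),
            class = "param_decl")
}

#' Widget declaration of a plugin panel
#'
#' @param widget One of drop_menu, text_box, press_button, explanatory_text.
#' @param label Display label.
#' @param binds Optional key of the input parameter the widget edits
#'   (press_button may bind the reserved action `"run"`).
#' @return A `widget_decl`.
#' @export
widget_decl <- function(widget, label = "", binds = NULL) {
  widget <- match.arg(widget, WIDGET_KINDS)
  structure(list(widget = widget, label = label, binds = binds),
            class = "widget_decl")
}

#' Construct and validate a plugin specification
#'
#' @param name Module name.
#' @param module_type One of segmentation, registration, annotation,
#'   analysis, aid.
#' @param program Path to the executable/script implementing the module.
#' @param inputs,outputs Named lists of [param_decl].
#' @param widgets List of [widget_decl]; bindings are validated against the
#'   declared inputs.
#' @return A `plugin_spec`.
#' @export
plugin_spec <- function(name, module_type, program, inputs = list(),
                        outputs = list(), widgets = list()) {
  module_type <- match.arg(module_type, PLUGIN_MODULE_TYPES)
  keys <- c(vapply(inputs, `[[`, "", "key"), vapply(outputs, `[[`, "", "key"))
  if (anyDuplicated(keys)) {
    plugin_abort("plugin_config_error", "duplicate parameter keys: %s",
                 paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  in_keys <- vapply(inputs, `[[`, "", "key")
  for (w in widgets) {
    if (is.null(w$binds) || identical(w$binds, "run")) next
    if (!w$binds %in% in_keys) {
      plugin_abort("plugin_config_error",
                   "widget '%s' binds undeclared input parameter '%s'",
                   w$label, w$binds)
    }
    if (w$widget == "drop_menu" &&
        inputs[[match(w$binds, in_keys)]]$kind != "choice") {
      plugin_abort("plugin_config_error",
                   "drop_menu widget '%s' must bind a choice parameter", w$label)
    }
  }
  structure(list(name = name, module_type = module_type, program = program,
                 inputs = inputs, outputs = outputs, widgets = widgets),
            class = "plugin_spec")
}

#' @export
print.plugin_spec <- function(x, ...) {
  cat(sprintf("<plugin_spec> '%s' (%s): %d inputs, %d outputs, %d widgets; program %s\n",
              x$name, x$module_type, length(x$inputs), length(x$outputs),
              length(x$widgets), x$program))
  invisible(x)
}

#' Write a plugin specification back to its configuration dialect
#'
#' Inverse of [parse_config()]: `parse_config(write_config(spec, f))`
#' reproduces `spec`.
#'
#' @param spec A `plugin_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(spec, path) {
  stopifnot(inherits(spec, "plugin_spec"))
  lines <- c("[module]",
             sprintf("name = %s", spec$name),
             sprintf("type = %s", spec$module_type),
             sprintf("program = %s", spec$program))
  fmt_param <- function(decl, role) {
    out <- c("", sprintf("[%s.%s]", role, decl$key),
             sprintf("kind = %s", decl$kind),
             sprintf("required = %s", tolower(as.character(decl$required))))
    if (!is.null(decl$default)) {
      out <- c(out, sprintf("default = %s", format(decl$default, digits = 15)))
    }
    if (!is.null(decl$choices)) {
      out <- c(out, sprintf("choices = %s", paste(decl$choices, collapse = ",")))
    }
    out
  }
  for (d in spec$inputs) lines <- c(lines, fmt_param(d, "input"))
  for (d in spec$outputs) lines <- c(lines, fmt_param(d, "output"))
  for (i in seq_along(spec$widgets)) {
    w <- spec$widgets[[i]]
    lines <- c(lines, "", sprintf("[widget.%d]", i),
               sprintf("widget = %s", w$widget),
               sprintf("label = %s", w$label))
    if (!is.null(w$binds)) lines <- c(lines, sprintf("binds = %s", w$binds))
  }
  writeLines(lines, path)
  invisible(path)
}

param_filename <- function(key, kind) {
  switch(kind,
         image = , mask = sprintf("%s.nii.gz", key),
         mesh = sprintf("%s.ply", key),
         annotation = sprintf("%s.json", key),
         NA_character_)  # scalar kinds live in params.json
}

#' Stage plugin inputs on disk (loose coupling, step 1)
#'
#' Writes every input value into `workdir` in its exchange format — images
#' and masks as NIfTI, meshes as PLY, annotation sets as JSON, scalar
#' parameters collected into a single `params.json` with stable
#' (alphabetical) key order — and records the exchange in `manifest.json`.
#' All values are validated against the declared parameter kinds before any
#' file is written.
#'
#' @param spec A `plugin_spec`.
#' @param values Named list mapping input keys to objects.
#' @param workdir Exchange directory (created if missing; should be fresh).
#' @return An `exchange_manifest`: `workdir`, `staged_inputs`,
#'   `expected_outputs`, `status = "staged"`.
#' @export
stage_inputs <- function(spec, values, workdir) {
  stopifnot(inherits(spec, "plugin_spec"))
  # validate first: no file is written if anything is missing or mistyped
  for (decl in spec$inputs) {
    v <- values[[decl$key]]
    if (is.null(v)) {
      if (!is.null(decl$default)) values[[decl$key]] <- decl$default
      else if (decl$required) {
        plugin_abort("plugin_staging_error",
                     "missing required input '%s'", decl$key)
      }
      next
    }
    ok <- switch(decl$kind,
                 image = inherits(v, "image3d"),
                 mask = inherits(v, "label_mask"),
                 mesh = inherits(v, "surface_mesh"),
                 annotation = inherits(v, "annotation_set"),
                 number = is.numeric(v) && length(v) == 1L && is.finite(v),
                 text = is.character(v) && length(v) == 1L,
                 choice = is.character(v) && length(v) == 1L && v %in% decl$choices)
    if (!ok) {
      plugin_abort("plugin_staging_error",
                   "input '%s' does not match declared kind '%s'",
                   decl$key, decl$kind)
    }
  }
  extra <- setdiff(names(values), vapply(spec$inputs, `[[`, "", "key"))
  if (length(extra)) {
    plugin_abort("plugin_staging_error", "undeclared input value(s): %s",
                 paste(extra, collapse = ", "))
  }

  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  staged <- list()
  scalars <- list()
  for (decl in spec$inputs) {
    v <- values[[decl$key]]
    if (is.null(v)) next
    fn <- param_filename(decl$key, decl$kind)
    if (is.na(fn)) {
      scalars[[decl$key]] <- v
    } else {
      p <- file.path(workdir, fn)
      switch(decl$kind,
             image = write_image(v, p),
             mask = write_image(v, p),
             mesh = write_mesh(v, p),
             annotation = write_annotations(v, p))
      staged[[decl$key]] <- fn
    }
  }
  if (length(scalars)) scalars <- scalars[order(names(scalars))]
  writeLines(jsonlite::toJSON(scalars, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(workdir, "params.json"))
  staged[["params"]] <- "params.json"
  expected <- list()
  for (decl in spec$outputs) {
    fn <- param_filename(decl$key, decl$kind)
    expected[[decl$key]] <- if (is.na(fn)) "results.json" else fn
  }
  manifest <- structure(
    list(workdir = workdir, plugin = spec$name,
         staged_inputs = staged, expected_outputs = expected,
         status = "staged"),
    class = "exchange_manifest")
  write_manifest(manifest)
  manifest
}

write_manifest <- function(manifest) {
  writeLines(jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(manifest$workdir, "manifest.json"))
  invisible(manifest)
}

#' Run a plugin program through the disk exchange (loose coupling, steps 2-3)
#'
#' Invokes the plugin program with the exchange directory as its single
#' argument; the program reads the staged files, computes, and writes its
#' outputs back into the directory. On a zero exit status with all expected
#' output files present, the outputs are loaded and returned. stdout and
#' stderr are captured to `plugin_stdout.log` / `plugin_stderr.log` in the
#' workdir. Failures raise distinct conditions carrying the log tail:
#' `plugin_exit_error` (nonzero exit), `plugin_timeout_error`, and
#' `plugin_output_error` (missing expected output). Programs ending in
#' `.R`/`.py`/`.sh` are run through `Rscript`/`python`/`sh`; anything else is
#' executed directly.
#'
#' @param spec A `plugin_spec`.
#' @param manifest The `exchange_manifest` from [stage_inputs()].
#' @param timeout Wall-clock limit in seconds (default 600).
#' @return Named list of loaded outputs (images/[label_mask]s/meshes/
#'   annotation sets by kind; scalar outputs from `results.json`).
#' @export
run_plugin <- function(spec, manifest, timeout = 600) {
  stopifnot(inherits(spec, "plugin_spec"), inherits(manifest, "exchange_manifest"))
  wd <- manifest$workdir
  for (fn in unlist(manifest$staged_inputs)) {
    if (!file.exists(file.path(wd, fn))) {
      plugin_abort("plugin_staging_error", "staged input missing on disk: %s", fn)
    }
  }
  manifest$status <- "running"
  write_manifest(manifest)
  run <- run_program(spec$program, wd, timeout)
  if (!is.null(run$error_class)) {
    manifest$status <- "failed"
    write_manifest(manifest)
    if (run$error_class == "plugin_timeout_error") {
      plugin_abort("plugin_timeout_error",
                   "plugin '%s' timed out after %g s\n%s", spec$name, timeout,
                   run$log_tail)
    }
    plugin_abort("plugin_exit_error",
                 "plugin '%s' exited with status %d\n%s", spec$name,
                 run$status, run$log_tail)
  }
  outputs <- list()
  for (decl in spec$outputs) {
    fn <- manifest$expected_outputs[[decl$key]]
    p <- file.path(wd, fn)
    if (!file.exists(p)) {
      manifest$status <- "failed"
      write_manifest(manifest)
      plugin_abort("plugin_output_error",
                   "plugin '%s' finished but expected output '%s' (%s) is missing\n%s",
                   spec$name, decl$key, fn, run$log_tail)
    }
    outputs[[decl$key]] <- switch(
      decl$kind,
      image = read_image(p),
      mask = {
        img <- read_image(p)
        label_mask(array(as.integer(round(img$voxels)), dim = dim(img$voxels)), img)
      },
      mesh = read_mesh(p),
      annotation = read_annotations(p),
      jsonlite::fromJSON(p)[[decl$key]])
  }
  manifest$status <- "done"
  write_manifest(manifest)
  outputs
}

#' Create a timestamped exchange directory
#'
#' Workdirs are never reused: each call returns a fresh directory named by
#' timestamp plus a unique suffix under `root`.
#'
#' @param root Parent directory.
#' @return Path to the created directory.
#' @export
plugin_workdir <- function(root = tempdir()) {
  # counter + pid rather than RNG so seeded experiments are not perturbed
  n <- get0("workdir_counter", envir = .sketchkit_env, ifnotfound = 0L) + 1L
  assign("workdir_counter", n, envir = .sketchkit_env)
  repeat {
    p <- file.path(root, sprintf("run_%s_p%d_%04d",
                                 format(Sys.time(), "%Y%m%d%H%M%S"),
                                 Sys.getpid(), n))
    if (!dir.exists(p)) {
      dir.create(p, recursive = TRUE)
      return(p)
    }
    n <- n + 1L
  }
}

.sketchkit_env <- new.env(parent = emptyenv())

# Invoke an external program with `wd` as its single argument, logs captured
# into the workdir. Returns list(status, log_tail, error_class): error_class
# is NULL on success, "plugin_timeout_error" or "plugin_exit_error" otherwise.
# Scripts are dispatched to their interpreter by extension.
run_program <- function(program, wd, timeout = 600) {
  ext <- tolower(tools::file_ext(program))
  cmd_args <- switch(ext,
                     r = c(file.path(R.home("bin"), "Rscript"), program),
                     py = c("python", program),
                     sh = c("sh", program),
                     c(program))
  out_log <- file.path(wd, "plugin_stdout.log")
  err_log <- file.path(wd, "plugin_stderr.log")
  status <- suppressWarnings(
    system2(cmd_args[1], args = c(cmd_args[-1], wd),
            stdout = out_log, stderr = err_log, timeout = timeout))
  tails <- c(utils::tail(tryCatch(readLines(err_log, warn = FALSE),
                                  error = function(e) character(0)), 5L),
             utils::tail(tryCatch(readLines(out_log, warn = FALSE),
                                  error = function(e) character(0)), 5L))
  list(status = status,
       log_tail = paste(tails, collapse = "\n"),
       error_class = if (identical(status, 124L)) "plugin_timeout_error"
                     else if (!identical(status, 0L)) "plugin_exit_error"
                     else NULL)
}
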