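#' Run manifest: provenance record for a set of outputs
#'
#' Captures the configuration snapshot, master seed, package version,
#' timestamp and output paths of a simulation or study run, so every
#' output file is traceable to the exact settings that produced it.
#'
#' @param config a \code{\link{study_config}} (or any list of settings).
#' @param outputs character vector of produced file paths.
#' @param extra optional named list merged into the manifest.
#' @return A list of class \code{run_manifest}.
#' @export
run_manifest <- function(config, outputs = character(), extra = list()) {
  m <- c(list(package = "semgfatigue",
              version = as.character(packageVersion("semgfatigue")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              master_seed = config$master_seed,
              config = unclass(config),
              outputs = outputs),
         extra)
  class(m) <- "run_manifest"
  m
}

#' @rdname run_manifest
#' @param manifest a \code{run_manifest}.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Run manifest (%s %s, seed %s, %s)\n", x$package, x$version,
              x$master_seed, x$timestamp))
  if (length(x$outputs)) cat("  outputs:", paste(x$outputs, collapse = ", "), "\n")
  invisible(x)
}
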