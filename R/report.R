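#' Write a run manifest
#'
#' Records alongside every output set what produced it: the analysis
#' name, seed, number of PSA draws and package version, so a run can be
#' reproduced bit-identically for the deterministic analyses.
#'
#' @param out_dir Output directory (created if missing).
#' @param analysis Short analysis name.
#' @param seed Master seed of the run.
#' @param n_draws PSA draws used.
#' @param config Optional path of the configuration used.
#' @return Path of the written `manifest.json`, invisibly.
#' @export
run_manifest <- function(out_dir, analysis, seed, n_draws,
                         config = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(analysis = analysis, seed = seed, n_draws = n_draws,
                   config = config,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   package = "ifmicost",
                   version = as.character(utils::packageVersion("ifmicost")))
  path <- file.path(out_dir, paste0("manifest_", analysis, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
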