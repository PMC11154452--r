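# Key-value run configuration with study defaults.

bu_config_defaults <- function() {
  list(
    n_explore = 2000,       # SAEM exploration iterations (final fits)
    n_smooth = 300,         # SAEM smoothing iterations (final fits)
    n_explore_build = 600,  # reduced counts during model building
    n_smooth_build = 100,
    npde_simulations = 10000,
    vpc_simulations = 1000,
    bootstrap = 500,
    seed = 1L,
    output_dir = "."
  )
}

#' Load a run configuration
#'
#' Reads a plain-text `key = value` file (comments start with `#`) and fills
#' unset keys with the study defaults: SAEM iterations 2000/300 for final
#' fits and 600/100 for model building, 10000 npde simulations, 1000 VPC
#' simulations, 500 bootstrap replicates.
#'
#' @param path Path to a config file, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- bu_config_defaults()
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(paste0("Malformed config line: '", ln, "'"))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) {
      abort(paste0("Unknown config key '", key, "'. Valid keys: ",
                   paste(names(cfg), collapse = ", ")))
    }
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (is.na(num)) val else num
  }
  cfg
}
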