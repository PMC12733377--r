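#' Pipeline configuration
#'
#' All tunables of the transfer pipeline in one validated object. Every
#' default that has a published value uses it: at least six landmark pairs,
#' closing element size 55, Gaussian size 63 with sigma 53 and threshold 0.1
#' for the tissue mask. Unknown keys are rejected rather than ignored.
#'
#' @param registration List: `normalization` (`"wh"`/`"max"`),
#'   `condition_cap`.
#' @param extraction List: `diff_threshold`, `closing_radius`.
#' @param tissue_mask A [tissue_mask_params()] object or a plain list of its
#'   fields.
#' @param transfer List: `erosion_size`, `overlay_color`, `overlay_thickness`.
#' @param metrics List: `extractor` (`"builtin"`), `quantile_type`.
#' @param seed Global seed recorded with every run.
#' @param out_dir Default output directory.
#' @param verbose Logical.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(registration = list(), extraction = list(),
                            tissue_mask = list(), transfer = list(),
                            metrics = list(), seed = 1L, out_dir = ".",
                            verbose = FALSE) {
  merge_section <- function(given, defaults, name) {
    given <- as.list(given)
    # YAML readers hand integers back for whole numbers; keep doubles so a
    # write/read round-trip reproduces an identical object
    given <- lapply(given, function(v) if (is.integer(v)) as.numeric(v) else v)
    bad <- setdiff(names(given), names(defaults))
    if (length(bad) > 0) {
      stop(sprintf("unknown key(s) in config section '%s': %s", name,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(defaults, given)
  }
  reg <- merge_section(registration,
                       list(normalization = "wh", condition_cap = 1e8),
                       "registration")
  ext <- merge_section(extraction,
                       list(diff_threshold = 10 / 255, closing_radius = 5),
                       "extraction")
  tm_defaults <- unclass(tissue_mask_params())
  tm <- merge_section(if (inherits(tissue_mask, "tissue_mask_params"))
                        unclass(tissue_mask) else tissue_mask,
                      tm_defaults, "tissue_mask")
  tm <- do.call(tissue_mask_params, tm)
  tr <- merge_section(transfer,
                      list(erosion_size = 15, overlay_color = c(0, 1, 0),
                           overlay_thickness = 3),
                      "transfer")
  me <- merge_section(metrics, list(extractor = "builtin", quantile_type = 7),
                      "metrics")
  structure(list(registration = reg, extraction = ext, tissue_mask = tm,
                 transfer = tr, metrics = me, seed = as.integer(seed),
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' The YAML mirrors the [pipeline_config()] sections; unknown sections or
#' keys are rejected with the offending name. `write_config()` followed by
#' `read_config()` reproduces an identical configuration.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  allowed <- c("registration", "extraction", "tissue_mask", "transfer",
               "metrics", "seed", "out_dir", "verbose")
  bad <- setdiff(names(y), allowed)
  if (length(bad) > 0) {
    stop(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, y)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  out$tissue_mask <- unclass(out$tissue_mask)
  out$tissue_mask <- Filter(Negate(is.null), out$tissue_mask)
  yaml::write_yaml(out, path)
  invisible(path)
}
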