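#' Run configuration
#'
#' A validated bundle of every tunable the pipeline exposes.  Defaults are
#' the literature-map-scale values (350 x 350 grid, 20 epochs, sigma0 175,
#' decay base 1.7, minimum term count 100); toy-scale runs override them via
#' a YAML config file or CLI flags.
#'
#' @param ... fields overriding the defaults; see [default_config()].
#' @return a validated `medsom_config` (named list).
#' @export
medsom_config <- function(...) {
  cfg <- utils::modifyList(default_config(), list(...))
  validate_config(cfg)
}

#' @rdname medsom_config
#' @export
default_config <- function() {
  list(
    rows = 350L, cols = 350L,
    epochs = 20L, sigma0 = 175, decay_base = 1.7,
    kernel = "gaussian", adjacency = "queen",
    min_term_count = 100L,
    k_max = 12L, kmeans_restarts = 10L,
    title_threshold = 0.90, journal_threshold = 0.80,
    ellipse_level = 0.95,
    seed = 1L
  )
}

#' @rdname medsom_config
#' @param cfg a config list to validate.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stopf("invalid config: %s", msg)
  chk(cfg$rows >= 1 && cfg$cols >= 1, "grid dimensions must be >= 1")
  chk(cfg$epochs >= 1, "epochs must be >= 1")
  chk(cfg$sigma0 > 0, "sigma0 must be > 0")
  chk(cfg$decay_base > 1, "decay_base must be > 1")
  chk(cfg$kernel %in% c("gaussian", "bubble"), "kernel must be gaussian|bubble")
  chk(cfg$adjacency %in% c("queen", "rook"), "adjacency must be queen|rook")
  chk(cfg$min_term_count >= 0, "min_term_count must be >= 0")
  chk(cfg$k_max >= 3, "k_max must be >= 3")
  chk(cfg$kmeans_restarts >= 1, "kmeans_restarts must be >= 1")
  chk(cfg$title_threshold >= 0 && cfg$title_threshold <= 1, "title_threshold in [0,1]")
  chk(cfg$journal_threshold >= 0 && cfg$journal_threshold <= 1, "journal_threshold in [0,1]")
  chk(cfg$ellipse_level > 0 && cfg$ellipse_level < 1, "ellipse_level in (0,1)")
  structure(cfg, class = "medsom_config")
}

#' Load a YAML config file over the defaults
#'
#' @param path YAML file; unknown keys are an error.
#' @return a validated `medsom_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(default_config()))
  if (length(unknown) > 0) {
    stopf("invalid config: unknown key(s) %s", paste(unknown, collapse = ", "))
  }
  do.call(medsom_config, y)
}

# Provenance JSON accompanying every CLI output: config, seeds, input file
# digests, package version.
write_provenance <- function(path, cfg, inputs = character()) {
  digests <- lapply(inputs, function(f) {
    fnv1a(readChar(f, file.info(f)$size, useBytes = TRUE))
  })
  names(digests) <- inputs
  jsonlite::write_json(
    list(tool = "medsom",
         version = as.character(utils::packageVersion("medsom")),
         config = unclass(cfg),
         input_digests = digests),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
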