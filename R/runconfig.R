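#' Read and write YAML run configurations
#'
#' A run configuration is a YAML file with optional sections \code{scene},
#' \code{augment}, \code{train}, \code{morph}, \code{match}, \code{zones}
#' (each holding arguments of the corresponding config constructor) plus
#' free-form \code{paths} and a top-level \code{seed}. A saved
#' configuration re-runs identically given the seed.
#'
#' @param path YAML file path.
#' @return \code{readRunConfig}: list with the parsed config objects
#'   (\code{scene}, \code{augment}, \code{train}, \code{morph},
#'   \code{match}, \code{zones}), \code{paths} and \code{seed}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, section) do.call(ctor, as.list(y[[section]]))
  list(scene = build(sceneConfig, "scene"),
       augment = build(augmentConfig, "augment"),
       train = build(trainConfig, "train"),
       morph = build(morphConfig, "morph"),
       match = build(matchConfig, "match"),
       zones = build(zoneConfig, "zones"),
       paths = y$paths,
       seed = if (is.null(y$seed)) 1L else as.integer(y$seed))
}

#' @rdname readRunConfig
#' @param config a list as returned by \code{readRunConfig} (S4 entries
#'   are flattened back to YAML sections).
#' @return \code{writeRunConfig}: the path, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  flat <- lapply(config, function(x) {
    if (isVirtualClass(class(x)) || !isS4(x)) return(x)
    s <- sapply(slotNames(x), function(nm) slot(x, nm), simplify = FALSE)
    lapply(s, function(v) if (is.integer(v) && length(v) == 1 && is.na(v))
      NULL else v)
  })
  yaml::write_yaml(flat, path)
  invisible(path)
}
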