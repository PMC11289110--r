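#' Dataset catalog I/O and validation
#'
#' The catalog is one CSV describing the experiment hierarchy: every image
#' belongs to exactly one tubule, every tubule to one (experiment,
#' treatment) pair, and multiple z-stack images are acquired per tubule
#' (treated as independent images). Required columns: \code{image_id},
#' \code{experiment_id}, \code{treatment_id}, \code{tubule_id},
#' \code{z_index}, \code{image_path}, \code{annotation_path}.
#'
#' @param path CSV file path.
#' @param catalog a catalog data.frame.
#' @return \code{readCatalog} returns the validated catalog data.frame.
#' @export
readCatalog <- function(path) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  cat$z_index <- as.integer(cat$z_index)
  validateCatalog(cat)
  cat
}

#' @rdname readCatalog
#' @export
writeCatalog <- function(catalog, path) {
  validateCatalog(catalog)
  utils::write.csv(catalog, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readCatalog
#' @export
validateCatalog <- function(catalog) {
  required <- c("image_id", "experiment_id", "treatment_id", "tubule_id",
                "z_index", "image_path", "annotation_path")
  missing <- setdiff(required, names(catalog))
  if (length(missing))
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(catalog$image_id))
    stop("catalog contains duplicate image_id(s): ",
         paste(unique(catalog$image_id[duplicated(catalog$image_id)]),
               collapse = ", "))
  key <- c("experiment_id", "treatment_id", "tubule_id")
  if (any(is.na(catalog[key]) | catalog[key] == ""))
    stop("catalog has empty experiment/treatment/tubule identifiers")
  invisible(catalog)
}

#' Composite tubule keys
#'
#' Tubule ids are only unique within an (experiment, treatment) pair, so
#' grouping and fold construction use the composite key
#' \code{experiment/treatment/tubule}.
#'
#' @param catalog a catalog data.frame.
#' @return character vector of composite keys, one per catalog row.
#' @export
tubuleKeys <- function(catalog) {
  paste(catalog$experiment_id, catalog$treatment_id, catalog$tubule_id,
        sep = "/")
}
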