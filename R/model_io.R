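#' Save and load microstate models as JSON
#'
#' The full model -- templates included -- serialises to a plain JSON
#' document, so fitted group maps can be archived next to the tables
#' they produced and reloaded for backfitting new data.
#'
#' @param model a `microstate_model`.
#' @param path output path.
#' @return `read_microstate_model()` returns a `microstate_model`.
#' @export
write_microstate_model <- function(model, path) {
  stopifnot(inherits(model, "microstate_model"))
  obj <- unclass(model)
  obj$templates <- as.data.frame(model$templates)
  obj$channel_names <- rownames(model$templates)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_microstate_model
#' @export
read_microstate_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  templates <- as.matrix(obj$templates)
  rownames(templates) <- obj$channel_names
  structure(list(k = obj$k, templates = templates,
                 gev_total = obj$gev_total,
                 gev_per_state = obj$gev_per_state,
                 sigma2 = obj$sigma2, cv = obj$cv,
                 labels = obj$labels, n_restarts = obj$n_restarts,
                 converged = obj$converged, n_maps = obj$n_maps),
            class = "microstate_model")
}

#' Save a segmentation as a two-column TSV
#'
#' One row per sample: `sample` (1-based index) and `label` (state index
#' or NA for unassigned).
#'
#' @param seg an `ms_segmentation`.
#' @param path output path.
#' @export
write_segmentation <- function(seg, path) {
  stopifnot(inherits(seg, "ms_segmentation"))
  utils::write.table(
    data.frame(sample = seq_along(seg$labels), label = seg$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
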