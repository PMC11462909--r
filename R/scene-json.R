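# Scenes serialize to a versioned JSON schema. Serialization is canonical:
# serialize -> parse -> serialize is byte-identical, which is what makes
# scene JSON usable as a determinism fingerprint of a plotting run.

scene_to_payload <- function(scene) {
  cls <- class(scene)[1L]
  body <- unclass(scene)
  body <- body[!vapply(body, is.null, logical(1L))]
  c(list(scene_class = cls), body)
}

scene_json <- function(scene) {
  payload <- if (inherits(scene, c("beading_scene", "companion_scene"))) {
    scene_to_payload(scene)
  } else scene
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = FALSE))
}

#' Write a plot scene to JSON
#'
#' Lossless, canonical serialization of a [build_beading_plot()] or
#' companion scene: numbers keep full precision and re-serializing a
#' parsed scene reproduces the file byte for byte.
#'
#' @param scene A `beading_scene` or `companion_scene`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scene_json <- function(scene, path) {
  writeLines(scene_json(scene), path, useBytes = TRUE)
  invisible(path)
}

#' Read a plot scene from JSON
#'
#' @param path JSON file written by [write_scene_json()].
#' @return The scene object with its class restored.
#' @export
read_scene_json <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cls <- payload$scene_class
  if (is.null(cls)) stop_validation("not a scene JSON file: %s", path)
  payload$scene_class <- NULL
  structure(payload, class = cls)
}
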