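#' Anatomical landmark
#'
#' A named point in world millimetres, e.g. the ventricular apex seed or the
#' harmonic-field inlet/outlet seeds.
#'
#' @param name landmark name (e.g. `"apex_seed"`, `"inlet_seed"`,
#'   `"outlet_seed"`, `"stj_point"`).
#' @param position length-3 numeric (mm).
#' @return object of class `landmark`.
#' @export
landmark <- function(name, position) {
  position <- as.numeric(position)
  if (length(position) != 3L || !all(is.finite(position)))
    stop("landmark position must be a finite 3D point")
  structure(list(name = as.character(name), position = position),
            class = "landmark")
}

#' @export
print.landmark <- function(x, ...) {
  cat(sprintf("<landmark> %s: (%.3f, %.3f, %.3f)\n", x$name,
              x$position[1], x$position[2], x$position[3]))
  invisible(x)
}

#' Read landmarks from JSON
#'
#' Expects an object of the form `{"apex_seed": [x, y, z], ...}`.
#'
#' @param path JSON file path.
#' @return named list of [landmark()] objects.
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(obj), function(nm) landmark(nm, obj[[nm]]))
  stats::setNames(out, names(obj))
}

#' Write landmarks to JSON
#' @param landmarks named list of [landmark()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  obj <- lapply(landmarks, function(l) l$position)
  names(obj) <- vapply(landmarks, function(l) l$name, character(1))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}
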