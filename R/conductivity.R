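#' Tissue conductivity sets
#'
#' A conductivity set maps tissue names to electrical conductivities in
#' S/m. Two bundled sets are provided: the literature default used for
#' human head tissue, and the set obtained by calibrating scalp and skull
#' against in vivo strip-field recordings (scalp 0.0004, skull 0.004 S/m,
#' roughly twice the defaults).
#'
#' @param values named numeric vector, tissue name -> conductivity (S/m).
#'   Must contain at least scalp, skull, CSF, gray_matter and white_matter.
#'   All values must be > 0 except `air`, which must be 0 if present.
#' @param provenance character tag: `"default"`, `"optimized"` or a free
#'   label for a named literature set.
#' @return An object of class `conductivity_set`: a named numeric vector
#'   with a `provenance` attribute.
#' @examples
#' sig <- default_conductivities()
#' sig[["skull"]]
#' optimized_conductivities()[c("scalp", "skull")]
#' @export
conductivity_set <- function(values, provenance = "custom") {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("conductivities must be a fully named numeric vector", call. = FALSE)
  values <- vapply(values, as.numeric, numeric(1))
  required <- c("scalp", "skull", "CSF", "gray_matter", "white_matter")
  missing <- setdiff(required, names(values))
  if (length(missing))
    stop("conductivity set is missing required tissues: ",
         paste(missing, collapse = ", "), call. = FALSE)
  non_air <- setdiff(names(values), "air")
  if (any(values[non_air] <= 0))
    stop("conductivities must be > 0 (except air)", call. = FALSE)
  if ("air" %in% names(values) && values[["air"]] != 0)
    stop("air conductivity must be exactly 0", call. = FALSE)
  structure(values, provenance = provenance, class = "conductivity_set")
}

#' @rdname conductivity_set
#' @export
default_conductivities <- function() {
  conductivity_set(c(
    gray_matter  = 0.0988,
    white_matter = 0.0626,
    CSF          = 2,
    skull        = 0.00227,
    scalp        = 0.0002,
    blood        = 0.659,
    muscle       = 0.321,
    air          = 0,
    # brain = volume-weighted stand-in used by single-compartment phantoms
    brain        = 0.0988
  ), provenance = "default")
}

#' @rdname conductivity_set
#' @export
optimized_conductivities <- function() {
  sig <- unclass(default_conductivities())
  sig[["skull"]] <- 0.004
  sig[["scalp"]] <- 0.0004
  conductivity_set(sig, provenance = "optimized")
}

#' @export
print.conductivity_set <- function(x, ...) {
  cat("Conductivity set (", attr(x, "provenance"), "), S/m:\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Serialize a conductivity set to/from JSON
#'
#' Round-trips losslessly: tissue names, values (full double precision) and
#' the provenance tag are preserved.
#'
#' @param x a `conductivity_set`
#' @param path file path; for reading, a path to a JSON file written by
#'   [write_conductivities()].
#' @return `read_conductivities()` returns a `conductivity_set`.
#' @export
write_conductivities <- function(x, path) {
  stopifnot(inherits(x, "conductivity_set"))
  obj <- list(
    units = "S/m",
    provenance = attr(x, "provenance"),
    conductivity = as.list(stats::setNames(as.numeric(x), names(x)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_conductivities
#' @export
read_conductivities <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  conductivity_set(unlist(obj$conductivity), provenance = obj$provenance)
}
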