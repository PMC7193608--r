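#' Model, montage and epoch serialization
#'
#' Plain-text I/O for the package's objects: JSON for models, montages
#' and conductivity sets (units stated in-file), CSV for voxel label
#' grids, strip samples and analysis results. See also
#' [write_conductivities()].
#'
#' @name shuntfield-io
NULL

#' Write/read a tissue model as JSON (+ CSV voxel grid)
#'
#' Slab and shell models serialize fully into one JSON file. Voxel
#' models write the grid as a flat CSV (`i,j,k,label`, 0-based indices,
#' air omitted) next to the JSON, referenced by file name.
#'
#' @param model a `tissue_model`.
#' @param path JSON output path.
#' @return `read_tissue_model()` returns a `tissue_model`.
#' @export
write_tissue_model <- function(model, path) {
  stopifnot(inherits(model, "tissue_model"))
  obj <- list(kind = model$kind, units = list(length = "mm",
                                              conductivity = "S/m"),
              conductivity = as.list(stats::setNames(
                as.numeric(model$conductivities),
                names(model$conductivities))),
              provenance = attr(model$conductivities, "provenance"))
  if (model$kind == "slab") obj$layers <- model$layers
  if (model$kind == "shells") obj$shells <- model$shells
  if (model$kind == "voxels") {
    grid_path <- sub("\\.json$", "_labels.csv", path)
    idx <- which(model$labels != 0L, arr.ind = TRUE)
    utils::write.csv(data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                                k = idx[, 3] - 1L,
                                label = model$labels[idx]),
                     grid_path, row.names = FALSE)
    obj$voxels <- list(dims = dim(model$labels), voxel_mm = model$voxel_mm,
                       origin_mm = model$origin_mm,
                       tissue_names = model$tissue_names,
                       labels_csv = basename(grid_path),
                       scalp_removed = isTRUE(model$scalp_removed))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_tissue_model
#' @export
read_tissue_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sig <- conductivity_set(unlist(obj$conductivity),
                          provenance = obj$provenance)
  if (obj$kind == "slab")
    return(build_slab(stats::setNames(obj$layers$thickness_mm,
                                      obj$layers$tissue), sig))
  if (obj$kind == "shells")
    return(build_shell_model(obj$shells$radius_mm, sig,
                             tissues = obj$shells$tissue))
  v <- obj$voxels
  grid <- utils::read.csv(file.path(dirname(path), v$labels_csv))
  labels <- array(0L, dim = v$dims)
  labels[cbind(grid$i + 1L, grid$j + 1L, grid$k + 1L)] <- grid$label
  new_tissue_model("voxels", sig, labels = labels,
                   tissue_names = v$tissue_names, voxel_mm = v$voxel_mm,
                   origin_mm = v$origin_mm,
                   scalp_removed = isTRUE(v$scalp_removed))
}

#' Tabulate field measurements as a results data frame
#'
#' Long-format table (one row per adjacent contact pair) suitable for
#' CSV export.
#'
#' @param measurements list of `field_measurement` objects.
#' @return Data frame with columns `condition`, `intensity_mA`,
#'   `frequency_hz`, `montage_id`, `pair_index`, `field_mV_per_mm`.
#' @export
measurements_table <- function(measurements) {
  do.call(rbind, lapply(measurements, function(m) {
    data.frame(condition = m$condition, intensity_mA = m$intensity_mA,
               frequency_hz = m$frequency_hz, montage_id = m$montage_id,
               pair_index = seq_along(m$pair_fields_mV_mm),
               field_mV_per_mm = m$pair_fields_mV_mm,
               stringsAsFactors = FALSE)
  }))
}
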