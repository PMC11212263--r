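# Integer-label atlas volumes with a region table.

#' Construct a label atlas
#'
#' Pairs an integer-label [volume()] with a region table.  The table is
#' always recomputed-consistent: `volume_mm3` is exactly
#' `voxel_count * prod(spacing)`, and every nonzero label present in the
#' grid must appear in the table and vice versa.
#'
#' @param labels A `volume` of kind `"label"`.
#' @param region_names Named character vector or `NULL`; names for region
#'   ids (defaults to `"region_<id>"`).
#' @return An object of class `label_atlas` with elements `labels` (volume)
#'   and `regions` (tibble: `region_id`, `name`, `voxel_count`,
#'   `volume_mm3`).
#' @export
label_atlas <- function(labels, region_names = NULL) {
  if (!is_volume(labels) || vol_kind(labels) != "label")
    stop("`labels` must be a volume of kind 'label'", call. = FALSE)
  vals <- as.integer(vol_values(labels))
  tab <- table(vals[vals > 0L])
  ids <- as.integer(names(tab))
  counts <- as.integer(tab)
  nm <- sprintf("region_%d", ids)
  if (!is.null(region_names)) {
    given <- region_names[as.character(ids)]
    nm[!is.na(given)] <- given[!is.na(given)]
  }
  vox_mm3 <- prod(vol_spacing(labels))
  regions <- tibble::tibble(
    region_id = ids, name = nm, voxel_count = counts,
    volume_mm3 = counts * vox_mm3
  )
  structure(list(labels = labels, regions = regions), class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_atlas> %d regions on a %d x %d x %d grid\n",
              nrow(x$regions), d[1], d[2], d[3]))
  print(x$regions, n = 8)
  invisible(x)
}
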