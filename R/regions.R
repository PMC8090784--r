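#' CNS regions quantified by the pipeline
#'
#' The six central nervous system regions whose volumes drive the
#' stratification: upper-cervical spinal cord, striatum, globus pallidus,
#' thalamus, cortical gray matter and brain white matter. Throughout the
#' package a visit table carries one volume column per region, named
#' `<region>_vol` (e.g. `sc_vol`), and rate/residual tables carry one rate
#' column per region, named by the region key itself.
#'
#' @return Named character vector mapping region keys to display labels.
#' @export
#' @examples
#' cns_regions()
cns_regions <- function() {
  c(
    sc       = "Spinal cord",
    striatum = "Striatum",
    gp       = "Globus pallidus",
    thalamus = "Thalamus",
    cgm      = "Cortical gray matter",
    wm       = "Brain white matter"
  )
}

region_keys <- function() names(cns_regions())

volume_cols <- function() paste0(region_keys(), "_vol")

# Pull the n x 6 region matrix out of a rate/residual tibble, preserving ids.
rate_matrix <- function(x) {
  keys <- region_keys()
  missing <- setdiff(keys, names(x))
  if (length(missing) > 0) {
    abort(paste0(
      "Missing region column(s): ", paste(missing, collapse = ", ")
    ))
  }
  m <- as.matrix(x[, keys])
  rownames(m) <- as.character(x$patient_id)
  m
}
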