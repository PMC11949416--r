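# On-disk interchange container for phantoms and acquisitions.
#
# A container file stores: `data` (the complex array with its documented
# axis order), `metadata` (scan_metadata), `truth` (phantom_truth or NULL
# for real acquisitions) and, for M-B-mode scans, the excitation position
# and axis label. Serialization uses R's native RDS format.

#' Write an OCT object to a container file
#'
#' @param x a `complex_volume` or `mb_scan`.
#' @param path output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_oct_container <- function(x, path) {
  if (!inherits(x, c("complex_volume", "mb_scan"))) {
    mf_stop("x must be a complex_volume or mb_scan", "invalid_container")
  }
  saveRDS(x, path)
  invisible(path)
}

#' Read an OCT object from a container file
#'
#' @param path file written by [write_oct_container()].
#' @return the stored `complex_volume` or `mb_scan`.
#' @export
read_oct_container <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, c("complex_volume", "mb_scan"))) {
    mf_stop("file does not contain an OCT container object", "invalid_container")
  }
  x
}
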