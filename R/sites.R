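#' Sampling-site code table
#'
#' The twelve two-letter site designations used throughout the cohort, and
#' the numeric codes under which some supplementary-style tables encode them
#' (1=BM, 2=HW, 3=LU, 4=WF, 7=GL, 8=WT, 9=PF, 10=ST, 11=JB, 12=PH, 13=SP,
#' 14=SK).
#'
#' @return Named character vector mapping numeric code (as name) to the
#'   two-letter site code.
#' @export
site_code_map <- function() {
  c(`1` = "BM", `2` = "HW", `3` = "LU", `4` = "WF", `7` = "GL", `8` = "WT",
    `9` = "PF", `10` = "ST", `11` = "JB", `12` = "PH", `13` = "SP", `14` = "SK")
}

#' @rdname site_code_map
#' @export
site_codes <- function() unname(site_code_map())

#' Map numeric site codes to two-letter designations
#'
#' @param code integer or character vector of numeric site codes, or already
#'   valid two-letter codes (returned unchanged).
#' @return Character vector of two-letter site codes. Unknown codes raise an
#'   error naming the offending value.
#' @export
map_site_code <- function(code) {
  m <- site_code_map()
  out <- character(length(code))
  for (i in seq_along(code)) {
    x <- code[i]
    if (is.na(x)) {
      out[i] <- NA_character_
    } else if (as.character(x) %in% m) {
      out[i] <- as.character(x)
    } else if (as.character(x) %in% names(m)) {
      out[i] <- m[[as.character(x)]]
    } else {
      stop("unknown site code '", x, "' at position ", i, call. = FALSE)
    }
  }
  out
}
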