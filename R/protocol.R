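#' OCT acquisition protocols
#'
#' Describes the two posterior-pole acquisition protocols behind the mapping
#' schemes: the standard posterior pole protocol (61 horizontal B-scans of 768
#' A-scans, averaged 9 times, over the central 30 x 25 degrees) feeding the
#' conventional 8 x 8 grid, and the high-density protocol (121 B-scans of 1536
#' A-scans) feeding the localized 12 x 12 grid.
#'
#' @param scheme `"CMA"` or `"LMA"`.
#' @return A list: `scheme`, `n_bscans`, `a_scans_per_bscan`, `averaging`,
#'   `field_deg` (width, height).
#' @export
oct_scan_protocol <- function(scheme = c("CMA", "LMA")) {
  scheme <- match.arg(scheme)
  if (scheme == "CMA") {
    list(scheme = scheme, n_bscans = 61L, a_scans_per_bscan = 768L,
         averaging = 9L, field_deg = c(30, 25))
  } else {
    list(scheme = scheme, n_bscans = 121L, a_scans_per_bscan = 1536L,
         averaging = 9L, field_deg = c(30, 25))
  }
}

#' Total B-scans acquired over a cohort
#'
#' One volume per subject: `n_bscans * n_subjects`. For the 48-subject study
#' configuration this gives 2928 B-scans with the standard protocol and 5808
#' with the high-density protocol.
#'
#' @param protocol An [oct_scan_protocol()].
#' @param n_subjects Number of subjects imaged.
#' @return Integer B-scan count.
#' @export
cohort_bscan_total <- function(protocol, n_subjects) {
  stopifnot(n_subjects >= 0)
  as.integer(protocol$n_bscans) * as.integer(n_subjects)
}
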