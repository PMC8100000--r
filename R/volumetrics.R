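# Volume derivations: ICV correction, composite subfields (CAt, HIP) and
# the left-right asymmetry index.

#' Correct a volume for intracranial volume
#'
#' `100 * volume / icv`, i.e. the volume expressed as a percentage of ICV.
#' Vectorized over both arguments.
#'
#' @param volume regional volume(s), mm3 (>= 0).
#' @param icv intracranial volume(s), mm3 (> 0).
#' @return Percent of ICV (unitless).
#' @examples
#' icvCorrect(500, 100000)  # 0.5
#' @export
icvCorrect <- function(volume, icv) {
    if (any(icv <= 0)) stop("ICV must be positive")
    if (any(volume < 0)) stop("volumes must be non-negative")
    100 * volume / icv
}

#' Derive composite subfield volumes
#'
#' Adds the CA-total and total-hippocampus composites to a volume table,
#' per hemisphere: `cat = ca1 + ca2 + ca3` and
#' `hip = sub + cat + dg + tail`. The entorhinal cortex is *not* part of
#' the hippocampus composite (it is a separate analyzed measure). The same
#' identities hold whether the inputs are raw mm3 or ICV-corrected values.
#'
#' @param volumes data.frame with columns `sub_l`, `ca1_l`, `ca2_l`,
#'   `ca3_l`, `dg_l`, `tail_l` and the `_r` counterparts (any other columns
#'   are carried through).
#' @return The input with added columns `cat_l`, `hip_l`, `cat_r`, `hip_r`.
#' @export
deriveComposites <- function(volumes) {
    for (h in c("l", "r")) {
        need <- paste0(c("sub", "ca1", "ca2", "ca3", "dg", "tail"), "_", h)
        missing <- setdiff(need, names(volumes))
        if (length(missing) > 0)
            stop("missing subfield column(s): ", paste(missing, collapse = ", "))
        volumes[[paste0("cat_", h)]] <- volumes[[paste0("ca1_", h)]] +
            volumes[[paste0("ca2_", h)]] + volumes[[paste0("ca3_", h)]]
        volumes[[paste0("hip_", h)]] <- volumes[[paste0("sub_", h)]] +
            volumes[[paste0("cat_", h)]] + volumes[[paste0("dg_", h)]] +
            volumes[[paste0("tail_", h)]]
    }
    volumes
}

#' Hemispheric asymmetry index
#'
#' `AI = 100 * (left - right) / (left + right)`, computed on uncorrected
#' volumes. Negative values indicate rightward asymmetry. Bounded in
#' (-100, 100) for positive volumes.
#'
#' @param left,right volumes (mm3); `left + right` must be positive.
#' @return Numeric AI (unitless).
#' @examples
#' asymmetryIndex(563, 483)  # 7.648...
#' @export
asymmetryIndex <- function(left, right) {
    if (any(left + right <= 0)) stop("left + right must be positive")
    100 * (left - right) / (left + right)
}

#' ICV-correct every volume column of a table
#'
#' Applies [icvCorrect()] per subject (per-row, before any averaging) to the
#' named volume columns, returning a table of percent-of-ICV values.
#'
#' @param volumes data.frame containing an `icv` column.
#' @param cols columns to correct (default: all subfield and composite
#'   columns present).
#' @return The table with the named columns replaced by percent-of-ICV
#'   values and `icv` retained.
#' @export
icvCorrectTable <- function(volumes, cols = NULL) {
    if (is.null(cols)) {
        base <- c("erc", "sub", "ca1", "ca2", "ca3", "dg", "tail", "cat", "hip")
        cols <- intersect(as.vector(outer(base, c("_l", "_r"), paste0)),
                          names(volumes))
    }
    for (cl in cols)
        volumes[[cl]] <- icvCorrect(volumes[[cl]], volumes$icv)
    volumes
}
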