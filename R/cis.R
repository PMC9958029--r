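#' Mean malignant aberration track
#'
#' Per-gene mean of the smoothed log ratios over malignant cells (epithelial
#' cells of CA/LN tissue). Used as the reference aberration pattern when
#' scoring premalignant epithelial cells for carcinoma-in-situ similarity.
#'
#' @param tracks genes x cells matrix of smoothed log ratios restricted to
#'   malignant cells (at least 50).
#' @return numeric per-gene mean track.
#' @export
mean_malignant_track <- function(tracks) {
  if (ncol(tracks) < 50) {
    stop("need >= 50 malignant cells to form the mean malignant track; got ",
         ncol(tracks), call. = FALSE)
  }
  rowMeans(tracks)
}

#' Classify leukoplakia epithelial cells as carcinoma in situ
#'
#' An LP epithelial cell is called CIS when its smoothed track correlates
#' with the mean malignant track at Pearson r of at least `r_min` AND its
#' aberrant-gene burden is at least `burden_min`. Cells with a zero-variance
#' track have correlation defined as 0. Both thresholds are needed: the
#' correlation captures the shared gain/loss pattern and the burden guards
#' against near-neutral tracks correlating by chance.
#'
#' @param tracks genes x cells matrix of smoothed log ratios for LP
#'   epithelial cells.
#' @param burden named per-cell aberrant-gene burden for the same cells.
#' @param malignant_track per-gene mean malignant track
#'   ([mean_malignant_track()]).
#' @param r_min minimum Pearson correlation (default 0.3).
#' @param burden_min minimum burden in genes (default 50).
#' @return data.frame with cell_id, burden, correlation_to_malignant, label
#'   (`CIS` or `normal_epithelial`).
#' @export
classify_cis <- function(tracks, burden, malignant_track, r_min = 0.3,
                         burden_min = 50) {
  stopifnot(nrow(tracks) == length(malignant_track))
  cells <- colnames(tracks)
  burden <- burden[cells]
  r <- apply(tracks, 2, function(x) {
    if (sd(x) == 0 || sd(malignant_track) == 0) return(0)
    cor(x, malignant_track)
  })
  label <- ifelse(r >= r_min & burden >= burden_min, "CIS",
                  "normal_epithelial")
  data.frame(cell_id = cells, burden = as.integer(burden),
             correlation_to_malignant = r, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag aberrant immune cells as undetermined
#'
#' Immune cells carrying a copy-number burden of strictly more than
#' `burden_undetermined` genes are reassigned as undetermined and excluded
#' from downstream immune analyses (their "immune" expression profile is
#' suspect).
#'
#' @param burden named per-cell burden of immune cells.
#' @param burden_undetermined strict threshold in genes (default 200).
#' @return character vector of flagged cell ids.
#' @export
flag_undetermined_immune <- function(burden, burden_undetermined = 200) {
  names(burden)[burden > burden_undetermined]
}
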