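#' Select the representative frames of a lesion
#'
#' Picks the five representative cross-section positions used for per-lesion
#' analysis: proximal and distal references (PR, DR; plaque-free frames
#' adjacent to the lesion, when present), the minimal lumen area frame (MLA),
#' and the proximal and distal shoulders (PS, DS) as the midpoints between
#' PR (or the proximal lesion edge) and MLA, and between MLA and DR (or the
#' distal lesion edge). Frame ids are ordered proximal to distal; midpoints
#' are taken in frame index with the floor rule (ties resolved toward the
#' more proximal frame, deterministically).
#'
#' @param lumen_areas numeric vector of per-frame lumen areas (mm^2) for the
#'   frames in `lesion_bounds`, ordered proximal to distal.
#' @param lesion_bounds integer range `c(first, last)` of frame ids spanned by
#'   `lumen_areas`.
#' @param pr,dr frame ids of the proximal/distal reference frames, or `NULL`
#'   when no plaque-free reference exists on that side.
#' @return object of class `"lesion_markers"`: list with elements `pr`, `ps`,
#'   `mla`, `ds`, `dr` (`pr`/`dr` may be `NA`).
#' @export
select_representative_frames <- function(lumen_areas, lesion_bounds,
                                         pr = NULL, dr = NULL) {
  if (!length(lumen_areas)) stop("empty lesion frame range")
  if (length(lumen_areas) < 3L) stop("need at least 3 frames in the lesion")
  if (any(!is.finite(lumen_areas)) || any(lumen_areas <= 0))
    stop("lumen areas must be positive")
  first <- as.integer(lesion_bounds[1])
  last <- as.integer(lesion_bounds[2])
  if (last - first + 1L != length(lumen_areas))
    stop("lesion_bounds does not match the number of lumen areas")
  frames <- seq.int(first, last)
  i_min <- which(lumen_areas == min(lumen_areas))
  if (length(i_min) > 1L)
    message("tie in minimal lumen area; selecting the most proximal frame ",
            frames[i_min[1]])
  mla <- frames[i_min[1]]
  p_anchor <- if (is.null(pr)) first else as.integer(pr)
  d_anchor <- if (is.null(dr)) last else as.integer(dr)
  if (p_anchor > mla || d_anchor < mla)
    stop("PR/DR markers must bracket the MLA frame")
  ps <- (p_anchor + mla) %/% 2L
  ds <- (mla + d_anchor) %/% 2L
  structure(list(pr = if (is.null(pr)) NA_integer_ else as.integer(pr),
                 ps = as.integer(ps), mla = as.integer(mla),
                 ds = as.integer(ds),
                 dr = if (is.null(dr)) NA_integer_ else as.integer(dr)),
            class = "lesion_markers")
}

#' @export
print.lesion_markers <- function(x, ...) {
  cat(sprintf("<lesion_markers> PR=%s PS=%d MLA=%d DS=%d DR=%s\n",
              ifelse(is.na(x$pr), "-", x$pr), x$ps, x$mla, x$ds,
              ifelse(is.na(x$dr), "-", x$dr)))
  invisible(x)
}
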