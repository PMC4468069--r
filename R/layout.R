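#' @include AllClasses.R
NULL

#' The standard 60-electrode MEA layout
#'
#' The 8x8 grid with the four corners (11, 18, 81, 88) absent, as on common
#' TiN glass arrays. Label \code{"CR"} means grid column C, row R; electrode
#' CR is placed at x = (C-1) * pitch, y = (R-1) * pitch, with row 1 at the
#' bottom so that y increases upward and a wave starting at electrode 12 or
#' 21 begins near the origin.
#'
#' @param pitch inter-electrode distance in um (default 200).
#' @return an [ElectrodeLayout-class] with 60 electrodes in ascending label
#'   order.
#' @examples
#' lay <- standardLayout()
#' length(electrodeLabels(lay))       # 60
#' electrodePositions(lay)["12", ]    # x = 0, y = 200
#' @export
standardLayout <- function(pitch = 200) {
  cr <- expand.grid(R = 1:8, C = 1:8)
  labels <- sprintf("%d%d", cr$C, cr$R)
  keep <- !labels %in% c("11", "18", "81", "88")
  cr <- cr[keep, ]
  labels <- labels[keep]
  ord <- order(as.integer(labels))
  cr <- cr[ord, ]
  labels <- labels[ord]
  pos <- cbind(x = (cr$C - 1) * pitch, y = (cr$R - 1) * pitch)
  rownames(pos) <- labels
  new("ElectrodeLayout", labels = labels, positions = pos, pitch = pitch)
}

#' Construct an arbitrary electrode layout
#'
#' For non-standard geometries (or transformed coordinates in equivariance
#' checks). Positions are in um.
#'
#' @param labels character vector of electrode labels.
#' @param positions n x 2 numeric matrix of (x, y) coordinates in um.
#' @param pitch nominal inter-electrode spacing in um.
#' @return an [ElectrodeLayout-class].
#' @export
electrodeLayout <- function(labels, positions, pitch) {
  positions <- as.matrix(positions)
  colnames(positions) <- c("x", "y")
  rownames(positions) <- labels
  new("ElectrodeLayout", labels = as.character(labels),
      positions = positions, pitch = pitch)
}
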