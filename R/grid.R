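#' Cell-centre coordinates
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param row,col integer vectors of 1-based cell indices (row 1 = north
#'   edge).
#' @return Two-column matrix of projected (x, y) cell centres.
#' @export
cellCenter <- function(grid, row, col) {
  cs <- grid@cellSize
  cbind(x = grid@originX + (col - 0.5) * cs,
        y = grid@originY + (grid@nRows - row + 0.5) * cs)
}

#' Locate points on a grid
#'
#' Maps projected coordinates to the containing cell. Points outside the
#' grid get NA indices.
#'
#' @param grid a \linkS4class{GridSpec}.
#' @param x,y numeric coordinate vectors.
#' @return data.frame with integer columns \code{row}, \code{col} (NA when
#'   outside the grid extent).
#' @export
xyToCell <- function(grid, x, y) {
  cs <- grid@cellSize
  col <- floor((x - grid@originX) / cs) + 1L
  row <- grid@nRows - floor((y - grid@originY) / cs)
  bad <- col < 1L | col > grid@nCols | row < 1L | row > grid@nRows |
    !is.finite(x) | !is.finite(y)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Do two layers share one grid geometry?
#' @param a,b GridSpec objects or grid layers.
#' @return TRUE/FALSE.
#' @export
sameGrid <- function(a, b) {
  ga <- if (is(a, "GridSpec")) a else gridSpec(a)
  gb <- if (is(b, "GridSpec")) b else gridSpec(b)
  isTRUE(ga@nRows == gb@nRows && ga@nCols == gb@nCols &&
           all.equal(ga@cellSize, gb@cellSize) == TRUE &&
           all.equal(ga@originX, gb@originX) == TRUE &&
           all.equal(ga@originY, gb@originY) == TRUE)
}

stopIfGridMismatch <- function(a, b, what = "layers") {
  if (!sameGrid(a, b))
    stop("grid mismatch: ", what, " must share an identical GridSpec ",
         "(shape, cell size, origin)")
  invisible(TRUE)
}

# Neighbour offsets for the accumulation stencil. 8 = queen moves;
# 16 adds the knight moves, reducing metric distortion.
neighborOffsets <- function(connectivity = 8L) {
  queen <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  if (connectivity == 8L) return(queen)
  knight <- cbind(dr = c(-2, -2, -1, -1, 1, 1, 2, 2),
                  dc = c(-1, 1, -2, 2, -2, 2, -1, 1))
  rbind(queen, knight)
}
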