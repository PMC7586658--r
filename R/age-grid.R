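#' Abridged age grid
#'
#' Constructs the 5-year age grid used throughout the package: contiguous
#' closed bins of equal width followed by a single open-ended terminal bin
#' (e.g. 30-34, 35-39, ..., 90-94, 95+). All rate tables, population states
#' and life tables are indexed by such a grid.
#'
#' @param start youngest age included (default 30, the adult onset filter).
#' @param open_start start of the open-ended terminal bin (default 95).
#' @param width width of the closed bins in years (default 5).
#' @return An object of class `age_grid`: a data frame with columns
#'   `age_start` and `age_width` (`Inf` for the open bin), plus row labels
#'   such as `"60-64"` and `"95+"`.
#' @examples
#' age_grid(60, 95)
#' @export
age_grid <- function(start = 30, open_start = 95, width = 5) {
  if (!is.numeric(start) || !is.numeric(open_start) || open_start <= start)
    stop("open_start must exceed start")
  if ((open_start - start) %% width != 0)
    stop("closed range must be a multiple of the bin width")
  age_start <- c(seq(start, open_start - width, by = width), open_start)
  g <- data.frame(
    age_start = age_start,
    age_width = c(rep(width, length(age_start) - 1L), Inf)
  )
  rownames(g) <- age_group_labels(g)
  class(g) <- c("age_grid", "data.frame")
  g
}

age_group_labels <- function(grid) {
  ifelse(is.finite(grid$age_width),
         paste0(grid$age_start, "-", grid$age_start + grid$age_width - 1),
         paste0(grid$age_start, "+"))
}

#' Assign ages to age-grid bins
#'
#' @param age numeric vector of exact ages in years.
#' @param grid an [age_grid()].
#' @return Integer vector of bin indices into `grid` (`NA` for ages below
#'   the grid).
#' @export
age_group_index <- function(age, grid) {
  idx <- findInterval(age, grid$age_start)
  idx[idx == 0L] <- NA_integer_
  idx
}

#' @export
print.age_grid <- function(x, ...) {
  cat("Abridged age grid:", nrow(x), "groups,",
      rownames(x)[1], "...", rownames(x)[nrow(x)], "\n")
  invisible(x)
}

# Overlap (in years) of [a0, a1) with each grid bin, for person-years splits.
# Returns a length(grid) vector for scalar a0/a1.
interval_overlap <- function(a0, a1, grid) {
  lo <- pmax(a0, grid$age_start)
  hi <- pmin(a1, grid$age_start + grid$age_width)
  pmax(0, hi - lo)
}

stopifnot_grid <- function(grid) {
  if (!inherits(grid, "age_grid")) stop("`grid` must be an age_grid object")
  invisible(grid)
}
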