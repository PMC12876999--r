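QUADRANTS <- c("TL", "TR", "BL", "BR")

#' Assign fixations to screen quadrants
#'
#' Splits the screen into four equally sized quadrant AOIs. Cells are
#' half-open: a point exactly on the vertical midline belongs to the right
#' quadrants, exactly on the horizontal midline to the lower quadrants, so
#' every on-screen point maps to exactly one quadrant.
#'
#' @param x_px,y_px Fixation coordinates (vectorized).
#' @param geometry A [screen_geometry()].
#' @return Factor with levels `TL`, `TR`, `BL`, `BR`.
#' @export
assign_quadrant <- function(x_px, y_px, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "screen_geometry"))
  if (any(x_px < 0 | x_px >= geometry$width_px |
          y_px < 0 | y_px >= geometry$height_px))
    stop("off-screen fixation passed to assign_quadrant")
  right <- x_px >= geometry$width_px / 2
  lower <- y_px >= geometry$height_px / 2
  q <- ifelse(lower, ifelse(right, "BR", "BL"), ifelse(right, "TR", "TL"))
  factor(q, levels = QUADRANTS)
}

#' Quadrant fixation-proportion profile of a scanpath
#'
#' Proportion of fixations falling in each quadrant AOI. For an empty
#' scanpath the proportions are undefined (`NA`) and the profile is flagged.
#'
#' @param sp A [scanpath()] (fixations must be on-screen; run
#'   [filter_fixations()] first).
#' @return An `aoi_profile`: list with `proportions` (named 4-vector over
#'   `TL`, `TR`, `BL`, `BR`), `n_fixations`, and `defined` flag.
#' @export
aoi_profile <- function(sp) {
  stopifnot(inherits(sp, "scanpath"))
  n <- nrow(sp$fixations)
  if (!n) {
    props <- stats::setNames(rep(NA_real_, 4), QUADRANTS)
    return(structure(list(proportions = props, n_fixations = 0L,
                          defined = FALSE), class = "aoi_profile"))
  }
  q <- assign_quadrant(sp$fixations$x_px, sp$fixations$y_px, sp$geometry)
  props <- as.numeric(table(q)) / n
  structure(list(proportions = stats::setNames(props, QUADRANTS),
                 n_fixations = n, defined = TRUE),
            class = "aoi_profile")
}

#' @export
print.aoi_profile <- function(x, ...) {
  cat("<aoi_profile>", x$n_fixations, "fixations\n")
  if (x$defined) print(round(x$proportions, 3)) else cat("  (undefined)\n")
  invisible(x)
}

#' Looking-at-nothing association between encoding and imagery
#'
#' Pools the per-trial quadrant proportions of the encoding and imagery
#' phases into (pair x quadrant) points and fits imagery proportion on
#' encoding proportion by ordinary least squares. A positive slope
#' operationalizes the looking-at-nothing effect: regions fixated more during
#' encoding are refixated more during imagery on the blank screen. This
#' pooled descriptive slope deliberately replaces a hierarchical
#' zero-one-inflated beta model; it preserves the sign and coupling strength
#' being tested without any sampler.
#'
#' @param encoding,imagery Lists (same length) of `aoi_profile`s, paired by
#'   position; pairs where either profile is undefined are dropped.
#' @return A `lan_fit`: list with `slope`, `intercept`, the underlying
#'   [stats::lm] fit, and the long-format point table (`pair`, `quadrant`,
#'   `encoding`, `imagery`). Methods: `print`, `coef`, `summary`, `plot`.
#' @export
lan_association <- function(encoding, imagery) {
  if (length(encoding) != length(imagery))
    stop("encoding and imagery profile lists must have equal length")
  ok <- vapply(seq_along(encoding), function(i)
    encoding[[i]]$defined && imagery[[i]]$defined, TRUE)
  encoding <- encoding[ok]; imagery <- imagery[ok]
  if (length(encoding) < 2)
    stop("need at least two pairs with defined proportions")
  tab <- do.call(rbind, lapply(seq_along(encoding), function(i) {
    data.frame(pair = i, quadrant = QUADRANTS,
               encoding = as.numeric(encoding[[i]]$proportions),
               imagery = as.numeric(imagery[[i]]$proportions))
  }))
  if (stats::var(tab$encoding) == 0)
    stop("encoding proportions have zero variance; slope undefined")
  fit <- stats::lm(imagery ~ encoding, data = tab)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fit = fit, points = tab, n_pairs = length(encoding)),
            class = "lan_fit")
}

#' @export
print.lan_fit <- function(x, ...) {
  cat(sprintf("<lan_fit> %d pairs (%d points): slope %.3f, intercept %.3f\n",
              x$n_pairs, nrow(x$points), x$slope, x$intercept))
  invisible(x)
}

#' @export
coef.lan_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.lan_fit <- function(object, ...) summary(object$fit, ...)

#' @export
plot.lan_fit <- function(x, ...) {
  plot(x$points$encoding, x$points$imagery,
       xlab = "encoding proportion", ylab = "imagery proportion",
       main = "Looking-at-nothing association", ...)
  graphics::abline(x$intercept, x$slope, col = 2)
  invisible(x)
}
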