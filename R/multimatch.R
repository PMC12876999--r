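#' Saccade vectors of a scanpath
#'
#' Represents a scanpath of `n` fixations as `n - 1` geometric saccade
#' vectors. Each vector carries its start position and the duration of its
#' originating fixation (used by the duration similarity dimension).
#'
#' @param sp A [scanpath()] with at least 2 fixations.
#' @return data.frame with columns `dx`, `dy`, `start_x`, `start_y`,
#'   `duration_ms`.
#' @export
saccade_vectors <- function(sp) {
  stopifnot(inherits(sp, "scanpath"))
  fx <- sp$fixations
  n <- nrow(fx)
  if (n < 2) stop("a scanpath needs at least 2 fixations to form saccades")
  data.frame(dx = diff(fx$x_px), dy = diff(fx$y_px),
             start_x = fx$x_px[-n], start_y = fx$y_px[-n],
             duration_ms = fx$duration_ms[-n])
}

vec_amp <- function(v) sqrt(v$dx^2 + v$dy^2)

# absolute angle difference, wrapped into [0, pi]; zero-amplitude vectors
# have no direction and are treated as matching
angle_diff <- function(dx1, dy1, dx2, dy2) {
  a1 <- sqrt(dx1^2 + dy1^2); a2 <- sqrt(dx2^2 + dy2^2)
  d <- abs(atan2(dy1, dx1) - atan2(dy2, dx2))
  d <- ifelse(d > pi, 2 * pi - d, d)
  ifelse(a1 == 0 | a2 == 0, 0, d)
}

#' Simplify a scanpath's saccade-vector sequence
#'
#' Iteratively merges consecutive saccade pairs that are either (a) both
#' shorter than `amp_threshold_frac` of the screen diagonal, or (b) separated
#' by less than `dir_threshold_deg` in direction — in both cases only when
#' the intervening fixation is shorter than `dur_threshold_ms`. Merging sums
#' the two vectors and pools (sums) their originating-fixation durations.
#' Passes repeat until a fixed point is reached; the vector count never
#' increases. These defaults (10% of the diagonal, 45 degrees, 300 ms) are
#' the common choices of the vector-alignment scanpath-comparison literature.
#'
#' @param sp A [scanpath()] with at least 2 fixations, or a saccade-vector
#'   data.frame as returned by [saccade_vectors()].
#' @param amp_threshold_frac Small-amplitude threshold as a fraction of the
#'   screen diagonal.
#' @param dir_threshold_deg Direction-merge threshold in degrees.
#' @param dur_threshold_ms Maximum intervening-fixation duration for a merge.
#' @param geometry Screen geometry (taken from `sp` when it is a scanpath).
#' @return data.frame of simplified saccade vectors.
#' @export
simplify_scanpath <- function(sp, amp_threshold_frac = 0.10,
                              dir_threshold_deg = 45, dur_threshold_ms = 300,
                              geometry = NULL) {
  if (inherits(sp, "scanpath")) {
    geometry <- sp$geometry
    v <- saccade_vectors(sp)
  } else {
    v <- sp
    if (is.null(geometry)) geometry <- screen_geometry()
  }
  amp_thr <- amp_threshold_frac * screen_diag_px(geometry)
  dir_thr <- dir_threshold_deg * pi / 180
  repeat {
    if (nrow(v) < 2) break
    merged <- FALSE
    i <- 1L
    out <- v[0, ]
    while (i <= nrow(v)) {
      if (i < nrow(v)) {
        a <- v[i, ]; b <- v[i + 1L, ]
        # b's originating fixation is the fixation between the two saccades
        brief <- b$duration_ms < dur_threshold_ms
        small <- vec_amp(a) < amp_thr && vec_amp(b) < amp_thr
        alike <- angle_diff(a$dx, a$dy, b$dx, b$dy) < dir_thr
        if (brief && (small || alike)) {
          out <- rbind(out, data.frame(
            dx = a$dx + b$dx, dy = a$dy + b$dy,
            start_x = a$start_x, start_y = a$start_y,
            duration_ms = a$duration_ms + b$duration_ms))
          i <- i + 2L
          merged <- TRUE
          next
        }
      }
      out <- rbind(out, v[i, ])
      i <- i + 1L
    }
    v <- out
    rownames(v) <- NULL
    if (!merged) break
  }
  v
}

#' Align two saccade-vector sequences
#'
#' Builds the |u| x |v| cost matrix of vector-difference magnitudes and finds
#' the lowest-cost monotone path from (1, 1) to (|u|, |v|) using steps right,
#' down, and diagonal (dynamic programming over the lattice); ties are broken
#' toward the diagonal step. The path defines which vectors of the two
#' sequences are compared by [similarity_profile()].
#'
#' @param u,v Saccade-vector data.frames (non-empty).
#' @return A two-column integer matrix of aligned (i, j) index pairs, from
#'   (1, 1) to (|u|, |v|); the total path cost is attached as attribute
#'   `cost`.
#' @export
align_vectors <- function(u, v) {
  m <- nrow(u); n <- nrow(v)
  if (!m || !n) stop("cannot align an empty vector sequence")
  cost <- outer(seq_len(m), seq_len(n), function(i, j)
    sqrt((u$dx[i] - v$dx[j])^2 + (u$dy[i] - v$dy[j])^2))
  D <- matrix(Inf, m, n)
  move <- matrix(0L, m, n)  # 1 = diagonal, 2 = from above, 3 = from left
  D[1, 1] <- cost[1, 1]
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (i == 1 && j == 1) next
    diag_ <- if (i > 1 && j > 1) D[i - 1, j - 1] else Inf
    up <- if (i > 1) D[i - 1, j] else Inf
    left <- if (j > 1) D[i, j - 1] else Inf
    if (diag_ <= up && diag_ <= left) {
      D[i, j] <- diag_ + cost[i, j]; move[i, j] <- 1L
    } else if (up <= left) {
      D[i, j] <- up + cost[i, j]; move[i, j] <- 2L
    } else {
      D[i, j] <- left + cost[i, j]; move[i, j] <- 3L
    }
  }
  path <- matrix(c(m, n), 1, 2)
  i <- m; j <- n
  while (i > 1 || j > 1) {
    mv <- move[i, j]
    if (mv == 1L) { i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) i <- i - 1L
    else j <- j - 1L
    path <- rbind(c(i, j), path)
  }
  colnames(path) <- c("i", "j")
  attr(path, "cost") <- D[m, n]
  path
}

#' Five-dimension scanpath similarity profile
#'
#' Compares two scanpaths after vector simplification and alignment, in the
#' style of the MultiMatch framework. Per aligned vector pair the normalized
#' dissimilarities are: shape `|u - v| / (2 diag)`, length
#' `||u| - |v|| / diag`, direction `angular difference / pi`, position
#' `distance between saccade endpoints / diag`, duration
#' `|d_u - d_v| / max(d_u, d_v)`; each dimension's similarity is one minus
#' the mean dissimilarity over aligned pairs, so identical scanpaths score 1
#' everywhere and all scores lie in [0, 1]. Shape, length, direction and
#' duration are translation invariant; position is not.
#'
#' @param a,b [scanpath()]s with at least 2 fixations each.
#' @param geometry Screen geometry (defaults to `a`'s).
#' @param simplify Apply [simplify_scanpath()] first (default `TRUE`).
#' @param amp_threshold_frac,dir_threshold_deg,dur_threshold_ms Simplification
#'   parameters, see [simplify_scanpath()].
#' @param aggregate Function pooling per-pair dissimilarities (default
#'   [mean]; [stats::median] is a common alternative).
#' @return A `similarity_profile`: named numeric vector-like object with
#'   elements `shape`, `length`, `direction`, `position`, `duration`.
#' @export
similarity_profile <- function(a, b, geometry = NULL, simplify = TRUE,
                               amp_threshold_frac = 0.10,
                               dir_threshold_deg = 45,
                               dur_threshold_ms = 300,
                               aggregate = mean) {
  stopifnot(inherits(a, "scanpath"), inherits(b, "scanpath"))
  if (is.null(geometry)) geometry <- a$geometry
  u <- saccade_vectors(a); v <- saccade_vectors(b)
  if (simplify) {
    u <- simplify_scanpath(u, amp_threshold_frac, dir_threshold_deg,
                           dur_threshold_ms, geometry = geometry)
    v <- simplify_scanpath(v, amp_threshold_frac, dir_threshold_deg,
                           dur_threshold_ms, geometry = geometry)
  }
  path <- align_vectors(u, v)
  dg <- screen_diag_px(geometry)
  ui <- u[path[, 1], ]; vj <- v[path[, 2], ]
  shape_d <- sqrt((ui$dx - vj$dx)^2 + (ui$dy - vj$dy)^2) / (2 * dg)
  len_d <- abs(vec_amp(ui) - vec_amp(vj)) / dg
  dir_d <- angle_diff(ui$dx, ui$dy, vj$dx, vj$dy) / pi
  pos_d <- sqrt((ui$start_x + ui$dx - vj$start_x - vj$dx)^2 +
                (ui$start_y + ui$dy - vj$start_y - vj$dy)^2) / dg
  mx <- pmax(ui$duration_ms, vj$duration_ms)
  dur_d <- ifelse(mx > 0, abs(ui$duration_ms - vj$duration_ms) / mx, 0)
  sim <- function(d) max(0, min(1, 1 - aggregate(d)))
  structure(list(shape = sim(shape_d), length = sim(len_d),
                 direction = sim(dir_d), position = sim(pos_d),
                 duration = sim(dur_d),
                 n_aligned = nrow(path)),
            class = "similarity_profile")
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat("<similarity_profile>", x$n_aligned, "aligned vector pairs\n")
  print(round(unlist(x[c("shape", "length", "direction", "position",
                         "duration")]), 4))
  invisible(x)
}

#' Similarity profile as a named numeric vector
#' @param x A `similarity_profile`.
#' @param ... Unused.
#' @return Named numeric vector of the five similarities.
#' @export
as.double.similarity_profile <- function(x, ...) {
  unlist(x[c("shape", "length", "direction", "position", "duration")])
}
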