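rqa_px <- function(sp, radius_px = 135, l_min = 2) {
  rqa(sp, rqa_config(l_min = l_min, radius_px = radius_px))
}

test_that("recurrence matrix uses an inclusive Euclidean threshold", {
  sp <- quick_scanpath(c(500, 500), c(500, 500))
  rp <- recurrence_matrix(sp, rqa_config())
  expect_true(all(rp$matrix))

  # pair at exactly the radius is recurrent
  sp2 <- quick_scanpath(c(500, 635), c(500, 500))
  rp2 <- recurrence_matrix(sp2, rqa_config(radius_px = 135))
  expect_true(rp2$matrix[1, 2])
  sp3 <- quick_scanpath(c(500, 635.01), c(500, 500))
  expect_false(recurrence_matrix(sp3, rqa_config(radius_px = 135))$matrix[1, 2])

  # all pairwise distances above the radius -> identity matrix
  far <- quick_scanpath(c(100, 600, 1100, 1600), c(100, 900, 100, 900))
  rpf <- recurrence_matrix(far, rqa_config(radius_px = 135))
  expect_equal(rpf$matrix, diag(4) == 1, ignore_attr = TRUE)

  expect_error(recurrence_matrix(quick_scanpath(1, 1), rqa_config()), "at least 2")
  # symmetry and true diagonal on a random path
  set.seed(6)
  rp4 <- recurrence_matrix(random_clustered_scanpath(12), rqa_config())
  expect_true(isSymmetric(rp4$matrix))
  expect_true(all(diag(rp4$matrix)))
})

test_that("fully recurrent and fully dispersed paths hit the extremes", {
  ident <- quick_scanpath(rep(500, 5), rep(500, 5))
  r <- rqa_px(ident)
  expect_equal(r$recurrence_rate, 100)
  expect_equal(r$determinism, 100)
  expect_equal(r$laminarity, 100)
  expect_equal(r$fixation_spread, 0)

  disp <- quick_scanpath(c(100, 600, 1100, 1600, 100), c(100, 900, 100, 900, 500))
  r0 <- rqa_px(disp)
  expect_equal(r0$recurrence_rate, 0)
  expect_equal(r0$determinism, 0)   # 0/0 convention
  expect_equal(r0$laminarity, 0)
  expect_true(r0$degenerate)
})

test_that("an ordered cluster tour is deterministic but not laminar", {
  # clusters A, B, C visited twice in the same order; within-cluster <= eps,
  # across > eps: all recurrences form one length-3 diagonal
  abc <- quick_scanpath(c(200, 960, 1700, 200, 960, 1700),
                        c(200, 800, 200, 200, 800, 200))
  r <- rqa_px(abc)
  expect_equal(r$rec_count, 3)
  expect_equal(r$recurrence_rate, 100 * 2 * 3 / (6 * 5))
  expect_equal(r$determinism, 100)
  expect_equal(r$laminarity, 0)
})

test_that("isolated mid-matrix recurrences count toward neither measure", {
  # fixations 2 and 5 recur, nothing else; the single point (2,5) is neither
  # on a qualifying diagonal nor on a row/column run
  iso <- quick_scanpath(c(100, 600, 1100, 1600, 600, 100, 1600),
                        c(100, 500, 100, 900, 500, 900, 100))
  r <- rqa_px(iso)
  expect_equal(r$rec_count, 1)
  expect_equal(r$determinism, 0)
  expect_equal(r$laminarity, 0)
})

test_that("a later dwell on an earlier location is laminar", {
  # one fixation at A, then far away, then a 3-fixation dwell back at A:
  # vertical/horizontal runs of length >= 2, but no ordered diagonal of 2
  dwell <- quick_scanpath(c(300, 1500, 300, 300, 300),
                          c(300, 800, 300, 300, 300))
  r <- rqa_px(dwell)
  expect_gt(r$laminarity, 0)
  expect_equal(r$rec_count, 6)
})

test_that("recurrence measures match the brute-force oracle on random paths", {
  set.seed(123)
  for (rep in 1:60) {
    n <- sample(5:25, 1)
    sp <- random_clustered_scanpath(n)
    r <- rqa_px(sp)
    o <- oracle_rqa(sp$fixations$x_px, sp$fixations$y_px, 135, 2)
    expect_identical(r$rec_count, o$R)
    expect_equal(r$recurrence_rate, o$rec)
    expect_equal(r$determinism, o$det)
    expect_equal(r$laminarity, o$lam)
  }
})

test_that("determinism and laminarity are rigid-motion invariant", {
  set.seed(77)
  sp <- random_clustered_scanpath(15)
  r <- rqa_px(sp)
  # translation
  tr <- sp
  tr$fixations$x_px <- tr$fixations$x_px + 40
  tr$fixations$y_px <- tr$fixations$y_px - 25
  rt <- rqa_px(tr)
  expect_equal(rt$determinism, r$determinism)
  expect_equal(rt$laminarity, r$laminarity)
  expect_equal(rt$recurrence_rate, r$recurrence_rate)
  # rotation about the centroid (distances preserved)
  th <- 0.4
  cx <- mean(sp$fixations$x_px); cy <- mean(sp$fixations$y_px)
  rot <- sp
  rot$fixations$x_px <- cx + cos(th) * (sp$fixations$x_px - cx) -
    sin(th) * (sp$fixations$y_px - cy)
  rot$fixations$y_px <- cy + sin(th) * (sp$fixations$x_px - cx) +
    cos(th) * (sp$fixations$y_px - cy)
  rr <- rqa_px(rot)
  expect_equal(rr$determinism, r$determinism)
  expect_equal(rr$laminarity, r$laminarity)
})

test_that("recurrence rate is monotone in the radius and saturates on shrink", {
  set.seed(55)
  sp <- random_clustered_scanpath(15)
  rates <- vapply(c(30, 80, 135, 300, 800, 2500),
                  function(e) rqa_px(sp, radius_px = e)$recurrence_rate,
                  numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[length(rates)], 100)
  # shrinking all distances below the radius drives everything to 100
  tiny <- sp
  tiny$fixations$x_px <- 500 + (sp$fixations$x_px - mean(sp$fixations$x_px)) * 0.01
  tiny$fixations$y_px <- 500 + (sp$fixations$y_px - mean(sp$fixations$y_px)) * 0.01
  rt <- rqa_px(tiny)
  expect_equal(rt$recurrence_rate, 100)
  expect_equal(rt$determinism, 100)
  expect_equal(rt$laminarity, 100)
})

test_that("fixation spread is the rms distance from the centroid", {
  expect_equal(fixation_spread(quick_scanpath(rep(7, 4), rep(7, 4))), 0)
  expect_equal(fixation_spread(quick_scanpath(c(0, 200), c(0, 0))), 100)
  set.seed(2)
  sp <- random_clustered_scanpath(20)
  x <- sp$fixations$x_px; y <- sp$fixations$y_px
  direct <- sqrt(sum((x - mean(x))^2 + (y - mean(y))^2) / 20)
  expect_equal(fixation_spread(sp), direct)
  expect_error(fixation_spread(quick_scanpath(1, 1)), "at least 2")
})

test_that("the default radius comes from the geometry (2.5 deg = 135 px)", {
  set.seed(10)
  sp <- random_clustered_scanpath(12)
  expect_equal(rqa(sp)$radius_px, 135)
  expect_equal(rqa(sp)$recurrence_rate, rqa_px(sp, 135)$recurrence_rate)
})
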