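#' Condition contrast with participant-level cluster bootstrap
#'
#' Descriptive contrast between two conditions of a proportion-valued gaze
#' measure, with a percentile confidence interval from a cluster bootstrap
#' that resamples participants (never trials within participants, which would
#' understate the between-participant variability). For participants observed
#' in both conditions the design is treated as paired: the estimate is the
#' mean over participants of the within-participant difference of condition
#' means; otherwise the difference of independent participant-mean averages
#' is used. This replaces a hierarchical Bayesian zero-one-inflated beta
#' model with a sampler-free procedure that preserves the sign-and-interval
#' decision rule.
#'
#' @param table data.frame with columns `participant`, `condition`, and the
#'   measure named by `measure` (one row per trial).
#' @param measure Column name of the measure to contrast.
#' @param condition_a,condition_b Condition labels; the contrast is a minus b.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed; the interval is bit-reproducible given
#'   (`seed`, `n_boot`).
#' @param conf Confidence level of the percentile interval (default 0.95).
#' @return A `contrast_result`: `measure`, `contrast` label, `point_estimate`,
#'   `ci_low`, `ci_high`, `n_boot`, `seed`, `paired`, `n_participants`.
#' @export
condition_contrast <- function(table, measure, condition_a, condition_b,
                               n_boot = 2000L, seed = 1L, conf = 0.95) {
  stopifnot(is.data.frame(table),
            all(c("participant", "condition", measure) %in% names(table)))
  for (cc in c(condition_a, condition_b))
    if (!cc %in% table$condition) stop("condition not present in table: ", cc)
  sub <- table[table$condition %in% c(condition_a, condition_b), ]
  # participant x condition means
  pm <- stats::aggregate(sub[[measure]],
                         by = list(participant = sub$participant,
                                   condition = sub$condition), FUN = mean)
  names(pm)[3] <- "value"
  a <- pm[pm$condition == condition_a, c("participant", "value")]
  b <- pm[pm$condition == condition_b, c("participant", "value")]
  shared <- intersect(a$participant, b$participant)
  paired <- length(shared) >= 2
  if (paired) {
    d <- a$value[match(shared, a$participant)] -
      b$value[match(shared, b$participant)]
    if (length(d) < 2) stop("need at least 2 participants per condition")
    est <- mean(d)
    set.seed(as.integer(seed))
    idx <- matrix(sample.int(length(d), length(d) * n_boot, replace = TRUE),
                  nrow = length(d))
    boots <- colMeans(matrix(d[idx], nrow = length(d)))
  } else {
    if (nrow(a) < 2 || nrow(b) < 2)
      stop("need at least 2 participants per condition")
    est <- mean(a$value) - mean(b$value)
    set.seed(as.integer(seed))
    boots <- vapply(seq_len(n_boot), function(k) {
      mean(a$value[sample.int(nrow(a), replace = TRUE)]) -
        mean(b$value[sample.int(nrow(b), replace = TRUE)])
    }, numeric(1))
  }
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  structure(list(measure = measure,
                 contrast = paste(condition_a, "-", condition_b),
                 point_estimate = est, ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 conf = conf, paired = paired,
                 n_participants = if (paired) length(shared)
                                  else c(nrow(a), nrow(b))),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> %s, %s: %.4f [%.4f, %.4f] (%s, %d boots)\n",
              x$measure, x$contrast, x$point_estimate, x$ci_low, x$ci_high,
              if (x$paired) "paired" else "independent", x$n_boot))
  invisible(x)
}

#' Behavioural summary of probe accuracy and vividness
#'
#' Plain means by condition and by stimulus category — no modelling.
#'
#' @param trials data.frame with columns `condition`, `category`, `accuracy`
#'   (0/1) and `vividness` (1-7 rating).
#' @return List of data.frames: `overall`, `by_condition`, `by_category`, with
#'   accuracy as a percentage and mean vividness.
#' @export
behavioural_summary <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("condition", "category", "accuracy", "vividness") %in%
                  names(trials)))
  agg <- function(by) {
    out <- stats::aggregate(cbind(accuracy, vividness) ~ get(by), data = trials,
                            FUN = mean)
    names(out)[1] <- by
    out$accuracy_pct <- 100 * out$accuracy
    out$accuracy <- NULL
    out[c(by, "accuracy_pct", "vividness")]
  }
  list(overall = data.frame(accuracy_pct = 100 * mean(trials$accuracy),
                            vividness = mean(trials$vividness)),
       by_condition = agg("condition"),
       by_category = agg("category"))
}
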