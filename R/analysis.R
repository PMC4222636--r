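#' Reconstruction distance analysis
#'
#' For every block with a reconstruction response, computes the Euclidean
#' distance from the reconstruction to the block's first stimulus
#' (`d_first`) and to its last stimulus (`d_last`), then tests the
#' 2 x 2 (first/last x gradual/jump) repeated-measures interaction on the
#' participant-level cell means. Retroactive interference predicts a
#' cross-over: reconstructions closer to the last stimulus (and farther
#' from the first) in the gradual condition than in the jump condition.
#'
#' @param responses A list of `"dpkf_responses"` (one per participant), or
#'   a single response set.
#' @param sessions The matching list of `"dpkf_session"` objects.
#' @return A list of class `"dpkf_distance_analysis"`:
#'   `table` (per participant x block distances), `cell_means`
#'   (participant x condition x reference means), `condition_means`
#'   (group means), `sem_within` (within-subject SEM per cell, after
#'   removing participant means), and `anova` (interaction `F`, `p`,
#'   degrees of freedom).
#' @export
distance_analysis <- function(responses, sessions) {
  if (inherits(responses, "dpkf_responses")) responses <- list(responses)
  if (inherits(sessions, "dpkf_session")) sessions <- list(sessions)
  stopifnot(length(responses) == length(sessions))
  if (length(responses) < 2L)
    stop("distance_analysis needs >= 2 participants", call. = FALSE)
  rows <- list()
  for (i in seq_along(responses)) {
    for (b in seq_along(sessions[[i]]$blocks)) {
      blk <- sessions[[i]]$blocks[[b]]
      rec <- responses[[i]]$reconstructions[[b]]
      if (is.null(rec) || anyNA(rec)) next
      stim <- blk$stimuli
      rows[[length(rows) + 1L]] <- data.frame(
        participant = i, block = b, condition = blk$condition,
        d_first = sqrt(sum((rec - stim[1L, ])^2)),
        d_last = sqrt(sum((rec - stim[nrow(stim), ])^2)))
    }
  }
  tab <- do.call(rbind, rows)
  long <- rbind(
    data.frame(participant = tab$participant, condition = tab$condition,
               reference = "first", distance = tab$d_first),
    data.frame(participant = tab$participant, condition = tab$condition,
               reference = "last", distance = tab$d_last))
  cells <- aggregate(distance ~ participant + condition + reference,
                     long, mean)
  if (nrow(cells) != length(responses) * 4L)
    stop("missing condition x reference cells for some participant",
         call. = FALSE)
  cells$participant <- factor(cells$participant)
  cells$condition <- factor(cells$condition)
  cells$reference <- factor(cells$reference)
  fit <- aov(distance ~ condition * reference +
               Error(participant / (condition * reference)), data = cells)
  st <- summary(fit)
  inter <- st[["Error: participant:condition:reference"]][[1]]
  interaction <- list(
    F = inter[["F value"]][1], p = inter[["Pr(>F)"]][1],
    df = as.integer(c(inter[["Df"]][1], inter[["Df"]][2])))
  cond_means <- aggregate(distance ~ condition + reference, cells, mean)
  # within-subject SEM (participant means removed before computing spread)
  ctr <- cells
  pm <- tapply(ctr$distance, ctr$participant, mean)
  ctr$distance <- ctr$distance - pm[as.character(ctr$participant)] +
    mean(ctr$distance)
  n <- length(unique(cells$participant))
  sem <- aggregate(distance ~ condition + reference, ctr,
                   function(x) sd(x) / sqrt(n))
  names(sem)[3] <- "sem_within"
  structure(list(table = tab, cell_means = cells,
                 condition_means = cond_means, sem_within = sem,
                 anova = interaction, n_participants = n),
            class = "dpkf_distance_analysis")
}

#' @export
print.dpkf_distance_analysis <- function(x, ...) {
  cat(sprintf("Reconstruction distances, %d participants\n",
              x$n_participants))
  print(x$condition_means)
  cat(sprintf("interaction (condition x first/last): F(%d,%d) = %.3f, p = %.4g\n",
              x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p))
  invisible(x)
}

#' Inferred mode counts by condition
#'
#' Runs the filter with each participant's fitted hyperparameters over
#' every block, counts the number of inferred modes `K`, averages per
#' condition and compares conditions with a paired t-test. The theory
#' predicts more modes in the jump condition.
#'
#' @param fits A list of `"dpkf_fit"` objects (one per participant), or a
#'   list of [dpkf_hyper()] objects paired with `sessions`.
#' @param sessions Matching list of sessions (defaults to the sessions
#'   stored in the fits).
#' @param pred_rule Prediction rule for the filter re-run.
#' @return A list with `per_participant` (data frame of mean K per
#'   condition), `means` (group means per condition), and `test` (paired
#'   t-test jump vs gradual).
#' @export
mode_count_analysis <- function(fits, sessions = NULL, pred_rule = "prev") {
  if (inherits(fits, "dpkf_fit")) fits <- list(fits)
  if (is.null(sessions))
    sessions <- lapply(fits, `[[`, "session")
  stopifnot(length(fits) == length(sessions))
  per <- do.call(rbind, lapply(seq_along(fits), function(i) {
    h <- if (inherits(fits[[i]], "dpkf_fit")) fits[[i]]$hyper else fits[[i]]
    ses <- sessions[[i]]
    K <- vapply(ses$blocks, function(blk)
      run_filter(blk$stimuli, h, pred_rule)$K, integer(1))
    conds <- vapply(ses$blocks, `[[`, character(1), "condition")
    data.frame(participant = i,
               K_gradual = mean(K[conds == "gradual"]),
               K_jump = mean(K[conds == "jump"]))
  }))
  test <- if (sd(per$K_jump - per$K_gradual) > 0)
    t.test(per$K_jump, per$K_gradual, paired = TRUE)
  else list(statistic = NA_real_, p.value = NA_real_,
            estimate = mean(per$K_jump - per$K_gradual))
  list(per_participant = per,
       means = c(gradual = mean(per$K_gradual), jump = mean(per$K_jump)),
       test = test)
}

#' Correlation between model and human reconstructions
#'
#' Per participant and stimulus dimension, the Pearson correlation across
#' blocks between observed reconstructions and the model's
#' reconstructions, Fisher z-transformed, with a group-level t-test of the
#' z values against 0 for each dimension. Perfect correlations (|r| = 1,
#' infinite z) are capped at `z_cap` and flagged.
#'
#' @param model_recons List (one per participant) of `n_blocks x D`
#'   matrices of model reconstructions.
#' @param human_recons Same layout, observed reconstructions.
#' @param z_cap Cap on |z| used for degenerate perfect correlations.
#' @return A list with `per_participant` (data frame: participant, dim,
#'   r, z, capped) and `tests` (per-dimension t-test of z vs 0).
#' @export
model_human_correlation <- function(model_recons, human_recons,
                                    z_cap = atanh(1 - 1e-12)) {
  stopifnot(length(model_recons) == length(human_recons))
  nb_m <- vapply(model_recons, nrow, integer(1))
  nb_h <- vapply(human_recons, nrow, integer(1))
  if (!all(nb_m == nb_h))
    stop("model and human reconstructions must have matching blocks",
         call. = FALSE)
  if (any(nb_m < 3L))
    stop("need >= 3 blocks per participant", call. = FALSE)
  D <- ncol(model_recons[[1]])
  rows <- list()
  for (i in seq_along(model_recons)) {
    for (d in seq_len(D)) {
      m <- model_recons[[i]][, d]
      h <- human_recons[[i]][, d]
      if (sd(m) == 0 || sd(h) == 0)
        stop("undefined correlation: zero-variance reconstructions for participant ",
             i, call. = FALSE)
      r <- cor(m, h)
      capped <- abs(r) >= 1 - 1e-12
      z <- if (capped) sign(r) * z_cap else atanh(r)
      rows[[length(rows) + 1L]] <- data.frame(
        participant = i, dim = d, r = r, z = z, capped = capped)
    }
  }
  per <- do.call(rbind, rows)
  tests <- lapply(seq_len(D), function(d) {
    z <- per$z[per$dim == d]
    if (sd(z) == 0) list(statistic = NA_real_, p.value = NA_real_,
                         estimate = mean(z))
    else t.test(z, mu = 0)
  })
  names(tests) <- paste0("dim", seq_len(D))
  list(per_participant = per, tests = tests)
}
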