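#' Task geometry configuration
#'
#' Geometry of the line-segment prediction task in the standardized
#' `[0, 100] x [0, 100]` orientation/length space. Each trial's stimulus is
#' generated from the previous one by adding or subtracting a fixed step
#' per dimension (a 45-degree move); jump blocks insert one step whose
#' per-dimension magnitude is `jump_mult` times larger between trials
#' `jump_after` and `jump_after + 1`. Whole trajectories are
#' rejection-sampled until the Euclidean start-to-end distance lies within
#' `dist_band` times the diagonal of the space, so that total distance
#' travelled is matched across conditions.
#'
#' @param step Per-dimension step magnitude (stimulus units). The default 5
#'   lets 17 unit steps span the required 60-70% of the diagonal.
#' @param jump_mult Multiplier for the jump step (default 4).
#' @param n_trials Stimuli per block (default 18).
#' @param jump_after Trial after which the jump occurs in jump blocks
#'   (default 9: between trials 9 and 10).
#' @param lower,upper Bounds of the stimulus space per dimension.
#' @param dist_band Admissible start-to-end distance as a fraction of the
#'   space's diagonal.
#' @param max_tries Maximum candidate trajectories per requested block
#'   before generation fails.
#' @return A list of class `"dpkf_geometry"`.
#' @export
task_geometry <- function(step = 5, jump_mult = 4, n_trials = 18L,
                          jump_after = 9L, lower = 0, upper = 100,
                          dist_band = c(0.60, 0.70), max_tries = 1e6) {
  stopifnot(step > 0, jump_mult > 0, n_trials >= 2, jump_after >= 1,
            jump_after < n_trials, upper > lower,
            length(dist_band) == 2L, dist_band[1] < dist_band[2])
  structure(list(step = step, jump_mult = jump_mult,
                 n_trials = as.integer(n_trials),
                 jump_after = as.integer(jump_after),
                 lower = lower, upper = upper, dist_band = dist_band,
                 max_tries = max_tries),
            class = "dpkf_geometry")
}

# Vectorized batch of candidate trajectories. Steps are drawn uniformly
# among the admissible sign combinations: never the exact reverse of the
# previous step, and never leaving the stimulus space (a redraw, not a
# reflection). Returns accepted trajectories as a list of n_trials x 2
# matrices.
generate_trajectories <- function(condition, n, geom = task_geometry()) {
  sx <- c(1, 1, -1, -1); sy <- c(1, -1, 1, -1)
  nstep <- geom$n_trials - 1L
  mags <- rep(geom$step, nstep)
  if (condition == "jump") mags[geom$jump_after] <- geom$step * geom$jump_mult
  lo <- geom$lower; hi <- geom$upper
  diag_len <- (hi - lo) * sqrt(2)
  out <- vector("list", n)
  got <- 0L
  tried <- 0
  B <- max(2000L, min(200000L, as.integer(n * 25)))
  while (got < n) {
    if (tried >= geom$max_tries * n)
      stop(sprintf(
        "trajectory generation failed: %d/%d accepted after %g candidates; geometry constraints may be unsatisfiable",
        got, n, tried), call. = FALSE)
    x0 <- runif(B, lo, hi); y0 <- runif(B, lo, hi)
    x <- x0; y <- y0
    px <- numeric(B); py <- numeric(B)
    SEL <- matrix(0L, B, nstep)
    alive <- rep(TRUE, B)
    for (j in seq_len(nstep)) {
      m <- mags[j]
      inx_p <- x + m <= hi; inx_m <- x - m >= lo
      iny_p <- y + m <= hi; iny_m <- y - m >= lo
      a1 <- inx_p & iny_p; a2 <- inx_p & iny_m
      a3 <- inx_m & iny_p; a4 <- inx_m & iny_m
      if (j > 1L) {
        a1 <- a1 & !(px == -1 & py == -1)
        a2 <- a2 & !(px == -1 & py ==  1)
        a3 <- a3 & !(px ==  1 & py == -1)
        a4 <- a4 & !(px ==  1 & py ==  1)
      }
      C1 <- as.numeric(a1); C2 <- C1 + a2; C3 <- C2 + a3; C4 <- C3 + a4
      alive <- alive & C4 > 0
      u <- runif(B) * C4
      sel <- 1L + (C1 <= u) + (C2 <= u) + (C3 <= u)
      sel[sel > 4L] <- 4L
      SEL[, j] <- sel
      px <- sx[sel]; py <- sy[sel]
      x <- x + m * px; y <- y + m * py
    }
    frac <- sqrt((x - x0)^2 + (y - y0)^2) / diag_len
    ok <- which(alive & frac >= geom$dist_band[1] & frac <= geom$dist_band[2])
    tried <- tried + B
    for (i in ok) {
      if (got >= n) break
      traj <- matrix(NA_real_, geom$n_trials, 2L)
      traj[1L, ] <- c(x0[i], y0[i])
      for (j in seq_len(nstep))
        traj[j + 1L, ] <- traj[j, ] +
          mags[j] * c(sx[SEL[i, j]], sy[SEL[i, j]])
      got <- got + 1L
      out[[got]] <- traj
    }
  }
  out
}

#' Generate one block of the prediction task
#'
#' @param condition `"gradual"` or `"jump"`.
#' @param geom A [task_geometry()] configuration.
#' @param probe_t Probed trial for the end-of-block reconstruction; drawn
#'   uniformly from `{1, 2, 3}` when `NULL`.
#' @return An object of class `"dpkf_block"`: a list with `condition`,
#'   `stimuli` (`n_trials x 2` matrix, columns `angle` and `length`),
#'   `jump_after` (`NA` for gradual blocks) and `probe_t`.
#' @examples
#' set.seed(1)
#' b <- generate_block("jump")
#' diff(b$stimuli)[b$jump_after, ]  # the 4x step
#' @export
generate_block <- function(condition = c("gradual", "jump"),
                           geom = task_geometry(), probe_t = NULL) {
  condition <- match.arg(condition)
  traj <- generate_trajectories(condition, 1L, geom)[[1]]
  colnames(traj) <- c("angle", "length")
  if (is.null(probe_t)) probe_t <- sample.int(3L, 1L)
  structure(list(condition = condition, stimuli = traj,
                 jump_after = if (condition == "jump") geom$jump_after
                              else NA_integer_,
                 probe_t = as.integer(probe_t)),
            class = "dpkf_block")
}

#' @export
print.dpkf_block <- function(x, ...) {
  cat(sprintf("%s block: %d trials, probe trial %d%s\n", x$condition,
              nrow(x$stimuli), x$probe_t,
              if (!is.na(x$jump_after))
                sprintf(", jump after trial %d", x$jump_after) else ""))
  invisible(x)
}

#' Assemble a full experimental session
#'
#' Twelve blocks — six gradual and six jump trajectories, randomly
#' interleaved — each with a reconstruction probe drawn uniformly from the
#' first three trials. Deterministic given the RNG state ([set.seed()]).
#'
#' @param participant_id Participant identifier.
#' @param geom A [task_geometry()] configuration.
#' @param n_per_condition Blocks per condition (default 6).
#' @return An object of class `"dpkf_session"`: a list with
#'   `participant_id` and `blocks` (list of [generate_block()] results).
#' @export
build_session <- function(participant_id = 1L, geom = task_geometry(),
                          n_per_condition = 6L) {
  conds <- sample(rep(c("gradual", "jump"), each = n_per_condition))
  # draw the trajectories per condition in one vectorized batch
  trajs <- list(
    gradual = generate_trajectories("gradual", n_per_condition, geom),
    jump = generate_trajectories("jump", n_per_condition, geom))
  used <- c(gradual = 0L, jump = 0L)
  blocks <- vector("list", length(conds))
  for (b in seq_along(conds)) {
    cond <- conds[b]
    used[cond] <- used[cond] + 1L
    traj <- trajs[[cond]][[used[cond]]]
    colnames(traj) <- c("angle", "length")
    blocks[[b]] <- structure(
      list(condition = cond, stimuli = traj,
           jump_after = if (cond == "jump") geom$jump_after else NA_integer_,
           probe_t = sample.int(3L, 1L)),
      class = "dpkf_block")
  }
  structure(list(participant_id = participant_id, blocks = blocks,
                 geometry = geom),
            class = "dpkf_session")
}

#' @export
print.dpkf_session <- function(x, ...) {
  conds <- vapply(x$blocks, `[[`, character(1), "condition")
  cat(sprintf("Session for participant %s: %d blocks (%d gradual, %d jump)\n",
              as.character(x$participant_id), length(x$blocks),
              sum(conds == "gradual"), sum(conds == "jump")))
  invisible(x)
}

#' Simulate a synthetic participant's responses
#'
#' Runs the filter over each block's stimuli and emits noisy behavioural
#' responses: the prediction on each trial is the model's one-step
#' prediction plus anisotropic Gaussian response noise `N(0, v)` per
#' dimension, and the end-of-block reconstruction is the within-mode
#' smoothed estimate of the probed trial ([reconstruct()]) plus the same
#' response noise.
#'
#' @param session A [build_session()] object.
#' @param hyper_true Generating hyperparameters ([dpkf_hyper()],
#'   2-dimensional).
#' @param pred_rule Prediction rule passed to [run_filter()].
#' @param extra_r Retrieval-noise offset passed to [reconstruct()].
#' @return An object of class `"dpkf_responses"`: a list with
#'   `predictions` (per block, `n_trials x 2`), `reconstructions` (per
#'   block, length-2 vector), `generator = "synthetic"` and `hyper_true`.
#' @export
simulate_responses <- function(session, hyper_true,
                               pred_rule = c("prev", "mixture", "map_prior"),
                               extra_r = 5) {
  stopifnot(inherits(session, "dpkf_session"))
  stopifnot_hyper(hyper_true)
  pred_rule <- match.arg(pred_rule)
  D <- hyper_true$n_dims
  preds <- recons <- vector("list", length(session$blocks))
  for (b in seq_along(session$blocks)) {
    blk <- session$blocks[[b]]
    tr <- run_filter(blk$stimuli, hyper_true, pred_rule)
    noise <- matrix(rnorm(length(tr$predicted), 0,
                          rep(sqrt(hyper_true$v), each = nrow(tr$predicted))),
                    nrow(tr$predicted), D)
    preds[[b]] <- tr$predicted + noise
    rec <- reconstruct(tr, blk$stimuli, blk$probe_t, hyper_true, extra_r)
    recons[[b]] <- rec$estimate + rnorm(D, 0, sqrt(hyper_true$v))
  }
  structure(list(predictions = preds,
                 reconstructions = recons,
                 generator = "synthetic", hyper_true = hyper_true,
                 participant_id = session$participant_id),
            class = "dpkf_responses")
}

#' @export
print.dpkf_responses <- function(x, ...) {
  cat(sprintf("Response set (%s) for participant %s: %d blocks\n",
              x$generator, as.character(x$participant_id),
              length(x$predictions)))
  invisible(x)
}

#' Tidy long-format behavioural table
#'
#' Combines a session and (optionally) a response set into the tidy
#' delimited layout used for data exchange: one row per trial with columns
#' `participant`, `block`, `condition`, `trial`,
#' `trial_type` (`prediction`/`reconstruction`), `stim_angle`,
#' `stim_length`, `resp_angle`, `resp_length`, `probe_t`. Reconstruction
#' rows carry the probed trial's stimulus.
#'
#' @param session A `"dpkf_session"`.
#' @param responses Optional matching `"dpkf_responses"`.
#' @return A data frame.
#' @export
session_table <- function(session, responses = NULL) {
  stopifnot(inherits(session, "dpkf_session"))
  rows <- lapply(seq_along(session$blocks), function(b) {
    blk <- session$blocks[[b]]
    n <- nrow(blk$stimuli)
    pred <- data.frame(
      participant = session$participant_id, block = b,
      condition = blk$condition, trial = seq_len(n),
      trial_type = "prediction",
      stim_angle = blk$stimuli[, 1], stim_length = blk$stimuli[, 2],
      resp_angle = NA_real_, resp_length = NA_real_,
      probe_t = blk$probe_t)
    rec <- data.frame(
      participant = session$participant_id, block = b,
      condition = blk$condition, trial = blk$probe_t,
      trial_type = "reconstruction",
      stim_angle = blk$stimuli[blk$probe_t, 1],
      stim_length = blk$stimuli[blk$probe_t, 2],
      resp_angle = NA_real_, resp_length = NA_real_,
      probe_t = blk$probe_t)
    if (!is.null(responses)) {
      pred$resp_angle <- responses$predictions[[b]][, 1]
      pred$resp_length <- responses$predictions[[b]][, 2]
      rec$resp_angle <- responses$reconstructions[[b]][1]
      rec$resp_length <- responses$reconstructions[[b]][2]
    }
    rbind(pred, rec)
  })
  do.call(rbind, rows)
}

#' @describeIn session_table write the tidy table to a tab-separated file.
#' @param path File path.
#' @export
write_session <- function(session, responses = NULL, path) {
  write.table(session_table(session, responses), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rebuild session and response objects from a tidy behavioural table
#'
#' Inverse of [session_table()] / [write_session()] for a single
#' participant. Jump blocks are recognized by their condition label; the
#' jump position is taken from `geom`.
#'
#' @param x A data frame in the [session_table()] layout, or a file path.
#' @param geom A [task_geometry()] used for block metadata.
#' @return A list with `session` and `responses` (`responses` is `NULL`
#'   when the table has no response columns filled).
#' @export
read_session <- function(x, geom = task_geometry()) {
  df <- if (is.character(x)) read.delim(x) else x
  stopifnot(all(c("participant", "block", "condition", "trial", "trial_type",
                  "stim_angle", "stim_length", "probe_t") %in% names(df)))
  pid <- unique(df$participant)
  if (length(pid) != 1L)
    stop("expected a single participant per table", call. = FALSE)
  blocks <- lapply(split(df, df$block), function(bd) {
    pd <- bd[bd$trial_type == "prediction", ]
    pd <- pd[order(pd$trial), ]
    stim <- cbind(angle = pd$stim_angle, length = pd$stim_length)
    structure(list(condition = pd$condition[1], stimuli = stim,
                   jump_after = if (pd$condition[1] == "jump")
                     geom$jump_after else NA_integer_,
                   probe_t = as.integer(pd$probe_t[1])),
              class = "dpkf_block")
  })
  blocks <- blocks[order(as.integer(names(blocks)))]
  names(blocks) <- NULL
  session <- structure(list(participant_id = pid, blocks = blocks,
                            geometry = geom),
                       class = "dpkf_session")
  responses <- NULL
  if (any(!is.na(df$resp_angle))) {
    preds <- lapply(split(df, df$block), function(bd) {
      pd <- bd[bd$trial_type == "prediction", ]
      pd <- pd[order(pd$trial), ]
      cbind(pd$resp_angle, pd$resp_length)
    })
    recs <- lapply(split(df, df$block), function(bd) {
      rd <- bd[bd$trial_type == "reconstruction", ]
      c(rd$resp_angle[1], rd$resp_length[1])
    })
    ord <- order(as.integer(names(preds)))
    responses <- structure(list(predictions = unname(preds[ord]),
                                reconstructions = unname(recs[ord]),
                                generator = "human", hyper_true = NULL,
                                participant_id = pid),
                           class = "dpkf_responses")
  }
  list(session = session, responses = responses)
}
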