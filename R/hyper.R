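#' Model hyperparameters
#'
#' Construct and validate the hyperparameter set of the switching
#' linear-Gaussian model. All variance parameters are per stimulus
#' dimension (scalars are recycled to `n_dims`).
#'
#' @param alpha Concentration parameter of the sticky Chinese restaurant
#'   process (unitless, `>= 0`). Larger values make new modes more likely;
#'   `alpha = 0` forbids any mode beyond the first.
#' @param beta Stickiness parameter (unitless, `>= 0`): an additive bonus on
#'   the mode that was active on the previous trial. `beta = 0` recovers the
#'   plain Chinese restaurant process.
#' @param q Per-dimension diffusion variance (stimulus units squared,
#'   `>= 0`). `q = 0` gives a stationary hidden state.
#' @param r Per-dimension sensory noise variance (stimulus units squared,
#'   `> 0`).
#' @param v Per-dimension response noise variance (stimulus units squared,
#'   `> 0`), used when modelling behavioural responses.
#' @param decay State decay \eqn{\lambda \in (0, 1]}; the state of every
#'   created mode evolves as \eqn{x \leftarrow \lambda x + \epsilon} with
#'   \eqn{\epsilon \sim N(0, q)}. The default 1 is a pure random walk.
#' @param m0 Per-dimension prior mean of a new mode's state (stimulus units).
#' @param prior_var Per-dimension prior variance \eqn{c} of a new mode's
#'   state. The default 1000 makes the distribution over mode starting
#'   points approximately uniform on the task's `[0, 100]` stimulus scale.
#' @param n_dims Number of stimulus dimensions (positive integer). Defaults
#'   to the longest length among `q`, `r`, `v`, `m0`, `prior_var`.
#'
#' @return An object of class `"dpkf_hyper"`: a validated list with fields
#'   `alpha`, `beta`, `q`, `r`, `v`, `decay`, `m0`, `prior_var`, `n_dims`.
#' @examples
#' h <- dpkf_hyper(alpha = 1, beta = 4, q = c(5, 5), r = c(10, 10),
#'                 v = c(5, 5), m0 = c(50, 50))
#' h
#' @export
dpkf_hyper <- function(alpha = 1, beta = 0, q = 0, r = 1, v = 1, decay = 1,
                       m0 = 0, prior_var = 1000, n_dims = NULL) {
  if (is.null(n_dims)) {
    n_dims <- max(length(q), length(r), length(v), length(m0),
                  length(prior_var))
  }
  n_dims <- as.integer(n_dims)
  if (length(n_dims) != 1L || is.na(n_dims) || n_dims < 1L)
    stop("'n_dims' must be a positive integer", call. = FALSE)
  rec <- function(x, nm) {
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
      stop(sprintf("'%s' must be finite numeric", nm), call. = FALSE)
    if (length(x) == 1L) x <- rep(as.numeric(x), n_dims)
    if (length(x) != n_dims)
      stop(sprintf("'%s' must have length 1 or n_dims = %d", nm, n_dims),
           call. = FALSE)
    as.numeric(x)
  }
  scal <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("'%s' must be a finite scalar", nm), call. = FALSE)
    as.numeric(x)
  }
  alpha <- scal(alpha, "alpha"); beta <- scal(beta, "beta")
  decay <- scal(decay, "decay")
  q <- rec(q, "q"); r <- rec(r, "r"); v <- rec(v, "v")
  m0 <- rec(m0, "m0"); prior_var <- rec(prior_var, "prior_var")
  if (alpha < 0) stop("'alpha' must be >= 0", call. = FALSE)
  if (beta < 0) stop("'beta' must be >= 0", call. = FALSE)
  if (any(q < 0)) stop("'q' must be >= 0", call. = FALSE)
  if (any(r <= 0)) stop("'r' must be > 0", call. = FALSE)
  if (any(v <= 0)) stop("'v' must be > 0", call. = FALSE)
  if (any(prior_var <= 0)) stop("'prior_var' must be > 0", call. = FALSE)
  if (decay <= 0 || decay > 1)
    stop("'decay' must lie in (0, 1]", call. = FALSE)
  structure(
    list(alpha = alpha, beta = beta, q = q, r = r, v = v, decay = decay,
         m0 = m0, prior_var = prior_var, n_dims = n_dims),
    class = "dpkf_hyper")
}

#' @export
print.dpkf_hyper <- function(x, ...) {
  cat("Switching linear-Gaussian model hyperparameters (", x$n_dims,
      "-dimensional)\n", sep = "")
  cat(sprintf("  alpha (concentration): %g\n", x$alpha))
  cat(sprintf("  beta  (stickiness):    %g\n", x$beta))
  cat(sprintf("  q     (diffusion var): %s\n", paste(signif(x$q, 4), collapse = ", ")))
  cat(sprintf("  r     (sensory var):   %s\n", paste(signif(x$r, 4), collapse = ", ")))
  cat(sprintf("  v     (response var):  %s\n", paste(signif(x$v, 4), collapse = ", ")))
  cat(sprintf("  decay (lambda):        %g\n", x$decay))
  cat(sprintf("  m0    (prior mean):    %s\n", paste(signif(x$m0, 4), collapse = ", ")))
  cat(sprintf("  c     (prior var):     %s\n", paste(signif(x$prior_var, 4), collapse = ", ")))
  invisible(x)
}

stopifnot_hyper <- function(hyper) {
  if (!inherits(hyper, "dpkf_hyper"))
    stop("'hyper' must be a 'dpkf_hyper' object (see dpkf_hyper())",
         call. = FALSE)
  hyper
}

#' Write or read a flat key-value hyperparameter config file
#'
#' The format is one `key = value` pair per line; vector values are
#' comma-separated. Unknown keys are rejected on read.
#'
#' @param hyper A [dpkf_hyper()] object.
#' @param path File path.
#' @return `read_hyper_config()` returns a `dpkf_hyper` object;
#'   `write_hyper_config()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".cfg")
#' write_hyper_config(dpkf_hyper(alpha = 2, r = c(10, 20)), p)
#' read_hyper_config(p)
#' @export
write_hyper_config <- function(hyper, path) {
  stopifnot_hyper(hyper)
  keys <- c("alpha", "beta", "q", "r", "v", "decay", "m0", "prior_var",
            "n_dims")
  lines <- vapply(keys, function(k) {
    sprintf("%s = %s", k, paste(format(hyper[[k]], digits = 17),
                                collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hyper_config
#' @export
read_hyper_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- lapply(kv, function(p) {
    as.numeric(trimws(strsplit(p[2], ",", fixed = TRUE)[[1]]))
  })
  allowed <- c("alpha", "beta", "q", "r", "v", "decay", "m0", "prior_var",
               "n_dims")
  unknown <- setdiff(keys, allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(dpkf_hyper, setNames(vals, keys))
}

# ---- model variants ---------------------------------------------------------

#' Model variants
#'
#' The four nested model variants fitted to behavioural data. "Stationary"
#' variants fix the diffusion variance `q` at 0 (the hidden state of a mode
#' does not drift); "KF" variants fix the concentration `alpha` at 0 (a
#' single mode, i.e. an ordinary Kalman filter). Free parameters are
#' per-dimension response noise `v`, per-dimension sensory noise `r` and the
#' state decay `decay` in every variant, plus per-dimension `q` for the
#' diffusing variants and `alpha`, `beta` for the Dirichlet-process
#' variants, giving 5, 7, 7 and 9 free parameters for `stationary_kf`,
#' `kf`, `stationary_dpkf` and `dpkf` respectively (for 2-dimensional
#' stimuli).
#'
#' @param variant One of `"stationary_kf"`, `"kf"`, `"stationary_dpkf"`,
#'   `"dpkf"`.
#' @param n_dims Number of stimulus dimensions.
#' @return A list with elements `name`, `free` (character vector of free
#'   parameter names, per-dimension parameters suffixed `1..n_dims`),
#'   `lower`, `upper` (named bound vectors) and `fixed` (named list of
#'   restrictions).
#' @examples
#' variant_spec("dpkf")$free
#' @export
variant_spec <- function(variant = c("dpkf", "kf", "stationary_dpkf",
                                     "stationary_kf"),
                         n_dims = 2L) {
  variant <- match.arg(variant)
  dimnm <- function(p) paste0(p, seq_len(n_dims))
  free <- c(dimnm("v"), dimnm("r"), "decay")
  lower <- c(rep(1e-3, n_dims), rep(1e-3, n_dims), 1e-3)
  upper <- c(rep(10, n_dims), rep(20, n_dims), 1)
  fixed <- list()
  if (variant %in% c("kf", "dpkf")) {
    free <- c(free, dimnm("q"))
    lower <- c(lower, rep(1e-3, n_dims))
    upper <- c(upper, rep(30, n_dims))
  } else {
    fixed$q <- 0
  }
  if (variant %in% c("stationary_dpkf", "dpkf")) {
    free <- c(free, "alpha", "beta")
    lower <- c(lower, 0, 0)
    upper <- c(upper, 10, 20)
  } else {
    fixed$alpha <- 0
    fixed$beta <- 0
  }
  names(lower) <- names(upper) <- free
  list(name = variant, free = free, lower = lower, upper = upper,
       fixed = fixed, n_dims = n_dims)
}

#' @export
#' @rdname variant_spec
dpkf_variants <- function() c("stationary_kf", "kf", "stationary_dpkf", "dpkf")

# Assemble a dpkf_hyper from a named free-parameter vector plus a variant's
# restrictions. Fixed scaffolding (m0, prior_var) comes from `base`.
variant_hyper <- function(par, variant, base) {
  vs <- if (is.list(variant)) variant else variant_spec(variant, base$n_dims)
  stopifnot(all(vs$free %in% names(par)))
  nd <- base$n_dims
  pick <- function(p) {
    nm <- paste0(p, seq_len(nd))
    if (all(nm %in% names(par))) unname(par[nm]) else NULL
  }
  q <- if (!is.null(vs$fixed$q)) rep(vs$fixed$q, nd) else pick("q")
  alpha <- if (!is.null(vs$fixed$alpha)) vs$fixed$alpha else unname(par["alpha"])
  beta <- if (!is.null(vs$fixed$beta)) vs$fixed$beta else unname(par["beta"])
  dpkf_hyper(alpha = alpha, beta = beta, q = q, r = pick("r"), v = pick("v"),
             decay = unname(par["decay"]), m0 = base$m0,
             prior_var = base$prior_var, n_dims = nd)
}
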