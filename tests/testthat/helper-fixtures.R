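# Shared fixtures and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noiseless generator settings: every stochastic knob off.
noiseless_params <- function(...) {
  scene_params(
    pixel_noise_sd = 0, scatter_slope_sd = 0, scatter_offset_sd = 0,
    shot_noise_scale = 0, dark_sd = 0, white_sd = 0, ...
  )
}

# Tiny reflectance cube with a known wavelength axis.
tiny_cube <- function(rows = 2, cols = 2, wl = c(400, 500, 600), fill = NULL) {
  nb <- length(wl)
  data <- if (is.null(fill)) {
    array(seq_len(rows * cols * nb) / (rows * cols * nb), c(rows, cols, nb))
  } else {
    array(fill, c(rows, cols, nb))
  }
  hyper_cube(data, wl)
}

# Three well-separated point clouds in 2-D for multiclass fixtures.
separated_classes <- function(n_per = 8, spread = 0.05, seed = 11) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4))
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(2 * n_per, 0, spread), n_per, 2), 2, centers[k, ], "+")
  }))
  list(X = X, labels = rep(1:3, each = n_per))
}

# Independent dense-QP oracle for the binary SVC dual: kernlab::ipop for the
# solution, then an exact KKT linear solve on the identified free set (kept
# only when it is feasible and does not worsen the objective). The bias is
# the midpoint of the KKT interval implied by the oracle multipliers;
# `b_gap` reports the width of that interval.
qp_oracle <- function(K, y, C) {
  n <- length(y)
  Q <- (y %o% y) * K
  obj_of <- function(a) 0.5 * sum(a * (Q %*% a)) - sum(a)
  sol <- kernlab::ipop(
    c = matrix(-1, n), H = Q, A = matrix(y, 1), b = 0,
    l = matrix(0, n), u = matrix(C, n), r = 0, sigf = 9, maxiter = 300
  )
  a_raw <- pmin(pmax(kernlab::primal(sol), 0), C)
  a <- a_raw
  free <- a > 1e-6 * C & a < C * (1 - 1e-6)
  if (any(free)) {
    Ff <- which(free)
    a_try <- a
    a_try[a <= 1e-6 * C] <- 0
    a_try[a >= C * (1 - 1e-6)] <- C
    rhs <- c(
      1 - as.numeric(Q[Ff, -Ff, drop = FALSE] %*% a_try[-Ff]),
      -sum(y[-Ff] * a_try[-Ff])
    )
    Mkkt <- rbind(cbind(Q[Ff, Ff, drop = FALSE], y[Ff]), c(y[Ff], 0))
    z <- tryCatch(solve(Mkkt, rhs), error = function(e) NULL)
    if (!is.null(z)) {
      a_try[Ff] <- z[seq_along(Ff)]
      a_cl <- pmin(pmax(a_try, 0), C)
      if (all(a_try >= -1e-9) && all(a_try <= C + 1e-9) &&
        obj_of(a_cl) <= obj_of(a_raw) + 1e-9) {
        a <- a_cl
      }
    }
  }
  g <- as.numeric(Q %*% a) - 1
  v <- -y * g
  I_up <- (y > 0 & a < C * (1 - 1e-8)) | (y < 0 & a > C * 1e-8)
  I_low <- (y > 0 & a > C * 1e-8) | (y < 0 & a < C * (1 - 1e-8))
  list(
    alpha = a,
    b = (max(v[I_up]) + min(v[I_low])) / 2,
    b_gap = max(v[I_up]) - min(v[I_low]),
    objective = obj_of(a)
  )
}

# One shared full-scale pipeline run (40 scenes per group, full 17 x 17
# decade grid, seed 1) for the end-to-end checks, computed lazily and
# reused across test files.
.e2e_env <- new.env(parent = emptyenv())
e2e_run <- function() {
  if (is.null(.e2e_env$run)) {
    .e2e_env$run <- run_pipeline(pipeline_config(n_per_group = 40L, seed = 1L))
  }
  .e2e_env$run
}
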