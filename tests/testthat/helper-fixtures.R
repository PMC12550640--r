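# Shared fixtures, all built in code.

# one-factor model with three indicators (marker loading fixed to 1)
toy_factor_model <- function() {
  sem_model(
    paste0("y", 1:3), "f",
    lambda = par_matrix(matrix(1, 3, 1), matrix(c(FALSE, TRUE, TRUE), 3, 1)),
    psi = par_matrix(matrix(1, 1, 1), matrix(TRUE, 1, 1)),
    theta = par_matrix(diag(0.5, 3), diag(3) == 1),
    nu = par_matrix(matrix(0, 3, 1), matrix(c(FALSE, TRUE, TRUE), 3, 1)),
    alpha = par_matrix(matrix(0, 1, 1), matrix(TRUE, 1, 1)))
}

toy_factor_data <- function(n = 300, seed = 1) {
  set.seed(seed)
  eta <- rnorm(n, 2, 1.5)
  y <- cbind(eta, 0.8 * eta + 0.3, 1.2 * eta - 0.5) +
    matrix(rnorm(3 * n, 0, 0.7), n, 3)
  colnames(y) <- paste0("y", 1:3)
  y
}

# saturated bivariate model (all moments free)
toy_saturated_model <- function() {
  sem_model(
    c("a", "b"),
    theta = par_matrix(diag(1, 2), matrix(TRUE, 2, 2)),
    nu = par_matrix(matrix(0, 2, 1), matrix(TRUE, 2, 1)))
}

# two tetrahedra sharing the face z = 0 plane x+y<=1: element 1 below
# (apex at z=-1), element 2 above (apex at z=+1)
toy_two_tet_mesh <- function(cdr_error = c(2, 0.5), cdr_correct = c(0.5, 0.5)) {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                 c(0, 0, -1), c(0, 0, 1))
  elements <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 5))
  tet_mesh(nodes, elements, cdr_error = cdr_error, cdr_correct = cdr_correct)
}

# small volume covering the toy mesh with voxel centers on a grid
toy_volume <- function(values, dims = c(4, 4, 4), spacing = 0.25,
                       origin = spacing / 2 - 0.5) {
  aff <- diag(c(spacing, spacing, spacing, 1))
  aff[1:3, 4] <- origin
  volume(array(values, dims), aff)
}

# minimal epoch set: deterministic signal injection
toy_epochs <- function(n_error = 4, n_correct = 4, noise_sd = 0,
                       amp = -5, latency = 50, seed = 1,
                       channels = c("FCz", "Cz", "Pz"),
                       cluster_weight = c(1, 1, 0.3)) {
  set.seed(seed)
  time_ms <- seq(-100, 200, by = 2)   # grid hits the default 50 ms latency
  cond <- rep(c("inc_error", "inc_correct"), c(n_error, n_correct))
  bump <- exp(-0.5 * ((time_ms - latency) / 10)^2)
  dat <- array(rnorm(length(channels) * length(time_ms) * length(cond),
                     0, noise_sd),
               c(length(channels), length(time_ms), length(cond)))
  for (tr in which(cond == "inc_error")) {
    dat[, , tr] <- dat[, , tr] + outer(cluster_weight, bump) * amp
  }
  epoch_set(dat, time_ms, channels, cond, 250)
}

# small, fast generator configuration
small_config <- function(n = 60L, ...) {
  generator_config(n_subjects = n, ...)
}
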