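# Mean-and-covariance structure SEM in the "all-y" LISREL parameterization:
#
#   y   = nu + Lambda eta + epsilon,     epsilon ~ N(0, Theta)
#   eta = alpha + B eta + zeta,          zeta    ~ N(0, Psi)
#
# implied moments:
#   mu    = nu + Lambda (I - B)^-1 alpha
#   Sigma = Lambda (I - B)^-1 Psi (I - B)^-T Lambda' + Theta
#
# Every matrix cell is tagged free / fixed(value) / constrained-equal(label);
# cells sharing a label map to a single free parameter.

#' Build a parameter matrix for [sem_model()]
#'
#' @param value numeric matrix of starting/fixed values
#' @param free logical matrix (same shape); `TRUE` marks a free parameter.
#'   Defaults to all-fixed.
#' @param label character matrix of equality-constraint labels (`NA` for
#'   unlabeled cells).  Free cells sharing a label are estimated as one
#'   parameter.
#' @return a `par_matrix` list
#' @export
par_matrix <- function(value, free = NULL, label = NULL) {
  value <- as.matrix(value)
  if (is.null(free)) free <- array(FALSE, dim(value))
  if (is.null(label)) label <- array(NA_character_, dim(value))
  free <- as.matrix(free); label <- as.matrix(label)
  stopifnot(identical(dim(free), dim(value)),
            identical(dim(label), dim(value)))
  structure(list(value = value, free = free, label = label),
            class = "par_matrix")
}

#' Specify a structural equation model
#'
#' @param observed character vector of observed-variable names
#' @param latent character vector of latent-variable names (may be empty)
#' @param lambda loadings (observed x latent), a [par_matrix()]
#' @param beta structural paths among latents (latent x latent); entry
#'   `[i, j]` is the path from latent j to latent i
#' @param psi latent (co)variances, symmetric
#' @param theta observed residual (co)variances, symmetric
#' @param nu observed intercepts (column matrix)
#' @param alpha latent intercepts/means (column matrix)
#' @return an object of class `sem_model`
#' @export
sem_model <- function(observed, latent = character(), lambda = NULL,
                      beta = NULL, psi = NULL, theta = NULL,
                      nu = NULL, alpha = NULL) {
  p <- length(observed); m <- length(latent)
  zero <- function(r, c) par_matrix(matrix(0, r, c))
  lambda <- lambda %||% zero(p, m)
  beta   <- beta   %||% zero(m, m)
  psi    <- psi    %||% zero(m, m)
  theta  <- theta  %||% zero(p, p)
  nu     <- nu     %||% zero(p, 1)
  alpha  <- alpha  %||% zero(m, 1)
  stopifnot(nrow(lambda$value) == p, ncol(lambda$value) == m,
            all(dim(beta$value) == c(m, m)),
            all(dim(psi$value) == c(m, m)),
            all(dim(theta$value) == c(p, p)),
            nrow(nu$value) == p, nrow(alpha$value) == m)
  model <- structure(
    list(observed = observed, latent = latent,
         lambda = lambda, beta = beta, psi = psi, theta = theta,
         nu = nu, alpha = alpha),
    class = "sem_model")
  model$pars <- sem_par_index(model)
  model
}

# Enumerate free parameters.  Symmetric matrices contribute their lower
# triangle only; equality labels collapse cells onto one parameter.
sem_par_index <- function(model) {
  entries <- list()
  add <- function(mat, name, symmetric) {
    v <- model[[mat]]
    idx <- which(v$free, arr.ind = TRUE)
    if (symmetric && nrow(idx)) idx <- idx[idx[, 1] >= idx[, 2], , drop = FALSE]
    if (!nrow(idx)) return()
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      lab <- v$label[i, j]
      if (is.na(lab)) lab <- sprintf("%s[%d,%d]", name, i, j)
      entries[[length(entries) + 1]] <<- list(
        matrix = mat, i = i, j = j, label = lab,
        symmetric = symmetric, start = v$value[i, j])
    }
  }
  add("lambda", "lambda", FALSE)
  add("beta",   "beta",   FALSE)
  add("psi",    "psi",    TRUE)
  add("theta",  "theta",  TRUE)
  add("nu",     "nu",     FALSE)
  add("alpha",  "alpha",  FALSE)
  labels <- vapply(entries, `[[`, "", "label")
  ulab <- unique(labels)
  start <- vapply(ulab, function(l) entries[[match(l, labels)]]$start, 0)
  list(entries = entries, labels = labels, free_labels = ulab, start = start)
}

#' Number of free parameters of a model
#' @param model an `sem_model`
#' @export
n_free_params <- function(model) length(model$pars$free_labels)

#' Insert a free-parameter vector into the model matrices
#'
#' @param model an `sem_model`
#' @param theta numeric vector, one value per unique free-parameter label
#'   (order of `model$pars$free_labels`)
#' @return the model with matrix values updated
#' @export
sem_set_params <- function(model, theta) {
  stopifnot(length(theta) == n_free_params(model))
  names(theta) <- NULL
  pos <- match(model$pars$labels, model$pars$free_labels)
  for (k in seq_along(model$pars$entries)) {
    e <- model$pars$entries[[k]]
    val <- theta[pos[k]]
    model[[e$matrix]]$value[e$i, e$j] <- val
    if (e$symmetric) model[[e$matrix]]$value[e$j, e$i] <- val
  }
  model
}

#' Model-implied mean vector and covariance matrix
#'
#' @param model an `sem_model`
#' @param theta optional free-parameter vector; when omitted the values
#'   stored in the model matrices are used
#' @return list with elements `mu` (named vector) and `sigma` (symmetric
#'   matrix)
#' @export
model_implied_moments <- function(model, theta = NULL) {
  if (!is.null(theta)) model <- sem_set_params(model, theta)
  p <- length(model$observed); m <- length(model$latent)
  if (m > 0) {
    imb <- diag(m) - model$beta$value
    inv <- tryCatch(solve(imb), error = function(e) NULL)
    if (is.null(inv)) {
      stop("(I - B) is singular: the structural paths contain a cycle among ",
           paste(model$latent, collapse = ", "))
    }
    lam_t <- model$lambda$value %*% inv
    mu <- model$nu$value + lam_t %*% model$alpha$value
    sigma <- lam_t %*% model$psi$value %*% t(lam_t) + model$theta$value
  } else {
    mu <- model$nu$value
    sigma <- model$theta$value
  }
  mu <- drop(mu); names(mu) <- model$observed
  sigma <- symm(sigma)
  dimnames(sigma) <- list(model$observed, model$observed)
  list(mu = mu, sigma = sigma)
}
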