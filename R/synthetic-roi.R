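#' Generate ROI RDMs with controlled shared and unique variance
#'
#' Builds one RDM per region of interest as a nonnegatively weighted sum of
#' a latent component shared across all ROIs and a latent component unique
#' to each ROI, plus symmetric zero-diagonal Gaussian noise; each resulting
#' RDM is rescaled to the unit interval over its off-diagonal entries. The
#' latent components and mixing weights are stored so that variance
#' partitioning of a target built from the same latents has a known answer.
#'
#' @param shared latent [rdm] common to every ROI.
#' @param uniques list of latent [rdm]s, one per ROI, same size as `shared`.
#' @param weights numeric matrix `[n_roi, 2]` of nonnegative mixing weights:
#'   column 1 for the shared component, column 2 for the ROI's unique
#'   component.
#' @param noise_sd standard deviation of the symmetric off-diagonal noise.
#' @param seed integer seed.
#' @param names optional ROI names.
#'
#' @return A `synthetic_roi_set`: list with `rdms` (named list of [rdm]s)
#'   and the ground truth (`shared`, `uniques`, `weights`, `noise_sd`).
#' @export
#'
#' @examples
#' n <- 10
#' rand_rdm <- function(s) {
#'   m <- as.matrix(dist(matrix(rnorm(n * 3), n)))
#'   rdm(m)
#' }
#' s <- rand_rdm(); u <- list(rand_rdm(), rand_rdm())
#' set <- generate_roi_rdm_set(s, u, weights = cbind(c(1, 1), c(1, 0)),
#'                             noise_sd = 0, seed = 1)
generate_roi_rdm_set <- function(shared, uniques, weights, noise_sd = 0,
                                 seed = 1L, names = NULL) {
  stopifnot(is_rdm(shared), is.list(uniques))
  n <- n_conditions(shared)
  for (u in uniques) {
    if (!is_rdm(u) || n_conditions(u) != n) {
      stop("all unique RDMs must match the shared RDM's size", call. = FALSE)
    }
  }
  weights <- as.matrix(weights)
  if (nrow(weights) != length(uniques) || ncol(weights) != 2L) {
    stop("`weights` must be an n_roi x 2 matrix (shared, unique)", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n_roi <- length(uniques)
  names <- names %||% paste0("roi_", seq_len(n_roi))

  rdms <- with_seed(child_seed(seed, 3L), {
    lapply(seq_len(n_roi), function(k) {
      m <- weights[k, 1] * unclass(shared) + weights[k, 2] * unclass(uniques[[k]])
      if (noise_sd > 0) {
        e <- matrix(rnorm(n * n, sd = noise_sd), n, n)
        e <- (e + t(e)) / 2
        diag(e) <- 0
        m <- m + e
      }
      off <- m[upper.tri(m)]
      rng <- range(off)
      if (diff(rng) > 0) {
        m <- (m - rng[1]) / diff(rng)
      } else {
        m[] <- 0
      }
      diag(m) <- 0
      m <- pmax(m, 0)
      rdm((m + t(m)) / 2, conditions = attr(shared, "conditions"),
          method = "synthetic_roi", validate = FALSE)
    })
  })
  names(rdms) <- names
  structure(list(rdms = rdms, shared = shared, uniques = uniques,
                 weights = weights, noise_sd = noise_sd, seed = seed),
            class = "synthetic_roi_set")
}
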